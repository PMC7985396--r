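#' Construct a single reaction
#'
#' A reaction is one biochemical transformation: an identifier plus the sets
#' of substrate and product compound identifiers. Stoichiometric coefficients
#' are not tracked; the network projections depend only on which compounds
#' participate on which side.
#'
#' @param reaction_id nonempty identifier string.
#' @param substrates character vector of substrate compound ids (may be empty).
#' @param products character vector of product compound ids (may be empty).
#'   At least one of `substrates`/`products` must be nonempty. A compound may
#'   appear on both sides; no self-edges arise from it in any projection.
#' @return an object of class `reaction`.
#' @export
#' @examples
#' reaction("R1", c("A", "B"), "C")
reaction <- function(reaction_id, substrates = character(), products = character()) {
  substrates <- sort(unique(as.character(substrates)))
  products <- sort(unique(as.character(products)))
  if (!is.character(reaction_id) || length(reaction_id) != 1L ||
      is.na(reaction_id) || !nzchar(reaction_id)) {
    stop("`reaction_id` must be a single nonempty string")
  }
  if (length(substrates) + length(products) == 0L) {
    stop("reaction '", reaction_id, "': substrates and products are both empty")
  }
  ids <- c(substrates, products)
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop("reaction '", reaction_id, "': compound ids must be nonempty strings")
  }
  structure(
    list(reaction_id = reaction_id, substrates = substrates, products = products),
    class = "reaction"
  )
}

#' Construct a reaction dataset
#'
#' A reaction dataset stands in for one genome (level `"individual"`) or one
#' metagenome (level `"ecosystem"`): the list of all reactions its enzymes
#' can catalyze. Reactions that are exact duplicates (same id and same sides)
#' are collapsed; a repeated id with conflicting sides is an error.
#'
#' @param dataset_id nonempty identifier string.
#' @param level `"individual"` or `"ecosystem"`.
#' @param reactions list of [reaction()] objects, at least one.
#' @return an object of class `reaction_dataset`.
#' @export
reaction_dataset <- function(dataset_id, level, reactions) {
  level <- match.arg(level, c("individual", "ecosystem"))
  if (!is.character(dataset_id) || length(dataset_id) != 1L || !nzchar(dataset_id)) {
    stop("`dataset_id` must be a single nonempty string")
  }
  if (length(reactions) == 0L) stop("dataset '", dataset_id, "' has no reactions")
  stopifnot(all(vapply(reactions, inherits, logical(1L), "reaction")))
  ids <- vapply(reactions, `[[`, character(1L), "reaction_id")
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    for (id in unique(ids[duplicated(ids)])) {
      grp <- reactions[ids == id]
      sides <- vapply(grp, function(r) {
        paste(paste(r$substrates, collapse = ","), paste(r$products, collapse = ","),
              sep = ">")
      }, character(1L))
      if (length(unique(sides)) > 1L) {
        stop("dataset '", dataset_id, "': reaction id '", id,
             "' repeated with conflicting substrate/product sets")
      }
    }
    reactions <- reactions[keep]
  }
  structure(
    list(dataset_id = dataset_id, level = level, reactions = reactions),
    class = "reaction_dataset"
  )
}

#' @export
print.reaction_dataset <- function(x, ...) {
  cat("<reaction_dataset>", x$dataset_id, "\n")
  cat("  level:    ", x$level, "\n")
  cat("  reactions:", length(x$reactions), "\n")
  cat("  compounds:", length(dataset_compounds(x)), "\n")
  invisible(x)
}

#' All compound ids occurring in a dataset
#'
#' @param dataset a [reaction_dataset()].
#' @return sorted character vector of distinct compound ids.
#' @export
dataset_compounds <- function(dataset) {
  sort(unique(unlist(lapply(dataset$reactions, function(r) {
    c(r$substrates, r$products)
  }), use.names = FALSE)))
}

.split_compounds <- function(field) {
  if (is.na(field) || !nzchar(trimws(field))) return(character())
  out <- trimws(strsplit(field, ",", fixed = TRUE)[[1L]])
  out[nzchar(out)]
}

#' Read a reaction dataset from a flat file
#'
#' Two interchange formats are supported. The TSV format has three
#' tab-separated columns `reaction_id`, `substrates`, `products`, with
#' compound ids comma-separated inside the last two fields and an optional
#' header line; empty lines and lines starting with `#` are skipped. The JSON
#' format is a list of `{reaction_id, substrates, products}` records,
#' optionally wrapped in `{dataset_id, level, reactions}` as written by
#' [write_reaction_table()].
#'
#' @param path path to the file.
#' @param level `"individual"` or `"ecosystem"`. Required for TSV; for JSON
#'   it overrides a stored level when supplied.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by file extension).
#' @param dataset_id identifier for the dataset; defaults to the file name
#'   without extension (TSV) or the stored id (JSON).
#' @return a [reaction_dataset()].
#' @export
read_reaction_table <- function(path, level = NULL,
                                format = c("auto", "tsv", "json"),
                                dataset_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(obj$reactions)) {
      recs <- obj$reactions
      if (is.null(dataset_id)) dataset_id <- obj$dataset_id
      if (is.null(level)) level <- obj$level
    } else {
      recs <- obj
    }
    if (is.null(level)) stop("`level` not stored in ", path, " and not supplied")
    if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
    reactions <- lapply(recs, function(r) {
      reaction(r$reaction_id,
               unlist(r$substrates, use.names = FALSE),
               unlist(r$products, use.names = FALSE))
    })
    return(reaction_dataset(dataset_id, level, reactions))
  }
  if (is.null(level)) stop("`level` must be supplied for TSV input")
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) && identical(tolower(strsplit(lines[keep[1L]], "\t")[[1L]][1L]),
                                "reaction_id")) {
    keep <- keep[-1L]
  }
  if (!length(keep)) stop("no reaction rows in ", path)
  reactions <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L || length(fields) > 3L) {
      stop("malformed row at line ", ln, " of ", path,
           ": expected 3 tab-separated fields, got ", length(fields))
    }
    if (length(fields) == 2L) fields <- c(fields, "")
    reactions[[i]] <- tryCatch(
      reaction(trimws(fields[1L]), .split_compounds(fields[2L]),
               .split_compounds(fields[3L])),
      error = function(e) {
        stop("malformed row at line ", ln, " of ", path, ": ",
             conditionMessage(e))
      }
    )
  }
  reaction_dataset(dataset_id, level, reactions)
}

#' Write a reaction dataset to a flat file
#'
#' Inverse of [read_reaction_table()]: TSV with a header row, or a JSON
#' bundle that also stores `dataset_id` and `level`.
#'
#' @param dataset a [reaction_dataset()].
#' @param path output path.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_reaction_table <- function(dataset, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "reaction_dataset"))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- list(
      dataset_id = dataset$dataset_id,
      level = dataset$level,
      reactions = lapply(dataset$reactions, function(r) {
        list(reaction_id = r$reaction_id,
             substrates = as.list(r$substrates),
             products = as.list(r$products))
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  rows <- vapply(dataset$reactions, function(r) {
    paste(r$reaction_id, paste(r$substrates, collapse = ","),
          paste(r$products, collapse = ","), sep = "\t")
  }, character(1L))
  writeLines(c("reaction_id\tsubstrates\tproducts", rows), path)
  invisible(path)
}

.ec_pattern <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.(n?[0-9]+|-)$"

#' Read an EC-number to reaction lookup table
#'
#' The table is TSV with two columns, `ec_number` and a comma-separated list
#' of `reaction_ids`, mirroring a flat export of an enzyme database. EC
#' numbers must match the dotted four-field pattern, with `-` wildcards
#' allowed in the trailing fields and preliminary `n`-prefixed serial
#' numbers accepted.
#'
#' @param path path to the TSV file.
#' @param reactions optional list of [reaction()] objects; when given, every
#'   mapped reaction id must be resolvable against it.
#' @return named list mapping EC number to character vector of reaction ids,
#'   of class `ec_map`.
#' @export
read_ec_map <- function(path, reactions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) && identical(tolower(strsplit(lines[keep[1L]], "\t")[[1L]][1L]),
                                "ec_number")) {
    keep <- keep[-1L]
  }
  entries <- list()
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L) {
      stop("malformed row at line ", ln, " of ", path,
           ": expected 2 tab-separated fields")
    }
    ec <- trimws(fields[1L])
    if (!grepl(.ec_pattern, ec)) {
      stop("malformed EC number '", ec, "' at line ", ln, " of ", path)
    }
    rids <- .split_compounds(fields[2L])
    entries[[ec]] <- sort(unique(c(entries[[ec]], rids)))
  }
  if (!is.null(reactions)) {
    known <- vapply(reactions, `[[`, character(1L), "reaction_id")
    bad <- setdiff(unique(unlist(entries, use.names = FALSE)), known)
    if (length(bad)) {
      stop("EC map references unknown reaction ids: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  structure(entries, class = "ec_map")
}

#' Resolve a list of EC numbers to a reaction dataset
#'
#' Looks every EC number up in the map and returns the union of the mapped
#' reactions; a reaction appears once however many EC numbers map to it, and
#' the result does not depend on the order or multiplicity of the EC list.
#' EC numbers absent from the map are skipped with a warning.
#'
#' @param ec_numbers character vector of EC numbers annotated on a genome or
#'   metagenome.
#' @param ec_map an [read_ec_map()] lookup.
#' @param reaction_table list of [reaction()] objects defining the substrate
#'   and product sets of every mappable reaction.
#' @param level `"individual"` or `"ecosystem"`.
#' @param dataset_id identifier for the resolved dataset.
#' @return a [reaction_dataset()]; an error if no EC number resolves to any
#'   reaction.
#' @export
resolve_ec_list <- function(ec_numbers, ec_map, reaction_table, level,
                            dataset_id = "resolved") {
  stopifnot(inherits(ec_map, "ec_map"))
  ec_numbers <- unique(as.character(ec_numbers))
  unknown <- setdiff(ec_numbers, names(ec_map))
  if (length(unknown)) {
    warning("skipping ", length(unknown), " EC number(s) absent from the map: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  rids <- sort(unique(unlist(unclass(ec_map)[setdiff(ec_numbers, unknown)],
                             use.names = FALSE)))
  if (!length(rids)) {
    stop("no EC number resolved to any reaction; resolved dataset is empty")
  }
  known <- vapply(reaction_table, `[[`, character(1L), "reaction_id")
  missing <- setdiff(rids, known)
  if (length(missing)) {
    stop("mapped reaction ids absent from the reaction table: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  reaction_dataset(dataset_id, level, reaction_table[match(rids, known)])
}
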