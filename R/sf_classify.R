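#' Assess one projection: power-law fit, goodness of fit, and alternatives
#'
#' Runs the full per-graph assessment — KS-selected power-law fit, bootstrap
#' goodness-of-fit p-value, and likelihood-ratio comparisons against the
#' four alternative families — and derives the four pass flags used by the
#' classification ladder:
#' \itemize{
#'   \item `pass_p`: goodness-of-fit `p >= 0.1` (power law not ruled out);
#'   \item `pass_tail`: `n_tail >= 50` (tail large enough to fit reliably);
#'   \item `pass_alpha`: `2 < alpha_hat < 3` (canonical scale-free range);
#'   \item `no_alt_favored`: no alternative distribution significantly
#'     favored over the power law.
#' }
#' Degenerate degree sequences (fewer than two distinct positive values)
#' yield an assessment with every flag `FALSE` and `degenerate = TRUE`.
#'
#' @param projection a `projection_graph` (see [build_projection()]).
#' @param n_boot bootstrap size for [gof_pvalue()].
#' @param seed integer seed for the bootstrap.
#' @return object of class `projection_assessment`: list with
#'   `construction`, `scope`, `n`, `n_edges`, `mean_degree`, `degenerate`,
#'   `fit` (a `powerlaw_fit` or `NULL`), `lr` (an `lr_comparison` or
#'   `NULL`), and `flags` (named logical vector of the four criteria).
#' @export
assess_projection <- function(projection, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(projection, "projection_graph"))
  degrees <- degree_sequence(projection)
  n <- length(degrees)
  if (n == 0L) stop("empty graph")
  n_edges <- igraph::ecount(projection$graph)
  mean_degree <- 2 * n_edges / n
  fit <- tryCatch(select_xmin(degrees), sfnet_degenerate = function(e) NULL)
  if (is.null(fit)) {
    return(structure(
      list(construction = projection$construction, scope = projection$scope,
           n = n, n_edges = n_edges, mean_degree = mean_degree,
           degenerate = TRUE, fit = NULL, lr = NULL,
           flags = c(pass_p = FALSE, pass_tail = FALSE, pass_alpha = FALSE,
                     no_alt_favored = FALSE)),
      class = "projection_assessment"
    ))
  }
  p <- gof_pvalue(degrees, fit, n_boot = n_boot, seed = seed)
  fit$gof_p <- as.numeric(p)
  fit$n_boot <- as.integer(n_boot)
  lr <- compare_alternatives(degrees, fit)
  flags <- c(
    pass_p = isTRUE(fit$gof_p >= 0.1),
    pass_tail = fit$n_tail >= 50L,
    pass_alpha = fit$alpha_hat > 2 && fit$alpha_hat < 3,
    no_alt_favored = !lr$any_alt_favored
  )
  structure(
    list(construction = projection$construction, scope = projection$scope,
         n = n, n_edges = n_edges, mean_degree = mean_degree,
         degenerate = FALSE, fit = fit, lr = lr, flags = flags),
    class = "projection_assessment"
  )
}

#' Classify a dataset on the Super-Weak to Strongest ladder
#'
#' Applies the scale-free classification scheme to the eight per-projection
#' assessments of one dataset. With exactly 8 graphs the percentage
#' thresholds become integer counts (applied as `>=`): 50% requires 4
#' graphs, 90% requires 8, 95% requires 8.
#' \describe{
#'   \item{Super-Weak}{at least 50% of graphs favor no alternative over the
#'     power law. Independent of the nested ladder below.}
#'   \item{Weakest}{at least 50% of graphs have goodness-of-fit `p >= 0.1`.}
#'   \item{Weak}{at least 50% of graphs have `p >= 0.1` and `n_tail >= 50`.}
#'   \item{Strong}{at least 50% of graphs have `p >= 0.1`, `n_tail >= 50`
#'     and `2 < alpha_hat < 3`, and the Super-Weak requirement holds.}
#'   \item{Strongest}{the Strong per-graph requirement for at least 90% of
#'     graphs and no alternative favored for at least 95% of graphs.}
#' }
#'
#' @param assessments list of exactly 8 `projection_assessment` objects (or
#'   the output of [assess_dataset()]'s internal expansion).
#' @param dataset_id,level optional labels carried into the result.
#' @return object of class `scale_free_call`: list with `dataset_id`,
#'   `level`, `super_weak` (logical), `ladder` (one of `"not_scale_free"`,
#'   `"weakest"`, `"weak"`, `"strong"`, `"strongest"`) and `per_projection`.
#' @export
classify_dataset <- function(assessments, dataset_id = NA_character_,
                             level = NA_character_) {
  if (length(assessments) != 8L) {
    stop("exactly 8 projection assessments are required, got ",
         length(assessments))
  }
  stopifnot(all(vapply(assessments, inherits, logical(1L),
                       "projection_assessment")))
  flags <- t(vapply(assessments, `[[`, logical(4L), "flags"))
  n_g <- nrow(flags)
  frac <- function(v) sum(v) / n_g
  weak_flag <- flags[, "pass_p"] & flags[, "pass_tail"]
  strong_flag <- weak_flag & flags[, "pass_alpha"]
  super_weak <- frac(flags[, "no_alt_favored"]) >= 0.5
  ladder <- "not_scale_free"
  if (frac(flags[, "pass_p"]) >= 0.5) ladder <- "weakest"
  if (frac(weak_flag) >= 0.5) ladder <- "weak"
  if (frac(strong_flag) >= 0.5 && super_weak) ladder <- "strong"
  if (frac(strong_flag) >= 0.9 && frac(flags[, "no_alt_favored"]) >= 0.95) {
    ladder <- "strongest"
  }
  structure(
    list(dataset_id = dataset_id, level = level, super_weak = super_weak,
         ladder = ladder, per_projection = assessments),
    class = "scale_free_call"
  )
}

#' @export
print.scale_free_call <- function(x, ...) {
  cat("<scale_free_call>", x$dataset_id, "(", x$level, ")\n")
  cat("  super_weak:", x$super_weak, " ladder:", x$ladder, "\n")
  invisible(x)
}

#' Assess and classify a whole reaction dataset
#'
#' Convenience wrapper: expands the dataset into its eight projections,
#' assesses each (with per-projection sub-seeds split deterministically
#' from `seed`), and classifies the dataset on the ladder.
#'
#' @param dataset a [reaction_dataset()].
#' @param n_boot bootstrap size per projection.
#' @param seed integer master seed.
#' @return a `scale_free_call`.
#' @export
assess_dataset <- function(dataset, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(dataset, "reaction_dataset"))
  proj <- expand_dataset(dataset)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 8L))
  assessments <- vector("list", 8L)
  for (i in seq_along(proj)) {
    assessments[[i]] <- assess_projection(proj[[i]]$graph, n_boot = n_boot,
                                          seed = seeds[i])
  }
  names(assessments) <- names(proj)
  classify_dataset(assessments, dataset_id = dataset$dataset_id,
                   level = dataset$level)
}
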