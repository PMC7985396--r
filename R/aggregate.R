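#' Binomial proportion with 2-standard-deviation error bar
#'
#' Treats a pass/fail count as binomial and reports the sample proportion
#' `p_hat = k/n` with `two_sd = 2 * sqrt(p_hat (1 - p_hat) / n)`, i.e. a
#' 95% confidence half-width around the proportion.
#'
#' @param k number of passes.
#' @param n total count (`n >= 1`).
#' @return list with `p_hat`, `two_sd`, `k`, `n`.
#' @export
#' @examples
#' proportion_ci(50, 100) # p_hat 0.5, two_sd 0.1
proportion_ci <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 1, k >= 0, k <= n)
  p_hat <- k / n
  list(p_hat = p_hat, two_sd = 2 * sqrt(p_hat * (1 - p_hat) / n),
       k = as.integer(k), n = as.integer(n))
}

.criteria <- c("no_alt_favored", "p_ge_0.1", "tail_ge_50", "alpha_in_2_3")
.flag_of <- c(no_alt_favored = "no_alt_favored", "p_ge_0.1" = "pass_p",
              tail_ge_50 = "pass_tail", alpha_in_2_3 = "pass_alpha")

#' Pass/fail indicator matrix of an ensemble
#'
#' One row per dataset; one logical column per (projection kind x
#' criterion), named `<construction>-<scope>.<criterion>` with criteria
#' `no_alt_favored`, `p_ge_0.1`, `tail_ge_50`, `alpha_in_2_3`.
#'
#' @param calls list of `scale_free_call` objects.
#' @return data.frame of logicals plus `dataset_id` and `level` columns.
#' @export
pass_matrix <- function(calls) {
  stopifnot(length(calls) >= 1L)
  rows <- lapply(calls, function(cl) {
    vals <- list(dataset_id = cl$dataset_id, level = cl$level)
    for (i in seq_along(cl$per_projection)) {
      a <- cl$per_projection[[i]]
      kind <- paste(a$construction, a$scope, sep = "-")
      for (cr in .criteria) {
        vals[[paste(kind, cr, sep = ".")]] <- unname(a$flags[.flag_of[[cr]]])
      }
    }
    as.data.frame(vals, check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of pass/fail indicators across projection types
#'
#' For one criterion, computes the Pearson correlation (phi coefficient, as
#' the indicators are 0/1) between every pair of projection-kind indicator
#' columns of a [pass_matrix()]. The diagonal is 1 by convention; entries
#' involving a constant column are undefined and reported as `NA`.
#'
#' @param pm a [pass_matrix()] data.frame (at least 2 rows).
#' @param criterion one of `no_alt_favored`, `p_ge_0.1`, `tail_ge_50`,
#'   `alpha_in_2_3`.
#' @return symmetric 8x8 correlation matrix over projection kinds.
#' @export
criterion_correlation <- function(pm, criterion = .criteria) {
  criterion <- match.arg(criterion)
  if (nrow(pm) < 2L) stop("at least 2 datasets are required")
  cols <- grep(paste0("\\.", criterion, "$"), names(pm), value = TRUE)
  mat <- vapply(pm[cols], as.numeric, numeric(nrow(pm)))
  colnames(mat) <- sub(paste0(".", criterion), "", cols, fixed = TRUE)
  res <- suppressWarnings(stats::cor(mat, method = "pearson"))
  res[!is.finite(res)] <- NA_real_
  diag(res) <- 1
  res
}

#' Ensemble summary tables
#'
#' Per level:
#' \describe{
#'   \item{`histograms`}{for each criterion, the distribution over datasets
#'     of how many of the 8 projections meet it (bins 0-8), normalized to
#'     the number of datasets in the level.}
#'   \item{`projection_pass`}{for each (criterion, projection kind), the
#'     proportion of datasets whose projection of that kind passes, with
#'     2SD error bars.}
#'   \item{`categories`}{proportions of datasets in each ladder tier (the
#'     tiers plus `not_scale_free` partition each level) and, separately,
#'     the Super-Weak proportion, with 2SD error bars.}
#' }
#'
#' @param calls list of `scale_free_call` objects carrying level labels.
#' @return list of three data.frames: `histograms`, `projection_pass`,
#'   `categories`.
#' @export
summarize_ensemble <- function(calls) {
  stopifnot(length(calls) >= 1L)
  pm <- pass_matrix(calls)
  levels_present <- unique(pm$level)
  kinds <- paste(projection_kinds()$construction, projection_kinds()$scope,
                 sep = "-")
  hist_rows <- list()
  pass_rows <- list()
  cat_rows <- list()
  for (lev in levels_present) {
    sub <- pm[pm$level == lev, , drop = FALSE]
    n_ds <- nrow(sub)
    for (cr in .criteria) {
      cols <- paste(kinds, cr, sep = ".")
      counts <- rowSums(sub[, cols, drop = FALSE])
      tab <- tabulate(counts + 1L, nbins = 9L)
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        level = lev, criterion = cr, n_projections = 0:8, count = tab,
        proportion = tab / n_ds, stringsAsFactors = FALSE
      )
      for (kd in kinds) {
        ci <- proportion_ci(sum(sub[[paste(kd, cr, sep = ".")]]), n_ds)
        pass_rows[[length(pass_rows) + 1L]] <- data.frame(
          level = lev, criterion = cr, kind = kd, k = ci$k, n = ci$n,
          p_hat = ci$p_hat, two_sd = ci$two_sd, stringsAsFactors = FALSE
        )
      }
    }
    lev_calls <- calls[vapply(calls, `[[`, character(1L), "level") == lev]
    ladders <- vapply(lev_calls, `[[`, character(1L), "ladder")
    for (cat in c("not_scale_free", "weakest", "weak", "strong", "strongest")) {
      ci <- proportion_ci(sum(ladders == cat), n_ds)
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        level = lev, category = cat, k = ci$k, n = ci$n, p_hat = ci$p_hat,
        two_sd = ci$two_sd, stringsAsFactors = FALSE
      )
    }
    sw <- vapply(lev_calls, `[[`, logical(1L), "super_weak")
    ci <- proportion_ci(sum(sw), n_ds)
    cat_rows[[length(cat_rows) + 1L]] <- data.frame(
      level = lev, category = "super_weak", k = ci$k, n = ci$n,
      p_hat = ci$p_hat, two_sd = ci$two_sd, stringsAsFactors = FALSE
    )
  }
  list(
    histograms = do.call(rbind, hist_rows),
    projection_pass = do.call(rbind, pass_rows),
    categories = do.call(rbind, cat_rows)
  )
}
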