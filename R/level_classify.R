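#' The 11 degree-distribution predictors
#'
#' @return character vector of predictor names in canonical order.
#' @export
level_predictors <- function() {
  c("alpha", "dexp", "dln", "dplwc", "dstrexp", "mean_degree",
    "n", "n_tail", "n_edges", "p", "xmin")
}

# signed normalized log-likelihood-ratio encoding for one family: the
# normalized ratio when a verdict was reached, 0 when inconclusive, NA when
# the family's fit failed (missing-coded, imputed downstream)
.d_encode <- function(lr_result) {
  if (is.null(lr_result) || !isTRUE(lr_result$fit_ok)) return(NA_real_)
  if (lr_result$verdict == "inconclusive") return(0)
  lr_result$norm_ratio
}

#' Extract the feature vector of one projection assessment
#'
#' One row per projection: the 11 predictors (power-law exponent, the four
#' signed likelihood-ratio encodings `dexp`, `dln`, `dplwc`, `dstrexp`,
#' mean degree, node/tail/edge counts, goodness-of-fit p-value and cutoff),
#' plus the level label and the projection kind. An `alt_favored` verdict
#' yields a strictly negative `d*` value, `pl_favored` a strictly positive
#' one, and an inconclusive comparison is encoded as 0; failed fits and
#' degenerate projections are missing-coded (`NA`).
#'
#' @param assessment a `projection_assessment`.
#' @param label `"individual"` or `"ecosystem"`.
#' @return one-row `data.frame` with columns [level_predictors()], `level`,
#'   `construction`, `scope`.
#' @export
extract_features <- function(assessment, label) {
  stopifnot(inherits(assessment, "projection_assessment"))
  label <- match.arg(label, c("individual", "ecosystem"))
  fit <- assessment$fit
  lr <- assessment$lr
  data.frame(
    alpha = if (is.null(fit)) NA_real_ else fit$alpha_hat,
    dexp = if (is.null(lr)) NA_real_ else .d_encode(lr$results$exponential),
    dln = if (is.null(lr)) NA_real_ else .d_encode(lr$results$lognormal),
    dplwc = if (is.null(lr)) NA_real_ else .d_encode(lr$results$powerlaw_cutoff),
    dstrexp = if (is.null(lr)) NA_real_ else
      .d_encode(lr$results$stretched_exponential),
    mean_degree = assessment$mean_degree,
    n = assessment$n,
    n_tail = if (is.null(fit)) NA_real_ else fit$n_tail,
    n_edges = assessment$n_edges,
    p = if (is.null(fit)) NA_real_ else fit$gof_p,
    xmin = if (is.null(fit)) NA_real_ else fit$xmin,
    level = label,
    construction = assessment$construction,
    scope = assessment$scope,
    stringsAsFactors = FALSE
  )
}

#' Feature table of an ensemble of classified datasets
#'
#' @param calls list of `scale_free_call` objects with level labels.
#' @return data.frame with one row per projection (8 per dataset) and a
#'   `dataset_id` column in addition to the [extract_features()] columns.
#' @export
features_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    rs <- lapply(cl$per_projection, extract_features, label = cl$level)
    out <- do.call(rbind, rs)
    out$dataset_id <- cl$dataset_id
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# median imputation: medians learned on the training split, applied to both
.impute_split <- function(train, test, cols) {
  for (cl in cols) {
    med <- stats::median(train[[cl]], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    train[[cl]][!is.finite(train[[cl]])] <- med
    test[[cl]][!is.finite(test[[cl]])] <- med
  }
  list(train = train, test = test)
}

.check_levels <- function(features) {
  if (!all(c("individual", "ecosystem") %in% features$level)) {
    stop("both levels (individual, ecosystem) must be present")
  }
}

#' Balanced single-predictor logistic discrimination
#'
#' Repeatedly fits a two-class logistic model of level on one predictor.
#' Each repeat draws a balanced training set — total size 80% of the
#' minority level's projection count, half from each level — fits the
#' model, and scores per-class accuracy on all held-out rows. Mean
#' per-class accuracies over the repeats are reported. (With two classes a
#' multinomial model reduces to this binary logistic model.)
#'
#' @param features a [features_table()] data.frame.
#' @param predictor one of [level_predictors()].
#' @param n_repeats number of balanced resampling repeats.
#' @param seed integer seed.
#' @return object of class `classifier_report`: list with `method`,
#'   `predictor`, `scenario = NA`, `per_class_accuracy` (named, mean over
#'   repeats), `oob_error = NA`, `n_train`, `n_repeats`, `seed`.
#' @export
balanced_logistic <- function(features, predictor, n_repeats = 100L, seed = 1L) {
  if (!predictor %in% level_predictors()) {
    stop("unknown predictor: ", predictor)
  }
  .check_levels(features)
  n_min <- min(table(features$level))
  n_half <- as.integer(floor(0.8 * n_min / 2))
  if (n_half < 2L) stop("too few projections per level for a balanced split")
  idx_by <- split(seq_len(nrow(features)), features$level)
  acc <- withr::with_seed(seed, {
    reps <- vapply(seq_len(n_repeats), function(r) {
      tr <- c(sample(idx_by$individual, n_half),
              sample(idx_by$ecosystem, n_half))
      train <- features[tr, c(predictor, "level")]
      test <- features[-tr, c(predictor, "level")]
      sp <- .impute_split(train, test, predictor)
      train <- sp$train
      test <- sp$test
      train$y <- as.integer(train$level == "ecosystem")
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = train[, c(predictor, "y")],
                   family = stats::binomial())
      )
      prob <- suppressWarnings(
        stats::predict(fit, newdata = test, type = "response")
      )
      pred <- ifelse(prob == 0.5, stats::runif(length(prob)) > 0.5, prob > 0.5)
      pred <- ifelse(pred, "ecosystem", "individual")
      c(ecosystem = mean(pred[test$level == "ecosystem"] == "ecosystem"),
        individual = mean(pred[test$level == "individual"] == "individual"))
    }, numeric(2L))
    rowMeans(reps)
  })
  structure(
    list(method = "logistic", predictor = predictor, scenario = NA_character_,
         per_class_accuracy = acc, oob_error = NA_real_,
         n_train = 2L * n_half, n_repeats = as.integer(n_repeats),
         importances = NULL, seed = seed),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>", x$method,
      if (!is.na(x$scenario)) paste0("[", x$scenario, "]"),
      if (!is.null(x$predictor) && !is.na(x$predictor))
        paste0("predictor=", x$predictor), "\n")
  if (is.list(x$per_class_accuracy) && !is.numeric(x$per_class_accuracy)) {
    for (nm in names(x$per_class_accuracy)) {
      cat(sprintf("  %-28s eco=%.3f ind=%.3f\n", nm,
                  x$per_class_accuracy[[nm]]["ecosystem"],
                  x$per_class_accuracy[[nm]]["individual"]))
    }
  } else {
    cat(sprintf("  accuracy: ecosystem=%.3f individual=%.3f\n",
                x$per_class_accuracy["ecosystem"],
                x$per_class_accuracy["individual"]))
  }
  if (length(x$oob_error) == 1L && !is.na(x$oob_error)) {
    cat(sprintf("  OOB error: %.3f\n", x$oob_error))
  }
  invisible(x)
}

# half/half split grouped by dataset and stratified by level: all
# projections of one dataset land in the same half, so test accuracy is
# measured on unseen datasets (a row-level split would leak dataset
# identity into the test half and inflate accuracy even for exchangeable
# levels)
.rf_one <- function(features, predictors, seed) {
  tr <- withr::with_seed(seed, {
    ids <- unique(features$dataset_id)
    lev_of <- features$level[match(ids, features$dataset_id)]
    tr_ids <- unlist(lapply(split(ids, lev_of), function(g) {
      sample(g, floor(length(g) / 2))
    }), use.names = FALSE)
    which(features$dataset_id %in% tr_ids)
  })
  train <- features[tr, , drop = FALSE]
  test <- features[-tr, , drop = FALSE]
  if (length(unique(train$level)) < 2L || length(unique(test$level)) < 2L) {
    stop("a level is absent from the train or test half; use more data")
  }
  sp <- .impute_split(train, test, predictors)
  train <- sp$train
  test <- sp$test
  fit <- withr::with_seed(seed + 1L, randomForest::randomForest(
    x = train[, predictors, drop = FALSE],
    y = factor(train$level, levels = c("individual", "ecosystem")),
    ntree = 100L, mtry = min(3L, length(predictors))
  ))
  oob <- unname(fit$err.rate[nrow(fit$err.rate), "OOB"])
  # vote ties in prediction are broken via the RNG; seed them too
  pred <- withr::with_seed(
    seed + 2L,
    stats::predict(fit, newdata = test[, predictors, drop = FALSE])
  )
  acc <- c(
    ecosystem = mean(pred[test$level == "ecosystem"] == "ecosystem"),
    individual = mean(pred[test$level == "individual"] == "individual")
  )
  imp <- sort(fit$importance[, "MeanDecreaseGini"], decreasing = TRUE)
  list(per_class_accuracy = acc, oob_error = oob, importances = imp,
       n_train = nrow(train),
       n_test_datasets = c(
         ecosystem = length(unique(test$dataset_id[test$level == "ecosystem"])),
         individual = length(unique(test$dataset_id[test$level == "individual"]))
       ))
}

#' Random-forest discrimination of individuals vs ecosystems
#'
#' Classifies projections into levels with a 100-tree random forest using 3
#' features per split, after a random half/half train-test split. Three
#' scenarios:
#' \describe{
#'   \item{`all_predictors`}{all 11 predictors.}
#'   \item{`no_size`}{drops the three direct network-size predictors `n`,
#'     `n_tail`, `n_edges`.}
#'   \item{`per_projection`}{runs the `no_size` forest independently on
#'     each of the eight projection kinds and reports per-kind accuracies.}
#' }
#' Per-class test accuracy, the out-of-bag (OOB) error from the training
#' half and Gini importances are reported.
#'
#' @param features a [features_table()] data.frame.
#' @param scenario one of `"all_predictors"`, `"no_size"`,
#'   `"per_projection"`.
#' @param seed integer seed (controls both the split and the forest).
#' @return a `classifier_report`; for `per_projection`,
#'   `per_class_accuracy`, `oob_error` and `importances` are named lists
#'   keyed by projection kind.
#' @export
random_forest_experiment <- function(features,
                                     scenario = c("all_predictors", "no_size",
                                                  "per_projection"),
                                     seed = 1L) {
  scenario <- match.arg(scenario)
  .check_levels(features)
  if (is.null(features$dataset_id)) features$dataset_id <- seq_len(nrow(features))
  size_preds <- c("n", "n_tail", "n_edges")
  if (scenario == "all_predictors") {
    predictors <- level_predictors()
  } else {
    predictors <- setdiff(level_predictors(), size_preds)
  }
  if (scenario == "per_projection") {
    kind <- paste(features$construction, features$scope, sep = "-")
    res <- lapply(split(features, kind), function(df) {
      .rf_one(df, predictors, seed)
    })
    out <- list(
      method = "random_forest", predictor = NA_character_,
      scenario = scenario,
      per_class_accuracy = lapply(res, `[[`, "per_class_accuracy"),
      oob_error = lapply(res, `[[`, "oob_error"),
      importances = lapply(res, `[[`, "importances"),
      n_train = vapply(res, `[[`, numeric(1L), "n_train"),
      n_test_datasets = lapply(res, `[[`, "n_test_datasets"),
      n_repeats = 1L, seed = seed
    )
  } else {
    res <- .rf_one(features, predictors, seed)
    out <- c(list(method = "random_forest", predictor = NA_character_,
                  scenario = scenario), res,
             list(n_repeats = 1L, seed = seed))
  }
  structure(out, class = "classifier_report")
}
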