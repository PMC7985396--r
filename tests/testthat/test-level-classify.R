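test_that("feature vectors transcribe assessment fields", {
  fit <- structure(
    list(alpha_hat = 2.4, sigma = 0.1, xmin = 3L, n_tail = 120L, ks_D = 0.03,
         gof_p = 0.22, n_boot = 50L),
    class = "powerlaw_fit"
  )
  lr <- list(results = list(
    exponential = list(family = "exponential", R = -30, p_value = 1e-5,
                       verdict = "alt_favored", norm_ratio = -4.4,
                       fit_ok = TRUE),
    lognormal = list(family = "lognormal", R = 2, p_value = 0.4,
                     verdict = "inconclusive", norm_ratio = 0.8,
                     fit_ok = TRUE),
    stretched_exponential = list(family = "stretched_exponential", R = NA,
                                 p_value = NA, verdict = "inconclusive",
                                 norm_ratio = NA, fit_ok = FALSE),
    powerlaw_cutoff = list(family = "powerlaw_cutoff", R = 8, p_value = 1e-4,
                           verdict = "pl_favored", norm_ratio = 2.2,
                           fit_ok = TRUE)
  ), any_alt_favored = TRUE)
  a <- structure(
    list(construction = "uni_compounds", scope = "entire", n = 500L,
         n_edges = 900L, mean_degree = 3.6, degenerate = FALSE, fit = fit,
         lr = lr,
         flags = c(pass_p = TRUE, pass_tail = TRUE, pass_alpha = TRUE,
                   no_alt_favored = FALSE)),
    class = "projection_assessment"
  )
  fv <- extract_features(a, "ecosystem")
  expect_equal(fv$mean_degree, 3.6)
  expect_equal(fv$n, 500L)
  expect_equal(fv$n_edges, 900L)
  expect_equal(fv$alpha, 2.4)
  expect_equal(fv$p, 0.22)
  expect_equal(fv$xmin, 3L)
  expect_equal(fv$level, "ecosystem")
  # encodings: favored alternative strictly negative, inconclusive 0,
  # failed fit missing, pl-favored positive
  expect_lt(fv$dexp, 0)
  expect_equal(fv$dln, 0)
  expect_true(is.na(fv$dstrexp))
  expect_gt(fv$dplwc, 0)
  expect_setequal(intersect(level_predictors(), names(fv)),
                  level_predictors())
})

test_that("balanced logistic sizes its training set from the minority level", {
  ft <- make_fake_features(20, effect = "size", seed = 2)
  # 20 datasets x 8 projections per level; minority count 160
  rep1 <- balanced_logistic(ft, "n", n_repeats = 5, seed = 3)
  expect_equal(rep1$n_train, 2L * floor(0.8 * 160 / 2))
  expect_error(balanced_logistic(ft, "bogus"), "unknown predictor")
  only1 <- ft[ft$level == "individual", ]
  expect_error(balanced_logistic(only1, "n"), "both levels")
})

test_that("single-predictor logistic separates planted sizes but not noise", {
  ft <- make_fake_features(25, effect = "size", seed = 4)
  rep_n <- balanced_logistic(ft, "n", n_repeats = 20, seed = 5)
  expect_gt(rep_n$per_class_accuracy[["ecosystem"]], 0.5)
  expect_gt(rep_n$per_class_accuracy[["individual"]], 0.5)

  # a predictor with no level signal stays near chance
  rep_a <- balanced_logistic(ft, "alpha", n_repeats = 20, seed = 5)
  expect_lt(abs(rep_a$per_class_accuracy[["ecosystem"]] - 0.5), 0.12)
  expect_lt(abs(rep_a$per_class_accuracy[["individual"]] - 0.5), 0.12)

  # bit-reproducible under a fixed seed
  rep_n2 <- balanced_logistic(ft, "n", n_repeats = 20, seed = 5)
  expect_identical(rep_n$per_class_accuracy, rep_n2$per_class_accuracy)
})

test_that("random forests exploit planted effects and respect scenarios", {
  ft <- make_fake_features(30, effect = c("size", "mean_degree"), seed = 6)
  rf_all <- random_forest_experiment(ft, "all_predictors", seed = 7)
  expect_gt(mean(rf_all$per_class_accuracy), 0.8)
  expect_lt(rf_all$oob_error, 0.2)
  # the planted discriminating features dominate the importances
  expect_true(any(c("n", "n_edges", "mean_degree") %in%
                    names(rf_all$importances)[1:3]))
  expect_identical(
    rf_all$per_class_accuracy,
    random_forest_experiment(ft, "all_predictors", seed = 7)$per_class_accuracy
  )

  # removing size predictors hurts a size-only signal
  ft_size <- make_fake_features(30, effect = "size", seed = 8)
  rf_full <- random_forest_experiment(ft_size, "all_predictors", seed = 9)
  rf_nosize <- random_forest_experiment(ft_size, "no_size", seed = 9)
  expect_gt(mean(rf_full$per_class_accuracy), 0.8)
  expect_lt(mean(rf_nosize$per_class_accuracy),
            mean(rf_full$per_class_accuracy) - 0.1)
  expect_false(any(c("n", "n_tail", "n_edges") %in%
                     names(rf_nosize$importances)))

  # per-projection scenario reports one entry per kind
  rf_pp <- random_forest_experiment(ft, "per_projection", seed = 10)
  expect_length(rf_pp$per_class_accuracy, 8L)
  expect_true(all(vapply(rf_pp$per_class_accuracy, length, integer(1)) == 2L))
})

test_that("forests find nothing in exchangeable levels", {
  ft0 <- make_fake_features(40, effect = character(), seed = 11)
  rf0 <- random_forest_experiment(ft0, "all_predictors", seed = 12)
  # 20 test datasets per class: conservative 3SD band around chance
  band <- 3 * 0.5 / sqrt(20)
  expect_lt(abs(rf0$per_class_accuracy[["ecosystem"]] - 0.5), band)
  expect_lt(abs(rf0$per_class_accuracy[["individual"]] - 0.5), band)
  # iid rows: the out-of-bag error is near chance too
  expect_lt(abs(rf0$oob_error - 0.5), 0.12)
})
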