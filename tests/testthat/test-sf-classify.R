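test_that("assess_projection derives flags, handles tiny and degenerate graphs", {
  # star K_{1,4} (hub substrate vs 4 products, cross-side edges only):
  # fits but the tail is far below 50 nodes
  star <- reaction_dataset("star", "individual", list(
    reaction("R1", "H", c("a", "b", "c", "d"))
  ))
  g <- build_projection(star, "uni_subs_not_connected")
  a <- assess_projection(g, n_boot = 20, seed = 1)
  expect_false(a$degenerate)
  expect_false(a$flags[["pass_tail"]])
  expect_equal(a$n, 5L)
  expect_equal(a$mean_degree, 2 * a$n_edges / a$n)

  # all-equal degrees (a triangle) are degenerate: every flag FALSE
  tri <- reaction_dataset("tri", "individual", list(
    reaction("R1", "x", "y"), reaction("R2", "y", "z"),
    reaction("R3", "z", "x")
  ))
  gt <- build_projection(tri, "uni_compounds")
  at <- assess_projection(gt, n_boot = 20, seed = 1)
  expect_true(at$degenerate)
  expect_false(any(at$flags))
  expect_null(at$fit)

  # flags are a pure function of the stored fit and comparisons
  x <- sample_discrete_powerlaw(2.5, 1, 4000, seed = 77)
  ds <- generate_reaction_dataset(generator_config(80, seed = 5))
  gp <- build_projection(ds, "uni_compounds")
  ap <- assess_projection(gp, n_boot = 30, seed = 9)
  expect_equal(unname(ap$flags[["pass_p"]]), unname(ap$fit$gof_p >= 0.1))
  expect_equal(unname(ap$flags[["pass_tail"]]), unname(ap$fit$n_tail >= 50))
  expect_equal(unname(ap$flags[["pass_alpha"]]),
               ap$fit$alpha_hat > 2 && ap$fit$alpha_hat < 3)
  expect_equal(unname(ap$flags[["no_alt_favored"]]), !ap$lr$any_alt_favored)
})

test_that("classify_dataset reproduces the worked ladder examples", {
  all_true <- matrix(TRUE, 8, 4,
                     dimnames = list(NULL, c("pass_p", "pass_tail",
                                             "pass_alpha", "no_alt_favored")))
  cl <- fake_call_from_flags(all_true)
  expect_true(cl$super_weak)
  expect_equal(cl$ladder, "strongest")

  # 4/8 meet p and tail but alpha fails everywhere; 6/8 no-alt -> weak,
  # super-weak
  m <- all_true
  m[, "pass_alpha"] <- FALSE
  m[5:8, c("pass_p", "pass_tail")] <- FALSE
  m[7:8, "no_alt_favored"] <- FALSE
  cl2 <- fake_call_from_flags(m)
  expect_true(cl2$super_weak)
  expect_equal(cl2$ladder, "weak")

  # 6/8 no-alt but only 1/8 with p >= 0.1 -> super-weak yet not scale-free
  m3 <- matrix(FALSE, 8, 4, dimnames = dimnames(all_true))
  m3[1:6, "no_alt_favored"] <- TRUE
  m3[1, "pass_p"] <- TRUE
  cl3 <- fake_call_from_flags(m3)
  expect_true(cl3$super_weak)
  expect_equal(cl3$ladder, "not_scale_free")

  expect_error(classify_dataset(list()), "exactly 8")
})

test_that("with 8 graphs the 90% and 95% thresholds require all 8", {
  base <- matrix(TRUE, 8, 4,
                 dimnames = list(NULL, c("pass_p", "pass_tail", "pass_alpha",
                                         "no_alt_favored")))
  # 7/8 strong-flag graphs is 87.5% < 90%: strongest unreachable
  m <- base
  m[8, "pass_alpha"] <- FALSE
  expect_equal(fake_call_from_flags(m)$ladder, "strong")
  # 7/8 no-alt is 87.5% < 95%: strongest unreachable even with 8/8 strong
  m2 <- base
  m2[8, "no_alt_favored"] <- FALSE
  expect_equal(fake_call_from_flags(m2)$ladder, "strong")
  # 4/8 is exactly the 50% boundary
  m3 <- matrix(FALSE, 8, 4, dimnames = dimnames(base))
  m3[1:4, c("pass_p", "pass_tail")] <- TRUE
  expect_equal(fake_call_from_flags(m3)$ladder, "weak")
  m3[4, "pass_tail"] <- FALSE
  expect_equal(fake_call_from_flags(m3)$ladder, "weakest")
})

test_that("classification agrees with the definition oracle and is monotone", {
  withr::with_seed(101, {
    for (i in 1:300) {
      flags <- matrix(stats::runif(32) < stats::runif(1), 8, 4,
                      dimnames = list(NULL, c("pass_p", "pass_tail",
                                              "pass_alpha", "no_alt_favored")))
      got <- fake_call_from_flags(flags)
      want <- oracle_ladder(flags)
      expect_equal(got$super_weak, want$super_weak)
      expect_equal(got$ladder, want$ladder)

      # flipping one FALSE to TRUE never lowers the ladder
      falses <- which(!flags)
      if (length(falses)) {
        f2 <- flags
        f2[sample(falses, 1)] <- TRUE
        up <- fake_call_from_flags(f2)
        ranks <- c(not_scale_free = 0, weakest = 1, weak = 2, strong = 3,
                   strongest = 4)
        expect_gte(ranks[[up$ladder]], ranks[[got$ladder]])
        expect_gte(up$super_weak, got$super_weak)
      }
    }
  })
})

test_that("assess_dataset ties the pipeline together reproducibly", {
  ds <- generate_reaction_dataset(generator_config(60, seed = 3))
  c1 <- assess_dataset(ds, n_boot = 20, seed = 4)
  c2 <- assess_dataset(ds, n_boot = 20, seed = 4)
  expect_s3_class(c1, "scale_free_call")
  expect_length(c1$per_projection, 8L)
  expect_equal(c1$ladder, c2$ladder)
  expect_identical(
    vapply(c1$per_projection, `[[`, logical(4), "flags"),
    vapply(c2$per_projection, `[[`, logical(4), "flags")
  )
  expect_identical(
    vapply(c1$per_projection, function(a) if (is.null(a$fit)) NA_real_ else
      a$fit$gof_p, numeric(1)),
    vapply(c2$per_projection, function(a) if (is.null(a$fit)) NA_real_ else
      a$fit$gof_p, numeric(1))
  )
})
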