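# shared fixtures and independent brute-force oracles

toy_dataset <- function() {
  reaction_dataset("toy", "individual", list(
    reaction("R1", c("A", "B"), "C"),
    reaction("R2", "C", c("D", "E"))
  ))
}

# small random dataset over a letter pool; sides may overlap, one side may
# be empty, arity 0-3 per side
random_small_dataset <- function(n_reactions, seed, pool = LETTERS[1:8]) {
  withr::with_seed(seed, {
    reactions <- lapply(seq_len(n_reactions), function(i) {
      repeat {
        subs <- sample(pool, sample(0:3, 1))
        prods <- sample(pool, sample(0:3, 1))
        if (length(subs) + length(prods) > 0 && !setequal(subs, prods)) break
      }
      reaction(sprintf("R%d", i), subs, prods)
    })
    reaction_dataset(sprintf("rand%d", seed), "individual", reactions)
  })
}

# canonical sorted edge-list string set of a projection_graph
edge_set <- function(projection) {
  el <- igraph::as_edgelist(projection$graph)
  if (!nrow(el)) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--"))
}

# brute-force double loop applying the quoted membership predicate of each
# construction rule; independent of the package's edge builders
oracle_edge_set <- function(dataset, construction) {
  rx <- dataset$reactions
  cpds <- dataset_compounds(dataset)
  in_rx <- function(c, r) c %in% c(r$substrates, r$products)
  edges <- character()
  if (construction == "bi_full") {
    for (c in cpds) for (r in rx) {
      if (in_rx(c, r)) edges <- c(edges, paste(pmin(c, r$reaction_id),
                                               pmax(c, r$reaction_id),
                                               sep = "--"))
    }
  } else if (construction == "uni_compounds") {
    for (i in seq_along(cpds)) for (j in seq_len(i - 1)) {
      u <- cpds[i]; v <- cpds[j]
      hit <- any(vapply(rx, function(r) in_rx(u, r) && in_rx(v, r), logical(1)))
      if (hit) edges <- c(edges, paste(min(u, v), max(u, v), sep = "--"))
    }
  } else if (construction == "uni_subs_not_connected") {
    for (i in seq_along(cpds)) for (j in seq_len(i - 1)) {
      u <- cpds[i]; v <- cpds[j]
      hit <- any(vapply(rx, function(r) {
        (u %in% r$substrates && v %in% r$products) ||
          (v %in% r$substrates && u %in% r$products)
      }, logical(1)))
      if (hit) edges <- c(edges, paste(min(u, v), max(u, v), sep = "--"))
    }
  } else if (construction == "uni_reactions") {
    ids <- vapply(rx, `[[`, character(1), "reaction_id")
    for (i in seq_along(rx)) for (j in seq_len(i - 1)) {
      shared <- length(intersect(c(rx[[i]]$substrates, rx[[i]]$products),
                                 c(rx[[j]]$substrates, rx[[j]]$products))) > 0
      if (shared) edges <- c(edges, paste(min(ids[i], ids[j]),
                                          max(ids[i], ids[j]), sep = "--"))
    }
  }
  sort(unique(edges))
}

# exhaustive cutoff scan oracle: exact MLE at every candidate via
# mle_alpha(), KS distance via ks_distance(), strict-minimum tie-break
# toward the smaller cutoff
brute_select_xmin <- function(x) {
  u <- sort(unique(x[x >= 1]))
  cand <- u[-length(u)]
  best <- NULL
  for (xm in cand) {
    est <- mle_alpha(x, xm, method = "exact")
    D <- ks_distance(x, est$alpha_hat, xm)
    if (is.null(best) || D < best$D - 1e-12) {
      best <- list(xmin = xm, alpha = est$alpha_hat, D = D)
    }
  }
  best
}

# direct re-evaluation of the quoted ladder definitions from an 8x4 logical
# flag matrix (columns pass_p, pass_tail, pass_alpha, no_alt_favored),
# using integer counts
oracle_ladder <- function(flags) {
  stopifnot(nrow(flags) == 8)
  sw <- sum(flags[, "no_alt_favored"]) >= 4
  weakest <- sum(flags[, "pass_p"]) >= 4
  weak <- sum(flags[, "pass_p"] & flags[, "pass_tail"]) >= 4
  strong_cnt <- sum(flags[, "pass_p"] & flags[, "pass_tail"] &
                      flags[, "pass_alpha"])
  strong <- strong_cnt >= 4 && sw
  strongest <- strong_cnt >= 8 && sum(flags[, "no_alt_favored"]) >= 8
  ladder <- if (strongest) "strongest" else if (strong) "strong" else
    if (weak) "weak" else if (weakest) "weakest" else "not_scale_free"
  list(super_weak = sw, ladder = ladder)
}

# minimal assessment stub carrying only what classify_dataset consumes
fake_assessment <- function(flags, construction = "bi_full", scope = "entire") {
  structure(
    list(construction = construction, scope = scope, n = 10L, n_edges = 9L,
         mean_degree = 1.8, degenerate = FALSE, fit = NULL, lr = NULL,
         flags = c(pass_p = flags[[1]], pass_tail = flags[[2]],
                   pass_alpha = flags[[3]], no_alt_favored = flags[[4]])),
    class = "projection_assessment"
  )
}

fake_call_from_flags <- function(flag_mat) {
  kinds <- projection_kinds()
  assessments <- lapply(1:8, function(i) {
    fake_assessment(as.logical(flag_mat[i, ]),
                    construction = kinds$construction[i],
                    scope = kinds$scope[i])
  })
  classify_dataset(assessments)
}

# synthetic feature tables for discrimination tests: 8 rows (one per
# projection kind) per dataset; `effect` plants level differences in n (and
# n_edges) and/or mean_degree
make_fake_features <- function(n_per_level, effect = c("size", "mean_degree"),
                               seed = 1) {
  kinds <- projection_kinds()
  withr::with_seed(seed, {
    rows <- list()
    did <- 0
    for (lev in c("individual", "ecosystem")) {
      boost_n <- if ("size" %in% effect && lev == "ecosystem") 2.2 else 1
      boost_k <- if ("mean_degree" %in% effect && lev == "ecosystem") 1.6 else 1
      for (d in seq_len(n_per_level)) {
        did <- did + 1
        base_n <- stats::rlnorm(1, log(300 * boost_n), 0.35)
        base_k <- stats::rlnorm(1, log(4 * boost_k), 0.25)
        for (i in 1:8) {
          n <- round(base_n * stats::runif(1, 0.6, 1.4))
          k <- base_k * stats::runif(1, 0.8, 1.2)
          rows[[length(rows) + 1]] <- data.frame(
            alpha = stats::rnorm(1, 2.5, 0.4),
            dexp = stats::rnorm(1), dln = stats::rnorm(1),
            dplwc = stats::rnorm(1), dstrexp = stats::rnorm(1),
            mean_degree = k, n = n, n_tail = round(n * 0.6),
            n_edges = round(n * k / 2), p = stats::runif(1),
            xmin = sample(1:6, 1), level = lev,
            construction = kinds$construction[i], scope = kinds$scope[i],
            dataset_id = sprintf("d%04d", did), stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
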