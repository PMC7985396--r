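#' Configuration for one synthetic reaction dataset
#'
#' The generator emulates the statistical shape of a genome- or
#' metagenome-derived reaction list: a few hub compounds participating in
#' many reactions while most compounds occur in few, with 1-6 compounds per
#' reaction side. Under `"preferential"` reuse each compound slot is filled
#' by a previously seen compound with weight equal to its current
#' participation count, or by a brand-new compound with weight
#' `reuse_strength` (a Chinese-restaurant scheme, the canonical
#' rich-get-richer mechanism); under `"uniform"` every slot is drawn
#' uniformly from a fixed pool of `pool_size` compounds, which produces a
#' near-homogeneous participation distribution.
#'
#' @param n_reactions number of reactions (genome scale is hundreds to
#'   thousands; default 600).
#' @param arity_range integer pair: min and max compounds per reaction side.
#' @param compound_reuse `"preferential"` or `"uniform"`.
#' @param reuse_strength innovation weight of the preferential scheme
#'   (larger means more distinct compounds; default 400, which at genome
#'   scale yields roughly one distinct compound per reaction, as in real
#'   metabolic annotations).
#' @param pool_size compound pool for `"uniform"` reuse; default
#'   `max(64, n_reactions / 2)`.
#' @param level `"individual"` or `"ecosystem"`.
#' @param seed integer seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_reactions = 600L, arity_range = c(1L, 3L),
                             compound_reuse = c("preferential", "uniform"),
                             reuse_strength = 400, pool_size = NULL,
                             level = c("individual", "ecosystem"), seed = 1L) {
  compound_reuse <- match.arg(compound_reuse)
  level <- match.arg(level)
  stopifnot(n_reactions >= 1, length(arity_range) == 2L,
            arity_range[1L] >= 1, arity_range[2L] >= arity_range[1L],
            arity_range[2L] <= 6, reuse_strength >= 0)
  if (is.null(pool_size)) pool_size <- max(64L, ceiling(n_reactions / 2))
  if (compound_reuse == "uniform" && pool_size < arity_range[2L]) {
    stop("infeasible config: pool_size smaller than the maximum side arity")
  }
  structure(
    list(n_reactions = as.integer(n_reactions),
         arity_range = as.integer(arity_range),
         compound_reuse = compound_reuse, reuse_strength = reuse_strength,
         pool_size = as.integer(pool_size), level = level,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic reaction dataset
#'
#' Builds reactions sequentially under the configured compound-reuse
#' scheme. Within a side, compounds are distinct; a reaction whose product
#' set would equal its substrate set is repaired by redrawing the products
#' (and, as a last resort, adding a fresh compound). Deterministic for a
#' fixed configuration.
#'
#' @param config a [generator_config()].
#' @param dataset_id identifier; default derives from level and seed.
#' @return a [reaction_dataset()].
#' @export
#' @examples
#' ds <- generate_reaction_dataset(generator_config(50, seed = 7))
#' length(ds$reactions)
generate_reaction_dataset <- function(config, dataset_id = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(dataset_id)) {
    dataset_id <- sprintf("sim_%s_%d", config$level, config$seed)
  }
  withr::with_seed(config$seed, .generate_dataset_impl(config, dataset_id))
}

.generate_dataset_impl <- function(config, dataset_id) {
  counts <- numeric(0) # participation count per seen compound
  n_seen <- 0L
  pool <- if (config$compound_reuse == "uniform") {
    sprintf("C%05d", seq_len(config$pool_size))
  }
  draw_side <- function(k, exclude = character()) {
    side <- character(0)
    if (config$compound_reuse == "uniform") {
      avail <- setdiff(pool, exclude)
      k <- min(k, length(avail))
      return(sample(avail, k))
    }
    for (j in seq_len(k)) {
      for (attempt in 1:50) {
        tot <- sum(counts)
        if (n_seen == 0L ||
            stats::runif(1L) < config$reuse_strength /
              (tot + config$reuse_strength)) {
          cand <- n_seen + 1L
        } else {
          cand <- sample.int(n_seen, 1L, prob = counts)
        }
        id <- sprintf("C%05d", cand)
        if (!(id %in% side)) break
      }
      if (id %in% side) next
      if (cand > n_seen) {
        counts[cand] <<- 0
        n_seen <<- cand
      }
      counts[cand] <<- counts[cand] + 1
      side <- c(side, id)
    }
    side
  }
  arity <- function() {
    sample(config$arity_range[1L]:config$arity_range[2L], 1L)
  }
  reactions <- vector("list", config$n_reactions)
  for (i in seq_len(config$n_reactions)) {
    subs <- draw_side(arity())
    prods <- draw_side(arity())
    tries <- 0L
    while (setequal(subs, prods) && tries < 10L) {
      prods <- draw_side(arity())
      tries <- tries + 1L
    }
    if (setequal(subs, prods)) {
      # force distinctness with a brand-new compound
      n_seen <- n_seen + 1L
      counts[n_seen] <- 1
      prods <- c(prods, sprintf("C%05d", n_seen))
    }
    reactions[[i]] <- reaction(sprintf("R%05d", i), subs, prods)
  }
  reaction_dataset(dataset_id, config$level, reactions)
}

#' Sample a degree sequence from one of the five candidate tail families
#'
#' Draws i.i.d. integer values from the discrete tail form of the named
#' family on `{xmin, xmin+1, ...}` — the same unnormalized densities and
#' numerical normalization used by the fitting code, so sampler and
#' likelihood agree by construction. The power-law family delegates to
#' [sample_discrete_powerlaw()].
#'
#' @param family `"powerlaw"`, `"exponential"`, `"lognormal"`,
#'   `"stretched_exponential"` or `"powerlaw_cutoff"`.
#' @param params named list/vector: `alpha` for `powerlaw`; `lambda` for
#'   `exponential`; `mu`, `s` for `lognormal`; `lambda`, `beta` for
#'   `stretched_exponential`; `alpha`, `lambda` for `powerlaw_cutoff`.
#'   `xmin` (default 1) may be included in `params`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return integer-valued numeric vector of length `n`.
#' @export
sample_degree_sequence <- function(family = c("powerlaw", alt_families()),
                                   params, n, seed = 1L) {
  family <- match.arg(family)
  params <- as.list(params)
  xmin <- if (is.null(params$xmin)) 1L else as.integer(params$xmin)
  stopifnot(n >= 1, xmin >= 1)
  if (family == "powerlaw") {
    return(sample_discrete_powerlaw(params$alpha, xmin, n, seed = seed))
  }
  spec <- .alt_spec(family)
  pars <- unlist(params[spec$par_names])
  if (length(pars) != length(spec$par_names) || any(is.na(pars))) {
    stop("family '", family, "' needs parameters: ",
         paste(spec$par_names, collapse = ", "))
  }
  if (any(pars < spec$lower) || any(pars > spec$upper)) {
    stop("parameters outside the valid range for family '", family, "'")
  }
  # cumulative table, doubling the support until < 1e-12 mass remains
  K <- xmin + 1023L
  repeat {
    lf <- spec$logf(xmin:K, pars)
    M <- max(lf)
    w <- exp(lf - M)
    logZ <- .alt_lognorm(spec$logf, pars, xmin, K)
    mass <- sum(w) * exp(M - logZ)
    if (mass >= 1 - 1e-12 || K >= xmin + 2^20) break
    K <- xmin + 2L * (K - xmin + 1L) - 1L
  }
  cdf <- cumsum(w) / sum(w)
  withr::with_seed(seed, xmin + findInterval(stats::runif(n), cdf))
}

#' Configuration for a two-level synthetic ensemble
#'
#' Defines the study conditions for individual-vs-ecosystem discrimination
#' experiments. Ecosystem-level datasets are metagenome stand-ins: under
#' the `"size"` planted effect they carry `size_ratio` times more reactions
#' than individual-level (genome) datasets; under the `"mean_degree"`
#' effect their reactions involve more compounds per side (arity 2-4 vs
#' 1-3), which raises the mean degree of every projection. With
#' `planted_effects = "none"` the two levels are exchangeable. Per-dataset
#' reaction counts are jittered by a uniform factor in [0.65, 1.45] so the
#' levels overlap rather than separate trivially.
#'
#' @param n_individual,n_ecosystem dataset counts per level.
#' @param base_reactions reaction count of an individual-level dataset
#'   before jitter.
#' @param size_ratio multiplier on `base_reactions` for ecosystem datasets
#'   under the size effect (> 1).
#' @param planted_effects character subset of `c("size", "mean_degree")`,
#'   or `"none"`.
#' @param reuse_strength passed to [generator_config()]; scaled with
#'   dataset size so compound richness tracks reaction count.
#' @param master_seed integer; per-dataset seeds are split from it.
#' @return validated list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_individual, n_ecosystem, base_reactions = 600L,
                            size_ratio = 3, planted_effects = c("size",
                                                                "mean_degree"),
                            reuse_strength = 400, master_seed = 1L) {
  if (!identical(planted_effects, "none")) {
    stopifnot(all(planted_effects %in% c("size", "mean_degree")))
  }
  stopifnot(n_individual >= 0, n_ecosystem >= 0,
            n_individual + n_ecosystem >= 1, size_ratio > 1,
            base_reactions >= 2)
  structure(
    list(n_individual = as.integer(n_individual),
         n_ecosystem = as.integer(n_ecosystem),
         base_reactions = as.integer(base_reactions),
         size_ratio = size_ratio, planted_effects = planted_effects,
         reuse_strength = reuse_strength,
         master_seed = as.integer(master_seed)),
    class = "ensemble_config"
  )
}

#' Generate a labeled two-level ensemble of reaction datasets
#'
#' @param config an [ensemble_config()].
#' @return list of [reaction_dataset()] objects (individual datasets first),
#'   reproducible from `master_seed` alone.
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  n_tot <- config$n_individual + config$n_ecosystem
  draws <- withr::with_seed(config$master_seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_tot),
    jitter = stats::runif(n_tot, 0.65, 1.45)
  ))
  has <- function(eff) {
    !identical(config$planted_effects, "none") &&
      eff %in% config$planted_effects
  }
  out <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    is_eco <- i > config$n_individual
    base <- config$base_reactions
    if (is_eco && has("size")) base <- round(base * config$size_ratio)
    n_rx <- max(2L, round(base * draws$jitter[i]))
    arity <- if (is_eco && has("mean_degree")) c(2L, 4L) else c(1L, 3L)
    cfg <- generator_config(
      n_reactions = n_rx, arity_range = arity,
      compound_reuse = "preferential",
      reuse_strength = config$reuse_strength * n_rx / config$base_reactions,
      level = if (is_eco) "ecosystem" else "individual",
      seed = draws$seeds[i]
    )
    out[[i]] <- generate_reaction_dataset(
      cfg, dataset_id = sprintf("sim_%s_%03d",
                                if (is_eco) "eco" else "ind", i)
    )
  }
  out
}
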