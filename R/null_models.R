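# Randomization machinery and standardized indices. Two nulls are available
# for every statistic: "independent_swap" (fixed row AND column sums, fresh
# checkerboard-swap chain per trial) and "richness" (uniform draws from the
# species pool at the plot's observed richness). Defaults follow the analysis
# design: NRI/NTI against independent swap, PD/RPD significance against the
# richness-preserving pool draw.

#' Independent-swap randomization of a binary community matrix
#'
#' Attempts `n_swap_attempts` random 2x2 checkerboard flips; every accepted
#' flip preserves all row and column sums exactly. The default chain length is
#' `10 * nrow * ncol` attempts, which folds burn-in into each fresh chain.
#'
#' @param m Binary community matrix (>= 2 plots, >= 2 species).
#' @param n_swap_attempts Number of attempted swaps.
#' @param seed Optional integer seed for the chain.
#' @return A randomized matrix with the same dimnames and marginals.
#' @export
independent_swap <- function(m, n_swap_attempts = 10 * nrow(m) * ncol(m),
                             seed = NULL) {
  check_community(m)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("independent swap needs at least 2 plots and 2 species")
  }
  if (!is.null(seed)) set.seed(seed)
  mi <- m
  storage.mode(mi) <- "integer"
  out <- cpp_independent_swap(mi, as.integer(n_swap_attempts))
  dimnames(out) <- dimnames(m)
  out
}

#' Random species set preserving a plot's richness
#'
#' Uniform random subset of the matrix's species pool with size equal to the
#' plot's observed richness. Uses the current RNG state; seed upstream.
#'
#' @param m Community matrix (defines the species pool).
#' @param plot Plot id.
#' @return Character vector of species ids.
#' @export
randomize_pool_fixed_richness <- function(m, plot) {
  check_community(m)
  if (!plot %in% rownames(m)) stop("unknown plot id: ", plot)
  k <- sum(m[plot, ])
  if (k > ncol(m)) stop("plot richness exceeds pool size")
  sample(colnames(m), k)
}

#' Standardized effect size against a null distribution
#'
#' `(observed - mean(null)) / sd(null)` with the sample standard deviation.
#' A zero-spread null yields SES 0 with `degenerate = TRUE` rather than an
#' error: it occurs legitimately when a plot equals the species pool.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of at least 2 randomized values.
#' @return List with `ses`, `null_mean`, `null_sd`, `degenerate`.
#' @export
ses <- function(observed, null_values) {
  if (length(null_values) < 2) stop("need at least 2 null values")
  mu <- mean(null_values)
  sdev <- sd(null_values)
  if (sdev == 0) {
    return(list(ses = 0, null_mean = mu, null_sd = 0, degenerate = TRUE))
  }
  list(ses = (observed - mu) / sdev, null_mean = mu, null_sd = sdev,
       degenerate = FALSE)
}

#' Bundle an observed statistic with its randomized values
#'
#' @param statistic Statistic name (e.g. `"MPD"`).
#' @param observed Observed value.
#' @param null_values Randomized values.
#' @param alpha Two-tailed level used for the stored flag.
#' @param seed Seed recorded for provenance.
#' @return An object of class `"null_distribution"` with fields `statistic`,
#'   `observed`, `null_values`, `null_mean`, `null_sd`, `ses`, `degenerate`,
#'   `flag`, `seed`.
#' @export
null_distribution <- function(statistic, observed, null_values,
                              alpha = 0.05, seed = NA_integer_) {
  s <- ses(observed, null_values)
  nd <- structure(
    list(statistic = statistic, observed = observed,
         null_values = null_values, null_mean = s$null_mean,
         null_sd = s$null_sd, ses = s$ses, degenerate = s$degenerate,
         flag = NA_character_, seed = seed),
    class = "null_distribution"
  )
  nd$flag <- significance_two_tailed(nd, alpha = alpha)
  nd
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("%s: observed %.4g, null %.4g +/- %.4g, SES %.3f [%s]%s\n",
              x$statistic, x$observed, x$null_mean, x$null_sd, x$ses, x$flag,
              if (x$degenerate) " (degenerate null)" else ""))
  invisible(x)
}

#' Two-tailed randomization significance flag
#'
#' Ranks the observed value within the reference set `{nulls, observed}`
#' (n_rand + 1 values, midranks for ties). The flag is `"high"` when the
#' quantile position exceeds `1 - alpha/2`, `"low"` when it is below
#' `alpha/2`, else `"none"`.
#'
#' @param nd A `"null_distribution"` object (or a list with `observed` and
#'   `null_values`).
#' @param alpha Two-tailed level, default 0.05 (2.5% in each tail).
#' @return `"high"`, `"low"` or `"none"`.
#' @export
significance_two_tailed <- function(nd, alpha = 0.05) {
  obs <- nd$observed
  nulls <- nd$null_values
  n <- length(nulls) + 1
  k_less <- sum(nulls < obs)
  k_eq <- sum(nulls == obs)
  midrank <- k_less + (k_eq + 2) / 2   # rank of obs among {nulls, obs}
  q <- midrank / n
  if (q > 1 - alpha / 2) "high" else if (q < alpha / 2) "low" else "none"
}

# Generate n_rand independent-swap null matrices from the original matrix,
# each by a fresh chain seeded from the current RNG stream.
swap_null_matrices <- function(m, n_rand, swap_multiplier = 10) {
  mi <- m
  storage.mode(mi) <- "integer"
  attempts <- as.integer(swap_multiplier * nrow(m) * ncol(m))
  lapply(seq_len(n_rand), function(i) cpp_independent_swap(mi, attempts))
}

# MPD / MNTD from a precomputed distance matrix and integer species indices.
mpd_idx <- function(d, idx) {
  k <- length(idx)
  sum(d[idx, idx]) / (k * (k - 1))
}
mntd_idx <- function(d, idx) {
  s <- d[idx, idx]
  diag(s) <- Inf
  mean(apply(s, 1, min))
}

# Null species-index sets for one plot: list of integer vectors, one per trial.
null_index_sets <- function(m, plot, n_rand, null, swap_multiplier, seed) {
  set.seed(seed)
  if (null == "independent_swap") {
    mats <- swap_null_matrices(m, n_rand, swap_multiplier)
    lapply(mats, function(x) which(x[match(plot, rownames(m)), ] == 1))
  } else {
    k <- sum(m[plot, ])
    lapply(seq_len(n_rand), function(i) sample.int(ncol(m), k))
  }
}

nri_nti_one <- function(tree, m, plot, n_rand, null, seed, swap_multiplier,
                        which_stat, alpha = 0.05) {
  check_community(m)
  check_tree(tree)
  if (!plot %in% rownames(m)) stop("unknown plot id: ", plot)
  if (sum(m[plot, ]) < 2) {
    stop(which_stat, " is undefined for plots with fewer than 2 species")
  }
  d <- patristic_matrix(tree)[colnames(m), colnames(m)]
  obs_idx <- which(m[plot, ] == 1)
  stat_fun <- if (which_stat == "NRI") mpd_idx else mntd_idx
  obs <- stat_fun(d, obs_idx)
  sets <- null_index_sets(m, plot, n_rand, null, swap_multiplier, seed)
  nulls <- vapply(sets, function(ix) stat_fun(d, ix), numeric(1))
  base <- if (which_stat == "NRI") "MPD" else "MNTD"
  nd <- null_distribution(base, obs, nulls, alpha = alpha, seed = seed)
  nd$statistic <- which_stat
  nd$ses <- -1 * nd$ses   # NRI/NTI are -1 x SES of MPD/MNTD
  nd
}

#' Net relatedness index (NRI)
#'
#' `-1 * SES(MPD)` against the chosen null; positive values indicate
#' phylogenetic clustering (co-occurring species more closely related than
#' expected), negative values overdispersion. The returned
#' `"null_distribution"` carries the raw MPD null values; its `ses` field is
#' the NRI and its `flag` the two-tailed significance of the observed MPD.
#'
#' @param tree A `"phylo"` object covering the species pool.
#' @param m Community matrix.
#' @param plot Plot id with richness >= 2.
#' @param n_rand Number of randomizations (default 999).
#' @param null `"independent_swap"` (default) or `"richness"`.
#' @param seed Integer seed for the null stream.
#' @param swap_multiplier Attempted swaps per chain = multiplier x rows x cols.
#' @param alpha Two-tailed level for the stored flag.
#' @return A `"null_distribution"` with `statistic = "NRI"`.
#' @export
nri <- function(tree, m, plot, n_rand = 999,
                null = c("independent_swap", "richness"), seed = 1,
                swap_multiplier = 10, alpha = 0.05) {
  nri_nti_one(tree, m, plot, n_rand, match.arg(null), seed, swap_multiplier,
              "NRI", alpha)
}

#' Nearest taxon index (NTI)
#'
#' `-1 * SES(MNTD)`; quantifies terminal clustering. See [nri()] for
#' interpretation and arguments.
#'
#' @inheritParams nri
#' @return A `"null_distribution"` with `statistic = "NTI"`.
#' @export
nti <- function(tree, m, plot, n_rand = 999,
                null = c("independent_swap", "richness"), seed = 1,
                swap_multiplier = 10, alpha = 0.05) {
  nri_nti_one(tree, m, plot, n_rand, match.arg(null), seed, swap_multiplier,
              "NTI", alpha)
}

#' Configuration for [structure_analysis()]
#'
#' @param n_rand Randomization trials per null (default 999).
#' @param alpha Two-tailed significance level (default 0.05: top/bottom 2.5%).
#' @param null_nri Null model for NRI/NTI (`"independent_swap"` default).
#' @param null_pd Null model for PD/RPD significance (`"richness"` default:
#'   uniform pool draws preserving per-plot richness).
#' @param swap_multiplier Attempted swaps per chain = multiplier x rows x cols.
#' @param pd_convention `"proportional"` (default; PD / total tree length) or
#'   `"raw"` for the `PD` column of the metric table.
#' @param seed Master seed; per-plot streams are derived from it.
#' @return A list of class `"structure_config"`.
#' @export
structure_config <- function(n_rand = 999, alpha = 0.05,
                             null_nri = c("independent_swap", "richness"),
                             null_pd = c("richness", "independent_swap"),
                             swap_multiplier = 10,
                             pd_convention = c("proportional", "raw"),
                             seed = 1) {
  stopifnot(n_rand >= 2, alpha > 0, alpha < 0.5)
  structure(
    list(n_rand = n_rand, alpha = alpha, null_nri = match.arg(null_nri),
         null_pd = match.arg(null_pd), swap_multiplier = swap_multiplier,
         pd_convention = match.arg(pd_convention), seed = as.integer(seed)),
    class = "structure_config"
  )
}

#' Per-plot phylogenetic structure analysis with randomization nulls
#'
#' For every plot: PD and RPD with two-tailed significance flags under the
#' PD null, and NRI / NTI with flags under their null, each from
#' `config$n_rand` randomizations. One set of independent-swap null matrices
#' (fresh chain each, from the original matrix) is shared across plots; the
#' richness-preserving pool draws use a per-plot stream derived from the
#' master seed, so results are reproducible and independent of plot order.
#'
#' @param tree A `"phylo"` object covering all species in `m`.
#' @param m Community matrix.
#' @param config A [structure_config()].
#' @return A list of class `"structure_analysis"` with `metric_table` (one
#'   row per plot: SR, PD, RPD, NRI, NTI and their flags), `diagnostics`
#'   (per plot and statistic: observed, null mean/sd, SES, flag, degeneracy,
#'   seed) and `config`.
#' @export
structure_analysis <- function(tree, m, config = structure_config()) {
  check_tree(tree)
  check_community(m)
  sp <- colnames(m)
  idx <- tip_index(tree, sp)
  inc <- edge_tip_incidence(tree)[, idx, drop = FALSE]
  bl <- tree$edge.length
  tot <- sum(bl)
  l_eq <- tot / nrow(tree$edge)
  d <- patristic_matrix(tree)[sp, sp]
  n_rand <- config$n_rand
  plots <- rownames(m)

  # shared swap-null index sets per plot (used by whichever statistics ask)
  need_swap <- "independent_swap" %in% c(config$null_nri, config$null_pd)
  swap_sets <- NULL
  if (need_swap) {
    set.seed(derive_seed(config$seed, "swap"))
    mats <- swap_null_matrices(m, n_rand, config$swap_multiplier)
    swap_sets <- lapply(plots, function(p) {
      i <- match(p, plots)
      lapply(mats, function(x) which(x[i, ] == 1))
    })
    names(swap_sets) <- plots
  }
  pool_sets_for <- function(p, k) {
    set.seed(derive_seed(config$seed, paste0("pool/", p)))
    lapply(seq_len(n_rand), function(i) sample.int(length(sp), k))
  }

  # returns c(spanning length, spanning edge count)
  pd_fun <- function(ix) {
    sel <- rowSums(inc[, ix, drop = FALSE]) > 0
    c(sum(bl[sel]), sum(sel))
  }

  rows <- list()
  diags <- list()
  for (p in plots) {
    obs_idx <- which(m[p, ] == 1)
    k <- length(obs_idx)
    obs_pd <- pd_fun(obs_idx)
    pd_raw <- obs_pd[1]
    rpd_obs <- pd_raw / (obs_pd[2] * l_eq)

    pd_seed <- derive_seed(config$seed, paste0("pool/", p))
    pd_sets <- if (config$null_pd == "richness") {
      pool_sets_for(p, k)
    } else {
      swap_sets[[p]]
    }
    null_pd_vals <- vapply(pd_sets, pd_fun, numeric(2))
    nd_pd <- null_distribution("PD", pd_raw, null_pd_vals[1, ],
                               alpha = config$alpha, seed = pd_seed)
    nd_rpd <- null_distribution(
      "RPD", rpd_obs,
      null_pd_vals[1, ] / (null_pd_vals[2, ] * l_eq),
      alpha = config$alpha, seed = pd_seed)

    if (k >= 2) {
      nri_sets <- if (config$null_nri == "independent_swap") {
        swap_sets[[p]]
      } else {
        pool_sets_for(p, k)
      }
      nri_seed <- if (config$null_nri == "independent_swap") {
        derive_seed(config$seed, "swap")
      } else {
        pd_seed
      }
      obs_mpd <- mpd_idx(d, obs_idx)
      obs_mntd <- mntd_idx(d, obs_idx)
      nd_nri <- null_distribution(
        "NRI", obs_mpd, vapply(nri_sets, function(ix) mpd_idx(d, ix), 0),
        alpha = config$alpha, seed = nri_seed)
      nd_nri$ses <- -1 * nd_nri$ses
      nd_nti <- null_distribution(
        "NTI", obs_mntd, vapply(nri_sets, function(ix) mntd_idx(d, ix), 0),
        alpha = config$alpha, seed = nri_seed)
      nd_nti$ses <- -1 * nd_nti$ses
    } else {
      nd_nri <- nd_nti <- NULL
    }

    rows[[p]] <- data.frame(
      plot = p, SR = k,
      PD = if (config$pd_convention == "proportional") pd_raw / tot else pd_raw,
      PD_raw = pd_raw, PD_prop = pd_raw / tot, RPD = rpd_obs,
      NRI = if (is.null(nd_nri)) NA_real_ else nd_nri$ses,
      NTI = if (is.null(nd_nti)) NA_real_ else nd_nti$ses,
      pd_flag = nd_pd$flag, rpd_flag = nd_rpd$flag,
      nri_flag = if (is.null(nd_nri)) NA_character_ else nd_nri$flag,
      nti_flag = if (is.null(nd_nti)) NA_character_ else nd_nti$flag,
      stringsAsFactors = FALSE)

    for (nd in Filter(Negate(is.null), list(nd_pd, nd_rpd, nd_nri, nd_nti))) {
      diags[[length(diags) + 1L]] <- data.frame(
        plot = p, statistic = nd$statistic, observed = nd$observed,
        null_mean = nd$null_mean, null_sd = nd$null_sd, ses = nd$ses,
        flag = nd$flag, degenerate = nd$degenerate, seed = nd$seed,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(metric_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         diagnostics = do.call(rbind, c(diags, list(make.row.names = FALSE))),
         config = config),
    class = "structure_analysis"
  )
}

#' @export
print.structure_analysis <- function(x, ...) {
  mt <- x$metric_table
  cat("Phylogenetic structure analysis:", nrow(mt), "plots,",
      x$config$n_rand, "randomizations\n")
  cat(" significant flags: PD", sum(mt$pd_flag != "none"),
      "| RPD", sum(mt$rpd_flag != "none"),
      "| NRI", sum(mt$nri_flag != "none", na.rm = TRUE),
      "| NTI", sum(mt$nti_flag != "none", na.rm = TRUE), "\n")
  invisible(x)
}
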