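# Alpha and beta phylogenetic diversity statistics. All are incidence-based.
# PD uses the rooted convention: the spanning branch set includes the path
# from the tip set's MRCA up to the root, so PD of the full tip set equals
# the total tree length exactly and PD is monotone under tip-set inclusion.

#' Faith's phylogenetic diversity of a tip set
#'
#' Total length of the branches connecting the tips, including the path from
#' their MRCA to the root (rooted convention).
#'
#' @param tree A `"phylo"` object.
#' @param tips Non-empty character vector of tip labels.
#' @return PD in branch-length units; equals `total_branch_length(tree)` when
#'   `tips` covers every tip.
#' @export
faith_pd <- function(tree, tips) {
  spanning_branch_set(tree, tips)$total
}

#' Proportional phylogenetic diversity
#'
#' `faith_pd / total_branch_length`, a dimensionless value in (0, 1]. This is
#' the scale on which the bundled Tianshan reference table reports PD
#' (values 0.1082–0.1741 on a tree dated in Ma).
#'
#' @inheritParams faith_pd
#' @return Scalar in (0, 1].
#' @export
pd_proportional <- function(tree, tips) {
  faith_pd(tree, tips) / total_branch_length(tree)
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Mean patristic distance over all unordered pairs of tips in the set.
#'
#' @inheritParams faith_pd
#' @param tips At least two tip labels.
#' @export
mpd <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) < 2) stop("MPD is undefined for fewer than 2 tips")
  d <- patristic_matrix(tree)[tips, tips]
  mean(d[upper.tri(d)])
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean, over tips in the set, of the minimum patristic distance to any other
#' tip in the set.
#'
#' @inheritParams mpd
#' @export
mntd <- function(tree, tips) {
  tips <- unique(tips)
  if (length(tips) < 2) stop("MNTD is undefined for fewer than 2 tips")
  d <- patristic_matrix(tree)[tips, tips]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' PhyloSor phylogenetic similarity between two tip sets
#'
#' Shared spanning-branch length divided by the average of the two sets'
#' spanning-branch lengths: `BL_shared / (0.5 * (BL_A + BL_B))`, in [0, 1],
#' symmetric, and 1 when the sets coincide. Zero-length branches contribute
#' nothing; a pair with zero total spanning length is rejected.
#'
#' @param tree A `"phylo"` object.
#' @param tipsA,tipsB Non-empty character vectors of tip labels.
#' @export
phylosor <- function(tree, tipsA, tipsB) {
  check_tree(tree)
  if (length(tipsA) == 0 || length(tipsB) == 0) {
    stop("both tip sets must be non-empty")
  }
  ia <- tip_index(tree, unique(tipsA))
  ib <- tip_index(tree, unique(tipsB))
  inc <- edge_tip_incidence(tree)
  bl <- tree$edge.length
  sa <- rowSums(inc[, ia, drop = FALSE]) > 0
  sb <- rowSums(inc[, ib, drop = FALSE]) > 0
  bla <- sum(bl[sa])
  blb <- sum(bl[sb])
  if (bla + blb == 0) stop("both tip sets span zero branch length")
  sum(bl[sa & sb]) / (0.5 * (bla + blb))
}

#' Pairwise PhyloSor matrix for a community matrix
#'
#' @param tree A `"phylo"` object covering all species in `m`.
#' @param m Community matrix.
#' @return Symmetric plot x plot matrix with unit diagonal.
#' @export
phylosor_matrix <- function(tree, m) {
  check_tree(tree)
  check_community(m)
  sp <- colnames(m)
  idx <- tip_index(tree, sp)
  inc <- edge_tip_incidence(tree)[, idx, drop = FALSE]
  bl <- tree$edge.length
  # span[e, p]: edge e is on some root-to-tip path of plot p's species
  span <- (inc %*% t(m)) > 0
  pd <- colSums(span * bl)
  if (any(pd == 0)) stop("plot(s) spanning zero branch length")
  shared <- crossprod(span * bl, span)   # shared spanning length per plot pair
  ps <- shared / (0.5 * outer(pd, pd, "+"))
  dimnames(ps) <- list(rownames(m), rownames(m))
  ps
}

#' Relative phylogenetic diversity (RPD)
#'
#' Faith's PD of the tip set on the actual tree divided by its PD on the
#' equal-branch-length comparison tree of [equalize_branch_lengths()].
#' Values above 1 signal over-representation of long branches
#' (overdispersion); below 1, of short branches (clustering).
#'
#' @inheritParams faith_pd
#' @export
rpd <- function(tree, tips) {
  bs <- spanning_branch_set(tree, tips)
  l_eq <- total_branch_length(tree) / nrow(tree$edge)
  bs$total / (length(bs$edges) * l_eq)
}

#' Per-plot diversity table
#'
#' SR, raw and proportional PD, MPD, MNTD and RPD for every plot of a
#' community matrix. MPD and MNTD are `NA` (not 0) for single-species plots;
#' the statistics are undefined there and silent zeros would bias nulls.
#'
#' @param tree A `"phylo"` object covering all species in `m`.
#' @param m Community matrix.
#' @return A data.frame with one row per plot.
#' @export
per_plot_diversity <- function(tree, m) {
  check_tree(tree)
  check_community(m)
  sp <- colnames(m)
  idx <- tip_index(tree, sp)
  inc <- edge_tip_incidence(tree)[, idx, drop = FALSE]
  bl <- tree$edge.length
  tot <- sum(bl)
  l_eq <- tot / nrow(tree$edge)
  d <- patristic_matrix(tree)[sp, sp]
  out <- lapply(rownames(m), function(p) {
    pres <- which(m[p, ] == 1)
    sel <- rowSums(inc[, pres, drop = FALSE]) > 0
    pd_raw <- sum(bl[sel])
    k <- length(pres)
    if (k >= 2) {
      dp <- d[pres, pres]
      mpd_v <- mean(dp[upper.tri(dp)])
      diag(dp) <- Inf
      mntd_v <- mean(apply(dp, 1, min))
    } else {
      mpd_v <- NA_real_
      mntd_v <- NA_real_
    }
    data.frame(plot = p, SR = k, PD_raw = pd_raw, PD_prop = pd_raw / tot,
               MPD = mpd_v, MNTD = mntd_v,
               RPD = pd_raw / (sum(sel) * l_eq),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
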