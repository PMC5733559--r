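# Shared fixtures and independent oracles. The oracles deliberately take a
# different route from the package implementation: edge membership through
# phangorn::Descendants, distances through ape's cophenetic method, and
# explicit pair loops.

toy4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
toy3 <- function() parse_newick("((A:3,B:1):1,C:4):0;")

random_tree <- function(n) ape::rtree(n)

# Edge e is spanned (rooted convention) iff any tip below its child is in the set.
oracle_edge_in_span <- function(tree, tips) {
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  vapply(desc, function(d) any(tree$tip.label[d] %in% tips), logical(1))
}

oracle_pd <- function(tree, tips) {
  sum(tree$edge.length[oracle_edge_in_span(tree, tips)])
}

oracle_phylosor <- function(tree, a, b) {
  sa <- oracle_edge_in_span(tree, a)
  sb <- oracle_edge_in_span(tree, b)
  bl <- tree$edge.length
  sum(bl[sa & sb]) / (0.5 * (sum(bl[sa]) + sum(bl[sb])))
}

oracle_mpd <- function(tree, tips) {
  d <- stats::cophenetic(tree)[tips, tips]
  vals <- numeric(0)
  for (i in 2:length(tips)) {
    for (j in 1:(i - 1)) vals <- c(vals, d[i, j])
  }
  mean(vals)
}

oracle_mntd <- function(tree, tips) {
  d <- stats::cophenetic(tree)[tips, tips]
  mins <- numeric(length(tips))
  for (i in seq_along(tips)) mins[i] <- min(d[i, -i])
  mean(mins)
}

# Exhaustive equal-richness null: SES of a statistic over ALL k-subsets of the
# pool (the reference distribution sampled nulls must converge to).
oracle_exhaustive_ses <- function(tree, pool, k, obs_tips, stat_fun) {
  subsets <- combn(pool, k, simplify = FALSE)
  vals <- vapply(subsets, function(s) stat_fun(tree, s), numeric(1))
  obs <- stat_fun(tree, obs_tips)
  (obs - mean(vals)) / sd(vals)
}

# A small deterministic community matrix on a given tree.
small_community <- function(tree, n_plots, k, seed) {
  set.seed(seed)
  sp <- tree$tip.label
  m <- t(vapply(seq_len(n_plots), function(i) {
    row <- integer(length(sp))
    row[sample.int(length(sp), k)] <- 1L
    row
  }, integer(length(sp))))
  dimnames(m) <- list(sprintf("P%02d", seq_len(n_plots)), sp)
  m
}
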