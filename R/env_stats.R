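# Group comparison, environment correlation screen, and distance decay of
# phylogenetic similarity.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midranks for ties. The p-value is exact (full
#' enumeration of rank assignments, doubling rule) when `n1 + n2 <= 12` and
#' there are no ties, otherwise a normal approximation with tie correction
#' and continuity correction is used. `U` is the statistic of the first
#' group, in `[0, n1 * n2]`.
#'
#' @param valuesA,valuesB Numeric vectors, both non-empty.
#' @return An object of class `"group_comparison"`: list with `U`, `n1`,
#'   `n2`, `p_value`, `direction` (`"A>B"`, `"A<B"`, `"none"`), `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(valuesA, valuesB) {
  if (length(valuesA) < 1 || length(valuesB) < 1) {
    stop("both groups must contain at least one value")
  }
  n1 <- length(valuesA)
  n2 <- length(valuesB)
  all_v <- c(valuesA, valuesB)
  r <- rank(all_v)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(all_v) > 0
  if (length(unique(all_v)) == 1) {
    warning("all values identical across both groups; p = 1")
    return(structure(list(U = mu, n1 = n1, n2 = n2, p_value = 1,
                          direction = "none", method = "degenerate"),
                     class = "group_comparison"))
  }
  if (n1 + n2 <= 12 && !ties) {
    # exact: enumerate every assignment of n1 ranks out of n1 + n2
    combos <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p_less <- mean(u_all <= u1)
    p_greater <- mean(u_all >= u1)
    p <- min(1, 2 * min(p_less, p_greater))
    method <- "exact"
  } else {
    n <- n1 + n2
    tie_tab <- table(all_v)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(
    list(U = u1, n1 = n1, n2 = n2, p_value = p,
         direction = if (u1 > mu) "A>B" else if (u1 < mu) "A<B" else "none",
         method = method),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g (%s), %s\n",
              x$U, x$n1, x$n2, x$p_value, x$method, x$direction))
  invisible(x)
}

# Correlation coefficient and two-sided p via the t distribution.
cor_with_p <- function(x, y, method = "pearson") {
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  if (abs(r) >= 1) return(c(r = sign(r), p = 0))
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(t_stat), df = n - 2))
}

#' Correlation screen of species richness against environment and refugia
#'
#' Correlates per-plot SR with each of the 25 environmental variables and
#' with the refugium indicator (refugial = 1, colonizing = 0; with Pearson
#' this is the point-biserial coefficient). Per-variable two-sided p-values
#' are starred at 0.05 and 0.01 without multiple-testing correction, and a
#' Benjamini-Hochberg q column is added for transparency. Zero-variance
#' variables yield `NA` with `note = "zero variance"`.
#'
#' @param sr Named numeric vector of per-plot richness, aligned to
#'   `site_table$plot` (names are matched when present).
#' @param site_table Site table with the 25 environmental columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data.frame with columns `variable`, `r`, `p`, `stars`, `q`, `note`.
#' @export
correlation_screen <- function(sr, site_table,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_sites(site_table, require_env = TRUE)
  if (!is.null(names(sr))) {
    if (!setequal(names(sr), site_table$plot)) {
      stop("plot ids of `sr` do not match the site table")
    }
    sr <- sr[site_table$plot]
  } else if (length(sr) != nrow(site_table)) {
    stop("`sr` length does not match the site table")
  }
  vars <- c(env_variable_names(), "refugium")
  vals <- site_table[, env_variable_names(), drop = FALSE]
  vals$refugium <- as.numeric(site_table$group == "refugial")
  out <- do.call(rbind, lapply(vars, function(v) {
    rp <- cor_with_p(as.numeric(vals[[v]]), as.numeric(sr), method)
    data.frame(variable = v, r = rp[["r"]], p = rp[["p"]],
               stringsAsFactors = FALSE)
  }))
  out$stars <- ifelse(is.na(out$p), "",
                      ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", "")))
  out$q <- p.adjust(out$p, method = "BH")
  out$note <- ifelse(is.na(out$r), "zero variance", "")
  out
}

#' Great-circle distance in kilometres (haversine)
#'
#' Spherical Earth of radius 6371 km; vectorized over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * 6371 * asin(sqrt(a))
}

#' Pairwise geographic distance matrix for a site table
#'
#' @param site_table Site table with `plot`, `lat`, `lon`.
#' @return Symmetric plot x plot matrix of great-circle distances (km).
#' @export
geographic_distance_matrix <- function(site_table) {
  check_sites(site_table)
  n <- nrow(site_table)
  d <- matrix(0, n, n, dimnames = list(site_table$plot, site_table$plot))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_km(site_table$lat[i], site_table$lon[i],
                                       site_table$lat[j], site_table$lon[j])
  }
  d
}

#' Standardized environmental distance matrix
#'
#' Each of the 25 environmental variables is z-scored across plots, then
#' plot pairs are compared by Euclidean distance. Standardization is needed
#' because the variables mix units (m, degrees C, mm, soil indices);
#' zero-variance variables are dropped with a warning.
#'
#' @param site_table Site table with the 25 environmental columns.
#' @return Symmetric, zero-diagonal plot x plot matrix (dimensionless).
#' @export
environmental_distance <- function(site_table) {
  check_sites(site_table, require_env = TRUE)
  ev <- as.matrix(site_table[, env_variable_names(), drop = FALSE])
  sds <- apply(ev, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance environmental variable(s): ",
            paste(colnames(ev)[sds == 0], collapse = ", "))
    ev <- ev[, sds > 0, drop = FALSE]
  }
  z <- scale(ev)
  d <- as.matrix(dist(z))
  dimnames(d) <- list(site_table$plot, site_table$plot)
  d
}

#' Mantel permutation test
#'
#' Pearson correlation between the lower triangles of two square distance (or
#' similarity) matrices, with significance from joint row/column permutations
#' of the second matrix. The p-value is two-sided on |r| by default; pairwise
#' values are non-independent, so this replaces naive regression p-values.
#'
#' @param x,y Square matrices with identical dimnames/order.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(x, y, n_perm = 999, seed = NULL,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!identical(dim(x), dim(y))) stop("matrices must have identical dimensions")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  lt <- lower.tri(x)
  xv <- x[lt]
  r_obs <- cor(xv, y[lt])
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    r_p <- cor(xv, y[p, p][lt])
    hit <- switch(alternative,
                  two.sided = abs(r_p) >= abs(r_obs),
                  less = r_p <= r_obs,
                  greater = r_p >= r_obs)
    if (isTRUE(hit)) hits <- hits + 1L
  }
  list(r = r_obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Distance decay of PhyloSor against geographic and environmental distance
#'
#' Builds the unordered plot-pair table and, for each distance axis, reports
#' the Pearson correlation, least-squares slope of PhyloSor on distance, and
#' a Mantel permutation p-value. A constant PhyloSor matrix yields slope 0
#' and `r = NA` with a note.
#'
#' @param phylosor_m Plot x plot PhyloSor matrix.
#' @param geo_m Plot x plot geographic distance matrix (km).
#' @param env_m Plot x plot environmental distance matrix.
#' @param n_perm Mantel permutations (default 999).
#' @param seed Optional seed for the permutations.
#' @return List of class `"distance_decay"` with `pairs` (plot_a, plot_b,
#'   phylosor, geo_km, env_dist) and `summary` (per axis: `r`, `slope`,
#'   `mantel_p`, `note`).
#' @export
distance_decay <- function(phylosor_m, geo_m, env_m, n_perm = 999,
                           seed = NULL) {
  plots <- rownames(phylosor_m)
  if (!identical(plots, rownames(geo_m)) || !identical(plots, rownames(env_m))) {
    stop("matrices are not aligned on the same plot ordering")
  }
  lt <- which(lower.tri(phylosor_m), arr.ind = TRUE)
  pairs <- data.frame(
    plot_a = plots[lt[, 2]], plot_b = plots[lt[, 1]],
    phylosor = phylosor_m[lower.tri(phylosor_m)],
    geo_km = geo_m[lower.tri(geo_m)],
    env_dist = env_m[lower.tri(env_m)],
    stringsAsFactors = FALSE
  )
  one_axis <- function(dm, tag) {
    ps <- pairs$phylosor
    dv <- dm[lower.tri(dm)]
    if (sd(ps) == 0) {
      return(list(r = NA_real_, slope = 0, mantel_p = NA_real_,
                  note = "constant PhyloSor"))
    }
    if (sd(dv) == 0) {
      return(list(r = NA_real_, slope = 0, mantel_p = NA_real_,
                  note = "constant distance"))
    }
    mt <- mantel_test(phylosor_m, dm, n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, tag))
    list(r = mt$r, slope = sum((dv - mean(dv)) * (ps - mean(ps))) /
           sum((dv - mean(dv))^2),
         mantel_p = mt$p_value, note = "")
  }
  structure(
    list(pairs = pairs,
         summary = list(geographic = one_axis(geo_m, "geo"),
                        environmental = one_axis(env_m, "env"))),
    class = "distance_decay"
  )
}

#' @export
print.distance_decay <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Distance decay over %d plot pairs\n", nrow(x$pairs)))
  cat(sprintf("  geographic:    r = %.3f, slope = %.3g, Mantel p = %.3f\n",
              s$geographic$r, s$geographic$slope, s$geographic$mantel_p))
  cat(sprintf("  environmental: r = %.3f, slope = %.3g, Mantel p = %.3f\n",
              s$environmental$r, s$environmental$slope, s$environmental$mantel_p))
  invisible(x)
}
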