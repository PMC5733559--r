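test_that("mann_whitney_u matches exact enumeration and wilcox.test", {
  gc <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$U, 0)
  expect_equal(gc$p_value, 0.1)
  expect_equal(gc$direction, "A<B")

  expect_warning(gc2 <- mann_whitney_u(c(5, 5), c(5, 5)), "identical")
  expect_equal(gc2$p_value, 1)

  # exact agreement with wilcox.test for tie-free inputs, n1 + n2 <= 10
  set.seed(61)
  for (i in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(1:50, n1)
    y <- sample(setdiff(1:50, x), n2)
    mine <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$U, unname(ref$statistic))
    expect_gte(mine$U, 0)
    expect_lte(mine$U, n1 * n2)
  }

  # normal approximation with ties tracks wilcox.test's corrected z-test
  set.seed(62)
  for (i in 1:10) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(2:8, 15, replace = TRUE)
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("correlation_screen recovers signals and matches brute force", {
  st <- generate_study(sim_config(seed = 63))
  sr <- richness(st$community)
  scr <- correlation_screen(sr, st$sites)
  expect_equal(nrow(scr), 26)
  expect_true("refugium" %in% scr$variable)
  # generator plants a refugial richness shift: indicator must be recovered
  ref_row <- scr[scr$variable == "refugium", ]
  expect_gt(ref_row$r, 0)
  expect_lt(ref_row$p, 0.05)

  # brute-force r agreement
  v <- st$sites$bio01
  r_brute <- sum((v - mean(v)) * (sr - mean(sr))) /
    sqrt(sum((v - mean(v))^2) * sum((sr - mean(sr))^2))
  expect_equal(scr$r[scr$variable == "bio01"], r_brute, tolerance = 1e-12)

  # perfect linearity
  s2 <- st$sites
  s2$altitude <- as.numeric(sr[s2$plot]) * 3 + 10
  scr2 <- correlation_screen(sr, s2)
  expect_equal(scr2$r[scr2$variable == "altitude"], 1, tolerance = 1e-12)
  expect_equal(scr2$p[scr2$variable == "altitude"], 0)

  # zero variance flagged, not fatal
  s3 <- st$sites
  s3$soil_depth <- 5
  scr3 <- correlation_screen(sr, s3)
  expect_true(is.na(scr3$r[scr3$variable == "soil_depth"]))
  expect_equal(scr3$note[scr3$variable == "soil_depth"], "zero variance")

  # spearman route
  scr4 <- correlation_screen(sr, st$sites, method = "spearman")
  expect_equal(scr4$r[scr4$variable == "bio01"],
               cor(st$sites$bio01, as.numeric(sr[st$sites$plot]),
                   method = "spearman"),
               tolerance = 1e-12)
})

test_that("haversine_km is a bounded metric with known values", {
  expect_equal(haversine_km(43, 85, 43, 85), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_error(haversine_km(91, 0, 0, 0), "out of range")
  set.seed(64)
  for (i in 1:20) {
    p <- runif(4, -80, 80)
    expect_equal(haversine_km(p[1], p[2], p[3], p[4]),
                 haversine_km(p[3], p[4], p[1], p[2]))
    expect_lte(haversine_km(p[1], p[2], p[3], p[4]), pi * 6371)
  }
})

test_that("environmental_distance is a standardized Euclidean metric", {
  st <- generate_study(sim_config(seed = 65))
  d <- environmental_distance(st$sites)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # brute-force oracle on a random pair
  ev <- as.matrix(st$sites[, env_variable_names()])
  z <- apply(ev, 2, function(col) (col - mean(col)) / sd(col))
  expect_equal(d[3, 17], sqrt(sum((z[3, ] - z[17, ])^2)), tolerance = 1e-9)
  # triangle inequality on sampled triples
  set.seed(65)
  for (i in 1:30) {
    ijk <- sample(nrow(d), 3)
    expect_gte(d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9,
               d[ijk[1], ijk[3]])
  }

  # two plots one sd apart in exactly one varying variable -> distance 1
  s <- st$sites[1:3, ]
  for (v in env_variable_names()) s[[v]] <- 0
  s$altitude <- c(0, 5, 10)   # sd is exactly 5
  expect_warning(d2 <- environmental_distance(s), "zero-variance")
  expect_equal(d2[1, 2], 1)

  # identical environments -> zero distance
  s4 <- st$sites
  s4[2, env_variable_names()] <- s4[1, env_variable_names()]
  expect_equal(environmental_distance(s4)[1, 2], 0)
})

test_that("mantel_test matches vegan's statistic and detects strong structure", {
  set.seed(66)
  n <- 20
  xy <- cbind(runif(n), runif(n))
  geo <- as.matrix(dist(xy))
  sim <- exp(-3 * geo) + matrix(rnorm(n * n, 0, 0.01), n, n)
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  mt <- mantel_test(sim, geo, n_perm = 499, seed = 1)
  ref <- vegan::mantel(as.dist(sim), as.dist(geo), permutations = 99)
  expect_equal(mt$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(mt$p_value, 0.05)
  # pure noise: p should be comfortably non-significant at this fixed seed
  noise <- matrix(rnorm(n * n), n, n)
  noise <- (noise + t(noise)) / 2
  mt2 <- mantel_test(noise, geo, n_perm = 499, seed = 2)
  expect_gt(mt2$p_value, 0.05)
})

test_that("distance_decay builds the pair table and flags degenerate input", {
  st <- generate_study(sim_config(seed = 67))
  ps <- phylosor_matrix(st$tree, st$community)
  geo <- geographic_distance_matrix(st$sites)
  env <- environmental_distance(st$sites)
  dd <- distance_decay(ps, geo, env, n_perm = 199, seed = 67)
  expect_equal(nrow(dd$pairs), choose(35, 2))
  expect_named(dd$summary, c("geographic", "environmental"))
  expect_true(is.finite(dd$summary$geographic$slope))

  const <- ps
  const[] <- 0.5
  dd2 <- distance_decay(const, geo, env, n_perm = 99)
  expect_true(is.na(dd2$summary$geographic$r))
  expect_equal(dd2$summary$geographic$slope, 0)
  expect_equal(dd2$summary$geographic$note, "constant PhyloSor")

  expect_error(distance_decay(ps, geo[c(2:35, 1), c(2:35, 1)], env), "aligned")
})
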