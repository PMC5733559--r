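test_that("simulate_yule_tree yields labelled ultrametric trees at depth", {
  tr <- simulate_yule_tree(5, 20, seed = 71)
  expect_equal(length(tr$tip.label), 5)
  expect_equal(anyDuplicated(tr$tip.label), 0)
  expect_true(is_ultrametric(tr))
  inc <- phylocomm:::edge_tip_incidence(tr)
  expect_equal(max(colSums(inc * tr$edge.length)), 20, tolerance = 1e-9)

  expect_identical(write_newick(simulate_yule_tree(12, 110, seed = 5)),
                   write_newick(simulate_yule_tree(12, 110, seed = 5)))
  expect_error(simulate_yule_tree(1, 10), "n_tips")
  # study scale
  big <- simulate_yule_tree(92, 110, seed = 72)
  expect_equal(length(big$tip.label), 92)
  expect_true(is_ultrametric(big))
})

test_that("simulate_bm_trait is deterministic with phylogenetic signal", {
  tr <- simulate_yule_tree(40, 50, seed = 73)
  expect_identical(simulate_bm_trait(tr, 1, seed = 1),
                   simulate_bm_trait(tr, 1, seed = 1))
  # sigma2 -> 0 limit: traits collapse to the root value
  expect_lt(max(abs(simulate_bm_trait(tr, 1e-12, seed = 2))), 1e-4)

  # siblings are closer in trait than random pairs, on average (scaled-down
  # replicate count; the generator property, not a per-draw guarantee)
  set.seed(74)
  sib_gap <- rand_gap <- numeric(30)
  for (i in 1:30) {
    tr <- simulate_yule_tree(30, 50)
    tra <- simulate_bm_trait(tr, 1)
    d <- patristic_matrix(tr)
    diag(d) <- Inf
    sib <- arrayInd(which.min(d), dim(d))
    sib_gap[i] <- abs(tra[sib[1]] - tra[sib[2]])
    pick <- sample(30, 2)
    rand_gap[i] <- abs(tra[pick[1]] - tra[pick[2]])
  }
  expect_lt(mean(sib_gap), mean(rand_gap))
})

test_that("assemble_communities honours scenario semantics", {
  tr <- simulate_yule_tree(10, 30, seed = 75)
  traits <- simulate_bm_trait(tr, 1, seed = 75)
  k_full <- setNames(rep(10L, 3), c("a", "b", "c"))
  cfg <- sim_config(seed = 75, pool_size = 10, richness_range = c(2, 5),
                    refugial_shift = 1)
  m <- assemble_communities(tr, traits, cfg, k_full, seed = 1)
  expect_true(all(m == 1))   # richness = pool size forces the full pool

  # filtering with w -> 0 picks the species nearest each optimum
  cfg_f <- sim_config(seed = 75, pool_size = 10, scenario = "filtering",
                      filter_width = 1e-9, richness_range = c(2, 5),
                      refugial_shift = 1)
  opt <- setNames(traits[c(3, 7)], c("a", "b"))
  k1 <- setNames(c(1L, 1L), c("a", "b"))
  mf <- assemble_communities(tr, traits, cfg_f, k1, optima = opt, seed = 2)
  expect_equal(colnames(mf)[mf["a", ] == 1], names(traits)[3])
  expect_equal(colnames(mf)[mf["b", ] == 1], names(traits)[7])

  # competition: admitted species respect the (possibly relaxed) radius
  cfg_c <- sim_config(seed = 75, pool_size = 10, scenario = "competition",
                      limiting_radius = 0.5, richness_range = c(2, 5),
                      refugial_shift = 1)
  k3 <- setNames(c(3L, 3L), c("a", "b"))
  mc <- assemble_communities(tr, traits, cfg_c, k3, seed = 3)
  expect_equal(unname(rowSums(mc)), c(3, 3))
  for (p in rownames(mc)) {
    tv <- sort(traits[colnames(mc)[mc[p, ] == 1]])
    radius <- 0.5
    notes <- attr(mc, "notes")
    if (!is.null(notes)) {
      relax <- grep(paste0("^", p, ":"), notes, value = TRUE)
      if (length(relax)) {
        radius <- min(as.numeric(sub(".*to ", "", relax)))
      }
    }
    expect_true(all(diff(tv) >= radius - 1e-9))
  }
})

test_that("simulate_site_table lays out the refugial west with 25 env vars", {
  cfg <- sim_config(seed = 76)
  sites <- simulate_site_table(cfg, seed = 76)
  expect_equal(nrow(sites), 35)
  expect_equal(length(unique(sites$site)), 17)
  expect_equal(sum(sites$group == "refugial"), 11)
  expect_true(all(env_variable_names() %in% names(sites)))
  # refugial block sits west of the colonizing block
  expect_lt(max(sites$lon[sites$group == "refugial"]),
            min(sites$lon[sites$group == "colonizing"]))
  expect_identical(simulate_site_table(cfg, seed = 76),
                   simulate_site_table(cfg, seed = 76))
})

test_that("generate_study reproduces the study scale and replays exactly", {
  st <- generate_study(sim_config(seed = 77))
  expect_equal(nrow(st$community), 35)
  expect_equal(ncol(st$community), 92)
  sr <- richness(st$community)
  expect_gte(min(sr), 10)
  expect_lte(max(sr), 26)
  expect_true(all(colnames(st$community) %in% st$tree$tip.label))
  expect_identical(st$community, generate_study(sim_config(seed = 77))$community)
  # refugial plots are richer in expectation (shift +5)
  expect_gt(mean(sr[st$sites$group == "refugial"]),
            mean(sr[st$sites$group == "colonizing"]))
})

test_that("the refugial richness shift is detectable at study size", {
  # power check, scaled down from 200 to 50 replicates for the unit suite
  set.seed(78)
  hits <- 0
  for (i in 1:50) {
    st <- generate_study(sim_config(seed = 1000 + i))
    sr <- richness(st$community)
    p <- mann_whitney_u(sr[st$sites$group == "refugial"],
                        sr[st$sites$group == "colonizing"])$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.8)
})

test_that("a zero shift with zero group effects carries no signal", {
  # null calibration, 40 replicates: refugium starred near the nominal rate
  hits <- 0
  for (i in 1:40) {
    cfg <- sim_config(seed = 2000 + i, refugial_shift = 0)
    st <- generate_study(cfg)
    sites <- st$sites
    for (v in env_variable_names()) {
      # strip group structure from the environment as well
      sites[[v]] <- sites[[v]][sample(nrow(sites))]
    }
    scr <- correlation_screen(richness(st$community), sites)
    if (scr$p[scr$variable == "refugium"] < 0.05) hits <- hits + 1
  }
  expect_lte(hits / 40, 0.15)
})

test_that("write_study emits files that round trip through the readers", {
  st <- generate_study(sim_config(seed = 79, pool_size = 15,
                                  richness_range = c(3, 6),
                                  refugial_shift = 2))
  dir <- tempfile()
  write_study(st, dir)
  expect_setequal(list.files(dir),
                  c("tree.nwk", "community.csv", "sites.csv", "provenance.json"))
  expect_true(ape::all.equal.phylo(read_newick(file.path(dir, "tree.nwk")),
                                   st$tree, use.edge.length = TRUE))
  expect_identical(read_community_csv(file.path(dir, "community.csv")),
                   st$community)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$config$seed, 79)
})
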