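test_that("BH-FDR matches the hand-evaluated step-up on the worked examples", {
  res <- bh_fdr(c(0.001, 0.02, 0.04, 0.8), q = 0.05)
  expect_equal(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  expect_equal(bh_fdr(rep(0, 5))$reject, rep(TRUE, 5))
  expect_identical(bh_fdr(numeric())$reject, logical())
  # single test: adjusted value equals the raw p
  expect_equal(bh_fdr(0.031)$q_value, 0.031)
})

test_that("BH-FDR equals the brute-force step-up on exhaustive short vectors", {
  grid_p <- c(0.004, 0.04, 0.3, 0.9)
  for (len in 1:5) {
    combos <- do.call(expand.grid, rep(list(grid_p), len))
    for (i in seq_len(nrow(combos))) {
      p <- as.numeric(combos[i, ])
      got <- bh_fdr(p, q = 0.05)
      want <- bh_oracle(p, q = 0.05)
      expect_identical(got$reject, want$reject)
      expect_equal(got$q_value, want$q_value, tolerance = 1e-12)
    }
  }
})

test_that("robustness labels follow the all/all-but-one rule and are monotone", {
  expect_equal(classify_robustness(6, 6), "robust")
  expect_equal(classify_robustness(5, 6), "marginal")
  expect_equal(classify_robustness(0, 6), "none")
  expect_equal(classify_robustness(4, 6), "none")
  lab <- vapply(0:6, classify_robustness, "", n_donors = 6)
  ranks <- match(lab, c("none", "marginal", "robust"))
  expect_true(all(diff(ranks) >= 0))
  # configurable thresholds
  expect_equal(classify_robustness(4, 6, robust_min = 4, marginal_min = 3), "robust")
})

test_that("screening one gene reproduces the core pipeline bit for bit", {
  cfg <- test_sim_config(seed = 11, planted_rho = c(CRY2 = 0.4))
  db <- generate_study_database(cfg)
  map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
  atl <- generate_expression_atlases(cfg, map)
  sc <- screen_genes("CRY2", db, cfg$term, atl, cfg$grid, radius = cfg$radius)
  direct <- correlate_gene_map("CRY2", map, atl)
  expect_identical(sc$p, direct$random_effects$p_two_tailed)
  expect_identical(sc$mean_slope, direct$random_effects$mean_slope)
  expect_identical(sc$repetitions, direct$repetitions)
  expect_identical(sc$q_value, sc$p)  # BH with m = 1
})

test_that("a screen covers every requested gene and flags missing ones", {
  cfg <- test_sim_config(seed = 12)
  db <- generate_study_database(cfg)
  map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
  atl <- generate_expression_atlases(cfg, map)
  genes <- c(clock_genes(), "NOT_A_GENE")
  expect_warning(
    sc <- screen_genes(genes, db, cfg$term, atl, cfg$grid, radius = cfg$radius),
    "NOT_A_GENE"
  )
  expect_equal(nrow(sc), 12)
  expect_equal(sc$gene, genes)
  expect_true(is.na(sc$p[sc$gene == "NOT_A_GENE"]))
  # the missing gene is excluded from the FDR family
  expect_true(all(!is.na(sc$q_value[sc$gene != "NOT_A_GENE"])))
})

test_that("domain profiles have full dimensions and flag empty sub-domains", {
  cfg <- test_sim_config(seed = 13)
  db <- generate_study_database(cfg)
  map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
  atl <- generate_expression_atlases(cfg, map)
  terms <- list(memory = c("spatial memory", "semantic memory", "nonexistent subdomain"))
  prof <- domain_profile("CRY2", terms, db, atl, cfg$grid, radius = cfg$radius)
  expect_equal(dim(prof$betas), c(3L, cfg$n_donors))
  expect_true(prof$summary$flagged[3])
  expect_true(all(is.na(prof$betas[3, ])))
  expect_false(any(prof$summary$flagged[1:2]))
  # full default profile: 9 domains x 3 sub-domains
  full <- domain_profile("CRY2", default_domains(), db, atl, cfg$grid,
                         radius = cfg$radius)
  expect_equal(nrow(full$summary), 27L)
  expect_equal(dim(full$betas), c(27L, cfg$n_donors))
})

test_that("a sub-domain sharing the planted gene's hotspots stands out", {
  grid <- tiny_grid(half = 40)
  hot <- rbind(c(-12, -12, -8), c(12, 12, 8))
  set.seed(31)
  mk_foci <- function(centers, n) {
    ctr <- centers[sample.int(nrow(centers), n, replace = TRUE), , drop = FALSE]
    ctr + matrix(rnorm(3 * n, sd = 6), n, 3)
  }
  studies <- c(
    lapply(1:12, function(i) make_study(paste0("nav", i), mk_foci(hot, 10),
                                        terms = "navigation")),
    lapply(1:12, function(i) make_study(paste0("hot", i), mk_foci(hot, 10),
                                        terms = c("spatial", "memory"))),
    lapply(1:12, function(i) make_study(paste0("uni", i),
                                        matrix(runif(30, -38, 38), 10, 3),
                                        terms = c("face", "perception")))
  )
  db <- study_database(studies)
  map <- build_activation_map(select_studies(db, "navigation"), grid, 10)
  cfg <- test_sim_config(seed = 31, planted_rho = c(CRY2 = 0.6),
                         n_sites_per_donor = 250L)
  atl <- generate_expression_atlases(cfg, map)
  prof <- domain_profile(
    "CRY2",
    list(memory = c("spatial memory"), perception = c("face perception")),
    db, atl, grid, radius = 10
  )
  hot_row <- prof$summary$mean_beta[prof$summary$subdomain == "spatial memory"]
  cold_row <- prof$summary$mean_beta[prof$summary$subdomain == "face perception"]
  expect_gt(hot_row, cold_row)
  expect_gt(hot_row, 0.2)
})
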