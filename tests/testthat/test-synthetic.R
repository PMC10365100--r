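test_that("generators are bit-identical under a fixed config", {
  cfg <- test_sim_config(seed = 99, planted_rho = c(CRY2 = 0.3))
  db1 <- generate_study_database(cfg)
  db2 <- generate_study_database(cfg)
  expect_identical(db1, db2)
  map <- build_activation_map(select_studies(db1, cfg$term), cfg$grid, cfg$radius)
  expect_identical(generate_expression_atlases(cfg, map),
                   generate_expression_atlases(cfg, map))
  expect_identical(generate_behavior(cfg), generate_behavior(cfg))
})

test_that("the study database carries the configured term and focus structure", {
  cfg <- simulation_config(seed = 42)
  db <- generate_study_database(cfg)
  expect_length(db$studies, 400)
  term_studies <- select_studies(db, "navigation")
  expect_length(term_studies, 61)
  counts <- vapply(db$studies, function(s) nrow(s$foci), 0)
  expect_true(all(counts >= 1))
  # total term-study foci close to 61 * 49 (Poisson: SD = sqrt(61 * 49))
  total <- sum(counts[names(term_studies)])
  expect_lt(abs(total - 61 * 49), 3 * sqrt(61 * 49))
  # term foci concentrate near hotspots, background foci do not
  near_hot <- function(foci) {
    d <- apply(foci, 1, function(p)
      min(sqrt(rowSums(sweep(cfg$hotspot_centers, 2, p)^2))))
    mean(d < 25)
  }
  term_frac <- mean(vapply(term_studies, function(s) near_hot(s$foci), 0))
  bg <- db$studies[setdiff(names(db$studies), names(term_studies))[1:30]]
  bg_frac <- mean(vapply(bg, function(s) near_hot(s$foci), 0))
  expect_gt(term_frac, 0.9)
  expect_lt(bg_frac, 0.2)
})

test_that("hotspots outside the grid are a configuration error", {
  expect_error(simulation_config(hotspot_centers = rbind(c(500, 0, 0))),
               "outside the grid")
  expect_error(simulation_config(n_term_studies = 500, n_studies_total = 400))
  expect_error(simulation_config(planted_rho = c(CRY2 = 1.2)))
})

test_that("the focal gene carries its three microarray probes", {
  cfg <- test_sim_config(seed = 7)
  db <- generate_study_database(cfg)
  map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
  atl <- generate_expression_atlases(cfg, map)
  for (a in atl) {
    probes <- names(a$probe_map)[a$probe_map == "CRY2"]
    expect_setequal(probes, c("A_23_P127394", "A_23_P388027", "A_24_P158587"))
  }
})

test_that("a near-unity planted correlation without probe noise is recovered", {
  cfg <- test_sim_config(seed = 8, planted_rho = c(CRY2 = 0.99),
                         probe_noise_sd = 0, n_sites_per_donor = 300L)
  db <- generate_study_database(cfg)
  map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
  atl <- generate_expression_atlases(cfg, map)
  res <- correlate_gene_map("CRY2", map, atl)
  expect_true(all(res$table$r > 0.95))
})

test_that("a zero planted correlation stays centered at zero", {
  rs <- c()
  for (seed in 1:25) {
    cfg <- test_sim_config(seed = seed, planted_rho = c(CRY2 = 0),
                           n_sites_per_donor = 150L, n_donors = 2L)
    db <- generate_study_database(cfg)
    map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
    atl <- generate_expression_atlases(cfg, map)
    rs <- c(rs, correlate_gene_map("CRY2", map, atl)$table$r)
  }
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("probe noise attenuates the observed correlation as predicted", {
  # expected attenuation: rho / sqrt(1 + sigma^2 / k) with k probes averaged
  rho <- 0.6; sigma <- 0.9; k <- 3
  expected <- rho / sqrt(1 + sigma^2 / k)
  rs <- c()
  for (seed in 1:15) {
    cfg <- test_sim_config(seed = seed, planted_rho = c(CRY2 = rho),
                           probe_noise_sd = sigma, n_sites_per_donor = 400L,
                           n_donors = 3L)
    db <- generate_study_database(cfg)
    map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
    atl <- generate_expression_atlases(cfg, map)
    rs <- c(rs, correlate_gene_map("CRY2", map, atl)$table$r)
  }
  expect_lt(abs(mean(rs) - expected), 0.04)
})

test_that("behavioral item responses respect their declared scales", {
  cfg <- test_sim_config(seed = 17, behavior_n = 150L, behavior_n_female = 70L)
  tab <- generate_behavior(cfg)
  items <- as.matrix(tab[, sprintf("item%02d", 1:16)])
  expect_true(all(items %in% 1:5))
  expect_true(all(tab$circadian %in% 1:9))
  expect_equal(sum(tab$sex == "F"), 70)
  expect_equal(nrow(tab), 150)
  expect_false(anyDuplicated(tab$participant_id) > 0)
})
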