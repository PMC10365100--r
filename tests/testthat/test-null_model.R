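null_fixture <- function(seed = 1, rho = 0.5, ...) {
  cfg <- test_sim_config(seed = seed, planted_rho = c(CRY2 = rho), ...)
  db <- generate_study_database(cfg)
  map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
  list(cfg = cfg, db = db, map = map,
       atlases = generate_expression_atlases(cfg, map))
}

test_that("resampled study sets match the term-set size and exclude term studies", {
  fx <- null_fixture()
  term_ids <- names(select_studies(fx$db, fx$cfg$term))
  set.seed(42)
  for (i in 1:50) {
    s <- resample_study_set(fx$db, fx$cfg$term)
    expect_length(s, length(term_ids))
    expect_length(intersect(names(s), term_ids), 0)     # membership audit
    expect_false(anyDuplicated(names(s)) > 0)
  }
})

test_that("a pool exactly matching the term count returns the whole pool", {
  db <- study_database(c(
    lapply(1:3, function(i) make_study(paste0("t", i), rbind(c(0, 0, 0)),
                                       terms = "navigation")),
    lapply(1:3, function(i) make_study(paste0("b", i), rbind(c(4, 0, 0)),
                                       terms = "memory"))
  ))
  s <- resample_study_set(db, "navigation")
  expect_setequal(names(s), c("b1", "b2", "b3"))
  db_small <- study_database(c(
    lapply(1:4, function(i) make_study(paste0("t", i), rbind(c(0, 0, 0)),
                                       terms = "navigation")),
    list(make_study("b1", rbind(c(4, 0, 0)), terms = "memory"))
  ))
  expect_error(resample_study_set(db_small, "navigation"), "insufficient")
})

test_that("a strong planted signal yields full repetition and a small empirical p", {
  fx <- null_fixture(seed = 8, rho = 0.7, n_sites_per_donor = 250L)
  nt <- repeatability_test(fx$db, fx$cfg$term, "CRY2", fx$atlases, fx$cfg$grid,
                           radius = fx$cfg$radius, B = 60, alpha = 0.05,
                           seed = 99)
  expect_equal(nt$observed_count, length(fx$atlases))
  expect_lte(nt$empirical_p, 0.05)
  expect_length(nt$null_counts, 60)
  expect_true(all(nt$null_counts[!is.na(nt$null_counts)] %in% 0:6))
  # empirical p recomputed from the published pieces
  ok <- nt$null_counts[!is.na(nt$null_counts)]
  expect_equal(nt$empirical_p, mean(ok >= nt$observed_count))
})

test_that("the add-one estimator is floored at 1/(B+1)", {
  fx <- null_fixture(seed = 8, rho = 0.7, n_sites_per_donor = 250L)
  nt <- repeatability_test(fx$db, fx$cfg$term, "CRY2", fx$atlases, fx$cfg$grid,
                           radius = fx$cfg$radius, B = 40, seed = 5,
                           estimator = "add_one")
  expect_gte(nt$empirical_p, 1 / 41)
  ok <- nt$null_counts[!is.na(nt$null_counts)]
  expect_equal(nt$empirical_p, (1 + sum(ok >= nt$observed_count)) / (length(ok) + 1))
})

test_that("site and map engines produce identical null distributions", {
  fx <- null_fixture(seed = 3, rho = 0.4, n_studies_total = 30L,
                     n_term_studies = 8L, n_sites_per_donor = 60L,
                     n_donors = 3L, foci_per_study_mean = 5)
  a <- repeatability_test(fx$db, fx$cfg$term, "CRY2", fx$atlases, fx$cfg$grid,
                          radius = fx$cfg$radius, B = 12, seed = 7,
                          engine = "site")
  b <- repeatability_test(fx$db, fx$cfg$term, "CRY2", fx$atlases, fx$cfg$grid,
                          radius = fx$cfg$radius, B = 12, seed = 7,
                          engine = "map")
  expect_identical(a$null_counts, b$null_counts)
  expect_identical(a$observed_count, b$observed_count)
  expect_identical(a$empirical_p, b$empirical_p)
})

test_that("the same seed reproduces the null exactly", {
  fx <- null_fixture(seed = 5, rho = 0.3)
  run <- function() repeatability_test(fx$db, fx$cfg$term, "CRY2", fx$atlases,
                                       fx$cfg$grid, radius = fx$cfg$radius,
                                       B = 20, seed = 123)
  expect_identical(run()$null_counts, run()$null_counts)
})
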