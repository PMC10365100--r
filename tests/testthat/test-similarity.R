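test_that("map sampling is nearest-voxel lookup, validated by brute force", {
  g <- tiny_grid()
  set.seed(9)
  m <- build_activation_map(lapply(1:4, function(i)
    make_study(paste0("s", i), matrix(runif(9, -18, 18), 3, 3))), g, 8)
  # voxel-center site returns that voxel's value
  ctr <- voxel_to_mm(g, c(2, 3, 4))[1, ]
  expect_equal(sample_map_at_sites(m, ctr),
               m$values[imgtx:::voxel_linear_index(g, c(2, 3, 4))])
  # all-zero map samples to zero
  zero <- m; zero$values <- numeric(length(m$values))
  expect_equal(sample_map_at_sites(zero, matrix(runif(15, -18, 18), 5, 3)),
               rep(0, 5))
  # brute-force nearest-center search over all voxels
  centers <- voxel_to_mm(g, linear_to_voxel_oracle(g, seq_along(m$values)))
  pts <- matrix(runif(30, -18, 18), 10, 3)
  got <- sample_map_at_sites(m, pts)
  for (i in 1:10) {
    d2 <- rowSums(sweep(centers, 2, pts[i, ])^2)
    expect_equal(got[i], m$values[which.min(d2)])
  }
  # sites outside the grid are reported by id
  bad <- data.frame(site_id = "way_out", x_mm = 500, y_mm = 0, z_mm = 0)
  expect_error(sample_map_at_sites(m, bad), "way_out")
})

test_that("donor correlation equals the textbook Pearson formula", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 500
    x <- rnorm(n)
    y <- 0.3 * x + sqrt(1 - 0.09) * rnorm(n)
    fit <- donor_correlation(y, x, donor_id = "d")
    expect_lt(abs(fit$pearson_r - pearson_oracle(x, y)), 1e-10)
    expect_equal(fit$slope, fit$pearson_r)
    # p-value against the established test
    expect_equal(fit$p_two_tailed, cor.test(x, y)$p.value, tolerance = 1e-12)
  }
})

test_that("perfect and inverted relations give slope +/- 1", {
  x <- rnorm(50)
  expect_equal(donor_correlation(x, x)$slope, 1)
  expect_equal(donor_correlation(-x, x)$slope, -1)
  expect_error(donor_correlation(rep(1, 50), x), "zero variance")
  expect_error(donor_correlation(x, x[-1]), "length mismatch")
})

test_that("random-effects test equals the closed form and the t oracle", {
  # mean 0.07, SD 0.03, n 6 gives t = 0.07 / (0.03 / sqrt(6))
  slopes <- c(0.04, 0.055, 0.07, 0.07, 0.085, 0.1)
  slopes <- (slopes - mean(slopes)) / sd(slopes) * 0.03 + 0.07
  re <- random_effects_test(slopes)
  expect_equal(re$t_stat, 0.07 / (0.03 / sqrt(6)), tolerance = 1e-12)
  expect_equal(re$df, 5L)
  expect_equal(re$t_stat, 5.715, tolerance = 1e-3)
  # antisymmetric slopes: t = 0, p = 1
  re0 <- random_effects_test(c(1, -1))
  expect_equal(re0$t_stat, 0)
  expect_equal(re0$p_two_tailed, 1)
  # random slope sets vs t.test and an explicit t-CDF evaluation
  set.seed(4)
  for (rep in 1:20) {
    s <- rnorm(6, 0.07, 0.03)
    re <- random_effects_test(s)
    tt <- t.test(s)
    expect_lt(abs(re$t_stat - tt$statistic), 1e-10)
    expect_lt(abs(re$p_two_tailed - tt$p.value), 1e-10)
    expect_lt(abs(re$p_two_tailed - 2 * pt(-abs(mean(s) / (sd(s) / sqrt(6))), 5)),
              1e-12)
  }
  expect_error(random_effects_test(rep(0.1, 6)), "degenerate")
})

test_that("repetition counting thresholds two-tailed p-values at alpha", {
  fits <- lapply(c(0.01, 0.04, 0.06, 0.2, 0.049, 0.5), fit_stub)
  expect_equal(count_repetitions(fits, alpha = 0.05), 3)
  expect_equal(count_repetitions(lapply(rep(0.5, 6), fit_stub)), 0)
  expect_equal(count_repetitions(lapply(rep(1e-7, 6), fit_stub)), 6)
  # same-sign option discounts donors opposing the mean slope
  mixed <- list(fit_stub(0.001, slope = 0.5), fit_stub(0.001, slope = 0.4),
                fit_stub(0.001, slope = -0.6))
  expect_equal(count_repetitions(mixed), 3)
  expect_equal(count_repetitions(mixed, same_sign = TRUE), 2)
})

test_that("results are invariant to positive rescaling of the map", {
  set.seed(14)
  x <- runif(200)
  y <- 0.4 * x + rnorm(200, sd = 0.5)
  f1 <- donor_correlation(y, x)
  f2 <- donor_correlation(y, 17.3 * x)
  expect_equal(f1$pearson_r, f2$pearson_r, tolerance = 1e-12)
  expect_equal(f1$p_two_tailed, f2$p_two_tailed, tolerance = 1e-12)
})

test_that("planted spatial correlations are recovered without probe noise", {
  # moderate planted effect, noise-free probes: mean recovered r near rho
  rs <- c()
  for (seed in 1:12) {
    cfg <- test_sim_config(seed = seed, planted_rho = c(CRY2 = 0.3),
                           probe_noise_sd = 0, n_sites_per_donor = 300L)
    db <- generate_study_database(cfg)
    map <- build_activation_map(select_studies(db, cfg$term), cfg$grid, cfg$radius)
    atl <- generate_expression_atlases(cfg, map)
    res <- correlate_gene_map("CRY2", map, atl)
    rs <- c(rs, res$table$r)
  }
  expect_lt(abs(mean(rs) - 0.3), 0.05)
})
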