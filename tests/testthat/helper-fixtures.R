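# Shared fixtures and independent oracles for the test suite.

# small grid centered on the origin: 11^3 voxels at 4 mm
tiny_grid <- function(spacing = 4, half = 20) {
  voxel_grid(spacing = spacing, xlim = c(-half, half),
             ylim = c(-half, half), zlim = c(-half, half))
}

make_study <- function(id, foci, terms = "navigation") {
  study_record(id, terms = terms, foci = foci)
}

# atlas with given per-gene site values, one probe per gene unless a probe
# matrix is supplied directly
make_atlas <- function(donor_id, gene_values, coords) {
  genes <- names(gene_values)
  pv <- do.call(rbind, gene_values)
  rownames(pv) <- paste0(genes, "_p1")
  pm <- stats::setNames(genes, rownames(pv))
  sites <- data.frame(site_id = sprintf("%s_s%03d", donor_id, seq_len(ncol(pv))),
                      x_mm = coords[, 1], y_mm = coords[, 2], z_mm = coords[, 3])
  expression_atlas(donor_id, sites, pv, pm)
}

# textbook Pearson correlation via the raw sum formula (independent of
# stats::cor / the package's standardization path)
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# hand-coded BH step-up: largest k with p_(k) <= k q / m rejected; adjusted
# values as the running minimum of m p_(j) / j from the largest rank
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  k <- if (any(ps <= thresh)) max(which(ps <= thresh)) else 0L
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  adj_sorted <- pmin(rev(cummin(rev(m * ps / seq_len(m)))), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  list(reject = reject, q_value = adj)
}

# per-voxel activation count by exhaustive distance checking over every
# voxel center and every focus of every study
map_oracle <- function(studies, grid, radius) {
  nv <- prod(grid$shape)
  centers <- voxel_to_mm(grid, linear_to_voxel_oracle(grid, seq_len(nv)))
  counts <- integer(nv)
  for (s in studies) {
    active <- rep(FALSE, nv)
    for (f in seq_len(nrow(s$foci))) {
      d2 <- rowSums(sweep(centers, 2, s$foci[f, ])^2)
      active <- active | (d2 <= radius^2)
    }
    counts <- counts + active
  }
  counts / length(studies)
}

linear_to_voxel_oracle <- function(grid, lin) {
  nx <- grid$shape[1]; nxy <- grid$shape[1] * grid$shape[2]
  lin0 <- lin - 1L
  cbind(lin0 %% nx + 1L, (lin0 %/% nx) %% grid$shape[2] + 1L, lin0 %/% nxy + 1L)
}

# stub per-donor fit with a given p-value and slope
fit_stub <- function(p, slope = 0.1, donor_id = "d") {
  structure(list(donor_id = donor_id, n_sites = 100L, slope = slope,
                 pearson_r = slope, p_two_tailed = p),
            class = "donor_correlation")
}

# small, fast simulation config for tests
test_sim_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed, n_sites_per_donor = 120L, n_studies_total = 80L,
    n_term_studies = 15L, foci_per_study_mean = 12,
    grid = tiny_grid(half = 40), hotspot_centers = rbind(c(-12, -12, -8), c(12, 12, 8))
  )
  do.call(simulation_config, utils::modifyList(defaults, args))
}
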