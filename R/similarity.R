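#' Sample an activation map at MNI coordinates
#'
#' Nearest-voxel lookup: each mm coordinate is rounded through the inverse
#' of the grid affine to its nearest voxel center and that voxel's value is
#' returned. Interpolation is deliberately not applied -- a sampling site is
#' read as "the corresponding value" of the voxel it falls in.
#'
#' @param map an `activation_map` (see [build_activation_map()]).
#' @param sites numeric matrix (n x 3) of MNI mm coordinates, or a
#'   data.frame with `x_mm`, `y_mm`, `z_mm` (and optionally `site_id`, used
#'   in error messages).
#' @return numeric vector of per-site map values.
#' @export
sample_map_at_sites <- function(map, sites) {
  stopifnot(inherits(map, "activation_map"))
  site_ids <- NULL
  if (is.data.frame(sites)) {
    site_ids <- sites$site_id
    sites <- as.matrix(sites[, c("x_mm", "y_mm", "z_mm")])
  }
  sites <- to_coord_matrix(sites)
  idx <- mm_to_voxel(map$grid, sites)
  bad <- is.na(idx[, 1])
  if (any(bad)) {
    lab <- if (!is.null(site_ids)) site_ids[bad] else which(bad)
    stop("sites outside the map grid: ", paste(lab, collapse = ", "))
  }
  map$values[voxel_linear_index(map$grid, idx)]
}

#' Per-donor expression-activation correlation
#'
#' Standardizes both the gene expression vector and the per-site map values
#' and fits the ordinary least-squares line; on standardized variables the
#' slope equals the Pearson correlation. The two-tailed p-value comes from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param expr a `gene_expression_vector` (see [average_probes()]) or a
#'   plain numeric vector.
#' @param map_values numeric vector of per-site activation values, same
#'   length as `expr`.
#' @param donor_id donor label when `expr` is a plain vector.
#' @return An object of class `donor_correlation`: list with `donor_id`,
#'   `n_sites`, `slope` (on standardized variables), `pearson_r`,
#'   `p_two_tailed`.
#' @export
donor_correlation <- function(expr, map_values, donor_id = NULL) {
  if (inherits(expr, "gene_expression_vector")) {
    if (is.null(donor_id)) donor_id <- expr$donor_id
    expr <- expr$values
  }
  if (is.null(donor_id)) donor_id <- NA_character_
  expr <- as.numeric(expr)
  map_values <- as.numeric(map_values)
  if (length(expr) != length(map_values)) {
    stop("length mismatch: ", length(expr), " expression values vs ",
         length(map_values), " map values")
  }
  n <- length(expr)
  if (n < 4L) stop("need at least 4 sites for a per-donor correlation")
  x <- standardize(map_values)  # errors "zero variance" on constant input
  y <- standardize(expr)
  r <- stats::cor(x, y)
  # r can brush |1| by rounding; clamp before the t transform
  r <- max(min(r, 1), -1)
  tt <- if (abs(r) == 1) Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(
    list(donor_id = donor_id, n_sites = n, slope = r, pearson_r = r,
         p_two_tailed = p),
    class = "donor_correlation"
  )
}

#' Approximate random-effects test across donors
#'
#' Treats the per-donor slopes as draws from a population of donors and
#' tests their mean against zero with a one-sample t-test:
#' `t = mean / (sd / sqrt(n))` with n - 1 degrees of freedom, two-tailed.
#' This is the aggregation step that lets a spatial expression-activation
#' correlation generalize beyond the sampled donors.
#'
#' @param fits list of [donor_correlation()] objects, or a numeric vector
#'   of slopes.
#' @return An object of class `random_effects_result`: `n_donors`,
#'   `mean_slope`, `sd_slope`, `t_stat`, `df`, `p_two_tailed`.
#' @export
random_effects_test <- function(fits) {
  slopes <- extract_slopes(fits)
  n <- length(slopes)
  if (n < 2L) stop("need at least 2 donors for the random-effects test")
  s <- stats::sd(slopes)
  if (s == 0) stop("degenerate slopes: zero variance across donors")
  m <- mean(slopes)
  tt <- m / (s / sqrt(n))
  structure(
    list(n_donors = n, mean_slope = m, sd_slope = s, t_stat = tt,
         df = n - 1L, p_two_tailed = 2 * stats::pt(-abs(tt), df = n - 1)),
    class = "random_effects_result"
  )
}

#' @export
print.random_effects_result <- function(x, ...) {
  cat(sprintf("random effects over %d donors: mean slope %.4f (SD %.4f), t(%d) = %.3f, p = %.4g\n",
              x$n_donors, x$mean_slope, x$sd_slope, x$df, x$t_stat, x$p_two_tailed))
  invisible(x)
}

extract_slopes <- function(fits) {
  if (is.numeric(fits)) return(as.numeric(fits))
  vapply(fits, function(f) {
    if (inherits(f, "donor_correlation")) f$slope else as.numeric(f)
  }, 0)
}

#' Count donors with individually significant correlations
#'
#' The inter-donor repetition count: how many donors' correlations are
#' individually significant at `alpha` (uncorrected). Sign-agnostic by
#' default; `same_sign = TRUE` additionally requires each significant
#' donor's slope to share the sign of the mean slope.
#'
#' @param fits list of [donor_correlation()] objects.
#' @param alpha per-donor significance level, default 0.05.
#' @param same_sign logical; restrict to donors matching the mean slope's
#'   sign.
#' @return integer count in `[0, n_donors]`.
#' @export
count_repetitions <- function(fits, alpha = 0.05, same_sign = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  p <- vapply(fits, function(f) f$p_two_tailed, 0)
  sig <- p < alpha
  if (same_sign) {
    slopes <- extract_slopes(fits)
    sig <- sig & (sign(slopes) == sign(mean(slopes)))
  }
  sum(sig)
}

#' Run the per-donor correlations and random-effects test for one gene
#'
#' Convenience wrapper over [average_probes()], [sample_map_at_sites()],
#' [donor_correlation()] and [random_effects_test()].
#'
#' @param gene gene symbol.
#' @param map an `activation_map`.
#' @param atlases list of [expression_atlas()] objects.
#' @param alpha per-donor level for the repetition count.
#' @return list with `fits` (per-donor list), `random_effects`,
#'   `repetitions`, and a per-donor `table` data.frame
#'   (donor_id, n_sites, slope, r, p).
#' @export
correlate_gene_map <- function(gene, map, atlases, alpha = 0.05) {
  fits <- lapply(atlases, function(a) {
    expr <- average_probes(a, gene)
    mv <- sample_map_at_sites(map, a$sites)
    donor_correlation(expr, mv)
  })
  tab <- data.frame(
    donor_id = vapply(fits, `[[`, "", "donor_id"),
    n_sites = vapply(fits, `[[`, 0L, "n_sites"),
    slope = vapply(fits, `[[`, 0, "slope"),
    r = vapply(fits, `[[`, 0, "pearson_r"),
    p = vapply(fits, `[[`, 0, "p_two_tailed")
  )
  rownames(tab) <- NULL
  list(
    gene = gene,
    fits = fits,
    random_effects = random_effects_test(fits),
    repetitions = count_repetitions(fits, alpha = alpha),
    table = tab
  )
}
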