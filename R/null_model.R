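#' Resample a null study set from the non-term pool
#'
#' Draws, uniformly without replacement, the same number of studies as the
#' term set from the studies NOT matching the term expression. This is the
#' building block of the repeatability null: each draw yields a
#' random-activation map of matched size built from unrelated studies.
#'
#' @param db a [study_database()].
#' @param term_expr term expression as in [select_studies()].
#' @param n number of studies to draw; defaults to the term-set size.
#' @return list of `study_record`s. Uses the current RNG state.
#' @export
resample_study_set <- function(db, term_expr, n = NULL) {
  term_ids <- names(select_studies(db, term_expr))
  pool <- setdiff(names(db$studies), term_ids)
  if (is.null(n)) n <- length(term_ids)
  if (length(pool) < n) {
    stop("insufficient non-term studies: pool of ", length(pool),
         " but ", n, " requested")
  }
  ids <- if (length(pool) == n) pool else sample(pool, n)
  db$studies[ids]
}

#' Inter-donor repeatability test via study resampling
#'
#' The observed statistic is the number of donors whose gene-expression
#' vector correlates significantly (two-tailed, uncorrected `alpha`) with
#' the term's activation map at the donor's sampling sites. The null
#' distribution of that count is built by drawing `B` random study sets of
#' matched size from the non-term studies, rebuilding the activation map
#' for each, and recounting. Without a genuine expression-activation link
#' the observed count should not sit in the null's upper tail.
#'
#' The empirical p is `#(null counts >= observed) / B` by default (ties
#' count as "as extreme"); `estimator = "add_one"` uses the bias-corrected
#' `(1 + #) / (B + 1)`, which is never below `1/(B+1)`.
#'
#' Two engines compute identical numbers. `"site"` (default) precomputes a
#' study-by-site activation indicator -- a voxel-snapped site is active for
#' a study exactly when its voxel center lies within `radius` of a focus --
#' so each resampled map's site values are a column mean over the drawn
#' rows. `"map"` naively rebuilds the full voxel map each iteration and
#' nearest-voxel samples it; it exists as a cross-check and for audit
#' output.
#'
#' Randomness: `seed` seeds a draw of `B` per-iteration seeds up front, so
#' results do not depend on iteration order and iterations could be
#' distributed. Iterations whose correlations fail (e.g., a constant map at
#' some donor's sites) are recorded; more than 1% failures aborts.
#'
#' @param db a [study_database()].
#' @param term_expr term expression for the observed map.
#' @param gene gene symbol present in every atlas.
#' @param atlases list of [expression_atlas()] objects.
#' @param grid a [voxel_grid()].
#' @param radius focus sphere radius in mm.
#' @param B number of resampling iterations (default 1000).
#' @param alpha per-donor significance level (default 0.05).
#' @param seed integer master seed.
#' @param estimator `"plain"` or `"add_one"`.
#' @param engine `"site"` or `"map"`.
#' @return An object of class `repeatability_null`: `B`,
#'   `n_studies_resampled`, `alpha`, `null_counts` (length-B integer,
#'   failed iterations NA), `observed_count`, `empirical_p`, `estimator`,
#'   `n_failed`, plus `observed_fits` and `random_effects` for the
#'   observed map.
#' @export
repeatability_test <- function(db, term_expr, gene, atlases, grid,
                               radius = 10, B = 1000, alpha = 0.05,
                               seed = 1L,
                               estimator = c("plain", "add_one"),
                               engine = c("site", "map")) {
  estimator <- match.arg(estimator)
  engine <- match.arg(engine)
  stopifnot(B >= 1)
  term_studies <- select_studies(db, term_expr)
  n_term <- length(term_studies)
  if (n_term == 0L) stop("no studies match the term expression")

  # standardized per-donor expression, fixed across iterations
  expr_std <- lapply(atlases, function(a) standardize(average_probes(a, gene)$values))
  site_mm <- lapply(atlases, atlas_site_mm)
  n_sites <- vapply(site_mm, nrow, 0L)
  donor_col <- rep(seq_along(atlases), n_sites)

  observed_map <- build_activation_map(term_studies, grid, radius,
                                       term = paste(term_expr, collapse = " "))
  observed_fits <- Map(function(a, e) {
    donor_correlation(e, sample_map_at_sites(observed_map, a$sites),
                      donor_id = a$donor_id)
  }, atlases, expr_std)
  observed_count <- count_repetitions(observed_fits, alpha = alpha)

  pool_ids <- setdiff(names(db$studies), names(term_studies))
  if (length(pool_ids) < n_term) {
    stop("insufficient non-term studies: pool of ", length(pool_ids),
         " but ", n_term, " required")
  }

  if (engine == "site") {
    all_mm <- do.call(rbind, site_mm)
    indicator <- study_site_indicator(db$studies[pool_ids], grid, radius, all_mm)
  }

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, B)
  null_counts <- rep(NA_integer_, B)
  for (b in seq_len(B)) {
    set.seed(iter_seeds[b])
    ids <- if (length(pool_ids) == n_term) pool_ids else sample(pool_ids, n_term)
    vals <- if (engine == "site") {
      rows <- match(ids, pool_ids)
      colMeans(indicator[rows, , drop = FALSE])
    } else {
      m <- build_activation_map(db$studies[ids], grid, radius,
                                term = "random-sample")
      unlist(lapply(atlases, function(a) sample_map_at_sites(m, a$sites)),
             use.names = FALSE)
    }
    cnt <- tryCatch({
      fits <- lapply(seq_along(atlases), function(d) {
        donor_correlation(expr_std[[d]], vals[donor_col == d])
      })
      count_repetitions(fits, alpha = alpha)
    }, error = function(e) NA_integer_)
    null_counts[b] <- cnt
  }
  n_failed <- sum(is.na(null_counts))
  if (n_failed > 0.01 * B) {
    stop(n_failed, " of ", B, " null iterations failed (> 1%); aborting")
  }
  ok <- null_counts[!is.na(null_counts)]
  n_extreme <- sum(ok >= observed_count)
  empirical_p <- switch(estimator,
    plain = n_extreme / length(ok),
    add_one = (1 + n_extreme) / (length(ok) + 1)
  )
  structure(
    list(B = B, n_studies_resampled = n_term, alpha = alpha,
         null_counts = null_counts, observed_count = observed_count,
         empirical_p = empirical_p, estimator = estimator,
         n_failed = n_failed, observed_fits = observed_fits,
         random_effects = random_effects_test(observed_fits),
         gene = gene, engine = engine, seed = seed),
    class = "repeatability_null"
  )
}

#' @export
print.repeatability_null <- function(x, ...) {
  ok <- x$null_counts[!is.na(x$null_counts)]
  cat(sprintf(
    "repeatability null for %s: observed %d/%d donors significant (alpha = %g)\n  null counts over B = %d: mean %.2f, SD %.2f; empirical p = %.4g (%s)\n",
    x$gene, x$observed_count, length(x$observed_fits), x$alpha, x$B,
    mean(ok), stats::sd(ok), x$empirical_p, x$estimator
  ))
  invisible(x)
}

# study-by-site activation indicator: row = study, column = site; a site is
# active for a study when its snapped voxel center is within radius of any
# focus. Identical to nearest-voxel sampling of the study's mask.
study_site_indicator <- function(studies, grid, radius, site_mm) {
  idx <- mm_to_voxel(grid, site_mm)
  if (any(is.na(idx[, 1]))) {
    stop("sites outside the grid: rows ", paste(which(is.na(idx[, 1])), collapse = ", "))
  }
  centers <- voxel_to_mm(grid, idx)
  c2 <- rowSums(centers^2)
  r2 <- radius^2
  out <- matrix(FALSE, length(studies), nrow(centers))
  for (s in seq_along(studies)) {
    foci <- studies[[s]]$foci
    if (nrow(foci) == 0L) next
    # squared cross-distances foci x sites without forming explicit loops
    d2 <- outer(rowSums(foci^2), c2, "+") - 2 * foci %*% t(centers)
    out[s, ] <- colSums(d2 <= r2 + 1e-9) > 0
  }
  out
}
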