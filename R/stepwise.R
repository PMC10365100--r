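#' Interaction term of two standardized expression vectors
#'
#' The elementwise product of the two genes' standardized expression
#' vectors. Inputs must already be standardized (|mean| <= 1e-6,
#' |SD - 1| <= 1e-3); passing raw vectors is an error because the product
#' of unstandardized levels is not the intended moderation term.
#'
#' @param g1_std,g2_std standardized numeric vectors of equal length.
#' @return numeric vector of elementwise products.
#' @export
interaction_term <- function(g1_std, g2_std) {
  g1_std <- as.numeric(g1_std); g2_std <- as.numeric(g2_std)
  if (length(g1_std) != length(g2_std)) stop("length mismatch")
  for (g in list(g1_std, g2_std)) {
    if (abs(mean(g)) > 1e-6 || abs(stats::sd(g) - 1) > 1e-3) {
      stop("inputs must be standardized (mean 0, SD 1) before forming the interaction")
    }
  }
  g1_std * g2_std
}

#' Bidirectional stepwise regression with p-value entry/removal
#'
#' Regresses per-site activation values on named candidate predictors by
#' p-value-driven bidirectional stepwise selection: starting from the
#' intercept-only model, the candidate with the smallest partial-t p-value
#' below `p_enter` is added; after each addition any included term whose
#' p-value exceeds `p_remove` is dropped (worst first); this repeats to a
#' fixed point. The intercept is always included and never a candidate.
#' Ties on entry break lexicographically by term name, so the procedure is
#' deterministic.
#'
#' The response is standardized internally, so with standardized candidates
#' the reported coefficients are standardized betas. Unselected terms get
#' beta exactly 0 (the zero-imputation convention used when aggregating
#' betas across donors).
#'
#' @param y numeric response (per-site activation values).
#' @param candidates named list or data.frame of numeric predictor vectors.
#' @param p_enter entry threshold (default 0.05); must be <= `p_remove`.
#' @param p_remove removal threshold (default 0.10).
#' @param donor_id optional donor label carried through.
#' @return An object of class `stepwise_fit`: `donor_id`, `candidates`
#'   (term names), `selected` (subset), `betas` (named, zeros for
#'   unselected), `adj_r2`, `model_p` (overall F-test p; `NA` for the
#'   empty model), `n_sites`.
#' @export
stepwise_fit <- function(y, candidates, p_enter = 0.05, p_remove = 0.10,
                         donor_id = NA_character_) {
  stopifnot(p_enter <= p_remove, p_enter > 0, p_remove < 1)
  if (is.data.frame(candidates)) candidates <- as.list(candidates)
  stopifnot(is.list(candidates), length(candidates) >= 1L,
            !is.null(names(candidates)), all(nzchar(names(candidates))))
  X <- do.call(cbind, lapply(candidates, as.numeric))
  colnames(X) <- names(candidates)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("length mismatch between y and candidates")
  if (n <= ncol(X) + 2L) stop("need more sites than candidates + 2")
  # reject (near-)collinear candidate pairs up front
  if (ncol(X) > 1L) {
    cc <- stats::cor(X)
    cc[upper.tri(cc, diag = TRUE)] <- 0
    bad <- which(abs(cc) > 0.9999, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("collinear candidates: ", colnames(X)[bad[1, 2]], " and ",
           rownames(cc)[bad[1, 1]])
    }
  }
  ys <- standardize(y)

  term_p <- function(sel) {
    # partial-t p-value of each selected term in the model with all of sel
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, sel, drop = FALSE]), ys)
    res <- ys - fit$fitted.values
    df_res <- n - length(sel) - 1L
    s2 <- sum(res^2) / df_res
    XtXinv <- chol2inv(chol(crossprod(cbind(1, X[, sel, drop = FALSE]))))
    se <- sqrt(s2 * diag(XtXinv))[-1]
    tt <- fit$coefficients[-1] / se
    p <- 2 * stats::pt(-abs(tt), df_res)
    names(p) <- sel
    p
  }

  tss <- sum((ys - mean(ys))^2)
  saturated <- function(sel) {
    if (length(sel) == 0L) return(FALSE)
    fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), ys)
    sum(fit$residuals^2) < 1e-12 * tss
  }

  selected <- character()
  repeat {
    changed <- FALSE
    # entry step; skipped once the model explains y to numerical precision,
    # where partial p-values on the ~0 residuals are meaningless
    candidates_left <- setdiff(colnames(X), selected)
    if (length(candidates_left) && !saturated(selected)) {
      entry_p <- vapply(sort(candidates_left), function(cand) {
        term_p(c(selected, cand))[[cand]]
      }, 0)
      best <- names(entry_p)[which.min(entry_p)]  # sorted names => lexicographic ties
      if (entry_p[[best]] < p_enter) {
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    # removal step(s)
    repeat {
      if (length(selected) == 0L) break
      pv <- term_p(selected)
      worst <- names(pv)[which.max(pv)]
      if (pv[[worst]] > p_remove) {
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  betas <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (length(selected)) {
    fit <- stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), ys)
    betas[selected] <- fit$coefficients[-1]
    k <- length(selected)
    rss <- sum(fit$residuals^2)
    tss <- sum((ys - mean(ys))^2)
    r2 <- 1 - rss / tss
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
    model_p <- stats::pf(fstat, k, n - k - 1, lower.tail = FALSE)
  } else {
    adj_r2 <- 0
    model_p <- NA_real_
  }
  structure(
    list(donor_id = donor_id, candidates = colnames(X), selected = selected,
         betas = betas, adj_r2 = unname(adj_r2), model_p = unname(model_p),
         n_sites = n),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise_fit (donor %s): selected {%s}; adj R2 = %.4f\n",
              x$donor_id, paste(x$selected, collapse = ", "), x$adj_r2))
  print(round(x$betas, 4))
  invisible(x)
}

#' Random-effects test on per-donor stepwise betas
#'
#' For each candidate term, runs the one-sample t-test across the donors'
#' betas, zeros included for donors that did not select the term. A term
#' with zero variance across donors (e.g., selected by no donor) is
#' reported as not testable rather than raising an error.
#'
#' @param fits list of [stepwise_fit()] objects sharing the same candidate
#'   set.
#' @return data.frame with one row per term: `term`, `mean_beta`,
#'   `sd_beta`, `t`, `df`, `p`, `n_selected`, `testable`.
#' @export
random_effects_on_betas <- function(fits) {
  stopifnot(length(fits) >= 2L)
  terms <- fits[[1]]$candidates
  for (f in fits) stopifnot(identical(f$candidates, terms))
  rows <- lapply(terms, function(tm) {
    b <- vapply(fits, function(f) f$betas[[tm]], 0)
    n_sel <- sum(vapply(fits, function(f) tm %in% f$selected, NA))
    if (stats::sd(b) == 0) {
      data.frame(term = tm, mean_beta = mean(b), sd_beta = 0, t = NA_real_,
                 df = length(b) - 1L, p = NA_real_, n_selected = n_sel,
                 testable = FALSE)
    } else {
      re <- random_effects_test(b)
      data.frame(term = tm, mean_beta = re$mean_slope, sd_beta = re$sd_slope,
                 t = re$t_stat, df = re$df, p = re$p_two_tailed,
                 n_selected = n_sel, testable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-donor two-gene stepwise analysis against an activation map
#'
#' For every donor: probe-average and standardize both genes, form their
#' interaction, and run [stepwise_fit()] of the map values at the donor's
#' sites on the three candidates; then aggregate betas across donors with
#' [random_effects_on_betas()].
#'
#' @param gene1,gene2 gene symbols.
#' @param map an `activation_map`.
#' @param atlases list of [expression_atlas()] objects.
#' @param p_enter,p_remove stepwise thresholds.
#' @return list with `fits` (per donor), `random_effects` (per-term
#'   data.frame), and `expression_correlation` (the per-donor correlation
#'   between the two genes' expression, aggregated across donors).
#' @export
stepwise_gene_pair <- function(gene1, gene2, map, atlases,
                               p_enter = 0.05, p_remove = 0.10) {
  fits <- lapply(atlases, function(a) {
    g1 <- standardize(average_probes(a, gene1)$values)
    g2 <- standardize(average_probes(a, gene2)$values)
    y <- sample_map_at_sites(map, a$sites)
    cand <- stats::setNames(
      list(g1, g2, interaction_term(g1, g2)),
      c(gene1, gene2, paste0(gene1, ":", gene2))
    )
    stepwise_fit(y, cand, p_enter = p_enter, p_remove = p_remove,
                 donor_id = a$donor_id)
  })
  gg <- lapply(atlases, function(a) {
    donor_correlation(average_probes(a, gene1)$values,
                      average_probes(a, gene2)$values,
                      donor_id = a$donor_id)
  })
  list(
    fits = fits,
    random_effects = random_effects_on_betas(fits),
    expression_correlation = list(
      fits = gg, random_effects = random_effects_test(gg)
    )
  )
}
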