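#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR control: adjusted values are computed with
#' `stats::p.adjust(method = "BH")` (monotone by construction via the
#' running minimum from the largest rank) and an item is rejected when its
#' adjusted value is at most `q` -- equivalent to the classic step-up rule
#' rejecting the `k` smallest p-values for the largest `k` with
#' `p_(k) <= k q / m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `q_value` (BH-adjusted p-values, same order as input)
#'   and `reject` (logical). Empty input gives empty output.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) {
    return(list(q_value = numeric(), reject = logical()))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            q > 0, q < 1)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(q_value = adj, reject = !is.na(adj) & adj <= q)
}

#' Classify robustness from the inter-donor repetition count
#'
#' A correlation is `"robust"` when it repeats in all donors, a
#' `"marginal"` trend when it repeats in all but one, and `"none"`
#' otherwise. The thresholds are configurable.
#'
#' @param repetitions integer count of donors with individually significant
#'   correlations.
#' @param n_donors total number of donors.
#' @param robust_min minimum repetitions for `"robust"`
#'   (default `n_donors`).
#' @param marginal_min minimum repetitions for `"marginal"`
#'   (default `n_donors - 1`).
#' @return one of `"robust"`, `"marginal"`, `"none"`.
#' @export
classify_robustness <- function(repetitions, n_donors,
                                robust_min = n_donors,
                                marginal_min = n_donors - 1L) {
  stopifnot(repetitions >= 0, repetitions <= n_donors,
            marginal_min <= robust_min)
  if (repetitions >= robust_min) "robust"
  else if (repetitions >= marginal_min) "marginal"
  else "none"
}

#' Screen a gene set against one activation map
#'
#' Runs the per-donor correlation + random-effects pipeline for each gene,
#' counts inter-donor repetitions, applies BH-FDR across the screened set's
#' random-effects p-values, and labels robustness by repetition count.
#' Genes missing from an atlas are skipped with a warning and reported as
#' an `NA` row (excluded from the FDR family).
#'
#' @param genes character vector of gene symbols.
#' @param db a [study_database()].
#' @param term_expr term expression for the map.
#' @param atlases list of [expression_atlas()] objects.
#' @param grid a [voxel_grid()].
#' @param radius focus sphere radius in mm.
#' @param alpha per-donor level for repetition counting.
#' @param q FDR level across the gene set.
#' @param map optional prebuilt `activation_map` (skips the build).
#' @return data.frame with one row per gene, in input order: `gene`,
#'   `mean_slope`, `sd_slope`, `t`, `df`, `p`, `repetitions`, `q_value`,
#'   `significant_fdr`, `robustness`.
#' @export
screen_genes <- function(genes, db, term_expr, atlases, grid, radius = 10,
                         alpha = 0.05, q = 0.05, map = NULL) {
  stopifnot(length(genes) >= 1L)
  if (is.null(map)) {
    map <- build_activation_map(select_studies(db, term_expr), grid, radius,
                                term = paste(term_expr, collapse = " "))
  }
  n_donors <- length(atlases)
  rows <- lapply(genes, function(g) {
    res <- tryCatch(correlate_gene_map(g, map, atlases, alpha = alpha),
                    error = function(e) {
                      warning("gene '", g, "' skipped: ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (is.null(res)) {
      return(data.frame(gene = g, mean_slope = NA_real_, sd_slope = NA_real_,
                        t = NA_real_, df = NA_integer_, p = NA_real_,
                        repetitions = NA_integer_))
    }
    re <- res$random_effects
    data.frame(gene = g, mean_slope = re$mean_slope, sd_slope = re$sd_slope,
               t = re$t_stat, df = re$df, p = re$p_two_tailed,
               repetitions = res$repetitions)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q_value <- NA_real_
  out$significant_fdr <- NA
  if (any(ok)) {
    fdr <- bh_fdr(out$p[ok], q = q)
    out$q_value[ok] <- fdr$q_value
    out$significant_fdr[ok] <- fdr$reject
  }
  out$robustness <- NA_character_
  out$robustness[ok] <- vapply(out$repetitions[ok], classify_robustness,
                               "", n_donors = n_donors)
  rownames(out) <- NULL
  out
}

#' Default cognitive-domain term list
#'
#' Nine broad cognitive domains involved in navigation, each with three
#' sub-domain term expressions chosen to span more- and less-spatial
#' facets. Two-word entries are resolved by [select_studies()] (direct
#' label if present, conjunction of the two words otherwise). The list is
#' a plain named list and fully user-editable.
#'
#' @return named list: domain -> character vector of three term
#'   expressions.
#' @export
default_domains <- function() {
  list(
    perception = c("scene perception", "object perception", "face perception"),
    memory = c("spatial memory", "semantic memory", "episodic memory"),
    social_cognition = c("self referential", "social interaction", "empathy"),
    intelligence = c("reasoning", "decision making", "problem solving"),
    language = c("speech perception", "phonology", "comprehension"),
    attention = c("spatial attention", "attention shift", "sustained attention"),
    executive = c("response selection", "response inhibition", "task switching"),
    motor = c("eye movements", "motor control", "grasping"),
    learning = c("spatial learning", "reinforcement learning", "skill learning")
  )
}

#' Gene-by-domain correlation profile
#'
#' For one gene, runs the per-donor correlation and random-effects test
#' against the activation map of every sub-domain of every domain: the
#' domain-matrix analog of profiling a gene's expression against the
#' activation likelihood of distinct cognitive processes. Sub-domains with
#' no matching studies are flagged and carry no betas; they do not abort
#' the profile. Domain p-values are reported uncorrected (an exploratory
#' profile, not a confirmatory screen).
#'
#' @param gene gene symbol.
#' @param domain_terms named list: domain -> character vector of term
#'   expressions (default [default_domains()]).
#' @param db a [study_database()].
#' @param atlases list of [expression_atlas()] objects.
#' @param grid a [voxel_grid()].
#' @param radius focus sphere radius in mm.
#' @param alpha per-donor level for repetition counting.
#' @return list with `summary` (data.frame: `domain`, `subdomain`,
#'   `n_studies`, `mean_beta`, `t`, `p`, `repetitions`, `flagged`) and
#'   `betas` (matrix, one row per sub-domain, one column per donor; `NA`
#'   rows for flagged sub-domains).
#' @export
domain_profile <- function(gene, domain_terms = default_domains(), db,
                           atlases, grid, radius = 10, alpha = 0.05) {
  n_donors <- length(atlases)
  donor_ids <- vapply(atlases, function(a) a$donor_id, "")
  rows <- list(); betas <- list()
  for (dom in names(domain_terms)) {
    for (sub in domain_terms[[dom]]) {
      studies <- withCallingHandlers(
        select_studies(db, sub),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (length(studies) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          domain = dom, subdomain = sub, n_studies = 0L,
          mean_beta = NA_real_, t = NA_real_, p = NA_real_,
          repetitions = NA_integer_, flagged = TRUE)
        betas[[length(betas) + 1L]] <- rep(NA_real_, n_donors)
        next
      }
      map <- build_activation_map(studies, grid, radius, term = sub)
      res <- correlate_gene_map(gene, map, atlases, alpha = alpha)
      re <- res$random_effects
      rows[[length(rows) + 1L]] <- data.frame(
        domain = dom, subdomain = sub, n_studies = length(studies),
        mean_beta = re$mean_slope, t = re$t_stat, p = re$p_two_tailed,
        repetitions = res$repetitions, flagged = FALSE)
      betas[[length(betas) + 1L]] <- vapply(res$fits, `[[`, 0, "slope")
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  bm <- do.call(rbind, betas)
  dimnames(bm) <- list(summary$subdomain, donor_ids)
  list(summary = summary, betas = bm)
}
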