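#' Default probe table for the focal and pathway genes
#'
#' Microarray probe identifiers for the genes handled by the default
#' simulation and screening configuration: the focal circadian gene CRY2
#' (three probes), the navigation-linked S100B, the magnetoreception
#' comparator ISCA1, and the core clock-component genes. CRY1 carries a
#' synthetic placeholder probe id (no microarray probe list is bundled for
#' it).
#'
#' @return data.frame with columns `gene`, `probe_id`.
#' @export
default_probe_table <- function() {
  tab <- list(
    CRY2 = c("A_23_P127394", "A_23_P388027", "A_24_P158587"),
    S100B = c("A_23_P143526", "CUST_17042_PI4162"),
    ISCA1 = c("A_23_P216766", "A_24_P387609", "A_24_P75543",
              "A_32_P25253", "CUST_7371_PI41626"),
    CLOCK = c("A_23_P419038", "CUST_16994_PI4162", "CUST_190_PI416408"),
    PER1 = c("A_23_P89589", "CUST_12126_PI4162"),
    PER2 = c("A_23_P209320", "A_23_P411162"),
    PER3 = c("A_23_P201461", "A_24_P230948", "A_24_P291231"),
    ARNTL = c("A_23_P162037", "CUST_14423_PI4162"),
    CSNK1D = "CUST_8506_PI4162",
    CSNK1E = c("A_23_P29263", "A_23_P40664", "A_24_P918436"),
    ARNT2 = c("A_23_P83579", "CUST_7028_PI41626"),
    NPAS2 = c("A_23_P218597", "A_23_P415984"),
    TIMELESS = c("A_23_P53276", "A_24_P231004"),
    CRY1 = "SYNTH_CRY1_P1"
  )
  data.frame(
    gene = rep(names(tab), lengths(tab)),
    probe_id = unlist(tab, use.names = FALSE)
  )
}

#' Core clock-component gene symbols
#'
#' The eleven circadian-pathway genes screened alongside the focal gene.
#'
#' @return character vector.
#' @export
clock_genes <- function() {
  c("CLOCK", "CRY1", "ARNTL", "PER1", "PER2", "PER3", "CSNK1D",
    "CSNK1E", "NPAS2", "TIMELESS", "ARNT2")
}

#' Simulation configuration
#'
#' Defines the synthetic study: a study database whose target-term studies
#' concentrate foci in hotspot regions, donor expression atlases with
#' planted expression-activation correlations, and a behavioral table with
#' a planted sex-adjusted correlation. Defaults mirror the scale of the
#' real resources this emulates: 6 donors with ~500 sampling sites each,
#' a target term carried by 61 studies averaging 49 foci (about 2,989
#' activations), three probes for the focal gene, and a behavioral sample
#' of 292 (155 female) with a planted sex-adjusted correlation of 0.15.
#'
#' @param seed integer seed; all three generators are deterministic given
#'   the config (which includes the seed).
#' @param n_donors number of donors.
#' @param n_sites_per_donor sampling sites per donor; a vector of length
#'   `n_donors` allows asymmetric coverage.
#' @param n_studies_total total studies in the database.
#' @param n_term_studies studies carrying the target term.
#' @param foci_per_study_mean mean per-study focus count
#'   (Poisson, truncated at 1).
#' @param focus_scatter_sd isotropic SD (mm) of term-study foci around
#'   their hotspot centers.
#' @param hotspot_centers matrix (k x 3) of MNI mm hotspot centers; must
#'   lie inside the grid box. Defaults to medial-temporal/retrosplenial
#'   coordinates typical of navigation activations.
#' @param planted_rho named numeric vector, gene -> planted site-level
#'   correlation with the target map (|rho| < 1). Genes not listed are
#'   generated with rho 0 when present in `n_probes` or the probe table.
#' @param n_probes named integer vector, gene -> probe count; genes absent
#'   here fall back to the probe table, then to 1.
#' @param probe_noise_sd SD of i.i.d. Gaussian probe noise around the
#'   latent gene signal (expression units; the latent signal has SD 1).
#' @param genes genes to simulate; default is every gene named in
#'   `planted_rho` plus the probe table's genes.
#' @param term target term label.
#' @param vocabulary pool of concept term expressions scattered over the
#'   studies; each study carries the constituent words of two sampled
#'   concepts, so conjunction queries resolve to non-trivial study sets.
#'   Defaults to the sub-domain expressions of [default_domains()].
#' @param support_fraction fraction of each donor's sites drawn from
#'   voxels with nonzero target-map support (the rest are uniform
#'   background voxels).
#' @param behavior_n,behavior_n_female behavioral sample size and female
#'   count.
#' @param behavior_partial_rho planted sex-adjusted latent correlation.
#' @param sex_effect_sod,sex_effect_circadian additive latent shifts (in
#'   SD units) for male participants; nonzero values create the
#'   confounding that the partial correlation must remove.
#' @param item_noise_sd SD of per-item noise around the latent
#'   sense-of-direction score.
#' @param reverse_items reverse-keyed item indices used when emitting item
#'   responses (so that scoring with the same set recovers the latent
#'   ordering).
#' @param grid the [voxel_grid()] everything is generated on.
#' @param radius focus sphere radius (mm) used when a config-driven
#'   pipeline builds maps.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_donors = 6L,
                              n_sites_per_donor = 500L,
                              n_studies_total = 400L,
                              n_term_studies = 61L,
                              foci_per_study_mean = 49,
                              focus_scatter_sd = 8,
                              hotspot_centers = default_hotspots(),
                              planted_rho = c(CRY2 = 0.3),
                              n_probes = NULL,
                              probe_noise_sd = 0.3,
                              genes = NULL,
                              term = "navigation",
                              vocabulary = NULL,
                              support_fraction = 0.5,
                              behavior_n = 292L,
                              behavior_n_female = 155L,
                              behavior_partial_rho = 0.15,
                              sex_effect_sod = 0.8,
                              sex_effect_circadian = 0.8,
                              item_noise_sd = 0.8,
                              reverse_items = default_reverse_items(),
                              grid = voxel_grid(),
                              radius = 10) {
  hotspot_centers <- to_coord_matrix(hotspot_centers)
  if (nrow(hotspot_centers) == 0L) stop("hotspot_centers must be non-empty")
  if (!all(inside_grid(grid, hotspot_centers))) {
    stop("hotspot center outside the grid bounding box")
  }
  stopifnot(
    n_term_studies <= n_studies_total,
    all(abs(planted_rho) < 1),
    foci_per_study_mean > 0, focus_scatter_sd > 0,
    probe_noise_sd >= 0,
    behavior_n_female >= 0, behavior_n_female <= behavior_n,
    abs(behavior_partial_rho) < 1,
    support_fraction >= 0, support_fraction <= 1
  )
  if (length(n_sites_per_donor) == 1L) {
    n_sites_per_donor <- rep(as.integer(n_sites_per_donor), n_donors)
  }
  stopifnot(length(n_sites_per_donor) == n_donors, all(n_sites_per_donor >= 4))
  probe_tab <- default_probe_table()
  if (is.null(genes)) {
    genes <- union(names(planted_rho), unique(probe_tab$gene))
  }
  np <- stats::setNames(integer(length(genes)), genes)
  for (g in genes) {
    np[g] <- if (!is.null(n_probes) && g %in% names(n_probes)) {
      as.integer(n_probes[[g]])
    } else if (g %in% probe_tab$gene) {
      sum(probe_tab$gene == g)
    } else 1L
  }
  stopifnot(all(np >= 1L))
  if (is.null(vocabulary)) {
    vocabulary <- setdiff(unname(unlist(default_domains())), term)
  }
  structure(
    list(seed = as.integer(seed), n_donors = as.integer(n_donors),
         n_sites_per_donor = n_sites_per_donor,
         n_studies_total = as.integer(n_studies_total),
         n_term_studies = as.integer(n_term_studies),
         foci_per_study_mean = foci_per_study_mean,
         focus_scatter_sd = focus_scatter_sd,
         hotspot_centers = hotspot_centers,
         planted_rho = planted_rho, n_probes = np,
         probe_noise_sd = probe_noise_sd, genes = genes, term = term,
         vocabulary = vocabulary, support_fraction = support_fraction,
         behavior_n = as.integer(behavior_n),
         behavior_n_female = as.integer(behavior_n_female),
         behavior_partial_rho = behavior_partial_rho,
         sex_effect_sod = sex_effect_sod,
         sex_effect_circadian = sex_effect_circadian,
         item_noise_sd = item_noise_sd, reverse_items = reverse_items,
         grid = grid, radius = radius),
    class = "simulation_config"
  )
}

#' Default hotspot centers (MNI mm)
#'
#' Bilateral hippocampus, parahippocampal gyrus and the retrosplenial
#' midline -- the canonical loci of navigation-task activations.
#'
#' @return numeric matrix (5 x 3).
#' @export
default_hotspots <- function() {
  rbind(
    c(-24, -24, -12),  # L hippocampus
    c(24, -24, -12),   # R hippocampus
    c(-26, -40, -10),  # L parahippocampal
    c(26, -40, -10),   # R parahippocampal
    c(2, -52, 10)      # retrosplenial
  )
}

#' Generate a synthetic study database
#'
#' `n_term_studies` of the `n_studies_total` studies carry the target term
#' and draw their foci from isotropic Gaussians around the hotspot centers
#' (a uniformly chosen center per focus, SD = `focus_scatter_sd`);
#' the remaining studies draw foci uniformly over the grid bounding box and
#' carry two random single-word labels from the vocabulary, giving the
#' resampling null genuine spatial heterogeneity and giving conjunction
#' queries non-trivial study sets. Per-study focus counts are Poisson with
#' mean `foci_per_study_mean`, truncated at 1. Fully reproducible from the
#' config's seed.
#'
#' @param cfg a [simulation_config()].
#' @return a [study_database()].
#' @export
generate_study_database <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, "studies"))
  n <- cfg$n_studies_total
  ids <- sprintf("study_%04d", seq_len(n))
  term_ids <- sort(sample.int(n, cfg$n_term_studies))
  is_term <- seq_len(n) %in% term_ids
  lo <- cfg$grid$origin
  hi <- grid_upper(cfg$grid)
  k <- nrow(cfg$hotspot_centers)
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    nf <- max(1L, stats::rpois(1, cfg$foci_per_study_mean))
    # each study is tagged with the constituent words of two concepts from
    # the vocabulary (term expressions, possibly two-word), so conjunction
    # queries resolve to non-trivial study sets
    concept_words <- unlist(strsplit(sample(cfg$vocabulary, 2), " "))
    if (is_term[i]) {
      ctr <- cfg$hotspot_centers[sample.int(k, nf, replace = TRUE), , drop = FALSE]
      foci <- ctr + matrix(stats::rnorm(3 * nf, sd = cfg$focus_scatter_sd), nf, 3)
      terms <- c(cfg$term, concept_words)
    } else {
      foci <- cbind(stats::runif(nf, lo[1], hi[1]),
                    stats::runif(nf, lo[2], hi[2]),
                    stats::runif(nf, lo[3], hi[3]))
      terms <- concept_words
    }
    studies[[i]] <- study_record(ids[i], terms = terms, foci = foci)
  }
  study_database(studies)
}

#' Generate donor expression atlases with planted spatial correlations
#'
#' Per donor, sampling sites are drawn from the voxels of the target map:
#' a `support_fraction` share from voxels with nonzero activation
#' likelihood and the rest uniformly over all voxels, each site jittered
#' uniformly within its voxel (so nearest-voxel lookup recovers the voxel).
#' For each gene with planted correlation rho, the latent site signal is
#' `rho * z + sqrt(1 - rho^2) * eps` where `z` is the donor's standardized
#' map value vector and `eps` is standard normal; each of the gene's probes
#' then adds independent `Normal(0, probe_noise_sd)` noise. With `k` probes
#' averaged, the expected observed correlation is attenuated to
#' `rho / sqrt(1 + probe_noise_sd^2 / k)`.
#'
#' @param cfg a [simulation_config()].
#' @param target_map an `activation_map` built on `cfg$grid`.
#' @return list of [expression_atlas()] objects, one per donor.
#' @export
generate_expression_atlases <- function(cfg, target_map) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(target_map, "activation_map"),
            identical(target_map$grid$shape, cfg$grid$shape))
  set.seed(derive_seed(cfg$seed, "atlases"))
  support <- which(target_map$values > 0)
  nv <- n_voxels(cfg$grid)
  probe_tab <- default_probe_table()
  rho <- function(g) if (g %in% names(cfg$planted_rho)) cfg$planted_rho[[g]] else 0

  lapply(seq_len(cfg$n_donors), function(d) {
    ns <- cfg$n_sites_per_donor[d]
    n_sup <- min(round(cfg$support_fraction * ns), length(support))
    vox <- c(
      if (n_sup > 0) sample(support, n_sup, replace = n_sup > length(support)),
      sample.int(nv, ns - n_sup, replace = TRUE)
    )
    centers <- voxel_to_mm(cfg$grid, linear_to_voxel(cfg$grid, vox))
    jitter <- matrix(stats::runif(3 * ns, -0.45, 0.45), ns, 3) * cfg$grid$spacing
    mm <- centers + jitter
    sites <- data.frame(site_id = sprintf("D%d_site_%04d", d, seq_len(ns)),
                        x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3])
    zraw <- target_map$values[vox]
    z <- if (stats::sd(zraw) > 0) (zraw - mean(zraw)) / stats::sd(zraw) else
      rep(0, ns)
    rows <- list(); probe_map <- character()
    for (g in cfg$genes) {
      r <- rho(g)
      latent <- r * z + sqrt(1 - r^2) * stats::rnorm(ns)
      kp <- cfg$n_probes[[g]]
      pids <- probe_tab$probe_id[probe_tab$gene == g]
      if (length(pids) < kp) {
        pids <- c(pids, sprintf("SYNTH_%s_P%d", g, seq_len(kp - length(pids))))
      }
      pids <- pids[seq_len(kp)]
      for (p in pids) {
        rows[[p]] <- latent + stats::rnorm(ns, sd = cfg$probe_noise_sd)
        probe_map[p] <- g
      }
    }
    pv <- do.call(rbind, rows)
    rownames(pv) <- names(rows)
    expression_atlas(sprintf("donor_%02d", d), sites, pv, probe_map)
  })
}

#' Generate a synthetic behavioral table
#'
#' Latent sense-of-direction and circadian-regularity scores are bivariate
#' standard normal with correlation `behavior_partial_rho`; male
#' participants additionally receive `sex_effect_sod` and
#' `sex_effect_circadian` SD shifts on the two latents, confounding the
#' marginal association. The latent sense-of-direction score is expressed
#' as 16 Likert items (per-item Gaussian noise, column-standardized, then
#' equal-width binning into 1..5, reverse-keyed items emitted as `6 - v`);
#' the circadian latent is binned into the 1..9 integer scale the same
#' way.
#'
#' @param cfg a [simulation_config()].
#' @return data.frame with `participant_id`, `sex` (`"F"`/`"M"`, female
#'   count exactly `behavior_n_female`), `item01`..`item16`, `circadian`.
#' @export
generate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, "behavior"))
  n <- cfg$behavior_n
  sex <- rep("M", n)
  sex[sample.int(n, cfg$behavior_n_female)] <- "F"
  male <- as.numeric(sex == "M")
  rho <- cfg$behavior_partial_rho
  sod <- stats::rnorm(n)
  circ <- rho * sod + sqrt(1 - rho^2) * stats::rnorm(n)
  sod <- sod + cfg$sex_effect_sod * male
  circ <- circ + cfg$sex_effect_circadian * male
  items <- matrix(0L, n, 16)
  for (j in 1:16) {
    v <- sod + stats::rnorm(n, sd = cfg$item_noise_sd)
    b <- bin_standardized(v, 5L)
    if (j %in% cfg$reverse_items) b <- 6L - b
    items[, j] <- b
  }
  colnames(items) <- sprintf("item%02d", 1:16)
  circ_b <- bin_standardized(circ, 9L)
  out <- data.frame(participant_id = sprintf("P%04d", seq_len(n)), sex = sex)
  out <- cbind(out, as.data.frame(items))
  out$circadian <- circ_b
  out
}

# standardize, then monotone equal-width binning onto 1..k; interior bins
# span about +/- 2 SD, the outer bins absorb the tails
bin_standardized <- function(v, k) {
  z <- (v - mean(v)) / stats::sd(v)
  width <- 4 / k
  cuts <- (seq_len(k - 1) - k / 2) * width
  as.integer(findInterval(z, cuts) + 1L)
}

# deterministic substream seed from a master seed and a stage label
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% (.Machine$integer.max - 1)) + 1L
}
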