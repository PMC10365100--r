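#' Donor expression atlas
#'
#' One donor's sampling sites (MNI mm coordinates) with probe-level
#' normalized expression and a probe-to-gene mapping. Values must be
#' complete: missing measurements are rejected rather than imputed, since
#' the intended inputs are already-normalized expression exports.
#'
#' @param donor_id donor identifier string.
#' @param sites data.frame with columns `site_id`, `x_mm`, `y_mm`, `z_mm`;
#'   site ids unique within the donor.
#' @param probe_values numeric matrix, probes x sites, with probe ids as
#'   row names; column count must equal `nrow(sites)`.
#' @param probe_map named character vector mapping probe id -> gene symbol
#'   (every probe maps to exactly one gene). Gene symbols are
#'   case-sensitive.
#' @return An object of class `expression_atlas`.
#' @export
expression_atlas <- function(donor_id, sites, probe_values, probe_map) {
  stopifnot(is.character(donor_id), length(donor_id) == 1L)
  stopifnot(is.data.frame(sites),
            all(c("site_id", "x_mm", "y_mm", "z_mm") %in% names(sites)))
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site_ids for donor ", donor_id)
  }
  probe_values <- as.matrix(probe_values)
  if (is.null(rownames(probe_values))) stop("probe_values must have probe-id row names")
  if (ncol(probe_values) != nrow(sites)) {
    stop("probe_values has ", ncol(probe_values), " columns but ",
         nrow(sites), " sites")
  }
  if (any(!is.finite(probe_values))) {
    stop("missing or non-finite expression values for donor ", donor_id)
  }
  probe_map <- unlist(probe_map)
  if (!all(rownames(probe_values) %in% names(probe_map))) {
    stop("probes without a gene mapping: ",
         paste(setdiff(rownames(probe_values), names(probe_map)), collapse = ", "))
  }
  structure(
    list(donor_id = donor_id, sites = sites, probe_values = probe_values,
         probe_map = probe_map[rownames(probe_values)]),
    class = "expression_atlas"
  )
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: donor %s, %d sites, %d probes, %d genes\n",
              x$donor_id, nrow(x$sites), nrow(x$probe_values),
              length(unique(x$probe_map))))
  invisible(x)
}

# mm coordinate matrix of an atlas's sites
atlas_site_mm <- function(atlas) {
  as.matrix(atlas$sites[, c("x_mm", "y_mm", "z_mm")])
}

#' Collapse an atlas's probes to a single gene expression vector
#'
#' Per sampling site, the unweighted mean over all probes mapped to the
#' gene -- the standard probe-averaging step before any spatial analysis.
#'
#' @param atlas an [expression_atlas()].
#' @param gene gene symbol (case-sensitive).
#' @return An object of class `gene_expression_vector`: list with
#'   `donor_id`, `gene`, `values` (one per site, in the atlas's site
#'   order), `site_ids`.
#' @export
average_probes <- function(atlas, gene) {
  stopifnot(inherits(atlas, "expression_atlas"))
  rows <- which(atlas$probe_map == gene)
  if (length(rows) == 0L) {
    stop("gene '", gene, "' not in atlas for donor ", atlas$donor_id,
         "; available: ", paste(sort(unique(atlas$probe_map)), collapse = ", "))
  }
  vals <- if (length(rows) == 1L) atlas$probe_values[rows, ]
          else colMeans(atlas$probe_values[rows, , drop = FALSE])
  structure(
    list(donor_id = atlas$donor_id, gene = gene, values = as.numeric(vals),
         site_ids = atlas$sites$site_id),
    class = "gene_expression_vector"
  )
}

#' Standardize a numeric vector to mean 0, sample SD 1
#'
#' Sample SD uses the n-1 denominator. Constant input is an error ("zero
#' variance") rather than a silent zero vector, because every downstream
#' correlation is undefined there.
#'
#' @param values numeric vector, length >= 3.
#' @return numeric vector with mean 0 and sample SD 1.
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 3L, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Write / read expression atlases as a long CSV
#'
#' Schema: `donor_id, site_id, x_mm, y_mm, z_mm, probe_id, gene, value`,
#' one row per (donor, site, probe). The round trip is lossless; duplicate
#' (donor, site, probe) keys or non-numeric values are load errors.
#'
#' @param atlases list of [expression_atlas()] objects.
#' @param path CSV file path.
#' @return `write_expression_csv` returns `path` invisibly;
#'   `load_expression_csv` returns a list of atlases named by donor id.
#' @export
write_expression_csv <- function(atlases, path) {
  if (inherits(atlases, "expression_atlas")) atlases <- list(atlases)
  rows <- lapply(atlases, function(a) {
    probes <- rownames(a$probe_values)
    data.frame(
      donor_id = a$donor_id,
      site_id = rep(a$sites$site_id, each = length(probes)),
      x_mm = rep(a$sites$x_mm, each = length(probes)),
      y_mm = rep(a$sites$y_mm, each = length(probes)),
      z_mm = rep(a$sites$z_mm, each = length(probes)),
      probe_id = rep(probes, times = nrow(a$sites)),
      gene = rep(unname(a$probe_map[probes]), times = nrow(a$sites)),
      # column-major flattening: probe varies fastest, matching the rep()s above
      value = as.numeric(a$probe_values)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
load_expression_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(
    donor_id = "character", site_id = "character", probe_id = "character",
    gene = "character"
  ))
  need <- c("donor_id", "site_id", "x_mm", "y_mm", "z_mm", "probe_id", "gene", "value")
  if (!all(need %in% names(d))) {
    stop("expression CSV missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (!is.numeric(d$value) || any(!is.finite(d$value))) {
    stop("non-numeric or missing expression values in ", path)
  }
  key <- paste(d$donor_id, d$site_id, d$probe_id, sep = "\r")
  if (anyDuplicated(key)) {
    k <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop(sprintf("duplicate expression row for donor=%s site=%s probe=%s",
                 k[1], k[2], k[3]))
  }
  lapply(split(d, d$donor_id), function(dd) {
    site_tab <- unique(dd[, c("site_id", "x_mm", "y_mm", "z_mm")])
    site_tab <- site_tab[order(match(site_tab$site_id, dd$site_id)), , drop = FALSE]
    rownames(site_tab) <- NULL
    probes <- unique(dd$probe_id)
    m <- matrix(NA_real_, length(probes), nrow(site_tab),
                dimnames = list(probes, NULL))
    m[cbind(match(dd$probe_id, probes), match(dd$site_id, site_tab$site_id))] <- dd$value
    pm <- dd$gene[match(probes, dd$probe_id)]
    names(pm) <- probes
    expression_atlas(dd$donor_id[1], site_tab, m, pm)
  })
}
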