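#' Per-study activation mask on a voxel grid
#'
#' A voxel is active for a study when its center lies within `radius` mm
#' (Euclidean) of at least one of the study's foci. Overlapping foci do not
#' double-count; foci outside the grid contribute only to voxels inside it.
#'
#' @param study a [study_record()].
#' @param grid a [voxel_grid()].
#' @param radius sphere radius in mm, >= 0. With `radius = 0` only voxels
#'   whose center coincides with a focus are active.
#' @return logical vector of length `prod(grid$shape)` in column-major
#'   voxel order.
#' @export
study_activation_mask <- function(study, grid, radius) {
  stopifnot(inherits(study, "study_record"), inherits(grid, "voxel_grid"),
            is.numeric(radius), length(radius) == 1L, radius >= 0)
  mask <- logical(n_voxels(grid))
  foci <- study$foci
  if (nrow(foci) == 0L) return(mask)
  sp <- grid$spacing
  org <- grid$origin
  shp <- grid$shape
  r2 <- radius^2
  for (f in seq_len(nrow(foci))) {
    p <- foci[f, ]
    # candidate index window per axis, clipped to the grid
    lo <- pmax(ceiling((p - radius - org) / sp) + 1, 1)
    hi <- pmin(floor((p + radius - org) / sp) + 1, shp)
    if (any(lo > hi)) next
    ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2]); kk <- seq.int(lo[3], hi[3])
    dx2 <- (org[1] + (ii - 1) * sp - p[1])^2
    dy2 <- (org[2] + (jj - 1) * sp - p[2])^2
    dz2 <- (org[3] + (kk - 1) * sp - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    hit <- which(d2 <= r2, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    lin <- voxel_linear_index(grid, cbind(ii[hit[, 1]], jj[hit[, 2]], kk[hit[, 3]]))
    mask[lin] <- TRUE
  }
  mask
}

#' Build a term-based meta-analytic activation map
#'
#' In the default `"likelihood"` mode each voxel's value is the fraction of
#' the supplied studies whose activation mask covers it -- the activation
#' likelihood of the voxel across the term's studies. The `"association"`
#' mode instead reports a two-proportion z statistic comparing the voxel's
#' activation frequency in the term studies against a set of comparison
#' (non-term) studies; values are then unbounded z scores, recorded in the
#' map's `mode` field.
#'
#' @param studies non-empty list of [study_record()]s.
#' @param grid a [voxel_grid()].
#' @param radius focus sphere radius in mm (default 10, the conventional
#'   meta-analytic kernel at this scale).
#' @param mode `"likelihood"` (default) or `"association"`.
#' @param comparison_studies list of [study_record()]s for the association
#'   mode's comparison proportion; required when `mode = "association"`.
#' @param term label recorded on the map (bookkeeping only).
#' @return An object of class `activation_map` with fields `grid`, `values`
#'   (numeric vector, column-major voxel order), `n_studies`, `term`,
#'   `mode`, `radius`.
#' @export
build_activation_map <- function(studies, grid, radius = 10,
                                 mode = c("likelihood", "association"),
                                 comparison_studies = NULL,
                                 term = NA_character_) {
  mode <- match.arg(mode)
  if (!is.list(studies) || length(studies) == 0L) {
    stop("no studies for term", if (!is.na(term)) paste0(" '", term, "'") else "")
  }
  counts <- integer(n_voxels(grid))
  for (s in studies) counts <- counts + study_activation_mask(s, grid, radius)
  n <- length(studies)
  if (mode == "likelihood") {
    values <- counts / n
  } else {
    if (is.null(comparison_studies) || length(comparison_studies) == 0L) {
      stop("association mode requires comparison_studies")
    }
    counts0 <- integer(n_voxels(grid))
    for (s in comparison_studies) {
      counts0 <- counts0 + study_activation_mask(s, grid, radius)
    }
    n0 <- length(comparison_studies)
    p1 <- counts / n
    p0 <- counts0 / n0
    pp <- (counts + counts0) / (n + n0)
    se <- sqrt(pp * (1 - pp) * (1 / n + 1 / n0))
    values <- ifelse(se > 0, (p1 - p0) / se, 0)
  }
  structure(
    list(grid = grid, values = values, n_studies = n, term = term,
         mode = mode, radius = radius),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "activation_map ('%s', %s mode): %d studies, radius %g mm, %d/%d voxels nonzero\n",
    x$term, x$mode, x$n_studies, x$radius, sum(x$values != 0), length(x$values)
  ))
  invisible(x)
}

#' Write / read an activation map as NIfTI-1
#'
#' The NIfTI affine is diagonal with the grid's spacing and carries the
#' grid origin, so voxel (1,1,1) maps to `grid$origin` in mm.
#'
#' @param map an `activation_map`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `write_activation_map_nifti` returns `path` invisibly;
#'   `read_activation_map_nifti` returns an `activation_map` (with `term`,
#'   `n_studies` and `mode` taken from `...` defaults since NIfTI does not
#'   carry them).
#' @export
write_activation_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  arr <- array(map$values, dim = map$grid$shape)
  img <- RNifti::asNifti(arr)
  aff <- diag(c(rep(map$grid$spacing, 3), 1))
  aff[1:3, 4] <- map$grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param term,n_studies,mode,radius metadata to attach on read.
#' @rdname write_activation_map_nifti
#' @export
read_activation_map_nifti <- function(path, term = NA_character_,
                                      n_studies = NA_integer_,
                                      mode = "likelihood", radius = NA_real_) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- aff[1, 1]
  origin <- aff[1:3, 4]
  shp <- dim(img)
  g <- voxel_grid(spacing = spacing,
                  xlim = c(origin[1], origin[1] + (shp[1] - 1) * spacing),
                  ylim = c(origin[2], origin[2] + (shp[2] - 1) * spacing),
                  zlim = c(origin[3], origin[3] + (shp[3] - 1) * spacing))
  structure(
    list(grid = g, values = as.numeric(img), n_studies = n_studies,
         term = term, mode = mode, radius = radius),
    class = "activation_map"
  )
}
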