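#' Study records and study databases
#'
#' A `study_record` holds one study's identifier, its lowercase term labels
#' (single words or two-word phrases, as produced by term-based tagging of
#' the literature), and its activation foci as MNI mm coordinates. A
#' `study_database` is a list of records plus a term-to-study index used for
#' fast term queries.
#'
#' @param study_id unique identifier string.
#' @param terms character vector of lowercase labels.
#' @param foci numeric matrix (n x 3) of MNI mm coordinates (possibly 0 rows).
#' @return `study_record` returns an object of class `study_record`.
#' @export
study_record <- function(study_id, terms = character(), foci = matrix(numeric(), 0, 3)) {
  stopifnot(is.character(study_id), length(study_id) == 1L, nzchar(study_id))
  terms <- unique(tolower(as.character(terms)))
  if (length(foci) == 0L) {
    foci <- matrix(numeric(), 0, 3)
  } else {
    foci <- to_coord_matrix(foci)
  }
  if (nrow(foci) && any(!is.finite(foci))) {
    stop("non-finite focus coordinates in study ", study_id)
  }
  structure(list(study_id = study_id, terms = terms, foci = foci),
            class = "study_record")
}

#' @param studies list of [study_record()] objects with unique ids.
#' @return `study_database` returns an object of class `study_database`
#'   with fields `studies` (named by study id) and `index`
#'   (term -> character vector of study ids).
#' @rdname study_record
#' @export
study_database <- function(studies) {
  stopifnot(is.list(studies), length(studies) > 0L)
  ids <- vapply(studies, function(s) s$study_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate study ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(studies) <- ids
  index <- list()
  for (s in studies) {
    for (tm in s$terms) index[[tm]] <- c(index[[tm]], s$study_id)
  }
  structure(list(studies = studies, index = index), class = "study_database")
}

#' @export
print.study_database <- function(x, ...) {
  nf <- sum(vapply(x$studies, function(s) nrow(s$foci), 0))
  cat(sprintf("study_database: %d studies, %d foci, %d distinct terms\n",
              length(x$studies), nf, length(x$index)))
  invisible(x)
}

#' Select studies matching a term expression
#'
#' A term expression is either a single label or a conjunction of two
#' labels. A string containing a space is first looked up verbatim (built-in
#' two-word phrases match directly); if absent from the index it is split
#' into its two words and the intersection of the two labels' study sets is
#' returned -- the conjunction rule used when a two-word concept has no
#' dedicated label.
#'
#' @param db a [study_database()].
#' @param term_expr a label string, a two-word phrase, or a length-2
#'   character vector (explicit conjunction).
#' @return list of `study_record`s ordered by study id. Unknown labels give
#'   an empty list with a warning, so screens over many terms can proceed.
#' @export
select_studies <- function(db, term_expr) {
  stopifnot(inherits(db, "study_database"))
  term_expr <- tolower(as.character(term_expr))
  stopifnot(length(term_expr) %in% 1:2, all(nzchar(term_expr)))

  lookup <- function(label) {
    ids <- db$index[[label]]
    if (is.null(ids)) {
      warning("term not found in database: '", label, "'", call. = FALSE)
      character()
    } else {
      ids
    }
  }

  if (length(term_expr) == 1L && grepl(" ", term_expr)) {
    if (!is.null(db$index[[term_expr]])) {
      ids <- db$index[[term_expr]]
    } else {
      words <- strsplit(term_expr, " +")[[1]]
      if (length(words) != 2L) {
        stop("term expressions may have at most two words: '", term_expr, "'")
      }
      term_expr <- words
      ids <- intersect(lookup(term_expr[1]), lookup(term_expr[2]))
    }
  } else if (length(term_expr) == 2L) {
    ids <- intersect(lookup(term_expr[1]), lookup(term_expr[2]))
  } else {
    ids <- lookup(term_expr)
  }
  db$studies[sort(ids)]
}

#' Write / read a study database as plain CSV files
#'
#' `studies.csv` holds `study_id` and pipe-delimited `terms`; `foci.csv`
#' holds one row per focus (`study_id, x_mm, y_mm, z_mm`).
#'
#' @param db a [study_database()].
#' @param dir directory to write into (created if needed).
#' @return `write_study_csv` returns `dir` invisibly; `read_study_csv`
#'   returns a [study_database()].
#' @export
write_study_csv <- function(db, dir) {
  stopifnot(inherits(db, "study_database"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(db$studies)
  terms <- vapply(db$studies, function(s) paste(s$terms, collapse = "|"), "")
  utils::write.csv(data.frame(study_id = ids, terms = terms),
                   file.path(dir, "studies.csv"), row.names = FALSE)
  foci <- do.call(rbind, lapply(db$studies, function(s) {
    if (nrow(s$foci) == 0L) return(NULL)
    data.frame(study_id = s$study_id, x_mm = s$foci[, 1],
               y_mm = s$foci[, 2], z_mm = s$foci[, 3])
  }))
  if (is.null(foci)) {
    foci <- data.frame(study_id = character(), x_mm = numeric(),
                       y_mm = numeric(), z_mm = numeric())
  }
  utils::write.csv(foci, file.path(dir, "foci.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(dir) {
  st <- utils::read.csv(file.path(dir, "studies.csv"), colClasses = "character")
  fo <- utils::read.csv(file.path(dir, "foci.csv"))
  foci_by_id <- split(seq_len(nrow(fo)), fo$study_id)
  studies <- lapply(seq_len(nrow(st)), function(i) {
    terms <- strsplit(st$terms[i], "|", fixed = TRUE)[[1]]
    rows <- foci_by_id[[st$study_id[i]]]
    foci <- if (is.null(rows)) matrix(numeric(), 0, 3) else
      as.matrix(fo[rows, c("x_mm", "y_mm", "z_mm")])
    study_record(st$study_id[i], terms = terms[nzchar(terms)], foci = foci)
  })
  study_database(studies)
}
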