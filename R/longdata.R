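#' Longitudinal abundance dataset
#'
#' Container for irregularly spaced longitudinal abundance data: one block
#' per subject holding the observation times and an `n_i x p` matrix of
#' (transformed) abundances. The stationary Gaussian graphical model assumes
#' each row is a draw from `N(0, Sigma)` with the same precision matrix
#' `Omega = Sigma^-1` shared by all subjects and times, and within-subject
#' correlation between two times decaying as `exp(-tau * |t1 - t2|)`.
#'
#' @param x a data.frame in wide form: one row per (subject, time)
#'   observation, with a subject-id column, a time column, and one numeric
#'   column per taxon.
#' @param subject,time names of the subject-id and time columns.
#' @param center if `TRUE` (default), each taxon is centered to mean zero
#'   across all rows pooled (the model assumes a single global mean).
#' @return an object of class `"longitudinal_data"`: a list with elements
#'   `subjects` (list of blocks, each with `subject_id`, `times`, `values`,
#'   and optionally `covariates`), `p`, `taxon_names`, `n` (total rows),
#'   `m` (number of subjects), and `centers` (the subtracted taxon means).
#' @examples
#' df <- data.frame(subject_id = rep(1:2, each = 3), time = rep(0:2, 2),
#'                  taxA = rnorm(6), taxB = rnorm(6))
#' d <- longitudinal_data(df)
#' d$m; d$n; d$p
#' @export
longitudinal_data <- function(x, subject = "subject_id", time = "time",
                              center = TRUE) {
  x <- as.data.frame(x)
  if (!subject %in% names(x)) stop("no subject column '", subject, "'")
  if (!time %in% names(x)) stop("no time column '", time, "'")
  taxa <- setdiff(names(x), c(subject, time))
  if (length(taxa) < 1L) stop("no taxon columns found")
  vals <- as.matrix(x[, taxa, drop = FALSE])
  if (!is.numeric(vals)) stop("taxon columns must be numeric")
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("abundance values must be finite with no missing entries")
  }
  tm <- x[[time]]
  if (!is.numeric(tm) || any(!is.finite(tm))) {
    stop("observation times must be finite numeric")
  }
  sid <- x[[subject]]
  blocks <- lapply(split(seq_len(nrow(x)), factor(sid, levels = unique(sid))),
                   function(idx) {
    ti <- tm[idx]
    o <- order(ti)
    ti <- ti[o]
    if (anyDuplicated(ti)) {
      stop("duplicate observation times for subject ", sid[idx[1L]])
    }
    list(subject_id = as.character(sid[idx[1L]]), times = ti,
         values = vals[idx[o], , drop = FALSE])
  })
  new_longitudinal_data(unname(blocks), taxon_names = taxa, center = center)
}

# internal constructor from a list of subject blocks
new_longitudinal_data <- function(blocks, taxon_names, center = TRUE) {
  p <- length(taxon_names)
  for (b in blocks) {
    if (length(b$times) != nrow(b$values) || ncol(b$values) != p) {
      stop("inconsistent block dimensions")
    }
    if (is.unsorted(b$times, strictly = TRUE)) {
      stop("times must be strictly increasing within a subject")
    }
  }
  blocks <- lapply(blocks, function(b) {
    colnames(b$values) <- taxon_names
    b
  })
  ni <- vapply(blocks, function(b) length(b$times), integer(1L))
  centers <- rep(0, p)
  if (center) {
    allv <- do.call(rbind, lapply(blocks, `[[`, "values"))
    centers <- colMeans(allv)
    blocks <- lapply(blocks, function(b) {
      b$values <- sweep(b$values, 2L, centers)
      b
    })
  }
  structure(list(subjects = blocks, p = p, taxon_names = taxon_names,
                 n = sum(ni), m = length(blocks), centers = centers),
            class = "longitudinal_data")
}

#' @export
print.longitudinal_data <- function(x, ...) {
  ni <- vapply(x$subjects, function(b) length(b$times), integer(1L))
  cat("Longitudinal abundance data:", x$m, "subjects,", x$p, "taxa,",
      x$n, "observations\n")
  cat("  observations per subject:", paste(range(ni), collapse = "-"),
      sprintf("(mean %.1f)\n", mean(ni)))
  invisible(x)
}

#' @export
as.data.frame.longitudinal_data <- function(x, ...) {
  do.call(rbind, lapply(x$subjects, function(b) {
    data.frame(subject_id = b$subject_id, time = b$times,
               b$values, check.names = FALSE, row.names = NULL)
  }))
}

#' Attach per-subject covariates to a dataset
#'
#' Matches a covariate table to the subjects of a [longitudinal_data]
#' object by subject id. Used by the covariate-adjusted solver, where the
#' prior rate of the subject-level dampening parameter is
#' `alpha_i = exp(alpha' x_i)` with `x_i = (1, x_i1, ..., x_iq)`.
#'
#' @param data a `longitudinal_data` object.
#' @param covariates a data.frame with a `subject_id` column plus numeric
#'   covariate columns (no intercept column; it is added internally).
#' @return `data` with each block carrying a `covariates` vector.
#' @export
set_covariates <- function(data, covariates) {
  stopifnot(inherits(data, "longitudinal_data"))
  covariates <- as.data.frame(covariates)
  if (!"subject_id" %in% names(covariates)) {
    stop("covariate table needs a 'subject_id' column")
  }
  cols <- setdiff(names(covariates), "subject_id")
  key <- as.character(covariates$subject_id)
  data$subjects <- lapply(data$subjects, function(b) {
    i <- match(b$subject_id, key)
    if (is.na(i)) stop("no covariates for subject ", b$subject_id)
    v <- as.numeric(covariates[i, cols])
    if (any(!is.finite(v))) stop("non-finite covariates for subject ", b$subject_id)
    b$covariates <- stats::setNames(v, cols)
    b
  })
  data
}

# design matrix (with leading intercept) from block covariates
design_matrix <- function(data) {
  has <- vapply(data$subjects, function(b) !is.null(b$covariates), logical(1L))
  if (!any(has)) {
    return(matrix(1, data$m, 1L, dimnames = list(NULL, "(Intercept)")))
  }
  if (!all(has)) stop("covariates present for some subjects but not all")
  X <- do.call(rbind, lapply(data$subjects, `[[`, "covariates"))
  cbind("(Intercept)" = 1, X)
}
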