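# Readers and writers for the plain-text interchange formats: long/wide
# abundance tables (TSV/CSV), edge lists, adjacency matrices, fit JSON.

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a longitudinal abundance table
#'
#' Long format has columns `subject_id, time, taxon, value`; wide format
#' has `subject_id, time` plus one column per taxon. The delimiter is
#' inferred from the extension (`.csv` comma, otherwise tab). Taxon
#' ordering follows first appearance in the input; times are sorted within
#' subject.
#'
#' @param path file path.
#' @param format `"auto"` (detect from the header), `"long"` or `"wide"`.
#' @param center center each taxon to mean zero (default `TRUE`).
#' @return a [longitudinal_data] object.
#' @export
read_longitudinal <- function(path, format = c("auto", "long", "wide"),
                              center = TRUE) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "time") %in% names(df))) {
    stop("input needs 'subject_id' and 'time' columns")
  }
  if (format == "auto") {
    format <- if (all(c("taxon", "value") %in% names(df))) "long" else "wide"
  }
  if (format == "long") {
    if (!all(c("taxon", "value") %in% names(df))) {
      stop("long format needs 'taxon' and 'value' columns")
    }
    if (!is.numeric(df$value)) stop("'value' must be numeric")
    taxa <- unique(df$taxon)
    key <- interaction(df$subject_id, df$time, drop = TRUE)
    if (anyDuplicated(paste(key, df$taxon))) {
      stop("duplicate (subject, time, taxon) rows")
    }
    counts <- table(key)
    if (length(unique(tapply(df$taxon, key, function(z) length(unique(z))))) > 1L ||
        any(counts != length(taxa))) {
      stop("ragged taxa: every (subject, time) row must report all taxa")
    }
    wide <- stats::reshape(df, idvar = c("subject_id", "time"),
                           timevar = "taxon", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[, c("subject_id", "time", taxa)]
    df <- wide
  } else if (anyDuplicated(df[, c("subject_id", "time")])) {
    stop("duplicate (subject, time) rows")
  }
  longitudinal_data(df, center = center)
}

#' Write a longitudinal dataset
#'
#' @param data a [longitudinal_data] object.
#' @param path output path (`.csv` for comma-separated, else tab).
#' @param format `"long"` (subject_id, time, taxon, value) or `"wide"`.
#' @export
write_longitudinal <- function(data, path, format = c("long", "wide")) {
  format <- match.arg(format)
  wide <- as.data.frame(data)
  out <- if (format == "wide") wide else {
    taxa <- data$taxon_names
    do.call(rbind, lapply(taxa, function(tx) {
      data.frame(subject_id = wide$subject_id, time = wide$time,
                 taxon = tx, value = wide[[tx]])
    }))
  }
  utils::write.table(out, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a fitted network to plain-text files
#'
#' Writes three files with a common prefix: `<prefix>_edges.tsv`
#' (taxon_a, taxon_b, omega entries above the edge threshold),
#' `<prefix>_adjacency.tsv` (binary matrix), and `<prefix>_fit.json`
#' (penalty, dampening estimates, per-subject rate forecasts,
#' log-likelihood, EBIC, convergence info).
#'
#' @param fit an `"sggm"` object.
#' @param prefix output path prefix.
#' @param ebic_T EBIC tuning parameter recorded in the JSON.
#' @return (invisibly) the three file paths.
#' @export
write_network <- function(fit, prefix, ebic_T = 2) {
  stopifnot(inherits(fit, "sggm"))
  A <- adjacency(fit, fit$edge_threshold)
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  edges <- data.frame(taxon_a = fit$taxon_names[idx[, 1L]],
                      taxon_b = fit$taxon_names[idx[, 2L]],
                      omega = fit$omega[idx])
  f_edges <- paste0(prefix, "_edges.tsv")
  f_adj <- paste0(prefix, "_adjacency.tsv")
  f_json <- paste0(prefix, "_fit.json")
  utils::write.table(edges, f_edges, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(A, f_adj, sep = "\t", quote = FALSE)
  meta <- list(model = fit$model, lambda = fit$lambda,
               tau = fit[["tau"]], alpha = fit[["alpha"]],
               coefficients = as.list(fit$coefficients),
               tau_i = as.list(fit$tau_i),
               loglik = fit$loglik,
               loglik_is_surrogate = isTRUE(fit$loglik_surrogate),
               ebic = ebic(fit, T = ebic_T), ebic_T = ebic_T,
               n_edges = fit$n_edges, n = fit$n, p = fit$p, m = fit$m,
               iterations = fit$iterations, converged = fit$converged)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1L))], f_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(edges = f_edges, adjacency = f_adj, json = f_json))
}

#' Read an adjacency matrix written by [write_network]
#' @param path the `_adjacency.tsv` file.
#' @return binary matrix with taxon dimnames.
#' @export
read_adjacency <- function(path) {
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rownames(M) <- colnames(M)
  M
}
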