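#' Expression matrix container
#'
#' The central currency of the pipeline: a probe-by-sample matrix of log2
#' expression values together with probe class labels and sample metadata.
#' Probe classes follow the TaqMan array layout: measured miRNAs are
#' \code{"target"}, endogenous controls (U6 and friends) are
#' \code{"housekeeping"}, and the plant spike-in ath-miR159a is
#' \code{"negative_control"}.
#'
#' @param values numeric matrix, probes in rows, samples in columns; both
#'   dimnames must be set and unique.
#' @param probe_class character vector aligned to rows; one of
#'   \code{"target"}, \code{"housekeeping"}, \code{"negative_control"}.
#'   Defaults to all \code{"target"}.
#' @param samples data frame of per-sample metadata with at least a
#'   \code{sample} column matching \code{colnames(values)}; typically also
#'   \code{species}, \code{subset}, \code{replicate}.
#' @param normalized logical provenance flag: has between-sample
#'   normalization been applied?
#'
#' @return An object of class \code{"mir_expr"}: a list with elements
#'   \code{E} (the matrix), \code{probes} (data frame: probe, class),
#'   \code{samples}, and \code{normalized}.
#' @export
expression_matrix <- function(values, probe_class = NULL, samples = NULL,
                              normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe IDs in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in expression matrix")
  if (is.null(probe_class)) probe_class <- rep("target", nrow(values))
  probe_class <- as.character(probe_class)
  if (length(probe_class) != nrow(values))
    stop("probe_class length must equal number of probes")
  bad <- setdiff(unique(probe_class),
                 c("target", "housekeeping", "negative_control"))
  if (length(bad))
    stop("unknown probe_class value(s): ", paste(bad, collapse = ", "))
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(values),
                          stringsAsFactors = FALSE)
  } else {
    samples <- as.data.frame(samples)
    if (!"sample" %in% names(samples))
      stop("sample metadata must contain a 'sample' column")
    if (!identical(as.character(samples$sample), colnames(values)))
      stop("sample metadata rows must align with matrix columns")
  }
  structure(list(E = values,
                 probes = data.frame(probe = rownames(values),
                                     class = probe_class,
                                     stringsAsFactors = FALSE),
                 samples = samples,
                 normalized = isTRUE(normalized)),
            class = "mir_expr")
}

#' @export
dim.mir_expr <- function(x) dim(x$E)

#' @export
print.mir_expr <- function(x, ...) {
  cat(sprintf("mir_expr: %d probes x %d samples (%s)\n",
              nrow(x$E), ncol(x$E),
              if (x$normalized) "normalized" else "raw"))
  cls <- table(x$probes$class)
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  if ("subset" %in% names(x$samples)) {
    ss <- table(x$samples$subset)
    cat("  subsets:",
        paste(sprintf("%s(n=%d)", names(ss), ss), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an expression matrix by probes and/or samples
#'
#' Metadata stays aligned with the matrix.
#'
#' @param x a \code{mir_expr} object.
#' @param i probe index (integer, logical or character).
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.mir_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$E))
  if (missing(j)) j <- seq_len(ncol(x$E))
  if (is.character(i)) i <- match(i, rownames(x$E))
  if (is.character(j)) j <- match(j, colnames(x$E))
  expression_matrix(x$E[i, j, drop = FALSE],
                    probe_class = x$probes$class[i],
                    samples = x$samples[j, , drop = FALSE],
                    normalized = x$normalized)
}

#' Ct plate set container
#'
#' Long-format container for raw TaqMan Ct records plus sample metadata.
#'
#' @param records data frame with columns \code{sample}, \code{probe},
#'   \code{probe_class}, \code{ct}. Ct values must lie in [0, 40] (the
#'   array's undetected ceiling) after coercion.
#' @param samples optional data frame of sample metadata (\code{sample},
#'   \code{species}, \code{subset}, \code{replicate}).
#' @return An object of class \code{"ct_plates"}.
#' @export
ct_plates <- function(records, samples = NULL) {
  records <- as.data.frame(records)
  need <- c("sample", "probe", "probe_class", "ct")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("Ct records missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(records[, c("sample", "probe")]))
    stop("duplicate (sample, probe) Ct records")
  if (any(records$ct < 0 | records$ct > 40))
    stop("Ct values outside [0, 40] after coercion")
  ## every sample must measure the same probe universe
  tab <- table(records$sample)
  if (length(unique(tab)) != 1L)
    stop("samples do not share a common probe universe")
  if (is.null(samples))
    samples <- data.frame(sample = unique(records$sample),
                          stringsAsFactors = FALSE)
  structure(list(records = records, samples = as.data.frame(samples)),
            class = "ct_plates")
}

#' @export
print.ct_plates <- function(x, ...) {
  cat(sprintf("ct_plates: %d samples x %d probes\n",
              length(unique(x$records$sample)),
              length(unique(x$records$probe))))
  invisible(x)
}

#' Read-count matrix container for tumor miRNA-seq profiles
#'
#' @param counts non-negative integer matrix, miRNA rows (possibly
#'   isoform-level) by sample columns.
#' @param features data frame with columns \code{id} (matching rownames)
#'   and \code{parent} (the parent miRNA symbol an isoform belongs to).
#' @param samples data frame with columns \code{sample} (matching
#'   colnames), \code{analyte_id}, \code{subtype}, and optionally
#'   \code{sample_type}.
#' @return An object of class \code{"mir_counts"} with a \code{lib_size}
#'   element equal to the column sums.
#' @export
count_matrix <- function(counts, features = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have dimnames")
  if (is.null(features))
    features <- data.frame(id = rownames(counts),
                           parent = rownames(counts),
                           stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- data.frame(sample = colnames(counts),
                          analyte_id = colnames(counts),
                          subtype = NA_character_,
                          stringsAsFactors = FALSE)
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  if (!identical(as.character(features$id), rownames(counts)))
    stop("feature metadata must align with count rows")
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop("sample metadata must align with count columns")
  structure(list(counts = counts, features = features, samples = samples,
                 lib_size = colSums(counts)),
            class = "mir_counts")
}

#' @export
dim.mir_counts <- function(x) dim(x$counts)

#' @export
print.mir_counts <- function(x, ...) {
  cat(sprintf("mir_counts: %d features x %d samples, median lib %.3g\n",
              nrow(x$counts), ncol(x$counts),
              stats::median(x$lib_size)))
  invisible(x)
}
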