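#' Read a TaqMan array Ct export
#'
#' Reads the long-format CSV produced by plate-reader export (and by
#' [write_ct_export()]): one row per well with columns `sample`, `probe`,
#' `probe_class` and `ct`. The literal token `"Undetermined"` (any case)
#' and empty cells are coerced to the ceiling Ct = 40; numeric Ct values
#' above 40 are likewise clamped to 40. Values outside [0, 45] before
#' clamping are rejected. Duplicate (sample, probe) rows are an error.
#'
#' @param path CSV file path.
#' @param samples optional sample metadata data frame (`sample`,
#'   `species`, `subset`, `replicate`). If the CSV itself carries
#'   `species`/`subset`/`replicate` columns they are used instead.
#' @return A [ct_plates()] object.
#' @export
read_ct_export <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(raw) <- tolower(names(raw))
  need <- c("sample", "probe", "probe_class", "ct")
  for (col in need)
    if (!col %in% names(raw))
      stop("Ct export is missing required column: ", col)
  ct_chr <- trimws(raw$ct)
  undet <- tolower(ct_chr) == "undetermined" | ct_chr == ""
  ct <- suppressWarnings(as.numeric(ct_chr))
  ct[undet] <- 40
  if (anyNA(ct))
    stop("non-numeric Ct value(s) at line(s): ",
         paste(utils::head(which(is.na(ct)) + 1L, 5), collapse = ", "))
  if (any(ct < 0 | ct > 45))
    stop("Ct value(s) outside the valid range [0, 45]")
  ct <- pmin(ct, 40)
  rec <- data.frame(sample = raw$sample, probe = raw$probe,
                    probe_class = raw$probe_class, ct = ct,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(rec[, c("sample", "probe")]))
    stop("duplicate (sample, probe) rows in Ct export")
  if (is.null(samples) &&
      all(c("species", "subset", "replicate") %in% names(raw))) {
    samples <- unique(raw[, c("sample", "species", "subset", "replicate")])
  }
  ct_plates(rec, samples)
}

#' Transform Ct values to the log2 expression scale
#'
#' The maximum measurable Ct is 40, so expression is `E = 40.5 - min(Ct,
#' 40)`: an undetected well maps to E = 0.5 and each PCR cycle earlier
#' doubles the estimated abundance (one log2 unit).
#'
#' @param plates a [ct_plates()] object.
#' @return An unnormalized [expression_matrix()] (probe x sample).
#' @export
ct_to_log2 <- function(plates) {
  stopifnot(inherits(plates, "ct_plates"))
  rec <- plates$records
  probes <- unique(rec$probe)
  smp <- unique(rec$sample)
  E <- matrix(NA_real_, length(probes), length(smp),
              dimnames = list(probes, smp))
  E[cbind(match(rec$probe, probes), match(rec$sample, smp))] <-
    40.5 - pmin(rec$ct, 40)
  if (anyNA(E)) stop("incomplete probe x sample grid")
  cls <- rec$probe_class[match(probes, rec$probe)]
  meta <- plates$samples[match(smp, plates$samples$sample), , drop = FALSE]
  expression_matrix(E, probe_class = cls, samples = meta,
                    normalized = FALSE)
}

#' Normalization parameters for housekeeping-weighted cyclic loess
#'
#' @param span loess span (0 < span <= 1), default 0.7.
#' @param iterations number of cyclic passes over all sample pairs,
#'   default 5.
#' @param housekeeping_weight multiplicative fit weight given to
#'   housekeeping probes in each pairwise local regression, default 100.
#' @return A list of class `"norm_params"`.
#' @export
norm_params <- function(span = 0.7, iterations = 5,
                        housekeeping_weight = 100) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (iterations < 1) stop("iterations must be >= 1")
  if (housekeeping_weight < 1) stop("housekeeping_weight must be >= 1")
  structure(list(span = span, iterations = iterations,
                 housekeeping_weight = housekeeping_weight,
                 method = "all-pairs"),
            class = "norm_params")
}

#' Cyclic loess normalization with up-weighted housekeeping probes
#'
#' Removes intensity-dependent between-sample biases. Per cyclic
#' iteration, every unordered sample pair (i, j) is visited: with
#' M = E_i - E_j and A = (E_i + E_j)/2, a degree-1 loess curve of M on A
#' is fitted with fit weights `housekeeping_weight` for housekeeping
#' probes and 1 otherwise (tricube neighborhood weights multiplied by the
#' probe weights), and the fitted M-hat/(2 (n - 1)) is subtracted from
#' sample i and added to sample j. Accumulated over all pairs this is the
#' classical all-pairs cyclic scheme: a constant offset on one sample
#' shrinks geometrically over iterations.
#'
#' The negative-control probe takes no part in the fit and is passed
#' through unadjusted. A single-sample matrix is returned unchanged with
#' a warning.
#'
#' @param expr an unnormalized [expression_matrix()].
#' @param params a [norm_params()] object.
#' @return The normalized [expression_matrix()] (flagged `normalized`).
#' @export
cyclic_loess_normalize <- function(expr, params = norm_params()) {
  stopifnot(inherits(expr, "mir_expr"), inherits(params, "norm_params"))
  E <- expr$E
  n <- ncol(E)
  if (n < 2) {
    warning("fewer than two samples: normalization is a no-op")
    out <- expr
    out$normalized <- TRUE
    return(out)
  }
  use <- expr$probes$class != "negative_control"
  w <- ifelse(expr$probes$class[use] == "housekeeping",
              params$housekeeping_weight, 1)
  sub <- E[use, , drop = FALSE]
  for (it in seq_len(params$iterations)) {
    adj <- matrix(0, nrow(sub), n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        M <- sub[, i] - sub[, j]
        A <- (sub[, i] + sub[, j]) / 2
        if (all(M == 0)) next
        fit <- stats::loess(M ~ A, weights = w, span = params$span,
                            degree = 1, family = "gaussian")
        mhat <- stats::fitted(fit) / (2 * (n - 1))
        adj[, i] <- adj[, i] - mhat
        adj[, j] <- adj[, j] + mhat
      }
    }
    sub <- sub + adj
  }
  E[use, ] <- sub
  expression_matrix(E, probe_class = expr$probes$class,
                    samples = expr$samples, normalized = TRUE)
}

#' Filter unexpressed probes
#'
#' Keeps target probes achieving a normalized value of at least
#' `min_value` in at least `min_samples` samples (both bounds inclusive).
#' Housekeeping and negative-control probes are removed from the analysis
#' set; their IDs, and the IDs of filtered target probes, are retained in
#' the `"filtered"` attribute for provenance.
#'
#' @param expr a normalized [expression_matrix()].
#' @param min_value expression threshold (default 2).
#' @param min_samples minimum number of samples meeting it (default 3).
#' @return The filtered [expression_matrix()] containing target probes
#'   only. Errors if no probe survives.
#' @export
filter_expressed <- function(expr, min_value = 2, min_samples = 3) {
  stopifnot(inherits(expr, "mir_expr"))
  is_target <- expr$probes$class == "target"
  n_ok <- rowSums(expr$E >= min_value)
  keep <- is_target & n_ok >= min_samples
  if (!any(keep))
    stop("no probe passes the expression filter (>= ", min_value,
         " in >= ", min_samples, " samples)")
  out <- expr[which(keep), ]
  attr(out, "filtered") <- list(
    unexpressed = rownames(expr$E)[is_target & !keep],
    controls = rownames(expr$E)[!is_target])
  out
}
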