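#' Collapse technical replicates and isoform rows
#'
#' Columns sharing an analyte ID are technical replicates and are summed;
#' rows sharing a parent miRNA symbol (e.g. -3p and -5p isoforms) are
#' summed into one parent row. Conflicting subtype labels within an
#' analyte ID are an error. When a `sample_type` field is present, only
#' primary solid tumor profiles are retained.
#'
#' @param counts a [count_matrix()] with analyte IDs and parent symbols.
#' @param primary_only keep only `"Primary Solid Tumor"` samples when the
#'   annotation has a `sample_type` column (default TRUE).
#' @return The collapsed [count_matrix()]: one column per analyte, one
#'   row per parent miRNA.
#' @export
collapse_replicates_and_isoforms <- function(counts, primary_only = TRUE) {
  stopifnot(inherits(counts, "mir_counts"))
  smp <- counts$samples
  x <- counts$counts
  if (primary_only && "sample_type" %in% names(smp)) {
    keep <- smp$sample_type == "Primary Solid Tumor"
    smp <- smp[keep, , drop = FALSE]
    x <- x[, keep, drop = FALSE]
  }
  lab <- unique(smp[, c("analyte_id", "subtype")])
  if (anyDuplicated(lab$analyte_id))
    stop("conflicting subtype labels within an analyte ID: ",
         lab$analyte_id[duplicated(lab$analyte_id)][1])
  aid <- factor(smp$analyte_id, levels = unique(smp$analyte_id))
  xc <- x %*% stats::model.matrix(~ 0 + aid)
  colnames(xc) <- levels(aid)
  parent <- factor(counts$features$parent,
                   levels = unique(counts$features$parent))
  xr <- t(stats::model.matrix(~ 0 + parent)) %*% xc
  rownames(xr) <- levels(parent)
  meta <- smp[match(levels(aid), smp$analyte_id), , drop = FALSE]
  meta$sample <- levels(aid)
  rownames(meta) <- NULL
  count_matrix(xr,
               features = data.frame(id = levels(parent),
                                     parent = levels(parent),
                                     stringsAsFactors = FALSE),
               samples = meta)
}

#' Filter miRNAs unexpressed across the tumor cohort
#'
#' Keeps rows achieving at least `min_cpm` reads per million (computed
#' on raw library sizes) in at least `min_samples` samples; both bounds
#' inclusive.
#'
#' @param counts a [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples meeting it (default 29).
#' @export
filter_cpm <- function(counts, min_cpm = 1, min_samples = 29) {
  stopifnot(inherits(counts, "mir_counts"))
  if (any(counts$lib_size <= 0)) stop("library sizes must be positive")
  cpm <- sweep(counts$counts, 2, counts$lib_size, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  count_matrix(counts$counts[keep, , drop = FALSE],
               features = counts$features[keep, , drop = FALSE],
               samples = counts$samples)
}

tmm_quantile_factor <- function(x, lib, p = 0.75) {
  apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = p)
}

#' Trimmed mean of M-values scaling factors
#'
#' Relative composition factors for count libraries. The reference
#' sample is the one whose upper-quartile CPM is closest to the mean
#' upper quartile. For each sample, gene-wise log2 CPM ratios M and
#' average log2 CPM abundances A versus the reference are computed over
#' genes with positive counts in both; after trimming the most extreme
#' `trim_M` fraction of M at each end and `trim_A` of A, the factor is
#' 2 to the weighted mean of M with inverse asymptotic (binomial)
#' variance weights. Factors are rescaled to have zero mean log, so they
#' multiply library sizes without changing the global scale.
#'
#' @param counts a [count_matrix()].
#' @param trim_M two-sided M trim fraction (default 0.30).
#' @param trim_A two-sided A trim fraction (default 0.05).
#' @return named per-sample factor vector.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(counts, "mir_counts"))
  x <- counts$counts
  lib <- counts$lib_size
  if (ncol(x) < 2) stop("need at least two samples")
  uq <- tmm_quantile_factor(x, lib)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(i) {
    if (i == ref) return(1)
    tmm_pair_factor(x[, i], x[, ref], lib[i], lib[ref], trim_M, trim_A)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

tmm_pair_factor <- function(obs, ref, nO, nR, trim_M, trim_A) {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stop("sample shares no positively expressed gene with the reference")
  obs <- obs[pos]
  ref <- ref[pos]
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  w <- 1 / ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))
  n <- length(M)
  loM <- floor(n * trim_M) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  f <- sum(w[keep] * M[keep]) / sum(w[keep])
  if (!is.finite(f) || abs(f) < 1e-6) f <- 0
  2^f
}

#' Log2 counts per million with a library-scaled prior count
#'
#' Effective library sizes are `lib * factor`; the prior count is scaled
#' per library as `prior * lib_i / mean(lib)` so that zero counts map to
#' comparable values across libraries. Value:
#' `log2((count + prior_i) / (lib_i + 2 prior_i) * 1e6)`.
#'
#' @param counts a [count_matrix()].
#' @param factors per-sample scaling factors (e.g. [tmm_factors()]);
#'   default all 1.
#' @param prior prior count (default 0.25).
#' @return log2-CPM matrix with the dimensions of the counts.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.25) {
  stopifnot(inherits(counts, "mir_counts"))
  if (is.null(factors)) factors <- rep(1, ncol(counts$counts))
  if (any(counts$lib_size <= 0)) stop("zero library size")
  L <- counts$lib_size * factors
  pc <- prior * L / mean(L)
  log2(sweep(sweep(counts$counts, 2, pc, "+"), 2, L + 2 * pc, "/") * 1e6)
}

#' Signature expression score for tumor profiles
#'
#' Given a subset signature (miRNA symbols with log2 fold changes from
#' the normal-subset DE analysis), the score of a tumor is
#' `sum(logFC * logCPM) / sum(abs(logFC))` over the signature miRNAs
#' present in the matrix: a logFC-weighted average of the tumor's
#' logCPM, high when the tumor expresses the subset's up-miRNAs and not
#' its down-miRNAs. Signature miRNAs absent from the matrix are dropped
#' with a message; an empty intersection is an error. Matching strips
#' species prefixes and is case-insensitive (see
#' [normalize_mirna_symbol()]).
#'
#' @param signature named numeric vector: miRNA symbol -> log2FC. A DE
#'   table is also accepted (signature rows are used).
#' @param logcpm log2-CPM matrix from [log_cpm()].
#' @return named per-tumor score vector.
#' @export
signature_score <- function(signature, logcpm) {
  if (is.data.frame(signature)) {
    sel <- if ("signature" %in% names(signature))
      signature$signature else rep(TRUE, nrow(signature))
    signature <- stats::setNames(signature$logFC[sel],
                                 signature$probe[sel])
  }
  if (!length(signature) || any(!is.finite(signature)))
    stop("signature must be a nonempty set of finite log fold changes")
  key <- normalize_mirna_symbol(rownames(logcpm))
  idx <- match(normalize_mirna_symbol(names(signature)), key)
  if (all(is.na(idx)))
    stop("no signature miRNA present in the logCPM matrix")
  if (anyNA(idx))
    message(sum(is.na(idx)), " signature miRNA(s) absent from the ",
            "matrix, dropped")
  lfc <- signature[!is.na(idx)]
  M <- logcpm[idx[!is.na(idx)], , drop = FALSE]
  colSums(lfc * M) / sum(abs(lfc))
}

#' Build the per-tumor score table for several signatures
#'
#' @param signatures named list of signatures (see [signature_score()]).
#' @param logcpm log2-CPM matrix.
#' @param subtype per-tumor subtype labels aligned to columns.
#' @return data frame of class `"score_table"`: sample, subtype, one
#'   score column per signature.
#' @export
score_table <- function(signatures, logcpm, subtype) {
  if (length(subtype) != ncol(logcpm))
    stop("subtype labels must align with tumor columns")
  out <- data.frame(sample = colnames(logcpm), subtype = subtype,
                    stringsAsFactors = FALSE)
  for (nm in names(signatures))
    out[[nm]] <- signature_score(signatures[[nm]], logcpm)
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Compare signature scores across tumor subtypes
#'
#' Five-number summaries per subtype plus, for a named subtype, a
#' one-sided Wilcoxon rank-sum p-value of that subtype's scores against
#' all other tumors pooled (alternative: the named subtype is higher).
#'
#' @param scores numeric score vector.
#' @param subtype subtype labels aligned to scores.
#' @param test_subtype subtype whose elevation is tested; NULL gives
#'   summaries only.
#' @return list with `summary` (data frame of five-number summaries per
#'   subtype) and `p` (NA when no test was requested or possible).
#' @export
score_by_subtype <- function(scores, subtype, test_subtype = NULL) {
  subtype <- as.character(subtype)
  tab <- table(subtype)
  summ <- do.call(rbind, lapply(names(tab), function(s) {
    q <- stats::fivenum(scores[subtype == s])
    data.frame(subtype = s, n = tab[[s]], min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  }))
  p <- NA_real_
  if (!is.null(test_subtype)) {
    if (!test_subtype %in% subtype)
      stop("subtype not present: ", test_subtype)
    if (length(tab) >= 2 && all(tab >= 2)) {
      p <- stats::wilcox.test(scores[subtype == test_subtype],
                              scores[subtype != test_subtype],
                              alternative = "greater",
                              exact = FALSE)$p.value
    }
  }
  list(summary = summ, p = p)
}
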