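#' Read an expression matrix TSV
#'
#' Inverse of [write_expression_tsv()]: probes in rows, first column
#' `probe`, remaining columns samples. Sample metadata comes from
#' `annot` when given; otherwise sample names of the generator's form
#' `<species>_<subset>_<replicate>` are parsed.
#'
#' @param path TSV path.
#' @param annot optional sample-annotation TSV (`sample`, `species`,
#'   `subset`, `replicate`) or data frame.
#' @param probe_class optional probe class vector (default all target).
#' @param normalized provenance flag for the returned object.
#' @return A [expression_matrix()].
#' @export
read_expression_tsv <- function(path, annot = NULL, probe_class = NULL,
                                normalized = TRUE) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(d)[1] != "probe")
    stop("expression TSV must have 'probe' as its first column")
  E <- as.matrix(d[, -1, drop = FALSE])
  rownames(E) <- d$probe
  if (!is.null(annot)) {
    samples <- if (is.data.frame(annot)) annot
               else utils::read.delim(annot, stringsAsFactors = FALSE)
    samples <- samples[match(colnames(E), samples$sample), , drop = FALSE]
  } else {
    parts <- strsplit(colnames(E), "_", fixed = TRUE)
    ok <- all(lengths(parts) >= 3)
    samples <- data.frame(
      sample = colnames(E),
      species = if (ok) vapply(parts, `[[`, "", 1) else NA_character_,
      subset = if (ok) vapply(parts, function(p)
        paste(p[2:(length(p) - 1)], collapse = "_"), "")
        else NA_character_,
      replicate = if (ok) vapply(parts, function(p)
        p[length(p)], "") else NA_character_,
      stringsAsFactors = FALSE)
  }
  expression_matrix(E, probe_class = probe_class, samples = samples,
                    normalized = normalized)
}

#' Read a tumor count matrix TSV plus sample annotation
#'
#' Inverse of [write_counts_tsv()]: first column `mirna`, optional
#' second column `parent`, remaining columns samples.
#'
#' @param path counts TSV path.
#' @param annot_path sample annotation TSV (`sample`, `analyte_id`,
#'   `subtype`, optional `sample_type`).
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path, annot_path = NULL) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (names(d)[1] != "mirna")
    stop("counts TSV must have 'mirna' as its first column")
  has_parent <- names(d)[2] == "parent"
  x <- as.matrix(d[, -(1:(1 + has_parent)), drop = FALSE])
  rownames(x) <- d$mirna
  features <- data.frame(id = d$mirna,
                         parent = if (has_parent) d$parent else d$mirna,
                         stringsAsFactors = FALSE)
  samples <- NULL
  if (!is.null(annot_path)) {
    samples <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
    samples <- samples[match(colnames(x), samples$sample), , drop = FALSE]
  }
  count_matrix(x, features = features, samples = samples)
}
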