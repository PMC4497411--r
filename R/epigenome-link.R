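#' Read miRNA loci from BED6 or miRBase-style GFF3
#'
#' Coordinates are converted to the package's single internal
#' convention, 0-based half-open (BED). For GFF3 input the `Name`
#' attribute provides the symbol.
#'
#' @param path BED6 (symbol in column 4) or GFF3 file; format inferred
#'   from the extension.
#' @return data frame: symbol, chrom, start, end, strand, partner (NA;
#'   fill from naming or supply externally).
#' @export
read_mirna_loci <- function(path) {
  gr <- rtracklayer::import(path)
  nm <- if (!is.null(gr$Name)) gr$Name else gr$name
  if (is.null(nm)) stop("loci file carries no feature names")
  data.frame(symbol = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # to 0-based
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             partner = NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a BED6 file of aligned reads
#' @param path BED path (one read per line, 0-based half-open).
#' @return data frame: chrom, start, end, name, score, strand.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (is.null(gr$name)) "." else gr$name,
             score = if (is.null(gr$score)) 0 else as.numeric(gr$score),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Flanked counting intervals for miRNA loci
#'
#' Each locus is extended by `flank` bp on both sides (strand-ignorant),
#' clipped at zero; 3p/5p isoform partners that share a genomic
#' interval are merged into a single counting interval carrying both
#' symbols.
#'
#' @param loci data frame from [read_mirna_loci()] or the synthetic
#'   generator (columns symbol, chrom, start, end, strand, partner).
#' @param flank bp added each side (default 3000; negative is an error).
#' @return data frame: interval_id, chrom, start, end, symbols
#'   (comma-joined member symbols).
#' @export
mirna_intervals <- function(loci, flank = 3000) {
  if (flank < 0) stop("flank must be >= 0")
  if (any(loci$start >= loci$end)) stop("locus start must be < end")
  key <- paste(loci$chrom, loci$start, loci$end)
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  syms <- vapply(split(loci$symbol, grp), paste, "", collapse = ",")
  data.frame(interval_id = paste0("ivl", formatC(unique(grp), width = 4,
                                                 flag = "0")),
             chrom = loci$chrom[first],
             start = pmax(0L, loci$start[first] - as.integer(flank)),
             end = loci$end[first] + as.integer(flank),
             symbols = syms[as.character(unique(grp))],
             stringsAsFactors = FALSE)
}

#' Count reads overlapping miRNA intervals
#'
#' A read contributes to every interval it overlaps by at least 1 bp,
#' strand-ignorant; the track's library size is its total read count.
#' Reads on chromosomes absent from the loci are ignored with a message.
#'
#' @param intervals data frame from [mirna_intervals()].
#' @param tracks named list of read data frames (chrom, start, end), one
#'   per `(subset, mark)` track, as produced by [gen_chip_reads()] or
#'   [read_reads_bed()].
#' @return list of class `"mark_counts"`: `counts` (interval x track
#'   matrix), `intervals`, `lib_size` (per track).
#' @export
count_reads <- function(intervals, tracks) {
  if (is.data.frame(tracks)) tracks <- list(track = tracks)
  gi <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  counts <- matrix(0L, nrow(intervals), length(tracks),
                   dimnames = list(intervals$interval_id, names(tracks)))
  lib <- stats::setNames(integer(length(tracks)), names(tracks))
  for (k in seq_along(tracks)) {
    rd <- tracks[[k]]
    lib[k] <- nrow(rd)
    off <- !rd$chrom %in% intervals$chrom
    if (any(off))
      message(sum(off), " read(s) on chromosome(s) absent from the ",
              "loci, ignored (track ", names(tracks)[k], ")")
    rd <- rd[!off, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      rd$chrom, IRanges::IRanges(start = rd$start + 1L, end = rd$end))
    counts[, k] <- GenomicRanges::countOverlaps(gi, gr, minoverlap = 1L,
                                                ignore.strand = TRUE)
  }
  structure(list(counts = counts, intervals = intervals,
                 lib_size = lib),
            class = "mark_counts")
}

#' Negative-binomial log2 fold changes at fixed dispersion
#'
#' One-factor NB log-linear model per row with log effective-library
#' offsets, fitted at a fixed dispersion. A library-size-scaled prior
#' count is added to the counts (and twice the prior to the offsets)
#' before fitting, shrinking log2 fold changes slightly toward zero so
#' that low counts cannot produce unstable estimates. With dispersion 0
#' the fit is the Poisson GLM (same closed form: the group's
#' offset-weighted mean).
#'
#' @param counts matrix (rows = loci) or `"mark_counts"` object.
#' @param groups factor/vector of group labels, one per column.
#' @param dispersion fixed NB dispersion (default 0.05).
#' @param prior_count prior count (default 1).
#' @param lib_size optional library sizes (default: `mark_counts`
#'   library sizes, else column sums).
#' @return matrix of log2 fold changes, one column per ordered group
#'   pair `first - second`.
#' @export
nbglm_logfc <- function(counts, groups, dispersion = 0.05,
                        prior_count = 1, lib_size = NULL) {
  if (inherits(counts, "mark_counts")) {
    if (is.null(lib_size)) lib_size <- counts$lib_size
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop("zero library size")
  groups <- factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups must align with columns")
  ## library-scaled prior, edgeR predFC convention
  pc <- prior_count * lib_size / mean(lib_size)
  y <- sweep(counts, 2, pc, "+")
  off <- log(lib_size + 2 * pc)

  ## per (row, group) NB MLE of beta in log mu = beta + offset:
  ## solve sum_i (y_i - mu_i)/(1 + phi mu_i) = 0 by Newton iteration
  beta <- matrix(NA_real_, nrow(y), nlevels(groups),
                 dimnames = list(rownames(y), levels(groups)))
  for (g in levels(groups)) {
    j <- which(groups == g)
    yg <- y[, j, drop = FALSE]
    og <- off[j]
    ## start at the offset-weighted mean (the Poisson solution)
    b <- log(rowSums(yg) / sum(exp(og)))
    if (dispersion > 0) {
      for (it in 1:50) {
        mu <- exp(outer(b, og, "+"))
        den <- 1 + dispersion * mu
        score <- rowSums((yg - mu) / den)
        info <- rowSums(mu / den^2 * (1 + dispersion * yg))
        step <- score / info
        step[!is.finite(step)] <- 0
        b <- b + step
        if (max(abs(step)) < 1e-12) break
      }
    }
    beta[, g] <- b
  }
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  out <- matrix(NA_real_, nrow(y), ncol(pairs),
                dimnames = list(rownames(y),
                                apply(pairs, 2, paste, collapse = " - ")))
  for (k in seq_len(ncol(pairs)))
    out[, k] <- (beta[, pairs[1, k]] - beta[, pairs[2, k]]) / log(2)
  out
}

#' Least-squares regression through the origin
#'
#' Slope `b = sum(xy)/sum(x^2)`, standard error
#' `sqrt(sum((y - bx)^2) / ((n - 1) sum(x^2)))`, two-sided p from a t
#' distribution on `n - 1` df.
#'
#' @param x,y numeric vectors of equal length >= 2; `x` must not be all
#'   zero.
#' @return list of class `"link_result"`: slope, se, t, p, n, x, y.
#' @export
origin_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two points")
  if (all(x == 0)) stop("all x values are zero: slope undefined")
  b <- sum(x * y) / sum(x^2)
  n <- length(x)
  se <- sqrt(sum((y - b * x)^2) / ((n - 1) * sum(x^2)))
  t <- if (se == 0) sign(b) * Inf else b / se
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  structure(list(slope = b, se = se, t = t, p = p, n = n, x = x, y = y),
            class = "link_result")
}

#' Top differentially expressed miRNAs
#'
#' First `n` probes by ascending p-value; ties broken by decreasing
#' absolute log fold change, then by symbol.
#'
#' @param de_table a DE table (probe, logFC, p).
#' @param n number wanted; larger than the table gives the whole table
#'   with a warning.
#' @return character vector of probe symbols.
#' @export
top_de_selection <- function(de_table, n) {
  if (n < 0) stop("n must be >= 0")
  if (n > nrow(de_table)) {
    warning("requested ", n, " probes but table has ", nrow(de_table))
    n <- nrow(de_table)
  }
  o <- order(de_table$p, -abs(de_table$logFC), de_table$probe)
  de_table$probe[o][seq_len(n)]
}

match_locus_symbols <- function(symbols, probes) {
  i <- match(symbols, probes)
  miss <- is.na(i)
  i[miss] <- match(sub("-(3p|5p)$", "", symbols[miss]), probes)
  i
}

#' Link histone-mark fold changes to miRNA expression fold changes
#'
#' Restricts to the top-`n_top` DE miRNAs, computes each mark's NB log2
#' fold change between the subset pair over the matching loci, and
#' regresses the expression log2 fold change through the origin on the
#' mark log2 fold change, one fit per mark. Locus symbols are matched to
#' DE probes exactly, falling back to stripping a -3p/-5p suffix. A
#' heatmap matrix (expression and per-mark log2FCs) is returned for the
#' top `n_heatmap` selection.
#'
#' @param expr_de DE table for the same subset pair (probe, logFC, p).
#' @param mark_counts a `"mark_counts"` object whose track names are
#'   `<subset>.<mark>`.
#' @param subset_pair length-2 character vector naming the subsets, in
#'   the order of the expression contrast.
#' @param n_top number of top DE miRNAs used in the regressions
#'   (default 200).
#' @param n_heatmap rows of the heatmap matrix (default 140).
#' @param dispersion,prior_count passed to [nbglm_logfc()].
#' @return list of class `"mark_link"`: per-mark `"link_result"`s in
#'   `$links`, the per-locus fold-change table in `$table`, and
#'   `$heatmap`.
#' @export
link_marks_to_expression <- function(expr_de, mark_counts, subset_pair,
                                     n_top = 200, n_heatmap = 140,
                                     dispersion = 0.05, prior_count = 1) {
  stopifnot(inherits(mark_counts, "mark_counts"))
  trk <- strsplit(colnames(mark_counts$counts), ".", fixed = TRUE)
  t_subset <- vapply(trk, `[[`, "", 1)
  t_mark <- vapply(trk, `[[`, "", 2)
  marks <- unique(t_mark)
  pair_key <- gsub("[^A-Za-z0-9]", "", subset_pair)

  top <- top_de_selection(expr_de, min(n_top, nrow(expr_de)))
  ## one locus row may carry several symbols (merged isoform intervals)
  sym_list <- strsplit(mark_counts$intervals$symbols, ",", fixed = TRUE)
  rep_sym <- vapply(sym_list, `[[`, "", 1)
  probe_idx <- match_locus_symbols(rep_sym, expr_de$probe)
  use <- !is.na(probe_idx) & expr_de$probe[probe_idx] %in% top
  if (sum(use) < 2)
    stop("fewer than two loci match the top DE miRNAs")

  tab <- data.frame(symbol = rep_sym[use],
                    expr_logFC = expr_de$logFC[probe_idx[use]],
                    stringsAsFactors = FALSE)
  links <- list()
  for (m in marks) {
    sel <- t_mark == m & t_subset %in% pair_key
    grp <- factor(t_subset[sel], levels = pair_key)
    lfc <- nbglm_logfc(mark_counts$counts[use, sel, drop = FALSE], grp,
                       dispersion = dispersion,
                       prior_count = prior_count,
                       lib_size = mark_counts$lib_size[sel])
    tab[[paste0(m, "_logFC")]] <- lfc[, 1]
    links[[m]] <- origin_regression(lfc[, 1], tab$expr_logFC)
  }
  o <- order(match(expr_de$probe[probe_idx[use]], top))
  hm <- tab[o, , drop = FALSE][seq_len(min(n_heatmap, nrow(tab))), ,
                               drop = FALSE]
  structure(list(links = links, table = tab, heatmap = hm,
                 subset_pair = subset_pair),
            class = "mark_link")
}

#' Reads-per-million coverage as bedGraph (visualization only)
#'
#' Per-base coverage of a track scaled to reads per million, emitted as
#' bedGraph intervals of constant coverage. No statistics are computed
#' on these values.
#'
#' @param reads read data frame (chrom, start, end).
#' @param path output bedGraph path.
#' @param region optional `c(chrom, start, end)` restriction.
#' @export
write_coverage_bedgraph <- function(reads, path, region = NULL) {
  rd <- reads
  if (!is.null(region)) {
    rd <- rd[rd$chrom == region[[1]] &
               rd$end > as.numeric(region[[2]]) &
               rd$start < as.numeric(region[[3]]), , drop = FALSE]
  }
  scale <- 1e6 / nrow(reads)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in unique(rd$chrom)) {
    r <- rd[rd$chrom == ch, , drop = FALSE]
    bk <- sort(unique(c(r$start, r$end)))
    if (length(bk) < 2) next
    cov <- vapply(seq_len(length(bk) - 1), function(i) {
      sum(r$start <= bk[i] & r$end >= bk[i + 1])
    }, 0)
    keep <- cov > 0
    writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, bk[-length(bk)][keep],
                       bk[-1][keep], cov[keep] * scale), con)
  }
  invisible(path)
}
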