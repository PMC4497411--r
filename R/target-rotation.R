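#' Load a miRNA -> target-gene map
#'
#' Reads a TargetScan-style two-column TSV (miRNA family / symbol and
#' target gene symbol). Target genes are intersected with the mRNA
#' universe when one is supplied; miRNAs whose targets all fall outside
#' the universe are dropped and counted in the `"dropped"` attribute.
#'
#' @param path TSV path with a header row naming a miRNA column
#'   (`mirna` or `mir_family`) and a gene column (`gene` or
#'   `gene_symbol`).
#' @param universe optional character vector of gene symbols present in
#'   the mRNA data.
#' @return data frame with columns `mirna` and `gene`.
#' @export
load_target_map <- function(path, universe = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty target map file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("unparseable target-map row at line ", bad[1],
         " (expected >= 2 tab-separated fields)")
  hdr <- tolower(parts[[1]])
  mcol <- which(hdr %in% c("mirna", "mir_family", "mirna_family"))[1]
  gcol <- which(hdr %in% c("gene", "gene_symbol", "target"))[1]
  if (is.na(mcol) || is.na(gcol))
    stop("target map header must name a miRNA and a gene column")
  body <- parts[-1]
  map <- data.frame(mirna = vapply(body, `[[`, "", mcol),
                    gene = vapply(body, `[[`, "", gcol),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  dropped <- character(0)
  if (!is.null(universe)) {
    before <- unique(map$mirna)
    map <- map[map$gene %in% universe, , drop = FALSE]
    dropped <- setdiff(before, unique(map$mirna))
    if (length(dropped))
      message(length(dropped),
              " miRNA(s) dropped: no targets in the mRNA universe")
  }
  rownames(map) <- NULL
  attr(map, "dropped") <- dropped
  map
}

#' Precompute the rotation-space representation of an expression matrix
#'
#' Projects each gene's expression vector onto (i) the unit direction in
#' sample space that carries the contrast estimate and (ii) an
#' orthonormal basis of the residual space, giving a
#' `(residual df + 1)`-dimensional vector per gene whose distribution is
#' spherical under the null. Rotation tests replace the contrast
#' direction by random unit vectors in this reduced space. The
#' moderation prior (`d0`, `s0^2`) is estimated once from all genes.
#'
#' @param expr [expression_matrix()] or matrix of mRNA log2 values.
#' @param design design matrix (samples x coefficients).
#' @param contrast contrast weight vector over the design coefficients.
#' @return list of class `"rotation_setup"`: `Z` (genes x (d+1)),
#'   residual df `d`, prior `d0`, `s0_2`.
#' @export
rotation_setup <- function(expr, design, contrast) {
  E <- if (inherits(expr, "mir_expr")) expr$E else as.matrix(expr)
  X <- as.matrix(design)
  p <- ncol(X)
  n <- nrow(X)
  if (length(contrast) != p)
    stop("contrast length must match design coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is not of full rank")
  d <- n - p
  if (d < 1) stop("no residual degrees of freedom")
  v <- X %*% solve(crossprod(X), contrast)
  u <- v / sqrt(sum(v^2))
  W <- qr.Q(qrX, complete = TRUE)[, (p + 1):n, drop = FALSE]
  Z <- E %*% cbind(u, W)
  s2 <- rowSums(Z[, -1, drop = FALSE]^2) / d
  pri <- fit_f_dist(s2, d)
  structure(list(Z = Z, d = d, d0 = pri$d0, s0_2 = pri$s0_2,
                 genes = rownames(E)),
            class = "rotation_setup")
}

post_var_rot <- function(s2, d, d0, s0_2) {
  if (is.infinite(d0)) return(array(s0_2, dim(as.array(s2))))
  (d0 * s0_2 + d * s2) / (d0 + d)
}

#' Directional rotation gene-set test
#'
#' Self-contained test of whether a gene set's moderated t-statistics
#' for a contrast are shifted in a given direction, valid for small
#' sample sizes. The set statistic is the arithmetic mean of the
#' per-gene moderated t values. The null distribution is generated by
#' `B` random rotations: the contrast direction in the reduced
#' `(d + 1)`-dimensional space is replaced by uniformly random unit
#' vectors (shared across genes, preserving inter-gene correlation) and
#' the set statistic recomputed. The one-sided p-value is
#' `(exceedances + 1)/(B + 1)`, so its minimum is `1/(B + 1)`.
#'
#' @param expr mRNA expression matrix (ignored if `setup` is given).
#' @param design design matrix (ignored if `setup` is given).
#' @param contrast contrast vector (ignored if `setup` is given).
#' @param gene_set character vector of member genes (>= 2 present).
#' @param direction `"up"` or `"down"`: the alternative tested.
#' @param B number of rotations (default 9999).
#' @param seed RNG seed; fixed seed gives identical p-values.
#' @param setup optional precomputed [rotation_setup()] (reused across
#'   many sets).
#' @return list of class `"rotation_test"`: `set_size`, observed `stat`,
#'   one-sided `p`, `direction`, `B`, `seed`.
#' @export
roast_directional <- function(expr = NULL, design = NULL, contrast = NULL,
                              gene_set, direction = c("up", "down"),
                              B = 9999, seed = 1L, setup = NULL) {
  direction <- match.arg(direction)
  if (is.null(setup)) setup <- rotation_setup(expr, design, contrast)
  stopifnot(inherits(setup, "rotation_setup"))
  idx <- match(gene_set, setup$genes)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2)
    stop("gene set must contain at least two genes present in the data")
  Zs <- setup$Z[idx, , drop = FALSE]
  d <- setup$d
  ss <- rowSums(Zs^2)

  mod_t <- function(eff) {
    s2 <- (ss - eff^2) / d
    s2[s2 < 0] <- 0  # numerical guard
    eff / sqrt(post_var_rot(s2, d, setup$d0, setup$s0_2))
  }
  stat_obs <- mean(mod_t(Zs[, 1]))

  set.seed(seed)
  R <- matrix(stats::rnorm(B * (d + 1)), B, d + 1)
  R <- R / sqrt(rowSums(R^2))
  Eb <- Zs %*% t(R)                       # set genes x B rotated effects
  S2b <- (ss - Eb^2) / d
  S2b[S2b < 0] <- 0
  Tb <- Eb / sqrt(post_var_rot(S2b, d, setup$d0, setup$s0_2))
  stat_b <- colMeans(Tb)

  b <- if (direction == "up") sum(stat_b >= stat_obs)
       else sum(stat_b <= stat_obs)
  structure(list(set_size = length(idx), stat = stat_obs,
                 p = (b + 1) / (B + 1), direction = direction,
                 B = B, seed = seed),
            class = "rotation_test")
}

#' Screen DE miRNAs for inverse movement of their target genes
#'
#' For each differentially expressed miRNA, tests whether the average
#' moderated t of its predicted target genes moves in the direction
#' opposite to the miRNA's own log2 fold change (a miRNA up in a subset
#' should push its targets down there). miRNAs with zero log fold change
#' are skipped with a logged reason; p-values are BH-adjusted across the
#' tested miRNAs.
#'
#' @param de_table DE table for the miRNAs (from [signature_de()] etc.).
#' @param target_map data frame `mirna`, `gene` (see
#'   [load_target_map()]).
#' @param mrna_expr mRNA [expression_matrix()].
#' @param design,contrast model for the mRNA data (same subset contrast
#'   as the miRNA DE analysis).
#' @param B rotations per miRNA (default 9999).
#' @param seed base seed; each miRNA uses `seed + its index`.
#' @param min_set minimum target-set size after intersection (default 2).
#' @return data frame: mirna, logFC, set_size, direction, p, FDR.
#' @export
inverse_correlation_screen <- function(de_table, target_map, mrna_expr,
                                       design, contrast, B = 9999,
                                       seed = 1L, min_set = 2) {
  setup <- rotation_setup(mrna_expr, design, contrast)
  mirnas <- intersect(de_table$probe, unique(target_map$mirna))
  res <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    m <- mirnas[i]
    lfc <- de_table$logFC[match(m, de_table$probe)]
    if (lfc == 0) {
      message("skipping ", m, ": zero log fold change, direction undefined")
      next
    }
    genes <- target_map$gene[target_map$mirna == m]
    genes <- intersect(genes, setup$genes)
    if (length(genes) < min_set) {
      message("skipping ", m, ": fewer than ", min_set,
              " targets in the mRNA universe")
      next
    }
    dir <- if (lfc > 0) "down" else "up"
    rt <- roast_directional(gene_set = genes, direction = dir, B = B,
                            seed = seed + i, setup = setup)
    res[[i]] <- data.frame(mirna = m, logFC = lfc,
                           set_size = rt$set_size, direction = dir,
                           p = rt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(mirna = character(), logFC = numeric(),
                      set_size = integer(), direction = character(),
                      p = numeric(), FDR = numeric(),
                      stringsAsFactors = FALSE))
  out$FDR <- bh_adjust(out$p)
  out <- out[order(out$p, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Barcode-plot data for a gene set along a ranked statistic
#'
#' Genes are ranked by the statistic in decreasing order; member
#' positions are recorded, and the "worm" is the boundary-corrected
#' kernel density of member positions (as fractions of the ranking)
#' minus the uniform baseline 1, so it is ~0 everywhere for a uniformly
#' spread set and integrates to ~0.
#'
#' @param stat named numeric vector of per-gene statistics (finite).
#' @param gene_set member gene names.
#' @param n_bins number of worm evaluation points (default 100).
#' @return list of class `"barcode_data"`: `ranked` (named sorted
#'   statistic), `positions` (member ranks), `worm_x`, `worm`,
#'   `n_genes`.
#' @export
barcode_data <- function(stat, gene_set, n_bins = 100) {
  if (any(!is.finite(stat))) stop("statistics must be finite")
  if (is.null(names(stat))) stop("statistic vector must be named")
  ranked <- sort(stat, decreasing = TRUE)
  positions <- which(names(ranked) %in% gene_set)
  if (!length(positions)) stop("no set member present in the statistic")
  n <- length(stat)
  rel <- (positions - 0.5) / n
  refl <- c(rel, -rel, 2 - rel)  # boundary reflection
  dens <- stats::density(refl, from = 0, to = 1, n = n_bins)
  structure(list(ranked = ranked, positions = positions,
                 worm_x = dens$x, worm = 3 * dens$y - 1,
                 n_genes = n),
            class = "barcode_data")
}

#' Select inversely differentially expressed target genes
#'
#' Implements the selection rule used for GO analysis: a gene is picked
#' if it is (i) a predicted target of a differentially expressed miRNA
#' and (ii) itself DE in the mRNA data at FDR below `mrna_fdr` with log
#' fold change opposite in sign to the miRNA's.
#'
#' @param mirna_de miRNA DE table (with FDR and logFC columns).
#' @param target_map data frame `mirna`, `gene`.
#' @param mrna_de mRNA DE table (probe = gene symbol).
#' @param mirna_fdr miRNA DE threshold (default 0.05).
#' @param mrna_fdr mRNA DE threshold (default 0.2).
#' @return character vector of selected gene symbols.
#' @export
select_inverse_targets <- function(mirna_de, target_map, mrna_de,
                                   mirna_fdr = 0.05, mrna_fdr = 0.2) {
  de_mir <- mirna_de[mirna_de$FDR < mirna_fdr & mirna_de$logFC != 0, ,
                     drop = FALSE]
  sel <- character(0)
  for (i in seq_len(nrow(de_mir))) {
    m <- de_mir$probe[i]
    genes <- target_map$gene[target_map$mirna == m]
    hit <- mrna_de$probe %in% genes & mrna_de$FDR < mrna_fdr &
      sign(mrna_de$logFC) == -sign(de_mir$logFC[i])
    sel <- union(sel, mrna_de$probe[hit])
  }
  sel
}

#' Hypergeometric GO term enrichment
#'
#' Upper-tail hypergeometric test of each annotation term's overlap with
#' the selected gene list, BH-adjusted across terms.
#'
#' @param selected selected gene symbols (must lie in `universe`).
#' @param universe all testable gene symbols.
#' @param annotation data frame with columns `gene`, `term` and
#'   optionally `term_name`.
#' @return data frame: term, term_name, overlap, term_size, set_size,
#'   universe_size, p, FDR; sorted by p. Empty selection returns an
#'   empty frame with a warning.
#' @export
go_enrichment <- function(selected, universe, annotation) {
  bad <- setdiff(selected, universe)
  if (length(bad))
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(bad, 3), collapse = ", "))
  if (!length(selected)) {
    warning("empty selection: no enrichment computed")
    return(data.frame(term = character(), term_name = character(),
                      overlap = integer(), term_size = integer(),
                      set_size = integer(), universe_size = integer(),
                      p = numeric(), FDR = numeric(),
                      stringsAsFactors = FALSE))
  }
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  nsel <- length(selected)
  terms <- split(ann$gene, ann$term)
  K <- vapply(terms, function(g) length(unique(g)), 0L)
  k <- vapply(terms, function(g) length(intersect(unique(g), selected)),
              0L)
  p <- stats::phyper(k - 1, K, N - K, nsel, lower.tail = FALSE)
  tn <- if ("term_name" %in% names(ann))
    ann$term_name[match(names(terms), ann$term)] else names(terms)
  out <- data.frame(term = names(terms), term_name = tn,
                    overlap = k, term_size = K, set_size = nsel,
                    universe_size = N, p = p, FDR = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
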