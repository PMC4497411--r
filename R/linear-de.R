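#' Cell-means design matrix for subset comparisons
#'
#' One indicator column per cell subset (no intercept), so contrasts are
#' plain weight vectors over subset means. Optional extra covariate
#' columns (e.g. a species indicator) are appended unchanged.
#'
#' @param samples sample metadata data frame with a `subset` column.
#' @param covariates optional numeric matrix of extra columns, rows
#'   aligned to samples.
#' @return design matrix (samples x coefficients) with subset names as
#'   the leading coefficient names.
#' @export
subset_design <- function(samples, covariates = NULL) {
  subset <- factor(samples$subset, levels = unique(samples$subset))
  X <- stats::model.matrix(~ 0 + subset)
  colnames(X) <- levels(subset)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(X))
      stop("covariates must align with samples")
    X <- cbind(X, covariates)
  }
  rownames(X) <- samples$sample
  X
}

#' Probe-wise ordinary least squares
#'
#' Fits the same linear model to every probe of a log2 expression matrix.
#'
#' @param expr a [expression_matrix()] or plain numeric matrix
#'   (probes x samples).
#' @param design design matrix (samples x coefficients), full column
#'   rank, at least one residual degree of freedom.
#' @return An object of class `"mir_fit"`: per-probe `coefficients`
#'   (log2 units), `stdev_unscaled`, residual variances `sigma2`,
#'   residual df `df_residual`, plus the shared `cov_unscaled`
#'   ((X'X)^-1) and `design`.
#' @export
fit_linear_model <- function(expr, design) {
  E <- if (inherits(expr, "mir_expr")) expr$E else as.matrix(expr)
  design <- as.matrix(design)
  if (nrow(design) != ncol(E))
    stop("design rows must match number of samples")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("design matrix is not of full rank; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- ncol(E) - ncol(design)
  if (df < 1) stop("no residual degrees of freedom")
  coef <- t(qr.coef(qrX, t(E)))
  fitted <- coef %*% t(design)
  res <- E - fitted
  sigma2 <- rowSums(res^2) / df
  cov_unscaled <- chol2inv(qr.R(qrX))
  unpiv <- order(qrX$pivot)
  cov_unscaled <- cov_unscaled[unpiv, unpiv, drop = FALSE]
  dimnames(cov_unscaled) <- list(colnames(design), colnames(design))
  stdev <- matrix(sqrt(diag(cov_unscaled)), nrow(E), ncol(design),
                  byrow = TRUE, dimnames = dimnames(coef))
  structure(list(coefficients = coef, stdev_unscaled = stdev,
                 sigma2 = sigma2, df_residual = df,
                 cov_unscaled = cov_unscaled, design = design,
                 probes = rownames(E)),
            class = "mir_fit")
}

#' Re-express a fit in terms of contrasts
#'
#' @param fit a `"mir_fit"` object.
#' @param contrasts numeric matrix (coefficients x contrasts) or a single
#'   contrast vector; comparative contrasts should have weights summing
#'   to zero.
#' @return A `"mir_fit"` whose coefficients are the contrast estimates.
#' @export
contrast_fit <- function(fit, contrasts) {
  stopifnot(inherits(fit, "mir_fit"))
  C <- as.matrix(contrasts)
  if (nrow(C) != ncol(fit$coefficients))
    stop("contrast length must match number of coefficients")
  if (is.null(colnames(C)))
    colnames(C) <- paste0("C", seq_len(ncol(C)))
  cov_c <- t(C) %*% fit$cov_unscaled %*% C
  coef <- fit$coefficients %*% C
  stdev <- matrix(sqrt(diag(cov_c)), nrow(coef), ncol(coef),
                  byrow = TRUE, dimnames = dimnames(coef))
  fit$coefficients <- coef
  fit$stdev_unscaled <- stdev
  fit$cov_unscaled <- cov_c
  fit
}

#' Inverse of the trigamma function (Newton iteration)
#' @param x positive numeric vector.
#' @return y with trigamma(y) = x.
#' @keywords internal
trigamma_inverse <- function(x) {
  y <- numeric(length(x))
  hi <- x > 1e7
  lo <- x < 1e-6
  y[hi] <- 1 / sqrt(x[hi])
  y[lo] <- 1 / x[lo]
  mid <- !hi & !lo
  if (any(mid)) {
    z <- 0.5 + 1 / x[mid]
    for (i in 1:75) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / x[mid]) / psigamma(z, deriv = 2)
      z <- z + dif
      if (max(abs(dif / z)) < 1e-10) break
    }
    y[mid] <- z
  }
  y
}

#' Fit a scaled F distribution to sample variances by moment matching
#'
#' Models `s2 ~ s0^2 F(df, d0)` and estimates the prior df `d0` and
#' prior variance `s0^2` by matching the mean and variance of `log(s2)`
#' to the log scaled-F distribution (digamma/trigamma inversion). Zero
#' or non-finite variances are excluded from estimation. If the observed
#' spread of `log(s2)` does not exceed its sampling component, `d0` is
#' infinite and `s0^2` is the (bias-corrected) geometric mean.
#'
#' @param s2 sample variances.
#' @param df their (common) degrees of freedom.
#' @return list with `d0` and `s0_2`.
#' @export
fit_f_dist <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) stop("need >= 2 positive variances")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (sum(ok) - 1) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    ## spread of log s2 no larger than its sampling component: common
    ## variance model, pooled (arithmetic mean) estimate
    d0 <- Inf
    s0_2 <- mean(s2[ok])
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderation of probe-wise variances
#'
#' Shrinks each probe's residual variance toward a common prior by
#' modeling the sample variances as scaled F: the prior df `d0` and
#' prior variance `s0^2` are estimated by matching the first two moments
#' of `log(s_g^2)` (digamma/trigamma inversion), giving posterior
#' variances `s~_g^2 = (d0 s0^2 + d_g s_g^2)/(d0 + d_g)`, moderated
#' t-statistics on `d0 + d_g` df, and, when the fit has several
#' contrasts, a moderated F over the contrast set.
#'
#' @param fit a `"mir_fit"` (typically after [contrast_fit()]).
#' @param d0_override optional forced prior df: `0` gives ordinary
#'   (unmoderated) statistics, `Inf` forces full shrinkage to `s0^2`.
#' @return An object of class `"mir_ebayes"`: `d0`, `s0_2`, `var_post`,
#'   `t`, `p_t` (two-sided), and for multi-contrast fits `F`, `p_F`.
#' @export
ebayes_moderate <- function(fit, d0_override = NULL) {
  stopifnot(inherits(fit, "mir_fit"))
  s2 <- fit$sigma2
  df <- fit$df_residual
  pri <- fit_f_dist(s2, df)
  d0 <- pri$d0
  s0_2 <- pri$s0_2
  if (!is.null(d0_override)) d0 <- d0_override
  var_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
              else if (d0 == 0) s2
              else (d0 * s0_2 + df * s2) / (d0 + df)
  df_total <- min(d0 + df, 1e9)
  tstat <- fit$coefficients / (fit$stdev_unscaled * sqrt(var_post))
  p_t <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- list(d0 = d0, s0_2 = s0_2, var_post = var_post,
              df_residual = df, df_total = df_total,
              coefficients = fit$coefficients,
              stdev_unscaled = fit$stdev_unscaled,
              t = tstat, p_t = p_t, probes = fit$probes)
  k <- ncol(fit$coefficients)
  if (k > 1) {
    Vinv <- solve(fit$cov_unscaled)
    quad <- rowSums((fit$coefficients %*% Vinv) * fit$coefficients)
    out$F <- quad / (k * var_post)
    out$p_F <- stats::pf(out$F, k, df_total, lower.tail = FALSE)
  }
  structure(out, class = "mir_ebayes")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p vector of p-values in [0, 1]; NA/NaN is an error.
#' @return adjusted values (monotone in p, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

de_table <- function(probes, logFC, stat, p, stat_name = "t") {
  fdr <- bh_adjust(p)
  out <- data.frame(probe = probes, logFC = logFC, stat = stat,
                    p = p, FDR = fdr,
                    direction = ifelse(logFC > 0, "up",
                                       ifelse(logFC < 0, "down", "none")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$probe), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stat_name") <- stat_name
  out
}

epi_subsets_present <- function(expr) {
  epi <- setdiff(unique(expr$samples$subset), "stroma")
  if (length(epi) != 3)
    stop("expected exactly three epithelial subsets, found: ",
         paste(epi, collapse = ", "))
  epi
}

#' Subset signature differential expression
#'
#' Tests each probe for the named epithelial subset against the average
#' of the other two (contrast weights 1, -1/2, -1/2) with moderated
#' t-statistics; signature probes are those at FDR below `fdr`, signed
#' by direction.
#'
#' @param expr filtered, normalized [expression_matrix()] containing the
#'   three epithelial subsets (stroma samples, if present, are dropped).
#' @param subset the subset whose signature is wanted.
#' @param fdr signature FDR threshold (default 0.05).
#' @return A DE table (probe, logFC, stat, p, FDR, direction, signature)
#'   sorted by p, ties broken by probe ID.
#' @export
signature_de <- function(expr, subset, fdr = 0.05) {
  stopifnot(inherits(expr, "mir_expr"))
  expr <- expr[, which(expr$samples$subset != "stroma")]
  epi <- epi_subsets_present(expr)
  if (!subset %in% epi)
    stop("subset label not present in the data: ", subset)
  X <- subset_design(expr$samples)
  cvec <- stats::setNames(rep(-0.5, 3), epi)
  cvec[subset] <- 1
  fit <- contrast_fit(fit_linear_model(expr, X[, epi, drop = FALSE]),
                      matrix(cvec[epi], dimnames = list(epi, subset)))
  eb <- ebayes_moderate(fit)
  out <- de_table(fit$probes, fit$coefficients[, 1], eb$t[, 1],
                  eb$p_t[, 1])
  out$signature <- out$FDR < fdr
  attr(out, "contrast") <- paste0(subset, " vs rest")
  out
}

#' Three-subset analysis of variance (moderated F)
#'
#' Tests whether a probe differs anywhere among the three epithelial
#' subsets, using a moderated F over a two-contrast basis spanning the
#' subset differences.
#'
#' @inheritParams signature_de
#' @return A DE table with the moderated F statistic, its p-value, BH
#'   FDR, and per-contrast log2 fold changes as extra columns.
#' @export
anova_de <- function(expr, fdr = 0.05) {
  stopifnot(inherits(expr, "mir_expr"))
  expr <- expr[, which(expr$samples$subset != "stroma")]
  epi <- epi_subsets_present(expr)
  X <- subset_design(expr$samples)[, epi, drop = FALSE]
  C <- cbind(c(1, -1, 0), c(0, 1, -1))
  rownames(C) <- epi
  colnames(C) <- c(paste(epi[1], "vs", epi[2]),
                   paste(epi[2], "vs", epi[3]))
  fit <- contrast_fit(fit_linear_model(expr, X), C)
  eb <- ebayes_moderate(fit)
  maxfc <- fit$coefficients[, 1]
  out <- de_table(fit$probes, maxfc, eb$F, eb$p_F, stat_name = "F")
  lfc <- as.data.frame(fit$coefficients)
  names(lfc) <- paste0("logFC.", gsub(" ", "", colnames(C)))
  out <- cbind(out, lfc[match(out$probe, fit$probes), , drop = FALSE])
  rownames(out) <- NULL
  out$signature <- out$FDR < fdr
  attr(out, "contrast") <- "anova(3 subsets)"
  out
}

#' MaSC/basal versus combined luminal differential expression
#'
#' Contrast of the MaSC/basal subset against the average of the two
#' luminal populations; reports up/down counts at the FDR cut as
#' attributes `n_up` and `n_down`.
#'
#' @inheritParams signature_de
#' @param basal_label label of the basal subset (default "MaSC/basal").
#' @export
basal_vs_luminal_de <- function(expr, basal_label = "MaSC/basal",
                                fdr = 0.05) {
  out <- signature_de(expr, basal_label, fdr = fdr)
  attr(out, "n_up") <- sum(out$FDR < fdr & out$logFC > 0)
  attr(out, "n_down") <- sum(out$FDR < fdr & out$logFC < 0)
  attr(out, "contrast") <- paste0(basal_label, " vs luminal")
  out
}

#' Pairwise subset differential expression
#'
#' Moderated-t contrast of one subset against another (`a - b`), the
#' contrast used when relating expression changes to histone-mark
#' changes between the same pair of subsets.
#'
#' @param expr a [expression_matrix()].
#' @param subset_a,subset_b the two subset labels.
#' @param fdr FDR threshold for the `signature` flag.
#' @export
pairwise_de <- function(expr, subset_a, subset_b, fdr = 0.05) {
  stopifnot(inherits(expr, "mir_expr"))
  subs <- unique(expr$samples$subset)
  for (s in c(subset_a, subset_b))
    if (!s %in% subs) stop("subset label not present in the data: ", s)
  X <- subset_design(expr$samples)[, subs, drop = FALSE]
  cvec <- stats::setNames(numeric(length(subs)), subs)
  cvec[subset_a] <- 1
  cvec[subset_b] <- -1
  fit <- contrast_fit(fit_linear_model(expr, X),
                      matrix(cvec[subs],
                             dimnames = list(subs, "pair")))
  eb <- ebayes_moderate(fit)
  out <- de_table(fit$probes, fit$coefficients[, 1], eb$t[, 1],
                  eb$p_t[, 1])
  out$signature <- out$FDR < fdr
  attr(out, "contrast") <- paste(subset_a, "vs", subset_b)
  out
}

#' Stroma versus total epithelium differential expression
#'
#' Contrast of the stroma subset against the average of the three
#' epithelial subsets.
#'
#' @inheritParams signature_de
#' @export
stroma_vs_epithelium_de <- function(expr, fdr = 0.05) {
  stopifnot(inherits(expr, "mir_expr"))
  subs <- unique(expr$samples$subset)
  if (!"stroma" %in% subs) stop("no stroma samples present")
  epi <- setdiff(subs, "stroma")
  X <- subset_design(expr$samples)[, subs, drop = FALSE]
  cvec <- stats::setNames(rep(-1 / length(epi), length(subs)), subs)
  cvec["stroma"] <- 1
  fit <- contrast_fit(fit_linear_model(expr, X),
                      matrix(cvec[subs], dimnames = list(subs, "stroma")))
  eb <- ebayes_moderate(fit)
  out <- de_table(fit$probes, fit$coefficients[, 1], eb$t[, 1],
                  eb$p_t[, 1])
  out$signature <- out$FDR < fdr
  attr(out, "contrast") <- "stroma vs epithelium"
  out
}

#' Normalize a miRNA symbol for cross-species matching
#'
#' Strips the species prefix (mmu-/hsa-) case-insensitively and lowers
#' the case; 3p/5p suffixes are left intact and must match exactly.
#'
#' @param x character vector of probe names.
#' @return normalized symbols.
#' @export
normalize_mirna_symbol <- function(x) {
  tolower(sub("^(mmu|hsa)-", "", x, ignore.case = TRUE))
}

#' Combined cross-species differential expression
#'
#' Stacks mouse and human probes matched by normalized miRNA symbol and
#' fits a model with subset means plus a species main-effect covariate
#' (no species-by-subset interaction), so only expression changes
#' concordant across species survive. Unmatched probes are reported in
#' the `"unmatched"` attribute.
#'
#' @param mouse_expr,human_expr filtered epithelial
#'   [expression_matrix()] objects for each species.
#' @param type which contrast to test: a named subset signature,
#'   basal-vs-luminal, or the three-subset ANOVA.
#' @param subset subset label for `type = "signature"`.
#' @param fdr FDR threshold.
#' @export
combined_species_de <- function(mouse_expr, human_expr,
                                type = c("basal-vs-luminal", "signature",
                                         "anova"),
                                subset = NULL, fdr = 0.05) {
  type <- match.arg(type)
  me <- mouse_expr[, which(mouse_expr$samples$subset != "stroma")]
  he <- human_expr[, which(human_expr$samples$subset != "stroma")]
  msym <- normalize_mirna_symbol(rownames(me$E))
  hsym <- normalize_mirna_symbol(rownames(he$E))
  common <- intersect(msym, hsym)
  if (!length(common)) stop("no probes matched between species")
  E <- cbind(me$E[match(common, msym), , drop = FALSE],
             he$E[match(common, hsym), , drop = FALSE])
  rownames(E) <- common
  keep <- c("sample", "species", "subset")
  samples <- rbind(me$samples[, keep], he$samples[, keep])
  epi <- unique(samples$subset)
  if (length(epi) != 3) stop("expected three epithelial subsets")
  species_cov <- matrix(as.numeric(samples$species ==
                                     samples$species[nrow(samples)]),
                        dimnames = list(NULL, "species"))
  X <- subset_design(samples, covariates = species_cov)
  fit0 <- fit_linear_model(E, X)
  eb_table <- function(C) {
    fit <- contrast_fit(fit0, C)
    eb <- ebayes_moderate(fit)
    if (ncol(C) > 1) de_table(fit$probes, fit$coefficients[, 1], eb$F,
                              eb$p_F, stat_name = "F")
    else de_table(fit$probes, fit$coefficients[, 1], eb$t[, 1],
                  eb$p_t[, 1])
  }
  p <- ncol(X)
  cvec <- function(w) {
    v <- stats::setNames(numeric(p), colnames(X))
    v[names(w)] <- w
    matrix(v, dimnames = list(colnames(X), "contrast"))
  }
  if (type == "anova") {
    C <- cbind(a = c(1, -1, 0, 0), b = c(0, 1, -1, 0))[seq_len(p), ,
                                                       drop = FALSE]
    rownames(C) <- colnames(X)
    out <- eb_table(C)
  } else {
    if (type == "basal-vs-luminal") subset <- "MaSC/basal"
    if (is.null(subset)) stop("subset required for signature contrast")
    if (!subset %in% epi) stop("subset label not present: ", subset)
    w <- stats::setNames(rep(-0.5, 3), epi)
    w[subset] <- 1
    out <- eb_table(cvec(w))
  }
  out$signature <- out$FDR < fdr
  attr(out, "contrast") <- paste0("combined:", type)
  attr(out, "unmatched") <- list(mouse = rownames(me$E)[!msym %in% common],
                                 human = rownames(he$E)[!hsym %in% common])
  out
}

#' Remove a species (batch) effect for visualization
#'
#' Subtracts the fitted species main effect from a stacked expression
#' matrix, estimated in a model that protects the subset effects. For
#' clustering and ordination only; differential expression always models
#' the covariate instead.
#'
#' @param expr a stacked [expression_matrix()] whose samples carry
#'   `subset` metadata.
#' @param covariate factor/vector of batch labels (defaults to the
#'   `species` column of the sample metadata).
#' @return The corrected [expression_matrix()].
#' @export
remove_species_batch <- function(expr, covariate = NULL) {
  stopifnot(inherits(expr, "mir_expr"))
  if (is.null(covariate)) covariate <- expr$samples$species
  ## first-appearing level is the reference, so the correction is
  ## deterministic and leaves the leading batch untouched
  covariate <- factor(covariate, levels = unique(covariate))
  if (length(covariate) != ncol(expr$E))
    stop("covariate must align with samples")
  B <- stats::model.matrix(~covariate)[, -1, drop = FALSE]
  if (ncol(B) == 0) return(expr)
  X <- subset_design(expr$samples, covariates = B)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("batch covariate is confounded with the subset structure")
  fit <- fit_linear_model(expr, X)
  gamma <- fit$coefficients[, (ncol(X) - ncol(B) + 1):ncol(X),
                            drop = FALSE]
  E <- expr$E - gamma %*% t(B)
  expression_matrix(E, probe_class = expr$probes$class,
                    samples = expr$samples, normalized = expr$normalized)
}

#' Classical MDS on leading log-fold-change distances
#'
#' The distance between two samples is the root-mean-square of their
#' `top_k` largest absolute log2 differences, i.e. the typical log2 fold
#' change of the most discordant probes for that pair; classical metric
#' scaling projects this to two dimensions. Sign convention: in each
#' dimension the coordinate with the largest magnitude is made positive.
#'
#' @param expr a [expression_matrix()] with >= 3 samples.
#' @param top_k number of leading probes per pair (capped at the probe
#'   count), default 500.
#' @return samples x 2 coordinate matrix with the distance matrix in the
#'   `"dist"` attribute.
#' @export
mds_coordinates <- function(expr, top_k = 500) {
  E <- if (inherits(expr, "mir_expr")) expr$E else as.matrix(expr)
  n <- ncol(E)
  if (n < 3) stop("need at least three samples for MDS")
  k <- min(top_k, nrow(E))
  D <- matrix(0, n, n, dimnames = list(colnames(E), colnames(E)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- sort((E[, i] - E[, j])^2, decreasing = TRUE)[seq_len(k)]
      D[i, j] <- D[j, i] <- sqrt(mean(d2))
    }
  }
  pts <- stats::cmdscale(D, k = 2)
  for (d in 1:2)
    if (pts[which.max(abs(pts[, d])), d] < 0) pts[, d] <- -pts[, d]
  colnames(pts) <- c("dim1", "dim2")
  attr(pts, "dist") <- D
  pts
}

#' Average-linkage hierarchical clustering of samples
#'
#' Euclidean distances between sample columns (use batch-corrected
#' values for cross-species data), average linkage; columns are ordered
#' by sample label first so that tied merges resolve deterministically.
#'
#' @param expr a [expression_matrix()] with >= 2 samples.
#' @return An [stats::hclust] object (merge list, heights, leaf order).
#' @export
hierarchical_cluster <- function(expr) {
  E <- if (inherits(expr, "mir_expr")) expr$E else as.matrix(expr)
  if (ncol(E) < 2) stop("need at least two samples to cluster")
  E <- E[, order(colnames(E)), drop = FALSE]
  stats::hclust(stats::dist(t(E)), method = "average")
}
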