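#' Configuration for the synthetic data generators
#'
#' One config object drives all four generators (Ct plates, target mRNA
#' matrix, tumor counts, ChIP reads) so that a single seed reproduces a
#' complete, internally consistent synthetic experiment.
#'
#' Defaults emulate the profiled design: four sorted mammary cell subsets
#' (MaSC/basal, luminal progenitor LP, mature luminal ML, stroma) with at
#' least three biological replicates each, an endogenous-control block of
#' stable housekeeping small RNAs, and a plant-miRNA negative control.
#'
#' @param n_probes number of target miRNA probes on the array.
#' @param n_housekeeping number of stable housekeeping probes (>= 1).
#' @param n_replicates biological replicates per subset (>= 3, the
#'   design's minimum replication).
#' @param subsets cell subset labels.
#' @param n_planted_per_subset number of probes planted differentially
#'   expressed (up) in each subset.
#' @param effect_size planted shift in log2 expression units (> 0 unless
#'   exactly 0, which plants nothing: the null model).
#' @param noise_sd residual SD of target-probe Ct values, log2 units.
#' @param plate_shift_sd SD of the per-sample additive plate shift
#'   (what cyclic loess normalization is there to remove).
#' @param undetected_fraction proportion of target wells censored to the
#'   undetected ceiling Ct = 40.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param species `"mouse"` or `"human"`; controls probe name prefixes.
#' @param hk_noise_sd residual SD of housekeeping Ct values (documented
#'   constant, default 0.1 log2 units).
#' @param n_genes,targets_per_mirna,decoys_per_mirna,mrna_coupling,mrna_noise_sd
#'   mRNA generator: gene universe size; true targets per planted miRNA;
#'   decoy genes listed per miRNA without planted effect; coupling of
#'   target-gene log2FC to miRNA log2FC (default -1: targets move equal
#'   and opposite); gene-level residual SD.
#' @param subtypes,n_tumors_per_subtype,tumor_elevation,tumor_dispersion,n_tech_replicates,isoform_fraction,mean_lib_size,subtype_map
#'   tumor generator: intrinsic subtype labels; tumors per subtype;
#'   planted log2 elevation of a subset's signature miRNAs in its matched
#'   subtype; NB dispersion (0 falls back to Poisson); number of samples
#'   duplicated as technical replicates sharing an analyte ID; fraction of
#'   miRNAs emitted as two isoform rows; average library size; named map
#'   subset -> subtype.
#' @param chip_subsets,chip_coupling,chip_n_loci,chip_base_reads,chip_background_reads,chip_mark_noise_sd,chip_flank,chip_read_length,chip_isoform_pairs
#'   ChIP generator: the subset pair profiled; named coupling slopes of
#'   expression log2FC on mark log2FC (active mark >= 0, repressive
#'   <= 0); number of miRNA loci; expected reads per locus at null;
#'   genome-wide background reads per track; SD of locus-level mark
#'   effect noise; interval flank in bp; read length; number of 3p/5p
#'   isoform pairs sharing one genomic interval.
#'
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(n_probes = 600,
                         n_housekeeping = 4,
                         n_replicates = 4,
                         subsets = c("MaSC/basal", "LP", "ML", "stroma"),
                         n_planted_per_subset = 25,
                         effect_size = 3,
                         noise_sd = 0.5,
                         plate_shift_sd = 0.5,
                         undetected_fraction = 0.05,
                         seed = 1L,
                         species = c("mouse", "human"),
                         hk_noise_sd = 0.1,
                         n_genes = 4000,
                         targets_per_mirna = 30,
                         decoys_per_mirna = 10,
                         mrna_coupling = -1,
                         mrna_noise_sd = 0.5,
                         subtypes = c("Basal", "LumA", "LumB", "Her2", "Normal"),
                         n_tumors_per_subtype = 20,
                         tumor_elevation = 2,
                         tumor_dispersion = 0.1,
                         n_tech_replicates = 3,
                         isoform_fraction = 0.1,
                         mean_lib_size = 2e5,
                         subtype_map = c("MaSC/basal" = "Normal",
                                         "LP" = "Basal",
                                         "ML" = "LumB"),
                         chip_subsets = c("MaSC/basal", "LP"),
                         chip_coupling = c(H3K4me3 = 0.5, H3K27me3 = -0.5),
                         chip_n_loci = 200,
                         chip_base_reads = 200,
                         chip_background_reads = 2000,
                         chip_mark_noise_sd = 0.25,
                         chip_flank = 3000,
                         chip_read_length = 36,
                         chip_isoform_pairs = 2) {
  species <- match.arg(species)
  cfg <- list(n_probes = n_probes, n_housekeeping = n_housekeeping,
              n_replicates = n_replicates, subsets = subsets,
              n_planted_per_subset = n_planted_per_subset,
              effect_size = effect_size, noise_sd = noise_sd,
              plate_shift_sd = plate_shift_sd,
              undetected_fraction = undetected_fraction,
              seed = as.integer(seed), species = species,
              hk_noise_sd = hk_noise_sd,
              n_genes = n_genes, targets_per_mirna = targets_per_mirna,
              decoys_per_mirna = decoys_per_mirna,
              mrna_coupling = mrna_coupling, mrna_noise_sd = mrna_noise_sd,
              subtypes = subtypes,
              n_tumors_per_subtype = n_tumors_per_subtype,
              tumor_elevation = tumor_elevation,
              tumor_dispersion = tumor_dispersion,
              n_tech_replicates = n_tech_replicates,
              isoform_fraction = isoform_fraction,
              mean_lib_size = mean_lib_size, subtype_map = subtype_map,
              chip_subsets = chip_subsets, chip_coupling = chip_coupling,
              chip_n_loci = chip_n_loci, chip_base_reads = chip_base_reads,
              chip_background_reads = chip_background_reads,
              chip_mark_noise_sd = chip_mark_noise_sd,
              chip_flank = chip_flank,
              chip_read_length = chip_read_length,
              chip_isoform_pairs = chip_isoform_pairs)
  if (cfg$n_housekeeping < 1) stop("n_housekeeping must be >= 1")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$undetected_fraction < 0 || cfg$undetected_fraction >= 1)
    stop("undetected_fraction must be in [0, 1)")
  if (cfg$n_replicates < 3)
    stop("n_replicates must be >= 3 (minimum biological replication)")
  if (length(cfg$subsets) < 2) stop("need at least two subsets")
  if (cfg$effect_size > 0 &&
      cfg$n_planted_per_subset * length(cfg$subsets) > cfg$n_probes)
    stop("n_probes too small for n_planted_per_subset x subsets")
  structure(cfg, class = "synth_config")
}

hk_probe_names <- function(n, species) {
  canonical <- if (species == "mouse") "U6"
               else c("U6", "RNU6B", "RNU24", "RNU43", "RNU44", "RNU48")
  if (n <= length(canonical)) return(canonical[seq_len(n)])
  c(canonical, sprintf("HK-syn-%02d", seq_len(n - length(canonical))))
}

epithelial_subsets <- function(subsets) setdiff(subsets, "stroma")

#' Generate synthetic TaqMan Ct plates with known ground truth
#'
#' Emulates a low-density-array miRNA profiling run: per-probe baseline Ct
#' values, subset-specific planted shifts of `effect_size` log2 units
#' (expression scale; i.e. the planted probes have *lower* Ct in their
#' subset), sample-wide additive plate shifts, stable housekeeping probes,
#' an always-undetected plant negative control, and random censoring of
#' target wells at the machine ceiling Ct = 40. Housekeeping wells are
#' never censored (they anchor the normalization; in real runs the
#' endogenous control is essentially never lost).
#'
#' @param config a [synth_config()].
#' @return A list with elements `plates` (a [ct_plates()] object) and
#'   `truth` (class `"mir_truth"`; `planted_de` maps probe to its subset
#'   and signed log2 effect, later generators append `target_truth`,
#'   `tumor_truth`, `chip_truth`).
#' @export
gen_ct_plates <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  prefix <- if (config$species == "mouse") "mmu-miR-syn" else "hsa-miR-syn"
  probes <- sprintf("%s-%04d", prefix, seq_len(config$n_probes))
  hk <- hk_probe_names(config$n_housekeeping, config$species)
  neg <- "ath-miR159a"

  subsets <- config$subsets
  samples <- data.frame(
    sample = paste(config$species,
                   rep(gsub("[^A-Za-z0-9]", "", subsets),
                       each = config$n_replicates),
                   rep(seq_len(config$n_replicates), length(subsets)),
                   sep = "_"),
    species = config$species,
    subset = rep(subsets, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(subsets)),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  base_ct <- stats::runif(config$n_probes, 22, 34)
  names(base_ct) <- probes
  ## housekeeping baselines spread over the abundance range so the
  ## weighted loess has anchors across A
  hk_ct <- seq(18, 28, length.out = length(hk)) +
    stats::rnorm(length(hk), 0, 0.3)
  names(hk_ct) <- hk

  ## planted subset-specific effects (expression scale, so Ct shift is -e)
  delta <- matrix(0, config$n_probes, length(subsets),
                  dimnames = list(probes, subsets))
  planted <- data.frame(probe = character(), subset = character(),
                        effect = numeric(), stringsAsFactors = FALSE)
  if (config$effect_size > 0 && config$n_planted_per_subset > 0) {
    pool <- sample(probes,
                   config$n_planted_per_subset * length(subsets))
    for (k in seq_along(subsets)) {
      pk <- pool[(k - 1) * config$n_planted_per_subset +
                   seq_len(config$n_planted_per_subset)]
      delta[pk, subsets[k]] <- -config$effect_size
      planted <- rbind(planted,
                       data.frame(probe = pk, subset = subsets[k],
                                  effect = config$effect_size,
                                  stringsAsFactors = FALSE))
    }
  }

  shift <- stats::rnorm(ns, 0, config$plate_shift_sd)

  ct_target <- outer(base_ct, shift, "+") +
    delta[, samples$subset, drop = FALSE] +
    matrix(stats::rnorm(config$n_probes * ns, 0, config$noise_sd),
           config$n_probes, ns)
  ct_hk <- outer(hk_ct, shift, "+") +
    matrix(stats::rnorm(length(hk) * ns, 0, config$hk_noise_sd),
           length(hk), ns)

  if (config$undetected_fraction > 0) {
    cens <- stats::runif(length(ct_target)) < config$undetected_fraction
    ct_target[cens] <- 40
  }
  ct <- rbind(ct_target, ct_hk,
              matrix(40, 1, ns, dimnames = list(neg, NULL)))
  ct <- pmin(pmax(ct, 0), 40)
  rownames(ct) <- c(probes, hk, neg)
  colnames(ct) <- samples$sample

  cls <- c(rep("target", length(probes)),
           rep("housekeeping", length(hk)), "negative_control")
  records <- data.frame(
    sample = rep(colnames(ct), each = nrow(ct)),
    probe = rep(rownames(ct), ns),
    probe_class = rep(cls, ns),
    ct = as.vector(ct),
    stringsAsFactors = FALSE)

  truth <- structure(list(planted_de = planted,
                          probes = probes,
                          config = config,
                          target_truth = NULL,
                          tumor_truth = NULL,
                          chip_truth = NULL),
                     class = "mir_truth")
  list(plates = ct_plates(records, samples), truth = truth)
}

#' Generate a synthetic target mRNA expression matrix and target map
#'
#' For each planted epithelial-subset miRNA, a disjoint set of target
#' genes receives a log2 effect of `mrna_coupling * effect` in the
#' miRNA's subset (default coupling -1: targets move equal and opposite,
#' the repression pattern the rotation tests look for). Non-target genes
#' are exchangeable Gaussian noise. The returned target map lists every
#' true target plus `decoys_per_mirna` unaffected decoy genes per miRNA.
#'
#' @param truth ground truth from [gen_ct_plates()].
#' @param config the same [synth_config()].
#' @return A list: `mrna` (a [expression_matrix()] of genes x samples over
#'   the epithelial subsets), `target_map` (data frame `mirna`, `gene`),
#'   and the updated `truth` with `target_truth` filled in.
#' @export
gen_mrna_matrix <- function(truth, config) {
  stopifnot(inherits(truth, "mir_truth"))
  set.seed(config$seed + 1L)
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  epi <- epithelial_subsets(config$subsets)
  planted <- truth$planted_de
  planted <- planted[planted$subset %in% epi, , drop = FALSE]

  samples <- data.frame(
    sample = paste("mrna", rep(gsub("[^A-Za-z0-9]", "", epi),
                               each = config$n_replicates),
                   rep(seq_len(config$n_replicates), length(epi)),
                   sep = "_"),
    species = config$species,
    subset = rep(epi, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(epi)),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  base <- stats::runif(config$n_genes, 4, 12)
  eff <- matrix(0, config$n_genes, length(epi),
                dimnames = list(genes, epi))

  n_mir <- nrow(planted)
  map <- data.frame(mirna = character(), gene = character(),
                    stringsAsFactors = FALSE)
  tt <- data.frame(mirna = character(), gene = character(),
                   effect = numeric(), stringsAsFactors = FALSE)
  if (n_mir > 0) {
    need <- n_mir * config$targets_per_mirna
    if (need > config$n_genes)
      stop("n_genes too small for disjoint target sets")
    tgt_pool <- sample(genes, need)
    for (i in seq_len(n_mir)) {
      tg <- tgt_pool[(i - 1) * config$targets_per_mirna +
                       seq_len(config$targets_per_mirna)]
      e <- config$mrna_coupling * planted$effect[i]
      eff[tg, planted$subset[i]] <- eff[tg, planted$subset[i]] + e
      decoys <- sample(setdiff(genes, tgt_pool), config$decoys_per_mirna)
      map <- rbind(map, data.frame(mirna = planted$probe[i],
                                   gene = c(tg, decoys),
                                   stringsAsFactors = FALSE))
      tt <- rbind(tt, data.frame(mirna = planted$probe[i], gene = tg,
                                 effect = e, stringsAsFactors = FALSE))
    }
  }

  E <- base + eff[, samples$subset, drop = FALSE] +
    matrix(stats::rnorm(config$n_genes * ns, 0, config$mrna_noise_sd),
           config$n_genes, ns)
  rownames(E) <- genes
  colnames(E) <- samples$sample
  truth$target_truth <- tt
  list(mrna = expression_matrix(E, samples = samples, normalized = TRUE),
       target_map = map, truth = truth)
}

#' Generate synthetic tumor miRNA-seq read counts
#'
#' Negative-binomial counts over the Ct-stage miRNA universe. Each
#' epithelial subset's planted signature miRNAs are elevated by
#' `tumor_elevation` log2 units in the matched intrinsic subtype
#' (`subtype_map`). A few samples are emitted twice under a shared
#' analyte ID (technical replicates) and a fraction of miRNAs appear as
#' two isoform rows (`-3p`/`-5p`) carrying the same parent symbol, so the
#' collapse step has real work to do. `tumor_dispersion = 0` falls back
#' to Poisson sampling.
#'
#' @param truth ground truth carrying `planted_de` from [gen_ct_plates()].
#' @param config the same [synth_config()].
#' @return A list: `counts` (a [count_matrix()]) and updated `truth` with
#'   `tumor_truth` (data frame `mirna`, `subtype`, `elevation`).
#' @export
gen_tumor_counts <- function(truth, config) {
  stopifnot(inherits(truth, "mir_truth"))
  if (length(config$subtypes) < 2 || config$n_tumors_per_subtype < 2)
    stop("need >= 2 subtypes with >= 2 tumors each")
  set.seed(config$seed + 2L)
  mirnas <- truth$probes
  n <- length(mirnas)

  subtype <- rep(config$subtypes, each = config$n_tumors_per_subtype)
  nt <- length(subtype)
  samples <- data.frame(
    sample = sprintf("TUMOR-%03d", seq_len(nt)),
    analyte_id = sprintf("ANL-%03d", seq_len(nt)),
    subtype = subtype,
    sample_type = "Primary Solid Tumor",
    stringsAsFactors = FALSE)

  ## planted elevations: subset signature miRNAs up in the matched subtype
  elev <- matrix(0, n, length(config$subtypes),
                 dimnames = list(mirnas, config$subtypes))
  tt <- data.frame(mirna = character(), subtype = character(),
                   elevation = numeric(), stringsAsFactors = FALSE)
  pl <- truth$planted_de
  for (s in names(config$subtype_map)) {
    st <- config$subtype_map[[s]]
    if (!st %in% config$subtypes) next
    mm <- pl$probe[pl$subset == s]
    mm <- intersect(mm, mirnas)
    if (!length(mm)) next
    elev[mm, st] <- elev[mm, st] + config$tumor_elevation
    tt <- rbind(tt, data.frame(mirna = mm, subtype = st,
                               elevation = config$tumor_elevation,
                               stringsAsFactors = FALSE))
  }

  base <- stats::rnorm(n, 5, 2)
  lib <- round(stats::runif(nt, 0.8, 1.2) * config$mean_lib_size)
  w <- 2^(base + elev[, samples$subtype, drop = FALSE])
  mu <- sweep(sweep(w, 2, colSums(w), "/"), 2, lib, "*")

  ## technical replicates: duplicate columns sharing the analyte ID
  if (config$n_tech_replicates > 0) {
    dup <- sample(nt, min(config$n_tech_replicates, nt))
    mu <- cbind(mu, mu[, dup, drop = FALSE])
    extra <- samples[dup, , drop = FALSE]
    extra$sample <- paste0(extra$sample, "-rep2")
    samples <- rbind(samples, extra)
  }

  ## isoform rows: split a fraction of miRNAs into -3p / -5p
  iso <- sample(n, round(config$isoform_fraction * n))
  features <- data.frame(id = mirnas, parent = mirnas,
                         stringsAsFactors = FALSE)
  if (length(iso)) {
    frac <- stats::runif(length(iso), 0.2, 0.8)
    mu3 <- mu[iso, , drop = FALSE] * frac
    mu5 <- mu[iso, , drop = FALSE] * (1 - frac)
    mu <- rbind(mu[-iso, , drop = FALSE], mu3, mu5)
    features <- rbind(
      features[-iso, , drop = FALSE],
      data.frame(id = paste0(mirnas[iso], "-3p"), parent = mirnas[iso],
                 stringsAsFactors = FALSE),
      data.frame(id = paste0(mirnas[iso], "-5p"), parent = mirnas[iso],
                 stringsAsFactors = FALSE))
  }
  rownames(mu) <- features$id

  counts <- if (config$tumor_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu,
                          size = 1 / config$tumor_dispersion),
           nrow(mu), ncol(mu))
  } else {
    matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  }
  dimnames(counts) <- list(features$id, samples$sample)

  truth$tumor_truth <- tt
  list(counts = count_matrix(counts, features, samples), truth = truth)
}

#' Generate synthetic ChIP-seq reads over miRNA loci
#'
#' Places `chip_n_loci` miRNA loci on one synthetic chromosome and, for
#' each (subset, mark) track, samples read start positions over each
#' locus +/- `chip_flank` with intensity `2^(planted mark effect)`, plus
#' uniform genome-wide background. The planted mark effect at each locus
#' is `expression_log2FC / coupling + noise`, so that regressing
#' expression log2FC through the origin on estimated mark log2FC
#' recovers the coupling slope (positive for the active mark H3K4me3,
#' negative for the repressive H3K27me3). A few 3p/5p isoform pairs share
#' one genomic interval with reads generated once.
#'
#' @param truth ground truth carrying `planted_de`.
#' @param config the same [synth_config()].
#' @return A list: `reads` (named list of BED-like data frames, one per
#'   `<subset>.<mark>` track), `loci` (data frame: symbol, chrom, start,
#'   end, strand, partner), `expr_logfc` (true expression log2FC per
#'   locus for the subset pair), and updated `truth` with `chip_truth`.
#' @export
gen_chip_reads <- function(truth, config) {
  stopifnot(inherits(truth, "mir_truth"))
  set.seed(config$seed + 3L)
  pair <- config$chip_subsets
  if (length(pair) != 2) stop("chip_subsets must name exactly two subsets")
  flank <- config$chip_flank
  if (flank < 0) stop("flank must be >= 0")
  rl <- config$chip_read_length

  pl <- truth$planted_de
  in_pair <- pl$probe[pl$subset %in% pair]
  others <- setdiff(truth$probes, pl$probe)
  n_loci <- min(config$chip_n_loci, length(in_pair) + length(others))
  symbols <- c(in_pair, others)[seq_len(n_loci)]

  ## true expression log2FC (pair[1] - pair[2]) per locus
  y <- numeric(n_loci)
  names(y) <- symbols
  y[intersect(symbols, pl$probe[pl$subset == pair[1]])] <- config$effect_size
  y[intersect(symbols, pl$probe[pl$subset == pair[2]])] <- -config$effect_size

  spacing <- 2 * flank + 4000
  width <- 80
  start <- 10000 + (seq_len(n_loci) - 1) * spacing
  loci <- data.frame(symbol = symbols, chrom = "chrS",
                     start = start, end = start + width,
                     strand = rep(c("+", "-"), length.out = n_loci),
                     partner = NA_character_,
                     stringsAsFactors = FALSE)

  ## isoform pairs share one interval: emit -3p/-5p records at one locus
  n_iso <- min(config$chip_isoform_pairs, n_loci)
  if (n_iso > 0) {
    idx <- seq_len(n_iso)
    a <- loci[idx, , drop = FALSE]
    b <- a
    a$symbol <- paste0(loci$symbol[idx], "-5p")
    b$symbol <- paste0(loci$symbol[idx], "-3p")
    a$partner <- b$symbol
    b$partner <- a$symbol
    y2 <- c(stats::setNames(y[idx], a$symbol),
            stats::setNames(y[idx], b$symbol),
            y[-idx])
    loci <- rbind(a, b, loci[-idx, , drop = FALSE])
    y <- y2
  }
  chrom_len <- max(loci$end) + flank + 10000

  ## one set of intervals per distinct genomic location
  uniq <- !duplicated(loci[, c("chrom", "start", "end")])
  uloci <- loci[uniq, , drop = FALSE]
  uy <- y[uniq]

  marks <- names(config$chip_coupling)
  mark_eff <- sapply(config$chip_coupling, function(cc) {
    uy / cc + stats::rnorm(nrow(uloci), 0, config$chip_mark_noise_sd)
  })
  rownames(mark_eff) <- uloci$symbol

  reads <- list()
  for (m in marks) {
    for (k in 1:2) {
      sgn <- if (k == 1) 0.5 else -0.5
      lam <- config$chip_base_reads * 2^(sgn * mark_eff[, m])
      nread <- stats::rpois(nrow(uloci), lam)
      pos <- unlist(lapply(seq_len(nrow(uloci)), function(i) {
        lo <- max(0, uloci$start[i] - flank)
        hi <- uloci$end[i] + flank - rl
        if (nread[i] == 0) integer(0)
        else lo + floor(stats::runif(nread[i]) * (hi - lo))
      }))
      bg <- floor(stats::runif(config$chip_background_reads) *
                    (chrom_len - rl))
      st <- sort(c(pos, bg))
      trk <- paste0(gsub("[^A-Za-z0-9]", "", pair[k]), ".", m)
      reads[[trk]] <- data.frame(chrom = "chrS", start = st,
                                 end = st + rl,
                                 name = sprintf("read%07d", seq_along(st)),
                                 score = 0L, strand = ".",
                                 stringsAsFactors = FALSE)
    }
  }

  truth$chip_truth <- list(
    coupling = config$chip_coupling,
    mark_effects = data.frame(symbol = rep(uloci$symbol, length(marks)),
                              mark = rep(marks, each = nrow(uloci)),
                              effect = as.vector(mark_eff),
                              stringsAsFactors = FALSE),
    expr_logfc = data.frame(symbol = names(y), logfc = as.numeric(y),
                            stringsAsFactors = FALSE))
  list(reads = reads, loci = loci,
       expr_logfc = truth$chip_truth$expr_logfc, truth = truth)
}

## ---- plain-text writers -------------------------------------------------

#' Write a Ct plate set as CSV
#'
#' @param plates a [ct_plates()] object.
#' @param path output CSV path.
#' @param undetermined_token if TRUE, wells at the Ct = 40 ceiling are
#'   written as the literal token `"Undetermined"`, exercising the
#'   reader's coercion rule.
#' @export
write_ct_export <- function(plates, path, undetermined_token = FALSE) {
  stopifnot(inherits(plates, "ct_plates"))
  rec <- plates$records
  ct <- as.character(rec$ct)
  if (undetermined_token) ct[rec$ct >= 40] <- "Undetermined"
  out <- data.frame(sample = rec$sample, probe = rec$probe,
                    probe_class = rec$probe_class, ct = ct,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV (probes in rows, first column `probe`)
#' @param expr a [expression_matrix()] object.
#' @param path output TSV path.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "mir_expr"))
  out <- data.frame(probe = rownames(expr$E), expr$E,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a count matrix plus sample annotation as TSV
#' @param counts a [count_matrix()] object.
#' @param path output counts TSV (first column `mirna`, second `parent`).
#' @param annot_path optional sample annotation TSV
#'   (`sample`, `analyte_id`, `subtype`, `sample_type`).
#' @export
write_counts_tsv <- function(counts, path, annot_path = NULL) {
  stopifnot(inherits(counts, "mir_counts"))
  out <- data.frame(mirna = counts$features$id,
                    parent = counts$features$parent, counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(annot_path))
    utils::write.table(counts$samples, annot_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write intervals or reads as 6-column BED (0-based half-open)
#' @param x data frame with columns chrom, start, end, name, score, strand.
#' @param path output BED path.
#' @export
write_bed6 <- function(x, path) {
  out <- x[, c("chrom", "start", "end", "name", "score", "strand")]
  out$start <- as.integer(out$start)  # never scientific notation
  out$end <- as.integer(out$end)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground truth as a flat key-value text file
#' @param truth a `"mir_truth"` object.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pd <- truth$planted_de
  if (nrow(pd))
    writeLines(sprintf("planted_de\t%s\t%s\t%g",
                       pd$probe, pd$subset, pd$effect), con)
  tt <- truth$target_truth
  if (!is.null(tt) && nrow(tt))
    writeLines(sprintf("target_truth\t%s\t%s\t%g",
                       tt$mirna, tt$gene, tt$effect), con)
  tu <- truth$tumor_truth
  if (!is.null(tu) && nrow(tu))
    writeLines(sprintf("tumor_truth\t%s\t%s\t%g",
                       tu$mirna, tu$subtype, tu$elevation), con)
  ch <- truth$chip_truth
  if (!is.null(ch))
    writeLines(sprintf("chip_coupling\t%s\t%g",
                       names(ch$coupling), ch$coupling), con)
  invisible(path)
}
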