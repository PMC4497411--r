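test_that("mirna_intervals flanks, clips and merges", {
  loci <- data.frame(symbol = c("a", "b-5p", "b-3p"),
                     chrom = "chr1",
                     start = c(5000L, 100L, 100L),
                     end = c(5080L, 180L, 180L),
                     strand = c("+", "+", "-"),
                     partner = c(NA, "b-3p", "b-5p"))
  ivl <- mirna_intervals(loci, flank = 3000)
  expect_equal(nrow(ivl), 2L)
  expect_equal(ivl$start[1], 2000)
  expect_equal(ivl$end[1], 8080)
  expect_equal(ivl$start[2], 0)          # clipped at chromosome start
  expect_equal(ivl$end[2], 3180)
  expect_identical(ivl$symbols[2], "b-5p,b-3p")
  expect_error(mirna_intervals(loci, flank = -1), ">= 0")
})

test_that("read counting is half-open and matches a quadratic oracle", {
  ivl <- data.frame(interval_id = c("i1", "i2"), chrom = "chr1",
                    start = c(2000L, 9000L), end = c(8080L, 9500L),
                    symbols = c("a", "b"))
  rd <- data.frame(chrom = "chr1",
                   start = c(2500L, 8080L, 1999L, 1960L, 9499L),
                   end = c(2536L, 8116L, 2035L, 2000L, 9535L),
                   name = paste0("r", 1:5), score = 0L, strand = ".")
  mc <- count_reads(ivl, list(t1 = rd))
  ## inside; start == interval end (excluded); 1 bp overlap (included);
  ## read end == interval start (excluded, half-open); 1 bp at end
  expect_equal(unname(mc$counts[, "t1"]), c(2L, 1L))
  expect_equal(unname(mc$lib_size["t1"]), 5L)
  ## off-chromosome reads are ignored with a message
  rd2 <- rbind(rd, data.frame(chrom = "chrX", start = 1L, end = 37L,
                              name = "r6", score = 0L, strand = "."))
  expect_message(mc2 <- count_reads(ivl, list(t1 = rd2)), "ignored")
  expect_equal(mc2$counts, mc$counts)
  ## quadratic brute-force oracle on random reads and intervals
  set.seed(91)
  ivl3 <- data.frame(interval_id = paste0("v", 1:25), chrom = "chr1",
                     start = st <- sort(sample(0:50000, 25)),
                     end = st + sample(200:2000, 25, replace = TRUE),
                     symbols = paste0("v", 1:25))
  rs <- sample(0:52000, 2000, replace = TRUE)
  rd3 <- data.frame(chrom = "chr1", start = rs, end = rs + 36,
                    name = paste0("q", 1:2000), score = 0L, strand = ".")
  mc3 <- count_reads(ivl3, list(t = rd3))
  oracle <- vapply(seq_len(25), function(i)
    sum(rd3$start < ivl3$end[i] & rd3$end > ivl3$start[i]), 0L)
  expect_equal(unname(mc3$counts[, 1]), oracle)
  ## additivity over split tracks
  mc_a <- count_reads(ivl3, list(t = rd3[1:900, ]))
  mc_b <- count_reads(ivl3, list(t = rd3[-(1:900), ]))
  expect_equal(mc_a$counts + mc_b$counts, mc3$counts)
})

## NB log-likelihood kernel valid for non-integer y (prior-augmented)
nb_loglik <- function(b, y, off, phi) {
  mu <- exp(b + off)
  if (phi == 0) sum(y * log(mu) - mu)
  else sum(y * log(mu) - (y + 1 / phi) * log(1 + phi * mu))
}

test_that("nbglm_logfc: closed form, limits and likelihood oracle", {
  ## group means 5 and 10, prior 1, equal libraries: log2(11/6)
  x <- matrix(c(5, 5, 10, 10), 1, 4,
              dimnames = list("L", paste0("s", 1:4)))
  lf <- nbglm_logfc(x, c("a", "a", "b", "b"), dispersion = 0.05,
                    prior_count = 1, lib_size = rep(1e4, 4))
  expect_equal(unname(lf[1, "a - b"]), log2(6 / 11), tolerance = 1e-10)
  ## identical groups give 0
  x2 <- matrix(c(7, 7, 7, 7), 1, 4,
               dimnames = list("L", paste0("s", 1:4)))
  expect_equal(unname(nbglm_logfc(x2, c("a", "a", "b", "b"),
                                  lib_size = rep(1e4, 4))[1, 1]), 0)
  ## growing prior shrinks |log2FC| monotonically toward 0
  lfs <- vapply(c(1, 10, 100, 1000), function(pc)
    abs(nbglm_logfc(x, c("a", "a", "b", "b"), prior_count = pc,
                    lib_size = rep(1e4, 4))[1, 1]), 0)
  expect_true(all(diff(lfs) < 0))
  ## unequal libraries: matches brute-force likelihood maximization
  set.seed(92)
  y <- matrix(rnbinom(6, mu = c(40, 80, 60, 200, 150, 180), size = 20),
              1, 6, dimnames = list("L", paste0("s", 1:6)))
  lib <- c(1e4, 2e4, 1.5e4, 1e4, 2e4, 1.2e4)
  grp <- rep(c("a", "b"), each = 3)
  phi <- 0.1
  lf2 <- nbglm_logfc(y, grp, dispersion = phi, prior_count = 1,
                     lib_size = lib)
  pc <- 1 * lib / mean(lib)
  yy <- y[1, ] + pc
  off <- log(lib + 2 * pc)
  ba <- stats::optimize(function(b) nb_loglik(b, yy[1:3], off[1:3], phi),
                        c(-20, 10), maximum = TRUE, tol = 1e-10)$maximum
  bb <- stats::optimize(function(b) nb_loglik(b, yy[4:6], off[4:6], phi),
                        c(-20, 10), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(lf2[1, "a - b"]), (ba - bb) / log(2),
               tolerance = 1e-4)
  ## dispersion 0 equals the Poisson closed form
  lf0 <- nbglm_logfc(y, grp, dispersion = 0, prior_count = 1,
                     lib_size = lib)
  pois <- log2(sum(yy[1:3]) / sum(exp(off[1:3]))) -
    log2(sum(yy[4:6]) / sum(exp(off[4:6])))
  expect_equal(unname(lf0[1, 1]), pois, tolerance = 1e-10)
})

test_that("origin_regression matches closed forms and the lm oracle", {
  r <- origin_regression(c(1, 2), c(2, 4))
  expect_equal(r$slope, 2)
  expect_equal(r$se, 0)
  ## orthogonal y gives slope 0
  expect_equal(origin_regression(c(1, -1), c(1, 1))$slope, 0)
  ## random case against lm(y ~ 0 + x)
  set.seed(93)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50)
  r2 <- origin_regression(x, y)
  s <- summary(stats::lm(y ~ 0 + x))
  expect_equal(r2$slope, unname(coef(s)[1, 1]), tolerance = 1e-10)
  expect_equal(r2$se, unname(coef(s)[1, 2]), tolerance = 1e-10)
  expect_equal(r2$p, unname(coef(s)[1, 4]), tolerance = 1e-10)
  ## scale equivariance: x -> c x scales the slope by 1/c
  r3 <- origin_regression(3 * x, y)
  expect_equal(r3$slope, r2$slope / 3, tolerance = 1e-12)
  expect_error(origin_regression(c(0, 0), c(1, 2)), "zero")
  expect_error(origin_regression(1, 1), "two points")
})

test_that("top_de_selection orders by p, |logFC|, symbol", {
  tb <- data.frame(probe = c("c", "a", "b", "d"),
                   logFC = c(1, -3, 2, 2),
                   p = c(0.5, 0.01, 0.01, 0.01))
  expect_identical(top_de_selection(tb, 0), character(0))
  ## ties on p: |logFC| descending, then symbol
  expect_identical(top_de_selection(tb, 3), c("a", "b", "d"))
  expect_warning(sel <- top_de_selection(tb, 10), "table has")
  expect_identical(sel, c("a", "b", "d", "c"))
  ## random table equals an explicit sort oracle
  set.seed(94)
  tb2 <- data.frame(probe = sample(letters), logFC = rnorm(26),
                    p = sample(rep(c(0.1, 0.2), 13)))
  o <- with(tb2, order(p, -abs(logFC), probe))
  expect_identical(top_de_selection(tb2, 26), tb2$probe[o])
})

test_that("decoupled marks give a near-zero slope", {
  cfg <- synth_config(n_probes = 120, n_planted_per_subset = 10,
                      chip_n_loci = 60, n_genes = 1500,
                      undetected_fraction = 0, seed = 95)
  g <- gen_ct_plates(cfg)
  ch <- gen_chip_reads(gen_tumor_counts(
    gen_mrna_matrix(g$truth, cfg)$truth, cfg)$truth, cfg)
  mc <- count_reads(mirna_intervals(ch$loci, 3000), ch$reads)
  e <- filter_expressed(cyclic_loess_normalize(ct_to_log2(g$plates)))
  de <- pairwise_de(e, "MaSC/basal", "LP")
  lk <- link_marks_to_expression(de, mc, c("MaSC/basal", "LP"),
                                 n_top = 60)
  ## couplings recovered with the right signs
  expect_gt(lk$links$H3K4me3$slope, 0.2)
  expect_lt(lk$links$H3K27me3$slope, -0.2)
  ## permuting counts across loci destroys the association
  set.seed(96)
  mcp <- mc
  mcp$counts <- mc$counts[sample(nrow(mc$counts)), , drop = FALSE]
  rownames(mcp$counts) <- rownames(mc$counts)
  lkp <- link_marks_to_expression(de, mcp, c("MaSC/basal", "LP"),
                                  n_top = 60)
  for (m in names(lkp$links)) {
    z <- abs(lkp$links[[m]]$slope) / lkp$links[[m]]$se
    expect_lt(z, 4)
  }
})

test_that("coverage bedGraph reports reads-per-million depth", {
  rd <- data.frame(chrom = "chr1", start = c(100L, 120L, 500L),
                   end = c(136L, 156L, 536L))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage_bedgraph(rd, f)
  bg <- utils::read.delim(f, header = FALSE,
                          col.names = c("chrom", "start", "end", "rpm"))
  ## depth 2 where the first two reads overlap: [120, 136)
  i <- bg$start == 120 & bg$end == 136
  expect_equal(bg$rpm[i], 2 / 3 * 1e6, tolerance = 1e-5)
  expect_equal(bg$rpm[bg$start == 500], 1 / 3 * 1e6, tolerance = 1e-5)
})

test_that("loci and reads round-trip through BED", {
  cfg <- synth_config(n_probes = 40, n_planted_per_subset = 3,
                      chip_n_loci = 10, chip_background_reads = 50,
                      n_genes = 500, seed = 97)
  g <- gen_ct_plates(cfg)
  ch <- gen_chip_reads(gen_tumor_counts(
    gen_mrna_matrix(g$truth, cfg)$truth, cfg)$truth, cfg)
  fl <- withr::local_tempfile(fileext = ".bed")
  write_bed6(data.frame(chrom = ch$loci$chrom, start = ch$loci$start,
                        end = ch$loci$end, name = ch$loci$symbol,
                        score = 0L, strand = ch$loci$strand), fl)
  back <- read_mirna_loci(fl)
  expect_equal(back$start, ch$loci$start)
  expect_equal(back$end, ch$loci$end)
  expect_identical(back$symbol, ch$loci$symbol)
  fr <- withr::local_tempfile(fileext = ".bed")
  trk <- ch$reads[[1]]
  write_bed6(trk, fr)
  rback <- read_reads_bed(fr)
  expect_equal(rback$start, trk$start)
  expect_equal(rback$end, trk$end)
})
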