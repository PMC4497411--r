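## Shared fixture builders. Everything is generated in code; no binary
## fixtures. Seeds are fixed so expected values frozen in tests are
## reproducible.

## small expression matrix with three epithelial subsets
make_epi_expr <- function(n_probes = 50, n_rep = 4, noise = 0.5,
                          seed = 99) {
  set.seed(seed)
  subsets <- c("MaSC/basal", "LP", "ML")
  samples <- data.frame(
    sample = paste0("s", seq_len(3 * n_rep)),
    species = "mouse",
    subset = rep(subsets, each = n_rep),
    replicate = rep(seq_len(n_rep), 3),
    stringsAsFactors = FALSE)
  E <- matrix(stats::rnorm(n_probes * 3 * n_rep, 10, noise),
              n_probes, 3 * n_rep,
              dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                              samples$sample))
  expression_matrix(E, samples = samples, normalized = TRUE)
}

## tiny Ct plate set built by hand
make_tiny_plates <- function() {
  rec <- expand.grid(sample = c("S1", "S2"),
                     probe = c("miR-1", "miR-2", "U6"),
                     stringsAsFactors = FALSE)
  rec$probe_class <- ifelse(rec$probe == "U6", "housekeeping", "target")
  rec$ct <- c(20, 21, 30, 31, 25, 25)
  ct_plates(rec)
}

## brute-force BH step-up oracle, independent of bh_adjust()
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(m * p[o][j:m] / (j:m)))
  }
  adj
}

## brute-force average-linkage agglomeration: returns sorted merge heights
average_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bh <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        h <- mean(D[clusters[[a]], clusters[[b]]])
        if (h < bh) { bh <- h; best <- c(a, b) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
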