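test_that("probe-wise least squares matches hand and oracle results", {
  ## two groups of three, values 1 vs 3: difference 2, zero variance
  E <- matrix(c(1, 1, 1, 3, 3, 3), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  X <- cbind(g1 = rep(c(1, 0), each = 3), g2 = rep(c(0, 1), each = 3))
  fit <- fit_linear_model(E, X)
  expect_equal(unname(fit$coefficients[1, "g2"] -
                        fit$coefficients[1, "g1"]), 2)
  expect_equal(unname(fit$sigma2), 0)
  ## intercept-only design gives the row mean
  fit0 <- fit_linear_model(E, matrix(1, 6, 1,
                                     dimnames = list(NULL, "mu")))
  expect_equal(unname(fit0$coefficients[1, 1]), 2)
  ## normal-equations oracle on a random 50 x 8 problem
  set.seed(41)
  E2 <- matrix(rnorm(50 * 8), 50, 8,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  X2 <- cbind(1, rnorm(8), rep(0:1, 4))
  colnames(X2) <- c("b0", "x", "z")
  fit2 <- fit_linear_model(E2, X2)
  beta_or <- t(solve(crossprod(X2), t(X2) %*% t(E2)))
  expect_lt(max(abs(fit2$coefficients - beta_or)), 1e-10)
  ## rank-deficient design names the collinear column
  X3 <- cbind(a = rep(1, 8), b = rep(1, 8))
  expect_error(fit_linear_model(E2, X3), "collinear")
})

test_that("eBayes limits behave and hyperparameters are recovered", {
  set.seed(42)
  E <- matrix(rnorm(100 * 8, sd = rep(runif(100, 0.5, 2), 8)), 100, 8,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  X <- cbind(A = rep(1:0, each = 4), B = rep(0:1, each = 4))
  fit <- contrast_fit(fit_linear_model(E, X),
                      matrix(c(1, -1), dimnames = list(c("A", "B"), "d")))
  ## d0 = 0: ordinary t
  eb0 <- ebayes_moderate(fit, d0_override = 0)
  t_ord <- fit$coefficients[, 1] /
    (fit$stdev_unscaled[, 1] * sqrt(fit$sigma2))
  expect_equal(unname(eb0$t[, 1]), unname(t_ord), tolerance = 1e-12)
  ## d0 = Inf: all posterior variances equal s0^2
  ebI <- ebayes_moderate(fit, d0_override = Inf)
  expect_true(all(ebI$var_post == ebI$s0_2))
  ## shrinkage pulls var_post strictly between s2 and s0^2
  eb <- ebayes_moderate(fit)
  if (is.finite(eb$d0)) {
    between <- (eb$var_post - fit$sigma2) * (eb$var_post - eb$s0_2) <= 0
    expect_true(all(between))
  }
  ## Monte-Carlo recovery of (d0 = 4, s0^2 = 2) from 5000 variances
  set.seed(43)
  d <- 10
  sigma2 <- 4 * 2 / rchisq(5000, df = 4)       # inverse-chisq prior
  s2 <- sigma2 * rchisq(5000, df = d) / d
  pri <- fit_f_dist(s2, d)
  expect_lt(abs(pri$d0 - 4) / 4, 0.25)
  expect_lt(abs(pri$s0_2 - 2) / 2, 0.10)
})

test_that("moderated t and F agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(44)
  s2true <- 2 * rchisq(300, 4) / 4
  E <- matrix(rnorm(300 * 9, sd = sqrt(rep(s2true, 9))), 300, 9,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:9)))
  X <- cbind(A = rep(c(1, 0, 0), each = 3), B = rep(c(0, 1, 0), each = 3),
             C = rep(c(0, 0, 1), each = 3))
  C2 <- cbind(AvB = c(1, -1, 0), BvC = c(0, 1, -1))
  rownames(C2) <- colnames(X)
  fit <- contrast_fit(fit_linear_model(E, X), C2)
  eb <- ebayes_moderate(fit)
  lf <- limma::eBayes(limma::contrasts.fit(limma::lmFit(E, X), C2))
  expect_equal(eb$d0, lf$df.prior, tolerance = 1e-10)
  expect_equal(eb$s0_2, lf$s2.prior, tolerance = 1e-10)
  expect_equal(unname(eb$t), unname(lf$t), tolerance = 1e-10)
  expect_equal(unname(eb$F), unname(lf$F), tolerance = 1e-10)
  expect_equal(unname(eb$p_F), unname(lf$F.p.value), tolerance = 1e-10)
})

test_that("bh_adjust matches closed forms and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  set.seed(45)
  p <- runif(1000)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  ## monotone in p
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
})

test_that("signature_de recovers planted probes and is exact on flats", {
  cfg <- synth_config(n_probes = 300, effect_size = 3, noise_sd = 0.5,
                      undetected_fraction = 0, seed = 46)
  g <- gen_ct_plates(cfg)
  e <- filter_expressed(cyclic_loess_normalize(ct_to_log2(g$plates)))
  de <- signature_de(e, "MaSC/basal")
  pl <- g$truth$planted_de
  planted <- intersect(pl$probe[pl$subset == "MaSC/basal"], de$probe)
  hit <- de$signature[match(planted, de$probe)] &
    de$logFC[match(planted, de$probe)] > 0
  expect_gte(mean(hit), 0.95)
  ## a probe equal across subsets has logFC exactly 0
  E <- matrix(7, 3, 12, dimnames = list(c("flat", "g2", "g3"),
                                        paste0("s", 1:12)))
  E[2, ] <- rnorm(12)
  E[3, ] <- rnorm(12)
  expr <- expression_matrix(E, samples = data.frame(
    sample = paste0("s", 1:12), species = "m",
    subset = rep(c("MaSC/basal", "LP", "ML"), each = 4),
    replicate = rep(1:4, 3)), normalized = TRUE)
  de2 <- signature_de(expr, "MaSC/basal")
  expect_equal(de2$logFC[de2$probe == "flat"], 0)
  expect_error(signature_de(expr, "nope"), "not present")
})

test_that("anova_de: flat probes give F = 0 and null p are uniform", {
  set.seed(47)
  samples <- data.frame(sample = paste0("s", 1:12), species = "m",
                        subset = rep(c("MaSC/basal", "LP", "ML"),
                                     each = 4),
                        replicate = rep(1:4, 3))
  E <- matrix(rnorm(500 * 12), 500, 12,
              dimnames = list(sprintf("g%03d", 1:500), samples$sample))
  E[1, ] <- 5
  expr <- expression_matrix(E, samples = samples, normalized = TRUE)
  av <- anova_de(expr)
  expect_equal(av$stat[av$probe == "g001"], 0)
  ks <- stats::ks.test(av$p[av$probe != "g001"], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("contrast negation flips logFC sign (antisymmetry)", {
  expr <- make_epi_expr(seed = 48)
  de <- basal_vs_luminal_de(expr)
  neg <- expr
  neg$E <- -neg$E
  de_neg <- basal_vs_luminal_de(neg)
  m <- match(de$probe, de_neg$probe)
  expect_equal(de$logFC, -de_neg$logFC[m], tolerance = 1e-12)
  expect_equal(de$p, de_neg$p[m], tolerance = 1e-12)
  expect_true(all(c("n_up", "n_down") %in% names(attributes(de))))
})

test_that("combined species analysis absorbs offsets and cancels
          discordant effects", {
  expr <- make_epi_expr(n_probes = 60, seed = 49)
  rownames(expr$E) <- sprintf("mmu-miR-%02d", seq_len(60))
  expr$probes$probe <- rownames(expr$E)
  ## planted effects: one concordant, one discordant probe
  basal <- expr$samples$subset == "MaSC/basal"
  expr$E[1, basal] <- expr$E[1, basal] + 3
  hum <- expr
  hum$E <- hum$E + 2                      # constant species offset
  rownames(hum$E) <- sub("mmu", "hsa", rownames(expr$E))
  hum$probes$probe <- rownames(hum$E)
  hum$samples$species <- "human"
  hum$samples$sample <- paste0("h", hum$samples$sample)
  colnames(hum$E) <- hum$samples$sample
  hum$E[1, basal] <- hum$E[1, basal] + 0          # concordant (+3 both)
  hum$E[2, basal] <- hum$E[2, basal] + 3          # mouse 0, human +3
  expr$E[2, basal] <- expr$E[2, basal] - 3        # discordant
  cm <- combined_species_de(expr, hum)
  i1 <- match(normalize_mirna_symbol("mmu-miR-01"), cm$probe)
  i2 <- match(normalize_mirna_symbol("mmu-miR-02"), cm$probe)
  expect_gt(cm$logFC[i1], 2)
  expect_true(cm$signature[i1])
  expect_lt(abs(cm$logFC[i2]), 1)        # equal and opposite cancels
  ## identical matrices modulo offset reduce to the single-species fit
  hum2 <- expr
  hum2$E <- hum2$E + 2
  rownames(hum2$E) <- sub("mmu", "hsa", rownames(expr$E))
  hum2$probes$probe <- rownames(hum2$E)
  hum2$samples$species <- "human"
  hum2$samples$sample <- paste0("h", hum2$samples$sample)
  colnames(hum2$E) <- hum2$samples$sample
  cm2 <- combined_species_de(expr, hum2)
  bl <- basal_vs_luminal_de(expr)
  m <- match(normalize_mirna_symbol(bl$probe), cm2$probe)
  expect_equal(cm2$logFC[m], bl$logFC, tolerance = 1e-10)
  expect_error(combined_species_de(expr, make_epi_expr(seed = 1)),
               "no probes matched")
})

test_that("remove_species_batch subtracts the fitted species effect", {
  expr <- make_epi_expr(n_probes = 40, seed = 50)
  sp2 <- expr
  sp2$samples$species <- "human"
  sp2$samples$sample <- paste0("h", sp2$samples$sample)
  colnames(sp2$E) <- sp2$samples$sample
  sp2$E <- sp2$E + 1.7
  stk <- expression_matrix(cbind(expr$E, sp2$E),
                           samples = rbind(expr$samples, sp2$samples),
                           normalized = TRUE)
  rb <- remove_species_batch(stk)
  n <- ncol(expr$E)
  expect_equal(rb$E[, 1:n], rb$E[, n + (1:n)], tolerance = 1e-10,
               ignore_attr = TRUE)
  ## zero covariate effect: identity
  stk0 <- expression_matrix(cbind(expr$E, {
    x <- expr$E
    colnames(x) <- paste0("h", colnames(x))
    x
  }), samples = rbind(expr$samples, sp2$samples), normalized = TRUE)
  rb0 <- remove_species_batch(stk0)
  expect_equal(rb0$E[, 1:n], expr$E, tolerance = 1e-10,
               ignore_attr = TRUE)
  ## random case equals the explicit two-step regression oracle
  set.seed(51)
  stk$E <- stk$E + rnorm(length(stk$E))
  rb2 <- remove_species_batch(stk)
  X <- stats::model.matrix(~ 0 + subset + I(species == "human"),
                           data = stk$samples)
  beta <- t(solve(crossprod(X), t(X) %*% t(stk$E)))
  oracle <- stk$E - beta[, ncol(X), drop = FALSE] %*%
    t(X[, ncol(X), drop = FALSE])
  expect_equal(rb2$E, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  ## confounded batch errors
  conf <- stk
  conf$samples$species <- ifelse(conf$samples$subset == "LP",
                                 "human", "mouse")
  expect_error(remove_species_batch(conf), "confounded")
})

test_that("mds distances follow the leading log fold change rule", {
  set.seed(52)
  E <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:5)))
  E[, 2] <- E[, 1]                    # duplicate sample
  E[, 3] <- E[, 1] + 2                # constant separation of 2
  pts <- mds_coordinates(E, top_k = 50)
  D <- attr(pts, "dist")
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 2)
  expect_equal(D, t(D))
  ## brute-force distance oracle
  for (i in 1:4) for (j in (i + 1):5) {
    d2 <- sort((E[, i] - E[, j])^2, decreasing = TRUE)[1:50]
    expect_equal(D[i, j], sqrt(mean(d2)))
  }
  expect_error(mds_coordinates(E[, 1:2]), "three samples")
})

test_that("hierarchical clustering matches a brute-force agglomeration", {
  set.seed(53)
  E <- matrix(rnorm(100 * 6), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  E[, 2] <- E[, 1]
  hc <- hierarchical_cluster(E)
  expect_equal(hc$height[1], 0)       # identical samples merge first
  first <- sort(hc$merge[1, ])
  expect_setequal(hc$labels[-first], c("s1", "s2"))
  D <- as.matrix(stats::dist(t(E)))
  expect_equal(sort(hc$height), average_linkage_heights(D),
               tolerance = 1e-10)
})
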