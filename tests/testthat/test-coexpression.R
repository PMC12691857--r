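test_that("count filtering applies the >min_count in >=fraction rule", {
  counts <- rbind(
    boundary = c(rep(11, 9), 0),   # >10 in 9/10 samples: kept
    allzero = rep(0, 10),          # removed
    low = rep(10, 10))             # 10 is not > 10: removed
  kept <- filter_features(counts)
  expect_equal(rownames(kept), "boundary")

  # Brute-force re-check per definition on a random matrix.
  set.seed(1)
  m <- matrix(rpois(20 * 8, 15), nrow = 20,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:8)))
  kept <- filter_features(m, min_count = 14, min_fraction = 0.6)
  keep_brute <- logical(20)
  for (i in 1:20) {
    n_ok <- 0L
    for (j in 1:8) if (m[i, j] > 14) n_ok <- n_ok + 1L
    keep_brute[i] <- n_ok >= ceiling(0.6 * 8)
  }
  expect_gt(nrow(kept), 0L)
  expect_equal(rownames(kept), rownames(m)[keep_brute])

  expect_warning(filter_features(matrix(0, 2, 4), min_count = 10),
                 "no feature")
})

test_that("median-of-ratios size factors behave like DESeq normalization", {
  # Doubling a sample doubles its size factor; normalized values align.
  set.seed(2)
  a <- matrix(rpois(40, 50), ncol = 2)
  counts <- cbind(a, a[, 1] * 2)
  norm <- size_factor_normalize(counts, log2 = FALSE)
  sf <- attr(norm, "size_factors")
  expect_equal(sf[3] / sf[1], 2, tolerance = 1e-12)
  expect_equal(norm[, 1], norm[, 3], ignore_attr = TRUE)

  # Single-feature matrix [10, 20]: factors proportional to 1:2.
  sf <- attr(size_factor_normalize(matrix(c(10, 20), nrow = 1)),
             "size_factors")
  expect_equal(sf[2] / sf[1], 2)

  # Identical samples: all size factors 1.
  counts <- matrix(rep(c(5, 9, 30), 3), ncol = 3)
  expect_equal(attr(size_factor_normalize(counts), "size_factors"),
               rep(1, 3))

  # Independent oracle: DESeq2's median-of-ratios, on a zero-free matrix
  # with an odd feature count (DESeq2 drops per-sample zeros and takes the
  # median on the log scale, which only matters for zeros and for the
  # even-count midpoint interpolation).
  skip_if_not_installed("DESeq2")
  set.seed(3)
  m <- matrix(rnbinom(306, mu = 100, size = 10), ncol = 6) + 1
  sf <- attr(size_factor_normalize(m), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)

  # No all-nonzero feature: library-size fallback with warning.
  m0 <- rbind(c(0, 5), c(7, 0))
  expect_warning(size_factor_normalize(m0), "library-size")
})

test_that("soft adjacency and TOM match brute-force oracles", {
  # Perfectly correlated pair gives adjacency 1 at any power.
  x <- rbind(1:6, 2 * (1:6) + 3)
  expect_equal(soft_adjacency(x, power = 7)[1, 2], 1)

  # r = 0.5 at power 12.
  set.seed(4)
  for (trial in 1:3) {
    n_feat <- sample(10:30, 1)
    expr <- matrix(rnorm(n_feat * 6), nrow = n_feat)
    a <- soft_adjacency(expr, 12)
    expect_lt(max(abs(a - brute_soft_adjacency(expr, 12))), 1e-12)
    expect_true(all(a >= 0 & a <= 1))

    adj <- brute_soft_adjacency(expr, 6)
    tom <- topological_overlap(adj)
    expect_lt(max(abs(tom - brute_tom(adj))), 1e-12)
  }

  # Identity adjacency: no edges, TOM off-diagonal 0.
  tom0 <- topological_overlap(diag(4))
  expect_equal(tom0, diag(4))

  # Two nodes with a_12 = 0.8: closed form TOM_12 = 0.8.
  a2 <- matrix(c(1, 0.8, 0.8, 1), 2)
  expect_equal(topological_overlap(a2)[1, 2], 0.8)

  # Validation.
  expect_error(topological_overlap(matrix(c(1, 0.2, 0.8, 1), 2)),
               "symmetric")
  expect_warning(soft_adjacency(rbind(c(1, 1, 1), c(1, 2, 3)), 12),
                 "zero-variance")
})

test_that("module detection recovers planted blocks and merges close ones", {
  # Two planted blocks, within-block r ~ 0.9, between ~ 0.
  set.seed(5)
  n_s <- 24
  f1 <- rnorm(n_s); f2 <- rnorm(n_s)
  expr <- rbind(
    t(replicate(40, f1 + rnorm(n_s, 0, 0.45))),
    t(replicate(40, f2 + rnorm(n_s, 0, 0.45))))
  rownames(expr) <- paste0("f", 1:80)
  tom <- topological_overlap(soft_adjacency(expr, 12))
  lab <- detect_modules(1 - tom, expr)
  truth <- rep(c("A", "B"), each = 40)
  expect_gt(mclust::adjustedRandIndex(lab, truth), 0.9)
  expect_length(setdiff(unique(lab), "grey"), 2L)

  # Pure noise with min_module_size > n: all grey with warning.
  noise <- matrix(rnorm(20 * 10), nrow = 20,
                  dimnames = list(paste0("f", 1:20), NULL))
  tomn <- topological_overlap(soft_adjacency(noise, 12))
  expect_warning(labn <- detect_modules(1 - tomn, noise,
                                        min_module_size = 21),
                 "grey")
  expect_true(all(labn == "grey"))

  # Two planted modules driven by near-identical factors (eigengene
  # dissimilarity < 0.25) merge into one.
  f <- rnorm(n_s)
  f_close <- 0.97 * f + sqrt(1 - 0.97^2) * rnorm(n_s)
  expr2 <- rbind(
    t(replicate(35, f + rnorm(n_s, 0, 0.2))),
    t(replicate(35, f_close + rnorm(n_s, 0, 0.2))))
  rownames(expr2) <- paste0("g", 1:70)
  tom2 <- topological_overlap(soft_adjacency(expr2, 12))
  lab2 <- detect_modules(1 - tom2, expr2, min_module_size = 30)
  expect_length(setdiff(unique(lab2), "grey"), 1L)
})

test_that("module eigengenes are unit-norm PC1 with a stable sign", {
  set.seed(6)
  n_s <- 30
  # Identical features: eigengene carries their common z profile.
  prof <- rnorm(n_s)
  expr <- matrix(rep(prof, each = 5), nrow = 5,
                 dimnames = list(paste0("f", 1:5),
                                 sprintf("s%02d", 1:n_s)))
  assignment <- setNames(rep("m1", 5), rownames(expr))
  me <- module_eigengenes(expr, assignment)
  expect_equal(abs(cor(me["m1", ], prof)), 1)
  expect_equal(sum(me["m1", ]^2), 1)

  # Latent factor + noise: eigengene tracks the factor.
  fac <- rnorm(n_s)
  expr2 <- t(replicate(50, fac + rnorm(n_s, 0, 0.3)))
  rownames(expr2) <- paste0("g", 1:50)
  colnames(expr2) <- sprintf("s%02d", 1:n_s)
  me2 <- module_eigengenes(expr2, setNames(rep("m1", 50), rownames(expr2)))
  expect_gt(abs(cor(me2["m1", ], fac)), 0.95)

  # Negating the data negates the eigengene.
  me2n <- module_eigengenes(-expr2, setNames(rep("m1", 50),
                                             rownames(expr2)))
  expect_equal(me2n["m1", ], -me2["m1", ], tolerance = 1e-8)

  # Single-feature module: its own z profile.
  expr3 <- rbind(expr2, single = rnorm(n_s))
  lab3 <- setNames(c(rep("m1", 50), "m2"), rownames(expr3))
  me3 <- module_eigengenes(expr3, lab3)
  z <- (expr3["single", ] - mean(expr3["single", ])) /
    sd(expr3["single", ])
  expect_equal(abs(cor(me3["m2", ], z)), 1)
})

test_that("module-trait statistics use the t-test and Bonferroni cap", {
  set.seed(7)
  n_s <- 30
  me <- matrix(rnorm(2 * n_s), nrow = 2,
               dimnames = list(c("m1", "m2"), sprintf("s%02d", 1:n_s)))

  # Trait equal to an eigengene: r = 1, p ~ 0.
  traits <- cbind(t1 = me["m1", ], t2 = rnorm(n_s))
  rownames(traits) <- colnames(me)
  res <- module_trait_correlation(me, traits)
  row <- res[res$module == "m1" & res$trait == "t1", ]
  expect_equal(row$r, 1)
  expect_lt(row$p_value, 1e-12)

  # r = 0.7, n = 30: t = 5.188, p from an independent t evaluation,
  # Bonferroni over 7 traits.
  r <- 0.7; n <- 30
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(t_stat, 5.18671, tolerance = 1e-5)
  expect_equal(2 * (1 - pt(t_stat, n - 2)), 1.664791e-5, tolerance = 1e-5)
  tr7 <- matrix(rnorm(n * 7), nrow = n,
                dimnames = list(colnames(me), paste0("t", 1:7)))
  res7 <- module_trait_correlation(me, tr7)
  expect_equal(res7$p_adjusted, pmin(1, res7$p_value * 7))
  expect_true(all(res7$p_adjusted >= res7$p_value, na.rm = TRUE))
  # cross-check one p-value against cor.test
  ct <- cor.test(me["m1", ], tr7[, 1])
  expect_equal(res7$p_value[res7$module == "m1" & res7$trait == "t1"],
               ct$p.value, tolerance = 1e-10)

  # Constant trait: statistics missing, row still emitted.
  trc <- cbind(const = rep(1, n))
  rownames(trc) <- colnames(me)
  resc <- module_trait_correlation(me, trc)
  expect_equal(nrow(resc), 2L)
  expect_true(all(is.na(resc$r)))

  # Missing values: pairwise-complete n reported.
  trm <- cbind(t1 = c(rep(NA, 5), rnorm(n - 5)))
  rownames(trm) <- colnames(me)
  resm <- module_trait_correlation(me, trm)
  expect_equal(resm$n_samples, rep(n - 5L, 2L))
})

test_that("classification follows the sign pattern of significant traits", {
  mk <- function(module, trait, r, p_adj) {
    data.frame(module = module, trait = trait, r = r, p_value = p_adj / 6,
               p_adjusted = p_adj, n_samples = 24L)
  }
  traits6 <- c("ta_mass", "max_force", "hanging_time",
               "central_nuclei", "abnormal_mitochondria", "small_fibers")
  base <- do.call(rbind, lapply(traits6, function(tr)
    mk("m1", tr, 0.1, 1)))

  # Significant positive TA-mass correlation only: beneficial.
  res <- base
  res[res$trait == "ta_mass", c("r", "p_adjusted")] <- c(0.6, 0.01)
  expect_equal(unname(classify_modules(res)["m1"]), "beneficial")

  # Significant positive central-nuclei correlation only: pathogenic.
  res <- base
  res[res$trait == "central_nuclei", c("r", "p_adjusted")] <- c(0.6, 0.01)
  expect_equal(unname(classify_modules(res)["m1"]), "pathogenic")

  # No significant correlation: unclassified.
  expect_equal(unname(classify_modules(base)["m1"]), "unclassified")

  # Conflicting significant patterns: unclassified.
  res <- base
  res[res$trait == "ta_mass", c("r", "p_adjusted")] <- c(0.6, 0.01)
  res[res$trait == "small_fibers", c("r", "p_adjusted")] <- c(0.6, 0.01)
  expect_equal(unname(classify_modules(res)["m1"]), "unclassified")

  # Invariant to row order.
  res_shuffled <- res[sample(nrow(res)), ]
  expect_equal(classify_modules(res_shuffled), classify_modules(res))

  # Missing classification trait: warning, not error.
  expect_warning(classify_modules(base[base$trait != "ta_mass", ]),
                 "skipped")
})

test_that("thresholded co-expression layers export the right edge set", {
  set.seed(8)
  expr <- matrix(rnorm(10 * 8), nrow = 10,
                 dimnames = list(paste0("f", 1:10), NULL))
  tom <- topological_overlap(soft_adjacency(expr, 6))

  lay <- export_coexpression_layer(tom, 0.15)
  # Brute-force pair scan.
  want <- 0L
  for (i in 1:9) for (j in (i + 1):10) if (tom[i, j] > 0.15) want <- want + 1L
  expect_equal(nrow(lay$edges), want)
  expect_true(all(lay$edges$weight > 0.15))

  # Threshold ~1: empty. Threshold 0: all pairs with nonzero TOM.
  expect_equal(nrow(export_coexpression_layer(tom, 1 - 1e-9)$edges), 0L)
  expect_equal(nrow(export_coexpression_layer(tom, 0)$edges),
               sum(tom[upper.tri(tom)] > 0))

  expect_error(export_coexpression_layer(tom, 1.2), "threshold")

  # Reference presets.
  p <- coexpression_presets()
  expect_equal(p$transcriptomic, list(power = 10, threshold = 0.15))
  expect_equal(p$proteomic, list(power = 12, threshold = 0.25))
  expect_equal(p$metabolomic, list(power = 5, threshold = 0.05))
})
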