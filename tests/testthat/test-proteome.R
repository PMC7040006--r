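test_that("per-feature ANOVA reproduces the hand-computed table", {
  # groups {1,2,3}, {2,3,4}, {6,7,8}: SSB = 42 (df 2), SSW = 6 (df 6)
  vals <- matrix(c(1, 2, 3, 2, 3, 4, 6, 7, 8), 1, 9,
                 dimnames = list("f1", paste0("s", 1:9)))
  m <- omics_matrix(vals, make_meta(paste0("s", 1:9), paste0("L", rep(1:3, 3)),
                                    rep(c("native", "d3", "d7"), each = 3),
                                    "protein_abundance"))
  an <- anova_by_feature(m, log_transform = FALSE)
  expect_equal(an$F, 21)
  expect_equal(an$p, pf(21, 2, 6, lower.tail = FALSE))
  expect_equal(an$p, 0.00195, tolerance = 1e-2)
  expect_equal(an$log2fc_d7, 5)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(31)
  for (i in 1:10) {
    x <- matrix(rnorm(8), 1, 8, dimnames = list("f", paste0("s", 1:8)))
    m <- omics_matrix(2^x, make_meta(paste0("s", 1:8), "L1",
                                     rep(c("native", "d3"), each = 4),
                                     "protein_abundance"))
    an <- anova_by_feature(m)
    tt <- t.test(x[1, 5:8], x[1, 1:4], var.equal = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(an$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("equal group means give F near zero; constant features are flagged", {
  vals <- 2^matrix(c(1, 2, 3, 2, 1, 3, 3, 1, 2,
                     rep(5, 9)), 2, 9, byrow = TRUE,
                   dimnames = list(c("f1", "f2"), paste0("s", 1:9)))
  m <- omics_matrix(vals, make_meta(paste0("s", 1:9), paste0("L", rep(1:3, 3)),
                                    rep(c("native", "d3", "d7"), each = 3),
                                    "protein_abundance"))
  an <- anova_by_feature(m)
  expect_equal(an$F[1], 0)
  expect_gt(an$p[1], 0.99)
  expect_true(is.na(an$p[2]))
  expect_true(an$degenerate[2])
})

test_that("Tukey-Kramer matches TukeyHSD and the two-group t-test relation", {
  set.seed(41)
  x <- rnorm(12, sd = 0.8)
  vals <- matrix(2^x, 1, 12, dimnames = list("f", paste0("s", 1:12)))
  tp <- rep(c("native", "d3", "d7"), each = 4)
  m <- omics_matrix(vals, make_meta(paste0("s", 1:12), "L1", tp,
                                    "protein_abundance"))
  tk <- tukey_posthoc(m, "f")
  hsd <- TukeyHSD(aov(x ~ factor(tp)))[[1]]
  for (i in seq_len(nrow(tk))) {
    key <- grep(tk$a[i], rownames(hsd))
    key <- intersect(key, grep(tk$b[i], rownames(hsd)))
    expect_equal(tk$p[i], hsd[key, "p adj"], tolerance = 1e-6)
  }
  # two groups: studentized range q = sqrt(2) |t|, p equals the pooled t-test
  y <- rnorm(8)
  m2 <- omics_matrix(matrix(2^y, 1, 8, dimnames = list("f", paste0("s", 1:8))),
                     make_meta(paste0("s", 1:8), "L1",
                               rep(c("native", "d3"), each = 4),
                               "protein_abundance"))
  tk2 <- tukey_posthoc(m2, "f")
  expect_equal(tk2$p, t.test(y[1:4], y[5:8], var.equal = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("a strongly shifted group is isolated by the post-hoc test", {
  set.seed(17)
  base <- rnorm(4, 0, 1)
  x <- c(base, base, rnorm(4, 5, 1))   # first two groups identical, third far
  m <- omics_matrix(matrix(2^x, 1, 12, dimnames = list("f", paste0("s", 1:12))),
                    make_meta(paste0("s", 1:12), "L1",
                              rep(c("native", "d3", "d7"), each = 4),
                              "protein_abundance"))
  tk <- tukey_posthoc(m, "f")
  p_far <- tk$p[tk$a == "native" & tk$b == "d7"]
  p_near <- tk$p[tk$a == "native" & tk$b == "d3"]
  expect_lt(p_far, 0.01)
  expect_gt(p_near, 0.5)
  # identical groups: p ~ 1
  m2 <- omics_matrix(matrix(2^c(base, base), 1, 16,
                            dimnames = list("f", paste0("s", 1:16))),
                     make_meta(paste0("s", 1:16), "L1",
                               rep(c("native", "d3"), each = 8),
                               "protein_abundance"))
  expect_gt(tukey_posthoc(m2, "f")$p, 0.999)
})

test_that("planted two-fold protein shifts pass the full gate in >=90% of runs", {
  hits <- 0L; total <- 0L
  for (s in 1:25) {
    set.seed(700 + s)
    n <- 120
    base <- rnorm(n, 20, 2)
    eff <- c(rep(1, 12), rep(0, n - 12))   # 2-fold at d3 and d7
    mk <- function(shift) vapply(1:6, function(i)
      2^(base + shift + rnorm(n, 0, 0.3)), numeric(n))
    vals <- cbind(mk(0), mk(eff), mk(eff))
    dimnames(vals) <- list(paste0("P", 1:n), paste0("s", 1:18))
    m <- omics_matrix(vals, make_meta(paste0("s", 1:18), paste0("L", rep(1:6, 3)),
                                      rep(c("native", "d3", "d7"), each = 6),
                                      "protein_abundance"))
    pd <- protein_differential(m)
    hits <- hits + sum(pd$diff$d3$significant[1:12] &
                         pd$diff$d3$direction[1:12] == "up")
    total <- total + 12L
  }
  expect_gte(hits / total, 0.9)
})

test_that("replicate correlation behaves on duplicated and negated samples", {
  set.seed(2)
  x <- matrix(rnorm(40, 10, 2), 10, 4,
              dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
  x[, 2] <- x[, 1]
  x[, 4] <- -x[, 3]
  m <- omics_matrix(abs(x), make_meta(paste0("s", 1:4), "L1",
                                      rep(c("native", "d3"), 2),
                                      "protein_abundance"))
  m$values <- x   # bypass positivity for the negation check, log off
  r <- replicate_correlation(m, log_transform = FALSE)
  expect_equal(r["s1", "s2"], 1)
  expect_equal(r["s3", "s4"], -1)
  expect_equal(unname(diag(r)), rep(1, 4))
  # constant sample: undefined correlation reported missing
  m$values[, 3] <- 5
  r2 <- replicate_correlation(m, log_transform = FALSE)
  expect_true(is.na(r2["s1", "s3"]))
})

test_that("PCA scores are reproducible, sign-fixed, and energy-preserving", {
  set.seed(13)
  vals <- 2^matrix(rnorm(60, 10, 2), 10, 6,
                   dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
  vals[, 2] <- vals[, 1]
  m <- omics_matrix(vals, make_meta(paste0("s", 1:6), "L1",
                                    rep(c("native", "d3", "d7"), 2),
                                    "protein_abundance"))
  pc <- pca_scores(m, 2)
  expect_equal(pc$scores["s1", ], pc$scores["s2", ])
  expect_true(all(pc$loadings[1, ] >= 0))
  expect_equal(sum(pc$scores^2), sum(pc$eigenvalues[1:2]))
  expect_error(pca_scores(m, 7), "fewer samples")
})

test_that("PC1 separates transfected from control samples at the planted effect", {
  cfg <- small_synth(seed = 5)
  st <- simulate_counts(cfg, "mrna")
  prot <- simulate_proteome(cfg, st)
  ts <- assign_true_targets(cfg, "hsa-miR-x-5p", st$truth$features)
  tx <- simulate_transfection(cfg, prot, ts, "hsa-miR-x-5p", "mimic")
  pc <- pca_scores(tx$matrix, 2)
  grp <- tx$matrix$samples$condition == "control_sirna"
  a <- pc$scores[grp, 1]; b <- pc$scores[!grp, 1]
  expect_true(max(a) < min(b) || max(b) < min(a))   # zero overlap on PC1
})

test_that("volcano tables transform p and mirror the significance flag", {
  d <- data.frame(feature_id = c("a", "b"), contrast = "d3_vs_native",
                  log2fc = c(2, 0.1), p = c(0.01, 0.5), q = c(0.02, 0.6),
                  significant = c(TRUE, FALSE))
  v <- volcano_table(d)
  expect_equal(v$neg_log10_p, c(2, -log10(0.5)))
  expect_identical(v$significant, d$significant)
})

test_that("direction flips between contrasts are counted, not assumed away", {
  mk <- function(fc, sig) data.frame(feature_id = paste0("P", seq_along(fc)),
                                     significant = sig,
                                     direction = direction_of(fc, sig))
  a <- mk(c(1, -1, 2), c(TRUE, TRUE, TRUE))
  b <- mk(c(-1, -2, 3), c(TRUE, TRUE, FALSE))
  expect_equal(direction_flip_count(a, b), 1)
  expect_equal(direction_flip_count(a, a), 0)
})
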