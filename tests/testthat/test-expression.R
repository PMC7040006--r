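test_that("CPM is counts scaled by library size times 1e6", {
  vals <- matrix(c(50L, 999950L, 50L, 499950L), 2, 2,
                 dimnames = list(c("f1", "f2"), c("a", "b")))
  m <- omics_matrix(vals, make_meta(c("a", "b"), "L1", c("native", "d3"),
                                    "mirna_counts"))
  cpm <- compute_cpm(m)
  expect_equal(cpm$values["f1", "a"], 50)
  expect_equal(cpm$values["f1", "b"], 100)
  expect_equal(unname(colSums(cpm$values)), c(1e6, 1e6))
  # hand-computed 3x2 grid
  v <- matrix(c(10L, 20L, 70L, 5L, 5L, 40L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  m2 <- omics_matrix(v, make_meta(c("a", "b"), "L1", c("native", "d3"),
                                  "mrna_counts"))
  expect_equal(compute_cpm(m2)$values,
               matrix(c(1e5, 2e5, 7e5, 1e5, 1e5, 8e5), 3, 2,
                      dimnames = dimnames(v)))
  # zero library size
  v0 <- matrix(c(1L, 0L, 2L, 0L), 2, 2, dimnames = list(c("f1", "f2"), c("a", "b")))
  m0 <- omics_matrix(v0, make_meta(c("a", "b"), "L1", c("native", "d3"),
                                   "mirna_counts"))
  m0$values[, "b"] <- 0
  expect_error(compute_cpm(m0), "zero library")
})

test_that("low-expression filter keeps features above the floor at any timepoint", {
  # 10 features x 4 timepoints of mean CPM; 4 fall below the floor everywhere
  means <- rbind(c(0, 0, 0, 0),        # dropped
                 c(0.5, 0.9, 1.0, 0.8),# dropped (1.0 is not > 1)
                 c(0.2, 0.1, 0.3, 0.9),# dropped
                 c(1.01, 0, 0, 0),     # kept (native)
                 c(0, 0, 0, 1.2),      # kept (only at d14)
                 c(0.4, 0.2, 0.2, 0.4),# dropped
                 c(5, 8, 2, 1),        # kept
                 c(1.2, 1.2, 1.2, 1.2),# kept
                 c(0, 2, 0, 0),        # kept
                 c(100, 0, 0, 0))      # kept
  rownames(means) <- paste0("f", 1:10)
  # single line per timepoint; library size forced to 1e8 so that
  # CPM = count / 100, i.e. count = mean CPM * 100 (integral)
  cnt <- round(means * 100)
  storage.mode(cnt) <- "integer"
  vals <- rbind(cnt, filler = as.integer(1e8 - colSums(cnt)))
  ids <- paste0("s", 1:4)
  colnames(vals) <- ids
  m <- omics_matrix(vals, make_meta(ids, "L1", c("native", "d3", "d7", "d14"),
                                    "mirna_counts"))
  cpm <- compute_cpm(m)
  kept <- filter_low_expression(cpm, 1)
  expect_setequal(setdiff(kept, "filler"),
                  c("f4", "f5", "f7", "f8", "f9", "f10"))
})

test_that("protein-coding filter intersects order-preservingly", {
  feats <- paste0("g", 1:8)
  coding <- c("g7", "g2", "g5", "g1", "g3")
  expect_equal(filter_protein_coding(feats, coding), c("g1", "g2", "g3", "g5", "g7"))
  expect_equal(filter_protein_coding(feats, feats), feats)
  expect_equal(filter_protein_coding(feats, "zz"), character(0))
  expect_warning(out <- filter_protein_coding(feats, character(0)), "empty")
  expect_equal(out, character(0))
})

test_that("fold changes versus native follow the ratio-of-means convention", {
  # printed-mean examples: 4066 -> 566 gives -2.8; 522 -> 8076 gives 4.0
  vals <- matrix(as.integer(rbind(c(4066, 566), c(522, 8076), c(10, 10),
                                  c(5, 0), c(0, 7))), 5, 2,
                 dimnames = list(paste0("f", 1:5), c("a", "b")))
  m <- omics_matrix(vals, make_meta(c("a", "b"), "L1", c("native", "d3"),
                                    "mirna_counts"))
  cpm <- m
  class(cpm) <- c("cpm_matrix", class(m))   # treat raw values as CPM
  fc <- log2fc_vs_native(cpm, "d3", pseudocount = 0)
  expect_equal(round_half_away(fc[["f1"]]), -2.8)
  expect_equal(round_half_away(fc[["f2"]]), 4.0)
  expect_equal(fc[["f3"]], 0)
  expect_true(is.na(fc[["f4"]]))   # zero numerator, pseudocount 0: undefined
  expect_true(is.na(fc[["f5"]]))   # zero denominator: never silent +/-Inf
  expect_error(log2fc_vs_native(cpm, "native"), "native")
})

test_that("swapping reference and alternative negates the fold change exactly", {
  set.seed(11)
  vals <- matrix(rpois(40, 200), 10, 4)
  dimnames(vals) <- list(paste0("f", 1:10), paste0("s", 1:4))
  m <- omics_matrix(vals, make_meta(paste0("s", 1:4), "L1",
                                    c("native", "native", "d3", "d3"),
                                    "mrna_counts"))
  sw <- m
  sw$samples$timepoint <- c("d3", "d3", "native", "native")
  for (pc in c(0, 0.5)) {
    f1 <- log2fc_vs_native(compute_cpm(m), "d3", pc)
    f2 <- log2fc_vs_native(compute_cpm(sw), "d3", pc)
    expect_equal(f1, -f2, tolerance = 1e-12)
  }
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "missing")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bf_bh(p))
    expect_equal(q, p.adjust(p, "BH"))   # independent reference
    expect_false(is.unsorted(q[order(p)]))   # isotonic in p-order
  }
})

test_that("identical groups give zero fold change and p of one", {
  set.seed(5)
  base <- matrix(rpois(30, 300), 10, 3)
  vals <- cbind(base, base)
  dimnames(vals) <- list(paste0("f", 1:10), paste0("s", 1:6))
  m <- omics_matrix(vals, make_meta(paste0("s", 1:6), paste0("L", rep(1:3, 2)),
                                    rep(c("native", "d3"), each = 3),
                                    "mrna_counts"))
  d <- test_differential(m, "d3")
  expect_true(all(abs(d$log2fc) < 1e-12))
  expect_true(all(d$p > 1 - 1e-9))
  expect_false(any(d$significant))
  expect_true(all(d$direction == "none"))
  # fewer than 2 replicates is an error naming the group
  m2 <- subset_omics(m, sample_idx = c(1, 2, 3, 4))
  expect_error(test_differential(m2, "d3"), "'d3'")
})

test_that("planted strong effects are recovered with the right direction", {
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    set.seed(900 + s)
    n <- 60
    base <- 2^rnorm(n, 9, 1)
    # balanced up/down planting keeps library composition stable
    eff <- c(rep(2, 5), rep(-2, 5), rep(0, n - 10))
    mk <- function(shift) {
      v <- vapply(1:3, function(i) round(base * 2^(shift + rnorm(n, 0, 0.2))),
                  numeric(n))
      v
    }
    vals <- cbind(mk(0), mk(eff))
    storage.mode(vals) <- "integer"
    dimnames(vals) <- list(paste0("f", 1:n), paste0("s", 1:6))
    m <- omics_matrix(vals, make_meta(paste0("s", 1:6), paste0("L", rep(1:3, 2)),
                                      rep(c("native", "d3"), each = 3),
                                      "mrna_counts"))
    d <- test_differential(m, "d3")
    hits <- hits + sum(d$significant[1:5] & d$direction[1:5] == "up") +
      sum(d$significant[6:10] & d$direction[6:10] == "down")
    total <- total + 10L
  }
  expect_gte(hits / total, 0.9)
})

test_that("relaxing thresholds never shrinks the significant set", {
  set.seed(21)
  st <- simulate_counts(small_synth(seed = 77, n_mrna = 500), "mrna")
  strict <- test_differential(st$matrix, "d3", pipeline_config())
  for (cfg in list(pipeline_config(fc_cut = 1.2), pipeline_config(q_cut = 0.2),
                   pipeline_config(p_cut = 0.05, q_cut = 0.2, fc_cut = 1.1))) {
    loose <- test_differential(st$matrix, "d3", cfg)
    expect_true(all(loose$significant[strict$significant]))
  }
})

test_that("consistent-direction selection requires all three timepoints to agree", {
  mk <- function(fc, sig) data.frame(feature_id = paste0("m", seq_along(fc)),
                                     log2fc = fc, significant = sig,
                                     direction = direction_of(fc, sig))
  d3 <- mk(c(-2, 1, -1), c(TRUE, TRUE, TRUE))
  d7 <- mk(c(-1, 2, -1), c(TRUE, TRUE, FALSE))
  d14 <- mk(c(2, 1, -2), c(TRUE, TRUE, TRUE))
  sel <- select_consistent_mirnas(d3, d7, d14)
  # m1 flips direction at d14, m3 misses significance at d7
  expect_equal(sel$feature_id, "m2")
  expect_equal(sel$direction, "up")
  expect_error(select_consistent_mirnas(d3, NULL, d14), "d7")
})
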