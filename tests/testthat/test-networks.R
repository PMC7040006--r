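test_that("miRNA names are canonicalised case-insensitively with the hsa- prefix", {
  expect_equal(normalize_mirna("MIR-221-5P"), "hsa-miR-221-5p")
  expect_equal(normalize_mirna("hsa-miR-221-5p"), "hsa-miR-221-5p")
  expect_equal(normalize_mirna("HSA-let-7i-5p"), "hsa-let-7i-5p")
  expect_equal(normalize_mirna("miR-24-2-5p"), "hsa-miR-24-2-5p")
})

test_that("prediction tables validate algorithms and collapse duplicate triples", {
  df <- data.frame(mirna = "miR-1-5p", gene_id = c("G1", "G1", "G2"),
                   algorithm = c("PITA", "PITA", "miRDB"))
  pt <- prediction_table(df)
  expect_equal(nrow(pt), 2)   # isoform duplicates collapse
  expect_error(prediction_table(data.frame(mirna = "m", gene_id = "g",
                                           algorithm = "MadeUp")),
               "MadeUp")
})

test_that("support filtering respects the boundary and matches brute force", {
  df <- data.frame(mirna = "hsa-miR-9-5p",
                   gene_id = c(rep("G1", 12), rep("G2", 4), rep("G3", 5)),
                   algorithm = c(PREDICTION_ALGORITHMS,
                                 PREDICTION_ALGORITHMS[1:4],
                                 PREDICTION_ALGORITHMS[5:9]))
  pt <- prediction_table(df)
  expect_setequal(support_filter(pt, "hsa-miR-9-5p", 5)$gene_id, c("G1", "G3"))
  expect_setequal(support_filter(pt, "hsa-miR-9-5p", 1)$gene_id,
                  c("G1", "G2", "G3"))
  expect_false("G2" %in% support_filter(pt, "hsa-miR-9-5p", 5)$gene_id)
  expect_equal(support_filter(pt, "hsa-miR-9-5p", 12)$gene_id, "G1")
  expect_error(support_filter(pt, "hsa-miR-9-5p", 13), "min_support")
  # random tables against naive group-and-count
  set.seed(37)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    rdf <- data.frame(mirna = "hsa-miR-7-5p",
                      gene_id = sample(paste0("G", 1:8), n, replace = TRUE),
                      algorithm = sample(PREDICTION_ALGORITHMS, n, replace = TRUE))
    rpt <- prediction_table(rdf)
    ms <- sample(1:6, 1)
    expect_setequal(support_filter(rpt, "hsa-miR-7-5p", ms)$gene_id,
                    bf_support(rpt, "hsa-miR-7-5p", ms))
  }
})

test_that("time-course directions take the significant union and reject flips", {
  mk <- function(ids, fc, sig) data.frame(feature_id = ids, significant = sig,
                                          direction = direction_of(fc, sig))
  d3 <- mk(paste0("P", 1:4), c(1, -1, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
  d7 <- mk(paste0("P", 1:4), c(1, -2, 2, 1), c(TRUE, TRUE, TRUE, FALSE))
  tc <- timecourse_directions(d3, d7)
  expect_setequal(tc$protein_id, c("P1", "P2", "P3"))
  expect_equal(tc$direction[tc$protein_id == "P3"], "up")
  d7_bad <- mk(paste0("P", 1:4), c(-1, -2, 2, 1), c(TRUE, TRUE, TRUE, FALSE))
  expect_error(timecourse_directions(d3, d7_bad), "P1")
})

test_that("inverse networks annotate predicting-miRNA counts and stay monotone", {
  mir <- data.frame(feature_id = c("hsa-miR-1-5p", "hsa-miR-2-3p"),
                    direction = "down")
  prot <- data.frame(protein_id = "P1", direction = "up")
  # miR-1 predicts G1 with 6 algorithms, miR-2 with 7
  df <- data.frame(mirna = c(rep("hsa-miR-1-5p", 6), rep("hsa-miR-2-3p", 7)),
                   gene_id = "G1",
                   algorithm = c(PREDICTION_ALGORITHMS[1:6],
                                 PREDICTION_ALGORITHMS[1:7]))
  pt <- prediction_table(df)
  map <- gene_protein_map("P1", "G1")
  net <- build_inverse_network(mir, prot, pt, map, "down-up", 5)
  expect_equal(net$proteins$n_predicting_mirnas, 2)
  expect_setequal(net$edges$support, c(6, 7))
  # no inversely regulated proteins: empty network
  net0 <- build_inverse_network(mir, data.frame(protein_id = "P1",
                                                direction = "down"),
                                pt, map, "down-up", 5)
  expect_equal(nrow(net0$edges), 0)
  # lowering min_support never removes an edge
  net1 <- build_inverse_network(mir, prot, pt, map, "down-up", 1)
  key <- function(n) paste(n$edges$mirna, n$edges$protein_id)
  expect_true(all(key(net) %in% key(net1)))
  # stability under row permutation of the prediction table
  pt2 <- pt[rev(seq_len(nrow(pt))), ]
  net_p <- build_inverse_network(mir, prot, prediction_table(pt2), map,
                                 "down-up", 5)
  expect_equal(net_p$edges, net$edges)
})

test_that("transfection contrasts are null under equality and antisymmetric", {
  set.seed(43)
  vals <- 2^matrix(rnorm(60, 20, 2), 10, 6,
                   dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
  meta <- make_meta(paste0("s", 1:6), "5/03", "d3", "protein_abundance",
                    condition = rep(c("mimic:hsa-miR-1-5p", "control_sirna"),
                                    each = 3))
  m <- omics_matrix(vals, meta)
  arms <- split_transfection(m)
  same <- transfection_diff(arms$trans, arms$trans)
  expect_false(any(same$significant))
  d <- transfection_diff(arms$trans, arms$control)
  d_sw <- transfection_diff(arms$control, arms$trans)
  expect_equal(d$log2fc, -d_sw$log2fc)
  expect_equal(d$p, d_sw$p)
  expect_error(transfection_diff(subset_omics(arms$trans, sample_idx = 1),
                                 arms$control), "replicates")
})

test_that("crossmatch equals brute-force set algebra on a planted fixture", {
  # 10 quantified proteins; 6 predicted; 4 regulated down; 2 of the
  # regulated-down are predicted; 3 timecourse-up of which 2 predicted;
  # overlap = regulated-down-predicted intersect timecourse-up-predicted
  prots <- paste0("P", 1:10)
  genes <- paste0("G", 1:10)
  map <- gene_protein_map(prots, genes)
  pred <- prediction_table(data.frame(
    mirna = "hsa-miR-5-5p", gene_id = genes[1:6], algorithm = "RNAhybrid"))
  diff <- data.frame(feature_id = prots,
                     significant = c(rep(TRUE, 4), rep(FALSE, 6)),
                     direction = c(rep("down", 2), "down", "down", rep("none", 6)))
  diff$significant[5] <- TRUE; diff$direction[5] <- "up"
  tc <- data.frame(protein_id = c("P1", "P2", "P9"), direction = "up")
  cm <- crossmatch(diff, pred, "hsa-miR-5-5p", "mimic", tc, map, "any")
  expect_equal(cm$n_quantified, 10)
  expect_equal(cm$n_predicted_of_quantified, 6)
  expect_equal(cm$n_regulated_down, 4)
  expect_equal(cm$n_regulated_up, 1)
  expect_equal(cm$n_regulated_expected_direction_and_predicted, 4)
  expect_equal(cm$n_inverse_regulated_predicted_in_timecourse, 2)
  expect_equal(cm$n_overlap, 2)
  bf <- bf_crossmatch(diff, pred, "hsa-miR-5-5p", "mimic", tc, map)
  expect_equal(unlist(cm[names(bf)]), bf, ignore_attr = TRUE)
  expect_error(crossmatch(diff, pred, "hsa-miR-404", "mimic", tc, map), "absent")
})

test_that("crossmatch overlap respects its parent sets on random instances", {
  set.seed(47)
  for (i in 1:60) {
    inst <- random_crossmatch_instance()
    cm <- crossmatch(inst$diff, prediction_table(inst$pred_df), inst$mirna,
                     inst$mode, inst$tc, inst$map, "any")
    expect_lte(cm$n_overlap, cm$n_regulated_expected_direction_and_predicted)
    expect_lte(cm$n_overlap, cm$n_inverse_regulated_predicted_in_timecourse)
    expect_lte(cm$n_predicted_of_quantified, cm$n_quantified)
    expect_lte(cm$n_regulated_up + cm$n_regulated_down, cm$n_quantified)
  }
})

test_that("predicted-target coverage is a plain fraction", {
  map <- gene_protein_map(paste0("P", 1:4), paste0("G", 1:4))
  pred_all <- prediction_table(data.frame(mirna = "hsa-miR-1-5p",
                                          gene_id = paste0("G", 1:4),
                                          algorithm = "PITA"))
  expect_equal(predicted_coverage_check(paste0("P", 1:4), pred_all,
                                        "hsa-miR-1-5p", map), 1)
  pred_none <- prediction_table(data.frame(mirna = "hsa-miR-1-5p",
                                           gene_id = "G9", algorithm = "PITA"))
  expect_equal(predicted_coverage_check(paste0("P", 1:4), pred_none,
                                        "hsa-miR-1-5p", map), 0)
  expect_error(predicted_coverage_check(character(0), pred_all,
                                        "hsa-miR-1-5p", map), "empty")
})
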