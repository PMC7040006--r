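# Independent brute-force oracles. These deliberately use explicit loops and
# naive set comprehension so they share no code path with the package
# implementations they check.

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    tail_vals <- numeric(0)
    for (j in i:m) tail_vals <- c(tail_vals, ps[j] * m / j)
    q[i] <- min(tail_vals, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

bf_venn <- function(sets) {
  nm <- names(sets)
  universe <- unique(unlist(sets))
  labels <- character(0)
  counts <- integer(0)
  combos <- list()
  for (k in seq_along(nm)) combos <- c(combos, utils::combn(nm, k, simplify = FALSE))
  for (cc in combos) {
    n <- 0L
    for (el in universe) {
      inside <- all(vapply(cc, function(s) el %in% sets[[s]], logical(1)))
      outside <- !any(vapply(setdiff(nm, cc), function(s) el %in% sets[[s]], logical(1)))
      if (inside && outside) n <- n + 1L
    }
    labels <- c(labels, paste(cc, collapse = "&"))
    counts <- c(counts, n)
  }
  stats::setNames(counts, labels)
}

# naive support counting: distinct algorithms per (mirna, gene) pair
bf_support <- function(pred_df, mirna, min_support) {
  rows <- pred_df[pred_df$mirna == mirna, , drop = FALSE]
  genes <- unique(rows$gene_id)
  keep <- character(0)
  for (g in genes) {
    n_alg <- length(unique(rows$algorithm[rows$gene_id == g]))
    if (n_alg >= min_support) keep <- c(keep, g)
  }
  sort(keep)
}

bf_crossmatch <- function(diff, pred_df, mirna, mode, tc, map, min_support = 1) {
  quantified <- unique(diff$feature_id)
  pred_genes <- bf_support(pred_df, mirna, min_support)
  pred_prots <- unique(map$protein_id[map$gene_id %in% pred_genes])
  predicted <- intersect(quantified, pred_prots)
  up <- diff$feature_id[diff$significant & diff$direction == "up"]
  down <- diff$feature_id[diff$significant & diff$direction == "down"]
  exp_dir <- if (mode == "mimic") "down" else "up"
  reg_exp <- if (exp_dir == "down") down else up
  reg_exp_pred <- intersect(reg_exp, predicted)
  tc_dir <- if (exp_dir == "down") "up" else "down"
  tc_pred <- intersect(tc$protein_id[tc$direction == tc_dir], pred_prots)
  c(n_quantified = length(quantified),
    n_predicted_of_quantified = length(predicted),
    n_regulated_up = length(up),
    n_regulated_down = length(down),
    n_regulated_expected_direction_and_predicted = length(reg_exp_pred),
    n_inverse_regulated_predicted_in_timecourse = length(tc_pred),
    n_overlap = length(intersect(reg_exp_pred, tc_pred)))
}

# random small crossmatch instance generator
random_crossmatch_instance <- function() {
  n_prot <- sample(5:25, 1)
  prots <- sprintf("P%02d", seq_len(n_prot))
  genes <- sub("P", "G", prots)
  map <- gene_protein_map(prots, genes)
  mirna <- "hsa-miR-1-5p"
  n_pred <- sample(0:40, 1)
  pred_df <- data.frame(
    mirna = rep(mirna, n_pred),
    gene_id = sample(genes, n_pred, replace = TRUE),
    algorithm = sample(PREDICTION_ALGORITHMS, n_pred, replace = TRUE),
    stringsAsFactors = FALSE)
  # crossmatch() needs the miRNA present in the table
  pred_df <- rbind(pred_df, data.frame(mirna = mirna, gene_id = genes[1],
                                       algorithm = "RNAhybrid"))
  sig <- runif(n_prot) < 0.4
  dirn <- ifelse(sig, sample(c("up", "down"), n_prot, replace = TRUE), "none")
  diff <- data.frame(feature_id = prots, significant = sig, direction = dirn,
                     stringsAsFactors = FALSE)
  tc_n <- sample(0:n_prot, 1)
  tc <- data.frame(protein_id = sample(prots, tc_n),
                   direction = sample(c("up", "down"), tc_n, replace = TRUE),
                   stringsAsFactors = FALSE)
  list(diff = diff, pred_df = pred_df, mirna = mirna,
       mode = sample(c("mimic", "inhibitor"), 1), tc = tc, map = map)
}
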