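# Synthetic study generator: negative-binomial mRNA/miRNA counts with line
# and timepoint effects, log-normal protein abundances whose true fold
# changes are correlated with the mRNA truth, multi-algorithm target
# predictions with controlled sensitivity/false-positive rate, and
# transfection experiments with planted target effects. Every output comes
# with its ground truth so parameter-recovery tests need no external data.

RNA_LINES <- c("4/101", "4/146", "5/03")
PROTEIN_LINES <- c("4/101", "4/146", "5/03", "5/73", "7/18", "8/77")
TRANSFECTION_LINE <- "5/03"

#' Synthetic study configuration
#'
#' All knobs of the generator, with defaults emulating the study design:
#' 3 cell lines x 4 timepoints of mRNA/miRNA sequencing, 6 lines x 3
#' timepoints of label-free proteome, a gene-protein map covering 96% of the
#' proteins, 12 independent prediction algorithms, and mimic/inhibitor
#' transfections of single miRNAs.
#'
#' @param seed integer seed; identical configurations give bitwise-identical
#'   outputs.
#' @param n_mrna,n_mirna,n_protein panel sizes.
#' @param map_coverage fraction of proteins represented by an mRNA gene.
#' @param frac_coding fraction of mRNA features that are protein-coding
#'   (mapped genes are always coding).
#' @param nb_dispersion negative-binomial dispersion shared across features.
#' @param line_effect_sd per-feature, per-line log2 effect SD.
#' @param lib_size_mrna,lib_size_mirna base library sizes; each sample's
#'   depth is scaled by a uniform factor in `[0.7, 1.3]`.
#' @param baseline_log2_sd spread of baseline log2 expression across
#'   features.
#' @param frac_up,frac_down per-timepoint fractions of up-/downregulated
#'   mRNA features.
#' @param mirna_frac_up,mirna_frac_down the same for miRNAs (sparser, as
#'   observed for miRNomes).
#' @param consistent_frac fraction of regulated features whose effect sign
#'   is shared across 3d/7d/14d.
#' @param effect_min,effect_max range of |log2FC| effect magnitudes
#'   (uniform).
#' @param rho_mrna_protein target correlation between true mRNA and protein
#'   log2 fold changes.
#' @param frac_inverse fraction of mapped pairs whose protein effect is
#'   sign-flipped (inversely regulated pairs).
#' @param protein_baseline_log2_mean,protein_baseline_log2_sd protein
#'   baseline abundance distribution (log2).
#' @param protein_noise_sd per-sample log2 noise of protein abundances
#'   (biological, across lines).
#' @param sensitivity,fp_rate per-algorithm probability of reporting a true
#'   pair / a false pair.
#' @param true_targets_per_mirna planted targets per miRNA.
#' @param mimic_effect,inhibitor_effect log2 shift applied to quantified
#'   true targets upon transfection.
#' @param transfection_noise_sd per-sample log2 noise of the transfection
#'   proteomes (technical replicates of a single line, hence tighter than
#'   `protein_noise_sd`).
#' @param transfection_replicates replicates per transfection arm.
#' @param offtarget_frac,offtarget_sd fraction of non-targets receiving an
#'   indirect effect upon transfection, and the SD of that effect.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_mrna = 13000, n_mirna = 600, n_protein = 1800,
                         map_coverage = 0.96, frac_coding = 0.9,
                         nb_dispersion = 0.1, line_effect_sd = 0.2,
                         lib_size_mrna = 14e6, lib_size_mirna = 5.5e6,
                         baseline_log2_sd = 2.2,
                         frac_up = 0.25, frac_down = 0.15,
                         mirna_frac_up = 0.05, mirna_frac_down = 0.05,
                         consistent_frac = 0.8,
                         effect_min = log2(1.5), effect_max = 3,
                         rho_mrna_protein = 0.65, frac_inverse = 0.01,
                         protein_baseline_log2_mean = 20,
                         protein_baseline_log2_sd = 2,
                         protein_noise_sd = 0.4,
                         sensitivity = 0.6, fp_rate = 0.02,
                         true_targets_per_mirna = 200,
                         mimic_effect = -1.0, inhibitor_effect = 0.7,
                         transfection_noise_sd = 0.15,
                         transfection_replicates = 3,
                         offtarget_frac = 0.02, offtarget_sd = 0.3) {
  probs <- c(map_coverage, frac_coding, frac_up, frac_down, mirna_frac_up,
             mirna_frac_down, consistent_frac, frac_inverse, sensitivity,
             fp_rate, offtarget_frac)
  if (any(probs < 0 | probs > 1)) stop_("all probabilities must lie in [0, 1]")
  if (frac_up + frac_down > 1) stop_("frac_up + frac_down must not exceed 1")
  if (mirna_frac_up + mirna_frac_down > 1)
    stop_("mirna_frac_up + mirna_frac_down must not exceed 1")
  if (nb_dispersion <= 0) stop_("nb_dispersion must be positive")
  if (!(rho_mrna_protein > -1 && rho_mrna_protein < 1))
    stop_("rho_mrna_protein must lie in (-1, 1)")
  if (effect_min <= 0 || effect_max < effect_min)
    stop_("effect range must satisfy 0 < effect_min <= effect_max")
  if (transfection_replicates < 2) stop_("need at least 2 replicates per arm")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

seed_for <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

# Per-feature true effects. "Consistent" regulated features carry the same
# sign at all timepoints; the remainder are regulated at a random non-empty
# subset of timepoints (timepoint-exclusive regulation, as in the observed
# Venn diagrams), with an occasional sign flip so the same-direction filter
# has something to reject.
draw_effects <- function(n, frac_up, frac_down, consistent_frac,
                         effect_min, effect_max, n_timepoints = 3,
                         flip_prob = 0.1) {
  u <- stats::runif(n)
  dir <- ifelse(u < frac_up, 1, ifelse(u < frac_up + frac_down, -1, 0))
  de <- dir != 0
  consistent <- stats::runif(n) < consistent_frac
  eff <- matrix(0, n, n_timepoints)
  active <- matrix(TRUE, n, n_timepoints)
  part <- de & !consistent
  if (any(part)) {
    active[part, ] <- stats::runif(sum(part) * n_timepoints) < 0.5
    none <- part & rowSums(active) == 0
    active[cbind(which(none), sample.int(n_timepoints, sum(none), replace = TRUE))] <- TRUE
  }
  for (t in seq_len(n_timepoints)) {
    mag <- stats::runif(n, effect_min, effect_max)
    sgn <- dir * ifelse(part & flip_prob > 0 & stats::runif(n) < flip_prob, -1, 1)
    eff[, t] <- ifelse(de & active[, t], sgn * mag, 0)
  }
  list(effects = eff, direction = c("down", "none", "up")[dir + 2],
       consistent = consistent & de)
}

new_ground_truth <- function(features, effects, direction, consistent,
                             modality, fc_cut = 1.5, extra = list()) {
  rownames(effects) <- features
  gt <- c(list(features = features, effects = effects, direction = direction,
               consistent = consistent,
               regulated = apply(abs(effects) > log2(fc_cut), 1, any),
               modality = modality), extra)
  structure(gt, class = "ground_truth")
}

#' Simulate an mRNA or miRNA count matrix
#'
#' Counts are negative binomial with mean `baseline * 2^(line effect +
#' timepoint effect)`, renormalised within each sample to a library size
#' drawn uniformly in `[0.7, 1.3]` times the base depth. The native
#' timepoint has zero timepoint effect; regulated features keep a consistent
#' effect sign across 3d/7d/14d for a configurable fraction.
#'
#' @param cfg a [synth_config()].
#' @param modality `"mrna"` or `"mirna"`.
#' @return list with `matrix` (an `omics_matrix`) and `truth`
#'   (a `ground_truth`).
#' @export
simulate_counts <- function(cfg, modality = c("mrna", "mirna")) {
  modality <- match.arg(modality)
  withr::with_seed(seed_for(cfg, if (modality == "mrna") 101 else 202), {
    n <- if (modality == "mrna") cfg$n_mrna else cfg$n_mirna
    feats <- if (modality == "mrna") sprintf("G%05d", seq_len(n)) else
      sprintf("hsa-miR-s%04d", seq_len(n))
    fu <- if (modality == "mrna") cfg$frac_up else cfg$mirna_frac_up
    fd <- if (modality == "mrna") cfg$frac_down else cfg$mirna_frac_down
    base_lib <- if (modality == "mrna") cfg$lib_size_mrna else cfg$lib_size_mirna
    b <- stats::rnorm(n, 0, cfg$baseline_log2_sd)
    # miRNA effects may occasionally flip sign between timepoints (the
    # same-direction filter then has something to reject); mRNA effects do
    # not, so the derived protein truth can stay flip-free
    eff <- draw_effects(n, fu, fd, cfg$consistent_frac,
                        cfg$effect_min, cfg$effect_max,
                        flip_prob = if (modality == "mrna") 0 else 0.1)
    lines <- RNA_LINES
    L <- matrix(stats::rnorm(n * length(lines), 0, cfg$line_effect_sd),
                n, length(lines))
    tps <- TIMEPOINTS
    grid <- expand.grid(line = seq_along(lines), tp = seq_along(tps))
    vals <- matrix(0L, n, nrow(grid))
    ids <- character(nrow(grid))
    for (s in seq_len(nrow(grid))) {
      l <- grid$line[s]; t <- grid$tp[s]
      e_t <- if (tps[t] == "native") 0 else eff$effects[, t - 1]
      mu_rel <- 2^(b + L[, l] + e_t)
      lib <- base_lib * stats::runif(1, 0.7, 1.3)
      vals[, s] <- stats::rnbinom(n, mu = mu_rel / sum(mu_rel) * lib,
                                  size = 1 / cfg$nb_dispersion)
      ids[s] <- sprintf("%s_%s_%s", modality, gsub("/", "-", lines[l]), tps[t])
    }
    dimnames(vals) <- list(feats, ids)
    samples <- data.frame(
      sample_id = ids, line = lines[grid$line], timepoint = tps[grid$tp],
      condition = "untreated",
      modality = paste0(modality, "_counts"), stringsAsFactors = FALSE)
    colnames(eff$effects) <- c("d3", "d7", "d14")
    # CPM estimates *relative* abundance: regulated features change the
    # per-sample total, shifting every feature's relative share. The
    # relative-scale truth (the estimand of a depth-normalised pipeline) is
    # the planted effect minus that composition shift.
    w <- 2^b
    shift <- vapply(1:3, function(t)
      log2(sum(w * 2^eff$effects[, t]) / sum(w)), numeric(1))
    eff_rel <- sweep(eff$effects, 2, shift, "-")
    dimnames(eff_rel) <- list(feats, colnames(eff$effects))
    list(matrix = omics_matrix(vals, samples),
         truth = new_ground_truth(feats, eff$effects, eff$direction,
                                  eff$consistent, paste0(modality, "_counts"),
                                  extra = list(effects_rel = eff_rel,
                                               composition_shift = shift)))
  })
}

#' Simulate the protein abundance matrix from the mRNA ground truth
#'
#' For mapped proteins the true protein log2FC is `rho * m + sqrt(1 - rho^2)
#' * sd(m) * eps`, so the population correlation of true fold changes equals
#' `rho_mrna_protein`; a small configured fraction of mapped pairs gets
#' sign-flipped effects (inverse regulation). Unmapped proteins receive
#' independent effects of the same marginal spread. Observed abundances are
#' `baseline * 2^(line effect + true FC + N(0, protein_noise_sd))` for
#' 6 lines at native/3d/7d.
#'
#' @param cfg a [synth_config()].
#' @param rna output of `simulate_counts(cfg, "mrna")`.
#' @return list with `matrix` (an `omics_matrix`), `truth` (a
#'   `ground_truth` with `$inverse`, `$gene_id` and `$baseline` extras) and
#'   `map` (a [gene_protein_map()]).
#' @export
simulate_proteome <- function(cfg, rna) {
  withr::with_seed(seed_for(cfg, 303), {
    genes <- rna$truth$features
    n_map <- round(cfg$map_coverage * cfg$n_protein)
    if (n_map > length(genes)) stop_("protein panel larger than the gene universe")
    mapped_genes <- sample(genes, n_map)
    prot_ids <- c(paste0("P_", mapped_genes),
                  sprintf("P_X%04d", seq_len(cfg$n_protein - n_map)))
    gene_ids <- c(mapped_genes, rep(NA_character_, cfg$n_protein - n_map))
    tps <- c("d3", "d7")
    eff <- matrix(0, cfg$n_protein, length(tps), dimnames = list(prot_ids, tps))
    rho <- cfg$rho_mrna_protein
    gate <- log2(1.5)
    # one shared noise draw per protein: the protein-specific component of
    # regulation persists across the time course, so true effect directions
    # never flip between 3d and 7d (matching the observed absence of flips)
    eps <- stats::rnorm(n_map)
    eps_x <- stats::rnorm(cfg$n_protein - n_map)
    for (t in tps) {
      m <- rna$truth$effects[mapped_genes, t]
      s_m <- stats::sd(m)
      e <- rho * m + sqrt(1 - rho^2) * s_m * eps
      # inverse regulation is the configured minority only: reflect chance
      # strong sign inversions of non-flagged pairs onto the mRNA side's sign
      refl <- abs(m) > gate & sign(e) == -sign(m) & abs(e) > gate
      e[refl] <- -e[refl]
      eff[seq_len(n_map), t] <- e
      if (cfg$n_protein > n_map)
        eff[(n_map + 1):cfg$n_protein, t] <- s_m * eps_x
    }
    # no true direction flips across the time course: resolve residual sign
    # clashes by flipping the side where the flip cannot manufacture an
    # inverse mRNA-protein pair (i.e. never leave a strong wrong-signed
    # effect opposite a strong mRNA effect); ties go to the weaker side
    m3 <- m7 <- rep(0, cfg$n_protein)
    m3[seq_len(n_map)] <- rna$truth$effects[mapped_genes, "d3"]
    m7[seq_len(n_map)] <- rna$truth$effects[mapped_genes, "d7"]
    clash <- eff[, "d3"] * eff[, "d7"] < 0
    bad3 <- abs(m3) > gate & abs(eff[, "d3"]) > gate & sign(eff[, "d7"]) != sign(m3)
    bad7 <- abs(m7) > gate & abs(eff[, "d7"]) > gate & sign(eff[, "d3"]) != sign(m7)
    flip7 <- clash & !bad7 & (bad3 | abs(eff[, "d7"]) <= abs(eff[, "d3"]))
    flip3 <- clash & !flip7
    eff[flip7, "d7"] <- -eff[flip7, "d7"]
    eff[flip3, "d3"] <- -eff[flip3, "d3"]
    inverse <- rep(FALSE, cfg$n_protein)
    reg_m <- which(rna$truth$regulated[mapped_genes])
    n_inv <- min(round(cfg$frac_inverse * n_map), length(reg_m))
    if (n_inv > 0) {
      inv_idx <- sample(reg_m, n_inv)
      eff[inv_idx, ] <- -eff[inv_idx, ]
      inverse[inv_idx] <- TRUE
    }
    base <- stats::rnorm(cfg$n_protein, cfg$protein_baseline_log2_mean,
                         cfg$protein_baseline_log2_sd)
    lines <- PROTEIN_LINES
    L <- matrix(stats::rnorm(cfg$n_protein * length(lines), 0, cfg$line_effect_sd),
                cfg$n_protein, length(lines))
    grid <- expand.grid(line = seq_along(lines), tp = c("native", tps),
                        stringsAsFactors = FALSE)
    vals <- matrix(0, cfg$n_protein, nrow(grid))
    ids <- character(nrow(grid))
    for (s in seq_len(nrow(grid))) {
      l <- grid$line[s]; tp <- grid$tp[s]
      e_t <- if (tp == "native") 0 else eff[, tp]
      vals[, s] <- 2^(base + L[, l] + e_t +
                        stats::rnorm(cfg$n_protein, 0, cfg$protein_noise_sd))
      ids[s] <- sprintf("prot_%s_%s", gsub("/", "-", lines[l]), tp)
    }
    dimnames(vals) <- list(prot_ids, ids)
    samples <- data.frame(
      sample_id = ids, line = lines[grid$line], timepoint = grid$tp,
      condition = "untreated", modality = "protein_abundance",
      stringsAsFactors = FALSE)
    up <- 2L + stats::rpois(cfg$n_protein, 4)
    names(up) <- prot_ids
    dir <- ifelse(rowSums(eff) > 0, "up", ifelse(rowSums(eff) < 0, "down", "none"))
    truth <- new_ground_truth(prot_ids, eff, dir,
                              consistent = rep(NA, cfg$n_protein),
                              modality = "protein_abundance",
                              extra = list(inverse = inverse, gene_id = gene_ids,
                                           baseline = stats::setNames(base, prot_ids)))
    list(matrix = omics_matrix(vals, samples, up), truth = truth,
         map = gene_protein_map(prot_ids[seq_len(n_map)], mapped_genes))
  })
}

#' Assign planted target sets to miRNAs
#'
#' @param cfg a [synth_config()].
#' @param mirnas miRNA names.
#' @param genes gene universe to draw targets from.
#' @return named list of gene vectors (`true_targets_per_mirna` each).
#' @export
assign_true_targets <- function(cfg, mirnas, genes) {
  withr::with_seed(seed_for(cfg, 404), {
    stats::setNames(lapply(mirnas, function(m)
      sort(sample(genes, cfg$true_targets_per_mirna))), mirnas)
  })
}

#' Simulate a multi-algorithm target-prediction table
#'
#' Each of the 12 algorithms independently reports each true (miRNA, gene)
#' pair with probability `sensitivity` and each false pair with probability
#' `fp_rate`, so the support count of a pair is binomial.
#'
#' @param cfg a [synth_config()].
#' @param target_sets named list of true target genes per miRNA (from
#'   [assign_true_targets()]).
#' @param genes full gene universe (false pairs are drawn from its
#'   complement of each target set).
#' @return a `prediction_table`.
#' @export
simulate_predictions <- function(cfg, target_sets, genes) {
  withr::with_seed(seed_for(cfg, 505), {
    algs <- PREDICTION_ALGORITHMS
    pieces <- lapply(names(target_sets), function(mir) {
      tg <- target_sets[[mir]]
      fg <- setdiff(genes, tg)
      hit_t <- matrix(stats::rbinom(length(tg) * length(algs), 1, cfg$sensitivity),
                      length(tg), length(algs))
      hit_f <- matrix(stats::rbinom(length(fg) * length(algs), 1, cfg$fp_rate),
                      length(fg), length(algs))
      it <- which(hit_t == 1, arr.ind = TRUE)
      jf <- which(hit_f == 1, arr.ind = TRUE)
      data.frame(mirna = mir,
                 gene_id = c(tg[it[, 1]], fg[jf[, 1]]),
                 algorithm = algs[c(it[, 2], jf[, 2])],
                 stringsAsFactors = FALSE)
    })
    prediction_table(do.call(rbind, pieces))
  })
}

#' Simulate a transfection experiment
#'
#' Paired transfected and control-siRNA replicate groups of a single line at
#' 3d of differentiation. Quantified true targets of the transfected miRNA
#' receive the transfection effect on the log2 scale (negative for a mimic,
#' positive for an inhibitor); a small random subset of non-targets receives
#' an indirect effect. Replicate noise is technical
#' (`transfection_noise_sd`).
#'
#' @param cfg a [synth_config()].
#' @param proteome output of [simulate_proteome()].
#' @param target_sets named list of true target genes per miRNA.
#' @param mirna the transfected miRNA (must be present in `target_sets`).
#' @param mode `"mimic"` or `"inhibitor"`.
#' @param seed_offset distinct offset per experiment so repeats differ.
#' @return list with `matrix` (both arms, conditions `mimic:<miRNA>` /
#'   `inhibitor:<miRNA>` and `control_sirna`) and `truth` (planted target
#'   and off-target protein IDs and the effect size).
#' @export
simulate_transfection <- function(cfg, proteome, target_sets, mirna,
                                  mode = c("mimic", "inhibitor"),
                                  seed_offset = 0) {
  mode <- match.arg(mode)
  mirna <- normalize_mirna(mirna)
  if (!mirna %in% names(target_sets)) stop_("unknown miRNA: %s", mirna)
  withr::with_seed(seed_for(cfg, 606 + seed_offset), {
    tr <- proteome$truth
    n <- length(tr$features)
    delta <- if (mode == "mimic") cfg$mimic_effect else cfg$inhibitor_effect
    is_target <- !is.na(tr$gene_id) & tr$gene_id %in% target_sets[[mirna]]
    off_pool <- which(!is_target)
    offtargets <- sort(sample(off_pool, round(cfg$offtarget_frac * length(off_pool))))
    off_shift <- rep(0, n)
    off_shift[offtargets] <- stats::rnorm(length(offtargets), 0, cfg$offtarget_sd)
    mu_ctrl <- tr$baseline + tr$effects[, "d3"]
    mu_trans <- mu_ctrl + delta * is_target + off_shift
    nrep <- cfg$transfection_replicates
    vals <- matrix(0, n, 2 * nrep)
    for (r in seq_len(nrep)) {
      vals[, r] <- 2^(mu_trans + stats::rnorm(n, 0, cfg$transfection_noise_sd))
      vals[, nrep + r] <- 2^(mu_ctrl + stats::rnorm(n, 0, cfg$transfection_noise_sd))
    }
    cond <- paste0(mode, ":", mirna)
    ids <- c(sprintf("%s_rep%d", gsub("[^A-Za-z0-9]", ".", cond), seq_len(nrep)),
             sprintf("ctrl_%s_rep%d", gsub("[^A-Za-z0-9]", ".", mirna), seq_len(nrep)))
    dimnames(vals) <- list(tr$features, ids)
    samples <- data.frame(
      sample_id = ids, line = TRANSFECTION_LINE, timepoint = "d3",
      condition = rep(c(cond, "control_sirna"), each = nrep),
      modality = "protein_abundance", stringsAsFactors = FALSE)
    list(matrix = omics_matrix(vals, samples),
         truth = list(mirna = mirna, mode = mode, effect = delta,
                      targets = tr$features[is_target],
                      offtargets = tr$features[offtargets]))
  })
}

#' Split a transfection matrix into its two arms
#'
#' @param m an `omics_matrix` holding both a `mimic:`/`inhibitor:` arm and a
#'   `control_sirna` arm.
#' @return list with `trans` and `control` `omics_matrix` objects.
#' @export
split_transfection <- function(m) {
  is_ctrl <- m$samples$condition == "control_sirna"
  if (!any(is_ctrl) || all(is_ctrl))
    stop_("matrix must contain both a transfected and a control_sirna arm")
  list(trans = subset_omics(m, sample_idx = !is_ctrl),
       control = subset_omics(m, sample_idx = is_ctrl))
}

#' Simulate the complete study
#'
#' Generates the full bundle: mRNA and miRNA count matrices, protein
#' abundances, the gene-protein map, the protein-coding list, target
#' predictions for all truly consistently regulated miRNAs, and three
#' transfection experiments (mimics for the two most strongly expressed
#' consistently downregulated miRNAs, an inhibitor for one consistently
#' upregulated miRNA) — each with ground truth.
#'
#' @param cfg a [synth_config()].
#' @return named list of class `synth_study`.
#' @export
simulate_study <- function(cfg = synth_config()) {
  mrna <- simulate_counts(cfg, "mrna")
  mirna <- simulate_counts(cfg, "mirna")
  prot <- simulate_proteome(cfg, mrna)
  coding <- withr::with_seed(seed_for(cfg, 707), {
    extra <- sample(setdiff(mrna$truth$features, prot$map$gene_id),
                    max(0, round(cfg$frac_coding * cfg$n_mrna) - nrow(prot$map)))
    sort(unique(c(prot$map$gene_id, extra)))
  })
  tr <- mirna$truth
  consistent <- tr$features[tr$consistent &
                              apply(abs(tr$effects) > log2(1.5), 1, all)]
  if (length(consistent) < 3)
    stop_("too few consistently regulated miRNAs; increase mirna_frac_up/down")
  target_sets <- assign_true_targets(cfg, consistent, mrna$truth$features)
  predictions <- simulate_predictions(cfg, target_sets, mrna$truth$features)
  native_cpm <- rowMeans(compute_cpm(mirna$matrix)$values[
    , mirna$matrix$samples$timepoint == "native", drop = FALSE])
  dirs <- tr$direction[match(consistent, tr$features)]
  down <- consistent[dirs == "down"]
  up <- consistent[dirs == "up"]
  down <- down[order(-native_cpm[down])]
  up <- up[order(-native_cpm[up])]
  if (length(down) < 2 || length(up) < 1)
    stop_("need at least two consistently down and one up miRNA for transfections")
  picks <- list(list(mirna = down[1], mode = "mimic"),
                list(mirna = down[2], mode = "mimic"),
                list(mirna = up[1], mode = "inhibitor"))
  transfections <- lapply(seq_along(picks), function(i)
    simulate_transfection(cfg, prot, target_sets, picks[[i]]$mirna,
                          picks[[i]]$mode, seed_offset = i))
  names(transfections) <- vapply(picks, function(p)
    paste0(p$mode, ":", p$mirna), character(1))
  structure(list(cfg = cfg, mrna = mrna, mirna = mirna, protein = prot,
                 map = prot$map, coding_ids = coding,
                 target_sets = target_sets, predictions = predictions,
                 transfections = transfections),
            class = "synth_study")
}

#' Write a simulated study bundle to a directory
#'
#' Matrices and metadata sidecars, the prediction table, the gene-protein
#' map, the coding list, and ground-truth effect tables — all as TSV.
#'
#' @param study a `synth_study`.
#' @param dir destination directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_matrix(study$mrna$matrix, p("mrna_counts.tsv"), p("mrna_samples.tsv"))
  write_matrix(study$mirna$matrix, p("mirna_counts.tsv"), p("mirna_samples.tsv"))
  write_matrix(study$protein$matrix, p("protein_abundance.tsv"), p("protein_samples.tsv"))
  utils::write.table(study$map, p("gene_protein_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(study$coding_ids, p("protein_coding_ids.txt"))
  utils::write.table(study$predictions, p("predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(study$transfections)) {
    tag <- gsub("[^A-Za-z0-9]", "_", nm)
    write_matrix(study$transfections[[nm]]$matrix,
                 p(sprintf("transfection_%s.tsv", tag)),
                 p(sprintf("transfection_%s_samples.tsv", tag)))
  }
  for (nm in c("mrna", "mirna")) {
    gt <- study[[nm]]$truth
    utils::write.table(
      data.frame(feature_id = gt$features, gt$effects,
                 direction = gt$direction, regulated = gt$regulated),
      p(sprintf("truth_%s.tsv", nm)), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gt <- study$protein$truth
  utils::write.table(
    data.frame(feature_id = gt$features, gt$effects, gene_id = gt$gene_id,
               inverse = gt$inverse, regulated = gt$regulated),
    p("truth_protein.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
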