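#' Configuration for a synthetic cell-line cohort
#'
#' Describes the generative model used to emulate a cell-line screen
#' cohort: per-gene Bernoulli disruption, each disruption realised as
#' either a disruptive variant row (intolerant missense or loss of
#' function) or a homozygous-deletion copy-number row, and ln IC50 that is
#' Gaussian noise around a baseline plus an additive planted effect for
#' every SC pair whose two genes are jointly disrupted.
#'
#' @param n_samples Number of cell lines.
#' @param n_genes Number of genes.
#' @param disruption_freq Per-gene disruption probability; scalar (recycled)
#'   or length `n_genes`.
#' @param planted_pairs `data.frame` with `gene_a`, `gene_b`, `delta`
#'   (additive shift of ln IC50, negative = sensitising) or `NULL`.
#' @param baseline_mu Baseline mean ln IC50.
#' @param noise_sd Gaussian noise SD on ln IC50 (> 0).
#' @param n_drugs Number of drugs in the response table.
#' @param shared_effect_drugs Indices of drugs that reuse the planted
#'   deltas; the rest are independent noise-only responses.
#' @param pair_corr Optional co-disruption correlation knob in `[0, 1)`:
#'   for each planted pair, this fraction of samples draws one Bernoulli
#'   shared by both genes.
#' @param seed Integer RNG seed.
#' @return A list of class `cell_cohort_config`.
#' @export
cell_cohort_config <- function(n_samples = 400L, n_genes = 50L,
                               disruption_freq = 0.15,
                               planted_pairs = NULL,
                               baseline_mu = -3, noise_sd = 1,
                               n_drugs = 1L, shared_effect_drugs = 1L,
                               pair_corr = 0, seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 2, noise_sd > 0,
            all(disruption_freq > 0), all(disruption_freq < 1),
            pair_corr >= 0, pair_corr < 1)
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene_a", "gene_b", "delta") %in% names(planted_pairs)))
    bad <- setdiff(unique(c(planted_pairs$gene_a, planted_pairs$gene_b)),
                   genes)
    if (length(bad) > 0L)
      stop("planted genes outside the gene set: ", paste(bad, collapse = ", "))
    if (any(planted_pairs$gene_a == planted_pairs$gene_b))
      stop("planted pair genes must be distinct")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 genes = genes,
                 samples = sprintf("S%04d", seq_len(n_samples)),
                 disruption_freq = rep_len(disruption_freq, n_genes),
                 planted_pairs = planted_pairs,
                 baseline_mu = baseline_mu, noise_sd = noise_sd,
                 n_drugs = as.integer(n_drugs),
                 shared_effect_drugs = as.integer(shared_effect_drugs),
                 pair_corr = pair_corr, seed = as.integer(seed)),
            class = "cell_cohort_config")
}

#' Pick planted SC pairs over the first genes of a config's gene set
#'
#' Convenience for simulation studies: pairs genes (G001, G002), (G003,
#' G004), ... with a common effect size.
#'
#' @param n_pairs Number of pairs.
#' @param delta Common additive ln IC50 shift for jointly disrupted samples.
#' @param n_genes Gene-set size (must hold `2 * n_pairs` genes).
#' @return `data.frame` with `gene_a`, `gene_b`, `delta`.
#' @export
planted_pair_grid <- function(n_pairs, delta = -2.5, n_genes = 50L) {
  stopifnot(2L * n_pairs <= n_genes)
  genes <- sprintf("G%03d", seq_len(n_genes))
  data.frame(gene_a = genes[seq(1L, by = 2L, length.out = n_pairs)],
             gene_b = genes[seq(2L, by = 2L, length.out = n_pairs)],
             delta = delta, stringsAsFactors = FALSE)
}

#' Simulate a cell-line cohort
#'
#' Draws the cohort described by a [cell_cohort_config()]: a variant table,
#' a copy-number table and a multi-drug response table in exactly the
#' layouts the ingest readers consume, plus a ground-truth record. Every
#' generated variant row classifies as disruptive under the default
#' disruption rules, and every homozygous deletion row as a copy-number
#' disruption, so the reconstructed matrix equals the latent Bernoulli
#' draw. Identical seeds give identical output.
#'
#' @param cfg A [cell_cohort_config()].
#' @return A list with `variants`, `copy_number`, `response` (data frames),
#'   and `truth` (list: `disruption` latent matrix, `planted_pairs`,
#'   `config`).
#' @export
simulate_cell_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cell_cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  g <- cfg$n_genes
  D <- matrix(rbinom(n * g, 1L, rep(cfg$disruption_freq, each = n)), n, g,
              dimnames = list(cfg$samples, cfg$genes))
  if (cfg$pair_corr > 0 && !is.null(cfg$planted_pairs)) {
    for (k in seq_len(nrow(cfg$planted_pairs))) {
      a <- cfg$planted_pairs$gene_a[k]; b <- cfg$planted_pairs$gene_b[k]
      shared <- runif(n) < cfg$pair_corr
      D[shared, b] <- D[shared, a]
    }
  }

  hits <- which(D == 1L, arr.ind = TRUE)
  n_hit <- nrow(hits)
  lof_terms <- lof_consequences()
  as_variant <- runif(n_hit) < 0.5
  var_idx <- which(as_variant)
  is_missense <- runif(length(var_idx)) < 0.5
  consequence <- ifelse(is_missense, "missense_variant",
                        sample(lof_terms, length(var_idx), replace = TRUE))
  sift <- ifelse(is_missense, runif(length(var_idx), 0, 0.0499), NA_real_)
  variants <- data.frame(
    sample_id = cfg$samples[hits[var_idx, 1]],
    gene = cfg$genes[hits[var_idx, 2]],
    consequence = consequence,
    sift_score = sift,
    esp_af = NA_real_, kg_af = NA_real_,
    stringsAsFactors = FALSE)
  cn_idx <- which(!as_variant)
  copy_number <- data.frame(
    sample_id = cfg$samples[hits[cn_idx, 1]],
    gene = cfg$genes[hits[cn_idx, 2]],
    total_copy_number = 0L,
    stringsAsFactors = FALSE)

  pair_effect <- rep(0, n)
  if (!is.null(cfg$planted_pairs) && nrow(cfg$planted_pairs) > 0L) {
    for (k in seq_len(nrow(cfg$planted_pairs))) {
      hit <- D[, cfg$planted_pairs$gene_a[k]] == 1L &
        D[, cfg$planted_pairs$gene_b[k]] == 1L
      pair_effect <- pair_effect + cfg$planted_pairs$delta[k] * hit
    }
  }
  resp <- list()
  for (d in seq_len(cfg$n_drugs)) {
    mu <- cfg$baseline_mu +
      if (d %in% cfg$shared_effect_drugs) pair_effect else 0
    resp[[d]] <- data.frame(sample_id = cfg$samples,
                            drug = sprintf("drug_%02d", d),
                            ln_ic50 = rnorm(n, mu, cfg$noise_sd),
                            stringsAsFactors = FALSE)
  }
  list(variants = variants, copy_number = copy_number,
       response = do.call(rbind, resp),
       truth = list(disruption = D, planted_pairs = cfg$planted_pairs,
                    config = cfg))
}

#' Pick planted SC pairs uniformly at random over a config's gene set
#'
#' Samples `n_pairs` distinct unordered pairs (genes may recur across
#' pairs, as in a real SC network where hub genes join many pairs) with a
#' common effect size. Used to emulate screens at the scale of a full SC
#' network rather than a handful of disjoint pairs.
#'
#' @param n_pairs Number of distinct pairs.
#' @param delta Common additive ln IC50 shift for jointly disrupted samples.
#' @param n_genes Gene-set size.
#' @param seed RNG seed for the pair draw.
#' @return `data.frame` with `gene_a`, `gene_b`, `delta`.
#' @export
planted_pair_random <- function(n_pairs, delta = -0.5, n_genes = 50L,
                                seed = 1L) {
  stopifnot(n_pairs <= choose(n_genes, 2))
  genes <- sprintf("G%03d", seq_len(n_genes))
  all_pairs <- t(utils::combn(genes, 2))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample(nrow(all_pairs), n_pairs)
  data.frame(gene_a = all_pairs[idx, 1], gene_b = all_pairs[idx, 2],
             delta = delta, stringsAsFactors = FALSE)
}

#' Configuration for a synthetic patient cohort
#'
#' Emulates the patient-validation design: independent Bernoulli anchor and
#' partner disruptions, exponential survival whose hazard is multiplied by
#' `hr_per_burden_in_anchor` per disrupted partner — but only in the
#' anchor-mutant stratum — independent exponential censoring, and an
#' independent ordinal stage.
#'
#' @param n_patients Cohort size.
#' @param anchor Anchor gene symbol.
#' @param partners Partner gene symbols.
#' @param anchor_mut_frac Anchor disruption probability.
#' @param partner_mut_fracs Per-partner disruption probabilities (recycled).
#' @param hr_per_burden_in_anchor Multiplicative hazard ratio per disrupted
#'   partner inside the anchor-mutant stratum (1 = no effect).
#' @param baseline_hazard Baseline exponential hazard (per day).
#' @param censoring_rate Exponential censoring hazard (per day).
#' @param stage_probs Probabilities of stages I--IV (sum to 1).
#' @param seed Integer RNG seed.
#' @return A list of class `patient_cohort_config`.
#' @export
patient_cohort_config <- function(n_patients = 800L, anchor = "TP53",
                                  partners = c("SYNE2", "SON"),
                                  anchor_mut_frac = 0.4,
                                  partner_mut_fracs = 0.3,
                                  hr_per_burden_in_anchor = 0.4,
                                  baseline_hazard = 1 / 1000,
                                  censoring_rate = 1 / 1500,
                                  stage_probs = c(0.15, 0.35, 0.3, 0.2),
                                  seed = 1L) {
  stopifnot(n_patients >= 2, anchor_mut_frac > 0, anchor_mut_frac < 1,
            all(partner_mut_fracs > 0), all(partner_mut_fracs < 1),
            hr_per_burden_in_anchor > 0, baseline_hazard > 0,
            censoring_rate > 0, length(stage_probs) == 4,
            abs(sum(stage_probs) - 1) < 1e-12, length(partners) >= 1)
  structure(list(n_patients = as.integer(n_patients), anchor = anchor,
                 partners = partners,
                 patients = sprintf("P%04d", seq_len(n_patients)),
                 anchor_mut_frac = anchor_mut_frac,
                 partner_mut_fracs = rep_len(partner_mut_fracs,
                                             length(partners)),
                 hr_per_burden_in_anchor = hr_per_burden_in_anchor,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 stage_probs = stage_probs, seed = as.integer(seed)),
            class = "patient_cohort_config")
}

#' Simulate a patient cohort
#'
#' Draws the cohort described by a [patient_cohort_config()]: a MAF-format
#' mutation table (classifications that the MAF ingest maps to disruptive
#' consequences) and a clinical table, plus a ground-truth record with the
#' latent disruption states.
#'
#' @param cfg A [patient_cohort_config()].
#' @return A list with `maf`, `clinical` (data frames) and `truth` (list:
#'   `disruption` matrix over anchor + partners, `burden`, `config`).
#' @export
simulate_patient_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "patient_cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  genes <- c(cfg$anchor, cfg$partners)
  probs <- c(cfg$anchor_mut_frac, cfg$partner_mut_fracs)
  D <- matrix(rbinom(n * length(genes), 1L, rep(probs, each = n)),
              n, length(genes), dimnames = list(cfg$patients, genes))
  burden <- as.integer(rowSums(D[, cfg$partners, drop = FALSE]))
  anchor_mut <- D[, cfg$anchor]
  hazard <- cfg$baseline_hazard *
    cfg$hr_per_burden_in_anchor^(burden * anchor_mut)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::rexp(n, rate = cfg$censoring_rate)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = cfg$stage_probs)

  disruptive_cls <- c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site")
  hits <- which(D == 1L, arr.ind = TRUE)
  cls <- sample(disruptive_cls, nrow(hits), replace = TRUE)
  sift <- ifelse(cls == "Missense_Mutation",
                 sprintf("deleterious(%0.3f)", runif(nrow(hits), 0, 0.049)),
                 "")
  maf <- data.frame(Hugo_Symbol = genes[hits[, 2]],
                    Tumor_Sample_Barcode = cfg$patients[hits[, 1]],
                    Variant_Classification = cls,
                    SIFT = sift, stringsAsFactors = FALSE)
  clinical <- data.frame(patient_id = cfg$patients, os_time = os_time,
                         os_event = os_event, stage = stage,
                         stringsAsFactors = FALSE)
  list(maf = maf, clinical = clinical,
       truth = list(disruption = D, burden = burden,
                    anchor_mut = anchor_mut, config = cfg))
}

#' Precision and recall of SC-pair recovery
#'
#' Compares declared SC pairs against planted ground truth; pairs are
#' unordered, so (A, B) matches (B, A).
#'
#' @param truth `data.frame` of planted pairs (`gene_a`, `gene_b`).
#' @param inferred An `sc_screen` object or a `data.frame` of declared
#'   pairs (`gene_a`, `gene_b`).
#' @return A list with `precision` (`NA` when nothing was declared),
#'   `recall`, `n_declared`, `n_planted`, and `detected` (logical flag per
#'   planted pair).
#' @export
recovery_metrics <- function(truth, inferred) {
  if (inherits(inferred, "sc_screen")) inferred <- sc_pairs(inferred)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  planted <- if (is.null(truth) || nrow(truth) == 0L) character(0)
             else key(truth$gene_a, truth$gene_b)
  declared <- if (nrow(inferred) == 0L) character(0)
              else key(inferred$gene_a, inferred$gene_b)
  detected <- planted %in% declared
  list(precision = if (length(declared) == 0L) NA_real_
                   else mean(declared %in% planted),
       recall = if (length(planted) == 0L) NA_real_ else mean(detected),
       n_declared = length(declared), n_planted = length(planted),
       detected = stats::setNames(detected, planted))
}

#' Write a simulated cell cohort to disk
#'
#' Writes the three tables in the dialects the ingest readers consume, plus
#' the ground truth as JSON-like plain text.
#'
#' @param sim Output of [simulate_cell_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cell_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(sim$variants, file.path(dir, "variants.tsv"))
  utils::write.table(sim$copy_number, file.path(dir, "copy_number.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$response, file.path(dir, "response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- sim$truth$planted_pairs
  if (!is.null(pp))
    utils::write.table(pp, file.path(dir, "truth_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a simulated patient cohort to disk
#'
#' @param sim Output of [simulate_patient_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_patient_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$maf, file.path(dir, "cohort.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
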