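test_that("cell-cohort generation is seed-deterministic", {
  cfg <- cell_cohort_config(n_samples = 60, n_genes = 10, seed = 99)
  a <- simulate_cell_cohort(cfg)
  b <- simulate_cell_cohort(cell_cohort_config(n_samples = 60, n_genes = 10,
                                               seed = 99))
  expect_identical(a$variants, b$variants)
  expect_identical(a$copy_number, b$copy_number)
  expect_identical(a$response, b$response)
  c2 <- simulate_cell_cohort(cell_cohort_config(n_samples = 60, n_genes = 10,
                                                seed = 100))
  expect_false(identical(a$response$ln_ic50, c2$response$ln_ic50))
})

test_that("generated events reconstruct the latent disruption matrix exactly", {
  cfg <- cell_cohort_config(n_samples = 80, n_genes = 12,
                            disruption_freq = 0.3, seed = 13)
  sim <- simulate_cell_cohort(cfg)
  # every emitted variant row classifies as disruptive under default rules
  expect_true(all(is_disruptive_variant(sim$variants$consequence,
                                        sim$variants$sift_score) == 1L))
  expect_true(all(sim$copy_number$total_copy_number == 0L))
  m <- build_disruption_matrix(sim$variants, sim$copy_number,
                               samples = cfg$samples, genes = cfg$genes)
  expect_equal(unclass(m)[, ], sim$truth$disruption[, ])
})

test_that("empirical disruption frequency converges to the target", {
  cfg <- cell_cohort_config(n_samples = 5000, n_genes = 4,
                            disruption_freq = c(0.05, 0.15, 0.4, 0.8),
                            seed = 17)
  sim <- simulate_cell_cohort(cfg)
  f_hat <- colMeans(sim$truth$disruption)
  f <- cfg$disruption_freq
  expect_true(all(abs(f_hat - f) <= 3 * sqrt(f * (1 - f) / 5000)))
})

test_that("response model: pure noise without pairs, shifted means with", {
  cfg0 <- cell_cohort_config(n_samples = 2000, n_genes = 6,
                             baseline_mu = -3, noise_sd = 1, seed = 19)
  sim0 <- simulate_cell_cohort(cfg0)
  y <- sim0$response$ln_ic50
  expect_equal(mean(y), -3, tolerance = 3 / sqrt(2000))
  expect_equal(stats::sd(y), 1, tolerance = 0.08)

  cfg1 <- cell_cohort_config(n_samples = 1000, n_genes = 6,
                             disruption_freq = 0.5,
                             planted_pairs = data.frame(gene_a = "G001",
                                                        gene_b = "G002",
                                                        delta = -3),
                             baseline_mu = -3, noise_sd = 1, seed = 23)
  sim1 <- simulate_cell_cohort(cfg1)
  D <- sim1$truth$disruption
  both <- D[, "G001"] == 1 & D[, "G002"] == 1
  y1 <- sim1$response$ln_ic50[match(rownames(D), sim1$response$sample_id)]
  expect_equal(mean(y1[both]), -6, tolerance = 3 / sqrt(sum(both)))
  expect_equal(mean(y1[!both]), -3, tolerance = 3 / sqrt(sum(!both)))

  expect_error(cell_cohort_config(planted_pairs = data.frame(
    gene_a = "G001", gene_b = "ZZZ", delta = -1)), "outside the gene set")
})

test_that("shared-effect drugs reuse deltas, independent drugs do not", {
  cfg <- cell_cohort_config(n_samples = 800, n_genes = 6,
                            disruption_freq = 0.5,
                            planted_pairs = data.frame(gene_a = "G001",
                                                       gene_b = "G002",
                                                       delta = -3),
                            n_drugs = 2, shared_effect_drugs = 1L, seed = 29)
  sim <- simulate_cell_cohort(cfg)
  D <- sim$truth$disruption
  both <- rownames(D)[D[, "G001"] == 1 & D[, "G002"] == 1]
  r2 <- sim$response[sim$response$drug == "drug_02", ]
  gap <- mean(r2$ln_ic50[r2$sample_id %in% both]) -
    mean(r2$ln_ic50[!r2$sample_id %in% both])
  expect_lt(abs(gap), 0.5)  # no planted effect leaks into the second drug
})

test_that("patient cohorts encode the burden-by-anchor hazard and censoring", {
  cfg <- patient_cohort_config(n_patients = 400, seed = 31)
  a <- simulate_patient_cohort(cfg)
  b <- simulate_patient_cohort(patient_cohort_config(n_patients = 400,
                                                     seed = 31))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$maf, b$maf)

  # MAF rows rebuild the latent disruption through the standard ingest path
  path <- withr::local_tempfile(fileext = ".maf")
  utils::write.table(a$maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- read_maf(path)
  m <- build_disruption_matrix(v, NULL, samples = cfg$patients,
                               genes = c(cfg$anchor, cfg$partners))
  expect_equal(unclass(m)[, ], a$truth$disruption[, ])

  # vanishing censoring rate drives the event fraction to one
  cfg2 <- patient_cohort_config(n_patients = 400, censoring_rate = 1e-9,
                                seed = 37)
  expect_gt(mean(simulate_patient_cohort(cfg2)$clinical$os_event), 0.999)

  expect_error(patient_cohort_config(stage_probs = c(0.5, 0.5, 0.1, 0.1)),
               "is not TRUE")
})

test_that("null patient cohorts show no burden effect on survival", {
  set.seed(41)
  rejections <- 0L
  for (k in 1:20) {
    cfg <- patient_cohort_config(n_patients = 200,
                                 hr_per_burden_in_anchor = 1.0,
                                 seed = 1000 + k)
    sim <- simulate_patient_cohort(cfg)
    keep <- sim$truth$anchor_mut == 1L
    d <- data.frame(time = sim$clinical$os_time[keep],
                    status = sim$clinical$os_event[keep],
                    burden = sim$truth$burden[keep])
    if (length(unique(d$burden)) < 2 || sum(d$status) == 0) next
    fit <- firth_coxph(survival::Surv(time, status) ~ burden, d)
    if (fit$p_value[["burden"]] < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)  # ~Binomial(20, 0.05): 4 allows 3 SD slack
})

test_that("recovery metrics treat pairs as unordered and handle edge cases", {
  truth <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                      stringsAsFactors = FALSE)
  hit <- data.frame(gene_a = c("B", "C"), gene_b = c("A", "D"),
                    stringsAsFactors = FALSE)
  m <- recovery_metrics(truth, hit)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  none <- recovery_metrics(truth, hit[0, ])
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)

  extra <- recovery_metrics(truth, rbind(hit, data.frame(gene_a = "X",
                                                         gene_b = "Y")))
  expect_equal(extra$precision, 2 / 3)
})

test_that("cohort writers emit the dialects the ingest readers accept", {
  cfg <- cell_cohort_config(n_samples = 40, n_genes = 6, seed = 43)
  sim <- simulate_cell_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cell_cohort(sim, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  cn <- read_copy_number_table(file.path(dir, "copy_number.tsv"))
  resp <- read_drug_response_table(file.path(dir, "response.tsv"))
  m <- build_disruption_matrix(v, cn, samples = cfg$samples,
                               genes = cfg$genes)
  expect_equal(unclass(m)[, ], sim$truth$disruption[, ])
  expect_equal(nrow(resp), 40L)

  pcfg <- patient_cohort_config(n_patients = 30, seed = 47)
  psim <- simulate_patient_cohort(pcfg)
  write_patient_cohort(psim, dir)
  cl <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(cl), 30L)
  expect_true(all(cl$stage %in% c("I", "II", "III", "IV")))
})
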