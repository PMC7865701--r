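test_that("variant table read/write round-trips and maps dialects", {
  v <- data.frame(sample_id = c("s1", "s2", "s3"),
                  gene = c("TP53", "SYNE2", "SON"),
                  consequence = c("missense_variant", "stop_gained",
                                  "synonymous_variant"),
                  sift_score = c(0.01, NA, 0.7),
                  esp_af = c(NA, 0.0001, NA),
                  kg_af = c(0.001, NA, NA), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path)
  expect_equal(back, v)

  # arbitrary headers through the dialect mapping; extra columns ignored
  alien <- data.frame(CellLine = "s1", Hugo = "TP53", Csq = "stop_gained",
                      junk = "x", stringsAsFactors = FALSE)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(alien, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_variant_table(p2, dialect = c(sample_id = "CellLine",
                                            gene = "Hugo",
                                            consequence = "Csq"))
  expect_equal(got$gene, "TP53")
  expect_true(is.na(got$sift_score))
})

test_that("variant reader rejects bad schemas and bad numerics by position", {
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = "s1", consequence = "stop_gained"),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(p), "gene")

  writeLines(c("sample_id\tgene\tconsequence\tsift_score",
               "s1\tTP53\tmissense_variant\tnot_a_number"), p)
  expect_error(read_variant_table(p), "row 1")

  # empty SIFT cell becomes a missing value, not zero
  writeLines(c("sample_id\tgene\tconsequence\tsift_score",
               "s1\tTP53\tmissense_variant\t"), p)
  expect_true(is.na(read_variant_table(p)$sift_score))
})

test_that("MAF reading maps classifications and flags unknown tokens", {
  p <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("#version 2.4",
               "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tSIFT",
               "TP53\tpt1\tNonsense_Mutation\t",
               "SYNE2\tpt1\tMissense_Mutation\tdeleterious(0.01)",
               "SON\tpt2\tSilent\t0.4",
               "KRAS\tpt2\tWeird_Class\t"), p)
  expect_warning(v <- read_maf(p), "Weird_Class")
  expect_equal(v$consequence,
               c("stop_gained", "missense_variant", "synonymous_variant",
                 "other"))
  expect_equal(v$sift_score, c(NA, 0.01, 0.4, NA))
  expect_equal(v$sample_id, c("pt1", "pt1", "pt2", "pt2"))
})

test_that("population-frequency filter keeps rare/missing, drops common", {
  v <- data.frame(sample_id = "s", gene = "g",
                  consequence = "missense_variant", sift_score = NA_real_,
                  esp_af = c(0.01, NA, 0.0001, NA),
                  kg_af = c(NA, NA, 0.001, 0.5), stringsAsFactors = FALSE)
  out <- filter_population_variants(v)
  # 0.01 >= 0.00025 removed; both-missing kept; 0.0001/0.001 below both
  # cutoffs kept; kg 0.5 removed
  expect_equal(nrow(out), 2L)
  expect_equal(out$esp_af, c(NA, 0.0001))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n[rep$step == "input"], 4L)
  expect_equal(rep$n[rep$step == "retained"], 2L)
  expect_equal(sum(rep$n[rep$step %in% c("removed_esp", "removed_kg")]), 2L)

  # idempotence and subset property
  again <- filter_population_variants(out)
  expect_equal(again[, names(v)], out[, names(v)], ignore_attr = TRUE)
  expect_true(all(do.call(paste, out[1:3]) %in% do.call(paste, v[1:3])))

  # thresholds of 1.0 make the filter the identity
  all_kept <- filter_population_variants(v, esp_max = 1, kg_max = 1)
  expect_equal(nrow(all_kept), nrow(v))

  expect_error(filter_population_variants(v, esp_max = -0.1), "thresholds")
})

test_that("other table readers validate their contracts", {
  p <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = "s1", gene = "g1",
                                total_copy_number = 0),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  cn <- read_copy_number_table(p)
  expect_identical(cn$total_copy_number, 0L)

  utils::write.table(data.frame(sample_id = "s1", gene = "g1",
                                total_copy_number = -1),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_copy_number_table(p), "non-negative")

  utils::write.table(data.frame(sample_id = "s1", drug = "paclitaxel",
                                ln_ic50 = -3.2),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_drug_response_table(p)$ln_ic50, -3.2)

  utils::write.table(data.frame(patient_id = "p1", os_time = 120,
                                os_event = 1, stage = "II"),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- read_clinical_table(p)
  expect_equal(cl$os_event, 1L)
  expect_equal(cl$stage, "II")

  utils::write.table(data.frame(patient_id = "p1", os_time = -5, os_event = 1),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical_table(p), "non-negative")
})
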