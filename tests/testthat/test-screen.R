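make_matrix <- function(status, samples = sprintf("s%02d", seq_len(nrow(status)))) {
  m <- matrix(as.integer(status), nrow(status), ncol(status),
              dimnames = list(samples, colnames(status)))
  structure(m, class = c("disruption_matrix", class(m)))
}

test_that("pair partition routes the 2x2 statuses exhaustively", {
  st <- cbind(gA = c(1, 1, 0, 0), gB = c(1, 0, 1, 0))
  m <- make_matrix(st)
  p <- partition_by_pair(m, "gA", "gB")
  expect_equal(p$both, "s01")
  expect_equal(p$a_only, "s02")
  expect_equal(p$b_only, "s03")
  expect_equal(p$neither, "s04")
  expect_setequal(c(p$both, p$a_only, p$b_only, p$neither), rownames(m))

  all0 <- make_matrix(cbind(gA = rep(0, 4), gB = rep(0, 4)))
  p0 <- partition_by_pair(all0, "gA", "gB")
  expect_equal(length(p0$neither), 4L)
  expect_equal(lengths(p0[c("both", "a_only", "b_only")]),
               c(both = 0L, a_only = 0L, b_only = 0L))

  # column order in the matrix is irrelevant
  p_swapcols <- partition_by_pair(m[, c("gB", "gA")], "gA", "gB")
  expect_equal(p_swapcols, p)

  expect_error(partition_by_pair(m, "gA", "gA"), "differ")
  expect_error(partition_by_pair(m, "gA", "gX"), "gX")
})

test_that("pairs with an under-occupied group are reported untested", {
  set.seed(21)
  n <- 407
  st <- cbind(gA = rbinom(n, 1, 0.3), gB = rbinom(n, 1, 0.3))
  # force exactly 10 jointly disrupted samples: below ceiling(0.025*407)=11
  both_idx <- which(st[, 1] == 1 & st[, 2] == 1)
  st[both_idx[-seq_len(10)], 2] <- 0
  m <- make_matrix(st, sprintf("s%03d", 1:n))
  y <- stats::setNames(rnorm(n), rownames(m))
  res <- evaluate_pair(m, y, "gA", "gB")
  expect_equal(res$n_both, 10L)
  expect_false(res$tested)
  expect_equal(res$is_sc, 0L)
  expect_true(is.na(res$p_vs_neither))
})

test_that("a strongly sensitising planted pair is declared SC", {
  set.seed(22)
  n <- 400
  st <- cbind(gA = rbinom(n, 1, 0.4), gB = rbinom(n, 1, 0.4))
  m <- make_matrix(st, sprintf("s%03d", 1:n))
  both <- st[, 1] == 1 & st[, 2] == 1
  y <- stats::setNames(rnorm(n, -3) - 3 * both, rownames(m))
  res <- evaluate_pair(m, y, "gA", "gB")
  expect_true(res$tested)
  expect_equal(res$is_sc, 1L)
  expect_true(all(unlist(res[c("p_vs_a_only", "p_vs_b_only",
                               "p_vs_neither")]) < 0.05))
  expect_equal(res$median_both,
               min(unlist(res[c("median_both", "median_a_only",
                                "median_b_only", "median_neither")])))
})

test_that("median direction requirement vetoes pairs with a high both-group", {
  set.seed(23)
  n <- 400
  st <- cbind(gA = rbinom(n, 1, 0.4), gB = rbinom(n, 1, 0.4))
  m <- make_matrix(st, sprintf("s%03d", 1:n))
  both <- st[, 1] == 1 & st[, 2] == 1
  y <- stats::setNames(rnorm(n, -3) + 3 * both, rownames(m))  # desensitising
  res <- evaluate_pair(m, y, "gA", "gB",
                       params = screen_params(alternative = "two.sided"))
  # the two-sided p-values are tiny, yet the direction rule blocks SC
  expect_true(all(unlist(res[c("p_vs_a_only", "p_vs_b_only",
                               "p_vs_neither")]) < 0.05))
  expect_equal(res$is_sc, 0L)
})

test_that("scan evaluates each unordered pair once, in stable order", {
  set.seed(24)
  n <- 200
  st <- sapply(1:3, function(i) rbinom(n, 1, 0.4))
  colnames(st) <- c("gC", "gA", "gB")
  m <- make_matrix(st, sprintf("s%03d", 1:n))
  y <- stats::setNames(rnorm(n), rownames(m))
  scr <- sc_screen(m, y)
  expect_equal(nrow(scr$pairs), 3L)  # C(3,2)
  expect_equal(scr$pairs$gene_a, c("gA", "gA", "gB"))
  expect_equal(scr$pairs$gene_b, c("gB", "gC", "gC"))

  # sample/gene input order never changes the result
  perm <- sample(n)
  scr2 <- sc_screen(m[perm, c("gB", "gC", "gA")], y)
  expect_equal(scr2$pairs, scr$pairs)

  # no gene passes the frequency filter -> empty result with a warning
  rare <- make_matrix(cbind(gA = c(1, rep(0, n - 1)),
                            gB = c(1, rep(0, n - 1))),
                      sprintf("s%03d", 1:n))
  expect_warning(scr0 <- sc_screen(rare, y), "frequency filter")
  expect_equal(nrow(scr0$pairs), 0L)
})

test_that("screen objects print, summarise and serialise", {
  set.seed(25)
  cfg <- cell_cohort_config(n_samples = 150, n_genes = 8,
                            disruption_freq = 0.4,
                            planted_pairs = data.frame(gene_a = "G001",
                                                       gene_b = "G002",
                                                       delta = -3),
                            seed = 5)
  sim <- simulate_cell_cohort(cfg)
  m <- build_disruption_matrix(sim$variants, sim$copy_number,
                               samples = cfg$samples, genes = cfg$genes)
  scr <- sc_screen(m, sim$response, drug = "drug_01")
  expect_output(print(scr), "SC screen")
  s <- summary(scr)
  expect_output(print(s), "SC pairs declared")
  expect_equal(s$n_pairs, choose(8, 2))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_sc_pairs(scr, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(scr$pairs))
  expect_true(file.exists(paste0(path, ".manifest.json")))
  expect_match(readLines(paste0(path, ".manifest.json")), "\"alpha\": 0.05")
})

test_that("Benjamini-Hochberg switch only ever prunes the declared set", {
  set.seed(26)
  cfg <- cell_cohort_config(n_samples = 300, n_genes = 12,
                            disruption_freq = 0.35,
                            planted_pairs = data.frame(
                              gene_a = c("G001", "G003"),
                              gene_b = c("G002", "G004"),
                              delta = -3), seed = 6)
  sim <- simulate_cell_cohort(cfg)
  m <- build_disruption_matrix(sim$variants, sim$copy_number,
                               samples = cfg$samples, genes = cfg$genes)
  raw <- sc_screen(m, sim$response, drug = "drug_01")
  bh <- sc_screen(m, sim$response, drug = "drug_01",
                  params = screen_params(p_adjust = "BH"))
  key <- function(d) paste(d$gene_a, d$gene_b)
  expect_true(all(key(sc_pairs(bh)) %in% key(sc_pairs(raw))))
})
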