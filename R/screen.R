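#' Screen parameters
#'
#' Bundles the tunable parameters of the SC screen: the per-test
#' significance level, the gene-level disruption-frequency filter (strictly
#' more than 5% of samples by default), the minimum group occupancy
#' (at least `ceiling(min_group_frac * n)` samples in each of the four
#' groups), the test direction, and the exact-branch cutoff of
#' [rank_sum_test()].
#'
#' @param alpha Per-test significance level.
#' @param min_gene_freq Gene disruption-frequency filter (strict `>`).
#' @param min_group_frac Minimum fraction of samples required in every one
#'   of the four partition groups for a pair to be tested.
#' @param alternative `"less"` for one-sided tests of the jointly disrupted
#'   group being more sensitive (the default reading), or `"two.sided"` for
#'   two-sided tests combined with the median-direction requirement.
#' @param exact_cutoff Passed to [rank_sum_test()].
#' @param p_adjust Multiple-testing adjustment applied across pairs to the
#'   maximum of the three p-values before calling a pair SC; `"none"`
#'   (default, raw p-values) or any method of [stats::p.adjust()].
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(alpha = 0.05, min_gene_freq = 0.05,
                          min_group_frac = 0.025,
                          alternative = c("less", "two.sided"),
                          exact_cutoff = 25, p_adjust = "none") {
  alternative <- match.arg(alternative)
  stopifnot(alpha > 0, alpha < 1, min_gene_freq > 0, min_gene_freq < 1,
            min_group_frac > 0, min_group_frac < 1, exact_cutoff >= 1)
  structure(list(alpha = alpha, min_gene_freq = min_gene_freq,
                 min_group_frac = min_group_frac, alternative = alternative,
                 exact_cutoff = exact_cutoff, p_adjust = p_adjust),
            class = "screen_params")
}

#' Partition samples by the disruption status of a gene pair
#'
#' Routes every sample into one of four disjoint groups by the 2x2
#' disruption status of the pair: `both`, `a_only`, `b_only`, `neither`.
#'
#' @param m A `disruption_matrix`.
#' @param gene_a,gene_b Distinct gene symbols present in `m`.
#' @return A list of class `pair_partition` with the four sample-identifier
#'   vectors and the gene names.
#' @export
partition_by_pair <- function(m, gene_a, gene_b) {
  if (identical(gene_a, gene_b)) stop("gene_a and gene_b must differ")
  for (g in c(gene_a, gene_b))
    if (!g %in% colnames(m)) stop("gene not in matrix: ", g)
  a <- m[, gene_a] == 1L
  b <- m[, gene_b] == 1L
  s <- rownames(m)
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 both = s[a & b], a_only = s[a & !b],
                 b_only = s[!a & b], neither = s[!a & !b]),
            class = "pair_partition")
}

# Minimum per-group occupancy for a cohort of n samples.
min_group_size <- function(n, min_group_frac) ceiling(min_group_frac * n)

#' Evaluate one gene pair for synthetic cytotoxicity
#'
#' Partitions the response-bearing samples by the pair's disruption status
#' and runs the rank-sum comparison three times: the jointly disrupted group
#' against each of the other three. The pair is SC when all three p-values
#' fall below `alpha` and the jointly disrupted group's median ln IC50 is
#' strictly the lowest of the four. Pairs with any group below the occupancy
#' minimum are returned untested (`tested = FALSE`, p-values `NA`).
#'
#' @param m A `disruption_matrix`.
#' @param response Either a named numeric vector of ln IC50 keyed by sample
#'   identifier, or a `data.frame` with `sample_id` and `ln_ic50` columns
#'   for a single drug. Samples without a response are excluded before
#'   partitioning.
#' @param gene_a,gene_b Distinct gene symbols in `m`.
#' @param params A [screen_params()] object.
#' @return A one-row `data.frame` with the group sizes, the four group
#'   medians of ln IC50, the three p-values (both vs a_only / b_only /
#'   neither), `tested` and `is_sc`.
#' @export
evaluate_pair <- function(m, response, gene_a, gene_b,
                          params = screen_params()) {
  y <- as_response_vector(response)
  keep <- rownames(m) %in% names(y)
  mm <- m[keep, , drop = FALSE]
  y <- y[rownames(mm)]
  part <- partition_by_pair(mm, gene_a, gene_b)
  evaluate_partition(part, y, params)
}

as_response_vector <- function(response) {
  if (is.data.frame(response)) {
    if (!all(c("sample_id", "ln_ic50") %in% names(response)))
      stop("response data.frame needs sample_id and ln_ic50 columns")
    if ("drug" %in% names(response) && length(unique(response$drug)) > 1L)
      stop("response table contains several drugs; subset to one first")
    if (anyDuplicated(response$sample_id))
      stop("duplicate sample_id in response table")
    stats::setNames(response$ln_ic50, response$sample_id)
  } else {
    if (is.null(names(response))) stop("response vector must be named by sample")
    response
  }
}

empty_pair_table <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             n_both = integer(), n_a_only = integer(),
             n_b_only = integer(), n_neither = integer(),
             median_both = numeric(), median_a_only = numeric(),
             median_b_only = numeric(), median_neither = numeric(),
             p_vs_a_only = numeric(), p_vs_b_only = numeric(),
             p_vs_neither = numeric(), tested = logical(),
             is_sc = integer(), stringsAsFactors = FALSE)
}

# Core per-pair evaluation on an already-aligned partition + response vector.
evaluate_partition <- function(part, y, params) {
  n <- length(y)
  groups <- lapply(part[c("both", "a_only", "b_only", "neither")],
                   function(s) unname(y[s]))
  sizes <- lengths(groups)
  row <- data.frame(gene_a = part$gene_a, gene_b = part$gene_b,
                    n_both = sizes[[1]], n_a_only = sizes[[2]],
                    n_b_only = sizes[[3]], n_neither = sizes[[4]],
                    median_both = NA_real_, median_a_only = NA_real_,
                    median_b_only = NA_real_, median_neither = NA_real_,
                    p_vs_a_only = NA_real_, p_vs_b_only = NA_real_,
                    p_vs_neither = NA_real_,
                    tested = FALSE, is_sc = 0L, stringsAsFactors = FALSE)
  med <- vapply(groups, function(g) if (length(g)) stats::median(g) else NA_real_,
                numeric(1))
  row[, c("median_both", "median_a_only", "median_b_only", "median_neither")] <-
    as.list(med)
  if (any(sizes < min_group_size(n, params$min_group_frac))) return(row)
  p <- vapply(groups[2:4], function(g)
    rank_sum_test(groups[[1]], g, alternative = params$alternative,
                  exact_cutoff = params$exact_cutoff)$p_value, numeric(1))
  row[, c("p_vs_a_only", "p_vs_b_only", "p_vs_neither")] <- as.list(p)
  row$tested <- TRUE
  row$is_sc <- as.integer(all(p < params$alpha) && all(med[1] < med[2:4]))
  row
}

#' Screen all gene pairs for synthetic cytotoxicity
#'
#' The package's core fit. Restricts the disruption matrix to samples with a
#' response for the chosen drug, keeps genes disrupted in strictly more than
#' `min_gene_freq` of those samples, and evaluates every unordered pair of
#' the surviving genes with [evaluate_pair()]. Output order is
#' lexicographic in the gene symbols and independent of input row/column
#' order.
#'
#' @param m A `disruption_matrix`.
#' @param response Drug-response table (`sample_id`, `drug`, `ln_ic50`) or a
#'   named ln IC50 vector for a single drug.
#' @param drug Drug to screen when `response` covers several drugs.
#' @param params A [screen_params()] object.
#' @return An object of class `sc_screen`: a list with `pairs` (one row per
#'   evaluated pair, see [evaluate_pair()]), `params`, `drug`, `n_samples`,
#'   `genes` (the frequency-passing genes) and `gene_freq`.
#' @export
sc_screen <- function(m, response, drug = NULL, params = screen_params()) {
  if (is.data.frame(response) && "drug" %in% names(response) &&
      !is.null(drug))
    response <- response[response$drug == drug, , drop = FALSE]
  y <- as_response_vector(response)
  keep <- rownames(m) %in% names(y)
  mm <- m[keep, , drop = FALSE]
  mm <- mm[sort(rownames(mm)), sort(colnames(mm)), drop = FALSE]
  y <- y[rownames(mm)]
  n <- nrow(mm)
  freq <- gene_disruption_frequency(mm)
  genes <- names(freq)[freq > params$min_gene_freq]
  if (length(genes) < 2L) {
    warning("fewer than two genes pass the disruption-frequency filter")
    pairs <- empty_pair_table()
  } else {
    min_n <- min_group_size(n, params$min_group_frac)
    cols <- mm[, genes, drop = FALSE] == 1L
    idx <- utils::combn(length(genes), 2L)
    rows <- vector("list", ncol(idx))
    for (k in seq_len(ncol(idx))) {
      a <- cols[, idx[1L, k]]; b <- cols[, idx[2L, k]]
      part <- structure(list(gene_a = genes[idx[1L, k]],
                             gene_b = genes[idx[2L, k]],
                             both = rownames(mm)[a & b],
                             a_only = rownames(mm)[a & !b],
                             b_only = rownames(mm)[!a & b],
                             neither = rownames(mm)[!a & !b]),
                        class = "pair_partition")
      rows[[k]] <- evaluate_partition(part, y, params)
    }
    pairs <- do.call(rbind, rows)
    rownames(pairs) <- NULL
    if (params$p_adjust != "none") {
      pmax3 <- pmax(pairs$p_vs_a_only, pairs$p_vs_b_only, pairs$p_vs_neither)
      padj <- stats::p.adjust(pmax3, method = params$p_adjust)
      med_ok <- pairs$median_both < pairs$median_a_only &
        pairs$median_both < pairs$median_b_only &
        pairs$median_both < pairs$median_neither
      pairs$is_sc <- as.integer(pairs$tested & !is.na(padj) &
                                  padj < params$alpha & med_ok)
    }
  }
  structure(list(pairs = pairs, params = params,
                 drug = if (is.null(drug)) NA_character_ else drug,
                 n_samples = n, genes = genes, gene_freq = freq),
            class = "sc_screen")
}

#' Extract the declared SC pairs from a screen
#'
#' @param x An `sc_screen` object.
#' @return The subset of the pair table with `is_sc == 1`.
#' @export
sc_pairs <- function(x) {
  stopifnot(inherits(x, "sc_screen"))
  x$pairs[x$pairs$is_sc == 1L, , drop = FALSE]
}

#' @export
print.sc_screen <- function(x, ...) {
  cat("SC screen", if (!is.na(x$drug)) paste0(" (", x$drug, ")"), ": ",
      x$n_samples, " samples, ", length(x$genes),
      " genes past the frequency filter\n", sep = "")
  cat("  pairs evaluated: ", nrow(x$pairs), "; tested: ", sum(x$pairs$tested),
      "; SC: ", sum(x$pairs$is_sc), "\n", sep = "")
  invisible(x)
}

#' @export
summary.sc_screen <- function(object, ...) {
  sc <- sc_pairs(object)
  out <- list(n_samples = object$n_samples,
              n_genes = length(object$genes),
              n_pairs = nrow(object$pairs),
              n_tested = sum(object$pairs$tested),
              n_sc = nrow(sc),
              sc_genes = sort(unique(c(sc$gene_a, sc$gene_b))),
              params = object$params)
  class(out) <- "summary.sc_screen"
  out
}

#' @export
print.summary.sc_screen <- function(x, ...) {
  cat("SC screen summary\n")
  cat("  samples:            ", x$n_samples, "\n")
  cat("  genes screened:     ", x$n_genes, "\n")
  cat("  pairs tested:       ", x$n_tested, "/", x$n_pairs, "\n")
  cat("  SC pairs declared:  ", x$n_sc, " (", length(x$sc_genes),
      " distinct genes)\n", sep = "")
  invisible(x)
}

#' @description Plotting a screen draws the four-group ln IC50 boxplot for
#' one gene pair (by default the SC pair with the smallest worst-case
#' p-value) — the per-pair view underlying the screen's decision rule.
#' @param x An `sc_screen` object.
#' @param pair Optional `c(gene_a, gene_b)` selecting the pair to draw.
#' @param response The response used for the screen (named vector or
#'   single-drug table), needed to reconstruct the group values.
#' @param m The `disruption_matrix` the screen was run on.
#' @param ... Passed to [graphics::boxplot()].
#' @rdname sc_screen
#' @export
plot.sc_screen <- function(x, m, response, pair = NULL, ...) {
  if (is.null(pair)) {
    sc <- sc_pairs(x)
    if (nrow(sc) == 0L) stop("no SC pairs to plot; supply `pair`")
    worst <- pmax(sc$p_vs_a_only, sc$p_vs_b_only, sc$p_vs_neither)
    best <- sc[which.min(worst), ]
    pair <- c(best$gene_a, best$gene_b)
  }
  y <- as_response_vector(response)
  mm <- m[rownames(m) %in% names(y), , drop = FALSE]
  part <- partition_by_pair(mm, pair[1], pair[2])
  groups <- lapply(part[c("both", "a_only", "b_only", "neither")],
                   function(s) unname(y[s]))
  names(groups) <- c("both", paste0(pair[1], " only"),
                     paste0(pair[2], " only"), "neither")
  graphics::boxplot(groups, ylab = "ln IC50",
                    main = paste(pair[1], "x", pair[2]), ...)
  invisible(x)
}

#' Write the SC pair table and a screen manifest
#'
#' The pair table goes to `path` as TSV; the screen parameters are recorded
#' alongside in `<path>.manifest.json` for reproducibility.
#'
#' @param x An `sc_screen` object.
#' @param path Output TSV path.
#' @export
write_sc_pairs <- function(x, path) {
  stopifnot(inherits(x, "sc_screen"))
  utils::write.table(x$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- x$params
  manifest <- sprintf(
    paste0('{"drug": "%s", "n_samples": %d, "alpha": %s, "min_gene_freq": %s, ',
           '"min_group_frac": %s, "alternative": "%s", "exact_cutoff": %d, ',
           '"p_adjust": "%s"}'),
    x$drug, x$n_samples, format(p$alpha), format(p$min_gene_freq),
    format(p$min_group_frac), p$alternative, as.integer(p$exact_cutoff),
    p$p_adjust)
  writeLines(manifest, paste0(path, ".manifest.json"))
  invisible(path)
}
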