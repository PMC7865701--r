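#' Per-sample SC burden
#'
#' The SC burden of a sample is the number of declared SC pairs whose two
#' genes are both disrupted in that sample.
#'
#' @param m A `disruption_matrix`.
#' @param pairs Either an `sc_screen` object (its declared SC pairs are
#'   used) or a `data.frame` with `gene_a` and `gene_b` columns.
#' @return Named integer vector of burdens, one per sample of `m`.
#' @export
compute_burden <- function(m, pairs) {
  if (inherits(pairs, "sc_screen")) pairs <- sc_pairs(pairs)
  if (nrow(pairs) == 0L)
    return(stats::setNames(integer(nrow(m)), rownames(m)))
  absent <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), colnames(m))
  if (length(absent) > 0L)
    stop("pair gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  hit <- mapply(function(a, b) m[, a] & m[, b], pairs$gene_a, pairs$gene_b)
  hit <- matrix(hit, nrow = nrow(m))
  stats::setNames(as.integer(rowSums(hit)), rownames(m))
}

#' Assign SC-burden groups
#'
#' Bins burdens into the four categorical groups: with the default
#' breakpoints `c(0, 2, 9)`, G1 holds samples with no SC pair, G2 one to
#' two, G3 three to nine, and G4 more than nine.
#'
#' @param burden Named integer vector from [compute_burden()].
#' @param breakpoints Strictly increasing non-negative integers; group i
#'   holds burdens in `(breakpoints[i-1], breakpoints[i]]` with G1 =
#'   `[0, breakpoints[1]]` and the last group open-ended.
#' @return A `data.frame` with `sample_id`, `burden` and `group` (factor
#'   G1..G4 with all levels present).
#' @export
assign_burden_groups <- function(burden, breakpoints = c(0, 2, 9)) {
  if (any(breakpoints < 0) || any(diff(breakpoints) <= 0) ||
      any(breakpoints != floor(breakpoints)))
    stop("breakpoints must be strictly increasing non-negative integers")
  labels <- paste0("G", seq_len(length(breakpoints) + 1L))
  grp <- cut(burden, breaks = c(-Inf, breakpoints, Inf), labels = labels)
  data.frame(sample_id = names(burden), burden = unname(burden),
             group = grp, stringsAsFactors = FALSE)
}

#' Compare drug response across burden groups
#'
#' Kruskal-Wallis comparison of ln IC50 across the populated burden groups,
#' plus per-group medians — the burden-versus-sensitivity summary.
#'
#' @param assignments Output of [assign_burden_groups()].
#' @param response Response table (`sample_id`, `ln_ic50`, optional `drug`)
#'   or named ln IC50 vector for one drug.
#' @param drug Optional drug to subset a multi-drug table.
#' @return A [kruskal_wallis()] result over the populated groups (in G1..G4
#'   order).
#' @export
burden_response_test <- function(assignments, response, drug = NULL) {
  if (is.data.frame(response) && "drug" %in% names(response) && !is.null(drug))
    response <- response[response$drug == drug, , drop = FALSE]
  y <- as_response_vector(response)
  common <- assignments$sample_id %in% names(y)
  if (!any(common)) stop("no overlap between burden assignments and responses")
  a <- assignments[common, , drop = FALSE]
  groups <- split(unname(y[a$sample_id]), a$group, drop = TRUE)
  kruskal_wallis(groups)
}

#' Cross-drug burden robustness test
#'
#' For each requested drug, compares ln IC50 between consecutive populated
#' burden groups (G1 vs G2, G2 vs G3, G3 vs G4) with one-sided rank-sum
#' tests of the higher-burden group being more sensitive. Groups without
#' response data are skipped with a note in the output.
#'
#' @param assignments Output of [assign_burden_groups()].
#' @param response Multi-drug response table (`sample_id`, `drug`,
#'   `ln_ic50`).
#' @param drugs Drugs to test; defaults to every drug in the table.
#' @param alternative Direction for the rank-sum test of the higher-burden
#'   group's ln IC50 against the lower's; `"greater"` means the lower-burden
#'   group tends to have the higher ln IC50 (less sensitive), the expected
#'   pattern.
#' @return A `data.frame` with `drug`, `comparison`, `n_low`, `n_high`,
#'   `median_low`, `median_high`, `p_value`.
#' @export
cross_drug_burden_test <- function(assignments, response, drugs = NULL,
                                   alternative = "greater") {
  stopifnot(is.data.frame(response),
            all(c("sample_id", "drug", "ln_ic50") %in% names(response)))
  if (is.null(drugs)) drugs <- sort(unique(response$drug))
  out <- list()
  for (d in drugs) {
    rd <- response[response$drug == d, , drop = FALSE]
    y <- as_response_vector(rd)
    a <- assignments[assignments$sample_id %in% names(y), , drop = FALSE]
    if (nrow(a) == 0L) stop("no overlap between assignments and responses for drug ", d)
    groups <- split(unname(y[a$sample_id]), a$group, drop = TRUE)
    populated <- names(groups)[lengths(groups) > 0L]
    if (length(populated) < 2L)
      stop("fewer than two populated burden groups for drug ", d)
    for (k in seq_len(length(populated) - 1L)) {
      lo <- populated[k]; hi <- populated[k + 1L]
      rt <- rank_sum_test(groups[[lo]], groups[[hi]],
                          alternative = alternative)
      out[[length(out) + 1L]] <- data.frame(
        drug = d, comparison = paste(lo, "vs", hi),
        n_low = length(groups[[lo]]), n_high = length(groups[[hi]]),
        median_low = stats::median(groups[[lo]]),
        median_high = stats::median(groups[[hi]]),
        p_value = rt$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write burden assignments as TSV
#'
#' @param assignments Output of [assign_burden_groups()].
#' @param path Output TSV path.
#' @export
write_burden_table <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Boxplot of response by burden group
#'
#' @param assignments Output of [assign_burden_groups()].
#' @param response Response table or named vector for one drug.
#' @param drug Optional drug to subset.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_burden_response <- function(assignments, response, drug = NULL, ...) {
  if (is.data.frame(response) && "drug" %in% names(response) && !is.null(drug))
    response <- response[response$drug == drug, , drop = FALSE]
  y <- as_response_vector(response)
  a <- assignments[assignments$sample_id %in% names(y), , drop = FALSE]
  graphics::boxplot(unname(y[a$sample_id]) ~ droplevels(a$group),
                    xlab = "SC burden group", ylab = "ln IC50", ...)
  invisible(NULL)
}
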