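#' Default loss-of-function consequence set
#'
#' Nonsense, frameshift, start-loss and splice-site-region terms. The splice
#' set includes `splice_region_variant` in addition to the canonical
#' donor/acceptor terms; pass your own set to [is_disruptive_variant()] or
#' [build_disruption_matrix()] for the narrower reading.
#'
#' @return Character vector of consequence terms.
#' @export
lof_consequences <- function() {
  c("stop_gained", "frameshift_variant", "start_lost",
    "splice_acceptor_variant", "splice_donor_variant",
    "splice_region_variant")
}

#' Classify a variant as disruptive
#'
#' A variant disrupts its gene when it is an intolerant missense change
#' (SIFT strictly below `sift_threshold`) or a loss-of-function consequence.
#' Missense variants with a missing SIFT score are not disruptive.
#'
#' @param consequence Character vector of consequence terms.
#' @param sift_score Numeric vector of SIFT scores (`NA` allowed).
#' @param sift_threshold Intolerance cutoff, default 0.05 (strict `<`).
#' @param lof Set of loss-of-function consequence terms.
#' @return Integer vector of 0/1 flags.
#' @examples
#' is_disruptive_variant("missense_variant", 0.03)  # 1
#' is_disruptive_variant("missense_variant", 0.05)  # 0: strict inequality
#' is_disruptive_variant("stop_gained", NA)         # 1
#' @export
is_disruptive_variant <- function(consequence, sift_score = NA_real_,
                                  sift_threshold = 0.05,
                                  lof = lof_consequences()) {
  if (length(lof) == 0L) stop("lof consequence set must be non-empty")
  n <- max(length(consequence), length(sift_score))
  consequence <- rep_len(consequence, n)
  sift_score <- rep_len(sift_score, n)
  intolerant_missense <- consequence == "missense_variant" &
    !is.na(sift_score) & sift_score < sift_threshold
  as.integer(intolerant_missense | consequence %in% lof)
}

#' Classify a copy-number state as disruptive
#'
#' Only homozygous deletions (total copy number exactly 0) disrupt a gene;
#' heterozygous losses and amplifications do not.
#'
#' @param total_copy_number Non-negative integer vector.
#' @return Integer vector of 0/1 flags.
#' @export
is_disruptive_copy_number <- function(total_copy_number) {
  if (any(total_copy_number < 0)) stop("total_copy_number must be non-negative")
  as.integer(total_copy_number == 0)
}

#' Build the binary disruption matrix
#'
#' Assembles the samples-by-genes binary matrix at the heart of the screen:
#' cell (s, g) is 1 iff at least one disruptive event — an intolerant
#' missense or loss-of-function variant, or a homozygous deletion — is
#' recorded for sample s in gene g. Samples with no events keep all-zero
#' rows (absence of evidence is not disruption).
#'
#' @param variants Variant `data.frame` ([read_variant_table()] layout), or
#'   `NULL`.
#' @param cnv Copy-number `data.frame` ([read_copy_number_table()] layout),
#'   or `NULL`.
#' @param samples Character vector of sample identifiers defining the row
#'   order. Event records for samples outside this set are dropped with a
#'   warning.
#' @param genes Character vector of gene symbols defining the column order,
#'   or `"auto"` (the union of genes seen in either input, sorted).
#' @param sift_threshold,lof Passed to [is_disruptive_variant()].
#' @return A `disruption_matrix`: an integer matrix with `dimnames`
#'   (samples, genes) and attribute `"provenance"`, a character matrix over
#'   the same dimnames with values `"none"`, `"variant"`, `"copy_number"` or
#'   `"both"`.
#' @export
build_disruption_matrix <- function(variants = NULL, cnv = NULL, samples,
                                    genes = "auto", sift_threshold = 0.05,
                                    lof = lof_consequences()) {
  if (length(samples) == 0L) stop("sample list must be non-empty")
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  var_hits <- if (!is.null(variants) && nrow(variants) > 0L) {
    d <- is_disruptive_variant(variants$consequence, variants$sift_score,
                               sift_threshold, lof) == 1L
    variants[d, c("sample_id", "gene"), drop = FALSE]
  } else data.frame(sample_id = character(), gene = character())
  cnv_hits <- if (!is.null(cnv) && nrow(cnv) > 0L) {
    d <- is_disruptive_copy_number(cnv$total_copy_number) == 1L
    cnv[d, c("sample_id", "gene"), drop = FALSE]
  } else data.frame(sample_id = character(), gene = character())

  if (identical(genes, "auto")) {
    pool <- c(if (!is.null(variants)) variants$gene,
              if (!is.null(cnv)) cnv$gene)
    genes <- sort(unique(pool))
  }
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")

  unknown <- setdiff(unique(c(var_hits$sample_id, cnv_hits$sample_id)), samples)
  if (length(unknown) > 0L) {
    warning("dropping event records for ", length(unknown),
            " sample(s) outside the sample list")
    var_hits <- var_hits[var_hits$sample_id %in% samples, , drop = FALSE]
    cnv_hits <- cnv_hits[cnv_hits$sample_id %in% samples, , drop = FALSE]
  }
  var_hits <- var_hits[var_hits$gene %in% genes, , drop = FALSE]
  cnv_hits <- cnv_hits[cnv_hits$gene %in% genes, , drop = FALSE]

  m_var <- matrix(0L, length(samples), length(genes),
                  dimnames = list(samples, genes))
  m_cnv <- m_var
  if (nrow(var_hits) > 0L)
    m_var[cbind(match(var_hits$sample_id, samples),
                match(var_hits$gene, genes))] <- 1L
  if (nrow(cnv_hits) > 0L)
    m_cnv[cbind(match(cnv_hits$sample_id, samples),
                match(cnv_hits$gene, genes))] <- 1L

  m <- pmax(m_var, m_cnv)
  prov <- matrix("none", length(samples), length(genes),
                 dimnames = list(samples, genes))
  prov[m_var == 1L] <- "variant"
  prov[m_cnv == 1L] <- "copy_number"
  prov[m_var == 1L & m_cnv == 1L] <- "both"
  structure(m, provenance = prov, class = c("disruption_matrix", class(m)))
}

#' @export
print.disruption_matrix <- function(x, ...) {
  cat("Disruption matrix: ", nrow(x), " samples x ", ncol(x), " genes, ",
      sum(x), " disrupted cells (",
      format(100 * mean(x), digits = 3), "%)\n", sep = "")
  invisible(x)
}

#' Per-gene disruption frequency
#'
#' @param m A `disruption_matrix` (or any binary samples-by-genes matrix).
#' @return Named numeric vector: fraction of samples with each gene
#'   disrupted.
#' @export
gene_disruption_frequency <- function(m) {
  if (nrow(m) < 1L) stop("matrix must have at least one sample")
  colMeans(m)
}

#' Serialize / read a disruption matrix as TSV
#'
#' Rows are samples, columns genes, cells 0/1; the provenance matrix is
#' written alongside as `<path>.provenance.tsv`.
#'
#' @param m A `disruption_matrix`.
#' @param path Output TSV path.
#' @export
write_disruption_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(m, "provenance")
  if (!is.null(prov)) {
    pdf <- data.frame(sample_id = rownames(m), as.data.frame(prov),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(pdf, paste0(path, ".provenance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_disruption_matrix
#' @return `read_disruption_matrix()` returns the `disruption_matrix`
#'   (provenance re-attached when the sidecar file exists).
#' @export
read_disruption_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  if (!all(m %in% c(0L, 1L))) stop("disruption matrix cells must be 0/1")
  side <- paste0(path, ".provenance.tsv")
  prov <- NULL
  if (file.exists(side)) {
    pdf <- utils::read.table(side, header = TRUE, sep = "\t", quote = "",
                             check.names = FALSE, stringsAsFactors = FALSE)
    prov <- as.matrix(pdf[, -1, drop = FALSE])
    rownames(prov) <- pdf$sample_id
  }
  structure(m, provenance = prov, class = c("disruption_matrix", class(m)))
}
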