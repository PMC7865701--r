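#' Read a variant table
#'
#' Reads a delimited (TSV/CSV) table of gene-annotated variant calls into the
#' canonical variant record layout used throughout the package: one row per
#' variant with the carrying sample, the gene symbol, the annotated
#' consequence term, the SIFT score and two population allele frequencies
#' (NHLBI ESP and 1000 Genomes). Column names in the file are mapped through
#' `dialect`, so arbitrary export headers can be consumed without renaming
#' the file.
#'
#' @param path Path to a delimited text file with a header line.
#' @param dialect Named character vector mapping canonical field names
#'   (`sample_id`, `gene`, `consequence`, `sift_score`, `esp_af`, `kg_af`)
#'   to the column names present in the file. Fields other than the three
#'   mandatory ones (`sample_id`, `gene`, `consequence`) may be omitted, in
#'   which case the corresponding column is filled with `NA`.
#' @param sep Field separator, default tab.
#' @return A `data.frame` with columns `sample_id`, `gene`, `consequence`
#'   (character) and `sift_score`, `esp_af`, `kg_af` (numeric, `NA` where
#'   missing). Extra columns in the file are ignored.
#' @export
read_variant_table <- function(path, dialect = variant_dialect(), sep = "\t") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  mandatory <- c("sample_id", "gene", "consequence")
  numeric_fields <- c("sift_score", "esp_af", "kg_af")
  missing_map <- setdiff(mandatory, names(dialect))
  if (length(missing_map) > 0L)
    stop("dialect must map mandatory fields: ", paste(missing_map, collapse = ", "))
  absent <- dialect[!dialect %in% names(raw) & names(dialect) %in% mandatory]
  if (length(absent) > 0L)
    stop("variant table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  out <- data.frame(
    sample_id = raw[[dialect[["sample_id"]]]],
    gene = raw[[dialect[["gene"]]]],
    consequence = raw[[dialect[["consequence"]]]],
    stringsAsFactors = FALSE
  )
  for (f in numeric_fields) {
    if (f %in% names(dialect) && dialect[[f]] %in% names(raw)) {
      out[[f]] <- parse_numeric_column(raw[[dialect[[f]]]], dialect[[f]])
    } else {
      out[[f]] <- NA_real_
    }
  }
  validate_variants(out)
  out
}

#' Default column mapping for variant tables
#'
#' @return Named character vector mapping canonical variant fields to the
#'   column names written by [write_variant_table()] (identity mapping).
#' @export
variant_dialect <- function() {
  c(sample_id = "sample_id", gene = "gene", consequence = "consequence",
    sift_score = "sift_score", esp_af = "esp_af", kg_af = "kg_af")
}

# numeric parsing with row-level diagnostics; empty / NA / "." become NA
parse_numeric_column <- function(x, column) {
  x[x %in% c("", "NA", "na", ".")] <- NA_character_
  suppressWarnings(v <- as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0L)
    stop("unparseable numeric value in column '", column, "' at data row ",
         bad[1L], ": '", x[bad[1L]], "'")
  v
}

validate_variants <- function(v) {
  for (f in c("sift_score", "esp_af", "kg_af")) {
    x <- v[[f]]
    if (any(!is.na(x) & (x < 0 | x > 1)))
      stop("column '", f, "' contains values outside [0, 1]")
  }
  if (any(is.na(v$consequence) | v$consequence == ""))
    stop("consequence must be a non-empty token for every variant")
  invisible(v)
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()] under the default dialect; the
#' read/write round trip is the identity on records.
#'
#' @param variants Variant `data.frame` as returned by [read_variant_table()].
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a copy-number table
#'
#' @param path Path to a delimited file with columns (after mapping)
#'   `sample_id`, `gene`, `total_copy_number`.
#' @param dialect Named character vector mapping those canonical names to the
#'   file's column names.
#' @param sep Field separator.
#' @return A `data.frame` with `sample_id`, `gene` (character) and
#'   `total_copy_number` (non-negative integer).
#' @export
read_copy_number_table <- function(path,
                                   dialect = c(sample_id = "sample_id",
                                               gene = "gene",
                                               total_copy_number = "total_copy_number"),
                                   sep = "\t") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  absent <- dialect[!dialect %in% names(raw)]
  if (length(absent) > 0L)
    stop("copy-number table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  cn <- parse_numeric_column(raw[[dialect[["total_copy_number"]]]],
                             dialect[["total_copy_number"]])
  if (any(is.na(cn)))
    stop("total_copy_number may not be missing")
  if (any(cn < 0 | cn != floor(cn)))
    stop("total_copy_number must be a non-negative integer")
  data.frame(sample_id = raw[[dialect[["sample_id"]]]],
             gene = raw[[dialect[["gene"]]]],
             total_copy_number = as.integer(cn),
             stringsAsFactors = FALSE)
}

#' Read a drug-response table
#'
#' @param path Path to a delimited file with (after mapping) columns
#'   `sample_id`, `drug`, `ln_ic50` — the natural log of the half-maximal
#'   inhibitory concentration.
#' @param dialect Named character vector mapping canonical names to file
#'   column names.
#' @param sep Field separator.
#' @return A `data.frame` with `sample_id`, `drug`, `ln_ic50` (finite numeric).
#' @export
read_drug_response_table <- function(path,
                                     dialect = c(sample_id = "sample_id",
                                                 drug = "drug",
                                                 ln_ic50 = "ln_ic50"),
                                     sep = "\t") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  absent <- dialect[!dialect %in% names(raw)]
  if (length(absent) > 0L)
    stop("drug-response table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  y <- parse_numeric_column(raw[[dialect[["ln_ic50"]]]], dialect[["ln_ic50"]])
  if (any(!is.finite(y)))
    stop("ln_ic50 must be finite for every row")
  data.frame(sample_id = raw[[dialect[["sample_id"]]]],
             drug = raw[[dialect[["drug"]]]],
             ln_ic50 = y, stringsAsFactors = FALSE)
}

#' Read a clinical table
#'
#' @param path Path to a delimited file with (after mapping) columns
#'   `patient_id`, `os_time` (days), `os_event` (1 = death), and optionally
#'   `stage` (I--IV, may be missing).
#' @param dialect Named character vector mapping canonical names to file
#'   column names; `stage` may be omitted.
#' @param sep Field separator.
#' @return A `data.frame` with `patient_id`, `os_time`, `os_event`, `stage`.
#' @export
read_clinical_table <- function(path,
                                dialect = c(patient_id = "patient_id",
                                            os_time = "os_time",
                                            os_event = "os_event",
                                            stage = "stage"),
                                sep = "\t") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  mandatory <- c("patient_id", "os_time", "os_event")
  absent <- dialect[mandatory][!dialect[mandatory] %in% names(raw)]
  if (length(absent) > 0L)
    stop("clinical table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  time <- parse_numeric_column(raw[[dialect[["os_time"]]]], dialect[["os_time"]])
  event <- parse_numeric_column(raw[[dialect[["os_event"]]]], dialect[["os_event"]])
  if (any(is.na(time) | time < 0)) stop("os_time must be non-negative")
  if (!all(event %in% c(0, 1))) stop("os_event must be 0 or 1")
  stage <- if ("stage" %in% names(dialect) && dialect[["stage"]] %in% names(raw)) {
    s <- raw[[dialect[["stage"]]]]
    s[s %in% c("", "NA")] <- NA_character_
    s
  } else NA_character_
  data.frame(patient_id = raw[[dialect[["patient_id"]]]],
             os_time = time, os_event = as.integer(event), stage = stage,
             stringsAsFactors = FALSE)
}

#' MAF Variant_Classification to consequence mapping
#'
#' The versioned mapping table used by [read_maf()] to translate MAF
#' `Variant_Classification` tokens into the controlled consequence vocabulary
#' shared with cell-line variant tables. Unmapped tokens become `"other"`.
#'
#' @return Named character vector: names are MAF classifications, values are
#'   consequence terms.
#' @export
maf_consequence_map <- function() {
  c(Nonsense_Mutation = "stop_gained",
    Frame_Shift_Del = "frameshift_variant",
    Frame_Shift_Ins = "frameshift_variant",
    Splice_Site = "splice_acceptor_variant",
    Splice_Region = "splice_region_variant",
    Translation_Start_Site = "start_lost",
    Missense_Mutation = "missense_variant",
    Nonstop_Mutation = "stop_lost",
    In_Frame_Del = "inframe_deletion",
    In_Frame_Ins = "inframe_insertion",
    Silent = "synonymous_variant",
    `3'UTR` = "3_prime_UTR_variant",
    `5'UTR` = "5_prime_UTR_variant",
    Intron = "intron_variant",
    RNA = "non_coding_transcript_variant")
}

#' Read a MAF (Mutation Annotation Format) file
#'
#' Reads a tab-separated MAF file (header line; `#`-prefixed comment lines
#' skipped), translating `Variant_Classification` terms to the controlled
#' consequence vocabulary via [maf_consequence_map()]. Unknown classification
#' tokens are kept with consequence `"other"` and a warning, never dropped.
#'
#' @param path Path to the MAF file.
#' @param sift_column Name of the column carrying the SIFT score, if any.
#'   TCGA MAFs often embed it as `SIFT` with values like `deleterious(0.01)`;
#'   both a bare numeric and that parenthesised form are parsed.
#' @return A variant `data.frame` in the same layout as
#'   [read_variant_table()] (population AFs are `NA`: MAFs carry somatic
#'   calls already filtered upstream).
#' @export
read_maf <- function(path, sift_column = "SIFT") {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  needed <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0L)
    stop("MAF is missing mandatory column(s): ", paste(absent, collapse = ", "))
  map <- maf_consequence_map()
  cls <- raw$Variant_Classification
  cons <- unname(map[cls])
  unknown <- is.na(cons)
  if (any(unknown)) {
    warning("unknown Variant_Classification token(s) kept as 'other': ",
            paste(unique(cls[unknown]), collapse = ", "))
    cons[unknown] <- "other"
  }
  sift <- rep(NA_real_, nrow(raw))
  if (sift_column %in% names(raw)) {
    s <- raw[[sift_column]]
    # accept "0.01" or "deleterious(0.01)"
    inner <- sub("^.*\\(([0-9.eE+-]+)\\).*$", "\\1", s)
    sift <- suppressWarnings(as.numeric(ifelse(grepl("\\(", s), inner, s)))
  }
  out <- data.frame(sample_id = raw$Tumor_Sample_Barcode,
                    gene = raw$Hugo_Symbol,
                    consequence = cons,
                    sift_score = sift,
                    esp_af = NA_real_, kg_af = NA_real_,
                    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

#' Filter out common population variants
#'
#' Removes putative germline variants and sequencing artifacts by population
#' allele frequency: a variant is retained only if its ESP frequency is
#' missing or below `esp_max` AND its 1000 Genomes frequency is missing or
#' below `kg_max`. The defaults are the ESP (< 0.00025) and 1000 Genomes
#' (< 0.0014) cutoffs used for the cell-line screen.
#'
#' @param variants Variant `data.frame` ([read_variant_table()] layout).
#' @param esp_max ESP allele-frequency cutoff, in (0, 1].
#' @param kg_max 1000 Genomes allele-frequency cutoff, in (0, 1].
#' @return The retained subset, with attribute `"filter_report"`: a
#'   `data.frame` with rows `input`, `removed_esp`, `removed_kg`, `retained`
#'   and their counts (a variant failing both cutoffs counts under ESP).
#' @export
filter_population_variants <- function(variants, esp_max = 0.00025,
                                       kg_max = 0.0014) {
  if (!is.numeric(esp_max) || !is.numeric(kg_max) ||
      esp_max <= 0 || esp_max > 1 || kg_max <= 0 || kg_max > 1)
    stop("frequency thresholds must lie in (0, 1]")
  esp_ok <- is.na(variants$esp_af) | variants$esp_af < esp_max
  kg_ok <- is.na(variants$kg_af) | variants$kg_af < kg_max
  keep <- esp_ok & kg_ok
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- data.frame(
    step = c("input", "removed_esp", "removed_kg", "retained"),
    n = c(nrow(variants), sum(!esp_ok), sum(esp_ok & !kg_ok), sum(keep)),
    stringsAsFactors = FALSE
  )
  attr(out, "filter_report") <- report
  out
}

#' Write a variant filter report
#'
#' @param variants Output of [filter_population_variants()].
#' @param path Output TSV path.
#' @export
write_filter_report <- function(variants, path) {
  report <- attr(variants, "filter_report")
  if (is.null(report)) stop("no filter report attached; run filter_population_variants() first")
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
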