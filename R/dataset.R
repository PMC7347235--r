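#' Names of the per-variant predictive features
#'
#' Eight continuous covariates, in canonical order: a functional assay
#' (`peak_current`, maximal channel current as a fraction of wild type), a
#' structure-derived score (`penetrance_density`, the disease burden of
#' spatially neighboring variants), and six sequence-based in-silico scores
#' (`sift`, `polyphen2`, `provean`, `blast_pssm`, `evolutionary_rate`, `pam`).
#' Any field may be missing per variant; missingness is tracked per field.
#'
#' @return Character vector of length 8.
#' @export
feature_names <- function() {
  c("peak_current", "penetrance_density", "sift", "polyphen2", "provean",
    "blast_pssm", "evolutionary_rate", "pam")
}

#' In-silico classifier subset of [feature_names()]
#' @return Character vector of length 6.
#' @export
insilico_features <- function() {
  c("sift", "polyphen2", "provean", "blast_pssm", "evolutionary_rate", "pam")
}

VARIANT_CLASSES <- c("missense", "inframe_insertion", "inframe_deletion")

COUNT_COLS <- c("n_affected", "n_unaffected_lit", "n_gnomad")

#' Default column mapping for the curated per-variant CSV dialect
#'
#' Maps canonical column names (names of the vector) to the header names
#' expected in the input CSV (values). Override entries to adapt to another
#' dialect; canonical and file names are identical by default.
#'
#' @return Named character vector.
#' @export
default_dialect <- function() {
  cols <- c("variant_id", "protein_change", "residue_index", "variant_class",
            COUNT_COLS, feature_names())
  stats::setNames(cols, cols)
}

#' Validate a variant table
#'
#' Checks the structural invariants of the per-variant table: required columns
#' present; counts non-negative integers; at least one heterozygote per row;
#' residue indices >= 1; variant classes in the allowed set; in-frame indels
#' carry no in-silico scores; features numeric.
#'
#' @param variants A data.frame in canonical column layout.
#' @return The table, invisibly, with `variant_class` normalized to character.
#' @export
validate_variants <- function(variants) {
  required <- c("variant_id", "residue_index", "variant_class", COUNT_COLS)
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols))
    stop("variant table: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (fc in setdiff(feature_names(), names(variants)))
    variants[[fc]] <- NA_real_
  for (cc in COUNT_COLS) {
    x <- variants[[cc]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad))
      stop("variant table: column '", cc, "' must hold non-negative integers; ",
           "first offending row: ", bad[1L], call. = FALSE)
  }
  tot <- rowSums(as.matrix(variants[COUNT_COLS]))
  if (any(tot < 1))
    stop("variant table: row(s) with zero total heterozygotes: ",
         paste(utils::head(which(tot < 1), 5L), collapse = ", "), call. = FALSE)
  if (any(!is.finite(variants$residue_index) | variants$residue_index < 1))
    stop("variant table: 'residue_index' must be >= 1", call. = FALSE)
  variants$variant_class <- as.character(variants$variant_class)
  badc <- which(!variants$variant_class %in% VARIANT_CLASSES)
  if (length(badc))
    stop("variant table: unknown variant_class '",
         variants$variant_class[badc[1L]], "' in row ", badc[1L], call. = FALSE)
  indel <- variants$variant_class != "missense"
  for (fc in insilico_features()) {
    variants[[fc]] <- as.numeric(variants[[fc]])
    if (any(indel & !is.na(variants[[fc]])))
      stop("variant table: in-frame indels must have in-silico field '", fc,
           "' missing", call. = FALSE)
  }
  for (fc in feature_names()) variants[[fc]] <- as.numeric(variants[[fc]])
  invisible(variants)
}

#' Load the per-variant table from CSV
#'
#' Reads a curated per-variant CSV (UTF-8, header row, empty string = missing
#' covariate), remaps columns through `dialect`, applies the inclusion rules
#' (drop intronic rows when a class column labels them; drop rows with zero
#' total heterozygotes), forces in-silico fields missing for in-frame indels,
#' and validates invariants. Load statistics are attached as attribute
#' `"manifest"` (rows read, rows excluded by rule, missingness-pattern census).
#'
#' @param path Path to the CSV file.
#' @param dialect Named character vector mapping canonical names to file
#'   headers; see [default_dialect()].
#' @param drop_zero_het Drop rows with zero total heterozygotes (default) or
#'   raise an error (`FALSE`).
#' @return A validated data.frame in canonical layout.
#' @export
load_dataset <- function(path, dialect = default_dialect(), drop_zero_het = TRUE) {
  if (!file.exists(path)) stop("load_dataset: no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  n_read <- nrow(raw)
  required <- c("variant_id", "residue_index", "variant_class", COUNT_COLS)
  for (canon in required) {
    src <- dialect[[canon]]
    if (is.null(src) || !src %in% names(raw))
      stop("load_dataset: required column '", canon, "' (file header '",
           if (is.null(src)) "<unmapped>" else src, "') not found", call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(n_read))
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  if (!"protein_change" %in% names(out)) out$protein_change <- NA_character_

  n_intronic <- 0L
  intronic <- tolower(as.character(out$variant_class)) %in% c("intronic", "intron")
  if (any(intronic)) {
    n_intronic <- sum(intronic)
    out <- out[!intronic, , drop = FALSE]
  }
  for (cc in COUNT_COLS) {
    x <- suppressWarnings(as.numeric(out[[cc]]))
    x[is.na(out[[cc]])] <- 0
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad))
      stop("load_dataset: invalid count in column '", cc, "', row ", bad[1L],
           call. = FALSE)
    out[[cc]] <- as.integer(x)
  }
  tot <- rowSums(as.matrix(out[COUNT_COLS]))
  n_zero <- sum(tot < 1)
  if (n_zero > 0L) {
    if (!drop_zero_het)
      stop("load_dataset: ", n_zero, " row(s) with zero heterozygotes", call. = FALSE)
    out <- out[tot >= 1, , drop = FALSE]
  }
  # indel simplification: keyed at start residue, no in-silico scores
  indel <- out$variant_class %in% c("inframe_insertion", "inframe_deletion")
  for (fc in insilico_features())
    out[[fc]][indel] <- NA
  rownames(out) <- NULL
  out <- validate_variants(out)
  census <- table(vapply(seq_len(nrow(out)), function(i)
    pattern_key(!is.na(unlist(out[i, feature_names()]))), character(1)))
  attr(out, "manifest") <- list(
    path = path, rows_read = n_read, rows_kept = nrow(out),
    excluded_intronic = n_intronic, excluded_zero_heterozygote = n_zero,
    pattern_census = as.list(census))
  out
}

#' Write a variant table (and optional truth column) to CSV
#'
#' Emits the canonical CSV dialect: header row, empty string for missing
#' covariates. Round-trips through [load_dataset()] bit-for-bit for counts and
#' covariates.
#'
#' @param variants A validated variant table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(variants, path) {
  cols <- intersect(names(default_dialect()), names(variants))
  out <- variants[cols]
  for (cc in names(out)) {
    x <- out[[cc]]
    if (is.double(x))  # 17 significant digits round-trip doubles exactly
      out[[cc]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Total heterozygotes observed for each variant
#'
#' Affected plus unaffected-in-literature plus population-database carriers
#' (the latter counted unaffected given disease rarity).
#'
#' @param variants A variant table.
#' @return Integer vector, one entry per row, all >= 1 after validation.
#' @export
total_heterozygotes <- function(variants) {
  as.integer(rowSums(as.matrix(variants[COUNT_COLS])))
}

#' Observed (raw) penetrance of each variant
#'
#' `n_affected / total heterozygotes` — the zero-prior limit of the posterior
#' mean.
#'
#' @param variants A variant table.
#' @return Numeric vector in \[0, 1\].
#' @export
observed_penetrance <- function(variants) {
  tot <- total_heterozygotes(variants)
  if (any(tot < 1))
    stop("observed_penetrance: zero total heterozygotes", call. = FALSE)
  variants$n_affected / tot
}

#' Canonical key of a missingness pattern
#'
#' @param observed Logical vector over [feature_names()] (TRUE = observed).
#' @return A string such as `"11000000"`, one digit per feature in canonical
#'   order.
#' @export
pattern_key <- function(observed) {
  stopifnot(length(observed) == length(feature_names()), !anyNA(observed))
  paste(as.integer(observed), collapse = "")
}

#' Missingness pattern of each variant
#'
#' Two variants with identical observed-feature masks map to the same key, so
#' grouping by this key partitions the table into its missing-data patterns.
#'
#' @param variants A variant table.
#' @return Character vector of pattern keys, one per row.
#' @export
pattern_of <- function(variants) {
  obs <- !is.na(as.matrix(variants[feature_names()]))
  unname(apply(obs, 1L, function(m) paste(as.integer(m), collapse = "")))
}
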