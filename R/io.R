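# TSV / FASTA readers and writers for the pipeline's tabular interfaces.
# PSM tables follow a MaxQuant-evidence-like dialect: one row per PSM with
# `sequence`, `protein`, `interference` and 16 `reporter_*` columns; empty
# fields are missing intensities.

.psm_required <- function() c("sequence", "protein", "interference")

#' Read a PSM-level reporter table
#'
#' @param path TSV file with columns `sequence`, `protein`, `interference`
#'   and the 16 reporter columns ([reporter_columns()]). A `column_map`
#'   (named character vector, `internal = file_column`) adapts other
#'   evidence-file dialects.
#' @param column_map Optional renaming map applied before validation.
#' @return Data frame of PSMs; zero intensities are coerced to `NA`
#'   (absent), interference validated to `[0, 1]`.
#' @export
read_psm_tsv <- function(path, column_map = NULL) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      j <- match(column_map[[internal]], names(x))
      if (is.na(j)) stop("column_map refers to absent column: ",
                         column_map[[internal]], call. = FALSE)
      names(x)[j] <- internal
    }
  }
  validate_psm_table(x)
}

#' Validate (and canonicalize) a PSM table
#'
#' @param psms Data frame of PSMs.
#' @return The table with reporter columns numeric, zeros coerced to `NA`.
#' @export
validate_psm_table <- function(psms) {
  need <- c(.psm_required(), reporter_columns())
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("PSM table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(psms$interference) | psms$interference < 0 |
          psms$interference > 1))
    stop("interference must lie in [0, 1]", call. = FALSE)
  for (cn in reporter_columns()) {
    v <- as.numeric(psms[[cn]])
    v[!is.na(v) & v == 0] <- NA_real_
    if (any(v < 0, na.rm = TRUE))
      stop("negative reporter intensity in column ", cn, call. = FALSE)
    psms[[cn]] <- v
  }
  psms
}

#' Write a PSM table (missing intensities as empty fields)
#'
#' @param psms PSM data frame.
#' @param path Output TSV path.
#' @export
write_psm_tsv <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a channel-to-sample study design table
#'
#' @param path TSV with columns `channel`, `sample_id`, `group` (young/old),
#'   `sex` (female/male), `hypertension` (logical or 0/1).
#' @return Validated design data frame (see [validate_design()]).
#' @export
read_design_tsv <- function(path) {
  validate_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a study design table
#'
#' @param design Data frame with `channel`, `sample_id`, `group`, `sex`,
#'   `hypertension`.
#' @return The design with `group`/`sex` as factors (young/female reference)
#'   and `hypertension` logical.
#' @export
validate_design <- function(design) {
  need <- c("channel", "sample_id", "group", "sex", "hypertension")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$channel))
    stop("design channels must be unique", call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("design sample ids must be unique", call. = FALSE)
  if (!all(design$group %in% c("young", "old")))
    stop("group must be 'young' or 'old'", call. = FALSE)
  if (!all(design$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  design$group <- factor(design$group, levels = c("young", "old"))
  design$sex <- factor(design$sex, levels = c("female", "male"))
  design$hypertension <- as.logical(design$hypertension)
  if (anyNA(design$hypertension) || anyNA(design$sex) || anyNA(design$group))
    stop("design covariates must be non-missing", call. = FALSE)
  design
}

#' Write a study design table
#' @param design Design data frame.
#' @param path Output TSV path.
#' @export
write_design_tsv <- function(design, path) {
  out <- design
  out$hypertension <- as.integer(as.logical(out$hypertension))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an impurity matrix TSV
#'
#' Accepts either a square matrix (first column = observed channel, header =
#' true channel; column convention) or a vendor-style isotope table with
#' columns `channel`, `minus2`, `minus1`, `plus1`, `plus2`.
#'
#' @param path TSV path.
#' @return Validated impurity matrix.
#' @export
read_impurity_tsv <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("minus2", "minus1", "plus1", "plus2") %in% names(x)))
    return(impurity_from_isotopes(x))
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  validate_impurity(m)
  m
}

#' Write an impurity matrix TSV (square, column convention)
#' @param impurity Impurity matrix.
#' @param path Output TSV path.
#' @export
write_impurity_tsv <- function(impurity, path) {
  out <- data.frame(channel = rownames(impurity), impurity,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a protein x sample matrix TSV
#'
#' Proteins in rows (first column `protein`), samples in columns; empty cell
#' means missing.
#'
#' @param path TSV path.
#' @param scale Scale tag of the stored values (`"raw"` or `"log2"`).
#' @return A [protein_quant()].
#' @export
read_protein_matrix_tsv <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  protein_quant(m, scale)
}

#' @rdname read_protein_matrix_tsv
#' @param quant A `protein_quant` to write.
#' @export
write_protein_matrix_tsv <- function(quant, path) {
  stopifnot(inherits(quant, "protein_quant"))
  out <- data.frame(protein = rownames(quant$values), quant$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a protein sequence database as FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta_db <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname read_fasta_db
#' @param db Named character vector of sequences.
#' @export
write_fasta_db <- function(db, path) {
  aa <- Biostrings::AAStringSet(db)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
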