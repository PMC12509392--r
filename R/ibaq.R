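# In-silico tryptic digestion and intensity-based absolute quantification
# (iBAQ): summed peptide intensity divided by the number of theoretical
# tryptic peptides in a 6-30 residue window.

#' Digestion rule for the theoretical tryptic digest
#'
#' Trypsin cleaves C-terminal to K or R except when the next residue is P.
#' The default window (6-30 residues, fully cleaved) is the conventional
#' iBAQ denominator definition; both are configurable.
#'
#' @param missed_cleavages Number of allowed missed cleavages (>= 0).
#' @param length_window Inclusive peptide length window for
#'   [count_theoretical_peptides()].
#' @return A `digest_rule` list.
#' @export
digest_rule <- function(missed_cleavages = 0L, length_window = c(6L, 30L)) {
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0", call. = FALSE)
  if (length(length_window) != 2L || length_window[1] > length_window[2])
    stop("length_window must be an increasing pair", call. = FALSE)
  structure(list(enzyme = "trypsin",
                 cleave_after = c("K", "R"),
                 suppress_before = "P",
                 missed_cleavages = as.integer(missed_cleavages),
                 length_window = as.integer(length_window)),
            class = "digest_rule")
}

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWY"

#' In-silico tryptic digestion of a protein sequence
#'
#' @param sequence Protein sequence (standard 20-letter alphabet, uppercase).
#' @param rule A [digest_rule()].
#' @return Character vector of peptides in positional order, including
#'   missed-cleavage variants, unfiltered by length.
#' @export
digest_in_silico <- function(sequence, rule = digest_rule()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  bad <- gsub(sprintf("[%s]", .aa_alphabet), "", sequence)
  if (nchar(bad) > 0L)
    stop("unknown residue(s) in sequence: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  frags <- strsplit(sequence, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
  mc <- rule$missed_cleavages
  if (mc == 0L) return(frags)
  n <- length(frags)
  peps <- character(0)
  for (k in 0:min(mc, n - 1L)) {
    for (i in seq_len(n - k)) {
      peps <- c(peps, paste(frags[i:(i + k)], collapse = ""))
    }
  }
  peps
}

#' Count theoretical tryptic peptides inside the length window
#'
#' Distinct digest peptides whose length falls inside the rule's inclusive
#' window — the iBAQ denominator.
#'
#' @inheritParams digest_in_silico
#' @return Integer count (>= 0).
#' @export
count_theoretical_peptides <- function(sequence, rule = digest_rule()) {
  peps <- unique(digest_in_silico(sequence, rule))
  lens <- nchar(peps)
  sum(lens >= rule$length_window[1] & lens <= rule$length_window[2])
}

#' Compute iBAQ from summed intensity and theoretical peptide count
#'
#' `iBAQ = summed_intensity / n_theoretical`; undefined (NA) when the
#' denominator is zero or the intensity is zero.
#'
#' @param summed_intensity Non-negative summed quantified peptide intensity
#'   (vectorized).
#' @param n_theoretical Theoretical peptide count (vectorized).
#' @return Data frame with `summed_intensity`, `n_theoretical`, `ibaq`,
#'   `ibaq_log10`.
#' @export
compute_ibaq <- function(summed_intensity, n_theoretical) {
  if (any(summed_intensity < 0, na.rm = TRUE))
    stop("summed_intensity must be non-negative", call. = FALSE)
  ibaq <- ifelse(n_theoretical > 0 & summed_intensity > 0,
                 summed_intensity / n_theoretical, NA_real_)
  data.frame(summed_intensity = summed_intensity,
             n_theoretical = n_theoretical,
             ibaq = ibaq,
             ibaq_log10 = log10(ibaq))
}

#' iBAQ table from a PSM table and a protein database
#'
#' The numerator is the per-protein sum of (impurity-corrected, raw,
#' pre-normalization) reporter intensities over all channels and PSMs —
#' overall abundance across the experiment; the denominator comes from the
#' in-silico digest of the database sequence.
#'
#' @param psms PSM table (ideally after [correct_impurities()]).
#' @param db Named sequence vector.
#' @param rule A [digest_rule()].
#' @return Data frame: `protein`, `summed_intensity`, `n_theoretical`,
#'   `ibaq`, `ibaq_log10`.
#' @export
ibaq_from_psms <- function(psms, db, rule = digest_rule()) {
  psms <- validate_psm_table(psms)
  rmat <- as.matrix(psms[reporter_columns()])
  tot <- rowSums(rmat, na.rm = TRUE)
  summed <- tapply(tot, psms$protein, sum)
  prot <- names(summed)
  miss <- setdiff(prot, names(db))
  if (length(miss))
    stop("proteins absent from database: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ntheo <- vapply(db[prot], count_theoretical_peptides, integer(1),
                  rule = rule)
  out <- compute_ibaq(as.numeric(summed), as.integer(ntheo))
  cbind(data.frame(protein = prot, stringsAsFactors = FALSE), out)
}

#' Rank table of iBAQ abundances
#'
#' Defined records sorted by descending `ibaq_log10` (ties broken by
#' accession), with a rank index; the median `ibaq_log10` is attached as
#' attribute `median_ibaq_log10`.
#'
#' @param records Data frame from [ibaq_from_psms()] or [compute_ibaq()]
#'   with a `protein` column.
#' @return Ranked data frame with a `rank` column.
#' @export
ibaq_rank_table <- function(records) {
  ok <- records[!is.na(records$ibaq_log10), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no defined iBAQ records", call. = FALSE)
  o <- order(-ok$ibaq_log10, ok$protein)
  ok <- ok[o, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  rownames(ok) <- NULL
  attr(ok, "median_ibaq_log10") <- stats::median(ok$ibaq_log10)
  ok
}
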