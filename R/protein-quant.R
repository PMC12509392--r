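#' Protein-by-sample quantitation matrix
#'
#' Lightweight container for a proteins x samples intensity matrix. Missing
#' values are `NA` (absent is distinct from zero: zero raw intensities are
#' coerced to missing on construction), and a `scale` tag records whether
#' values are raw intensities or log2.
#'
#' @param values Numeric matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids).
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `protein_quant`.
#' @export
protein_quant <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have protein rownames and sample colnames", call. = FALSE)
  if (scale == "raw") {
    if (any(values < 0, na.rm = TRUE))
      stop("raw intensities must be non-negative", call. = FALSE)
    values[!is.na(values) & values == 0] <- NA_real_
  }
  structure(list(values = values, scale = scale), class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.protein_quant <- function(x) dim(x$values)

#' @export
as.matrix.protein_quant <- function(x, ...) x$values

#' Subset a protein_quant by protein and/or sample
#'
#' @param x A `protein_quant`.
#' @param proteins Optional accession vector or row index.
#' @param samples Optional sample-id vector or column index.
#' @return A `protein_quant` restricted to the requested rows/columns.
#' @export
subset_quant <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "protein_quant"))
  v <- x$values
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  protein_quant(v, x$scale)
}
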