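#' TMTpro 16-plex reporter channel labels
#'
#' Channel labels in reporter-ion mass order, as used for column naming
#' throughout the package (`reporter_126` ... `reporter_134N`).
#'
#' @return Character vector of length 16.
#' @export
tmtpro_channels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
    "130C", "131N", "131C", "132N", "132C", "133N", "133C", "134N")
}

#' Reporter intensity column names of a PSM table
#'
#' @return Character vector, `"reporter_"` prefixed channel labels.
#' @export
reporter_columns <- function() {
  paste0("reporter_", tmtpro_channels())
}

#' Identity impurity matrix (perfectly pure labels)
#'
#' @param n Number of channels (default 16).
#' @return `n x n` identity matrix with channel dimnames when `n == 16`.
#' @export
identity_impurity <- function(n = 16L) {
  m <- diag(n)
  if (n == 16L) dimnames(m) <- list(tmtpro_channels(), tmtpro_channels())
  m
}

#' Validate a reporter-ion impurity matrix
#'
#' The internal convention is column-wise: column `j` gives the distribution
#' of true channel `j`'s signal across observed channels. Columns must sum to
#' a physically plausible total (isotopic envelope mass may fall outside the
#' plex and be lost, so sums below 1 are allowed) and the matrix must be
#' numerically invertible.
#'
#' @param impurity Square numeric matrix, non-negative entries.
#' @param n_channels Expected dimension (default `ncol(impurity)`).
#' @param sum_band Allowed band for column sums; default `c(0.8, 1.05)`.
#' @return The matrix, invisibly, after validation.
#' @export
validate_impurity <- function(impurity, n_channels = ncol(impurity),
                              sum_band = c(0.8, 1.05)) {
  if (!is.matrix(impurity) || nrow(impurity) != ncol(impurity))
    stop("impurity matrix must be square", call. = FALSE)
  if (ncol(impurity) != n_channels)
    stop(sprintf("impurity matrix must be %d x %d, got %d x %d",
                 n_channels, n_channels, nrow(impurity), ncol(impurity)),
         call. = FALSE)
  if (any(impurity < 0))
    stop("impurity matrix entries must be non-negative", call. = FALSE)
  cs <- colSums(impurity)
  if (any(cs < sum_band[1] - 1e-12) || any(cs > sum_band[2] + 1e-12))
    stop(sprintf("impurity column sums outside [%g, %g] sanity band",
                 sum_band[1], sum_band[2]), call. = FALSE)
  kappa_est <- kappa(impurity, exact = FALSE)
  if (!is.finite(kappa_est) || kappa_est > 1e12)
    stop(sprintf("impurity matrix is numerically singular (condition number %.3g)",
                 kappa_est), call. = FALSE)
  invisible(impurity)
}

#' Build a column-convention impurity matrix from vendor-style isotope rows
#'
#' TMT reagent data sheets report, per channel, the percentage of label with
#' -2, -1, +1 and +2 isotopes, i.e. reporter signal appearing in the
#' neighbouring channels (in reporter mass order). This converts such a table
#' into the internal column convention; mass that would fall outside the plex
#' is dropped (its column then sums below 1).
#'
#' @param isotopes Data frame with columns `channel`, `minus2`, `minus1`,
#'   `plus1`, `plus2` (percentages, 0-100), rows in channel mass order.
#' @return Square impurity matrix, columns = true channel.
#' @export
impurity_from_isotopes <- function(isotopes) {
  need <- c("channel", "minus2", "minus1", "plus1", "plus2")
  if (!all(need %in% names(isotopes)))
    stop("isotope table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(isotopes)
  m <- matrix(0, n, n, dimnames = list(isotopes$channel, isotopes$channel))
  for (j in seq_len(n)) {
    frac <- c(isotopes$minus2[j], isotopes$minus1[j],
              isotopes$plus1[j], isotopes$plus2[j]) / 100
    m[j, j] <- 1 - sum(frac)
    off <- c(-2L, -1L, 1L, 2L)
    for (k in seq_along(off)) {
      i <- j + off[k]
      if (i >= 1L && i <= n) m[i, j] <- frac[k]
    }
  }
  validate_impurity(m)
  m
}

#' Example TMTpro 16-plex impurity matrix (synthetic)
#'
#' A synthetic isotope-impurity matrix of realistic magnitude (purity
#' 94-98%, -1/+1 spillover of a few percent, small -2/+2 terms). It is not a
#' vendor lot sheet; use [impurity_from_isotopes()] or [read_impurity_tsv()]
#' to load real correction factors.
#'
#' @return 16 x 16 impurity matrix (column convention).
#' @export
example_impurity_matrix <- function() {
  ch <- tmtpro_channels()
  # deterministic, mildly channel-dependent percentages
  i <- seq_len(16L)
  iso <- data.frame(
    channel = ch,
    minus2  = 0.10 + 0.01 * (i %% 3),
    minus1  = 1.20 + 0.15 * (i %% 5),
    plus1   = 2.50 - 0.10 * (i %% 4),
    plus2   = 0.20 + 0.02 * (i %% 2)
  )
  impurity_from_isotopes(iso)
}
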