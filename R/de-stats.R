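# Moderated differential expression: per-protein least-squares fits with
# clinical covariates, empirical-Bayes pooling of the protein-specific
# variances toward an assay-wide prior (moment matching on log variances via
# digamma/trigamma inversion), moderated t statistics, and tail-area FDR
# (pi0-scaled Benjamini-Hochberg q-values).

#' Build the samples x coefficients design matrix
#'
#' Treatment coding with young, female, non-hypertensive as reference
#' levels; the tested coefficient is the old-vs-young group indicator.
#'
#' @param design Validated study design.
#' @param covariates Character subset of `c("sex", "hypertension")`.
#' @return Numeric design matrix with attribute `coef` naming the tested
#'   column.
#' @export
build_design_matrix <- function(design, covariates = c("sex", "hypertension")) {
  design <- validate_design(design)
  if (length(covariates))
    covariates <- match.arg(covariates, c("sex", "hypertension"),
                            several.ok = TRUE)
  df <- data.frame(group = design$group)
  if ("sex" %in% covariates) df$sex <- design$sex
  if ("hypertension" %in% covariates)
    df$hypertension <- design$hypertension
  X <- stats::model.matrix(~ ., df)
  rownames(X) <- design$sample_id
  if (qr(X)$rank < ncol(X))
    warning("design matrix is rank deficient over the full sample set")
  attr(X, "coef") <- "groupold"
  X
}

#' Per-protein ordinary least-squares fits
#'
#' Fits each protein's present log2 values against the design. Proteins
#' with complete data share one QR decomposition; proteins with missing
#' values are fitted on their reduced sample set and flagged untestable if
#' the reduced design loses rank or residual degrees of freedom fall below
#' one ("no imputation": the fit uses only observed samples).
#'
#' @param quant Log2-scale [protein_quant()].
#' @param X Design matrix from [build_design_matrix()].
#' @return Data frame per protein: `protein`, `logFC` (tested coefficient),
#'   `s2` (residual variance), `df` (residual df), `v` (unscaled variance of
#'   the tested coefficient), `n_obs`, `testable`.
#' @export
fit_protein_lm <- function(quant, X) {
  stopifnot(inherits(quant, "protein_quant"))
  if (quant$scale != "log2")
    stop("fit_protein_lm expects log2-scale values", call. = FALSE)
  Y <- quant$values
  if (ncol(Y) != nrow(X))
    stop("sample dimension mismatch between matrix and design", call. = FALSE)
  cidx <- match(attr(X, "coef"), colnames(X))
  if (is.na(cidx)) stop("design matrix lacks tested coefficient", call. = FALSE)
  p <- ncol(X)
  n <- nrow(Y)
  logFC <- s2 <- v <- rep(NA_real_, n)
  dfres <- rep(NA_real_, n)
  n_obs <- rowSums(!is.na(Y))
  testable <- rep(FALSE, n)

  complete <- rowSums(is.na(Y)) == 0L
  if (any(complete)) {
    qrX <- qr(X)
    if (qrX$rank < p)
      stop("design matrix is rank deficient; drop a covariate", call. = FALSE)
    Yt <- t(Y[complete, , drop = FALSE])
    cf <- qr.coef(qrX, Yt)
    res <- qr.resid(qrX, Yt)
    d <- nrow(X) - p
    XtXinv <- chol2inv(qr.R(qrX))
    logFC[complete] <- cf[cidx, ]
    s2[complete] <- colSums(res^2) / d
    dfres[complete] <- d
    v[complete] <- XtXinv[cidx, cidx]
    testable[complete] <- d >= 1
  }
  for (i in which(!complete)) {
    obs <- !is.na(Y[i, ])
    Xo <- X[obs, , drop = FALSE]
    d <- sum(obs) - p
    if (d < 1 || qr(Xo)$rank < p) next
    fit <- stats::lm.fit(Xo, Y[i, obs])
    logFC[i] <- fit$coefficients[cidx]
    s2[i] <- sum(fit$residuals^2) / d
    dfres[i] <- d
    v[i] <- chol2inv(qr.R(fit$qr))[cidx, cidx]
    testable[i] <- TRUE
  }
  data.frame(protein = rownames(Y), logFC = logFC, s2 = s2, df = dfres,
             v = v, n_obs = n_obs, testable = testable,
             stringsAsFactors = FALSE)
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Moment matching of `log(s2)` against its theoretical scaled
#' log-chi-square distribution under the hierarchical model
#' `s2 | sigma2 ~ sigma2 * chisq(d)/d`, `sigma2 ~ s0_sq * d0 / chisq(d0)`:
#' the excess spread of `log(s2)` beyond the sampling floor
#' `trigamma(d/2)` determines the prior degrees of freedom `d0` via
#' trigamma inversion, and the corrected mean determines `s0_sq`. When the
#' spread is at or below the floor, `d0` is infinite (all proteins share
#' one variance).
#'
#' @param s2 Residual variances (>= 10 finite positive values required).
#' @param df Residual degrees of freedom (scalar or per-protein).
#' @return List `d0` (prior df, possibly `Inf`) and `s0_sq` (prior
#'   variance).
#' @export
estimate_eb_hyperparams <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 10L)
    stop("fewer than 10 usable variances; fall back to ordinary t-tests",
         call. = FALSE)
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (stats::var(z) == 0) {
    # degenerate input: identical variances carry no sampling spread
    return(list(d0 = Inf, s0_sq = s2[1]))
  }
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t statistic
#'
#' Posterior variance `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`;
#' `t = logFC / sqrt(s2_post * v)` with `df + d0` total degrees of freedom
#' (standard normal when `d0` is infinite). All arguments are vectorized.
#'
#' @param logFC Fitted group coefficient (log2).
#' @param s2 Residual variance.
#' @param df Residual degrees of freedom.
#' @param v Unscaled variance of the tested coefficient.
#' @param hyper Hyperparameters from [estimate_eb_hyperparams()].
#' @return Data frame: `t`, `df_total`, `p_value` (two-sided).
#' @export
moderated_t <- function(logFC, s2, df, v, hyper) {
  d0 <- hyper$d0; s0 <- hyper$s0_sq
  if (!(d0 >= 0) || !(s0 > 0)) stop("invalid hyperparameters", call. = FALSE)
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(logFC))
    df_total <- rep(Inf, length(logFC))
  } else {
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  t <- logFC / sqrt(s2_post * v)
  p <- 2 * stats::pt(-abs(t), df = df_total)
  data.frame(t = t, df_total = df_total, p_value = p)
}

#' Adjust p-values for multiple testing
#'
#' `"tail_area"` computes Storey-type q-values: `q(i) = pi0 * m * p(i) /
#' rank(i)` with cumulative-minimum monotonization from the largest p down,
#' where `pi0` is the lambda-averaged tail estimator
#' `mean over lambda of #{p > lambda} / ((1 - lambda) m)` capped to
#' `[0, 1]`. `"bh"` is the same with `pi0 = 1` (Benjamini-Hochberg).
#'
#' @param p P-values in `[0, 1]`.
#' @param method `"tail_area"` or `"bh"`.
#' @param lambda Tail grid for the pi0 estimator.
#' @return Adjusted p-values (same order as input), attribute `pi0`.
#' @export
adjust_fdr <- function(p, method = c("tail_area", "bh"),
                       lambda = seq(0.2, 0.8, by = 0.1)) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  pi0 <- if (method == "tail_area") {
    est <- vapply(lambda, function(l) sum(p > l) / ((1 - l) * m), numeric(1))
    min(1, max(0, mean(est)))
  } else 1
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))
  q[o] <- q
  attr(q, "pi0") <- pi0
  q
}

#' Run the moderated differential-expression analysis
#'
#' Per-protein fits, one assay-wide hyperparameter estimation over all
#' testable proteins, moderated t statistics, FDR adjustment and
#' significance flags. Log-fold changes are old minus young (log2).
#'
#' @param quant Log2-scale, normalized [protein_quant()] that has passed the
#'   group-missingness filter.
#' @param design Study design.
#' @param covariates Covariates to adjust for (default sex and
#'   hypertension).
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param fdr `"auto"` (tail_area when >= 200 proteins, else bh),
#'   `"tail_area"` or `"bh"`.
#' @return Data frame per protein: `protein`, `logFC`, `t`, `df_total`,
#'   `p_value`, `p_adjusted`, `neg_log10_p_adjusted`, `significant`,
#'   `n_obs`; untestable proteins carry NA statistics. Attributes: `hyper`,
#'   `pi0`, `fdr_method`, `n_untestable`.
#' @export
run_de <- function(quant, design, covariates = c("sex", "hypertension"),
                   alpha = 0.05, fdr = c("auto", "tail_area", "bh")) {
  fdr <- match.arg(fdr)
  X <- build_design_matrix(design, covariates)
  fits <- fit_protein_lm(quant, X)
  ok <- fits$testable
  if (!any(ok)) stop("no testable proteins", call. = FALSE)
  hyper <- estimate_eb_hyperparams(fits$s2[ok], fits$df[ok])
  mt <- moderated_t(fits$logFC[ok], fits$s2[ok], fits$df[ok], fits$v[ok],
                    hyper)
  method <- if (fdr == "auto") {
    if (sum(ok) >= 200L) "tail_area" else "bh"
  } else fdr
  q <- adjust_fdr(mt$p_value, method)
  out <- data.frame(protein = fits$protein,
                    logFC = fits$logFC,
                    t = NA_real_, df_total = NA_real_,
                    p_value = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  out$t[ok] <- mt$t
  out$df_total[ok] <- mt$df_total
  out$p_value[ok] <- mt$p_value
  out$p_adjusted[ok] <- as.numeric(q)
  out$neg_log10_p_adjusted <- -log10(out$p_adjusted)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out$n_obs <- fits$n_obs
  attr(out, "hyper") <- hyper
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "fdr_method") <- method
  attr(out, "n_untestable") <- sum(!ok)
  out
}
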