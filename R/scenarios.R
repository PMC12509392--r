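# Self-contained validation scenarios for the statistical engine. These are
# the package's study conditions: they generate ground-truthed synthetic
# data, run the pipeline, and measure operating characteristics
# (calibration, power, false-discovery proportion, parameter recovery).

#' Null calibration of the moderated t
#'
#' Simulates a fully null experiment (no differential proteins) at the
#' protein level, with per-protein variances drawn from the scaled inverse
#' chi-square prior (`d0 = 4`, `s0_sq = 0.05`) so Gaussian log2 noise
#' follows the moderated-t hierarchical model exactly, then runs the full
#' differential-expression analysis and reports the fraction of raw
#' p-values below 0.05 (nominal 0.05) and the number of proteins called
#' significant after FDR at q < 0.05 (expected at most ~1).
#'
#' @param n_proteins Number of null proteins (default 20000).
#' @param seed Integer seed.
#' @return List: `frac_p_lt_05`, `n_significant`, `n_proteins`.
#' @export
scenario_null_calibration <- function(n_proteins = 20000L, seed = 1L) {
  design <- default_study_design()
  cfg <- sim_config(n_proteins = n_proteins, de_fraction = 0, seed = seed)
  truth <- simulate_ground_truth(cfg, design)
  quant <- simulate_protein_matrix(truth,
                                   var_prior = list(d0 = 4, s0_sq = 0.05),
                                   seed = seed + 1L)
  de <- run_de(quant, design)
  list(frac_p_lt_05 = mean(de$p_value < 0.05, na.rm = TRUE),
       n_significant = sum(de$significant, na.rm = TRUE),
       n_proteins = n_proteins)
}

#' Power, FDR control and effect-size recovery of the full pipeline
#'
#' Replicated PSM-level simulations (10% differential proteins at
#' |log2 FC| = `effect`, reporter noise CV 0.1, no co-isolation and no
#' missingness so ratio compression and dropout do not confound the
#' statistical operating characteristics) pushed through impurity
#' correction, interference filtering, rollup, log2 transform and moderated
#' differential expression. Reports sensitivity and false-discovery
#' proportion at q < 0.05 and the mean sign-corrected estimated log-fold
#' change over true differential proteins, averaged over replicates.
#'
#' @param n_replicates Number of simulated experiments (default 20).
#' @param n_proteins Proteins per replicate (default 500).
#' @param effect True |log2 FC| of differential proteins (default 2).
#' @param seed Integer seed.
#' @return List: `sensitivity`, `fdp`, `mean_logfc_de` (sign-corrected),
#'   per-replicate vectors, and the settings used.
#' @export
scenario_power_fdr <- function(n_replicates = 20L, n_proteins = 500L,
                               effect = 2, seed = 1L) {
  design <- default_study_design()
  impurity <- example_impurity_matrix()
  db <- generate_protein_db(n_proteins, seed = seed)
  sens <- fdp <- lfc <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_proteins = n_proteins, de_fraction = 0.1,
                      effect_size_log2 = effect, reporter_noise_cv = 0.1,
                      interference = list(dist = "fixed", value = 0),
                      missing_rate = 0, seed = seed + 13L * r)
    truth <- simulate_ground_truth(cfg, design)
    psms <- simulate_psm_table(truth, db, impurity, cfg)
    q <- quantify_psms(psms, impurity, design, normalize = FALSE)
    de <- run_de(q$quant, design)
    m <- merge(de, truth$table, by.x = "protein", by.y = "protein_id")
    is_de <- m$is_differential
    called <- m$significant & !is.na(m$significant)
    sens[r] <- mean(called[is_de])
    fdp[r] <- sum(called & !is_de) / max(1L, sum(called))
    lfc[r] <- mean(m$logFC[is_de] * sign(m$group_effect_log2[is_de]))
  }
  list(sensitivity = mean(sens), fdp = mean(fdp), mean_logfc_de = mean(lfc),
       sensitivity_by_rep = sens, fdp_by_rep = fdp, logfc_by_rep = lfc,
       effect = effect, n_replicates = n_replicates,
       n_proteins = n_proteins)
}

#' Recovery of empirical-Bayes hyperparameters
#'
#' Draws per-protein variances from the hierarchical model with known prior
#' (`sigma2 ~ s0_sq * d0 / chisq(d0)`, `s2 | sigma2 ~ sigma2 * chisq(df)/df`)
#' and re-estimates the hyperparameters by the package's moment-matching
#' estimator.
#'
#' @param n_proteins Number of simulated variances (default 20000).
#' @param d0,s0_sq True prior degrees of freedom and variance.
#' @param df Residual degrees of freedom per protein (default 12, the
#'   16-sample 4-coefficient design).
#' @param seed Integer seed.
#' @return List: `d0_hat`, `s0_sq_hat`, plus the true values.
#' @export
scenario_eb_recovery <- function(n_proteins = 20000L, d0 = 4, s0_sq = 0.05,
                                 df = 12, seed = 1L) {
  set.seed(seed)
  sigma2 <- s0_sq * d0 / stats::rchisq(n_proteins, d0)
  s2 <- sigma2 * stats::rchisq(n_proteins, df) / df
  h <- estimate_eb_hyperparams(s2, df)
  list(d0_hat = h$d0, s0_sq_hat = h$s0_sq, d0 = d0, s0_sq = s0_sq, df = df)
}

#' Impurity-correction round trip error
#'
#' Forward-mixes random positive reporter vectors through an impurity
#' matrix and corrects them back; reports the maximum absolute recovery
#' error over PSMs.
#'
#' @param n_psms Number of random PSMs (default 1000).
#' @param impurity Impurity matrix (default [example_impurity_matrix()]).
#' @param seed Integer seed.
#' @return List: `max_abs_error`, `n_psms`.
#' @export
scenario_impurity_roundtrip <- function(n_psms = 1000L,
                                        impurity = example_impurity_matrix(),
                                        seed = 1L) {
  set.seed(seed)
  n_ch <- ncol(impurity)
  true <- matrix(stats::rlnorm(n_psms * n_ch, 0, 1), n_psms, n_ch)
  mixed <- true %*% t(impurity)
  corrected <- .correct_reporter_matrix(mixed, impurity)
  list(max_abs_error = max(abs(corrected - true)), n_psms = n_psms)
}
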