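# Clinical-table statistics: exact Fisher tests on 2x2 contingency tables
# by hypergeometric enumeration, group summaries (mean (SD), count (%)),
# and two-sample tests for continuous characteristics.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact enumeration: the two-sided p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables at
#' most as probable as the observed one (a relative tolerance factor of
#' `1 + 1e-7` guards floating-point comparisons at symmetric tables).
#' Degenerate margins (an all-zero row or column) give p = 1.
#'
#' @param tab 2x2 integer matrix: rows = groups (young/old), columns =
#'   trait present/absent.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("tab must be a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total
  n <- sum(tab[2, ])   # row 2 total
  k <- sum(tab[, 1])   # column 1 total
  if (m == 0 || n == 0 || k == 0 || sum(tab[, 2]) == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  mass <- stats::dhyper(supp, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(mass[mass <= p_obs * (1 + 1e-7)]))
}

#' Printed contingency counts of a 16-patient nephrectomy cohort
#'
#' Categorical characteristics of a matched nephrectomy cohort (8 young, 8
#' old) used as the reference example for [fisher_exact_2x2()]: counts of
#' patients with the trait in each group.
#'
#' @return Data frame: `characteristic`, `young_yes`, `young_n`, `old_yes`,
#'   `old_n`.
#' @export
nephrectomy_cohort_counts <- function() {
  data.frame(
    characteristic = c("sex_female", "race_white", "hypertension",
                       "diabetes", "smoking_history"),
    young_yes = c(3L, 7L, 0L, 0L, 3L),
    young_n = 8L,
    old_yes = c(4L, 8L, 4L, 0L, 4L),
    old_n = 8L,
    stringsAsFactors = FALSE
  )
}

# 2x2 table from trait counts: rows young/old, cols present/absent
contingency_from_counts <- function(young_yes, young_n, old_yes, old_n) {
  matrix(c(young_yes, young_n - young_yes,
           old_yes, old_n - old_yes),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("young", "old"), c("present", "absent")))
}

#' Two-sample test for a continuous clinical characteristic
#'
#' Wilcoxon rank-sum (exact enumeration when the combined sample size is at
#' most 20 and there are no ties, normal approximation with tie correction
#' otherwise) or Welch's t-test. When all values are tied across both
#' groups, p = 1.
#'
#' @param young,old Numeric vectors (each n >= 2).
#' @param method `"wilcoxon"` (default) or `"welch_t"`.
#' @return Two-sided p-value.
#' @export
continuous_group_test <- function(young, old,
                                  method = c("wilcoxon", "welch_t")) {
  method <- match.arg(method)
  young <- young[!is.na(young)]; old <- old[!is.na(old)]
  if (length(young) < 2L || length(old) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  all_vals <- c(young, old)
  if (length(unique(all_vals)) == 1L) return(1)
  if (method == "wilcoxon") {
    exact <- length(all_vals) <= 20L && !any(duplicated(all_vals))
    suppressWarnings(
      stats::wilcox.test(old, young, exact = exact, correct = TRUE)$p.value)
  } else {
    stats::t.test(old, young, var.equal = FALSE)$p.value
  }
}

# percent rounded half-up to integer (matches "3 (38%)" style formatting)
round_half_up <- function(x) floor(x + 0.5)

#' Group summaries of patient characteristics
#'
#' Numeric columns are summarized per group as mean (sample SD, n-1
#' denominator); categorical/logical columns as count (percent, rounded
#' half-up to an integer). P-values use Fisher's exact test for categorical
#' rows and [continuous_group_test()] for numeric rows.
#'
#' @param data Per-patient data frame including a group column.
#' @param group_col Name of the group column (levels young/old).
#' @param test_continuous Method for numeric rows (`"wilcoxon"` or
#'   `"welch_t"`).
#' @param digits Decimals for mean/SD formatting (default 1).
#' @return Data frame: `characteristic`, `level`, `young`, `old`,
#'   `p_value`, `method`.
#' @export
summarize_characteristics <- function(data, group_col = "group",
                                      test_continuous = "wilcoxon",
                                      digits = 1) {
  if (!group_col %in% names(data))
    stop("no column '", group_col, "' in data", call. = FALSE)
  grp <- factor(data[[group_col]], levels = c("young", "old"))
  rows <- list()
  fmt_num <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return("")
    sprintf("%.*f (%.*f)", digits, mean(x), digits, stats::sd(x))
  }
  fmt_cat <- function(hits, n) {
    if (n == 0L) return("")
    sprintf("%d (%d%%)", hits, round_half_up(100 * hits / n))
  }
  for (cn in setdiff(names(data), group_col)) {
    x <- data[[cn]]
    if (is.numeric(x)) {
      p <- tryCatch(
        continuous_group_test(x[grp == "young"], x[grp == "old"],
                              method = test_continuous),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = cn, level = "",
        young = fmt_num(x[grp == "young"]),
        old = fmt_num(x[grp == "old"]),
        p_value = p, method = test_continuous,
        stringsAsFactors = FALSE)
    } else {
      x <- if (is.logical(x)) factor(x, levels = c(TRUE, FALSE),
                                     labels = c("yes", "no")) else factor(x)
      ny <- sum(grp == "young", na.rm = TRUE)
      no <- sum(grp == "old", na.rm = TRUE)
      first <- levels(x)[1]
      tab <- contingency_from_counts(
        sum(x == first & grp == "young", na.rm = TRUE), ny,
        sum(x == first & grp == "old", na.rm = TRUE), no)
      p <- fisher_exact_2x2(tab)
      for (lv in levels(x)) {
        rows[[length(rows) + 1L]] <- data.frame(
          characteristic = cn, level = lv,
          young = fmt_cat(sum(x == lv & grp == "young", na.rm = TRUE), ny),
          old = fmt_cat(sum(x == lv & grp == "old", na.rm = TRUE), no),
          p_value = p, method = "fisher_exact",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
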