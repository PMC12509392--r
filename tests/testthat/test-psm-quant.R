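test_that("impurity correction solves the mixing system", {
  psms <- make_psms("AAAK", "P1", 0, flat_reporters(1, value = 0) +
                      matrix(100 * (1:16), 1))
  out <- correct_impurities(psms, identity_impurity())
  expect_equal(as.numeric(out[reporter_columns()]),
               as.numeric(psms[reporter_columns()]))

  # 2-channel reduced case: forward-multiply oracle, round trip to <= 1e-9
  M <- matrix(c(0.95, 0.05, 0.03, 0.97), 2, 2)  # columns: true channels
  true <- c(100, 200)
  observed <- as.numeric(M %*% true)
  expect_equal(observed, c(101, 199))
  corrected <- tmtquant:::.correct_reporter_matrix(matrix(observed, 1), M)
  expect_lt(max(abs(corrected - true)), 1e-9)

  # negative exact solution is clipped (and zero becomes missing)
  M2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  exact <- solve(M2, c(1, 0))
  expect_lt(exact[2], 0)
  clipped <- tmtquant:::.correct_reporter_matrix(matrix(c(1, 0), 1), M2)
  expect_equal(clipped[1, 1], exact[1])
  expect_true(is.na(clipped[1, 2]))
})

test_that("impurity round trip holds for random near-stochastic matrices", {
  set.seed(11)
  for (rep in 1:5) {
    M <- identity_impurity() * 0.94
    off <- matrix(stats::runif(256, 0, 0.006), 16, 16)
    diag(off) <- 0
    M <- M + off
    signal <- matrix(stats::rlnorm(50 * 16, 2, 1), 50, 16)
    mixed <- signal %*% t(M)
    back <- tmtquant:::.correct_reporter_matrix(mixed, M)
    expect_lt(max(abs(back - signal)), 1e-9)
  }
})

test_that("singular and malformed impurity matrices are rejected", {
  M <- identity_impurity()
  M[, 2] <- M[, 1]
  expect_error(validate_impurity(M), "singular")
  expect_error(validate_impurity(matrix(1, 3, 4)), "square")
  expect_error(validate_impurity(diag(16) * 0.5), "sanity band")
})

test_that("interference filter keeps the 50% boundary and preserves order", {
  psms <- make_psms(c("AK", "CK", "DK"), "P1", c(0.10, 0.50, 0.51),
                    flat_reporters(3))
  out <- filter_interference(psms)
  expect_equal(out$interference, c(0.10, 0.50))
  expect_equal(attr(out, "n_removed"), 1)

  empty <- filter_interference(psms[0, ])
  expect_equal(nrow(empty), 0)
  none <- filter_interference(make_psms("AK", "P1", 0, flat_reporters(1)))
  expect_equal(attr(none, "n_removed"), 0)

  # idempotence
  twice <- filter_interference(out)
  expect_equal(twice$interference, out$interference)
  expect_equal(attr(twice, "n_removed"), 0)
})

test_that("rollup sums PSMs per protein and masks all-absent cells", {
  design <- default_study_design()
  psms <- make_psms(c("AAAK", "CCCK"), "P1", 0, flat_reporters(2, 10))
  r <- rollup_to_protein(psms, design)
  expect_equal(unname(r$values["P1", ]), rep(20, 16))

  psms2 <- make_psms("DDDK", "P2", 0, flat_reporters(1, 10, na_cols = 3))
  r2 <- rollup_to_protein(rbind(psms, psms2), design)
  expect_true(is.na(r2$values["P2", 3]))
  expect_equal(unname(r2$values["P2", 1]), 10)

  # additivity: splitting one PSM's intensity into two leaves the matrix
  # unchanged
  half <- make_psms(c("AAAK", "AAAZ", "CCCK"), "P1", 0,
                    rbind(flat_reporters(2, 5), flat_reporters(1, 10)))
  half$sequence[2] <- "AAAK"  # same peptide, split intensity
  r3 <- rollup_to_protein(half, design)
  expect_equal(r3$values, r$values)

  # order invariance
  perm <- rbind(psms2, psms)[c(3, 1, 2), ]
  r4 <- rollup_to_protein(perm, design)
  expect_equal(r4$values[rownames(r2$values), ], r2$values)

  # shared peptides are excluded with a warning
  shared <- rbind(psms,
                  make_psms("AAAK", "P9", 0, flat_reporters(1, 10)))
  expect_warning(r5 <- rollup_to_protein(shared, design), "shared")
  expect_false("P9" %in% rownames(r5$values))
  # P1 keeps only its unique peptide CCCK
  expect_equal(unname(r5$values["P1", ]), rep(10, 16))
})

test_that("group missingness filter removes at >= 50% in either group", {
  design <- default_study_design()
  v <- matrix(100, 3, 16,
              dimnames = list(c("A", "B", "C"), design$sample_id))
  v["A", 1:4] <- NA  # 4 of 8 young missing = 50% -> removed
  v["B", c(1:3, 9:11)] <- NA  # 3 of 8 in each group -> retained
  q <- protein_quant(v, "raw")
  out <- filter_missing_by_group(q, design)
  expect_equal(rownames(out$values), c("B", "C"))
  expect_equal(attr(out, "removed"), "A")

  # exclusive variant keeps the exactly-50% protein
  out2 <- filter_missing_by_group(q, design, inclusive = FALSE)
  expect_equal(rownames(out2$values), c("A", "B", "C"))

  # idempotence
  again <- filter_missing_by_group(out, design)
  expect_equal(again$values, out$values)
})

test_that("log2 transform and median normalization follow their contracts", {
  design <- default_study_design()
  v <- matrix(8, 2, 16, dimnames = list(c("A", "B"), design$sample_id))
  v["B", 2] <- 1
  v["B", 3] <- NA
  q <- log2_transform(protein_quant(v, "raw"))
  expect_equal(q$scale, "log2")
  expect_equal(unname(q$values["A", 1]), 3)
  expect_equal(unname(q$values["B", 2]), 0)
  expect_true(is.na(q$values["B", 3]))

  vneg <- v; vneg["A", 5] <- -1
  qneg <- structure(list(values = vneg, scale = "raw"),
                    class = "protein_quant")
  expect_error(log2_transform(qneg), "negative intensity")

  m <- matrix(c(1, 2, 3), 3, 16,
              dimnames = list(c("A", "B", "C"), design$sample_id))
  n <- median_normalize(protein_quant(m, "log2"))
  expect_equal(unname(n$values[, 1]), c(-1, 0, 1))
  const <- median_normalize(protein_quant(
    matrix(5, 3, 16, dimnames = dimnames(m)), "log2"))
  expect_true(all(const$values == 0))

  set.seed(8)
  r <- matrix(stats::rnorm(48), 3, 16, dimnames = dimnames(m))
  r[1, 2] <- NA
  rn <- median_normalize(protein_quant(r, "log2"))
  meds <- apply(rn$values, 2, stats::median, na.rm = TRUE)
  expect_lt(max(abs(meds)), 1e-12)
  expect_error(median_normalize(protein_quant(2^r, "raw")), "log2")
})

test_that("quantify_psms reports per-step counts on the bundled toy table", {
  design <- read_design_tsv(system.file("extdata", "toy_design.tsv",
                                        package = "tmtquant"))
  psms <- read_psm_tsv(system.file("extdata", "toy_psms.tsv",
                                   package = "tmtquant"))
  res <- quantify_psms(psms, identity_impurity(), design)
  rep <- res$report
  expect_equal(rep$remaining[rep$step == "input_psms"], 12)
  expect_equal(rep$removed[rep$step == "interference_filter"], 4)
  expect_equal(rep$remaining[rep$step == "proteins_rolled_up"], 3)
  expect_equal(rep$removed[rep$step == "group_missingness_filter"], 1)
  expect_equal(sort(rownames(res$quant$values)), c("P1", "P4"))
})
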