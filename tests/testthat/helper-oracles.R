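# Independent oracles and small fixture builders shared across tests.

# Character-by-character tryptic digestion: cleave after K/R unless the next
# residue is P. Deliberately a different implementation path from the
# package's regex split.
oracle_digest <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  peps <- character(0)
  cur <- character(0)
  for (i in seq_along(chars)) {
    cur <- c(cur, chars[i])
    nxt <- if (i < length(chars)) chars[i + 1] else ""
    if (chars[i] %in% c("K", "R") && nxt != "P") {
      peps <- c(peps, paste(cur, collapse = ""))
      cur <- character(0)
    }
  }
  if (length(cur)) peps <- c(peps, paste(cur, collapse = ""))
  peps
}

oracle_count_peptides <- function(sequence, lo = 6, hi = 30) {
  p <- unique(oracle_digest(sequence))
  sum(nchar(p) >= lo & nchar(p) <= hi)
}

random_protein <- function(len, kr_boost = TRUE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep(1, 20)
  if (kr_boost) w[aa %in% c("K", "R", "P")] <- 3  # enrich K/R-P edge cases
  paste(sample(aa, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

# Minimal PSM table builder: one row per call element, all 16 reporters.
make_psms <- function(sequence, protein, interference, reporters) {
  df <- data.frame(sequence = sequence, protein = protein,
                   interference = interference, stringsAsFactors = FALSE)
  stopifnot(ncol(reporters) == 16)
  cbind(df, stats::setNames(as.data.frame(reporters),
                            tmtquant::reporter_columns()))
}

flat_reporters <- function(n_rows, value = 100, na_cols = NULL) {
  m <- matrix(value, n_rows, 16)
  if (!is.null(na_cols)) m[, na_cols] <- NA_real_
  m
}

# Brute-force average-linkage agglomeration returning merge heights.
oracle_average_linkage_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  d <- as.matrix(dist(x))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}
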