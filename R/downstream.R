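# Descriptive multivariate views: PCA biplot tables, Z-score heatmap with
# hierarchical clustering, per-group five-number summaries, and annotation
# overlap/coverage counting.

#' PCA biplot tables for a protein subset
#'
#' Complete-case proteins only (proteins with any missing value are dropped
#' and reported); each protein row is centered and by default unit-scaled
#' before singular value decomposition of the samples x proteins matrix.
#' Returns score and loading tables plus the top proteins by loading norm
#' over the first two components.
#'
#' @param quant Log2-scale [protein_quant()].
#' @param proteins Optional accession subset (default: all).
#' @param k_loadings How many top-loading proteins to report (default 10).
#' @param scale. Unit-scale protein rows (default TRUE; zero-variance rows
#'   are dropped when scaling).
#' @return List of class `pca_biplot`: `scores` (samples x PCs), `loadings`
#'   (proteins x PCs), `explained_variance_ratio`, `top_loadings`,
#'   `dropped` (incomplete or constant proteins).
#' @export
pca_biplot <- function(quant, proteins = NULL, k_loadings = 10L,
                       scale. = TRUE) {
  stopifnot(inherits(quant, "protein_quant"))
  v <- quant$values
  if (!is.null(proteins)) {
    miss <- setdiff(proteins, rownames(v))
    if (length(miss))
      stop("proteins not in matrix: ", paste(miss, collapse = ", "),
           call. = FALSE)
    v <- v[proteins, , drop = FALSE]
  }
  complete <- rowSums(is.na(v)) == 0L
  dropped <- rownames(v)[!complete]
  v <- v[complete, , drop = FALSE]
  if (scale.) {
    sds <- apply(v, 1, stats::sd)
    dropped <- c(dropped, rownames(v)[sds == 0])
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 3L)
    stop("fewer than 3 complete proteins for PCA", call. = FALSE)
  pr <- stats::prcomp(t(v), center = TRUE, scale. = scale.)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  norm2 <- sqrt(rowSums(pr$rotation[, 1:2, drop = FALSE]^2))
  top <- names(sort(norm2, decreasing = TRUE))[seq_len(min(k_loadings,
                                                           length(norm2)))]
  structure(list(scores = pr$x, loadings = pr$rotation,
                 explained_variance_ratio = evr, top_loadings = top,
                 dropped = dropped),
            class = "pca_biplot")
}

#' @export
print.pca_biplot <- function(x, ...) {
  cat(sprintf("PCA biplot: %d samples x %d proteins; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), nrow(x$loadings),
              100 * x$explained_variance_ratio[1],
              100 * x$explained_variance_ratio[2]))
  cat("top loadings:", paste(x$top_loadings, collapse = ", "), "\n")
  invisible(x)
}

#' Z-score heatmap specification for the top differentially expressed proteins
#'
#' Selects the `k` proteins with the smallest adjusted p (ties broken by
#' larger |logFC| then accession), Z-scores each protein row over present
#' values, and orders rows and columns by hierarchical clustering
#' (Euclidean distance, average linkage by default).
#'
#' @param de DE result table from [run_de()].
#' @param quant [protein_quant()] holding the plotted values.
#' @param k Number of proteins (default 50; all testable if fewer).
#' @param dist_method,linkage Distance and linkage for [stats::hclust()].
#' @return List of class `heatmap_spec`: `matrix` (Z-scores, clustered
#'   protein order not applied), `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust`, `proteins`.
#' @export
zscore_heatmap <- function(de, quant, k = 50L, dist_method = "euclidean",
                           linkage = "average") {
  stopifnot(inherits(quant, "protein_quant"))
  ok <- de[!is.na(de$p_adjusted), , drop = FALSE]
  o <- order(ok$p_adjusted, -abs(ok$logFC), ok$protein)
  top <- ok$protein[o][seq_len(min(k, nrow(ok)))]
  m <- quant$values[top, , drop = FALSE]
  z <- t(apply(m, 1, function(r) {
    mu <- mean(r, na.rm = TRUE)
    s <- stats::sd(r, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, length(r)) else (r - mu) / s
  }))
  dimnames(z) <- dimnames(m)
  rh <- stats::hclust(stats::dist(z, method = dist_method), method = linkage)
  ch <- stats::hclust(stats::dist(t(z), method = dist_method),
                      method = linkage)
  structure(list(matrix = z, row_order = rh$order, col_order = ch$order,
                 row_hclust = rh, col_hclust = ch, proteins = top),
            class = "heatmap_spec")
}

#' Per-protein per-group five-number summaries
#'
#' Min, lower quartile, median, upper quartile and max over present values
#' (linear-interpolation quantiles), for box-plot style displays.
#'
#' @param quant [protein_quant()].
#' @param design Study design.
#' @param proteins Accessions to summarize.
#' @return Data frame: `protein`, `group`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max` (all NA when a group has no present values).
#' @export
group_boxplot_stats <- function(quant, design, proteins) {
  stopifnot(inherits(quant, "protein_quant"))
  design <- validate_design(design)
  miss <- setdiff(proteins, rownames(quant$values))
  if (length(miss))
    stop("proteins not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (p in proteins) {
    for (g in levels(design$group)) {
      x <- quant$values[p, design$group == g]
      x <- x[!is.na(x)]
      if (length(x) == 0L) {
        qs <- rep(NA_real_, 5)
      } else {
        qs <- unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein = p, group = g, n = length(x),
        min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap and per-family coverage against an annotation table
#'
#' Counts identified proteins intersecting an annotated set (for example a
#' curated solute-carrier list) and the fraction of each annotation family
#' that was identified.
#'
#' @param identified Character vector of identified accessions.
#' @param annotation Data frame with columns `accession` and `family`.
#' @return List: `n_overlap`, `by_family` (family, n_annotated,
#'   n_identified, fraction), `mean_fraction`.
#' @export
annotation_overlap <- function(identified, annotation) {
  if (!all(c("accession", "family") %in% names(annotation)))
    stop("annotation needs columns 'accession' and 'family'", call. = FALSE)
  identified <- unique(identified)
  hit <- annotation$accession %in% identified
  fam <- split(hit, annotation$family)
  by_family <- data.frame(
    family = names(fam),
    n_annotated = vapply(fam, length, integer(1)),
    n_identified = vapply(fam, sum, integer(1)),
    stringsAsFactors = FALSE)
  by_family$fraction <- by_family$n_identified / by_family$n_annotated
  rownames(by_family) <- NULL
  list(n_overlap = length(intersect(identified,
                                    unique(annotation$accession))),
       by_family = by_family,
       mean_fraction = mean(by_family$fraction))
}
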