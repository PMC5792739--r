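# Parental-vs-derivative differential expression: median-of-ratios size
# factors, FPKM, a negative-binomial Wald test with method-of-moments
# dispersion, the joint padj/fold-change call with base-mean pre-filtering,
# replicate-correlation QC and z-score matrices.

#' Differential-expression configuration
#'
#' @param min_base_mean Genes with mean normalised count below this are
#'   removed before the final multiple-testing adjustment (default 10).
#' @param padj_threshold Adjusted-p threshold for a DE call (default 0.01).
#' @param lfc_threshold Minimum absolute log2 fold change for a DE call
#'   (default 2, i.e. a fourfold change).
#' @param dispersion_floor Lower bound for the method-of-moments dispersion,
#'   avoiding degenerate Wald standard errors.
#' @param qc_transform Abundance transform for replicate-correlation QC.
#' @return A `de_config` list.
#' @export
de_config <- function(min_base_mean = 10, padj_threshold = 0.01,
                      lfc_threshold = 2, dispersion_floor = 1e-8,
                      qc_transform = c("log2_fpkm", "log2_tpm")) {
  if (min_base_mean <= 0 || padj_threshold <= 0 || lfc_threshold <= 0)
    stopf("thresholds must be positive")
  structure(list(min_base_mean = min_base_mean,
                 padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold,
                 dispersion_floor = dispersion_floor,
                 qc_transform = match.arg(qc_transform)),
            class = "de_config")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of the
#' gene's count to its across-sample geometric mean. Because the
#' geometric-mean reference is computed from the same matrix, a global
#' rescaling of all counts leaves the factors unchanged; only relative
#' library depth moves them.
#'
#' @param counts Genes x samples non-negative matrix.
#' @return Named per-sample factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  nz <- rowSums(counts > 0) == ncol(counts)
  if (!any(nz)) stopf("no gene has nonzero counts in every sample")
  logg <- rowMeans(log(counts[nz, , drop = FALSE]))
  apply(counts[nz, , drop = FALSE], 2, function(col) median(exp(log(col) - logg)))
}

#' Fragments per kilobase per million
#'
#' `fpkm_gj = count_gj * 1e9 / (length_g * total_j)`.
#'
#' @param counts Genes x samples matrix.
#' @param gene_lengths Per-gene lengths in bp (> 0).
#' @param totals Per-sample library totals (> 0); defaults to column sums.
#' @return Matrix of FPKM values.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(gene_lengths <= 0)) stopf("gene lengths must be > 0")
  if (any(totals <= 0)) stopf("library totals must be > 0")
  counts * 1e9 / outer(as.numeric(gene_lengths), as.numeric(totals))
}

# Transcripts per million; used as the alternative QC transform.
tpm <- function(counts, gene_lengths) {
  rate <- as.matrix(counts) / as.numeric(gene_lengths)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' Per gene: dispersion is estimated by method of moments on size-factor
#' normalised counts (pooled within-group residual variance, floored at
#' `dispersion_floor`), then a negative-binomial GLM with log link, a group
#' indicator and log size-factor offsets is fitted at that fixed dispersion.
#' The Wald statistic on the group coefficient is referred to a t
#' distribution with `n - 2` degrees of freedom, which compensates for the
#' dispersion being estimated from few replicates and keeps the null
#' type-I error calibrated (a normal reference is anticonservative at 5
#' replicates per group).
#'
#' @param counts_a,counts_b Genes x replicates count matrices for the
#'   reference (parental) and comparison (derivative) group; `log2fc` is B
#'   relative to A.
#' @param size_factors Per-sample factors in the order `cbind(a, b)`;
#'   defaults to [size_factors_median_of_ratios()] of the combined matrix.
#' @param dispersion_floor See [de_config()].
#' @return Tibble with `gene`, `base_mean` (mean normalised count over all
#'   samples), `log2fc`, `se_log2fc`, `stat`, `p`, `dispersion`, `status`
#'   (`"ok"` or `"all_zero"`; all-zero genes get `NA` statistics).
#' @export
nb_wald_test <- function(counts_a, counts_b, size_factors = NULL,
                         dispersion_floor = 1e-8) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) != nrow(counts_b)) stopf("gene sets differ between groups")
  na <- ncol(counts_a); nb <- ncol(counts_b)
  if (na < 2 || nb < 2) stopf("need >= 2 replicates per group")
  if (any(dispersion_floor < 0)) stopf("negative dispersion floor")
  counts <- cbind(counts_a, counts_b)
  if (is.null(size_factors)) size_factors <- size_factors_median_of_ratios(counts)
  if (length(size_factors) != na + nb || any(size_factors <= 0))
    stopf("`size_factors` must be %d positive values", na + nb)

  grp <- c(rep(0L, na), rep(1L, nb))
  off <- log(size_factors)
  yn <- sweep(counts, 2, size_factors, "/")
  m_a <- rowMeans(yn[, grp == 0, drop = FALSE])
  m_b <- rowMeans(yn[, grp == 1, drop = FALSE])
  rss <- rowSums((yn[, grp == 0, drop = FALSE] - m_a)^2) +
    rowSums((yn[, grp == 1, drop = FALSE] - m_b)^2)
  s2 <- rss / (na + nb - 2)
  mu_bar <- rowMeans(yn)
  mu_sq <- (na * m_a^2 + nb * m_b^2) / (na + nb)
  disp <- pmax((s2 - mu_bar) / pmax(mu_sq, 1e-300), dispersion_floor)

  genes <- rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts)))
  all_zero <- rowSums(counts) == 0
  est <- map(seq_len(nrow(counts)), function(g) {
    if (all_zero[g]) return(c(NA_real_, NA_real_))
    fit <- tryCatch(
      suppressWarnings(glm(counts[g, ] ~ grp + offset(off),
                           family = MASS::negative.binomial(theta = 1 / disp[g]))),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA_real_))
    sm <- suppressWarnings(summary(fit)$coefficients)
    if (nrow(sm) < 2) return(c(NA_real_, NA_real_))
    c(sm[2, 1], sm[2, 2])
  })
  beta <- map_dbl(est, 1); se <- map_dbl(est, 2)
  stat <- beta / se
  tibble(gene = genes,
         base_mean = unname(mu_bar),
         log2fc = beta / log(2),
         se_log2fc = se / log(2),
         stat = stat,
         p = 2 * pt(-abs(stat), df = na + nb - 2),
         dispersion = unname(disp),
         status = unname(ifelse(all_zero, "all_zero",
                                ifelse(is.na(beta), "unstable", "ok"))))
}

#' Run a derivative-vs-parental differential-expression comparison
#'
#' Applies [nb_wald_test()] between the two named groups of a count matrix,
#' removes genes with mean normalised count below `config$min_base_mean`
#' *before* re-running the Benjamini-Hochberg adjustment on the survivors,
#' and calls a gene differentially expressed when `padj` is below
#' `padj_threshold` *and* `|log2fc|` is at least `lfc_threshold`.
#'
#' @param cm A `count_matrix` (see [simulate_counts()]), or a list with
#'   `counts` and a `samples` tibble holding `sample` and `group`.
#' @param derivative,parental Group labels to compare (fold changes are
#'   derivative relative to parental).
#' @param config A [de_config()].
#' @return Tibble with `gene`, `base_mean`, `log2fc`, `p`, `padj`, `is_de`,
#'   `direction` (`"over"`/`"under"`) and `status` (`"ok"`,
#'   `"filtered_low_count"`, `"all_zero"`, `"unstable"`); attribute
#'   `comparison` labels the contrast.
#' @export
run_de_comparison <- function(cm, derivative, parental, config = de_config()) {
  s <- cm$samples
  if (!all(c(derivative, parental) %in% s$group))
    stopf("group '%s' or '%s' not present in the count matrix",
          derivative, parental)
  ia <- which(s$group == parental); ib <- which(s$group == derivative)
  counts_a <- cm$counts[, ia, drop = FALSE]
  counts_b <- cm$counts[, ib, drop = FALSE]
  res <- nb_wald_test(counts_a, counts_b,
                      dispersion_floor = config$dispersion_floor)
  res <- res |>
    mutate(status = ifelse(.data$status == "ok" &
                             .data$base_mean < config$min_base_mean,
                           "filtered_low_count", .data$status))
  keep <- res$status == "ok"
  res$padj <- NA_real_
  res$padj[keep] <- bh_adjust(res$p[keep])
  res <- res |>
    mutate(is_de = !is.na(.data$padj) &
             .data$padj < config$padj_threshold &
             abs(.data$log2fc) >= config$lfc_threshold,
           direction = ifelse(is.na(.data$log2fc), NA_character_,
                              ifelse(.data$log2fc > 0, "over", "under"))) |>
    select("gene", "base_mean", "log2fc", "p", "padj", "is_de",
           "direction", "status")
  attr(res, "comparison") <- paste0(derivative, "_vs_", parental)
  res
}

#' Union of differential-expression calls across comparisons
#'
#' Collects the DE genes of several comparisons, retains the per-comparison
#' direction, reports Venn-style counts per comparison-subset, and flags
#' genes called in opposite directions in different comparisons as
#' `ambiguous`.
#'
#' @param de_list Named list of [run_de_comparison()] tibbles.
#' @return A `de_union` object: list with `members` (gene x comparison x
#'   direction), `union` (per-gene consensus direction with `ambiguous`
#'   flag), and `venn` (counts per subset of comparisons).
#' @export
de_union <- function(de_list) {
  if (is.null(names(de_list)) && length(de_list))
    names(de_list) <- paste0("cmp", seq_along(de_list))
  members <- imap_dfr(de_list, function(tbl, nm) {
    tbl |> filter(.data$is_de) |>
      mutate(comparison = nm) |>
      select("gene", "comparison", "direction")
  })
  if (nrow(members) == 0) {
    out <- list(members = members,
                union = tibble(gene = character(), direction = character(),
                               ambiguous = logical()),
                venn = tibble(subset = character(), n = integer()),
                comparisons = names(de_list))
    return(structure(out, class = "de_union"))
  }
  union_tbl <- members |>
    group_by(.data$gene) |>
    summarise(ambiguous = length(unique(.data$direction)) > 1,
              direction = if (length(unique(.data$direction)) == 1)
                first(.data$direction) else "ambiguous",
              .groups = "drop")
  venn <- members |>
    group_by(.data$gene) |>
    summarise(subset = paste(sort(unique(.data$comparison)), collapse = "&"),
              .groups = "drop") |>
    dplyr::count(.data$subset, name = "n")
  structure(list(members = members, union = union_tbl, venn = venn,
                 comparisons = names(de_list)),
            class = "de_union")
}

#' @export
print.de_union <- function(x, ...) {
  cat(sprintf("<de_union: %d genes across %d comparisons (%d ambiguous)>\n",
              nrow(x$union), length(x$comparisons), sum(x$union$ambiguous)))
  invisible(x)
}

#' Replicate-correlation quality control
#'
#' Computes blind pairwise Pearson correlations between samples on a
#' transformed abundance scale (log2(FPKM + 1) by default, log2(TPM + 1) by
#' config), groups samples by average-linkage hierarchical clustering on
#' correlation distance, and flags any replicate whose most-correlated
#' neighbour belongs to another group. The conventional QC bar for
#' within-group replicate correlation is r > 0.95.
#'
#' @param cm A `count_matrix`.
#' @param config A [de_config()]; `qc_transform` selects the scale.
#' @param k Number of clusters to cut; defaults to the number of groups.
#' @return A `replicate_qc` object: list with `correlations` (matrix),
#'   `samples` (tibble with cluster and nearest-neighbour flags) and
#'   `constant_samples`.
#' @export
replicate_correlation_qc <- function(cm, config = de_config(), k = NULL) {
  if (ncol(cm$counts) < 2) stopf("need >= 2 samples")
  mat <- switch(config$qc_transform,
                log2_fpkm = log2(fpkm(cm$counts, cm$gene_lengths) + 1),
                log2_tpm = log2(tpm(cm$counts, cm$gene_lengths) + 1))
  sds <- apply(mat, 2, sd)
  constant <- colnames(mat)[sds == 0]
  use <- sds > 0
  C <- suppressWarnings(cor(mat[, use, drop = FALSE]))
  hc <- hclust(as.dist(1 - C), method = "average")
  k <- k %||% length(unique(cm$samples$group))
  cl <- cutree(hc, k = min(k, ncol(C)))
  nearest <- vapply(seq_len(ncol(C)), function(j) {
    cc <- C[, j]; cc[j] <- -Inf
    colnames(C)[which.max(cc)]
  }, character(1))
  samp <- cm$samples |>
    filter(.data$sample %in% colnames(C)) |>
    mutate(cluster = unname(cl[.data$sample]),
           nearest = nearest[match(.data$sample, colnames(C))])
  grp <- setNames(cm$samples$group, cm$samples$sample)
  samp <- samp |>
    mutate(nearest_group = unname(grp[.data$nearest]),
           flagged = .data$nearest_group != .data$group)
  structure(list(correlations = C, samples = samp,
                 constant_samples = constant),
            class = "replicate_qc")
}

#' @export
print.replicate_qc <- function(x, ...) {
  cat(sprintf("<replicate_qc: %d samples, %d flagged, min within-group r = %.3f>\n",
              nrow(x$samples), sum(x$samples$flagged),
              min_within_group_cor(x)))
  invisible(x)
}

min_within_group_cor <- function(qc) {
  s <- qc$samples
  vals <- unlist(lapply(split(s$sample, s$group), function(ss) {
    if (length(ss) < 2) return(numeric(0))
    m <- qc$correlations[ss, ss]
    m[upper.tri(m)]
  }))
  if (!length(vals)) NA_real_ else min(vals)
}

#' Per-gene expression z-scores
#'
#' Centres and scales each gene across samples: `(value - mean) / sd`. Genes
#' with zero standard deviation are dropped with a warning.
#'
#' @param mat Genes x samples numeric matrix (e.g. normalised counts).
#' @param genes Optional subset of rownames to keep.
#' @return Matrix of z-scores (rows: retained genes).
#' @export
expression_zscores <- function(mat, genes = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(genes)) mat <- mat[intersect(genes, rownames(mat)), , drop = FALSE]
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant gene(s) with zero variance", sum(sds == 0)))
    mat <- mat[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (mat - rowMeans(mat)) / sds
}
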