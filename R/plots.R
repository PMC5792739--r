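# ggplot2 graphics for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_col
#'   geom_histogram geom_vline geom_tile facet_grid facet_wrap labs
#'   scale_fill_gradient2 theme_minimal element_text theme
#' @export
ggplot2::autoplot

#' Kaplan-Meier curves for a median split
#'
#' @param object A `km_split` from [km_median_split()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_split <- function(object, ...) {
  ggplot(object$curves, aes(.data$time, .data$estimate,
                            colour = .data$stratum)) +
    geom_step() +
    labs(x = "Time (months)", y = "Survival probability",
         colour = "Expression") +
    theme_minimal()
}

#' Null distribution of the randomisation test
#'
#' Histogram of the null concordant-overlap counts with the observed count
#' marked.
#'
#' @param object A `randomisation_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.randomisation_test <- function(object, ...) {
  ggplot(tidy(object), aes(.data$concordant)) +
    geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$observed_count, colour = "red",
               linetype = "dashed") +
    labs(x = "Concordant overlapping genes per random sample", y = "Samples",
         subtitle = sprintf("P(X >= %d) = %.4g", object$observed_count,
                            object$empirical_p)) +
    theme_minimal()
}

#' Signature profiles from an NMF fit
#'
#' @param object An `nmf_signatures`.
#' @param ... Unused.
#' @return A ggplot with one panel per signature, 96 bars each.
#' @export
autoplot.nmf_signatures <- function(object, ...) {
  d <- tidy(object) |>
    mutate(substitution = substr(.data$class, 3, 5),
           class = factor(.data$class, levels = sbs96_classes()))
  ggplot(d, aes(.data$class, .data$weight, fill = .data$substitution)) +
    geom_col() +
    facet_grid(rows = "signature") +
    labs(x = NULL, y = "Probability", fill = "Substitution") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, size = 4))
}

#' Dual-cohort significance scatter
#'
#' Plots -log10 FDR in cohort A against cohort B for the shared genes,
#' highlighting an optional gene subset (e.g. concordant candidates).
#'
#' @param res_a,res_b Screen tibbles from [run_cohort_screen()].
#' @param highlight Optional character vector of genes to colour.
#' @return A ggplot.
#' @export
plot_cohort_scatter <- function(res_a, res_b, highlight = NULL) {
  d <- inner_join(res_a, res_b, by = "gene", suffix = c("_a", "_b")) |>
    mutate(highlighted = .data$gene %in% (highlight %||% character(0)))
  ggplot(d, aes(-log10(.data$fdr_a), -log10(.data$fdr_b),
                colour = .data$highlighted)) +
    geom_point(alpha = 0.5, size = 0.8) +
    labs(x = "-log10 FDR (cohort A)", y = "-log10 FDR (cohort B)",
         colour = "Candidate") +
    theme_minimal()
}

#' Funnel bar chart
#'
#' @param x A `funnel_report` or a funnel tibble (`stage`, `n`).
#' @return A ggplot.
#' @export
plot_funnel <- function(x) {
  d <- if (inherits(x, "funnel_report")) x$funnel else x
  d <- d |> mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot(d, aes(.data$stage, .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Genes") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Z-score heatmap of selected genes
#'
#' @param z A z-score matrix from [expression_zscores()].
#' @return A ggplot tile map.
#' @export
plot_zscore_heatmap <- function(z) {
  d <- as_tibble(as.data.frame.table(z, stringsAsFactors = FALSE)) |>
    setNames(c("gene", "sample", "z"))
  ggplot(d, aes(.data$sample, .data$gene, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90))
}
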