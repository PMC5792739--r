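# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.randomisation_test <- function(x, ...) {
  tibble(sample = seq_along(x$null_counts), concordant = x$null_counts)
}

#' @export
glance.randomisation_test <- function(x, ...) {
  tibble(n_samples = x$params$n_samples, m = x$params$m,
         universe_size = x$params$universe_size,
         list_size = x$params$list_size, p_under = x$params$p_under,
         null_mean = mean(x$null_counts), null_sd = sd(x$null_counts),
         observed = x$observed_count, empirical_p = x$empirical_p,
         empirical_p_plus_one = x$empirical_p_plus_one)
}

#' @export
tidy.nmf_signatures <- function(x, ...) {
  as_tibble(as.data.frame.table(x$signatures, stringsAsFactors = FALSE)) |>
    setNames(c("signature", "class", "weight"))
}

#' @export
glance.nmf_signatures <- function(x, ...) {
  tibble(k = x$k, loss = x$loss, divergence = x$divergence,
         iterations = length(x$objective))
}

#' @export
tidy.km_split <- function(x, ...) x$curves

#' @export
glance.km_split <- function(x, ...) {
  dplyr::bind_cols(tibble(split_value = x$split_value), x$hr)
}

#' @export
tidy.concordance_result <- function(x, ...) x$table

#' @export
glance.concordance_result <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
}

#' @export
tidy.variant_filter_result <- function(x, ...) x$counts

#' @export
glance.variant_filter_result <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "bucket", values_from = "n")
}

#' @export
tidy.funnel_report <- function(x, ...) x$funnel

#' @export
glance.funnel_report <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n") |>
    mutate(randomisation_p = x$randomisation$empirical_p,
           randomisation_p_plus_one = x$randomisation$empirical_p_plus_one)
}

#' @export
tidy.de_union <- function(x, ...) x$members

#' @export
glance.de_union <- function(x, ...) {
  tibble(n_union = nrow(x$union), n_ambiguous = sum(x$union$ambiguous),
         n_comparisons = length(x$comparisons))
}

#' @export
tidy.replicate_qc <- function(x, ...) x$samples

#' @export
glance.replicate_qc <- function(x, ...) {
  tibble(n_samples = nrow(x$samples), n_flagged = sum(x$samples$flagged),
         min_within_group_r = min_within_group_cor(x))
}
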