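# Orthologue resolution, mouse-human direction concordance, candidate
# ranking, and the gene-sampling randomisation null.

#' Resolve a mouse-human orthology table to a one-to-one map
#'
#' Mouse genes whose orthology class is `many2many` are dropped entirely.
#' For `one2many` genes the human partner with the highest protein-identity
#' percentage is kept; identity ties are broken lexicographically on the
#' human identifier with a warning. The result assigns at most one human
#' gene per mouse gene.
#'
#' @param records Tibble with `mouse_gene`, `human_gene`, `ortho_class`,
#'   `pct_identity` (0-100). Duplicate (mouse, human) rows with conflicting
#'   identity are an error.
#' @return Tibble with one row per retained mouse gene.
#' @export
resolve_orthologues <- function(records) {
  need <- c("mouse_gene", "human_gene", "ortho_class", "pct_identity")
  if (!all(need %in% names(records)))
    stopf("orthology records need columns %s", paste(need, collapse = ", "))
  if (any(records$pct_identity < 0 | records$pct_identity > 100))
    stopf("`pct_identity` must lie in [0, 100]")
  records <- distinct(records)
  dup <- records |>
    dplyr::count(.data$mouse_gene, .data$human_gene, name = "nrec") |>
    filter(.data$nrec > 1)
  if (nrow(dup))
    stopf("conflicting identity for %d duplicated mouse/human pair(s), e.g. %s/%s",
          nrow(dup), dup$mouse_gene[1], dup$human_gene[1])

  m2m <- unique(records$mouse_gene[records$ortho_class == "many2many"])
  kept <- records |> filter(!(.data$mouse_gene %in% m2m))
  ties <- kept |>
    group_by(.data$mouse_gene) |>
    filter(.data$pct_identity == max(.data$pct_identity)) |>
    summarise(n_top = n(), .groups = "drop") |>
    filter(.data$n_top > 1)
  if (nrow(ties))
    warn(sprintf("identity ties for %d mouse gene(s); broken lexicographically on human id",
                 nrow(ties)))
  kept |>
    group_by(.data$mouse_gene) |>
    arrange(dplyr::desc(.data$pct_identity), .data$human_gene,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$mouse_gene)
}

#' Expression level associated with poor outcome, from two cohort fits
#'
#' A hazard ratio below 1 per unit log2 expression means higher expression is
#' protective, so *low* expression marks poor outcome; above 1, *high*
#' expression does. The call requires agreement between the two cohorts;
#' disagreement (or an HR of exactly 1) gives `"undefined"`.
#'
#' @param hr_a,hr_b Hazard ratios for the same gene in the two cohorts
#'   (vectorised).
#' @return Character vector in `c("low", "high", "undefined")`.
#' @export
#' @examples
#' human_direction_of_poor_outcome(c(0.60, 1.37, 0.8), c(0.52, 3.45, 1.2))
human_direction_of_poor_outcome <- function(hr_a, hr_b) {
  case_when(
    hr_a < 1 & hr_b < 1 ~ "low",
    hr_a > 1 & hr_b > 1 ~ "high",
    TRUE ~ "undefined"
  )
}

#' Intersect mouse differential expression with human survival hits
#'
#' Maps mouse DE genes through a resolved orthologue map, restricts to the
#' screened human panel, intersects with the dual-significant table and
#' flags concordance: a mouse under-expressed gene is concordant when its
#' human orthologue's poor-outcome expression level is `low`, an
#' over-expressed gene when it is `high`. Funnel counts are reported at every
#' stage.
#'
#' @param mouse_de Tibble with `gene` and `direction` (`"over"`/`"under"`)
#'   for the mouse DE genes (ambiguous-direction genes should be excluded
#'   upstream).
#' @param ortho_map Output of [resolve_orthologues()].
#' @param human_dual Output of [intersect_cohorts()] (dual-significant genes
#'   with `hr_a`, `hr_b`, `same_direction`).
#' @param screened_genes Optional character vector: the human panel analysed
#'   in both cohorts. When given, an intermediate funnel stage counts mapped
#'   genes whose orthologue is on the panel.
#' @return A `concordance_result` object: list with `table` (per-gene rows incl.
#'   human statistics and `concordant` flag) and `funnel` (stage counts).
#' @export
concordance_intersect <- function(mouse_de, ortho_map, human_dual,
                                  screened_genes = NULL) {
  if (!all(c("gene", "direction") %in% names(mouse_de)))
    stopf("`mouse_de` needs columns gene, direction")
  mapped <- mouse_de |>
    inner_join(ortho_map |> select("mouse_gene", "human_gene"),
               by = c(gene = "mouse_gene")) |>
    rename(mouse_gene = "gene", mouse_direction = "direction")
  on_panel <- if (is.null(screened_genes)) mapped else
    mapped |> filter(.data$human_gene %in% screened_genes)
  hits <- on_panel |>
    inner_join(human_dual, by = c(human_gene = "gene"))
  hits <- hits |>
    mutate(human_direction = human_direction_of_poor_outcome(.data$hr_a, .data$hr_b),
           concordant = (.data$mouse_direction == "under" & .data$human_direction == "low") |
             (.data$mouse_direction == "over" & .data$human_direction == "high"))
  funnel <- tibble(
    stage = c("de_genes", "orthologue_mapped",
              if (!is.null(screened_genes)) "panel_intersected",
              "dual_significant", "concordant"),
    n = c(nrow(mouse_de), nrow(mapped),
          if (!is.null(screened_genes)) nrow(on_panel),
          nrow(hits), sum(hits$concordant))
  )
  structure(list(table = hits, funnel = funnel), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result funnel>\n")
  for (i in seq_len(nrow(x$funnel)))
    cat(sprintf("  %-18s %d\n", x$funnel$stage[i], x$funnel$n[i]))
  invisible(x)
}

#' Rank concordant candidate genes
#'
#' Orders candidates by ascending cohort-A hazard ratio with adverse genes
#' (HR > 1) placed last, breaking ties by the cohort-B p-value — the layout
#' of a published candidate table where the strongest protective gene leads
#' and the single adverse gene closes the list.
#'
#' @param candidates Tibble with at least `hr_a` and `p_b`.
#' @return The same tibble, reordered.
#' @export
rank_candidates <- function(candidates) {
  if (!all(c("hr_a", "p_b") %in% names(candidates)))
    stopf("`candidates` needs columns hr_a and p_b")
  candidates |> arrange(.data$hr_a > 1, .data$hr_a, .data$p_b)
}

#' Randomisation test for the concordant-overlap count
#'
#' Draws `n_samples` random gene sets of size `m` from the universe without
#' replacement, assigns each drawn gene an independent random direction
#' (under-expressed with probability `p_under`), and counts how many drawn
#' genes are on the human poor-outcome list *and* match that gene's
#' poor-outcome expression direction (under paired with `low`, over with
#' `high`). The empirical tail probability is inclusive:
#' `P(X >= observed_count)`; the `(r + 1) / (n + 1)` variant is reported
#' alongside.
#'
#' @param universe Tibble with `gene`, `in_human_list` (logical) and
#'   `human_direction` (`"low"`/`"high"` for list genes).
#' @param m Sample size per draw (<= number of universe genes).
#' @param observed_count The observed concordant count whose tail
#'   probability is wanted.
#' @param n_samples Number of random samples (default 1000).
#' @param p_under Probability of assigning "under" (default the
#'   under-expressed frequency observed in the motivating mouse data,
#'   0.4621429; over-expression has probability `1 - p_under`).
#' @param seed Integer seed; fixing it reproduces `null_counts` exactly.
#' @return A `randomisation_test` object with `null_counts`, `empirical_p`,
#'   `empirical_p_plus_one` and the call parameters.
#' @export
randomisation_test <- function(universe, m, observed_count, n_samples = 1000,
                               p_under = 0.4621429, seed = 1) {
  if (!all(c("gene", "in_human_list", "human_direction") %in% names(universe)))
    stopf("`universe` needs columns gene, in_human_list, human_direction")
  N <- nrow(universe)
  m <- check_count(m, "m", min = 0L)
  if (m > N) stopf("`m` (%d) exceeds the universe size (%d)", m, N)
  observed_count <- check_count(observed_count, "observed_count", min = 0L)
  check_prob(p_under, "p_under")
  in_list <- universe$in_human_list
  dir_low <- universe$human_direction == "low"
  p_match <- ifelse(dir_low, p_under, 1 - p_under)

  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      idx <- sample.int(N, m)
      hit <- idx[in_list[idx]]
      if (!length(hit)) return(0L)
      sum(runif(length(hit)) < p_match[hit])
    }, integer(1))
  })
  structure(
    list(null_counts = null_counts,
         observed_count = observed_count,
         empirical_p = mean(null_counts >= observed_count),
         empirical_p_plus_one =
           (sum(null_counts >= observed_count) + 1) / (n_samples + 1),
         params = list(m = m, n_samples = n_samples, p_under = p_under,
                       universe_size = N, list_size = sum(in_list),
                       seed = seed)),
    class = "randomisation_test")
}

#' @export
print.randomisation_test <- function(x, ...) {
  cat(sprintf("<randomisation_test: m = %d of %d, %d samples; observed %d, P(X >= obs) = %.4g (+1: %.4g)>\n",
              x$params$m, x$params$universe_size, x$params$n_samples,
              x$observed_count, x$empirical_p, x$empirical_p_plus_one))
  invisible(x)
}

#' Closed-form moments of the randomisation null
#'
#' For a draw of `m` genes from `N` without replacement and independent
#' direction assignment, the concordant count is `X = sum_j Z_j` over the
#' human-list genes in the universe, with `Z_j` the product of the
#' hypergeometric inclusion indicator and an independent Bernoulli with
#' success probability `p_under` (direction `low`) or `1 - p_under`
#' (`high`). Then `E X = (m/N) sum_j p_j` and the variance follows from the
#' pairwise inclusion probability `m(m-1) / (N(N-1))`.
#'
#' @inheritParams randomisation_test
#' @return One-row tibble with `expectation`, `variance`, `sd`.
#' @export
analytic_expected_concordant <- function(universe, m, p_under = 0.4621429) {
  N <- nrow(universe)
  m <- check_count(m, "m", min = 0L)
  if (m > N) stopf("`m` exceeds the universe size")
  lst <- universe |> filter(.data$in_human_list)
  if (nrow(lst) == 0 || m == 0)
    return(tibble(expectation = 0, variance = 0, sd = 0))
  p <- ifelse(lst$human_direction == "low", p_under, 1 - p_under)
  q <- m / N
  p2 <- if (N > 1) m * (m - 1) / (N * (N - 1)) else q
  s1 <- sum(p); s2 <- sum(p^2)
  ex <- q * s1
  ex2 <- q * s1 + p2 * (s1^2 - s2)
  tibble(expectation = ex, variance = ex2 - ex^2, sd = sqrt(ex2 - ex^2))
}
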