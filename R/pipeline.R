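# End-to-end orchestration: screen both cohorts, call differential
# expression, resolve orthologues, intersect with direction concordance,
# rank candidates and run the randomisation null — all from one config, with
# a machine-readable funnel report.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the cross-stage parameters. All
#' thresholds default to the analysis' published values: screen FDR 0.1,
#' DE adjusted p 0.01 with |log2fc| >= 2 and base-mean filter 10,
#' variant QUAL 20 / support 5 / SNV gap 10 / SV pad 50, and 1000
#' randomisation samples.
#'
#' @param screen_a,screen_b [screen_config()] for the two cohorts. By
#'   default cohort A is adjusted for age and sex and cohort B is not
#'   (mirroring the published design, where adjustment is stated for one
#'   cohort only).
#' @param de A [de_config()].
#' @param filter A [filter_config()] (carried for variant stages).
#' @param n_randomisation Randomisation samples.
#' @param p_under Direction probability for the randomisation null; `NULL`
#'   (default) estimates it from the observed mouse DE direction mix.
#' @param seed Seed propagated to the stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(screen_a = screen_config(),
                            screen_b = screen_config(adjust_covariates = character(0)),
                            de = de_config(), filter = filter_config(),
                            n_randomisation = 1000, p_under = NULL,
                            seed = 1) {
  structure(list(screen_a = screen_a, screen_b = screen_b, de = de,
                 filter = filter, n_randomisation = n_randomisation,
                 p_under = p_under, seed = seed),
            class = "pipeline_config")
}

#' Run the full cross-species pipeline
#'
#' Executes, in dependency order: gene-wise Cox screens of both cohorts,
#' dual-cohort intersection with direction agreement, derivative-vs-parental
#' differential expression for every requested contrast, the DE union,
#' orthologue resolution, the concordance intersection with funnel counts,
#' candidate ranking, and the randomisation null for the concordant count.
#' Results are identical to running the stages individually with the same
#' seeds.
#'
#' The randomisation universe is the set of expressed mouse genes (base mean
#' at or above the DE filter in at least one contrast); a universe gene is
#' "on the human list" when its resolved orthologue is dual-significant with
#' a defined poor-outcome direction. The sample size `m` is the number of
#' orthologue-mapped DE genes, and `p_under` defaults to the observed
#' under-expressed fraction of the DE union.
#'
#' @param cohort_a,cohort_b `cohort_dataset` objects.
#' @param counts A `count_matrix`.
#' @param orthology Orthology record tibble.
#' @param config A [pipeline_config()].
#' @param contrasts List of `c(derivative, parental)` label pairs; default
#'   every non-parental group against the first group.
#' @return A `funnel_report`: list with all stage outputs, the funnel
#'   tibble, ranked `candidates`, the `randomisation` result and a `log` of
#'   applied thresholds.
#' @export
run_all <- function(cohort_a, cohort_b, counts, orthology,
                    config = pipeline_config(), contrasts = NULL) {
  groups <- unique(counts$samples$group)
  if (is.null(contrasts))
    contrasts <- map(setdiff(groups, groups[1]), function(g) c(g, groups[1]))

  log <- c(
    sprintf("screen FDR threshold: %g", config$screen_a$fdr_threshold),
    sprintf("DE: padj < %g, |log2fc| >= %g, base mean >= %g",
            config$de$padj_threshold, config$de$lfc_threshold,
            config$de$min_base_mean),
    sprintf("randomisation: %d samples, seed %d",
            config$n_randomisation, config$seed))

  screen_a <- run_cohort_screen(cohort_a, config$screen_a)
  screen_b <- run_cohort_screen(cohort_b, config$screen_b)
  human_dual <- intersect_cohorts(screen_a, screen_b,
                                  config$screen_a$fdr_threshold)
  human_list <- human_dual |> filter(.data$same_direction)

  de_tables <- map(contrasts, function(ct)
    run_de_comparison(counts, ct[1], ct[2], config$de))
  names(de_tables) <- vapply(de_tables, attr, character(1), "comparison")
  de_un <- de_union(de_tables)
  mouse_de <- de_un$union |> filter(!.data$ambiguous) |>
    select("gene", "direction")

  ortho_map <- resolve_orthologues(orthology)
  screened <- intersect(screen_a$gene, screen_b$gene)
  conc <- concordance_intersect(mouse_de, ortho_map, human_dual,
                                screened_genes = screened)
  candidates <- rank_candidates(conc$table |> filter(.data$concordant))

  # randomisation null over the expressed-gene universe
  expressed <- unique(unlist(map(de_tables, function(tbl)
    tbl$gene[!is.na(tbl$base_mean) &
               tbl$base_mean >= config$de$min_base_mean])))
  dual_dir <- human_list |>
    mutate(direction_poor = human_direction_of_poor_outcome(.data$hr_a, .data$hr_b))
  universe <- tibble(gene = expressed) |>
    left_join(ortho_map |> select("mouse_gene", "human_gene"),
              by = c(gene = "mouse_gene")) |>
    left_join(dual_dir |> select("gene", "direction_poor"),
              by = c(human_gene = "gene")) |>
    mutate(in_human_list = !is.na(.data$direction_poor),
           human_direction = .data$direction_poor) |>
    select("gene", "in_human_list", "human_direction")
  mapped_de <- mouse_de |>
    inner_join(ortho_map |> select("mouse_gene"), by = c(gene = "mouse_gene"))
  m <- sum(mapped_de$gene %in% universe$gene)
  p_under <- config$p_under %||%
    (if (nrow(mouse_de)) mean(mouse_de$direction == "under") else 0.5)
  rand <- randomisation_test(universe, m = m,
                             observed_count = nrow(candidates),
                             n_samples = config$n_randomisation,
                             p_under = p_under, seed = config$seed)

  funnel <- conc$funnel
  structure(
    list(screen_a = screen_a, screen_b = screen_b, human_dual = human_dual,
         de = de_tables, de_union = de_un, ortho_map = ortho_map,
         concordance = conc, candidates = candidates,
         randomisation = rand, funnel = funnel, config = config, log = log),
    class = "funnel_report")
}

#' Render a funnel report as text
#'
#' A pure summary: the stage funnel, the ranked candidate table and the
#' randomisation null; regenerable from the report object alone and never
#' mutating it.
#'
#' @param x A `funnel_report`.
#' @return Character vector of lines, invisibly printable via `cat`.
#' @export
report <- function(x) {
  stopifnot(inherits(x, "funnel_report"))
  lines <- c("Cross-species concordance funnel",
             sprintf("  %-18s %d", x$funnel$stage, x$funnel$n))
  if (nrow(x$candidates) == 0) {
    lines <- c(lines, "", "No concordant candidate genes at the configured thresholds.")
  } else {
    lines <- c(lines, "", sprintf("Candidates (%d), ranked by cohort-A hazard ratio:",
                                  nrow(x$candidates)))
    lines <- c(lines, sprintf("  %-12s %-12s HR_A=%.3f  HR_B=%.3f  dir=%s",
                              x$candidates$mouse_gene, x$candidates$human_gene,
                              x$candidates$hr_a, x$candidates$hr_b,
                              x$candidates$mouse_direction))
  }
  r <- x$randomisation
  lines <- c(lines, "",
             sprintf("Randomisation null (%d samples, m = %d): mean %.2f, P(X >= %d) = %.4g (+1 variant %.4g)",
                     r$params$n_samples, r$params$m, mean(r$null_counts),
                     r$observed_count, r$empirical_p, r$empirical_p_plus_one))
  lines
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}

#' Write the funnel report as JSON
#'
#' @param x A `funnel_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_funnel_json <- function(x, path) {
  stopifnot(inherits(x, "funnel_report"))
  obj <- list(
    funnel = setNames(as.list(x$funnel$n), x$funnel$stage),
    n_candidates = nrow(x$candidates),
    candidates = x$candidates$human_gene,
    randomisation = list(
      m = x$randomisation$params$m,
      n_samples = x$randomisation$params$n_samples,
      p_under = x$randomisation$params$p_under,
      observed = x$randomisation$observed_count,
      empirical_p = x$randomisation$empirical_p,
      empirical_p_plus_one = x$randomisation$empirical_p_plus_one),
    log = x$log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
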