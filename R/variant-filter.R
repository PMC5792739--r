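# Matched-normal-free somatic variant filtering: quality/support thresholds,
# SNV-near-indel (SnpGap-style) removal, strain-panel subtraction in place of
# a paired normal, exclusion near structural variants, and shared/private
# partitioning across cell-line series. Coordinates are 1-based inclusive
# (VCF convention) throughout.

#' Variant filter configuration
#'
#' @param qual_min Minimum variant QUAL kept; records with `qual < qual_min`
#'   are removed (boundary kept).
#' @param support_min Minimum variant-supporting read count kept (strict
#'   inequality for removal, as for QUAL).
#' @param snp_gap SNVs closer than this many bp to an indel are removed
#'   (strict `< snp_gap`); indels themselves are unaffected.
#' @param sv_pad Records within `[start - sv_pad, end + sv_pad]` of a
#'   structural variant (inclusive both ends) are removed.
#' @param panel_match_alt Match the strain panel on chrom+pos+alt (default)
#'   or chrom+pos only.
#' @return A `filter_config` list.
#' @export
filter_config <- function(qual_min = 20, support_min = 5, snp_gap = 10,
                          sv_pad = 50, panel_match_alt = TRUE) {
  if (any(c(qual_min, support_min, snp_gap, sv_pad) < 0))
    stopf("all thresholds must be >= 0")
  structure(list(qual_min = qual_min, support_min = support_min,
                 snp_gap = snp_gap, sv_pad = sv_pad,
                 panel_match_alt = panel_match_alt),
            class = "filter_config")
}

check_records <- function(records) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "support", "vtype")
  if (!all(need %in% names(records)))
    stopf("variant records need columns %s", paste(need, collapse = ", "))
  if (any(records$pos < 1, na.rm = TRUE)) stopf("positions must be >= 1")
  if (!"id" %in% names(records))
    records$id <- sprintf("var%04d", seq_len(nrow(records)))
  records
}

split_kept <- function(records, reason) {
  reason <- as.character(reason)
  removed <- records |> filter(!is.na(reason)) |>
    mutate(reason = reason[!is.na(reason)])
  kept <- records |> filter(is.na(reason))
  list(kept = kept, removed = removed)
}

#' Quality and supporting-read filter
#'
#' Removes records with `qual < qual_min` (reason `"quality"`) or
#' supporting-read count `< support_min` (reason `"support"`); a record
#' failing both is attributed to quality. Boundary values are kept. Records
#' with a missing qual or support field cannot be evaluated and are removed
#' with reason `"unevaluable"`.
#'
#' @param records Variant-record tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `support`, `vtype`).
#' @param config A [filter_config()].
#' @return List with `kept` and `removed` (the latter with a `reason`
#'   column); the two partition the input.
#' @export
quality_support_filter <- function(records, config = filter_config()) {
  records <- check_records(records)
  reason <- case_when(
    is.na(records$qual) | is.na(records$support) ~ "unevaluable",
    records$qual < config$qual_min ~ "quality",
    records$support < config$support_min ~ "support",
    TRUE ~ NA_character_
  )
  split_kept(records, reason)
}

#' Remove SNVs near indels
#'
#' Follows the SnpGap convention of the standard variant toolkits: an SNV
#' whose distance to the nearest indel position on the same contig is
#' strictly less than `gap` is removed (reason `"snp_gap"`); indels are
#' never removed by this stage. Input must be sorted by (chrom, pos).
#'
#' @param records Sorted variant-record tibble.
#' @param config A [filter_config()]; `snp_gap` is the distance.
#' @return `kept` / `removed` partition as in [quality_support_filter()].
#' @export
snp_gap_filter <- function(records, config = filter_config()) {
  records <- check_records(records)
  srt <- order(records$chrom, records$pos)
  if (!identical(srt, seq_len(nrow(records))))
    stopf("records must be sorted by (chrom, pos)")
  gap <- config$snp_gap
  near <- rep(FALSE, nrow(records))
  for (ch in unique(records$chrom)) {
    in_ch <- records$chrom == ch
    ind_pos <- records$pos[in_ch & records$vtype == "indel"]
    if (!length(ind_pos)) next
    snv <- which(in_ch & records$vtype == "snv")
    if (!length(snv)) next
    d <- vapply(records$pos[snv], function(p) min(abs(p - ind_pos)), numeric(1))
    near[snv] <- d < gap
  }
  split_kept(records, ifelse(near, "snp_gap", NA_character_))
}

#' Subtract a strain variant panel
#'
#' Removes records matching the panel exactly on chrom+pos+alt (default) or
#' on chrom+pos only, standing in for a matched germline sample (reason
#' `"strain_panel"`).
#'
#' @param records Variant-record tibble.
#' @param panel Tibble with `chrom`, `pos` and (for exact mode) `alt`.
#' @param config A [filter_config()]; `panel_match_alt` selects the mode.
#' @return `kept` / `removed` partition.
#' @export
subtract_strain_panel <- function(records, panel, config = filter_config()) {
  records <- check_records(records)
  if (is.null(panel) || nrow(panel) == 0)
    return(list(kept = records, removed = records[0, ] |> mutate(reason = character(0))))
  keys <- if (config$panel_match_alt) c("chrom", "pos", "alt") else c("chrom", "pos")
  in_panel <- do.call(paste, records[keys]) %in% do.call(paste, panel[keys])
  split_kept(records, ifelse(in_panel, "strain_panel", NA_character_))
}

#' Exclude variants near structural variants
#'
#' Removes records whose position falls within `[start - pad, end + pad]`
#' (both ends inclusive) of any structural-variant interval on the same
#' contig (reason `"sv_proximity"`).
#'
#' @param records Variant-record tibble.
#' @param svs Tibble of 1-based inclusive intervals (`chrom`, `start`,
#'   `end`).
#' @param config A [filter_config()]; `sv_pad` is the padding.
#' @return `kept` / `removed` partition.
#' @export
exclude_near_sv <- function(records, svs, config = filter_config()) {
  records <- check_records(records)
  if (is.null(svs) || nrow(svs) == 0)
    return(list(kept = records, removed = records[0, ] |> mutate(reason = character(0))))
  if (any(svs$start > svs$end)) stopf("SV intervals need start <= end")
  pad <- config$sv_pad
  hit <- rep(FALSE, nrow(records))
  for (ch in unique(svs$chrom)) {
    s <- svs$start[svs$chrom == ch] - pad
    e <- svs$end[svs$chrom == ch] + pad
    in_ch <- which(records$chrom == ch)
    if (!length(in_ch)) next
    hit[in_ch] <- vapply(records$pos[in_ch],
                         function(p) any(p >= s & p <= e), logical(1))
  }
  split_kept(records, ifelse(hit, "sv_proximity", NA_character_))
}

#' Run the full matched-normal-free filter pipeline
#'
#' Applies the stages in order: quality/support, SNV-near-indel, strain-panel
#' subtraction, structural-variant proximity. Every input record lands in
#' exactly one bucket (kept, or a single removal reason), so
#' `kept + sum(removal buckets) = input` always holds and re-running the
#' pipeline on its own kept set removes nothing.
#'
#' @param vcf Path to a VCF file (read with [read_vcf_records()]) or a
#'   variant-record tibble.
#' @param panel Strain panel tibble (or `NULL`).
#' @param svs Structural-variant interval tibble (or `NULL`).
#' @param config A [filter_config()].
#' @return A `variant_filter_result`: list with `kept`, `removed` (with
#'   `reason` and `stage`), and `counts` (per-bucket tally incl. `input` and
#'   `kept`).
#' @export
run_filter_pipeline <- function(vcf, panel = NULL, svs = NULL,
                                config = filter_config()) {
  records <- if (is.character(vcf)) read_vcf_records(vcf) else check_records(vcf)
  records <- records |> arrange(.data$chrom, .data$pos)
  n_input <- nrow(records)

  removed <- list()
  st <- quality_support_filter(records, config)
  removed$quality_support <- st$removed
  st2 <- snp_gap_filter(st$kept, config)
  removed$snp_gap <- st2$removed
  st3 <- subtract_strain_panel(st2$kept, panel, config)
  removed$strain_panel <- st3$removed
  st4 <- exclude_near_sv(st3$kept, svs, config)
  removed$sv_proximity <- st4$removed
  kept <- st4$kept
  removed_all <- imap_dfr(removed, function(tbl, nm) mutate(tbl, stage = nm))

  buckets <- c("quality", "support", "unevaluable", "snp_gap",
               "strain_panel", "sv_proximity")
  counts <- tibble(
    bucket = c("input", buckets, "kept"),
    n = c(n_input,
          vapply(buckets, function(b) sum(removed_all$reason == b), integer(1)),
          nrow(kept))
  )
  stopifnot(nrow(kept) + nrow(removed_all) == n_input)
  structure(list(kept = kept, removed = removed_all, counts = counts),
            class = "variant_filter_result")
}

#' @export
print.variant_filter_result <- function(x, ...) {
  cat("<variant_filter_result>\n")
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-14s %d\n", x$counts$bucket[i], x$counts$n[i]))
  invisible(x)
}

#' Partition variants shared between cell lines
#'
#' Venn-region counts for two or three variant sets keyed by
#' (chrom, pos, ref, alt): each region is a subset of set names joined by
#' `&`, and every region (including empty ones) is reported.
#'
#' @param sets Named list of 2 or 3 variant-record tibbles (or character
#'   vectors of pre-built keys).
#' @return Tibble with `region` and `n`.
#' @export
partition_shared <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3)
    stopf("shared/private partitioning supports 2 or 3 sets, not %d", length(sets))
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  keys <- map(sets, function(s) {
    if (is.character(s)) unique(s)
    else unique(do.call(paste, s[c("chrom", "pos", "ref", "alt")]))
  })
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  map_dfr(seq_len(nrow(combos)), function(i) {
    pat <- unlist(combos[i, ])
    tibble(region = paste(names(sets)[pat], collapse = "&"),
           n = if (length(all_keys))
             sum(apply(member, 1, function(r) identical(unname(r), unname(pat))))
           else 0L)
  })
}
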