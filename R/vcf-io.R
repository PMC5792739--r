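# Plain-text VCF v4.2 I/O for the filter pipeline. Reading goes through the
# vcfR parser; multi-allelic records are decomposed into one record per
# alternate allele before filtering. Writing emits a minimal header with the
# DP (supporting reads) INFO field the pipeline consumes.

#' Read variant records from a VCF file
#'
#' Parses a VCF v4.2 file, decomposes multi-allelic records into one row per
#' alternate allele, and extracts QUAL and the DP INFO field (used as the
#' supporting-read count). Variant type is classified from allele lengths.
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return Variant-record tibble (`id`, `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `support`, `vtype`).
#' @export
read_vcf_records <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("malformed VCF '%s': %s", path,
                                          conditionMessage(e)))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fx) == 0)
    return(tibble(id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), qual = numeric(),
                  support = numeric(), vtype = character()))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  rec <- tibble(
    id = ifelse(is.na(fx$ID) | fx$ID == ".", sprintf("var%04d", seq_len(nrow(fx))), fx$ID),
    chrom = fx$CHROM,
    pos = as.integer(fx$POS),
    ref = fx$REF,
    alt = fx$ALT,
    qual = suppressWarnings(as.numeric(fx$QUAL)),
    support = dp
  )
  # decompose multi-allelic rows
  rec <- rec |>
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) |>
    tidyr::unnest("alt")
  rec |>
    mutate(vtype = ifelse(nchar(.data$ref) == 1 & nchar(.data$alt) == 1,
                          "snv", "indel")) |>
    arrange(.data$chrom, .data$pos)
}

#' Write variant records as VCF v4.2
#'
#' @param records Variant-record tibble.
#' @param path Output path.
#' @param contig_lengths Optional named contig lengths for header lines.
#' @return `path`, invisibly.
#' @export
write_vcf_records <- function(records, path, contig_lengths = NULL) {
  records <- check_records(records)
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Reads supporting the variant\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\tDP=%d",
                  records$chrom, records$pos, records$id, records$ref,
                  records$alt,
                  ifelse(is.na(records$qual), ".", format(records$qual,
                                                          trim = TRUE)),
                  as.integer(records$support))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a strain variant panel
#'
#' Accepts either a VCF (any record fields beyond chrom/pos/alt are ignored)
#' or a headered 3-column TSV (`chrom`, `pos`, `alt`).
#'
#' @param path Panel file path.
#' @return Tibble with `chrom`, `pos`, `alt`.
#' @export
read_strain_panel <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    read_vcf_records(path) |> select("chrom", "pos", "alt")
  } else {
    as_tibble(read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)) |>
      select("chrom", "pos", "alt")
  }
}

#' Read structural-variant intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used by the filter (`start + 1`, `end` unchanged).
#'
#' @param path Path to a 3+ column BED file (no header).
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_sv_bed <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  tibble(chrom = b[[1]], start = as.integer(b[[2]]) + 1L,
         end = as.integer(b[[3]]))
}
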