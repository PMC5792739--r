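rec_tbl <- function(...) {
  d <- tibble::tibble(...)
  if (!"ref" %in% names(d)) d$ref <- "A"
  if (!"alt" %in% names(d)) d$alt <- "T"
  if (!"qual" %in% names(d)) d$qual <- 50
  if (!"support" %in% names(d)) d$support <- 20
  if (!"vtype" %in% names(d)) d$vtype <- "snv"
  if (!"chrom" %in% names(d)) d$chrom <- "chr1"
  d
}

test_that("quality/support thresholds are strict with kept boundaries", {
  r <- rec_tbl(pos = c(100, 200, 300, 400),
               qual = c(19.9, 20, 30, NA),
               support = c(10, 5, 4, 10))
  out <- quality_support_filter(r)
  expect_equal(out$removed$reason[out$removed$pos == 100], "quality")
  expect_equal(out$removed$reason[out$removed$pos == 300], "support")
  expect_equal(out$removed$reason[out$removed$pos == 400], "unevaluable")
  expect_equal(out$kept$pos, 200)  # qual 20, support 5 both kept
})

test_that("SNV-near-indel removal uses a strict gap and spares indels", {
  r <- rec_tbl(pos = c(100, 105, 110, 500),
               vtype = c("indel", "snv", "snv", "snv"))
  out <- snp_gap_filter(r)
  expect_equal(out$removed$pos, 105)       # 5 bp < 10
  expect_true(all(c(100, 110, 500) %in% out$kept$pos))  # 10 bp boundary kept
  # indels are never removed by this stage, even next to each other
  r2 <- rec_tbl(pos = c(100, 103), vtype = c("indel", "indel"))
  expect_equal(nrow(snp_gap_filter(r2)$removed), 0)
  # a file with no indels passes through unchanged
  r3 <- rec_tbl(pos = c(10, 12, 14))
  expect_equal(nrow(snp_gap_filter(r3)$removed), 0)
  expect_error(snp_gap_filter(rec_tbl(pos = c(200, 100))), "sorted")
})

test_that("strain-panel subtraction matches exactly or by position per config", {
  r <- rec_tbl(pos = c(100, 200), alt = c("T", "G"))
  panel <- tibble::tibble(chrom = "chr1", pos = c(100, 200), alt = c("T", "C"))
  exact <- subtract_strain_panel(r, panel)
  expect_equal(exact$removed$pos, 100)
  expect_equal(exact$kept$pos, 200)  # same position, different alt
  posonly <- subtract_strain_panel(r, panel,
                                   filter_config(panel_match_alt = FALSE))
  expect_equal(sort(posonly$removed$pos), c(100, 200))
  none <- subtract_strain_panel(r, panel[0, ])
  expect_equal(nrow(none$removed), 0)
})

test_that("SV proximity exclusion is inclusive at exactly the pad", {
  svs <- tibble::tibble(chrom = "chr1", start = 1000, end = 1100)
  r <- rec_tbl(pos = c(950, 949, 1150, 1151, 1050))
  out <- exclude_near_sv(r, svs)
  expect_setequal(out$removed$pos, c(950, 1150, 1050))  # boundaries removed
  expect_setequal(out$kept$pos, c(949, 1151))
  r2 <- rec_tbl(chrom = "chr9", pos = 1000)
  expect_equal(nrow(exclude_near_sv(r2, svs)$removed), 0)
})

test_that("SV exclusion agrees with a brute-force position scan", {
  withr::with_seed(19, {
    svs <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                          start = sample.int(10000, 30))
    svs$end <- svs$start + sample.int(300, 30)
    r <- rec_tbl(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                 pos = sample.int(12000, 200)) |> dplyr::arrange(chrom, pos)
  })
  out <- exclude_near_sv(r, svs, filter_config(sv_pad = 50))
  brute <- vapply(seq_len(nrow(r)), function(i) {
    any(svs$chrom == r$chrom[i] &
          r$pos[i] >= svs$start - 50 & r$pos[i] <= svs$end + 50)
  }, logical(1))
  expect_setequal(out$removed$pos, r$pos[brute])
  expect_equal(nrow(out$removed), sum(brute))
})

test_that("the full pipeline buckets every record exactly once and is idempotent", {
  sim <- simulate_variants(n_clean = 50, seed = 23)
  res <- run_filter_pipeline(sim$records, sim$panel, sim$svs)
  counts <- setNames(res$counts$n, res$counts$bucket)
  expect_equal(unname(counts["kept"]), 50)
  expect_equal(unname(counts[c("quality", "support", "snp_gap",
                               "strain_panel", "sv_proximity")]), rep(10, 5))
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(sim$records))
  expect_setequal(res$kept$id, sim$truth$id[sim$truth$bucket == "kept"])
  # idempotence: re-filtering the kept set removes nothing
  res2 <- run_filter_pipeline(res$kept, sim$panel, sim$svs)
  expect_equal(nrow(res2$removed), 0)
  expect_setequal(res2$kept$id, res$kept$id)
})

test_that("independent-predicate stages commute on the final kept set", {
  sim <- simulate_variants(n_clean = 30, seed = 29)
  cfg <- filter_config()
  # quality/support, panel and SV proximity test record-intrinsic predicates,
  # so any order yields the same survivors
  a <- quality_support_filter(sim$records, cfg)
  b <- subtract_strain_panel(a$kept, sim$panel, cfg)
  c1 <- exclude_near_sv(b$kept, sim$svs, cfg)
  x <- exclude_near_sv(sim$records, sim$svs, cfg)
  y <- subtract_strain_panel(x$kept, sim$panel, cfg)
  z <- quality_support_filter(y$kept, cfg)
  expect_setequal(c1$kept$id, z$kept$id)
})

test_that("VCF round trip preserves records and decomposes multi-allelics", {
  sim <- simulate_variants(n_clean = 10, seed = 31)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_records(sim$records, path, contig_lengths = c(chr1 = 2e6, chr2 = 2e6))
  back <- read_vcf_records(path)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$pos, sim$records$pos)
  expect_equal(back$support, sim$records$support)
  expect_equal(back$vtype, sim$records$vtype)
  # multi-allelic decomposition
  manual <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t500\tmv1\tA\tC,G\t44\t.\tDP=9"), manual)
  dec <- read_vcf_records(manual)
  expect_equal(nrow(dec), 2)
  expect_setequal(dec$alt, c("C", "G"))
  # an empty VCF gives an empty record set through the pipeline
  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), empty)
  res <- suppressWarnings(run_filter_pipeline(empty, sim$panel, sim$svs))
  expect_equal(nrow(res$kept), 0)
  expect_true(all(res$counts$n == 0))
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1100", "chr2\t0\t50"), path)
  b <- read_sv_bed(path)
  expect_equal(b$start, c(1000L, 1L))
  expect_equal(b$end, c(1100L, 50L))
})

test_that("shared/private partitioning reproduces hand-enumerated Venn counts", {
  key <- function(pos) tibble::tibble(chrom = "chr1", pos = pos,
                                      ref = "A", alt = "T")
  same <- partition_shared(list(A = key(1:7), B = key(1:7), C = key(1:7)))
  expect_equal(same$n[same$region == "A&B&C"], 7)
  expect_true(all(same$n[same$region != "A&B&C"] == 0))
  disj <- partition_shared(list(A = key(1:3), B = key(4:5)))
  expect_equal(disj$n[disj$region == "A"], 3)
  expect_equal(disj$n[disj$region == "B"], 2)
  expect_equal(disj$n[disj$region == "A&B"], 0)
  hand <- partition_shared(list(A = key(c(1, 2, 3, 4)), B = key(c(3, 4, 5)),
                                C = key(c(4, 5, 6))))
  expect_equal(hand$n[hand$region == "A"], 2)        # 1, 2
  expect_equal(hand$n[hand$region == "A&B"], 1)      # 3
  expect_equal(hand$n[hand$region == "A&B&C"], 1)    # 4
  expect_equal(hand$n[hand$region == "B&C"], 1)      # 5
  expect_equal(hand$n[hand$region == "C"], 1)        # 6
  expect_error(partition_shared(list(key(1), key(1), key(1), key(1))),
               "2 or 3")
})
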