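test_that("every generator is byte-identical under a fixed seed", {
  pairs <- list(
    list(simulate_cohort(50, 20, seed = 3), simulate_cohort(50, 20, seed = 3)),
    list(simulate_cohort_marginal(50, 20, effect_genes = c(G0001 = 0.7), seed = 3),
         simulate_cohort_marginal(50, 20, effect_genes = c(G0001 = 0.7), seed = 3)),
    list(simulate_counts(30, 3, seed = 3), simulate_counts(30, 3, seed = 3)),
    list(simulate_orthology(50, seed = 3), simulate_orthology(50, seed = 3)),
    list(simulate_variants(10, seed = 3), simulate_variants(10, seed = 3)),
    list(simulate_catalogues(simulate_signature_matrix(2, seed = 1),
                             matrix(c(1, 0, 0, 1), 2), 1000, seed = 3),
         simulate_catalogues(simulate_signature_matrix(2, seed = 1),
                             matrix(c(1, 0, 0, 1), 2), 1000, seed = 3)),
    list(make_end_to_end_fixture(seed = 3, n_patients = 40, n_genes = 80,
                                 n_concordant = 3, n_discordant = 1,
                                 n_human_only = 1, n_mouse_only = 1),
         make_end_to_end_fixture(seed = 3, n_patients = 40, n_genes = 80,
                                 n_concordant = 3, n_discordant = 1,
                                 n_human_only = 1, n_mouse_only = 1))
  )
  for (p in pairs)
    expect_identical(serialize(p[[1]], NULL), serialize(p[[2]], NULL))
  expect_false(identical(simulate_counts(30, 3, seed = 3),
                         simulate_counts(30, 3, seed = 4)))
})

test_that("cohort simulation honours the no-censoring limit and validates rates", {
  ch <- simulate_cohort(n_patients = 100, n_genes = 5, censor_rate = 0, seed = 2)
  expect_true(all(ch$samples$event == 1))
  expect_error(simulate_cohort(10, 5, baseline_hazard = 0), "> 0")
  expect_error(simulate_cohort(10, 5, censor_rate = -1), ">= 0")
  expect_error(simulate_cohort(10, 5, effect_genes = c(NOPE = 1)),
               "gene identifiers")
})

test_that("NB counts satisfy the mean-variance relation within 3 standard errors", {
  n <- 5000  # 1e4 draws in total across the two groups
  for (case in list(c(mu = 100, alpha = 0.05), c(mu = 40, alpha = 0.3),
                    c(mu = 100, alpha = 0))) {
    cm <- simulate_counts(n_genes = 1, replicates_per_group = n,
                          baseline_means = case[["mu"]],
                          dispersions = case[["alpha"]],
                          size_factors = rep(1, 2 * n), seed = 21)
    draws <- as.numeric(cm$counts)
    sigma2 <- case[["mu"]] + case[["alpha"]] * case[["mu"]]^2
    se_var <- sqrt((nb_central_moment4(case[["mu"]], case[["alpha"]]) -
                      sigma2^2) / length(draws))
    expect_lt(abs(var(draws) - sigma2), 3 * se_var)
  }
  expect_error(simulate_counts(10, 2, dispersions = -0.1), ">= 0")
})

test_that("size factors scale expected column sums linearly", {
  sf <- c(1, 1, 1, 2, 1, 1)
  cm <- simulate_counts(n_genes = 4000, replicates_per_group = 3,
                        baseline_means = 50, dispersions = 0.05,
                        size_factors = sf, seed = 8)
  sums <- colSums(cm$counts)
  expect_equal(unname(sums[4] / mean(sums[c(1, 2, 3, 5, 6)])), 2,
               tolerance = 0.05)
})

test_that("orthology simulation respects class contracts", {
  pure <- simulate_orthology(200, class_mix = c(one2one = 1, one2many = 0,
                                                many2many = 0), seed = 4)
  expect_equal(nrow(pure), 200)
  expect_equal(anyDuplicated(pure$mouse_gene), 0)
  mix <- simulate_orthology(1000, seed = 4)
  per_gene <- dplyr::count(mix, mouse_gene, ortho_class)
  expect_true(all(per_gene$n[per_gene$ortho_class == "one2one"] == 1))
  expect_true(all(per_gene$n[per_gene$ortho_class == "one2many"] >= 2))
  o2m <- dplyr::filter(mix, ortho_class == "one2many")
  dup_id <- dplyr::summarise(dplyr::group_by(o2m, mouse_gene),
                             dup = anyDuplicated(pct_identity) > 0)
  expect_false(any(dup_id$dup))
  # many2many fraction 0.1 of 1000 -> ~100 dropped by the resolver
  n_m2m <- length(unique(mix$mouse_gene[mix$ortho_class == "many2many"]))
  expect_lt(abs(n_m2m - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_error(simulate_orthology(10, class_mix = c(one2one = 0.5,
                                                    one2many = 0.2,
                                                    many2many = 0.2)),
               "sum to 1")
})

test_that("variant fixture construction is countable per trigger class", {
  sim <- simulate_variants(n_clean = 50, seed = 6)
  expect_equal(nrow(sim$records), 100)
  expect_equal(sum(sim$truth$bucket == "kept"), 50)
  expect_equal(as.vector(table(sim$truth$bucket)[c("quality", "support",
                                                   "snp_gap", "strain_panel",
                                                   "sv_proximity")]),
               rep(10L, 5))
  # panel trigger matches the panel exactly on chrom+pos+alt
  trig <- sim$records[sim$records$id %in%
                        sim$truth$id[sim$truth$bucket == "strain_panel"], ]
  expect_true(all(do.call(paste, trig[c("chrom", "pos", "alt")]) %in%
                    do.call(paste, sim$panel)))
  # with no triggers the filter pipeline is the identity
  clean <- simulate_variants(n_clean = 25,
                             n_per_trigger = c(low_qual = 0, low_support = 0,
                                               near_indel = 0, in_panel = 0,
                                               near_sv = 0), seed = 6)
  res <- run_filter_pipeline(clean$records, clean$panel, clean$svs)
  expect_equal(nrow(res$kept), 25)
  expect_equal(nrow(res$removed), 0)
  expect_error(simulate_variants(n_clean = 5000,
                                 contig_lengths = c(chr1 = 1e5)),
               "overflow")
})

test_that("catalogue simulation follows the planted mixture", {
  sigs <- simulate_signature_matrix(2, seed = 10)
  one <- simulate_catalogues(sigs, matrix(c(1, 0), 1), 1e5, seed = 10)
  expect_gte(cosine_similarity(one[, 1], sigs[1, ]), 0.999)
  zero <- simulate_catalogues(sigs, matrix(c(1, 0), 1), 0, seed = 10)
  expect_true(all(zero == 0))
  both <- simulate_catalogues(sigs, matrix(c(0.5, 0.5), 1), 1e5, seed = 10)
  expect_gte(cosine_similarity(both[, 1], colMeans(sigs)), 0.99)
  expect_error(simulate_catalogues(sigs, matrix(c(-1, 2), 1), 100),
               "non-negative")
  expect_error(simulate_catalogues(sigs * 2, matrix(c(1, 0), 1), 100),
               "sum to 1")
})

test_that("the end-to-end fixture plants the requested role structure", {
  fx <- make_end_to_end_fixture(seed = 2, n_patients = 40, n_genes = 120,
                                n_concordant = 4, n_discordant = 2,
                                n_human_only = 2, n_mouse_only = 2)
  expect_equal(as.vector(table(fx$truth$role)[c("concordant", "discordant",
                                                "human_only", "mouse_only")]),
               c(4L, 2L, 2L, 2L))
  conc <- dplyr::filter(fx$truth, role == "concordant")
  expect_true(all((conc$mouse_direction == "under") ==
                    (conc$human_direction == "low")))
  disc <- dplyr::filter(fx$truth, role == "discordant")
  expect_true(all((disc$mouse_direction == "under") !=
                    (disc$human_direction == "low")))
  # planted log2 fold changes are present in the count simulation truth
  expect_setequal(fx$counts$truth$gene,
                  fx$truth$mouse_gene[fx$truth$log2fc != 0])
})
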