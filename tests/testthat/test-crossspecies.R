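test_that("orthologue resolution follows the identity and class rules", {
  rec <- tibble::tibble(
    mouse_gene = c("m1", "m2", "m2", "m3", "m3"),
    human_gene = c("H1", "H2A", "H2B", "H3A", "H3B"),
    ortho_class = c("one2one", "one2many", "one2many", "many2many", "many2many"),
    pct_identity = c(95, 80, 90, 99, 98))
  map <- resolve_orthologues(rec)
  expect_equal(map$human_gene[map$mouse_gene == "m1"], "H1")
  expect_equal(map$human_gene[map$mouse_gene == "m2"], "H2B")  # 90 beats 80
  expect_false("m3" %in% map$mouse_gene)                       # many2many dropped
  expect_equal(anyDuplicated(map$mouse_gene), 0)
})

test_that("identity ties warn and break lexicographically; conflicts error", {
  tie <- tibble::tibble(mouse_gene = "m1", human_gene = c("HB", "HA"),
                        ortho_class = "one2many", pct_identity = c(88, 88))
  expect_warning(map <- resolve_orthologues(tie), "ties")
  expect_equal(map$human_gene, "HA")
  conflict <- tibble::tibble(mouse_gene = "m1", human_gene = "H1",
                             ortho_class = "one2one", pct_identity = c(90, 91))
  expect_error(resolve_orthologues(conflict), "conflicting")
  bad <- tibble::tibble(mouse_gene = "m1", human_gene = "H1",
                        ortho_class = "one2one", pct_identity = 130)
  expect_error(resolve_orthologues(bad), "0, 100")
})

test_that("resolver properties hold on simulated tables", {
  tab <- simulate_orthology(800, seed = 13)
  map <- resolve_orthologues(tab)
  m2m <- unique(tab$mouse_gene[tab$ortho_class == "many2many"])
  expect_length(intersect(map$mouse_gene, m2m), 0)
  expect_equal(anyDuplicated(map$mouse_gene), 0)
  # picked partner always carries the maximal identity for its mouse gene
  best <- dplyr::summarise(dplyr::group_by(
    dplyr::filter(tab, !(mouse_gene %in% m2m)), mouse_gene),
    top = max(pct_identity), .groups = "drop")
  joined <- dplyr::inner_join(map, best, by = "mouse_gene")
  expect_true(all(joined$pct_identity == joined$top))
})

test_that("poor-outcome expression direction follows the dual hazard ratios", {
  expect_equal(human_direction_of_poor_outcome(0.60248, 0.52328), "low")
  expect_equal(human_direction_of_poor_outcome(1.37339, 3.45380), "high")
  expect_equal(human_direction_of_poor_outcome(0.8, 1.2), "undefined")
  expect_equal(human_direction_of_poor_outcome(1, 0.5), "undefined")
})

test_that("concordance intersection computes the funnel and flags", {
  mouse_de <- tibble::tibble(gene = c("m1", "m2", "m3", "m4"),
                             direction = c("under", "over", "under", "over"))
  ortho <- tibble::tibble(mouse_gene = c("m1", "m2", "m3"),
                          human_gene = c("H1", "H2", "H3"),
                          ortho_class = "one2one", pct_identity = 90)
  dual <- tibble::tibble(gene = c("H1", "H2"),
                         hr_a = c(0.5, 0.6), hr_b = c(0.6, 0.7),
                         fdr_a = 0.01, fdr_b = 0.01, same_direction = TRUE)
  cc <- concordance_intersect(mouse_de, ortho, dual,
                              screened_genes = c("H1", "H2", "H3"))
  expect_equal(cc$funnel$n,
               c(4L, 3L, 3L, 2L, 1L))  # de, mapped, panel, dual, concordant
  expect_true(cc$table$concordant[cc$table$mouse_gene == "m1"])   # under+low
  expect_false(cc$table$concordant[cc$table$mouse_gene == "m2"])  # over+low
  expect_true(all(diff(cc$funnel$n) <= 0))
  empty <- concordance_intersect(mouse_de[0, ], ortho, dual)
  expect_true(all(empty$funnel$n == 0))
})

test_that("candidate ranking is ascending HR with adverse genes last", {
  tbl <- tibble::tibble(gene = c("slow", "fast", "adverse", "tie"),
                        hr_a = c(0.60, 0.58, 1.4, 0.60),
                        p_b = c(5e-5, 2e-4, 1e-6, 1e-6))
  r <- rank_candidates(tbl)
  expect_equal(r$gene, c("fast", "tie", "slow", "adverse"))
})

test_that("randomisation degenerate case returns the exact intersection count", {
  universe <- tibble::tibble(gene = sprintf("g%02d", 1:40),
                             in_human_list = rep(c(TRUE, FALSE), c(8, 32)),
                             human_direction = rep(c("low", NA), c(8, 32)))
  rt <- randomisation_test(universe, m = 40, observed_count = 8,
                           n_samples = 200, p_under = 1, seed = 5)
  expect_true(all(rt$null_counts == 8))
  expect_equal(rt$empirical_p, 1)
  # observed beyond the null support gives a raw empirical p of zero
  rt2 <- randomisation_test(universe, m = 40, observed_count = 9,
                            n_samples = 200, p_under = 1, seed = 5)
  expect_equal(rt2$empirical_p, 0)
  expect_equal(rt2$empirical_p_plus_one, 1 / 201)
  expect_error(randomisation_test(universe, m = 41, observed_count = 0), "exceeds")
})

test_that("randomisation null mean matches the analytic expectation", {
  universe <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                             in_human_list = rep(c(TRUE, FALSE), c(10, 90)),
                             human_direction = rep(c("low", NA), c(10, 90)))
  an <- analytic_expected_concordant(universe, m = 50, p_under = 0.5)
  expect_equal(an$expectation, 2.5)  # hand: (50/100) * 10 * 0.5
  rt <- randomisation_test(universe, m = 50, observed_count = 3,
                           n_samples = 1000, p_under = 0.5, seed = 17)
  expect_lt(abs(mean(rt$null_counts) - an$expectation),
            3 * an$sd / sqrt(1000))
  # fixed seed reproduces the null exactly
  rt2 <- randomisation_test(universe, m = 50, observed_count = 3,
                            n_samples = 1000, p_under = 0.5, seed = 17)
  expect_identical(rt$null_counts, rt2$null_counts)
})

test_that("analytic expectation handles edge cases", {
  universe <- tibble::tibble(gene = c("a", "b"), in_human_list = FALSE,
                             human_direction = NA_character_)
  expect_equal(analytic_expected_concordant(universe, 2)$expectation, 0)
  u2 <- tibble::tibble(gene = c("a", "b"), in_human_list = c(TRUE, FALSE),
                       human_direction = c("high", NA))
  expect_equal(analytic_expected_concordant(u2, 0)$expectation, 0)
  # mixed directions weight by p_over for "high"
  u3 <- tibble::tibble(gene = c("a", "b"), in_human_list = TRUE,
                       human_direction = c("low", "high"))
  an <- analytic_expected_concordant(u3, 1, p_under = 0.3)
  expect_equal(an$expectation, 0.5 * (0.3 + 0.7))
})

test_that("tidy and glance summarise a randomisation test", {
  universe <- tibble::tibble(gene = sprintf("g%02d", 1:20),
                             in_human_list = rep(c(TRUE, FALSE), 10),
                             human_direction = rep(c("low", NA), 10))
  rt <- randomisation_test(universe, m = 10, observed_count = 2,
                           n_samples = 50, seed = 2)
  expect_equal(nrow(tidy(rt)), 50)
  g <- glance(rt)
  expect_equal(g$observed, 2)
  expect_equal(g$null_mean, mean(rt$null_counts))
})
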