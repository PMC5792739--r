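# Synthetic-data generators. Every pipeline input can be produced here with
# planted ground truth, so all downstream stages are testable without any
# external download. All generators are deterministic given `seed`.

#' Simulate a patient cohort with survival outcomes
#'
#' Draws per-gene log2 expression as independent standard normals (a
#' mean-centred array-expression analogue), then generates event times from an
#' exponential hazard that is log-linear in expression and covariates:
#' `h_i = baseline_hazard * exp(sum_g beta_g x_gi + b_age age_i + b_sex sex_i)`.
#' Proportional hazards holds exactly, so recovery by a Cox screen is a fair
#' test of the screen rather than of model misspecification. Censoring is an
#' independent exponential; the observed time is the minimum of event and
#' censoring times.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_genes Number of genes.
#' @param effect_genes Named numeric vector of true log-hazard ratios per unit
#'   log2 expression; names must be gene identifiers (see `gene_ids`).
#' @param baseline_hazard Event rate per month at covariate value zero (> 0).
#' @param censor_rate Independent censoring rate per month (>= 0; 0 disables
#'   censoring).
#' @param covariate_effects Named vector with elements `age` (log-hazard per
#'   year, age centred at 60) and `sex` (log-hazard for male vs female).
#' @param expr_mean,expr_sd Normal parameters for simulated log2 expression.
#' @param gene_ids Optional gene identifiers (default `G0001`, ...).
#' @param cohort_label Label stored with the cohort.
#' @param seed Integer seed; the whole object is reproducible from it.
#' @return A `cohort_dataset`: list with `expression` (genes x samples matrix,
#'   log2 scale), `samples` (tibble with `sample`, `time`, `event`, `age`,
#'   `sex`), `label`, and `truth` (planted effects).
#' @export
simulate_cohort <- function(n_patients = 400, n_genes = 2000,
                            effect_genes = numeric(0),
                            baseline_hazard = 0.01, censor_rate = 0.01,
                            covariate_effects = c(age = 0.02, sex = 0.3),
                            expr_mean = 0, expr_sd = 1,
                            gene_ids = NULL, cohort_label = "cohort",
                            seed = 1) {
  n_patients <- check_count(n_patients, "n_patients", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  if (baseline_hazard <= 0) stopf("`baseline_hazard` must be > 0")
  if (censor_rate < 0) stopf("`censor_rate` must be >= 0")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes) stopf("`gene_ids` must have length n_genes")
  if (length(effect_genes) && !all(names(effect_genes) %in% gene_ids))
    stopf("all `effect_genes` names must be gene identifiers in the cohort")

  withr::with_seed(seed, {
    expr <- matrix(rnorm(n_genes * n_patients, expr_mean, expr_sd),
                   nrow = n_genes, dimnames = list(gene_ids, NULL))
    colnames(expr) <- sprintf("P%04d", seq_len(n_patients))
    age <- round(rnorm(n_patients, 60, 12))
    sex <- rbinom(n_patients, 1, 0.5)
    lp <- rep(0, n_patients)
    if (length(effect_genes))
      lp <- lp + drop(crossprod(expr[names(effect_genes), , drop = FALSE],
                                effect_genes))
    lp <- lp + covariate_effects[["age"]] * (age - 60) +
      covariate_effects[["sex"]] * sex
    t_event <- rexp(n_patients, rate = baseline_hazard * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n_patients, censor_rate) else rep(Inf, n_patients)
    samples <- tibble(
      sample = colnames(expr),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      age = age, sex = sex
    )
    structure(
      list(expression = expr, samples = samples, label = cohort_label,
           truth = tibble(gene = names(effect_genes),
                          beta = unname(effect_genes))),
      class = "cohort_dataset"
    )
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset '%s': %d genes x %d patients, %d events, %d planted effects>\n",
              x$label, nrow(x$expression), ncol(x$expression),
              sum(x$samples$event), nrow(x$truth)))
  invisible(x)
}

#' Simulate a cohort where planted effects are exact marginal hazard ratios
#'
#' Alternative survival generator for many simultaneous effect genes. In the
#' forward joint model of [simulate_cohort()] every effect gene contributes
#' to one shared hazard, so a *univariate* screen of a cohort carrying tens
#' of strong effects sees heavily attenuated marginal hazard ratios
#' (omitted-covariate non-collapsibility). Here, instead, event times are
#' drawn once from the covariate model with a latent anchor gene at effect
#' size `abs(beta)`, and each planted gene's expression is then drawn from
#' its exact conditional distribution given the observed (time, event,
#' covariates) under the single-gene proportional-hazards model
#' `h = h0 exp(beta x + covariates)` with `x ~ N(0, 1)`. Each planted gene's
#' marginal law is therefore exactly that single-gene model — `beta` *is*
#' the per-gene marginal log hazard ratio a univariate Cox fit estimates —
#' while planted genes are mutually dependent only through the outcome
#' (conditionally independent given it), like co-prognostic but not
#' co-regulated genes. All planted effects must share one absolute value;
#' signs are free. Background genes are independent standard normals.
#'
#' @inheritParams simulate_cohort
#' @param effect_genes Named vector of signed effects; all `abs()` equal.
#' @return A `cohort_dataset`, as [simulate_cohort()].
#' @export
simulate_cohort_marginal <- function(n_patients = 400, n_genes = 2000,
                                     effect_genes = numeric(0),
                                     baseline_hazard = 0.01, censor_rate = 0.01,
                                     covariate_effects = c(age = 0.02, sex = 0.3),
                                     gene_ids = NULL, cohort_label = "cohort",
                                     seed = 1) {
  n_patients <- check_count(n_patients, "n_patients", min = 2L)
  n_genes <- check_count(n_genes, "n_genes")
  if (baseline_hazard <= 0) stopf("`baseline_hazard` must be > 0")
  if (censor_rate < 0) stopf("`censor_rate` must be >= 0")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (length(effect_genes) && !all(names(effect_genes) %in% gene_ids))
    stopf("all `effect_genes` names must be gene identifiers in the cohort")
  mags <- unique(round(abs(effect_genes), 12))
  if (length(mags) > 1)
    stopf("all planted effects must share one absolute value; got %s",
          paste(mags, collapse = ", "))
  beta_abs <- if (length(mags)) mags else 0

  withr::with_seed(seed, {
    age <- round(rnorm(n_patients, 60, 12))
    sex <- rbinom(n_patients, 1, 0.5)
    a <- baseline_hazard * exp(covariate_effects[["age"]] * (age - 60) +
                                 covariate_effects[["sex"]] * sex)
    anchor <- rnorm(n_patients)
    t_event <- rexp(n_patients, rate = a * exp(beta_abs * anchor))
    t_cens <- if (censor_rate > 0) rexp(n_patients, censor_rate) else rep(Inf, n_patients)
    y <- pmin(t_event, t_cens)
    delta <- as.integer(t_event <= t_cens)

    expr <- matrix(rnorm(n_genes * n_patients), nrow = n_genes,
                   dimnames = list(gene_ids, sprintf("P%04d", seq_len(n_patients))))
    if (length(effect_genes) && beta_abs > 0) {
      draws <- sample_expr_given_outcome(y, delta, a, beta_abs,
                                         length(effect_genes))
      signs <- sign(effect_genes)
      for (j in seq_along(effect_genes))
        expr[names(effect_genes)[j], ] <- signs[j] * draws[, j]
    }
    samples <- tibble(sample = colnames(expr), time = y, event = delta,
                      age = age, sex = sex)
    structure(
      list(expression = expr, samples = samples, label = cohort_label,
           truth = tibble(gene = names(effect_genes),
                          beta = unname(effect_genes))),
      class = "cohort_dataset"
    )
  })
}

# Draw expression from the conditional law given the observed outcome under
# the single-gene PH model: for an event at y the density is proportional to
# phi(x) exp(beta x - a y e^(beta x)); for censoring at y the exp(beta x)
# tilt is absent. Sampled by inverse-CDF on a fine grid (half-step jitter
# smooths the discretisation); weights are normalised in log space.
sample_expr_given_outcome <- function(y, delta, a, beta, n_draws,
                                      grid = seq(-5, 5, by = 0.005)) {
  h <- grid[2] - grid[1]
  lphi <- dnorm(grid, log = TRUE)
  out <- matrix(0, length(y), n_draws)
  for (i in seq_along(y)) {
    lw <- lphi + delta[i] * beta * grid - a[i] * y[i] * exp(beta * grid)
    w <- exp(lw - max(lw))
    idx <- sample.int(length(grid), n_draws, replace = TRUE, prob = w)
    out[i, ] <- grid[idx] + runif(n_draws, -h / 2, h / 2)
  }
  out
}

#' Simulate an RNA-seq count matrix with planted fold changes
#'
#' Counts are negative binomial with mean
#' `size_factor_j * baseline_g * 2^(log2fc_g)` for derivative-group samples
#' (baseline alone for the parental group) and variance `mu + alpha mu^2`.
#' `alpha = 0` gives the Poisson limit.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_group Biological replicates per cell line.
#' @param baseline_means Per-gene baseline expected counts (recycled);
#'   defaults to a log-normal draw around 100.
#' @param dispersions Per-gene NB dispersion alpha >= 0 (recycled).
#' @param planted_log2fc Named numeric vector of log2 fold changes
#'   (derivative vs parental) for a subset of genes.
#' @param size_factors Per-sample positive scale factors; default a mild
#'   log-normal spread around 1.
#' @param group_labels Length-2 character vector: parental then derivative.
#' @param gene_ids Optional gene identifiers (default `Mgene0001`, ...).
#' @param gene_lengths Per-gene lengths in bp; default uniform 200-10000.
#' @param seed Integer seed.
#' @return A `count_matrix`: list with integer `counts` (genes x samples),
#'   `gene_lengths`, `samples` (tibble `sample`, `group`, `replicate`) and
#'   `truth` (planted log2 fold changes).
#' @export
simulate_counts <- function(n_genes = 2000, replicates_per_group = 5,
                            baseline_means = NULL, dispersions = 0.05,
                            planted_log2fc = numeric(0), size_factors = NULL,
                            group_labels = c("parental", "derivative"),
                            gene_ids = NULL, gene_lengths = NULL, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  replicates_per_group <- check_count(replicates_per_group, "replicates_per_group")
  if (any(dispersions < 0)) stopf("`dispersions` must be >= 0")
  if (length(group_labels) != 2L) stopf("`group_labels` must have length 2")
  if (is.null(gene_ids)) gene_ids <- sprintf("Mgene%04d", seq_len(n_genes))
  if (length(planted_log2fc) && !all(names(planted_log2fc) %in% gene_ids))
    stopf("all `planted_log2fc` names must be gene identifiers")
  n_samples <- 2L * replicates_per_group

  withr::with_seed(seed, {
    if (is.null(baseline_means)) baseline_means <- rlnorm(n_genes, log(100), 1.2)
    baseline_means <- rep_len(baseline_means, n_genes)
    dispersions <- rep_len(dispersions, n_genes)
    if (is.null(size_factors)) size_factors <- rlnorm(n_samples, 0, 0.15)
    if (length(size_factors) != n_samples || any(size_factors <= 0))
      stopf("`size_factors` must be %d positive values", n_samples)
    if (is.null(gene_lengths)) gene_lengths <- sample(200:10000, n_genes, replace = TRUE)

    lfc <- setNames(rep(0, n_genes), gene_ids)
    lfc[names(planted_log2fc)] <- planted_log2fc
    group <- rep(group_labels, each = replicates_per_group)
    mu <- outer(baseline_means, size_factors)
    mu[, group == group_labels[2]] <- mu[, group == group_labels[2]] * 2^lfc
    counts <- matrix(0L, n_genes, n_samples)
    for (j in seq_len(n_samples)) {
      pois <- dispersions == 0
      counts[pois, j] <- rpois(sum(pois), mu[pois, j])
      if (any(!pois))
        counts[!pois, j] <- rnbinom(sum(!pois), mu = mu[!pois, j],
                                    size = 1 / dispersions[!pois])
    }
    dimnames(counts) <- list(gene_ids,
                             paste0(group, "_r", rep(seq_len(replicates_per_group), 2)))
    structure(
      list(counts = counts,
           gene_lengths = setNames(as.numeric(gene_lengths), gene_ids),
           samples = tibble(sample = colnames(counts), group = group,
                            replicate = rep(seq_len(replicates_per_group), 2)),
           truth = tibble(gene = names(planted_log2fc),
                          log2fc = unname(planted_log2fc))),
      class = "count_matrix"
    )
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %d genes x %d samples (%s), %d planted fold changes>\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$group), collapse = " / "), nrow(x$truth)))
  invisible(x)
}

#' Simulate a mouse-human orthology table
#'
#' Mouse genes are assigned an orthology class (`one2one`, `one2many`,
#' `many2many`). `one2one` genes have a single human partner; `one2many`
#' genes have 2-3 partners with distinct protein-identity percentages (so a
#' highest-identity partner always exists); `many2many` genes carry partners
#' but are flagged for removal by the resolver.
#'
#' @param n_mouse Number of mouse genes.
#' @param class_mix Named proportions for the three classes; must sum to 1.
#' @param identity_range Range of protein-identity percentages.
#' @param gene_ids Optional mouse gene identifiers.
#' @param human_ids Optional human partner identifiers (one primary per mouse
#'   gene; extra partners get suffixed identifiers).
#' @param seed Integer seed.
#' @return Tibble with `mouse_gene`, `human_gene`, `ortho_class`,
#'   `pct_identity`.
#' @export
simulate_orthology <- function(n_mouse = 1000,
                               class_mix = c(one2one = 0.8, one2many = 0.1,
                                             many2many = 0.1),
                               identity_range = c(60, 100),
                               gene_ids = NULL, human_ids = NULL, seed = 1) {
  n_mouse <- check_count(n_mouse, "n_mouse")
  if (abs(sum(class_mix) - 1) > 1e-8) stopf("`class_mix` must sum to 1")
  if (!all(c("one2one", "one2many", "many2many") %in% names(class_mix)))
    stopf("`class_mix` needs elements one2one, one2many, many2many")
  if (is.null(gene_ids)) gene_ids <- sprintf("Mgene%04d", seq_len(n_mouse))
  if (is.null(human_ids)) human_ids <- toupper(sub("^M", "H", gene_ids))

  withr::with_seed(seed, {
    cls <- sample(names(class_mix), n_mouse, replace = TRUE, prob = class_mix)
    # identities on a 0.01 grid so distinctness within a gene is enforceable
    draw_id <- function(n) {
      sample(seq(identity_range[1] * 100, identity_range[2] * 100), n) / 100
    }
    rows <- imap_dfr(seq_len(n_mouse), function(i, ...) {
      n_part <- switch(cls[i], one2one = 1L, sample(2:3, 1))
      partners <- c(human_ids[i],
                    if (n_part > 1) paste0(human_ids[i], "P", seq_len(n_part - 1)))
      tibble(mouse_gene = gene_ids[i], human_gene = partners,
             ortho_class = cls[i], pct_identity = draw_id(n_part))
    })
    rows
  })
}

#' Simulate VCF-style variant records engineered to trigger each filter stage
#'
#' Builds `n_clean` records that pass every filter plus, for each of the five
#' removal classes (low QUAL, low supporting-read count, SNV near an indel,
#' present in the strain panel, within the padded window of a structural
#' variant), `n_per_trigger` records that violate exactly that one filter.
#' Records are laid out on a coarse position grid so proximity filters cannot
#' fire accidentally; near-indel triggers are placed next to clean indel
#' records (the indel itself is unaffected by the SNV-gap rule).
#'
#' @param n_clean Number of records passing all filters; must be at least
#'   `n_per_trigger[["near_indel"]]` so each trigger SNV has a clean indel
#'   companion.
#' @param n_per_trigger Named counts for classes `low_qual`, `low_support`,
#'   `near_indel`, `in_panel`, `near_sv`.
#' @param contig_lengths Named contig lengths; positions are spread across
#'   contigs and must fit (else an overflow error).
#' @param config A [filter_config()]; thresholds the triggers are built
#'   against.
#' @param seed Integer seed.
#' @return List with `records` (tibble sorted by chrom, pos), `panel`
#'   (chrom/pos/alt strain-panel tibble), `svs` (1-based inclusive intervals)
#'   and `truth` (record id -> expected filter bucket, `kept` for clean).
#' @export
simulate_variants <- function(n_clean = 50,
                              n_per_trigger = c(low_qual = 10, low_support = 10,
                                                near_indel = 10, in_panel = 10,
                                                near_sv = 10),
                              contig_lengths = c(chr1 = 2e6, chr2 = 2e6),
                              config = filter_config(), seed = 1) {
  n_clean <- check_count(n_clean, "n_clean", min = 0L)
  need <- c("low_qual", "low_support", "near_indel", "in_panel", "near_sv")
  miss <- setdiff(need, names(n_per_trigger))
  if (length(miss)) n_per_trigger[miss] <- 0
  n_per_trigger <- n_per_trigger[need]
  if (n_per_trigger[["near_indel"]] > n_clean && n_per_trigger[["near_indel"]] > 0)
    stopf("need at least %d clean records to host near-indel triggers",
          n_per_trigger[["near_indel"]])

  n_total <- n_clean + sum(n_per_trigger)
  spacing <- 1000L  # far larger than snp_gap + sv_pad
  capacity <- sum(floor(contig_lengths / spacing)) - length(contig_lengths)
  if (n_total > capacity)
    stopf("contig overflow: %d records do not fit in the given contigs", n_total)

  withr::with_seed(seed, {
    # grid slots across contigs
    slots <- map_dfr(names(contig_lengths), function(ch) {
      tibble(chrom = ch,
             pos = seq(spacing, floor(contig_lengths[[ch]]) - spacing, by = spacing))
    })
    if (n_total > nrow(slots))
      stopf("contig overflow: %d records do not fit in the given contigs", n_total)
    slots <- slots[seq_len(n_total), ]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    rec <- tibble(
      id = sprintf("var%04d", seq_len(n_total)),
      chrom = slots$chrom, pos = slots$pos, ref = ref, alt = alt,
      qual = round(runif(n_total, config$qual_min + 10, config$qual_min + 40), 2),
      support = sample(seq(config$support_min + 1, config$support_min + 25),
                       n_total, replace = TRUE),
      vtype = "snv"
    )
    idx <- seq_len(n_clean)
    bucket <- rep("kept", n_total)
    # some clean records are indels; near-indel triggers attach to them
    n_ni <- n_per_trigger[["near_indel"]]
    if (n_clean > 0) {
      n_indel <- max(n_ni, min(5L, n_clean))
      indel_idx <- idx[seq_len(n_indel)]
      rec$vtype[indel_idx] <- "indel"
      rec$alt[indel_idx] <- paste0(rec$ref[indel_idx], "A")
    }
    at <- n_clean
    take <- function(n) { out <- at + seq_len(n); at <<- at + n; out }

    i <- take(n_per_trigger[["low_qual"]])
    rec$qual[i] <- round(runif(length(i), 1, config$qual_min - 0.5), 2)
    bucket[i] <- "quality"

    i <- take(n_per_trigger[["low_support"]])
    rec$support[i] <- sample(seq(0, config$support_min - 1), length(i), replace = TRUE)
    bucket[i] <- "support"

    i <- take(n_ni)
    if (n_ni > 0) {
      host <- idx[seq_len(n_ni)]  # clean indels
      rec$chrom[i] <- rec$chrom[host]
      rec$pos[i] <- rec$pos[host] + sample(seq_len(config$snp_gap - 1),
                                           n_ni, replace = TRUE)
      bucket[i] <- "snp_gap"
    }

    i <- take(n_per_trigger[["in_panel"]])
    panel <- tibble(chrom = rec$chrom[i], pos = rec$pos[i], alt = rec$alt[i])
    bucket[i] <- "strain_panel"

    i <- take(n_per_trigger[["near_sv"]])
    svs <- tibble(chrom = rec$chrom[i],
                  start = rec$pos[i] + sample(0:config$sv_pad, length(i), replace = TRUE))
    svs$end <- svs$start + sample(20:200, nrow(svs), replace = TRUE)
    svs$start <- pmax(1, svs$start - sample(0:config$sv_pad, nrow(svs), replace = TRUE))
    # keep the record inside [start - pad, end + pad]
    svs$start <- pmin(svs$start, rec$pos[i] + config$sv_pad)
    bucket[i] <- "sv_proximity"

    rec <- rec |> mutate(.bucket = bucket) |> arrange(.data$chrom, .data$pos)
    truth <- tibble(id = rec$id, bucket = rec$.bucket)
    rec$.bucket <- NULL
    list(records = rec, panel = panel, svs = svs, truth = truth)
  })
}

#' Simulate mutation catalogues from known signature mixtures
#'
#' Each sample's 96-class catalogue is a multinomial draw with class
#' probabilities given by the exposure-weighted mixture of the signatures.
#'
#' @param signatures k x 96 row-stochastic matrix (rows sum to 1).
#' @param exposures samples x k non-negative contribution matrix.
#' @param n_mutations Mutations per sample (scalar or per-sample vector;
#'   0 gives a zero catalogue).
#' @param seed Integer seed.
#' @return 96 x samples integer matrix with `sbs96_classes()` rownames.
#' @export
simulate_catalogues <- function(signatures, exposures, n_mutations, seed = 1) {
  signatures <- as.matrix(signatures)
  exposures <- as.matrix(exposures)
  if (ncol(signatures) != 96) stopf("`signatures` must have 96 columns")
  if (any(signatures < 0)) stopf("`signatures` must be non-negative")
  if (any(abs(rowSums(signatures) - 1) > 1e-6))
    stopf("`signatures` rows must each sum to 1")
  if (any(exposures < 0)) stopf("`exposures` must be non-negative")
  if (ncol(exposures) != nrow(signatures))
    stopf("`exposures` must have one column per signature")
  n_mutations <- rep_len(n_mutations, nrow(exposures))
  if (any(n_mutations < 0)) stopf("`n_mutations` must be >= 0")

  withr::with_seed(seed, {
    out <- matrix(0L, 96, nrow(exposures),
                  dimnames = list(sbs96_classes(),
                                  rownames(exposures) %||%
                                    sprintf("S%02d", seq_len(nrow(exposures)))))
    for (s in seq_len(nrow(exposures))) {
      w <- exposures[s, ]
      if (sum(w) == 0 || n_mutations[s] == 0) next
      p <- drop(crossprod(signatures, w / sum(w)))
      out[, s] <- rmultinom(1, n_mutations[s], p)[, 1]
    }
    out
  })
}

#' Generate a synthetic row-stochastic signature matrix
#'
#' Draws sparse, well-separated signatures from a symmetric Dirichlet with a
#' small concentration parameter; useful as planted truth for factorisation
#' tests and as a synthetic stand-in for a reference signature table.
#'
#' @param k Number of signatures.
#' @param concentration Dirichlet concentration (small = spiky).
#' @param seed Integer seed.
#' @return k x 96 matrix, rows summing to 1, with class colnames.
#' @export
simulate_signature_matrix <- function(k = 2, concentration = 0.1, seed = 1) {
  k <- check_count(k, "k")
  withr::with_seed(seed, {
    m <- matrix(rgamma(k * 96, shape = concentration), nrow = k)
    m <- m / rowSums(m)
    dimnames(m) <- list(paste0("SigSim", seq_len(k)), sbs96_classes())
    m
  })
}

#' Build a complete synthetic mini-study with planted concordant genes
#'
#' Assembles two patient cohorts, a mouse cell-line count matrix and an
#' orthology table whose planted structure the full cross-species pipeline
#' should recover. Roles planted in the `truth` table:
#' \describe{
#'   \item{concordant}{mouse gene differentially expressed with
#'     `|log2fc| = lfc_effect` and human orthologue carrying a survival effect
#'     `|beta| = beta_effect` in both cohorts, with matching direction
#'     (mouse under-expression paired with poor-outcome-low, and vice versa).}
#'   \item{discordant}{both effects present but directions opposed.}
#'   \item{human_only}{survival effect only, no expression change.}
#'   \item{mouse_only}{expression change only, no survival effect.}
#' }
#' A slice of non-planted genes is given `one2many` orthology (the correct
#' partner has the highest identity) and another slice `many2many` (dropped by
#' the resolver), so orthologue resolution is exercised end to end.
#'
#' @param seed Integer seed governing every sub-generator via derived seeds.
#' @param n_patients Patients per cohort.
#' @param n_genes Genes (mouse and human panels are the same size).
#' @param n_concordant,n_discordant,n_human_only,n_mouse_only Planted counts.
#' @param beta_effect Absolute per-unit-log2 log-hazard of planted survival
#'   genes.
#' @param lfc_effect Absolute planted log2 fold change.
#' @param replicates_per_group Count-matrix replicates per cell line.
#' @param p_under Probability a planted mouse change is under-expression (the
#'   direction mix observed in the motivating study).
#' @return List with `cohort_a`, `cohort_b`, `counts`, `orthology`, `truth`.
#' @export
make_end_to_end_fixture <- function(seed = 1, n_patients = 400, n_genes = 2000,
                                    n_concordant = 20, n_discordant = 5,
                                    n_human_only = 10, n_mouse_only = 10,
                                    beta_effect = 0.7, lfc_effect = 3,
                                    replicates_per_group = 5,
                                    p_under = 0.4621429) {
  n_genes <- check_count(n_genes, "n_genes")
  n_planted <- n_concordant + n_discordant + n_human_only + n_mouse_only
  if (n_planted > n_genes) stopf("planted genes exceed `n_genes`")

  mouse <- sprintf("Mgene%04d", seq_len(n_genes))
  human <- sprintf("HGENE%04d", seq_len(n_genes))

  roles <- withr::with_seed(derive_seed(seed, 1L), {
    pick <- sample.int(n_genes, n_planted)
    role <- rep("background", n_genes)
    role[pick] <- rep(c("concordant", "discordant", "human_only", "mouse_only"),
                      times = c(n_concordant, n_discordant, n_human_only, n_mouse_only))
    under <- rbinom(n_genes, 1, p_under) == 1
    list(role = role, under = under)
  })
  role <- roles$role; under <- roles$under

  has_lfc <- role %in% c("concordant", "discordant", "mouse_only")
  has_beta <- role %in% c("concordant", "discordant", "human_only")
  lfc <- ifelse(under, -lfc_effect, lfc_effect)[has_lfc]
  names(lfc) <- mouse[has_lfc]
  # concordant: mouse under  <-> human poor-outcome-low  <-> HR < 1 (beta < 0)
  beta_sign <- ifelse(under, -1, 1)
  beta_sign[role == "discordant"] <- -beta_sign[role == "discordant"]
  beta <- (beta_sign * beta_effect)[has_beta]
  names(beta) <- human[has_beta]

  cohort_a <- simulate_cohort_marginal(n_patients, n_genes,
                                       effect_genes = beta,
                                       gene_ids = human,
                                       cohort_label = "cohort_a",
                                       seed = derive_seed(seed, 2L))
  cohort_b <- simulate_cohort_marginal(n_patients, n_genes,
                                       effect_genes = beta,
                                       covariate_effects = c(age = 0, sex = 0),
                                       gene_ids = human,
                                       cohort_label = "cohort_b",
                                       seed = derive_seed(seed, 3L))

  baselines <- withr::with_seed(derive_seed(seed, 4L), {
    b <- rlnorm(n_genes, log(80), 1.5)
    b[has_lfc] <- runif(sum(has_lfc), 100, 400)  # planted DE genes clear the
    b                                            # base-mean filter comfortably
  })
  counts <- simulate_counts(n_genes, replicates_per_group,
                            baseline_means = baselines, dispersions = 0.05,
                            planted_log2fc = lfc, gene_ids = mouse,
                            seed = derive_seed(seed, 5L))

  orthology <- withr::with_seed(derive_seed(seed, 6L), {
    ortho <- tibble(mouse_gene = mouse, human_gene = human,
                    ortho_class = "one2one",
                    pct_identity = round(runif(n_genes, 70, 100), 2))
    bg <- which(role == "background")
    o2m <- bg[seq_len(min(30L, length(bg)))]
    m2m <- bg[min(30L, length(bg)) + seq_len(min(20L, length(bg) - 30L))]
    ortho$ortho_class[o2m] <- "one2many"
    extra <- tibble(mouse_gene = mouse[o2m],
                    human_gene = paste0(human[o2m], "P1"),
                    ortho_class = "one2many",
                    pct_identity = ortho$pct_identity[o2m] - runif(length(o2m), 5, 20))
    ortho$ortho_class[m2m] <- "many2many"
    bind_rows(ortho, extra) |> arrange(.data$mouse_gene)
  })

  truth <- tibble(
    mouse_gene = mouse, human_gene = human, role = role,
    mouse_direction = ifelse(has_lfc, ifelse(under, "under", "over"), NA_character_),
    human_direction = ifelse(has_beta,
                             ifelse(beta_sign < 0, "low", "high"), NA_character_),
    beta = ifelse(has_beta, beta_sign * beta_effect, 0),
    log2fc = ifelse(has_lfc, ifelse(under, -lfc_effect, lfc_effect), 0)
  )
  list(cohort_a = cohort_a, cohort_b = cohort_b, counts = counts,
       orthology = orthology, truth = truth,
       params = list(seed = seed, n_patients = n_patients, n_genes = n_genes,
                     beta_effect = beta_effect, lfc_effect = lfc_effect,
                     p_under = p_under))
}
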