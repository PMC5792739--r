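# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Hand-written Breslow log partial likelihood, vectorised over a beta grid:
# ll(b) = sum_{i: event} b x_i - sum_{distinct event times t} d_t log(sum_{j
# at risk at t} exp(b x_j)).
breslow_loglik_grid <- function(betas, x, time, event) {
  ll <- betas * sum(x[event == 1])
  for (t in sort(unique(time[event == 1]))) {
    d <- sum(time == t & event == 1)
    at_risk <- x[time >= t]
    ll <- ll - d * log(colSums(exp(outer(at_risk, betas))))
  }
  ll
}

# Grid-search maximiser of the Breslow partial likelihood (step 1e-4).
cox_grid_oracle <- function(x, time, event, lo = -4, hi = 4, step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  betas[which.max(breslow_loglik_grid(betas, x, time, event))]
}

# Exact central fourth moment of NB/Poisson by truncated summation; used for
# the 3-standard-error band of the sample-variance moment check.
nb_central_moment4 <- function(mu, alpha) {
  if (alpha == 0) {
    kmax <- ceiling(mu + 12 * sqrt(mu))
    k <- 0:kmax
    p <- stats::dpois(k, mu)
  } else {
    size <- 1 / alpha
    kmax <- ceiling(mu + 14 * sqrt(mu + alpha * mu^2))
    k <- 0:kmax
    p <- stats::dnbinom(k, mu = mu, size = size)
  }
  sum((k - mu)^4 * p) / sum(p)
}

# Small two-group exponential-survival fixtures (n <= 10) for the
# brute-force equivalence checks.
small_cox_fixtures <- function() {
  list(
    list(x = c(0, 0, 0, 0, 1, 1, 1, 1),
         time = c(5, 1, 11, 3, 2, 8, 4, 6),  # interleaved: no separation
         event = rep(1, 8)),
    list(x = c(0.2, -1.1, 0.5, 1.7, -0.3, 0.9),
         time = c(3, 9, 4, 1, 7, 2),
         event = c(1, 1, 0, 1, 1, 1)),
    list(x = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
         time = c(2, 2, 5, 5, 7, 3, 9, 4, 10, 6),  # ties at 2 and 5
         event = c(1, 1, 1, 1, 0, 1, 1, 1, 0, 1)),
    list(x = c(-0.5, 0.1, 0.7, 1.3, -1.2, 0.4, 2.0),
         time = c(6, 2, 8, 1, 9, 3, 4),
         event = c(1, 0, 1, 1, 1, 1, 1))
  )
}

# Tiny count-matrix container for constructed DE inputs.
make_cm <- function(counts, groups, gene_lengths = NULL) {
  structure(list(
    counts = counts,
    gene_lengths = gene_lengths %||%
      stats::setNames(rep(1000, nrow(counts)), rownames(counts)),
    samples = tibble::tibble(sample = colnames(counts), group = groups,
                             replicate = stats::ave(seq_along(groups), groups,
                                                    FUN = seq_along)),
    truth = tibble::tibble(gene = character(), log2fc = numeric())
  ), class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
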