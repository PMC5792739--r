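# 96-context mutation catalogues, NMF signature extraction by multiplicative
# updates, and cosine matching against a reference signature matrix. The
# factorisation itself is authored here (generalised Kullback-Leibler
# updates with restarts); catalogue construction follows the pyrimidine-
# strand convention of the standard reference tables.

#' Build a 96-class substitution catalogue from SNVs with context
#'
#' Each SNV carries its reference base, alternate base and the trinucleotide
#' context centred on the variant. Substitutions with a purine reference
#' (A/G) are reverse-complemented into the pyrimidine classes, then tallied
#' into the fixed [sbs96_classes()] ordering. Records whose context centre
#' does not match the reference base are rejected (kept in the `rejected`
#' attribute with a reason), so the catalogue total always equals the number
#' of accepted SNVs.
#'
#' @param snvs Tibble with `ref`, `alt` (single bases) and `context`
#'   (3-mer).
#' @return Named integer vector of length 96 with attribute `rejected`.
#' @export
build_96_spectrum <- function(snvs) {
  if (!all(c("ref", "alt", "context") %in% names(snvs)))
    stopf("`snvs` needs columns ref, alt, context")
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  ctx <- toupper(snvs$context)
  bad_shape <- nchar(ref) != 1 | nchar(alt) != 1 | nchar(ctx) != 3 |
    !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T")
  centre_mismatch <- !bad_shape & substr(ctx, 2, 2) != ref
  reject <- bad_shape | centre_mismatch
  rejected <- snvs[reject, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(bad_shape[reject], "malformed",
                              "context_centre_mismatch")

  ref <- ref[!reject]; alt <- alt[!reject]; ctx <- ctx[!reject]
  purine <- ref %in% c("A", "G")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  ref2 <- ifelse(purine, comp(ref), ref)
  alt2 <- ifelse(purine, comp(alt), alt)
  ctx2 <- ifelse(purine, revcomp(ctx), ctx)
  cls <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx2, 3, 3))
  out <- table(factor(cls, levels = sbs96_classes()))
  out <- setNames(as.integer(out), sbs96_classes())
  attr(out, "rejected") <- rejected
  out
}

# Generalised KL divergence D(V || WH); the V log V term is taken as 0 where
# V = 0.
gkl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

nmf_run_kl <- function(V, k, max_iter, tol, eps = 1e-12) {
  n <- nrow(V); s <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * s, 0.1, 1), k, s)
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    d <- gkl_divergence(V, W %*% H + eps)
    obj <- c(obj, d)
    if (is.finite(prev) && abs(prev - d) <= tol * max(1, abs(prev))) break
    prev <- d
  }
  list(W = W, H = H, divergence = d, objective = obj)
}

nmf_run_frobenius <- function(V, k, max_iter, tol, eps = 1e-12) {
  n <- nrow(V); s <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * s, 0.1, 1), k, s)
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
    d <- sum((V - W %*% H)^2)
    obj <- c(obj, d)
    if (is.finite(prev) && abs(prev - d) <= tol * max(1, abs(prev))) break
    prev <- d
  }
  list(W = W, H = H, divergence = d, objective = obj)
}

#' Extract mutational signatures by non-negative matrix factorisation
#'
#' Factorises a 96 x samples catalogue matrix as `V ~ W H` with
#' multiplicative updates minimising the generalised Kullback-Leibler
#' divergence (the convention of the signature-analysis literature;
#' Frobenius updates available by `loss`). The objective is non-increasing
#' at every iteration; the best of `n_restarts` random restarts by final
#' divergence is kept. Signatures are normalised to row-stochastic form with
#' the exposures rescaled to compensate, so `W H` is unchanged.
#'
#' @param catalogues 96 x samples non-negative matrix (or a single
#'   catalogue vector).
#' @param k Number of signatures (<= min(samples, 96)).
#' @param n_restarts Random restarts.
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed; fixed seed gives identical factors.
#' @param loss `"kl"` (default) or `"frobenius"`.
#' @return An `nmf_signatures` object: `signatures` (k x 96,
#'   row-stochastic), `exposures` (samples x k), `divergence`, `objective`
#'   (trace of the winning restart), `k`, `loss`.
#' @export
nmf_extract <- function(catalogues, k = 2, n_restarts = 10, max_iter = 2000,
                        tol = 1e-8, seed = 1, loss = c("kl", "frobenius")) {
  loss <- match.arg(loss)
  V <- as.matrix(catalogues)
  if (nrow(V) == 1 || (is.null(dim(catalogues)) && length(catalogues) == 96))
    V <- matrix(as.numeric(catalogues), ncol = 1,
                dimnames = list(sbs96_classes(), "S01"))
  if (nrow(V) != 96) stopf("catalogues must have 96 rows")
  if (any(V < 0)) stopf("catalogues must be non-negative")
  k <- check_count(k, "k")
  if (k > min(ncol(V), 96))
    stopf("k = %d exceeds the feasible rank min(samples, 96) = %d",
          k, min(ncol(V), 96))
  runner <- switch(loss, kl = nmf_run_kl, frobenius = nmf_run_frobenius)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(derive_seed(seed, r),
                            runner(V, k, max_iter, tol))
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  scale <- colSums(best$W)
  W <- sweep(best$W, 2, scale, "/")
  H <- best$H * scale
  signatures <- t(W)
  dimnames(signatures) <- list(paste0("Sig", seq_len(k)),
                               rownames(V) %||% sbs96_classes())
  exposures <- t(H)
  dimnames(exposures) <- list(colnames(V) %||% sprintf("S%02d", seq_len(ncol(V))),
                              rownames(signatures))
  structure(list(signatures = signatures, exposures = exposures,
                 divergence = best$divergence, objective = best$objective,
                 k = k, loss = loss),
            class = "nmf_signatures")
}

#' @export
print.nmf_signatures <- function(x, ...) {
  cat(sprintf("<nmf_signatures: k = %d (%s loss), divergence %.6g after %d iterations>\n",
              x$k, x$loss, x$divergence, length(x$objective)))
  invisible(x)
}

#' Match extracted signatures to a reference matrix
#'
#' For each extracted signature, finds the reference signature with the
#' highest cosine similarity. Both matrices must use the same 96-class
#' column ordering (checked via colnames when present).
#'
#' @param extracted k x 96 matrix (e.g. `nmf_extract()$signatures`).
#' @param reference Reference signatures x 96 row matrix.
#' @return Tibble with `signature`, `best_match`, `cosine`.
#' @export
match_to_reference <- function(extracted, reference) {
  extracted <- as.matrix(extracted); reference <- as.matrix(reference)
  if (ncol(extracted) != 96 || ncol(reference) != 96)
    stopf("both matrices must have 96 columns")
  if (!is.null(colnames(extracted)) && !is.null(colnames(reference)) &&
      !identical(colnames(extracted), colnames(reference)))
    stopf("class ordering differs between extracted and reference matrices")
  map_dfr(seq_len(nrow(extracted)), function(i) {
    sims <- apply(reference, 1, function(r) cosine_similarity(extracted[i, ], r))
    tibble(signature = rownames(extracted)[i] %||% paste0("Sig", i),
           best_match = rownames(reference)[which.max(sims)] %||%
             paste0("Ref", which.max(sims)),
           cosine = max(sims))
  })
}
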