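#' Reduced-model fit (polygenic only)
#'
#' Weighted least-squares fit of the reduced model
#' `y = 1 mu + Z V_g alpha + eps`, whose residuals feed the within-trait
#' permutations.
#'
#' @param context `ldla_context`.
#' @return List with `fitted`, `residuals` (both on the phenotype scale),
#'   `qr` of the weighted design, and `rank`.
#' @export
reduced_fit <- function(context) {
  n <- context$n_p
  X <- cbind(rep(1, n), context$ZVg)
  sw <- sqrt(context$w)
  qf <- qr(X * sw)
  fitted_w <- qr.fitted(qf, context$y * sw)
  fitted <- fitted_w / sw
  list(
    fitted = fitted, residuals = context$y - fitted,
    qr = qf, rank = qf$rank
  )
}

#' Permuted phenotype replicates
#'
#' Standardizes the reduced-model residuals by `R^{1/2}`, permutes them,
#' de-standardizes and adds back the reduced-model fitted values. Each
#' permutation uses its own derived seed (`seed + i`), so replicates are
#' reproducible independently of evaluation order.
#'
#' @param context `ldla_context`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param reduced Optional precomputed [reduced_fit()].
#' @return `n_P x n_perm` matrix of permuted phenotype vectors.
#' @export
permute_phenotypes <- function(context, n_perm, seed = 1, reduced = NULL) {
  if (is.null(reduced)) reduced <- reduced_fit(context)
  sw <- sqrt(context$w)
  e_std <- reduced$residuals * sw
  n <- context$n_p
  Y <- matrix(NA_real_, n, n_perm)
  for (i in seq_len(n_perm)) {
    set.seed((seed + i) %% .Machine$integer.max)
    Y[, i] <- reduced$fitted + e_std[sample.int(n)] / sw
  }
  Y
}

#' Genome-wide significance threshold by permutation
#'
#' Runs the breed-S scan on within-trait permutations of the reduced-model
#' residuals, records the genome-wide maximum of `-log10(p)` of each
#' permutation, and returns the empirical `(1 - alpha)` quantile (type 7) as
#' the genome-wide threshold.
#'
#' @param context `ldla_context`.
#' @param model `ldla_model`.
#' @param n_perm Number of permutations (default 2000).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Integer seed.
#' @param loci SNP indices (default: all).
#' @param hypothesis Tested block, default `"S"`.
#' @return Object of class `ldla_permnull`: `maxima` (length `n_perm`),
#'   `threshold`, `alpha`, `n_perm`, `seed`.
#' @export
gw_threshold <- function(context, model, n_perm = 2000, alpha = 0.05,
                         seed = 1, loci = NULL, hypothesis = "S") {
  stopifnot(n_perm >= 1, alpha > 0, alpha <= 1)
  if (n_perm < 1 / alpha) {
    warning("n_perm < 1/alpha: the threshold quantile is poorly estimated")
  }
  Y <- permute_phenotypes(context, n_perm, seed = seed)
  sc <- scan_core(context, model, Y, loci = loci, hypotheses = hypothesis)
  maxima <- apply(sc$logp[[hypothesis]], 2, max, na.rm = TRUE)
  structure(
    list(
      maxima = maxima,
      threshold = quantile(maxima, 1 - alpha, type = 7, names = FALSE),
      alpha = alpha, n_perm = n_perm, seed = seed, hypothesis = hypothesis
    ),
    class = "ldla_permnull"
  )
}

#' @export
print.ldla_permnull <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%d permutations, %s test): %.0f%% GW threshold = %.3f\n",
    x$n_perm, x$hypothesis, 100 * (1 - x$alpha), x$threshold
  ))
  invisible(x)
}

#' Common threshold across traits
#'
#' The most conservative (largest) per-trait genome-wide threshold, used as
#' the common threshold when several traits are analysed.
#'
#' @param ... `ldla_permnull` objects (or a single list of them).
#' @return The maximum threshold.
#' @export
common_threshold <- function(...) {
  nulls <- list(...)
  if (length(nulls) == 1 && !inherits(nulls[[1]], "ldla_permnull")) {
    nulls <- nulls[[1]]
  }
  max(vapply(nulls, function(x) x$threshold, 0))
}
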