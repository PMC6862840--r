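# Shared fixtures, built once per test run.

ldla_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(ldla_test_cache[[name]])) {
    ldla_test_cache[[name]] <- force(expr)
  }
  ldla_test_cache[[name]]
}

# Small two-generation population with a strong QTL (quarter of the
# phenotypic variance) so locus-level signal is clearly present.
sim_small <- function() {
  cached("sim_small", sim_population(
    n_sires = 4, daughters_per_sire = 10, n_generations = 2,
    n_snps = 200, n_chr = 2, chr_length_mb = 60,
    qtl_frac = 0.25, n_f1_sires = 2, seed = 42
  ))
}

model_small <- function() {
  cached("model_small", {
    s <- sim_small()
    suppressWarnings(ldla_prepare(s$genotypes, s$pedigree, s$map))
  })
}

context_small <- function() {
  cached("context_small", design_context(model_small(), sim_small()$phenotypes))
}

# Brute-force weighted least squares by normal equations (independent oracle
# for the QR path): F test of a column block via two explicit solves.
oracle_wls_ftest <- function(y, X, w, cols) {
  fit_rss <- function(M) {
    b <- solve(crossprod(M, M * w), crossprod(M, y * w))
    r <- y - M %*% b
    sum(w * r^2)
  }
  rss_full <- fit_rss(X)
  rss_red <- fit_rss(X[, -cols, drop = FALSE])
  df1 <- length(cols)
  df2 <- nrow(X) - ncol(X)
  F <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(F = F, df1 = df1, df2 = df2, rss = rss_full)
}

# Random full-rank WLS instance.
random_wls_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  y <- rnorm(n)
  w <- runif(n, 0.2, 1)
  list(y = y, X = X, w = w)
}

# A 0/1 descent matrix with unit rows (certain transmissions).
random_unit_row_h <- function(n_rh, n_bh, seed) {
  set.seed(seed)
  H <- matrix(0, n_rh, n_bh)
  H[cbind(seq_len(n_rh), sample.int(n_bh, n_rh, replace = TRUE))] <- 1
  H
}
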