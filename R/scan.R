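#' Reliability of average performance deviations
#'
#' Fits the one-way repeatability model `y_ij = a_i + e_ij` by the ANOVA
#' method of moments and returns per-individual reliabilities
#' `r_i = n_i var_a / (n_i var_a + var_e)` (the balanced-data closed form of
#' `1 - se(a_hat_i)^2 / var_a`).
#'
#' @param records Tibble with columns `id` and `value` (one row per repeated
#'   record).
#' @return Tibble (`id`, `n_records`, `r`) with the variance-component
#'   estimates in attributes `sigma_a2`, `sigma_e2`.
#' @export
compute_reliability <- function(records) {
  stopifnot(all(c("id", "value") %in% names(records)))
  grp <- split(records$value, records$id)
  ni <- lengths(grp)
  if (all(ni < 2)) stop("variance components need repeated records")
  a <- length(grp)
  N <- sum(ni)
  gm <- mean(records$value)
  means <- vapply(grp, mean, 0)
  ssw <- sum(vapply(grp, function(v) sum((v - mean(v))^2), 0))
  ssb <- sum(ni * (means - gm)^2)
  msw <- ssw / (N - a)
  msb <- ssb / (a - 1)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  sigma_e2 <- msw
  sigma_a2 <- (msb - msw) / n0
  if (sigma_a2 <= 0) {
    warning("estimated between-individual variance is zero; all r = 0")
    sigma_a2 <- 0
  }
  r <- ni * sigma_a2 / (ni * sigma_a2 + sigma_e2)
  r[!is.finite(r)] <- 0
  out <- tibble::tibble(id = names(grp), n_records = as.integer(ni), r = r)
  attr(out, "sigma_a2") <- sigma_a2
  attr(out, "sigma_e2") <- sigma_e2
  out
}

# Assemble the locus design pieces shared by fit_locus / scan / permutation:
# descent matrix, LD IBD matrix, per-breed basis, folded score columns.
locus_design <- function(context, model, locus) {
  Hf <- transmission_matrix(model$trans, locus)
  U <- ld_ibd_locus(model$bh, locus, model$map,
    window = model$window,
    breed = model$breed, prior = model$prior, chance = model$chance
  )
  basis <- locus_basis(U, Hf$f, model$breed, threshold = model$pc_threshold)
  V_l <- locus_scores(Hf$H, Hf$f, basis)
  list(
    Hf = Hf, U = U, basis = basis, V_l = V_l,
    ZVl = fold_gametes(context, V_l), blocks = attr(V_l, "blocks")
  )
}

# Weighted QR fits of the full and block-reduced designs; returns the partial
# F statistics for the requested hypothesis blocks given the weighted
# response(s). Yw may have several columns (permutation replicates).
wls_block_tests <- function(Xw, cols_test, Yw) {
  qf <- qr(Xw)
  rank_f <- qf$rank
  n <- nrow(Xw)
  df_res <- n - rank_f
  Qf <- qr.qy(qf, diag(1, n, rank_f))
  tot <- colSums(Yw^2)
  rss_f <- pmax(tot - colSums(crossprod(Qf, Yw)^2), 0)
  tests <- lapply(cols_test, function(cols) {
    if (length(cols) == 0 || df_res <= 0) {
      return(list(F = rep(NA_real_, ncol(Yw)), df1 = 0L, df2 = df_res))
    }
    qr0 <- qr(Xw[, -cols, drop = FALSE])
    Q0 <- qr.qy(qr0, diag(1, n, qr0$rank))
    rss_0 <- pmax(tot - colSums(crossprod(Q0, Yw)^2), 0)
    df1 <- rank_f - qr0$rank
    if (df1 <= 0) {
      return(list(F = rep(NA_real_, ncol(Yw)), df1 = 0L, df2 = df_res))
    }
    Fs <- ((rss_0 - rss_f) / df1) / (rss_f / df_res)
    list(F = Fs, df1 = df1, df2 = df_res)
  })
  list(qr = qf, rank = rank_f, df_res = df_res, rss = rss_f, tests = tests)
}

#' Weighted least-squares fit with block F-tests
#'
#' Low-level engine behind [fit_locus()]: fits `y = X b + eps` with diagonal
#' weights (QR with column pivoting; collinear columns dropped) and computes
#' the partial F statistic of each requested column block against the model
#' without that block.
#'
#' @param y Response vector.
#' @param X Design matrix (including the intercept column).
#' @param weights Positive observation weights.
#' @param test_cols Named list of column index vectors to test.
#' @return List with `coefficients` (NA for dropped columns), `rss`,
#'   `df_residual`, `rank`, and a `tests` tibble (`hypothesis`, `statistic`,
#'   `df1`, `df2`, `p_value`).
#' @export
fit_wls <- function(y, X, weights = rep(1, length(y)),
                    test_cols = list(all = seq_len(ncol(X))[-1])) {
  stopifnot(length(y) == nrow(X), length(weights) == length(y),
            all(weights > 0))
  sw <- sqrt(weights)
  w <- wls_block_tests(X * sw, test_cols, matrix(y * sw, ncol = 1))
  tests <- tibble::tibble(
    hypothesis = names(test_cols),
    statistic = unname(vapply(w$tests, function(t) t$F[1], 0)),
    df1 = unname(vapply(w$tests, function(t) as.integer(t$df1), 0L)),
    df2 = unname(vapply(w$tests, function(t) as.integer(t$df2), 0L))
  )
  tests$p_value <- pf(tests$statistic, tests$df1, tests$df2,
    lower.tail = FALSE
  )
  list(
    coefficients = qr.coef(w$qr, y * sw), rss = w$rss[1],
    df_residual = w$df_res, rank = w$rank, tests = tests
  )
}

logp_from_f <- function(F, df1, df2, cap = 300) {
  lp <- -(pf(F, df1, df2, lower.tail = FALSE, log.p = TRUE)) / log(10)
  lp[is.infinite(F) & F > 0] <- cap  # perfect fit: p underflows
  lp[is.na(F)] <- NA_real_
  pmin(lp, cap)
}

#' Fit the LDLA model at one SNP
#'
#' Weighted least-squares fit of
#' `y = 1 mu + Z V_l beta_l + Z V_g alpha_l + eps`,
#' `eps ~ N(0, sigma_eps^2 R^{-1})` with `R = diag(r)`, and partial F-tests
#' of the three null hypotheses `beta_l = 0`, `beta_l^S = 0`, `beta_l^L = 0`.
#' Rank-deficient columns are dropped by pivoted QR; the numerator degrees of
#' freedom are the retained tested columns and the denominator degrees of
#' freedom `n_P - rank(full design)`. `-log10(p)` is capped at 300.
#'
#' @param context `ldla_context` for the trait.
#' @param model `ldla_model`.
#' @param locus SNP index.
#' @return Object of class `ldla_fit`: coefficient estimates (`mu`, `beta`
#'   split by breed block, `alpha`), residual sum of squares, a `tests`
#'   tibble with F statistics and `-log10(p)` per hypothesis, the fitted QTL
#'   effect vector `Z V_l beta_l`, and the locus basis.
#' @export
fit_locus <- function(context, model, locus) {
  ld <- locus_design(context, model, locus)
  n <- context$n_p
  X <- cbind(`(Intercept)` = rep(1, n), ld$ZVl, context$ZVg)
  p_l <- ncol(ld$ZVl)
  p_g <- ncol(context$ZVg)
  colnames(X) <- c(
    "(Intercept)",
    unlist(lapply(names(ld$blocks), function(b) {
      sprintf("q%s%d", b, seq_along(ld$blocks[[b]]))
    })),
    if (p_g > 0) sprintf("g%d", seq_len(p_g))
  )
  if (n <= ncol(X)) {
    warning("fewer observations than design columns; locus skipped")
  }
  sw <- sqrt(context$w)
  Xw <- X * sw
  yw <- context$y * sw
  qtl_cols <- 1L + seq_len(p_l)
  cols_test <- list(
    all = qtl_cols,
    S = if (!is.null(ld$blocks$S)) 1L + ld$blocks$S else integer(0),
    L = if (!is.null(ld$blocks$L)) 1L + ld$blocks$L else integer(0)
  )
  w <- wls_block_tests(Xw, cols_test, matrix(yw, ncol = 1))
  beta_full <- qr.coef(w$qr, yw)
  beta_full[is.na(beta_full)] <- 0
  beta_l <- beta_full[qtl_cols]
  tests <- tibble::tibble(
    hypothesis = c("beta_l", "beta_l_S", "beta_l_L"),
    statistic = unname(vapply(w$tests, function(t) t$F[1], 0)),
    df1 = unname(vapply(w$tests, function(t) as.integer(t$df1), 0L)),
    df2 = unname(vapply(w$tests, function(t) as.integer(t$df2), 0L))
  )
  tests$minus_log10_p <- logp_from_f(tests$statistic, tests$df1, tests$df2)
  structure(
    list(
      locus = locus, snp_id = model$map$snp_id[locus],
      coefficients = stats::setNames(beta_full, colnames(X)),
      mu = beta_full[1],
      beta_l = beta_l,
      beta_s = beta_full[cols_test$S],
      beta_lac = beta_full[cols_test$L],
      alpha = if (p_g > 0) beta_full[1L + p_l + seq_len(p_g)] else numeric(0),
      rss = w$rss[1], df_residual = w$df_res,
      sigma2 = w$rss[1] / w$df_res,
      rank = w$rank, n_dropped = ncol(X) - w$rank,
      tests = tests,
      fitted_qtl = as.numeric(ld$ZVl %*% beta_l),
      basis = ld$basis, f = ld$Hf$f, n_pc_l = ncol(ld$ZVl)
    ),
    class = "ldla_fit"
  )
}

#' @export
print.ldla_fit <- function(x, ...) {
  cat(sprintf(
    "LDLA locus fit at %s: %d QTL PCs, rss %.4g on %d df\n",
    x$snp_id, x$n_pc_l, x$rss, x$df_residual
  ))
  print(x$tests)
  invisible(x)
}

#' @rdname fit_locus
#' @param x `ldla_fit` object.
#' @param ... Unused.
#' @method tidy ldla_fit
#' @export
tidy.ldla_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname fit_locus
#' @method glance ldla_fit
#' @export
glance.ldla_fit <- function(x, ...) {
  t <- x$tests
  tibble::tibble(
    snp_id = x$snp_id, n_pc_l = x$n_pc_l, rss = x$rss,
    sigma2 = x$sigma2, df_residual = x$df_residual,
    statistic_all = t$statistic[1], minus_log10_p_all = t$minus_log10_p[1],
    statistic_S = t$statistic[2], minus_log10_p_S = t$minus_log10_p[2],
    statistic_L = t$statistic[3], minus_log10_p_L = t$minus_log10_p[3]
  )
}

#' Per-base-haplotype allelic effects at a locus
#'
#' Back-transforms the estimated PC effects to one additive effect per base
#' haplotype: `beta_l^BH = F_l^{-1/2} V_l^w beta_l`, used to rank the BH
#' contributing to a significance peak.
#'
#' @param fit `ldla_fit` object, or a replicate-count vector `f`.
#' @param ... Further arguments for the default method.
#' @return Tibble (`bh`, `breed`, `f`, `effect`).
#' @export
bh_effects <- function(fit, ...) UseMethod("bh_effects")

#' @rdname bh_effects
#' @param Vw Retained eigenvector matrix of `U_l^w` (default method).
#' @param beta Estimated PC effects (default method).
#' @export
bh_effects.default <- function(fit, Vw, beta, ...) {
  f <- fit
  stopifnot(nrow(Vw) == length(f), ncol(Vw) == length(beta))
  as.numeric((Vw / sqrt(f)) %*% beta)
}

#' @rdname bh_effects
#' @export
bh_effects.ldla_fit <- function(fit, ...) {
  out <- list()
  for (b in names(fit$basis$blocks)) {
    bl <- fit$basis$blocks[[b]]
    beta <- if (b == "S") fit$beta_s else fit$beta_lac
    eff <- bh_effects.default(fit$f[bl$idx], bl$vectors, beta)
    out[[b]] <- tibble::tibble(
      bh = names(fit$f)[bl$idx] %||% as.character(bl$idx),
      breed = b, f = fit$f[bl$idx], effect = eff
    )
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scan a set of loci for one or many response vectors; returns -log10 p
# matrices for the requested hypotheses plus fitted QTL effect vectors of the
# first response. Core shared by scan_genome(), gw_threshold() and the
# calibration tests.
scan_core <- function(context, model, Y, loci = NULL,
                      hypotheses = c("all", "S", "L"), effects = FALSE) {
  if (is.null(loci)) loci <- seq_len(nrow(model$map))
  Y <- as.matrix(Y)
  sw <- sqrt(context$w)
  Yw <- Y * sw
  n <- context$n_p
  out <- lapply(hypotheses, function(h) {
    matrix(NA_real_, length(loci), ncol(Y))
  })
  names(out) <- hypotheses
  npc <- matrix(NA_integer_, length(loci), 3,
    dimnames = list(NULL, c("all", "S", "L"))
  )
  eff <- if (effects) matrix(0, n, length(loci)) else NULL
  for (i in seq_along(loci)) {
    l <- loci[i]
    ld <- locus_design(context, model, l)
    X <- cbind(rep(1, n), ld$ZVl, context$ZVg)
    Xw <- X * sw
    p_l <- ncol(ld$ZVl)
    cols <- list(
      all = 1L + seq_len(p_l),
      S = if (!is.null(ld$blocks$S)) 1L + ld$blocks$S else integer(0),
      L = if (!is.null(ld$blocks$L)) 1L + ld$blocks$L else integer(0)
    )
    w <- wls_block_tests(Xw, cols[hypotheses], Yw)
    for (j in seq_along(hypotheses)) {
      t <- w$tests[[j]]
      out[[j]][i, ] <- logp_from_f(t$F, t$df1, t$df2)
    }
    npc[i, ] <- c(
      p_l,
      length(cols$S),
      length(cols$L)
    )
    if (effects) {
      beta <- qr.coef(w$qr, Yw[, 1])
      beta[is.na(beta)] <- 0
      eff[, i] <- as.numeric(ld$ZVl %*% beta[cols$all])
    }
  }
  list(logp = out, n_pc = npc, effects = eff, loci = loci)
}

#' Genome scan
#'
#' Tests the LDLA model at every SNP position by partial F-tests of the three
#' null hypotheses (all QTL PCs, the breed-S block and the breed-L block) and
#' returns a Manhattan-ready tibble. The breed-S test is the primary
#' reported statistic.
#'
#' @param context `ldla_context` for the trait.
#' @param model `ldla_model`.
#' @param loci SNP indices to test (default: all).
#' @return Tibble of class `ldla_scan` (`snp_id`, `chrom`, `pos_bp`,
#'   `pos_mb`, `n_pc_l`, `minus_log10_p_all`, `minus_log10_p_S`,
#'   `minus_log10_p_L`) with the fitted per-SNP QTL effect vectors
#'   (`n_P x n_loci`) in `attr(, "effects")`.
#' @export
scan_genome <- function(context, model, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(nrow(model$map))
  sc <- scan_core(context, model, matrix(context$y, ncol = 1),
    loci = loci,
    hypotheses = c("all", "S", "L"), effects = TRUE
  )
  out <- tibble::tibble(
    snp_id = model$map$snp_id[loci],
    chrom = model$map$chrom[loci],
    pos_bp = model$map$pos_bp[loci],
    pos_mb = model$map$pos_bp[loci] / 1e6,
    n_pc_l = sc$n_pc[, "all"],
    n_pc_s = sc$n_pc[, "S"],
    n_pc_lac = sc$n_pc[, "L"],
    minus_log10_p_all = sc$logp$all[, 1],
    minus_log10_p_S = sc$logp$S[, 1],
    minus_log10_p_L = sc$logp$L[, 1]
  )
  attr(out, "effects") <- sc$effects
  attr(out, "trait") <- context$trait
  attr(out, "loci") <- loci
  class(out) <- c("ldla_scan", class(out))
  out
}

#' @rdname scan_genome
#' @param x `ldla_scan` object.
#' @param ... Unused.
#' @method glance ldla_scan
#' @export
glance.ldla_scan <- function(x, ...) {
  peak <- which.max(x$minus_log10_p_S)
  tibble::tibble(
    trait = attr(x, "trait") %||% NA_character_,
    n_loci = nrow(x),
    mean_n_pc_l = mean(x$n_pc_l),
    peak_snp = x$snp_id[peak],
    peak_chrom = x$chrom[peak],
    peak_mb = x$pos_mb[peak],
    peak_minus_log10_p_S = x$minus_log10_p_S[peak]
  )
}
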