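#' Replicate-weighted IBD matrix
#'
#' Weights an IBD probability matrix by the per-BH replicate counts:
#' `U^w = F^{1/2} U F^{1/2}`, i.e. `U^w[i, j] = sqrt(f_i f_j) U[i, j]`.
#'
#' @param U Symmetric IBD matrix.
#' @param f Non-negative replicate counts, one per row of `U`.
#' @return The weighted symmetric matrix.
#' @export
weighted_ibd <- function(U, f) {
  if (length(f) != nrow(U) || nrow(U) != ncol(U)) stop("dimension mismatch")
  if (any(f < 0)) stop("replicate counts must be non-negative")
  s <- sqrt(f)
  U * outer(s, s)
}

#' Eigendecomposition with a deterministic sign convention
#'
#' Full symmetric eigendecomposition, eigenvalues in descending order, each
#' eigenvector oriented so that its largest-magnitude element is positive.
#' Negative eigenvalues (from non-positive-definite IBD estimates) are
#' returned but never retained by [select_pcs()].
#'
#' @param M Symmetric matrix (asymmetry beyond 1e-10 is an error).
#' @return List of class `ldla_eigen` with `values` and `vectors`.
#' @export
eigen_decompose <- function(M) {
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-10) {
    stop("input is not symmetric")
  }
  E <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- E$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(values = E$values, vectors = V), class = "ldla_eigen")
}

#' Number of principal components to retain
#'
#' Smallest leading set of (positive) eigenvalues whose cumulative share of
#' `total` exceeds `threshold`.
#'
#' @param values Eigenvalues in descending order.
#' @param threshold Variance share in (0, 1].
#' @param total Denominator of the share; defaults to `sum(values)` (the
#'   trace of the decomposed matrix).
#' @return Integer count of retained components.
#' @export
select_pcs <- function(values, threshold = 0.99, total = sum(values)) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  pos <- values[values > 0]
  if (length(pos) == 0) return(0L)
  cs <- cumsum(pos)
  k <- which(cs > threshold * total - 1e-12)
  if (length(k) == 0) return(length(pos))
  k[1]
}

#' Per-breed locus PC basis
#'
#' Decomposes the replicate-weighted IBD matrix `U_l^w` block by breed (the
#' cross-breed entries are zero, so the blocks decouple), retaining within
#' each breed the components explaining more than `threshold` of the
#' within-breed variation (the trace of that breed's block). BH with `f = 0`
#' at the locus are excluded from the basis.
#'
#' @param U Per-locus IBD matrix between BH.
#' @param f Per-locus replicate counts.
#' @param breed Breed label per BH.
#' @param threshold Variance share (default 0.99).
#' @return List of class `ldla_basis`: per-breed blocks with `idx` (BH
#'   indices), `vectors` (retained eigenvectors of the block), `values`
#'   (all eigenvalues), `n_pc`; plus totals `n_pc`.
#' @export
locus_basis <- function(U, f, breed, threshold = 0.99) {
  blocks <- list()
  for (b in intersect(c("S", "L"), unique(breed))) {
    idx <- which(breed == b & f > 0)
    if (length(idx) == 0) next
    Uw <- weighted_ibd(U[idx, idx, drop = FALSE], f[idx])
    E <- eigen_decompose(Uw)
    k <- select_pcs(E$values, threshold, total = sum(diag(Uw)))
    blocks[[b]] <- list(
      idx = idx, values = E$values,
      vectors = E$vectors[, seq_len(k), drop = FALSE], n_pc = k
    )
  }
  structure(
    list(blocks = blocks, n_pc = sum(vapply(blocks, `[[`, 1L, "n_pc"))),
    class = "ldla_basis"
  )
}

#' PC scores of replicated haplotypes at a locus
#'
#' `V_l = H_l F_l^{-1/2} V_l^w`, assembled per breed block and concatenated
#' as `[V_l^S  V_l^L]`.
#'
#' @param H Per-locus descent matrix (n_RH x n_BH).
#' @param f Per-locus replicate counts.
#' @param basis `ldla_basis` from [locus_basis()].
#' @return Score matrix (n_RH x n_PC_l) with a `blocks` attribute giving the
#'   column indices of each breed block.
#' @export
locus_scores <- function(H, f, basis) {
  parts <- list()
  cols <- list()
  at <- 0L
  for (b in names(basis$blocks)) {
    bl <- basis$blocks[[b]]
    Vw <- bl$vectors / sqrt(f[bl$idx])
    parts[[b]] <- H[, bl$idx, drop = FALSE] %*% Vw
    cols[[b]] <- at + seq_len(bl$n_pc)
    at <- at + bl$n_pc
  }
  V <- do.call(cbind, parts)
  attr(V, "blocks") <- cols
  V
}

# Greedy selection pass; returns NULL when no candidate has a usable Schur
# complement (singular U_g_hh) before reaching coverage.
bhh_greedy <- function(U_g, f_g, coverage, ridge) {
  n <- length(f_g)
  n_rh <- sum(f_g)
  t_all <- as.numeric(U_g %*% f_g)
  dg <- 1 + ridge
  sel <- integer(0)
  M <- NULL
  repeat {
    if (length(sel) == 0) {
      pick <- which.max(t_all / dg)
      M <- matrix(1 / dg, 1, 1)
      sel <- pick
    } else {
      cand <- setdiff(seq_len(n), sel)
      if (length(cand) == 0) break
      Uhc <- U_g[sel, cand, drop = FALSE]
      MU <- M %*% Uhc
      s <- dg - colSums(Uhc * MU)
      M1 <- rowSums(M)
      uM1 <- as.numeric(crossprod(Uhc, M1))
      tA <- t_all[sel]
      const <- sum(tA * M1)
      tAMU <- as.numeric(crossprod(MU, tA))
      score <- const + tAMU * (uM1 - 1) / s + t_all[cand] * (1 - uM1) / s
      score[s <= 1e-10] <- -Inf
      if (!any(is.finite(score))) return(NULL)
      j <- which.max(score)
      c_idx <- cand[j]
      u <- U_g[sel, c_idx]
      Mu <- as.numeric(M %*% u)
      sc <- dg - sum(u * Mu)
      M <- rbind(
        cbind(M + tcrossprod(Mu) / sc, -Mu / sc),
        c(-Mu / sc, 1 / sc)
      )
      sel <- c(sel, c_idx)
    }
    sumf <- sum(t_all[sel] * rowSums(M))
    if (sumf / n_rh > coverage || length(sel) == n) {
      return(list(sel = sel, M = M, coverage = sumf / n_rh))
    }
  }
  NULL
}

#' Select the high-impact base haplotypes BH_h
#'
#' Iteratively selects the smallest set of base haplotypes whose updated
#' replicate count `f_gh = W' f_g`, with `W = U_gh U_ghh^{-1}`, covers more
#' than `coverage` of the replicated haplotypes (`sum(f_gh) / n_RH >
#' coverage`). Selection is greedy by marginal gain in `sum(f_gh)`,
#' deterministic with ties broken by the lowest BH index. If `U_ghh` becomes
#' numerically singular, a ridge of 1e-8 is added to its diagonal with a
#' warning.
#'
#' @param U_g Genome-average IBD matrix between BH.
#' @param f_g Genome-average replicate counts.
#' @param coverage Required replicate coverage (default 0.99).
#' @param ridge Diagonal ridge used in the singular fallback.
#' @return List of class `ldla_bhh`: `idx` (selected BH, in selection order),
#'   `W` (n_BH x n_BHh coefficients), `f_gh`, `coverage`.
#' @export
select_bh_h <- function(U_g, f_g, coverage = 0.99, ridge = 1e-8) {
  if (any(f_g < 0)) stop("replicate counts must be non-negative")
  res <- bhh_greedy(U_g, f_g, coverage, ridge = 0)
  if (is.null(res)) {
    warning("U_g_hh numerically singular; adding 1e-8 ridge to its diagonal")
    res <- bhh_greedy(U_g, f_g, coverage, ridge = ridge)
  }
  sel <- res$sel
  W <- U_g[, sel, drop = FALSE] %*% res$M
  f_gh <- as.numeric(crossprod(W, f_g))
  structure(
    list(
      idx = sel, W = W, f_gh = f_gh, coverage = res$coverage,
      U_hh = U_g[sel, sel, drop = FALSE]
    ),
    class = "ldla_bhh"
  )
}

#' Genome-level PC basis over BH_h
#'
#' Decomposes `U_ghh^w = F_gh^{1/2} U_ghh F_gh^{1/2}` and retains the
#' components explaining more than `threshold` of the total variation.
#'
#' @param bhh `ldla_bhh` object from [select_bh_h()].
#' @param threshold Variance share (default 0.99).
#' @return List of class `ldla_gbasis`: `vectors`, `values`, `n_pc`, `f_gh`.
#' @export
genome_basis <- function(bhh, threshold = 0.99) {
  f_gh <- bhh$f_gh
  if (any(f_gh <= 0)) {
    warning("non-positive updated replicate counts clamped to 1e-8")
    f_gh <- pmax(f_gh, 1e-8)
  }
  Uw <- weighted_ibd(bhh$U_hh, f_gh)
  E <- eigen_decompose(Uw)
  k <- select_pcs(E$values, threshold, total = sum(diag(Uw)))
  structure(
    list(
      values = E$values, vectors = E$vectors[, seq_len(k), drop = FALSE],
      n_pc = k, f_gh = f_gh
    ),
    class = "ldla_gbasis"
  )
}

#' Genome-wide PC scores of replicated haplotypes
#'
#' `V_g = H_g W F_gh^{-1/2} V_ghh^w`; constant across loci.
#'
#' @param H_g Genome-average descent matrix.
#' @param bhh `ldla_bhh` selection.
#' @param gbasis `ldla_gbasis` from [genome_basis()].
#' @return Score matrix (n_RH x n_PC_g).
#' @export
genome_scores <- function(H_g, bhh, gbasis) {
  H_g %*% bhh$W %*% (gbasis$vectors / sqrt(gbasis$f_gh))
}
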