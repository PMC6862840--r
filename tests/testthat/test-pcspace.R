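test_that("replicate weighting scales IBD as sqrt(f_i f_j)", {
  U <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(weighted_ibd(U, c(1, 1)), U)
  expect_equal(weighted_ibd(diag(2), c(4, 9)), diag(c(4, 9)))
  expect_equal(
    weighted_ibd(U, c(4, 1)),
    matrix(c(4, 1, 1, 1), 2)
  )
  expect_error(weighted_ibd(U, c(-1, 1)), "non-negative")
  expect_error(weighted_ibd(U, 1), "dimension")
})

test_that("eigendecomposition is exact, ordered and sign-deterministic", {
  E <- eigen_decompose(diag(3))
  expect_equal(E$values, rep(1, 3))
  E2 <- eigen_decompose(diag(c(4, 1)))
  expect_equal(E2$values, c(4, 1))
  expect_equal(abs(E2$vectors), diag(2), tolerance = 1e-12)

  set.seed(1)
  M <- crossprod(matrix(rnorm(25), 5))
  E3 <- eigen_decompose(M)
  expect_lt(
    max(abs(E3$vectors %*% diag(E3$values) %*% t(E3$vectors) - M)), 1e-10
  )
  # sign convention: largest-magnitude element positive
  for (j in 1:5) {
    expect_gt(E3$vectors[which.max(abs(E3$vectors[, j])), j], 0)
  }
  # 3x3 eigenvalues against the characteristic-polynomial oracle
  M3 <- crossprod(matrix(rnorm(9), 3))
  ch <- polyroot(c(
    -det(M3),
    M3[1, 1] * M3[2, 2] - M3[1, 2]^2 + M3[1, 1] * M3[3, 3] - M3[1, 3]^2 +
      M3[2, 2] * M3[3, 3] - M3[2, 3]^2,
    -sum(diag(M3)), 1
  ))
  expect_equal(
    sort(Re(ch), decreasing = TRUE), eigen_decompose(M3)$values,
    tolerance = 1e-8
  )
  expect_error(eigen_decompose(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("PC retention is the minimal set exceeding the threshold", {
  expect_equal(select_pcs(c(98.5, 1, 0.5), 0.99), 2L)
  expect_equal(select_pcs(c(100, 0, 0), 0.99), 1L)
  expect_error(select_pcs(c(1, 1), 0), "threshold")
  # no compression possible: mutually non-IBD BH with uniform replicates
  n <- 20
  basis <- locus_basis(diag(n), rep(2, n), rep("S", n), threshold = 0.99)
  expect_equal(basis$blocks$S$n_pc, n)
  # minimality on random weighted IBD matrices
  set.seed(4)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    A <- matrix(runif(n * n), n)
    U <- (A %*% t(A))
    U <- stats::cov2cor(U)
    f <- rpois(n, 3) + 1
    vals <- eigen_decompose(weighted_ibd(U, f))$values
    kk <- select_pcs(vals, 0.99)
    tot <- sum(vals)
    expect_gt(sum(vals[seq_len(kk)]), 0.99 * tot - 1e-9)
    if (kk > 1) expect_lte(sum(vals[seq_len(kk - 1)]), 0.99 * tot + 1e-9)
  }
})

test_that("locus scores follow V_l = H F^{-1/2} V^w", {
  set.seed(2)
  n_bh <- 10
  A <- matrix(runif(n_bh^2), n_bh)
  U <- stats::cov2cor(A %*% t(A))
  breed <- rep("S", n_bh)
  # permutation-like 0/1 H with f all 1 selects rows of V^w
  H <- diag(n_bh)[sample.int(n_bh), ]
  basis <- locus_basis(U, colSums(H), breed, threshold = 1)
  V <- locus_scores(H, colSums(H), basis)
  expect_equal(unname(V), unname(H %*% basis$blocks$S$vectors),
    ignore_attr = TRUE
  )

  # a 0.5/0.5 row averages the two BH score rows
  H2 <- rbind(diag(n_bh), c(0.5, 0.5, rep(0, n_bh - 2)))
  f2 <- colSums(H2)
  basis2 <- locus_basis(U, f2, breed, threshold = 1)
  V2 <- locus_scores(H2, f2, basis2)
  scores_bh <- (basis2$blocks$S$vectors / sqrt(f2))
  expect_equal(V2[n_bh + 1, ], 0.5 * (scores_bh[1, ] + scores_bh[2, ]),
    ignore_attr = TRUE
  )
})

test_that("PC scores from G_l match V_l for certain transmissions", {
  # the equivalence that justifies decomposing U^w instead of G_l
  m <- model_small()
  keep <- which(m$breed == "S")[1:25]
  U <- ld_ibd_locus(m$bh[keep, ], 40, m$map,
    breed = rep("S", 25), prior = 0.1
  )
  H <- random_unit_row_h(60, 25, seed = 11)
  f <- colSums(H)
  used <- f > 0
  G <- H %*% U %*% t(H)
  Uw <- weighted_ibd(U[used, used], f[used])
  eg <- eigen_decompose(G)
  ew <- eigen_decompose(Uw)
  k <- sum(ew$values > 1e-8)
  expect_equal(eg$values[seq_len(k)], ew$values[seq_len(k)],
    tolerance = 1e-8
  )
  basis <- locus_basis(U, f, rep("S", 25), threshold = 0.99)
  V <- locus_scores(H, f, basis)
  npc <- basis$blocks$S$n_pc
  for (j in seq_len(npc)) {
    gap_ok <- if (j < length(ew$values)) {
      abs(ew$values[j] - ew$values[j + 1]) > 1e-6
    } else {
      TRUE
    }
    if (gap_ok && (j == 1 || abs(ew$values[j] - ew$values[j - 1]) > 1e-6)) {
      align <- abs(sum(eg$vectors[, j] * V[, j])) /
        sqrt(sum(eg$vectors[, j]^2) * sum(V[, j]^2))
      expect_equal(align, 1, tolerance = 1e-6)
    }
  }
})

test_that("BH_h selection is minimal-greedy with unit member rows", {
  # mutually non-IBD BH with uniform replicates: no borrowing possible
  n <- 10
  sel <- select_bh_h(diag(n), rep(3, n), coverage = 0.99)
  expect_gte(length(sel$idx), ceiling(0.99 * n))
  W <- sel$W
  expect_equal(W[sel$idx, ], diag(length(sel$idx)),
    tolerance = 1e-9, ignore_attr = TRUE
  )

  # two identical BH carrying all replicates: one suffices, the twin's W row
  # is a unit coefficient on the member
  U <- diag(4)
  U[1, 2] <- U[2, 1] <- 1
  f <- c(10, 10, 0.05, 0.05)
  sel2 <- select_bh_h(U, f, coverage = 0.99)
  expect_equal(sort(sel2$idx), 1L)
  expect_equal(sel2$W[2, 1], 1, tolerance = 1e-9)
  expect_gt(sum(sel2$f_gh) / sum(f), 0.99)

  expect_error(select_bh_h(diag(2), c(-1, 1)), "non-negative")
})

test_that("genome scores reduce to the locus formula when W = I", {
  m <- model_small()
  n_bh <- nrow(m$U_g)
  # degenerate selection: every BH is high-impact
  sel <- list(
    idx = seq_len(n_bh), W = diag(n_bh), f_gh = m$f_g,
    coverage = 1, U_hh = m$U_g
  )
  class(sel) <- "ldla_bhh"
  gb <- genome_basis(sel, threshold = 0.99)
  Vg <- genome_scores(m$H_g, sel, gb)
  direct <- m$H_g %*% (gb$vectors / sqrt(m$f_g))
  expect_equal(Vg, direct)

  # single BH_h: one column, rows proportional to total descent weights
  one <- list(
    idx = 1L, W = matrix(m$U_g[, 1], ncol = 1),
    f_gh = sum(m$U_g[, 1] * m$f_g), coverage = NA,
    U_hh = m$U_g[1, 1, drop = FALSE]
  )
  class(one) <- "ldla_bhh"
  gb1 <- genome_basis(one, threshold = 0.99)
  expect_equal(gb1$n_pc, 1L)
  expect_equal(ncol(genome_scores(m$H_g, one, gb1)), 1L)
})

test_that("genome PCs track the polygenic background", {
  sim <- sim_population(
    n_sires = 6, daughters_per_sire = 12, n_generations = 2,
    n_snps = 200, n_chr = 2, chr_length_mb = 60, qtl_frac = 0,
    n_f1_sires = 2, var_polygenic = 0.5, var_error = 0.5,
    polygenic_model = "genomic", seed = 77
  )
  model <- suppressWarnings(ldla_prepare(sim$genotypes, sim$pedigree, sim$map))
  ctx <- design_context(model, sim$phenotypes)
  a <- sim$phenotypes$true_polygenic[match(ctx$ids, sim$phenotypes$id)]
  r2_vg <- summary(lm(a ~ ctx$ZVg))$r.squared
  # comparison: 5 random BH dosage columns (descent counts per ewe)
  set.seed(1)
  r2_rand <- vapply(1:20, function(i) {
    cols <- sample.int(nrow(model$U_g), 5)
    Hf <- model$H_g[, cols, drop = FALSE]
    Z <- Hf[ctx$odd, ] + Hf[ctx$even, ]
    summary(lm(a ~ Z))$r.squared
  }, 0)
  expect_gt(r2_vg, max(r2_rand))
})
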