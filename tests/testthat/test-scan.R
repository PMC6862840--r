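test_that("reliabilities follow the balanced closed form", {
  set.seed(10)
  n <- 4000
  a <- rnorm(n, 0, 1)
  rec4 <- tibble::tibble(
    id = rep(sprintf("i%04d", 1:n), each = 4),
    value = rep(a, each = 4) + rnorm(4 * n, 0, 1)
  )
  rel <- compute_reliability(rec4)
  expect_lt(max(abs(rel$r - 0.8)), 0.02)

  # an individual with a single record gets r = sigma_a2/(sigma_a2+sigma_e2)
  rec_mix <- dplyr::bind_rows(
    rec4,
    tibble::tibble(id = "single", value = rnorm(1))
  )
  rel_mix <- compute_reliability(rec_mix)
  expect_lt(abs(rel_mix$r[rel_mix$id == "single"] - 0.5), 0.03)

  # vanishing between-individual variance: all group means identical while
  # within-group spread is large, so the moment estimate of var_a is <= 0
  flat <- tibble::tibble(
    id = rep(sprintf("i%02d", 1:50), each = 2),
    value = rep(c(-1, 1), 50)
  )
  expect_warning(rel0 <- compute_reliability(flat), "zero")
  expect_true(all(rel0$r == 0))
  expect_error(
    compute_reliability(tibble::tibble(id = c("a", "b"), value = 1:2)),
    "repeated records"
  )
})

test_that("fit_wls agrees with the normal-equations oracle", {
  for (k in 1:25) {
    inst <- random_wls_instance(n = sample(20:50, 1), p = 6, seed = 200 + k)
    cols <- 3:5
    fit <- fit_wls(inst$y, inst$X, inst$w, test_cols = list(blk = cols))
    orc <- oracle_wls_ftest(inst$y, inst$X, inst$w, cols)
    expect_equal(fit$tests$statistic, orc$F, tolerance = 1e-8)
    expect_equal(fit$rss, orc$rss, tolerance = 1e-8)
    expect_equal(fit$tests$df1, length(cols))
    expect_equal(fit$tests$df2, nrow(inst$X) - ncol(inst$X))
  }
})

test_that("fit_locus matches fit_wls on the assembled locus design", {
  m <- model_small()
  ctx <- context_small()
  l <- 25
  fit <- fit_locus(ctx, m, l)
  ld <- ldlapca:::locus_design(ctx, m, l)
  X <- cbind(1, ld$ZVl, ctx$ZVg)
  qtl_cols <- 1L + seq_len(ncol(ld$ZVl))
  ref <- fit_wls(ctx$y, X, ctx$w, test_cols = list(all = qtl_cols))
  expect_equal(fit$tests$statistic[1], ref$tests$statistic, tolerance = 1e-10)
  expect_equal(fit$rss, ref$rss, tolerance = 1e-10)
  # glance/tidy expose the fit as tibbles
  expect_s3_class(tidy(fit), "tbl_df")
  g <- glance(fit)
  expect_equal(g$minus_log10_p_S,
    fit$tests$minus_log10_p[fit$tests$hypothesis == "beta_l_S"])
})

test_that("perfect fit caps -log10 p at 300 and pure polygenic stays null", {
  m <- model_small()
  ctx <- context_small()
  l <- 40
  ld <- ldlapca:::locus_design(ctx, m, l)
  # noiseless response in the span of the locus block
  set.seed(1)
  ctx2 <- ctx
  ctx2$y <- as.numeric(ld$ZVl %*% rnorm(ncol(ld$ZVl)))
  fit2 <- fit_locus(ctx2, m, l)
  expect_equal(fit2$tests$minus_log10_p[1], 300)

  # response in the span of the polygenic block: locus test near null
  ctx3 <- ctx
  ctx3$y <- as.numeric(ctx$ZVg %*% rnorm(ncol(ctx$ZVg))) +
    rnorm(ctx$n_p, 0, 0.05)
  fit3 <- fit_locus(ctx3, m, l)
  expect_lt(fit3$tests$minus_log10_p[1], 2)
})

test_that("the scan localizes a strong planted QTL", {
  s <- sim_small()
  m <- model_small()
  ctx <- context_small()
  sc <- scan_genome(ctx, m)
  expect_equal(nrow(sc), nrow(m$map))
  expect_true(all(sc$minus_log10_p_S >= 0, na.rm = TRUE))
  j <- match(s$qtl$snp_id, m$map$snp_id)
  pk <- which.max(sc$minus_log10_p_S)
  expect_equal(sc$chrom[pk], m$map$chrom[j])
  expect_lt(abs(sc$pos_bp[pk] - m$map$pos_bp[j]) / 1e6, 8)
  # a single-locus scan yields exactly one record
  sc1 <- scan_genome(ctx, m, loci = j)
  expect_equal(nrow(sc1), 1L)
})

test_that("null p-values are approximately uniform", {
  sim <- sim_population(
    n_sires = 4, daughters_per_sire = 12, n_generations = 2,
    n_snps = 200, n_chr = 2, chr_length_mb = 60, qtl_frac = 0,
    n_f1_sires = 2, seed = 55
  )
  model <- suppressWarnings(ldla_prepare(sim$genotypes, sim$pedigree, sim$map))
  ctx <- design_context(model, sim$phenotypes)
  sc <- scan_genome(ctx, model)
  p <- 10^(-sc$minus_log10_p_S)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH effects recover the planted allele classes", {
  # a near-Mendelian QTL so the locus fit pins down the allelic contrast
  s <- cached("sim_bh", sim_population(
    n_sires = 6, daughters_per_sire = 15, n_generations = 2,
    n_snps = 200, n_chr = 1, chr_length_mb = 80,
    qtl_frac = 0.5, var_polygenic = 0.1, var_error = 0.2,
    n_f1_sires = 2, seed = 13
  ))
  m <- cached("model_bh", suppressWarnings(
    ldla_prepare(s$genotypes, s$pedigree, s$map)
  ))
  ctx <- design_context(m, s$phenotypes)
  j <- match(s$qtl$snp_id, m$map$snp_id)
  fit <- fit_locus(ctx, m, j)
  eff <- bh_effects(fit)
  expect_s3_class(eff, "tbl_df")
  # beta = 0 gives all-zero effects
  fit0 <- fit
  fit0$beta_s <- fit0$beta_s * 0
  fit0$beta_lac <- fit0$beta_lac * 0
  eff0 <- bh_effects(fit0)
  expect_true(all(eff0$effect == 0))
  # single-PC basis: effects proportional to the scaled eigenvector
  f1 <- c(4, 1)
  Vw1 <- matrix(c(0.8, 0.6), 2, 1)
  expect_equal(
    bh_effects(f1, Vw1, 2),
    as.numeric(Vw1 / sqrt(f1) * 2)
  )
  # planted classes: BH carrying allele 1 should show larger effects
  expect_gt(fit$tests$minus_log10_p[2], 4)
  bh_true <- m$bh[, j]
  cls <- eff[match(rownames(m$bh), eff$bh), ]
  keep <- !is.na(bh_true) & cls$f >= 5 & cls$breed == "S"
  expect_gt(sum(keep), 3)
  split_eff <- split(cls$effect[keep], bh_true[keep])
  if (length(split_eff) == 2) {
    expect_gt(
      mean(split_eff[["1"]]) * sign(s$qtl$effect),
      mean(split_eff[["0"]]) * sign(s$qtl$effect)
    )
    # classification by the midpoint separates >= 90% of well-replicated BH
    mid <- (mean(split_eff[["1"]]) + mean(split_eff[["0"]])) / 2
    lab <- as.integer(cls$effect[keep] > mid)
    expect_gte(mean(lab == bh_true[keep]), 0.9)
  }
})
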