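test_that("pedigree structure follows the family parameters", {
  ped <- simulate_pedigree(2, 3, 1, seed = 1)
  expect_equal(sum(ped$sex == "M"), 2)
  expect_equal(sum(ped$phenotyped), 6)
  expect_equal(sum(!ped$genotyped), 6) # founder dams, one per ewe

  big <- simulate_pedigree(161, 23, 1, seed = 7)
  expect_equal(sum(big$phenotyped), 161 * 23)
  expect_equal(length(unique(big$sire[big$phenotyped])), 161)

  # generation-2 ewes must have genotyped dams drawn from generation 1,
  # and every parent must precede its offspring (traversal oracle)
  ped2 <- simulate_pedigree(10, 5, 2, seed = 3)
  gen2 <- ped2[ped2$generation == 2 & ped2$sex == "F", ]
  dam_rows <- match(gen2$dam, ped2$id)
  expect_true(all(ped2$genotyped[dam_rows]))
  expect_true(all(ped2$generation[dam_rows] == 1))
  for (k in which(!is.na(ped2$sire))) {
    expect_lt(match(ped2$sire[k], ped2$id), k)
    expect_lt(match(ped2$dam[k], ped2$id), k)
  }
})

test_that("pedigree parameters are validated", {
  expect_error(simulate_pedigree(0, 3, 1), "must all be >= 1")
  expect_error(simulate_pedigree(2, 3, 0), "must all be >= 1")
})

test_that("base gametes follow the per-SNP frequency model", {
  map <- sim_map(10, 1, 10, seed = 1)
  b <- simulate_base_gametes(4, 0, map, maf_range = c(0.5, 0.5), seed = 1)
  expect_equal(dim(b$alleles), c(4L, 10L))
  # per-SNP counts are Binomial(4, 0.5): mean allele frequency near 0.5
  expect_gt(mean(b$alleles), 0.3)
  expect_lt(mean(b$alleles), 0.7)

  b2 <- simulate_base_gametes(2, 2, map, maf_range = c(0.1, 0.4), seed = 2)
  expect_equal(b2$breed, c("S", "S", "L", "L"))

  # Monte-Carlo check of the frequency draw: mean MAF of U(0.05, 0.5) draws
  big_map <- sim_map(1000, 1, 100, seed = 2)
  b3 <- simulate_base_gametes(50, 10, big_map,
    maf_range = c(0.05, 0.5),
    seed = 9
  )
  p <- colMeans(b3$alleles[b3$breed == "S", ])
  expect_gt(mean(pmin(p, 1 - p)), 0.2)
  expect_lt(mean(pmin(p, 1 - p)), 0.35)

  expect_error(
    simulate_base_gametes(2, 2, map[0, ], maf_range = c(0.1, 0.4)),
    "empty map"
  )
  expect_error(
    simulate_base_gametes(2, 2, map, maf_range = c(0, 0.5)),
    "maf_range"
  )
})

test_that("gamete dropping is Mendelian and tracks crossovers", {
  s <- sim_small()
  gam <- s$gametes
  ped <- s$pedigree
  geno_ids <- rownames(gam$pat)
  for (k in seq_along(geno_ids)) {
    row <- ped[ped$id == geno_ids[k], ]
    sire <- row$sire
    if (!is.na(sire) && sire %in% geno_ids) {
      child <- gam$pat[k, ]
      ok <- child == gam$pat[sire, ] | child == gam$mat[sire, ]
      expect_true(all(ok))
      # origin track switches exactly at the recorded crossovers
      org <- gam$origin_pat[k, ]
      xo <- gam$crossovers[gam$crossovers$id == geno_ids[k] &
        gam$crossovers$side == "pat", ]
      for (cc in unique(s$map$chrom)) {
        sel <- s$map$chrom == cc
        n_switch <- sum(diff(org[sel]) != 0)
        # crossovers between the same pair of SNPs cancel; switches can be
        # fewer but never more numerous than crossovers on the chromosome
        expect_lte(n_switch, sum(xo$chrom == cc))
      }
    }
  }
})

test_that("a zero-length chromosome never recombines", {
  map1 <- tibble::tibble(
    snp_id = "only", chrom = 1L, pos_bp = 5L, pos_cm = 5e-6
  )
  ped <- simulate_pedigree(1, 4, 1, seed = 2)
  base <- simulate_base_gametes(n_base_needed(ped)[["S"]], 0, map1, seed = 3)
  gam <- drop_gametes(ped, base, map1, seed = 4)
  for (e in ped$id[ped$phenotyped]) {
    expect_true(gam$pat[e, 1] %in% c(gam$pat["S1", 1], gam$mat["S1", 1]))
  }
})

test_that("crossover counts are Poisson with mean = length in Morgan", {
  # one sire, many meioses over a 100 cM chromosome
  ped <- simulate_pedigree(1, 2000, 1, seed = 5)
  map <- sim_map(50, 1, 100, seed = 5)
  # stretch to exactly 100 cM endpoints for a clean expected length
  map$pos_cm[1] <- 0
  map$pos_cm[nrow(map)] <- 100
  base <- simulate_base_gametes(n_base_needed(ped)[["S"]], 0, map, seed = 5)
  gam <- drop_gametes(ped, base, map, seed = 5)
  counts <- table(factor(gam$crossovers$id,
    levels = ped$id[ped$phenotyped]
  ))
  lambda <- 1 # 100 cM = 1 Morgan
  expect_lt(abs(mean(counts) - lambda), 0.08)
  # chi-square goodness of fit against Poisson(1), bins 0..4+
  obs <- table(factor(pmin(as.integer(counts), 4L), levels = 0:4))
  pr <- c(dpois(0:3, lambda), ppois(3, lambda, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("phenotypes follow the repeatability model", {
  s <- sim_small()
  # noiseless case: APD equals the summed gamete effects
  ph0 <- simulate_phenotypes(s$gametes, s$qtl, 0, 0, 3, seed = 1)
  expect_equal(ph0$y, ph0$true_qtl)
  expect_equal(ph0$r, rep(0, nrow(ph0)))

  # balanced closed-form reliability
  ph1 <- simulate_phenotypes(s$gametes, s$qtl[0, ], 1, 1, 4, seed = 2)
  expect_equal(unique(ph1$r), 0.8)

  # APD variance is var_a + var_e / n (Monte-Carlo, bigger population)
  ped <- simulate_pedigree(5, 400, 1, seed = 6)
  map <- sim_map(20, 1, 10, seed = 6)
  base <- simulate_base_gametes(n_base_needed(ped)[["S"]], 0, map, seed = 6)
  gam <- drop_gametes(ped, base, map, seed = 6)
  ph2 <- simulate_phenotypes(
    gam, tibble::tibble(snp_id = character(), effect = numeric()),
    1, 1, 4,
    seed = 7
  )
  expect_lt(abs(var(ph2$y) - 1.25), 0.1)

  # with no QTL the APD is uncorrelated with any SNP dosage
  idx <- match(ph2$id, rownames(gam$pat))
  cors <- vapply(seq_len(nrow(map)), function(j) {
    cor(ph2$y, gam$pat[idx, j] + gam$mat[idx, j])
  }, 0)
  expect_lt(max(abs(cors), na.rm = TRUE), 4 / sqrt(nrow(ph2)))

  expect_error(
    simulate_phenotypes(
      gam, tibble::tibble(snp_id = "nope", effect = 1), 1, 1, 4
    ),
    "not on map"
  )
})

test_that("qtl_effect_for_variance hits the target variance fraction", {
  a <- qtl_effect_for_variance(0.1, 0.3, 0.3, 0.7, 4)
  base_var <- 0.3 + 0.7 / 4
  var_qtl <- 2 * 0.3 * 0.7 * a^2
  expect_equal(var_qtl / (var_qtl + base_var), 0.1, tolerance = 1e-10)
  expect_equal(qtl_effect_for_variance(0, 0.3, 1, 1, 4), 0)
})
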