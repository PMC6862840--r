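test_that("origin probabilities interpolate by the flanking rule", {
  p1 <- ldlapca:::origin1_probability
  # flanks agreeing at origin 1, symmetric distances
  r <- ldlapca:::haldane_r(10)
  expect_equal(
    p1(50, c(40, 60), c(1L, 1L)),
    (1 - r)^2 / ((1 - r)^2 + r^2)
  )
  # equidistant flanks with opposite origins -> 0.5/0.5
  expect_equal(p1(50, c(40, 60), c(1L, 2L)), 0.5)
  # single flank -> 1 - r
  expect_equal(p1(50, 40, 1L), 1 - r)
  expect_equal(p1(50, 40, 2L), r)
  # no information -> 0.5
  expect_equal(p1(c(1, 2), numeric(0), integer(0)), c(0.5, 0.5))
  # informative position itself -> certainty
  expect_equal(p1(40, c(40, 60), c(1L, 2L)), 1)
})

test_that("descent matrices are row-stochastic and conserve replicates", {
  s <- sim_small()
  m <- model_small()
  tr <- m$trans
  n_rh <- attr(m$classes, "n_rh")
  for (l in c(1, 57, 150)) {
    Hf <- transmission_matrix(tr, l)
    expect_true(all(Hf$H >= 0 & Hf$H <= 1))
    expect_equal(rowSums(Hf$H), rep(1, n_rh), tolerance = 1e-12,
      ignore_attr = TRUE)
    expect_equal(sum(Hf$f), n_rh, tolerance = 1e-9)
  }
  # dense markers: descent of each ewe gamete is traced almost certainly
  la <- genome_average_la(tr)
  maxes <- vapply(
    c(10, 50, 120), function(l) mean(apply(transmission_matrix(tr, l)$H, 1, max)),
    0
  )
  expect_gte(mean(maxes), 0.95)
  expect_equal(sum(la$f_g), n_rh, tolerance = 1e-9)
})

test_that("certain transmissions give unit H rows", {
  s <- sim_small()
  m <- model_small()
  # a generation-1 ewe's paternal gamete descends from its sire's two BH;
  # at a sire-heterozygous phased SNP with known child allele the origin is
  # certain, so the row is a unit vector
  tr <- m$trans
  me <- tr$meioses
  k <- which(me$side == "pat" & me$parent %in% c("S3", "S4"))[1]
  certain <- which(tr$origin1[k, ] %in% c(0, 1))
  expect_gt(length(certain), 0)
  Hf <- transmission_matrix(tr, certain[1])
  row <- Hf$H[match(me$gamete_id[k], rownames(Hf$H)), ]
  expect_equal(max(row), 1, tolerance = 1e-12)
  expect_equal(sum(row > 0), 1)
})

test_that("windowed IBD has the correct limits and structure", {
  s <- sim_small()
  m <- model_small()
  bh <- m$bh
  l <- 30
  U <- ld_ibd_locus(bh, l, m$map, breed = m$breed, prior = m$prior)
  expect_equal(U, t(U))
  expect_equal(diag(U), rep(1, nrow(U)), ignore_attr = TRUE)
  expect_true(all(U >= 0 & U <= 1))
  # cross-breed entries exactly zero
  expect_true(all(U[m$breed == "S", m$breed == "L"] == 0))

  # two identical haplotypes over the whole window
  A <- rbind(bh, bh[3, ])
  attr(A, "breed") <- c(m$breed, "S")
  U2 <- ld_ibd_locus(A, l, m$map, breed = attr(A, "breed"), prior = m$prior)
  expect_gte(U2[3, nrow(A)], 0.95)

  # haplotypes differing at the focal SNP get exactly zero
  dif <- which(bh[1, ] != bh[2, ] & !is.na(bh[1, ]) & !is.na(bh[2, ]))
  U3 <- ld_ibd_locus(bh, dif[1], m$map, breed = m$breed, prior = m$prior)
  expect_identical(U3[1, 2], 0)

  # trimodal distribution: exact zeros outnumber intermediate values
  ss <- which(m$breed == "S")
  off <- U[ss, ss][upper.tri(diag(length(ss)))]
  expect_gt(mean(off == 0), mean(off > 0.45 & off < 0.55))

  expect_error(ld_ibd_locus(bh, l, m$map, window = 20), "odd")
  expect_error(ld_ibd_locus(bh, 10^6, m$map), "range")
  expect_warning(
    ld_ibd_locus(bh[m$breed == "S", , drop = FALSE][1:3, ], 5, m$map,
      breed = c("S", "S", "L"), prior = 0.1
    ),
    "fewer than 2"
  )
})

test_that("a planted literal copy of a base gamete is recovered as IBD", {
  m <- model_small()
  twin <- rbind(m$bh[m$breed == "S", ][1:10, ], m$bh[m$breed == "S", ][1, ])
  interior <- seq(15, nrow(m$map) - 15, by = 12)
  ok <- vapply(interior, function(l) {
    U <- ld_ibd_locus(twin, l, m$map,
      breed = rep("S", nrow(twin)),
      prior = 0.1
    )
    U[1, nrow(twin)]
  }, 0)
  expect_true(all(ok >= 0.95))
})

test_that("genome averages preserve the per-locus structure", {
  # single locus: averages equal the locus matrices
  H1 <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  avg1 <- genome_average(H = list(H1), f = list(colSums(H1)))
  expect_equal(avg1$H_g, H1)
  # two loci with opposite certain descent average to 0.5
  H2 <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  avg2 <- genome_average(H = list(H1, H2))
  expect_equal(avg2$H_g, matrix(0.5, 2, 2))
  expect_error(genome_average(H = list()), "empty")

  # full simulated genome: replicate conservation survives averaging
  m <- model_small()
  expect_equal(sum(m$f_g), attr(m$classes, "n_rh"), tolerance = 1e-8)
  expect_equal(m$U_g, t(m$U_g))
  expect_equal(diag(m$U_g), rep(1, nrow(m$U_g)), ignore_attr = TRUE)
})

test_that("certain 0/1 descent implies F_l = H_l' H_l", {
  H <- random_unit_row_h(40, 12, seed = 8)
  f <- colSums(H)
  expect_equal(crossprod(H), diag(f), ignore_attr = TRUE)
})
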