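#' Build a SNP map
#'
#' Generates a genetic map of biallelic SNPs spread uniformly at random over a
#' set of chromosomes. Map positions follow the 1 Mb = 1 cM assumption used
#' throughout the package.
#'
#' @param n_snps Total number of SNPs over all chromosomes.
#' @param n_chr Number of chromosomes.
#' @param chr_length_mb Chromosome length in Mb (recycled over chromosomes).
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return A tibble with columns `snp_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   sorted by (`chrom`, `pos_bp`), strictly increasing within chromosome.
#' @export
sim_map <- function(n_snps, n_chr = 1, chr_length_mb = 100, seed = 1) {
  stopifnot(n_snps >= n_chr, n_chr >= 1, all(chr_length_mb > 0))
  set.seed(seed)
  len <- rep_len(chr_length_mb, n_chr)
  per <- rep(n_snps %/% n_chr, n_chr)
  extra <- n_snps - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  purrr::map_dfr(seq_len(n_chr), function(cc) {
    bp <- sort(sample.int(len[cc] * 1e6, per[cc]))
    tibble::tibble(
      snp_id = sprintf("snp%d_%d", cc, seq_len(per[cc])),
      chrom = cc,
      pos_bp = bp,
      pos_cm = bp / 1e6
    )
  })
}

#' Simulate a sire-family pedigree
#'
#' Builds a half-sib family structure resembling a dairy-sheep resource
#' population: genotyped sires (optionally including F1 sires carrying a
#' paternal gamete of the second breed), generation-1 ewes out of distinct
#' ungenotyped founder dams, and later generations whose dams are sampled from
#' the ewes of the previous generation (avoiding sire-daughter matings).
#'
#' @param n_sires Number of genotyped sires.
#' @param daughters_per_sire Daughters per sire per generation.
#' @param n_generations Number of ewe generations (>= 1).
#' @param seed Integer seed.
#' @param n_f1_sires Number of sires whose (ungenotyped) father is of the
#'   second breed ("L"); their paternal gamete is a base haplotype of that
#'   breed. Default 0.
#' @return A tibble with one row per individual: `id`, `sire`, `dam` (NA for
#'   unknown), `sex`, `generation`, `genotyped`, `phenotyped`, `sire_breed`,
#'   `dam_breed` (breed of the paternal / maternal parental line). Parents
#'   always precede their offspring.
#' @export
simulate_pedigree <- function(n_sires, daughters_per_sire, n_generations,
                              seed = 1, n_f1_sires = 0) {
  if (n_sires < 1 || daughters_per_sire < 1 || n_generations < 1) {
    stop("n_sires, daughters_per_sire and n_generations must all be >= 1")
  }
  stopifnot(n_f1_sires <= n_sires)
  set.seed(seed)
  sires <- tibble::tibble(
    id = sprintf("S%d", seq_len(n_sires)),
    sire = NA_character_, dam = NA_character_,
    sex = "M", generation = 0L, genotyped = TRUE, phenotyped = FALSE,
    sire_breed = c(rep("L", n_f1_sires), rep("S", n_sires - n_f1_sires)),
    dam_breed = "S"
  )
  ped <- sires
  prev_ewes <- NULL
  dam_counter <- 0L
  ewe_counter <- 0L
  for (g in seq_len(n_generations)) {
    rows <- purrr::map_dfr(seq_len(n_sires), function(s) {
      sire_id <- sires$id[s]
      n <- daughters_per_sire
      if (g == 1L || is.null(prev_ewes)) {
        dams <- sprintf("D%d", dam_counter + (s - 1L) * n + seq_len(n))
        dam_geno <- FALSE
      } else {
        pool <- prev_ewes$id[prev_ewes$sire != sire_id]
        if (length(pool) < 1) pool <- prev_ewes$id
        dams <- sample(pool, n, replace = length(pool) < n)
        dam_geno <- TRUE
      }
      tibble::tibble(
        id = sprintf("E%d", ewe_counter + (s - 1L) * n + seq_len(n)),
        sire = sire_id, dam = dams,
        sex = "F", generation = g, genotyped = TRUE, phenotyped = TRUE,
        sire_breed = "S", dam_breed = "S", dam_genotyped = dam_geno
      )
    })
    if (g == 1L) {
      founder_dams <- tibble::tibble(
        id = unique(rows$dam), sire = NA_character_, dam = NA_character_,
        sex = "F", generation = 0L, genotyped = FALSE, phenotyped = FALSE,
        sire_breed = "S", dam_breed = "S"
      )
      dam_counter <- dam_counter + nrow(founder_dams)
      ped <- dplyr::bind_rows(ped, founder_dams)
    }
    ewe_counter <- ewe_counter + nrow(rows)
    rows$dam_genotyped <- NULL
    ped <- dplyr::bind_rows(ped, rows)
    prev_ewes <- rows
  }
  ped
}

#' Simulate base gametes
#'
#' Draws the founder (base) haplotypes of the two breed pools. Per-SNP allele
#' frequencies are drawn uniformly within `maf_range`, independently for the
#' two breeds, so that cross-breed LD-based IBD is essentially zero. With
#' `n_ancestral_*` set, base gametes are sampled as mutated copies of a small
#' pool of ancestral haplotypes, reproducing the strongly related base-gamete
#' structure of a real population (trimodal IBD, compressible PC space);
#' with the default (`NULL`) every gamete is drawn independently per SNP.
#'
#' @param n_bh_s,n_bh_l Number of base haplotypes of breed "S" and "L".
#' @param map Map tibble from [sim_map()].
#' @param maf_range Length-2 numeric in (0, 0.5].
#' @param seed Integer seed.
#' @param n_ancestral_s,n_ancestral_l Optional size of the ancestral haplotype
#'   pool per breed; `NULL` means independent sampling per gamete.
#' @param mutation_rate Per-SNP flip probability when copying an ancestral
#'   haplotype.
#' @param segment_cm Mean length (cM) of the ancestral mosaic segments: each
#'   base gamete is a recombinant mosaic of the ancestral pool with junctions
#'   from a Poisson process of rate `1/segment_cm`, emulating historical
#'   recombination so that local ancestry varies along the genome while the
#'   genome-average IBD between two base gametes stays moderate
#'   (about `1/n_ancestral`).
#' @return A list of class `ldla_base` with elements `alleles` (0/1 matrix,
#'   one row per base gamete), `breed` (character vector "S"/"L"), `freq`
#'   (list of per-breed allele-1 frequency vectors used for sampling) and
#'   `ancestor` (per-gamete x per-SNP ancestral index matrix, NULL under
#'   independent sampling).
#' @export
simulate_base_gametes <- function(n_bh_s, n_bh_l, map, maf_range = c(0.05, 0.5),
                                  seed = 1, n_ancestral_s = NULL,
                                  n_ancestral_l = NULL, mutation_rate = 0.01,
                                  segment_cm = 25) {
  if (nrow(map) < 1) stop("empty map")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5)) {
    stop("maf_range must lie in (0, 0.5]")
  }
  set.seed(seed)
  m <- nrow(map)
  draw_pool <- function(n, n_anc) {
    p <- runif(m, maf_range[1], maf_range[2])
    # allele 1 is the minor allele by construction of the frequency draw
    if (n == 0) {
      return(list(A = matrix(integer(0), 0, m), p = p, anc = NULL))
    }
    if (is.null(n_anc)) {
      A <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
      anc <- NULL
    } else {
      anc_pool <- matrix(rbinom(n_anc * m, 1L, rep(p, each = n_anc)), n_anc, m)
      anc <- matrix(NA_integer_, n, m)
      for (k in seq_len(n)) {
        for (cc in unique(map$chrom)) {
          idx <- which(map$chrom == cc)
          cm <- map$pos_cm[idx]
          len <- max(cm) - min(cm)
          n_j <- rpois(1, len / segment_cm)
          jn <- if (n_j > 0) sort(runif(n_j, min(cm), max(cm))) else numeric(0)
          seg <- findInterval(cm, jn) + 1L
          anc_seg <- sample.int(n_anc, n_j + 1L, replace = TRUE)
          anc[k, idx] <- anc_seg[seg]
        }
      }
      A <- matrix(anc_pool[cbind(as.vector(anc), rep(seq_len(m), each = n))],
        n, m
      )
      flips <- matrix(rbinom(n * m, 1L, mutation_rate), n, m)
      A <- abs(A - flips)
    }
    list(A = A, p = p, anc = anc)
  }
  s <- draw_pool(n_bh_s, n_ancestral_s)
  l <- draw_pool(n_bh_l, n_ancestral_l)
  alleles <- rbind(s$A, l$A)
  rownames(alleles) <- c(
    if (n_bh_s) sprintf("BHS%d", seq_len(n_bh_s)),
    if (n_bh_l) sprintf("BHL%d", seq_len(n_bh_l))
  )
  structure(
    list(
      alleles = alleles,
      breed = c(rep("S", n_bh_s), rep("L", n_bh_l)),
      freq = list(S = s$p, L = l$p),
      ancestor = if (!is.null(s$anc) || !is.null(l$anc)) {
        rbind(s$anc, l$anc)
      } else {
        NULL
      },
      map = map
    ),
    class = "ldla_base"
  )
}

haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# One meiosis under the Haldane model: crossovers are a Poisson process along
# the chromosome (1 cM = 1% recombination, no interference).
meiosis_gamete <- function(hap1, hap2, pos_cm, chrom) {
  n <- length(hap1)
  out <- integer(n)
  origin <- integer(n)
  xo_all <- list()
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    cm <- pos_cm[idx]
    len <- max(cm) - min(cm)
    n_x <- rpois(1, len / 100)
    xo <- if (n_x > 0) sort(runif(n_x, min(cm), max(cm))) else numeric(0)
    start <- sample.int(2L, 1L)
    seg <- findInterval(cm, xo)  # number of crossovers to the left
    org <- 1L + (start - 1L + seg) %% 2L
    origin[idx] <- org
    out[idx] <- ifelse(org == 1L, hap1[idx], hap2[idx])
    if (n_x > 0) xo_all[[as.character(cc)]] <- xo
  }
  list(alleles = out, origin = origin, crossovers = xo_all)
}

#' Drop base gametes through the pedigree
#'
#' Assigns base haplotypes to every gamete inherited from an ungenotyped (or
#' unknown) parent, and simulates every other gamete as a recombinant meiosis
#' of the transmitting parent's two gametes. Crossovers follow a Poisson
#' process with intensity 1 per Morgan (Haldane, no interference); the
#' realized grandparental-origin track of every meiosis is stored as ground
#' truth.
#'
#' @param pedigree Tibble from [simulate_pedigree()].
#' @param base_gametes `ldla_base` object from [simulate_base_gametes()]. The
#'   per-breed pools must be at least as large as the number of base-haplotype
#'   slots in the pedigree (see [n_base_needed()]).
#' @param map Map tibble.
#' @param seed Integer seed.
#' @return A list of class `ldla_gametes` with allele matrices `pat`/`mat`
#'   (rows = genotyped individuals), origin tracks `origin_pat`/`origin_mat`
#'   (1 = transmitting parent's paternal gamete, 2 = maternal, NA for base
#'   gametes), base-pool indices `bh_pat`/`bh_mat`, a `crossovers` tibble, and
#'   the inputs (`base`, `map`, `pedigree`).
#' @export
drop_gametes <- function(pedigree, base_gametes, map, seed = 1) {
  set.seed(seed)
  need <- n_base_needed(pedigree)
  have <- table(factor(base_gametes$breed, levels = c("S", "L")))
  if (need[["S"]] > have[["S"]] || need[["L"]] > have[["L"]]) {
    stop(sprintf(
      "base gamete pool too small: need %d S and %d L, have %d S and %d L",
      need[["S"]], need[["L"]], have[["S"]], have[["L"]]
    ))
  }
  geno_ids <- pedigree$id[pedigree$genotyped]
  m <- nrow(map)
  n <- length(geno_ids)
  pat <- mat <- matrix(NA_integer_, n, m, dimnames = list(geno_ids, NULL))
  origin_pat <- origin_mat <- matrix(NA_integer_, n, m,
    dimnames = list(geno_ids, NULL)
  )
  bh_pat <- bh_mat <- rep(NA_integer_, n)
  names(bh_pat) <- names(bh_mat) <- geno_ids
  next_free <- list(
    S = which(base_gametes$breed == "S"),
    L = which(base_gametes$breed == "L")
  )
  take_base <- function(breed) {
    i <- next_free[[breed]][1]
    next_free[[breed]] <<- next_free[[breed]][-1]
    i
  }
  xo_rec <- list()
  ped_geno <- pedigree[pedigree$genotyped, ]
  geno_set <- stats::setNames(rep(TRUE, n), geno_ids)
  for (k in seq_len(n)) {
    ind <- ped_geno[k, ]
    for (side in c("pat", "mat")) {
      parent <- if (side == "pat") ind$sire else ind$dam
      breed <- if (side == "pat") ind$sire_breed else ind$dam_breed
      parent_geno <- !is.na(parent) && isTRUE(geno_set[parent])
      if (!parent_geno) {
        b <- take_base(breed)
        seqs <- base_gametes$alleles[b, ]
        if (side == "pat") {
          pat[k, ] <- seqs; bh_pat[k] <- b
        } else {
          mat[k, ] <- seqs; bh_mat[k] <- b
        }
      } else {
        g <- meiosis_gamete(pat[parent, ], mat[parent, ], map$pos_cm, map$chrom)
        if (side == "pat") {
          pat[k, ] <- g$alleles; origin_pat[k, ] <- g$origin
        } else {
          mat[k, ] <- g$alleles; origin_mat[k, ] <- g$origin
        }
        if (length(g$crossovers)) {
          xo_rec[[length(xo_rec) + 1L]] <- tibble::tibble(
            id = ind$id, side = side,
            chrom = as.integer(rep(names(g$crossovers),
              vapply(g$crossovers, length, 1L)
            )),
            pos_cm = unlist(g$crossovers, use.names = FALSE)
          )
        }
      }
    }
  }
  crossovers <- if (length(xo_rec)) {
    dplyr::bind_rows(xo_rec)
  } else {
    tibble::tibble(
      id = character(), side = character(),
      chrom = integer(), pos_cm = numeric()
    )
  }
  structure(
    list(
      pat = pat, mat = mat,
      origin_pat = origin_pat, origin_mat = origin_mat,
      bh_pat = bh_pat, bh_mat = bh_mat,
      crossovers = crossovers,
      base = base_gametes, map = map, pedigree = pedigree
    ),
    class = "ldla_gametes"
  )
}

#' Count base-haplotype slots in a pedigree
#'
#' @param pedigree Pedigree tibble.
#' @return Named integer vector with the number of base gametes of each breed
#'   required to populate the pedigree's founder gamete slots.
#' @export
n_base_needed <- function(pedigree) {
  geno <- pedigree[pedigree$genotyped, ]
  is_geno <- function(p) !is.na(p) & p %in% pedigree$id[pedigree$genotyped]
  pat_base <- !is_geno(geno$sire)
  mat_base <- !is_geno(geno$dam)
  breeds <- c(geno$sire_breed[pat_base], geno$dam_breed[mat_base])
  c(S = sum(breeds == "S"), L = sum(breeds == "L"))
}

#' Genotypes of the simulated individuals
#'
#' @param gametes `ldla_gametes` object.
#' @return Integer matrix (individuals x SNPs) of allele-1 counts 0/1/2.
#' @export
genotype_matrix <- function(gametes) {
  g <- gametes$pat + gametes$mat
  storage.mode(g) <- "integer"
  g
}

#' Inject missing genotypes
#'
#' @param genotypes 0/1/2 integer matrix.
#' @param rate Per-call missingness probability.
#' @param seed Integer seed.
#' @return The matrix with entries set to NA at random.
#' @export
inject_missing <- function(genotypes, rate = 0, seed = 1) {
  if (rate <= 0) return(genotypes)
  set.seed(seed)
  drop <- matrix(runif(length(genotypes)) < rate, nrow(genotypes))
  genotypes[drop] <- NA_integer_
  genotypes
}

#' QTL allele effect for a target variance fraction
#'
#' Converts a desired fraction of the phenotypic variance of the average
#' performance deviation (APD) into an additive per-allele-copy effect at a
#' SNP, given the allele-1 frequency `p` among the base gametes:
#' `var_qtl = 2 p (1 - p) a^2` under Hardy-Weinberg, and the APD phenotypic
#' variance is `var_qtl + var_polygenic + var_error / n_records`.
#'
#' @param frac Fraction of phenotypic variance explained by the QTL.
#' @param p Allele-1 frequency at the QTL SNP.
#' @param var_polygenic,var_error Variance components of the repeatability
#'   model.
#' @param n_records Records per ewe.
#' @return The additive allele substitution effect `a`.
#' @export
qtl_effect_for_variance <- function(frac, p, var_polygenic, var_error,
                                    n_records) {
  stopifnot(frac >= 0, frac < 1, p > 0, p < 1)
  if (frac == 0) return(0)
  base_var <- var_polygenic + var_error / n_records
  var_qtl <- frac / (1 - frac) * base_var
  sqrt(var_qtl / (2 * p * (1 - p)))
}

#' Simulate repeatability phenotypes and their APD
#'
#' Each phenotyped ewe gets `records_per_ewe` repeated records
#' `y_ij = q_i + a_i + e_ij`, where `q_i` is the summed additive QTL effect of
#' her two gametes, `a_i` the polygenic value and `e_ij ~ N(0, var_error)`.
#' The pseudo-phenotype is the average performance deviation
#' `APD_i = mean_j(y_ij)` with reliability from the balanced one-way
#' closed form `r = n var_a / (n var_a + var_e)`.
#'
#' @param gametes `ldla_gametes` object.
#' @param qtl_spec Tibble with columns `snp_id` and `effect` (additive effect
#'   per copy of allele 1); may have zero rows.
#' @param var_polygenic,var_error Variance components (>= 0).
#' @param records_per_ewe Number of repeated records (>= 1).
#' @param seed Integer seed.
#' @param polygenic_model `"iid"` draws `a_i ~ N(0, var_polygenic)`
#'   independently; `"genomic"` builds `a_i` as a sum of many small additive
#'   SNP effects over the ewe's two gametes, rescaled to variance
#'   `var_polygenic`, so that the polygene is heritable and trackable by
#'   genome-wide IBD.
#' @return Tibble (`id`, `y`, `n_records`, `r`, `true_qtl`,
#'   `true_polygenic`) with the per-record data in `attr(, "records")`.
#' @export
simulate_phenotypes <- function(gametes, qtl_spec, var_polygenic, var_error,
                                records_per_ewe, seed = 1,
                                polygenic_model = c("iid", "genomic")) {
  stopifnot(var_polygenic >= 0, var_error >= 0, records_per_ewe >= 1)
  polygenic_model <- match.arg(polygenic_model)
  set.seed(seed)
  ped <- gametes$pedigree
  ids <- ped$id[ped$phenotyped]
  idx <- match(ids, rownames(gametes$pat))
  n <- length(ids)
  qtl <- numeric(n)
  if (nrow(qtl_spec) > 0) {
    snp_idx <- match(qtl_spec$snp_id, gametes$map$snp_id)
    if (anyNA(snp_idx)) stop("QTL SNP not on map")
    for (j in seq_along(snp_idx)) {
      dose <- gametes$pat[idx, snp_idx[j]] + gametes$mat[idx, snp_idx[j]]
      qtl <- qtl + qtl_spec$effect[j] * unname(dose)
    }
  }
  if (var_polygenic == 0) {
    a <- numeric(n)
  } else if (polygenic_model == "iid") {
    a <- rnorm(n, 0, sqrt(var_polygenic))
  } else {
    m <- ncol(gametes$pat)
    eff <- rnorm(m)
    raw <- as.numeric((gametes$pat[idx, , drop = FALSE] +
      gametes$mat[idx, , drop = FALSE]) %*% eff)
    s <- sd(raw)
    a <- if (s > 0) (raw - mean(raw)) / s * sqrt(var_polygenic) else numeric(n)
  }
  e <- matrix(rnorm(n * records_per_ewe, 0, sqrt(var_error)),
    n, records_per_ewe
  )
  records <- qtl + a + e
  apd <- rowMeans(records)
  rel <- records_per_ewe * var_polygenic /
    (records_per_ewe * var_polygenic + var_error)
  if (var_polygenic == 0 && var_error == 0) rel <- 0
  out <- tibble::tibble(
    id = ids, y = apd, n_records = records_per_ewe,
    r = rel, true_qtl = qtl, true_polygenic = a
  )
  attr(out, "records") <- tibble::tibble(
    id = rep(ids, records_per_ewe),
    record = rep(seq_len(records_per_ewe), each = n),
    value = as.numeric(records)
  )
  out
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulate_pedigree()], [sim_map()],
#' [simulate_base_gametes()], [drop_gametes()] and [simulate_phenotypes()]
#' with the package's default study conditions (half-sib families over two
#' generations, an ancestral-pool base-gamete structure, a repeatability
#' phenotype).
#'
#' @param n_sires,daughters_per_sire,n_generations Pedigree structure.
#' @param n_snps,n_chr,chr_length_mb Map structure.
#' @param qtl Tibble (`snp_id`, `effect`) or NULL; alternatively use
#'   `qtl_frac` plus `qtl_snp` to plant one QTL by variance fraction.
#' @param qtl_frac,qtl_snp Fraction of phenotypic variance and SNP id (or
#'   index) of a single planted QTL; ignored when `qtl` is given.
#' @param var_polygenic,var_error,records_per_ewe Phenotype parameters.
#' @param n_f1_sires F1 sires carrying a breed-"L" paternal base gamete.
#' @param n_ancestral_s,n_ancestral_l,maf_range,mutation_rate,segment_cm
#'   Base-gamete structure (see [simulate_base_gametes()]).
#' @param polygenic_model Passed to [simulate_phenotypes()].
#' @param seed Integer seed driving all stages.
#' @return List of class `ldla_sim` with `pedigree`, `map`, `base`, `gametes`,
#'   `genotypes`, `phenotypes`, `qtl`.
#' @export
sim_population <- function(n_sires = 10, daughters_per_sire = 40,
                           n_generations = 2, n_snps = 500, n_chr = 3,
                           chr_length_mb = 100, qtl = NULL, qtl_frac = 0,
                           qtl_snp = NULL, var_polygenic = 0.3,
                           var_error = 0.7, records_per_ewe = 4,
                           n_f1_sires = 2, n_ancestral_s = 8,
                           n_ancestral_l = 4, maf_range = c(0.05, 0.5),
                           mutation_rate = 0.005, segment_cm = 15,
                           polygenic_model = "iid", seed = 1) {
  ped <- simulate_pedigree(n_sires, daughters_per_sire, n_generations,
    seed = seed, n_f1_sires = n_f1_sires
  )
  map <- sim_map(n_snps, n_chr, chr_length_mb, seed = seed + 1L)
  need <- n_base_needed(ped)
  base <- simulate_base_gametes(need[["S"]], need[["L"]], map,
    maf_range = maf_range, seed = seed + 2L,
    n_ancestral_s = n_ancestral_s, n_ancestral_l = n_ancestral_l,
    mutation_rate = mutation_rate, segment_cm = segment_cm
  )
  gam <- drop_gametes(ped, base, map, seed = seed + 3L)
  if (is.null(qtl)) {
    if (qtl_frac > 0) {
      if (is.null(qtl_snp)) {
        # a common SNP near the first quarter of the genome, so the causal
        # variant survives MAF editing and segregates in the families
        pool_p <- colMeans(base$alleles)
        common <- which(pmin(pool_p, 1 - pool_p) >= 0.2)
        if (length(common) == 0) common <- seq_len(nrow(map))
        qtl_snp <- map$snp_id[common[which.min(abs(common - nrow(map) / 4))]]
      }
      if (is.numeric(qtl_snp)) qtl_snp <- map$snp_id[qtl_snp]
      j <- match(qtl_snp, map$snp_id)
      p <- mean(base$alleles[, j])
      p <- min(max(p, 0.05), 0.95)
      a <- qtl_effect_for_variance(
        qtl_frac, p, var_polygenic, var_error,
        records_per_ewe
      )
      qtl <- tibble::tibble(snp_id = qtl_snp, effect = a)
    } else {
      qtl <- tibble::tibble(snp_id = character(), effect = numeric())
    }
  }
  phen <- simulate_phenotypes(gam, qtl, var_polygenic, var_error,
    records_per_ewe,
    seed = seed + 4L, polygenic_model = polygenic_model
  )
  structure(
    list(
      pedigree = ped, map = map, base = base, gametes = gam,
      genotypes = genotype_matrix(gam), phenotypes = phen, qtl = qtl
    ),
    class = "ldla_sim"
  )
}
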