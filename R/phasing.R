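#' Classify gametes into base and replicated haplotypes
#'
#' A gamete (the whole haploid autosome set inherited from one parent) is a
#' base haplotype (BH) when the transmitting parent is ungenotyped or unknown,
#' and a replicated haplotype (RH) when the parent is genotyped. BH carry the
#' breed label of their parental line ("S" or "L"). The gametes carried by
#' the phenotyped ewes form the RH rows of the descent matrices; a ewe gamete
#' that is itself a BH is its own (certain) replicate.
#'
#' @param pedigree Pedigree tibble (see [simulate_pedigree()] for the schema).
#' @return A tibble of class `ldla_classes` with one row per gamete of every
#'   genotyped individual: `gamete_id`, `id`, `side` ("pat"/"mat"), `class`
#'   ("BH_S", "BH_L" or "RH"), `parent` (transmitting parent id, NA if
#'   unknown). Attributes: `bh` (BH gametes ordered with the S block first),
#'   `rh` (gametes of phenotyped individuals, paternal then maternal per ewe),
#'   `n_bh`, `n_rh`.
#' @export
classify_gametes <- function(pedigree) {
  geno <- pedigree[pedigree$genotyped, ]
  geno_ids <- geno$id
  is_geno <- function(p) !is.na(p) & p %in% geno_ids
  rows <- purrr::map_dfr(c("pat", "mat"), function(side) {
    parent <- if (side == "pat") geno$sire else geno$dam
    breed <- if (side == "pat") geno$sire_breed else geno$dam_breed
    tibble::tibble(
      gamete_id = paste0(geno$id, if (side == "pat") "_p" else "_m"),
      id = geno$id, side = side,
      class = ifelse(is_geno(parent), "RH", paste0("BH_", breed)),
      parent = parent
    )
  })
  # restore per-individual (pat, mat) interleaving in pedigree order
  rows <- rows[order(match(rows$id, geno_ids), rows$side == "mat"), ]
  bh <- rows[rows$class != "RH", ]
  bh <- bh[order(bh$class != "BH_S"), ]  # S block first, then L
  phen_ids <- pedigree$id[pedigree$phenotyped & pedigree$genotyped]
  rh <- rows[rows$id %in% phen_ids, ]
  rh <- rh[order(match(rh$id, phen_ids), rh$side == "mat"), ]
  out <- structure(rows,
    bh = bh, rh = rh,
    n_bh = nrow(bh), n_rh = nrow(rh),
    n_bh_s = sum(bh$class == "BH_S"), n_bh_l = sum(bh$class == "BH_L"),
    class = c("ldla_classes", class(rows))
  )
  out
}

#' SNP editing filters
#'
#' Applies the standard pre-phasing SNP edits: call rate and minor allele
#' frequency thresholds (defaults 95% and 1%).
#'
#' @param genotypes 0/1/2/NA integer matrix (individuals x SNPs).
#' @param map Map tibble aligned with the genotype columns.
#' @param call_rate Minimum fraction of non-missing calls per SNP.
#' @param maf Minimum minor allele frequency.
#' @return List with the filtered `genotypes` and `map`, and a `report`
#'   tibble (`snp_id`, `reason`) of removed SNPs.
#' @export
filter_snps <- function(genotypes, map, call_rate = 0.95, maf = 0.01) {
  stopifnot(ncol(genotypes) == nrow(map))
  cr <- colMeans(!is.na(genotypes))
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  mafv <- pmin(p, 1 - p)
  bad_cr <- cr < call_rate
  bad_maf <- !bad_cr & (is.na(mafv) | mafv < maf)
  report <- dplyr::bind_rows(
    tibble::tibble(snp_id = map$snp_id[bad_cr], reason = "call_rate"),
    tibble::tibble(snp_id = map$snp_id[bad_maf], reason = "maf")
  )
  keep <- !(bad_cr | bad_maf)
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    map = map[keep, , drop = FALSE],
    report = report
  )
}

# P(origin == 1) at every position of one chromosome, given informative
# positions with observed grandparental origins. Flanking-recombination rule:
# with both flanks, p1 = l1*r1 / (l1*r1 + (1-l1)*(1-r1)) where l1 (r1) is the
# probability of origin 1 implied by the left (right) flank under Haldane;
# a single flank gives 1 - r; no flank gives 0.5.
origin1_probability <- function(pos_cm, inf_pos_cm, inf_origin) {
  n <- length(pos_cm)
  if (length(inf_pos_cm) == 0) return(rep(0.5, n))
  o <- order(inf_pos_cm)
  ip <- inf_pos_cm[o]
  io <- inf_origin[o]
  li <- findInterval(pos_cm, ip)
  ri <- li + 1L
  has_l <- li >= 1L
  has_r <- ri <= length(ip)
  l1 <- rep(NA_real_, n)
  r1 <- rep(NA_real_, n)
  dl <- pos_cm - ifelse(has_l, ip[pmax(li, 1L)], NA_real_)
  dr <- ifelse(has_r, ip[pmin(ri, length(ip))], NA_real_) - pos_cm
  rl <- haldane_r(dl)
  rr <- haldane_r(dr)
  l1[has_l] <- ifelse(io[li[has_l]] == 1L, 1 - rl[has_l], rl[has_l])
  r1[has_r] <- ifelse(io[ri[has_r]] == 1L, 1 - rr[has_r], rr[has_r])
  p1 <- rep(0.5, n)
  both <- has_l & has_r
  num <- l1[both] * r1[both]
  den <- num + (1 - l1[both]) * (1 - r1[both])
  p1[both] <- ifelse(den < 1e-300, 0.5, num / den)
  only_l <- has_l & !has_r
  p1[only_l] <- l1[only_l]
  only_r <- !has_l & has_r
  p1[only_r] <- r1[only_r]
  p1
}

#' Phase the gametes of a family-structured population
#'
#' Deterministic family-based phasing of biallelic genotypes:
#' \enumerate{
#'   \item homozygous positions phase trivially;
#'   \item heterozygous positions phase by Mendelian exclusion against
#'     homozygous parent genotypes;
#'   \item heterozygous positions of parents with several genotyped offspring
#'     are phased by progeny majority vote with origin tracking along the
#'     chromosome;
#'   \item remaining heterozygous positions phase by the nearest flanking
#'     informative positions of the same parental meiosis, keeping the
#'     assignment only when its origin probability (flanking-recombination
#'     rule under Haldane, 1 Mb = 1 cM) reaches `certainty_threshold`.
#' }
#' Mendelian-inconsistent positions are set missing for the trio and counted;
#' an individual with more than `max_inconsistency` inconsistent SNPs is an
#' error. Individuals with both parents ungenotyped get arbitrary
#' paternal/maternal labels.
#'
#' @param genotypes 0/1/2/NA matrix, rownames = ids of genotyped individuals.
#' @param pedigree Pedigree tibble (parents precede offspring).
#' @param map Map tibble aligned with genotype columns.
#' @param certainty_threshold Minimum origin probability to keep a
#'   linkage-rule assignment (default 0.99).
#' @param max_inconsistency Maximum tolerated fraction of Mendelian
#'   inconsistencies per individual.
#' @param min_offspring Minimum number of genotyped offspring for
#'   progeny-based parent phasing.
#' @return List of class `ldla_phase`: allele matrices `pat` and `mat`
#'   (0/1/NA), `inconsistencies` tibble (`id`, `n`), per-SNP inconsistency
#'   counts `snp_inconsistencies`, and the share of phased entries in
#'   `stats`.
#' @export
phase_population <- function(genotypes, pedigree, map,
                             certainty_threshold = 0.99,
                             max_inconsistency = 0.05,
                             min_offspring = 2) {
  geno_ids <- pedigree$id[pedigree$genotyped]
  stopifnot(all(geno_ids %in% rownames(genotypes)))
  G <- genotypes[geno_ids, , drop = FALSE]
  n <- nrow(G)
  m <- ncol(G)
  stopifnot(m == nrow(map))
  pat <- mat <- matrix(NA_integer_, n, m, dimnames = list(geno_ids, NULL))
  bad_n <- stats::setNames(integer(n), geno_ids)
  snp_bad <- integer(m)
  ped_geno <- pedigree[pedigree$genotyped, ]
  sire_of <- stats::setNames(ped_geno$sire, ped_geno$id)
  dam_of <- stats::setNames(ped_geno$dam, ped_geno$id)
  has_geno <- function(p) !is.na(p) && p %in% geno_ids

  ## pass A: homozygous + Mendelian exclusion
  for (k in seq_len(n)) {
    g <- G[k, ]
    sg <- if (has_geno(sire_of[k])) G[sire_of[k], ] else rep(NA_integer_, m)
    dg <- if (has_geno(dam_of[k])) G[dam_of[k], ] else rep(NA_integer_, m)
    bad <- (!is.na(g) & !is.na(sg) & ((g == 0L & sg == 2L) | (g == 2L & sg == 0L))) |
      (!is.na(g) & !is.na(dg) & ((g == 0L & dg == 2L) | (g == 2L & dg == 0L))) |
      (!is.na(g) & g == 1L & !is.na(sg) & !is.na(dg) &
        sg %in% c(0L, 2L) & dg == sg)
    g[bad] <- NA_integer_
    hom0 <- !is.na(g) & g == 0L
    hom2 <- !is.na(g) & g == 2L
    pat[k, hom0] <- 0L; mat[k, hom0] <- 0L
    pat[k, hom2] <- 1L; mat[k, hom2] <- 1L
    het <- !is.na(g) & g == 1L
    sp <- het & !is.na(sg) & sg == 0L & !bad
    pat[k, sp] <- 0L; mat[k, sp] <- 1L
    sp <- het & !is.na(sg) & sg == 2L & !bad
    pat[k, sp] <- 1L; mat[k, sp] <- 0L
    un <- het & is.na(pat[k, ])
    dp <- un & !is.na(dg) & dg == 0L
    mat[k, dp] <- 0L; pat[k, dp] <- 1L
    dp <- un & !is.na(dg) & dg == 2L
    mat[k, dp] <- 1L; pat[k, dp] <- 0L
    bad_n[k] <- sum(bad)
    snp_bad[bad] <- snp_bad[bad] + 1L
    G[k, ] <- g
  }
  frac_bad <- bad_n / m
  if (any(frac_bad > max_inconsistency)) {
    stop(sprintf(
      "Mendelian inconsistency rate above %.0f%% for: %s",
      100 * max_inconsistency,
      paste(geno_ids[frac_bad > max_inconsistency], collapse = ", ")
    ))
  }

  ## pass B: progeny-based phasing of parents
  offspring_of <- split(
    rep(ped_geno$id, 2L),
    factor(c(ped_geno$sire, ped_geno$dam), levels = geno_ids)
  )
  for (p_id in geno_ids) {
    offs <- offspring_of[[p_id]]
    if (length(offs) < min_offspring) next
    pk <- match(p_id, geno_ids)
    ok <- match(offs, geno_ids)
    p_is_sire <- ped_geno$sire[ok] == p_id & !is.na(ped_geno$sire[ok])
    recv <- matrix(NA_integer_, length(offs), m)
    recv[p_is_sire, ] <- pat[ok[p_is_sire], , drop = FALSE]
    recv[!p_is_sire, ] <- mat[ok[!p_is_sire], , drop = FALSE]
    for (cc in unique(map$chrom)) {
      csel <- which(map$chrom == cc)
      hsites <- csel[!is.na(G[pk, csel]) & G[pk, csel] == 1L]
      if (length(hsites) == 0) next
      o <- rep(NA_integer_, length(offs))
      for (l in hsites) {
        obs <- recv[, l]
        known_phase <- !is.na(pat[pk, l]) && !is.na(mat[pk, l]) &&
          pat[pk, l] != mat[pk, l]
        if (known_phase) {
          upd <- !is.na(obs)
          o[upd] <- ifelse(obs[upd] == pat[pk, l], 1L, 2L)
        } else {
          kn <- !is.na(obs) & !is.na(o)
          if (any(kn)) {
            proposed <- ifelse(o[kn] == 1L, obs[kn], 1L - obs[kn])
            t1 <- sum(proposed == 1L)
            t0 <- sum(proposed == 0L)
            if (t1 == t0) next
            a <- as.integer(t1 > t0)
          } else if (all(is.na(o)) && any(!is.na(obs))) {
            a <- obs[which(!is.na(obs))[1]]  # arbitrary label seed
          } else {
            next
          }
          pat[pk, l] <- a
          mat[pk, l] <- 1L - a
          upd <- !is.na(obs)
          o[upd] <- ifelse(obs[upd] == a, 1L, 2L)
        }
      }
    }
  }

  ## pass C: linkage rule against phased parents, pedigree order
  for (k in seq_len(n)) {
    for (side in c("pat", "mat")) {
      p_id <- if (side == "pat") sire_of[k] else dam_of[k]
      if (!has_geno(p_id)) next
      pk <- match(p_id, geno_ids)
      child <- if (side == "pat") pat else mat
      other <- if (side == "pat") mat else pat
      ph <- !is.na(pat[pk, ]) & !is.na(mat[pk, ]) & pat[pk, ] != mat[pk, ]
      for (cc in unique(map$chrom)) {
        csel <- map$chrom == cc
        inf <- which(csel & ph & !is.na(child[k, ]))
        targ <- which(csel & ph & is.na(child[k, ]) & !is.na(G[k, ]) &
          G[k, ] == 1L)
        if (length(targ) == 0 || length(inf) == 0) next
        org <- ifelse(child[k, inf] == pat[pk, inf], 1L, 2L)
        p1 <- origin1_probability(map$pos_cm[targ], map$pos_cm[inf], org)
        keep <- pmax(p1, 1 - p1) >= certainty_threshold
        if (!any(keep)) next
        tk <- targ[keep]
        from_pat <- p1[keep] >= 0.5
        allele <- ifelse(from_pat, pat[pk, tk], mat[pk, tk])
        child[k, tk] <- allele
        other[k, tk] <- 1L - allele
      }
      if (side == "pat") {
        pat <- child; mat <- other
      } else {
        mat <- child; pat <- other
      }
    }
  }

  phased_share <- mean(!is.na(pat[!is.na(G)])) # among called genotypes
  structure(
    list(
      pat = pat, mat = mat, ids = geno_ids, map = map,
      inconsistencies = tibble::tibble(id = geno_ids, n = as.integer(bad_n)),
      snp_inconsistencies = snp_bad,
      stats = list(phased_share = phased_share)
    ),
    class = "ldla_phase"
  )
}

#' Base-haplotype allele matrix
#'
#' Extracts the phased allele sequences of the base haplotypes, in the BH
#' order of the classification (S block first).
#'
#' @param phase `ldla_phase` object (or an equivalent list with `pat`/`mat`
#'   matrices rownamed by individual).
#' @param classes `ldla_classes` object.
#' @return Integer matrix (n_BH x n_SNP, NA = unphased) with rownames the BH
#'   gamete ids and a `breed` attribute ("S"/"L" per row).
#' @export
bh_allele_matrix <- function(phase, classes) {
  bh <- attr(classes, "bh")
  out <- matrix(NA_integer_, nrow(bh), ncol(phase$pat),
    dimnames = list(bh$gamete_id, NULL)
  )
  for (k in seq_len(nrow(bh))) {
    src <- if (bh$side[k] == "pat") phase$pat else phase$mat
    out[k, ] <- src[bh$id[k], ]
  }
  attr(out, "breed") <- ifelse(bh$class == "BH_S", "S", "L")
  out
}

#' True gamete phases as a phase object
#'
#' Wraps the simulator's ground-truth gametes in the same shape as
#' [phase_population()] output, for oracle comparisons and for running the
#' downstream stages on perfectly known phases.
#'
#' @param gametes `ldla_gametes` object.
#' @return An `ldla_phase` object with no missing entries.
#' @export
true_phase <- function(gametes) {
  structure(
    list(
      pat = gametes$pat, mat = gametes$mat,
      ids = rownames(gametes$pat), map = gametes$map,
      inconsistencies = tibble::tibble(
        id = rownames(gametes$pat),
        n = 0L
      ),
      snp_inconsistencies = integer(ncol(gametes$pat)),
      stats = list(phased_share = 1)
    ),
    class = "ldla_phase"
  )
}

#' Phasing accuracy against simulation truth
#'
#' Compares phased alleles with the simulator's true gametes, allowing a
#' per-individual-per-chromosome label swap for individuals whose
#' paternal/maternal assignment is arbitrary (both parents ungenotyped).
#'
#' @param phase `ldla_phase` object.
#' @param gametes `ldla_gametes` truth.
#' @param pedigree Pedigree tibble.
#' @return A list with `accuracy` (share of phased alleles matching truth)
#'   and `yield` (share of called genotype entries phased).
#' @export
phase_accuracy <- function(phase, gametes, pedigree) {
  ids <- phase$ids
  map <- phase$map
  geno_ids <- pedigree$id[pedigree$genotyped]
  arbitrary <- vapply(ids, function(i) {
    row <- pedigree[pedigree$id == i, ]
    s_geno <- !is.na(row$sire) && row$sire %in% geno_ids
    d_geno <- !is.na(row$dam) && row$dam %in% geno_ids
    !s_geno && !d_geno
  }, logical(1))
  n_match <- 0; n_tot <- 0
  for (k in seq_along(ids)) {
    tp <- gametes$pat[ids[k], ]
    tm <- gametes$mat[ids[k], ]
    for (cc in unique(map$chrom)) {
      sel <- map$chrom == cc
      pp <- phase$pat[k, sel]; pm <- phase$mat[k, sel]
      ok <- !is.na(pp) & !is.na(pm)
      if (!any(ok)) next
      direct <- sum(pp[ok] == tp[sel][ok]) + sum(pm[ok] == tm[sel][ok])
      if (arbitrary[k]) {
        swapped <- sum(pp[ok] == tm[sel][ok]) + sum(pm[ok] == tp[sel][ok])
        direct <- max(direct, swapped)
      }
      n_match <- n_match + direct
      n_tot <- n_tot + 2 * sum(ok)
    }
  }
  list(
    accuracy = n_match / n_tot,
    yield = phase$stats$phased_share
  )
}
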