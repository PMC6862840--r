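#' Linkage-analysis transmission tracing
#'
#' Estimates, for every meiosis from a genotyped parent, the grandparental
#' origin of the transmitted gamete at every SNP. The origin is certain where
#' the parent is phased-heterozygous and the child's received allele is known;
#' elsewhere it is interpolated from the nearest informative flanking loci via
#' recombination fractions (Haldane, 1 Mb = 1 cM). Descent from base
#' haplotypes is later composed recursively down the pedigree by
#' [transmission_matrix()] (the gametic recursion of linkage analysis).
#'
#' @param phase `ldla_phase` object.
#' @param classes `ldla_classes` object from [classify_gametes()].
#' @param pedigree Pedigree tibble.
#' @param map Map tibble.
#' @return Object of class `ldla_trans` holding the per-meiosis origin
#'   probabilities and the pedigree wiring needed to assemble per-locus
#'   descent matrices.
#' @export
la_transmission <- function(phase, classes, pedigree, map) {
  gam <- tibble::as_tibble(classes)
  gam$row <- seq_len(nrow(gam))
  row_of <- stats::setNames(gam$row, gam$gamete_id)
  bh <- attr(classes, "bh")
  bh_col <- stats::setNames(seq_len(nrow(bh)), bh$gamete_id)
  is_rh <- gam$class == "RH"
  meioses <- gam[is_rh, ]
  m <- nrow(map)
  origin1 <- matrix(NA_real_, nrow(meioses), m)
  for (k in seq_len(nrow(meioses))) {
    child_id <- meioses$id[k]
    p_id <- meioses$parent[k]
    child_seq <- if (meioses$side[k] == "pat") {
      phase$pat[child_id, ]
    } else {
      phase$mat[child_id, ]
    }
    pp <- phase$pat[p_id, ]
    pm <- phase$mat[p_id, ]
    ph <- !is.na(pp) & !is.na(pm) & pp != pm
    for (cc in unique(map$chrom)) {
      csel <- map$chrom == cc
      inf <- which(csel & ph & !is.na(child_seq))
      org <- ifelse(child_seq[inf] == pp[inf], 1L, 2L)
      origin1[k, csel] <- origin1_probability(
        map$pos_cm[csel], map$pos_cm[inf], org
      )
    }
  }
  # wiring for the recursion: child gamete row -> parent gamete rows
  meioses$parent_pat_row <- row_of[paste0(meioses$parent, "_p")]
  meioses$parent_mat_row <- row_of[paste0(meioses$parent, "_m")]
  unreachable <- is.na(meioses$parent_pat_row) | is.na(meioses$parent_mat_row)
  if (any(unreachable)) {
    stop(
      "replicated haplotype(s) whose ancestry never reaches a base haplotype: ",
      paste(meioses$gamete_id[unreachable], collapse = ", ")
    )
  }
  # recursion depth per meiosis (generation layers), so the per-locus
  # assembly can run one vectorized update per layer
  gen_of <- stats::setNames(pedigree$generation, pedigree$id)
  meioses$depth <- as.integer(gen_of[meioses$id])
  rh <- attr(classes, "rh")
  structure(
    list(
      gametes = gam, meioses = meioses, origin1 = origin1,
      bh_col = bh_col, bh = bh, rh_rows = row_of[rh$gamete_id],
      rh = rh, map = map, n_bh = nrow(bh), n_rh = nrow(rh)
    ),
    class = "ldla_trans"
  )
}

#' Per-locus descent matrix H_l
#'
#' Assembles the linkage-analysis descent matrix at one SNP position:
#' `H[r, b]` is the probability that replicated haplotype `r` descends from
#' base haplotype `b`. Rows of base gametes are unit vectors; rows of other
#' gametes chain the per-meiosis origin probabilities through the pedigree.
#' Probabilities below 1e-12 are zeroed and rows renormalized to sum to 1.
#'
#' @param trans `ldla_trans` object.
#' @param locus SNP index (column of the map).
#' @return List with `H` (n_RH x n_BH), `f` (= `colSums(H)`, the per-BH
#'   replicate counts) and `locus`.
#' @export
transmission_matrix <- function(trans, locus) {
  gam <- trans$gametes
  n_gam <- nrow(gam)
  n_bh <- trans$n_bh
  A <- matrix(0, n_gam, n_bh)
  is_bh <- gam$class != "RH"
  A[cbind(gam$row[is_bh], trans$bh_col[gam$gamete_id[is_bh]])] <- 1
  me <- trans$meioses
  q <- trans$origin1[, locus]
  for (d in sort(unique(me$depth))) {
    k <- which(me$depth == d)
    A[me$row[k], ] <- q[k] * A[me$parent_pat_row[k], , drop = FALSE] +
      (1 - q[k]) * A[me$parent_mat_row[k], , drop = FALSE]
  }
  H <- A[trans$rh_rows, , drop = FALSE]
  H[H < 1e-12] <- 0
  H <- H / rowSums(H)
  dimnames(H) <- list(trans$rh$gamete_id, trans$bh$gamete_id)
  list(H = H, f = colSums(H), locus = locus)
}

#' Windowed LD-based IBD matrix at one locus
#'
#' Estimates identity-by-descent probabilities between base haplotypes at a
#' SNP from the identity-by-state status of the surrounding marker window
#' (default 21 SNPs: 10 upstream, 10 downstream, truncated at chromosome
#' ends). The default estimator is an IBS-run posterior: pairs sharing the
#' focal allele get `prior / (prior + (1 - prior) * q_run)` with `q_run` the
#' chance probability of the observed uninterrupted IBS run given the
#' within-breed expected homozygosity; pairs differing at the focal SNP get
#' 0. Cross-breed entries are exactly 0 and the diagonal is 1.
#'
#' @param bh BH allele matrix from [bh_allele_matrix()] (with a `breed`
#'   attribute, or supply `breed`).
#' @param locus SNP index.
#' @param map Map tibble (for chromosome boundaries).
#' @param window Odd window size in SNPs (default 21).
#' @param breed Breed label per BH row; defaults to `attr(bh, "breed")`.
#' @param prior Prior IBD probability between same-breed base haplotypes.
#' @param chance Optional list of per-breed chance-IBS vectors; defaults to
#'   expected homozygosity from the BH allele frequencies of each breed.
#' @param estimator Pluggable kernel `function(A, locus, half_window, chance,
#'   chrom, prior)` returning the within-breed IBD matrix; defaults to the
#'   compiled IBS-run estimator.
#' @return Symmetric n_BH x n_BH matrix, unit diagonal, zero across breeds.
#' @export
ld_ibd_locus <- function(bh, locus, map, window = 21,
                         breed = attr(bh, "breed"), prior = 0.1,
                         chance = NULL, estimator = NULL) {
  if (window %% 2 != 1) stop("window must be odd")
  if (locus < 1 || locus > ncol(bh)) stop("locus out of range")
  half <- (window - 1) %/% 2
  if (is.null(chance)) chance <- chance_ibs(bh, breed)
  if (is.null(estimator)) {
    estimator <- function(A, l, h, ch, chrom, pr) {
      ibd_ibs_run(A, l - 1L, h, ch, chrom, pr)
    }
  }
  n <- nrow(bh)
  U <- matrix(0, n, n, dimnames = list(rownames(bh), rownames(bh)))
  diag(U) <- 1
  for (b in unique(breed)) {
    idx <- which(breed == b)
    if (length(idx) < 2) {
      if (length(idx) == 1) {
        warning(sprintf("fewer than 2 base haplotypes of breed %s; identity block", b))
      }
      next
    }
    U[idx, idx] <- estimator(
      bh[idx, , drop = FALSE], locus, half,
      chance[[b]], as.integer(map$chrom), prior
    )
  }
  U
}

#' Expected chance-IBS per SNP and breed
#'
#' @param bh BH allele matrix.
#' @param breed Breed label per row.
#' @return Named list of per-SNP probabilities that two random haplotypes of
#'   the breed carry the same allele (expected homozygosity).
#' @export
chance_ibs <- function(bh, breed = attr(bh, "breed")) {
  out <- lapply(unique(breed), function(b) {
    p <- colMeans(bh[breed == b, , drop = FALSE], na.rm = TRUE)
    p[is.na(p)] <- 0.5
    p^2 + (1 - p)^2
  })
  stats::setNames(out, unique(breed))
}

#' Genome-average LD IBD matrix U_g
#'
#' Element-wise mean of the per-locus IBD matrices over all (or the given)
#' loci, computed in a single streaming pass.
#'
#' @inheritParams ld_ibd_locus
#' @param loci Integer SNP indices (default: all).
#' @return Symmetric matrix with unit diagonal and zero cross-breed entries.
#' @export
ld_ibd_genome <- function(bh, map, loci = NULL, window = 21,
                          breed = attr(bh, "breed"), prior = 0.1,
                          chance = NULL) {
  if (is.null(loci)) loci <- seq_len(ncol(bh))
  if (length(loci) == 0) stop("empty locus list")
  half <- (window - 1) %/% 2
  if (is.null(chance)) chance <- chance_ibs(bh, breed)
  n <- nrow(bh)
  U <- matrix(0, n, n, dimnames = list(rownames(bh), rownames(bh)))
  diag(U) <- 1
  for (b in unique(breed)) {
    idx <- which(breed == b)
    if (length(idx) < 2) next
    U[idx, idx] <- ibd_ibs_run_mean(
      bh[idx, , drop = FALSE], as.integer(loci - 1L), half,
      chance[[b]], as.integer(map$chrom), prior
    )
  }
  U
}

#' Genome-average descent matrix H_g and replicate counts f_g
#'
#' @param trans `ldla_trans` object.
#' @param loci Integer SNP indices (default: all).
#' @return List with `H_g`, `f_g`.
#' @export
genome_average_la <- function(trans, loci = NULL) {
  if (is.null(loci)) loci <- seq_len(ncol(trans$origin1))
  if (length(loci) == 0) stop("empty locus list")
  acc <- NULL
  for (l in loci) {
    Hf <- transmission_matrix(trans, l)
    acc <- if (is.null(acc)) Hf$H else acc + Hf$H
  }
  H_g <- acc / length(loci)
  list(H_g = H_g, f_g = colSums(H_g))
}

#' Element-wise genome averages of per-locus matrices
#'
#' Averages lists of per-locus descent matrices `H_l`, IBD matrices `U_l` and
#' replicate-count vectors `f_l`; all entries must share dimensions.
#'
#' @param H,U,f Lists of per-locus matrices/vectors (any may be NULL).
#' @return List with the element-wise means `H_g`, `U_g`, `f_g` (NULL where
#'   the input was NULL).
#' @export
genome_average <- function(H = NULL, U = NULL, f = NULL) {
  avg <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) == 0) stop("empty locus list")
    Reduce(`+`, x) / length(x)
  }
  list(H_g = avg(H), U_g = avg(U), f_g = avg(f))
}
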