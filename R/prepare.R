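#' Prepare the LDLA model components from genotypes and pedigree
#'
#' Runs the genotype-side stages once: SNP editing, phasing, gamete
#' classification, linkage-analysis transmission tracing, genome-average IBD
#' matrices, selection of the high-impact base haplotypes and the genome-wide
#' PC scores. The returned object is then shared by every trait scan.
#'
#' @param genotypes 0/1/2/NA matrix, rownames = genotyped individual ids.
#' @param pedigree Pedigree tibble.
#' @param map Map tibble aligned with the genotype columns.
#' @param window IBS window size in SNPs for LD-based IBD (default 21).
#' @param pc_threshold Variance share for PC retention (default 0.99).
#' @param bhh_coverage Replicate coverage for BH_h selection (default 0.99).
#' @param prior Prior same-breed IBD probability of the window estimator.
#' @param phase_certainty Origin-probability cut-off for phasing.
#' @param call_rate,maf SNP editing thresholds.
#' @param phase Optional precomputed `ldla_phase` (e.g. [true_phase()]);
#'   skips phasing. SNP filters are not applied in that case.
#' @return Object of class `ldla_model` bundling the filtered map, phase,
#'   classification, transmission object, BH allele matrix, `U_g`, `H_g`,
#'   `f_g`, the BH_h selection, genome basis and `V_g` scores.
#' @export
ldla_prepare <- function(genotypes, pedigree, map, window = 21,
                         pc_threshold = 0.99, bhh_coverage = 0.99,
                         prior = 0.1, phase_certainty = 0.99,
                         call_rate = 0.95, maf = 0.01, phase = NULL) {
  filter_report <- NULL
  if (is.null(phase)) {
    flt <- filter_snps(genotypes, map, call_rate = call_rate, maf = maf)
    genotypes <- flt$genotypes
    map <- flt$map
    filter_report <- flt$report
    phase <- phase_population(genotypes, pedigree, map,
      certainty_threshold = phase_certainty
    )
  } else {
    stopifnot(ncol(phase$pat) == nrow(map))
  }
  classes <- classify_gametes(pedigree)
  bh <- bh_allele_matrix(phase, classes)
  trans <- la_transmission(phase, classes, pedigree, map)
  chance <- chance_ibs(bh)
  U_g <- ld_ibd_genome(bh, map, window = window, prior = prior, chance = chance)
  la_g <- genome_average_la(trans)
  bhh <- select_bh_h(U_g, la_g$f_g, coverage = bhh_coverage)
  gbasis <- genome_basis(bhh, threshold = pc_threshold)
  V_g <- genome_scores(la_g$H_g, bhh, gbasis)
  structure(
    list(
      map = map, pedigree = pedigree, phase = phase, classes = classes,
      bh = bh, breed = attr(bh, "breed"), trans = trans, chance = chance,
      U_g = U_g, H_g = la_g$H_g, f_g = la_g$f_g, bhh = bhh,
      gbasis = gbasis, V_g = V_g, window = window,
      pc_threshold = pc_threshold, prior = prior,
      filter_report = filter_report
    ),
    class = "ldla_model"
  )
}

#' @export
print.ldla_model <- function(x, ...) {
  cat("LDLA model components\n")
  cat(sprintf(
    "  %d SNPs on %d chromosome(s); %d BH (%d S, %d L); %d RH\n",
    nrow(x$map), length(unique(x$map$chrom)),
    attr(x$classes, "n_bh"), attr(x$classes, "n_bh_s"),
    attr(x$classes, "n_bh_l"), attr(x$classes, "n_rh")
  ))
  cat(sprintf(
    "  BH_h: %d members covering %.1f%% of replicates; n_PC_g = %d\n",
    length(x$bhh$idx), 100 * x$bhh$coverage, x$gbasis$n_pc
  ))
  invisible(x)
}

#' Design context for a trait
#'
#' Binds the phenotypes of one trait to the model: the APD vector `y`, the
#' reliability weights, the ewe-to-gamete incidence (two gametes per ewe) and
#' the folded genome-wide PC covariates `Z V_g`.
#'
#' @param model `ldla_model` object.
#' @param phenotypes Tibble with columns `id`, `y` (or the column named by
#'   `trait`) and `r` (reliability in (0, 1]).
#' @param trait Name of the phenotype column (default "y").
#' @return Object of class `ldla_context`.
#' @export
design_context <- function(model, phenotypes, trait = "y") {
  rh <- attr(model$classes, "rh")
  ewes <- unique(rh$id)
  stopifnot(all(ewes %in% phenotypes$id))
  ph <- phenotypes[match(ewes, phenotypes$id), ]
  y <- ph[[trait]]
  stopifnot(all(is.finite(y)))
  r <- ph$r
  if (any(r <= 0)) {
    warning("non-positive reliabilities clamped to 1e-6")
    r <- pmax(r, 1e-6)
  }
  if (any(r > 1)) stop("reliabilities must be in (0, 1]")
  n <- length(ewes)
  odd <- seq(1L, 2L * n, by = 2L)
  even <- odd + 1L
  stopifnot(all(rh$id[odd] == ewes), all(rh$id[even] == ewes))
  ZVg <- model$V_g[odd, , drop = FALSE] + model$V_g[even, , drop = FALSE]
  structure(
    list(
      y = y, w = r, ids = ewes, odd = odd, even = even,
      ZVg = ZVg, n_p = n, trait = trait
    ),
    class = "ldla_context"
  )
}

# fold a gamete-level score matrix to the ewe level (Z %*% V)
fold_gametes <- function(context, V) {
  V[context$odd, , drop = FALSE] + V[context$even, , drop = FALSE]
}
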