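#' Fitted locus-effect vector
#'
#' The per-ewe fitted QTL contribution `Z V_l beta_l` at a SNP; correlations
#' between these vectors drive the clustering of significant positions into
#' QTL regions.
#'
#' @param context `ldla_context`.
#' @param V_l Locus score matrix (n_RH x n_PC_l).
#' @param beta Estimated PC effects.
#' @return Numeric vector of length n_P.
#' @export
fitted_effect_vector <- function(context, V_l, beta) {
  as.numeric(fold_gametes(context, V_l) %*% beta)
}

# Cluster one trait's significant SNPs on one chromosome; returns a list of
# integer vectors (indices into `sig`), one per region, first element = peak.
cluster_chromosome <- function(logp, pos_bp, corr, corr_threshold) {
  n <- length(logp)
  ord <- order(-logp, pos_bp)
  peaks <- integer(0)
  for (k in ord) {
    if (length(peaks) == 0 || all(abs(corr[k, peaks]) < corr_threshold)) {
      peaks <- c(peaks, k)
    }
  }
  assign <- vapply(seq_len(n), function(k) {
    if (k %in% peaks) return(match(k, peaks))
    ck <- abs(corr[k, peaks])
    best <- which(ck == max(ck))
    if (length(best) > 1) best <- best[order(pos_bp[peaks[best]])][1]
    best
  }, 0L)
  lapply(seq_along(peaks), function(j) {
    members <- which(assign == j)
    c(peaks[j], setdiff(members, peaks[j]))
  })
}

#' Cluster significant positions into QTL regions
#'
#' Per trait and chromosome: the strongest genome-wide-significant signal
#' seeds the first region; further peaks are added iteratively among the
#' significant positions whose absolute correlation of fitted locus-effect
#' vectors with every existing peak is below `corr_threshold`; remaining
#' significant positions are assigned to the peak they correlate with most.
#' Regions of different traits whose bp intervals overlap are merged into a
#' single region. Deterministic; ties are broken by lower bp.
#'
#' @param scans A single `ldla_scan` or a named list of per-trait scans
#'   (each carrying its fitted effect vectors).
#' @param threshold Genome-wide significance threshold on
#'   `minus_log10_p_S` (positions strictly above it are significant).
#' @param corr_threshold Correlation cut-off separating peaks (default 0.15).
#' @return Tibble of class `ldla_regions`: `region`, `chrom`, `n_snps`,
#'   `peak_snp`, `peak_mb`, `start_mb`, `end_mb`, `max_minus_log10_p`,
#'   `traits`, plus one `max_logp_<trait>` column per trait; the per-SNP
#'   assignment in `attr(, "members")`.
#' @export
cluster_regions <- function(scans, threshold, corr_threshold = 0.15) {
  if (inherits(scans, "ldla_scan")) {
    nm <- attr(scans, "trait") %||% "y"
    scans <- stats::setNames(list(scans), nm)
  }
  stopifnot(length(scans) >= 1, !is.null(names(scans)))
  member_rows <- list()
  for (trait in names(scans)) {
    sc <- scans[[trait]]
    eff <- attr(sc, "effects")
    sig <- which(!is.na(sc$minus_log10_p_S) & sc$minus_log10_p_S > threshold)
    if (length(sig) == 0) next
    for (cc in unique(sc$chrom[sig])) {
      s <- sig[sc$chrom[sig] == cc]
      E <- eff[, s, drop = FALSE]
      corr <- suppressWarnings(abs(cor(E)))
      corr[!is.finite(corr)] <- 0
      cl <- cluster_chromosome(
        sc$minus_log10_p_S[s], sc$pos_bp[s], corr, corr_threshold
      )
      for (j in seq_along(cl)) {
        idx <- s[cl[[j]]]
        member_rows[[length(member_rows) + 1L]] <- tibble::tibble(
          trait = trait, chrom = cc,
          snp_id = sc$snp_id[idx], pos_bp = sc$pos_bp[idx],
          logp = sc$minus_log10_p_S[idx],
          is_peak = seq_along(idx) == 1L,
          trait_region = sprintf("%s_%d_%d", trait, cc, j)
        )
      }
    }
  }
  if (length(member_rows) == 0) {
    out <- tibble::tibble(
      region = integer(0), chrom = integer(0), n_snps = integer(0),
      peak_snp = character(0), peak_mb = numeric(0), start_mb = numeric(0),
      end_mb = numeric(0), max_minus_log10_p = numeric(0), traits = character(0)
    )
    class(out) <- c("ldla_regions", class(out))
    return(out)
  }
  members <- dplyr::bind_rows(member_rows)
  # merge trait-level regions whose intervals overlap (shared chromosome)
  iv <- members |>
    dplyr::group_by(.data$trait_region, .data$chrom) |>
    dplyr::summarise(
      start = min(.data$pos_bp), end = max(.data$pos_bp),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  group <- integer(nrow(iv))
  gid <- 0L
  cur_end <- -Inf
  cur_chrom <- NA_integer_
  for (k in seq_len(nrow(iv))) {
    if (!identical(iv$chrom[k], cur_chrom) || iv$start[k] > cur_end) {
      gid <- gid + 1L
      cur_chrom <- iv$chrom[k]
      cur_end <- iv$end[k]
    } else {
      cur_end <- max(cur_end, iv$end[k])
    }
    group[k] <- gid
  }
  iv$group <- group
  members <- dplyr::left_join(
    members, iv[, c("trait_region", "group")],
    by = "trait_region"
  )
  summar <- members |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      n_snps = dplyr::n_distinct(.data$snp_id),
      peak_snp = .data$snp_id[which.max(.data$logp)],
      peak_mb = .data$pos_bp[which.max(.data$logp)] / 1e6,
      start_mb = min(.data$pos_bp) / 1e6,
      end_mb = max(.data$pos_bp) / 1e6,
      max_minus_log10_p = max(.data$logp),
      traits = paste(sort(unique(.data$trait)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start_mb)
  per_trait <- members |>
    dplyr::group_by(.data$group, .data$trait) |>
    dplyr::summarise(max_logp = max(.data$logp), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "trait", values_from = "max_logp",
      names_prefix = "max_logp_"
    )
  out <- dplyr::left_join(summar, per_trait, by = "group")
  out$region <- seq_len(nrow(out))
  out <- dplyr::select(
    out, "region", "chrom", "n_snps", "peak_snp", "peak_mb",
    "start_mb", "end_mb", "max_minus_log10_p", "traits",
    dplyr::starts_with("max_logp_")
  )
  attr(out, "members") <- members
  class(out) <- c("ldla_regions", class(out))
  out
}
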