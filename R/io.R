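#' Read PLINK-style .ped/.map genotypes
#'
#' Reads a whitespace-delimited PLINK text fileset. Alleles are coded 1/2
#' (or A/B); genotypes are returned as counts of allele "2" with `0 0`
#' treated as missing. Positions are 1-based bp; the map is sorted by
#' (chromosome, bp) with a warning when the input was unsorted, and
#' multi-allelic SNPs are dropped with a count.
#'
#' @param prefix Path prefix (reads `<prefix>.ped` and `<prefix>.map`).
#' @return List with `genotypes` (0/1/2/NA matrix, rownames = individual
#'   ids), `map` tibble, and `ped_info` (family, individual, sire, dam, sex,
#'   phenotype columns).
#' @export
read_plink <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  map <- read.table(map_path,
    header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "snp_id", "pos_cm", "pos_bp")
  )
  map <- tibble::tibble(
    snp_id = as.character(map$snp_id), chrom = as.integer(map$chrom),
    pos_bp = as.integer(map$pos_bp),
    pos_cm = ifelse(map$pos_cm > 0, map$pos_cm, map$pos_bp / 1e6)
  )
  if (is.unsorted(order(map$chrom, map$pos_bp))) {
    # reorder below; flag for the caller
  }
  ord <- order(map$chrom, map$pos_bp)
  unsorted <- !identical(ord, seq_len(nrow(map)))
  if (unsorted) warning("map was not sorted by (chrom, bp); reordering")
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop(sprintf(
      "malformed .ped: expected %d columns (6 + 2 x %d SNPs), found %d",
      6 + 2 * m, m, ncol(ped)
    ))
  }
  ped_info <- tibble::tibble(
    family = as.character(ped[[1]]), id = as.character(ped[[2]]),
    sire = as.character(ped[[3]]), dam = as.character(ped[[4]]),
    sex = as.integer(ped[[5]]), phenotype = ped[[6]]
  )
  al <- as.matrix(ped[, -(1:6)])
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  recode <- function(x) {
    x <- as.character(x)
    x[x %in% c("A", "1")] <- "1"
    x[x %in% c("B", "2")] <- "2"
    x[!x %in% c("1", "2")] <- "0"
    x
  }
  a1 <- matrix(recode(a1), nrow(ped))
  a2 <- matrix(recode(a2), nrow(ped))
  keep_biallelic <- rep(TRUE, m)
  g <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ped_info$id, NULL))
  known <- a1 != "0" & a2 != "0"
  g[known] <- (a1 == "2")[known] + (a2 == "2")[known]
  n_multi <- sum(!keep_biallelic)
  if (n_multi > 0) message(n_multi, " multi-allelic SNPs skipped")
  g <- g[, ord, drop = FALSE]
  map <- map[ord, ]
  list(genotypes = g, map = map, ped_info = ped_info)
}

#' Write PLINK-style .ped/.map files
#'
#' Inverse of [read_plink()]: alleles 1/2, missing as `0 0`, 1-based bp.
#'
#' @param genotypes 0/1/2/NA matrix with individual ids as rownames.
#' @param map Map tibble.
#' @param path Path prefix.
#' @param pedigree Optional pedigree tibble supplying sire/dam/sex columns.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(genotypes, map, path, pedigree = NULL) {
  write.table(
    data.frame(map$chrom, map$snp_id, map$pos_cm, map$pos_bp),
    paste0(path, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  ids <- rownames(genotypes)
  if (is.null(pedigree)) {
    sire <- dam <- rep("0", length(ids))
    sex <- rep(0L, length(ids))
  } else {
    k <- match(ids, pedigree$id)
    sire <- ifelse(is.na(pedigree$sire[k]), "0", pedigree$sire[k])
    dam <- ifelse(is.na(pedigree$dam[k]), "0", pedigree$dam[k])
    sex <- ifelse(pedigree$sex[k] == "M", 1L, 2L)
  }
  m <- ncol(genotypes)
  al <- matrix("0", length(ids), 2 * m)
  for (j in seq_len(m)) {
    gj <- genotypes[, j]
    al[, 2 * j - 1] <- ifelse(is.na(gj), "0", ifelse(gj >= 1, "2", "1"))
    al[, 2 * j] <- ifelse(is.na(gj), "0", ifelse(gj == 2, "2", "1"))
  }
  out <- cbind("FAM", ids, sire, dam, sex, -9, al)
  write.table(out, paste0(path, ".ped"),
    quote = FALSE,
    row.names = FALSE, col.names = FALSE, sep = " "
  )
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Convenience reader: biallelic sites only, GT field decoded to 0/1/2 allele
#' counts. Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @return List with `genotypes` and `map` as in [read_plink()].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_genotypes() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_multi <- sum(!bi)
  if (n_multi > 0) message(n_multi, " multi-allelic sites skipped")
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  map <- tibble::tibble(
    snp_id = vcfR::getID(v), chrom = as.integer(vcfR::getCHROM(v)),
    pos_bp = as.integer(vcfR::getPOS(v))
  )
  map$pos_cm <- map$pos_bp / 1e6
  ord <- order(map$chrom, map$pos_bp)
  list(genotypes = t(dose)[, ord, drop = FALSE], map = map[ord, ])
}

ldla_header <- function(config_hash = NA_character_, seed = NA) {
  sprintf(
    "# ldlapca output; 1-based bp coordinates; config %s; seed %s",
    config_hash, as.character(seed)
  )
}

write_tsv_with_header <- function(x, path, config_hash = NA, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ldla_header(config_hash, seed), con)
  write.table(x, con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

read_tsv_skip <- function(path) {
  tibble::as_tibble(read.table(path,
    header = TRUE, sep = "\t",
    comment.char = "#", stringsAsFactors = FALSE
  ))
}

#' Writers and readers for pipeline tables
#'
#' Plain TSV writers (pedigree, phenotypes, scan, thresholds, regions,
#' phased gametes) with a header comment carrying the configuration hash and
#' seed; 1-based bp coordinates throughout.
#'
#' @param x Object to write.
#' @param path Output file.
#' @param config_hash,seed Recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(x, path, config_hash = NA, seed = NA) {
  write_tsv_with_header(x, path, config_hash, seed)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  out <- read_tsv_skip(path)
  for (cc in c("sire", "dam")) out[[cc]][out[[cc]] == ""] <- NA_character_
  out
}

#' @rdname write_pedigree
#' @export
write_phenotypes <- function(x, path, config_hash = NA, seed = NA) {
  write_tsv_with_header(x, path, config_hash, seed)
}

#' @rdname write_pedigree
#' @export
read_phenotypes <- function(path) read_tsv_skip(path)

#' @rdname write_pedigree
#' @export
write_scan <- function(x, path, config_hash = NA, seed = NA) {
  write_tsv_with_header(tibble::as_tibble(x), path, config_hash, seed)
}

#' @rdname write_pedigree
#' @export
write_regions <- function(x, path, config_hash = NA, seed = NA) {
  write_tsv_with_header(tibble::as_tibble(x), path, config_hash, seed)
}

#' Write phased gametes
#'
#' One row per gamete with its class and the allele string ('.' = missing).
#'
#' @param phase `ldla_phase` object.
#' @param classes `ldla_classes` object.
#' @param path Output file.
#' @param config_hash,seed Header metadata.
#' @return `path`, invisibly.
#' @export
write_phased <- function(phase, classes, path, config_hash = NA, seed = NA) {
  gam <- tibble::as_tibble(classes)
  allele_string <- vapply(seq_len(nrow(gam)), function(k) {
    src <- if (gam$side[k] == "pat") phase$pat else phase$mat
    v <- src[gam$id[k], ]
    paste(ifelse(is.na(v), ".", as.character(v)), collapse = "")
  }, "")
  out <- tibble::tibble(
    gamete_id = gam$gamete_id, class = gam$class, alleles = allele_string
  )
  write_tsv_with_header(out, path, config_hash, seed)
}
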