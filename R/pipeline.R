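#' Default run configuration
#'
#' All analysis parameters with their standard values: SNP editing call rate
#' 0.95 and MAF 0.01, phasing certainty 0.99, 21-SNP IBS windows, 99% PC
#' variance threshold at locus and genome level, 99% BH_h replicate coverage,
#' 2000 permutations at alpha = 0.05, and a 0.15 correlation cut-off for QTL
#' regions.
#'
#' @param ... Overrides as `name = value`.
#' @return Named list of parameters.
#' @export
ldla_config <- function(...) {
  cfg <- list(
    window = 21, pc_threshold = 0.99, bhh_coverage = 0.99,
    n_perm = 2000, alpha = 0.05, qtlr_corr = 0.15,
    call_rate = 0.95, maf = 0.01, phase_certainty = 0.99,
    prior_ibd = 0.1, seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(
      window %% 2 == 1, pc_threshold > 0, pc_threshold <= 1,
      bhh_coverage > 0, bhh_coverage <= 1, alpha > 0, alpha < 1,
      qtlr_corr > 0, qtlr_corr <= 1, call_rate >= 0, call_rate <= 1,
      maf >= 0, maf <= 0.5, phase_certainty > 0, phase_certainty <= 1
    )
  })
  cfg
}

#' Read a key=value configuration file
#'
#' Plain text, one `key = value` per line, `#` comments; values are parsed
#' as numbers where possible.
#'
#' @param path File path.
#' @return Config list from [ldla_config()] with the file's overrides.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(ldla_config, stats::setNames(parsed, keys))
}

stage_manifest <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  p <- stage_manifest(dir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

# Returns TRUE when the stage's recorded input hashes match and all its
# outputs exist, i.e. the stage can be skipped on rerun.
stage_current <- function(manifest, stage, inputs, outputs) {
  rec <- manifest[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  now <- hash_files(inputs)
  identical(rec$inputs[order(names(rec$inputs))], now[order(names(now))])
}

#' Run the full LDLA mapping pipeline on files
#'
#' Chains the stages phase -> ibd/pcspace -> scan -> permute -> regions from
#' a PLINK fileset plus pedigree and phenotype TSVs, writing each stage's
#' outputs to `out_dir` together with a manifest of input hashes; on rerun,
#' stages whose inputs and outputs are unchanged are skipped.
#'
#' @param genotype_prefix PLINK .ped/.map prefix.
#' @param pedigree_file Pedigree TSV (id, sire, dam, sex, generation,
#'   genotyped, phenotyped, sire_breed, dam_breed).
#' @param phenotype_file Phenotype TSV (id, one column per trait, r).
#' @param out_dir Output directory (created if needed).
#' @param traits Trait column names in the phenotype file.
#' @param config Configuration list from [ldla_config()].
#' @return Invisibly, a list with the model, scans, permutation nulls,
#'   common threshold and regions.
#' @export
run_pipeline <- function(genotype_prefix, pedigree_file, phenotype_file,
                         out_dir, traits = "y", config = ldla_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(
    paste0(genotype_prefix, ".ped"), paste0(genotype_prefix, ".map"),
    pedigree_file, phenotype_file
  )
  cfg_hash <- substr(
    tools::md5sum(
      written <- local({
        f <- file.path(out_dir, "config.txt")
        writeLines(
          paste(names(config), unlist(config), sep = " = "), f
        )
        f
      })
    ), 1, 8
  )
  seed <- config$seed
  manifest <- read_manifest(out_dir)
  gp <- read_plink(genotype_prefix)
  pedigree <- read_pedigree(pedigree_file)
  phen <- read_phenotypes(phenotype_file)

  model <- ldla_prepare(gp$genotypes, pedigree, gp$map,
    window = config$window, pc_threshold = config$pc_threshold,
    bhh_coverage = config$bhh_coverage, prior = config$prior_ibd,
    phase_certainty = config$phase_certainty,
    call_rate = config$call_rate, maf = config$maf
  )
  phased_file <- file.path(out_dir, "phased.tsv")
  write_phased(model$phase, model$classes, phased_file, cfg_hash, seed)

  scans <- list()
  nulls <- list()
  rerun_scan <- FALSE
  for (trait in traits) {
    context <- design_context(model, phen, trait = trait)
    scan_file <- file.path(out_dir, sprintf("scan_%s.tsv", trait))
    stage <- sprintf("scan_%s", trait)
    sc <- scan_genome(context, model)
    scans[[trait]] <- sc
    if (!stage_current(manifest, stage, inputs, scan_file)) {
      write_scan(
        dplyr::select(
          tibble::as_tibble(sc), -"pos_mb", -"n_pc_s", -"n_pc_lac"
        ),
        scan_file, cfg_hash, seed
      )
      manifest[[stage]] <- list(inputs = hash_files(inputs))
      rerun_scan <- TRUE
    }
    nulls[[trait]] <- gw_threshold(context, model,
      n_perm = config$n_perm,
      alpha = config$alpha, seed = seed
    )
  }
  thr <- common_threshold(nulls)
  thr_file <- file.path(out_dir, "thresholds.tsv")
  write_tsv_with_header(
    tibble::tibble(
      trait = names(nulls), alpha = config$alpha,
      threshold = vapply(nulls, function(x) x$threshold, 0),
      common = thr
    ),
    thr_file, cfg_hash, seed
  )
  maxima_file <- file.path(out_dir, "null_maxima.tsv")
  write_tsv_with_header(
    tibble::tibble(
      trait = rep(names(nulls), each = config$n_perm),
      perm = rep(seq_len(config$n_perm), length(nulls)),
      max_minus_log10_p = unlist(lapply(nulls, function(x) x$maxima))
    ),
    maxima_file, cfg_hash, seed
  )
  regions_file <- file.path(out_dir, "regions.tsv")
  stage <- "regions"
  regions <- cluster_regions(scans, thr, corr_threshold = config$qtlr_corr)
  if (rerun_scan || !stage_current(manifest, stage, inputs, regions_file)) {
    write_regions(regions, regions_file, cfg_hash, seed)
    manifest[[stage]] <- list(inputs = hash_files(inputs))
  }
  jsonlite::write_json(manifest, stage_manifest(out_dir), auto_unbox = TRUE)
  invisible(list(
    model = model, scans = scans, nulls = nulls,
    threshold = thr, regions = regions
  ))
}

#' Write a simulated population to pipeline input files
#'
#' @param sim `ldla_sim` object from [sim_population()].
#' @param dir Output directory.
#' @param prefix File prefix (default "sim").
#' @return Named list of the written paths.
#' @export
write_sim_inputs <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, prefix)
  write_plink(sim$genotypes, sim$map, gp, sim$pedigree)
  ped_file <- file.path(dir, paste0(prefix, "_pedigree.tsv"))
  write_pedigree(sim$pedigree, ped_file)
  phe_file <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
  write_phenotypes(sim$phenotypes, phe_file)
  truth_file <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_tsv_with_header(sim$gametes$crossovers, truth_file)
  list(
    genotype_prefix = gp, pedigree = ped_file,
    phenotypes = phe_file, truth = truth_file
  )
}
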