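PIPELINE_DEFAULTS <- list(
  # inputs (NULL means: simulate genotypes / skip the optional stage)
  genome_file = NULL, genotype_file = NULL, nrbc_file = NULL,
  homolog_file = NULL, transcript_fasta = NULL, cds_file = NULL,
  snp_site_file = NULL,
  dialect = "standard",
  # simulation settings (used when genotype_file is NULL)
  n_f2 = 250, n_nrbc = 19,
  genotyping_error_rate = 0, missing_rate = 0,
  # thresholds
  lod_min = 1.0, r_max = 0.4, chi2_flag = 14, rf_threshold = 0.25,
  alpha = 0.05, n_tests = 4, n_perm = 1000,
  # reference constants
  genome_Mb = 244.5, reference_length_cM = 484.8,
  include_unanchored = FALSE,
  rng_seed = 1L,
  out_dir = NULL
)

#' Pipeline configuration
#'
#' Flat keyed configuration for [run_pipeline()]. Any key absent falls back
#' to its default; unknown keys are rejected. Thresholds default to the
#' package's standard analysis profile (grouping at LOD >= 1.0 and
#' r <= 0.4, chi-square flag at 14, female-recombination exclusion above
#' 0.25, 1000 permutations with Bonferroni correction for 4 reference
#' genomes); reference constants default to a 244.5 Mbp genome and a
#' 484.8 cM reference map length.
#'
#' @param ... Named settings overriding the defaults (see
#'   `achiasmap:::PIPELINE_DEFAULTS` for the full key list).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  for (k in c("lod_min", "r_max", "chi2_flag", "rf_threshold", "alpha")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0) stop("`", k, "` must be non-negative")
  }
  if (cfg$r_max > 0.5 || cfg$rf_threshold > 0.5 || cfg$alpha > 1) {
    stop("threshold outside its documented range")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, a YAML subset) mapping of configuration keys; see
#' [pipeline_config()].
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full mapping pipeline
#'
#' Stage order: obtain genotypes (read, or simulate a study-scale cross) ->
#' segregation-distortion QC -> pairwise two-point estimation -> linkage
#' grouping and marker ordering -> map construction -> implied-female-
#' recombination exclusion and map rebuild -> non-recombinant-backcross
#' confirmation -> map statistics -> optional SNP coding-effect annotation
#' and synteny permutation tests. Deterministic given `rng_seed`; every
#' threshold applied and every excluded marker is recorded in the log.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `genotypes`,
#'   `segregation`, `pairwise`, `map` (after exclusions), `qc`
#'   (female-recombination filter table), `excluded`, `confirmation`,
#'   `summary`, `annotations`, `effect_summary`, `synteny`, `accounting`
#'   and `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  note("config: %s", paste(sprintf("%s=%s", names(config),
       vapply(config, function(x) paste(format(x), collapse = ","), "")),
       collapse = " "))

  genome <- NULL
  geno <- stage("genotypes", {
    if (!is.null(config$genotype_file)) {
      note("reading genotypes from %s (dialect %s)",
           config$genotype_file, config$dialect)
      read_genotypes(config$genotype_file, dialect = config$dialect)
    } else {
      genome <- if (!is.null(config$genome_file)) {
        read_genome(config$genome_file)
      } else default_genome()
      note("simulating F2 cross: %d individuals, error %.3g, missing %.3g, seed %d",
           config$n_f2, config$genotyping_error_rate, config$missing_rate,
           config$rng_seed)
      simulate_f2(genome, cross_config(
        n_f2 = config$n_f2, n_nrbc = config$n_nrbc,
        genotyping_error_rate = config$genotyping_error_rate,
        missing_rate = config$missing_rate, rng_seed = config$rng_seed))
    }
  })

  seg <- stage("segregation_test", segregation_test(geno, config$chi2_flag))
  note("segregation test: %d/%d markers flagged at chi2 > %g",
       sum(seg$flagged), nrow(seg), config$chi2_flag)

  pw <- stage("pairwise_estimates", pairwise_estimates(geno))
  groups <- stage("grouping",
                  group_markers(pw, lod_min = config$lod_min,
                                r_max = config$r_max,
                                markers = rownames(geno)))
  note("grouping at LOD >= %g, r <= %g: %d linkage groups",
       config$lod_min, config$r_max, length(groups))
  ordered <- stage("ordering", lapply(groups, order_group, pairwise = pw))
  map0 <- stage("map", build_map(ordered, pw,
                                 provenance = list(lod_min = config$lod_min,
                                                   r_max = config$r_max,
                                                   rng_seed = config$rng_seed)))

  qc <- stage("female_recomb_filter",
              female_recomb_filter(map0, geno, config$rf_threshold))
  excluded <- qc$marker[qc$excluded]
  map <- map0
  if (length(excluded)) {
    note("excluding %d marker(s) with implied female recombination > %g: %s",
         length(excluded), config$rf_threshold, paste(excluded, collapse = ", "))
    kept <- lapply(ordered, setdiff, y = excluded)
    kept <- kept[vapply(kept, length, integer(1)) > 0L]
    map <- stage("map_rebuild", build_map(kept, pw,
                                          provenance = attr(map0, "provenance")))
  } else {
    note("no markers excluded by the female-recombination filter")
  }

  confirmation <- NULL
  if (!is.null(config$nrbc_file)) {
    nrbc <- stage("nrbc", read_genotypes(config$nrbc_file, config$dialect))
    confirmation <- stage("nrbc_confirmation", confirm_with_nrbc(map, nrbc))
  } else if (!is.null(genome)) {
    nrbc <- stage("nrbc", simulate_nrbc(genome, cross_config(
      n_nrbc = config$n_nrbc, rng_seed = config$rng_seed)))
    confirmation <- stage("nrbc_confirmation", confirm_with_nrbc(map, nrbc))
  }
  if (!is.null(confirmation)) {
    note("nrBC confirmation: %s",
         if (confirmation$all_consistent) "all groups consistent" else "INCONSISTENT groups present")
  }

  summ <- stage("map_stats", map_summary(
    map, genome_size_Mb = config$genome_Mb,
    reference_length_cM = config$reference_length_cM))

  annotations <- NULL
  eff <- NULL
  if (!is.null(config$snp_site_file) && !is.null(config$transcript_fasta) &&
      !is.null(config$cds_file)) {
    annotations <- stage("snp_effects", {
      sites <- read_snp_sites(config$snp_site_file)
      trs <- read_transcripts(config$transcript_fasta, config$cds_file)
      annotate_snps(sites, trs)
    })
    eff <- summarize_effects(annotations)
    note("snp effects: %d/%d translated", eff$n_translated, eff$n_sites)
  }

  synteny <- NULL
  if (!is.null(config$homolog_file)) {
    synteny <- stage("synteny", {
      tables <- read_homologs(config$homolog_file,
                              include_unanchored = config$include_unanchored)
      if (inherits(tables, "homolog_table")) tables <- list(tables)
      res <- lapply(seq_along(tables), function(i) {
        permutation_test(tables[[i]], n_perm = config$n_perm,
                         alpha = config$alpha, n_tests = config$n_tests,
                         rng_seed = config$rng_seed + i)
      })
      multi_genome_report(res)
    })
  }

  # accounting: every input marker is mapped, excluded (with reason) or unplaced
  status <- rep("unplaced", nrow(geno))
  names(status) <- rownames(geno)
  status[map$marker] <- "mapped"
  status[excluded] <- "excluded"
  accounting <- data.frame(marker = names(status), status = unname(status),
                           stringsAsFactors = FALSE)

  out <- structure(list(genotypes = geno, segregation = seg, pairwise = pw,
                        map = map, qc = qc, excluded = excluded,
                        confirmation = confirmation, summary = summ,
                        annotations = annotations, effect_summary = eff,
                        synteny = synteny, accounting = accounting,
                        log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  out
}

.write_bundle <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_map(result$map, fp("map.tsv"))
  utils::write.table(result$segregation, fp("segregation_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$qc, fp("female_recomb_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$pairwise, fp("pairwise_twopoint.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$accounting, fp("marker_accounting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$annotations)) {
    utils::write.table(result$annotations, fp("snp_annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$synteny)) {
    utils::write.table(result$synteny, fp("synteny_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(unlist(.summary_lines(result$summary)), fp("map_summary.txt"))
  writeLines(result$log, fp("pipeline_log.txt"))
  invisible(dir)
}

.summary_lines <- function(s) {
  sprintf("%s\t%s", names(unclass(s)),
          vapply(unclass(s), function(v) paste(format(v), collapse = ","), ""))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$summary)
  if (length(x$excluded)) {
    cat("excluded markers:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
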