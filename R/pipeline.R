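#' Default end-to-end run configuration
#'
#' Nested list mirroring the YAML config consumed by
#' \code{\link{run_pipeline}}: simulation parameters (see
#' \code{\link{sim_config}}), mutation model, genotyper thresholds, scan
#' settings, and the master seed from which every stage derives its own
#' stream.
#'
#' @param design "F2", "RIL" or "MA".
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(design = "F2", seed = 1L) {
  list(
    design = design,
    seed = seed,
    simulation = list(
      n_individuals = 93, n_generations = NULL,
      parental_copies = list(NOR2 = c(500, 2500), NOR4 = c(300, 300)),
      depth_mean = 20, depth_dispersion = 0.5,
      snp_density = 300, low_diversity_rate = 0.05, low_diversity_mean = 50,
      call_rate = 0.9, error_rate = 0.01, n_replicates = 5),
    mutation = list(jump_probability = 0, jump_sd = 100),
    genotyper = list(min_segregating = 100, min_called = 40,
                     homozygous_fraction = 0.90, het_fraction = 0.25,
                     parental_diff_fraction = 0.30),
    scan = list(step_cM = 2, alpha = 0.05, n_permutations = 1000)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields are filled from \code{\link{default_run_config}}.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(design = cfg$design %||% "F2",
                             seed = cfg$seed %||% 1L)
  for (section in c("simulation", "mutation", "genotyper", "scan")) {
    for (nm in names(cfg[[section]]))
      base[[section]][[nm]] <- cfg[[section]][[nm]]
  }
  base
}

#' Run the full simulate-estimate-genotype-scan(-stability) pipeline
#'
#' Executes the stages in dependency order, materializing every
#' intermediate table as TSV/JSON in \code{outdir} so each stage is
#' independently inspectable, and finishes with a summary and a
#' reproducibility manifest (config echo, master seed, file checksums).
#' Stage seeds are derived from the master seed, so a rerun with an
#' identical config reproduces byte-identical tables. A stage failure
#' aborts with the failing stage named; earlier outputs are retained.
#' F2/RIL runs perform the QTL scan; MA runs perform the stability
#' analysis (mixed-model LRTs and the CV-by-generation series).
#'
#' @param config nested configuration list (see
#'   \code{\link{default_run_config}}) or path to a YAML file.
#' @param outdir output directory, created if needed.
#' @return invisible report bundle: list of stage output paths plus the
#'   summary list.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  logf <- file.path(outdir, "run.log")
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    log("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  seed <- config$seed
  design <- config$design
  genome <- genome_model()
  sim <- config$simulation

  # --- simulate -------------------------------------------------------
  pop <- stage("simulate", {
    sc <- sim_config(design = design,
                     n_individuals = sim$n_individuals,
                     n_generations = sim$n_generations,
                     parental_copies = lapply(sim$parental_copies, as.numeric),
                     depth_mean = sim$depth_mean,
                     depth_dispersion = sim$depth_dispersion,
                     snp_density = sim$snp_density,
                     low_diversity_rate = sim$low_diversity_rate,
                     low_diversity_mean = sim$low_diversity_mean,
                     call_rate = sim$call_rate, error_rate = sim$error_rate,
                     n_replicates = sim$n_replicates,
                     seed = seed)
    mut <- mutation_model(config$mutation$jump_probability,
                          config$mutation$jump_sd)
    p <- simulate_cross(sc, genome, mut)
    paths$population <- write_tsv(population_table(p),
                                   file.path(outdir, "population.tsv"))
    set.seed(derive_seed(seed, "coverage"))
    cov <- simulate_coverage(p, sim$depth_mean, sim$depth_dispersion)
    paths$coverage <- write_tsv(cov, file.path(outdir, "coverage.tsv"))
    set.seed(derive_seed(seed, "window_calls"))
    calls <- simulate_window_calls(p, snp_density = sim$snp_density,
                                   low_diversity_rate = sim$low_diversity_rate,
                                   low_diversity_mean = sim$low_diversity_mean,
                                   call_rate = sim$call_rate,
                                   error_rate = sim$error_rate)
    paths$window_calls <- write_tsv(calls,
                                     file.path(outdir, "window_calls.tsv"))
    p
  })
  cov <- read_tsv(paths$coverage)
  calls <- read_tsv(paths$window_calls)

  # --- estimate -------------------------------------------------------
  est <- stage("estimate", {
    e <- estimate_ngs(cov)
    paths$estimates <- write_tsv(e, file.path(outdir, "estimates.tsv"))
    e
  })

  summary <- list(design = design, seed = seed,
                  n_individuals = length(pop$individuals))

  if (design %in% c("F2", "RIL")) {
    # --- genotype -----------------------------------------------------
    gt <- config$genotyper
    res <- stage("genotype", {
      thr <- genotyper_thresholds(gt$min_segregating, gt$min_called,
                                  gt$homozygous_fraction, gt$het_fraction,
                                  gt$parental_diff_fraction)
      gm <- genotype_population(calls, thr)
      gdf <- data.frame(sample_id = rownames(gm$calls), gm$calls,
                        check.names = FALSE)
      paths$genotypes <- write_tsv(gdf, file.path(outdir, "genotypes.tsv"))
      map <- build_genetic_map(gm, design = design)
      paths$map <- write_tsv(as.data.frame(map), file.path(outdir, "map.tsv"))
      list(gm = gm, map = map)
    })

    # --- scan ---------------------------------------------------------
    stage("scan", {
      probs <- genotype_probabilities(res$gm, res$map,
                                      step_cM = config$scan$step_cM,
                                      design = design)
      pheno <- stats::setNames(est$value, est$sample_id)
      scan <- scan_sim(probs, pheno)
      paths$scan <- write_tsv(as.data.frame(scan),
                               file.path(outdir, "scan.tsv"))
      thr <- permutation_threshold(probs, pheno,
                                   alpha = config$scan$alpha,
                                   n_perm = config$scan$n_permutations,
                                   seed = derive_seed(seed, "permutations"))
      jsonlite::write_json(
        list(alpha = thr$alpha, n_perm = thr$n_perm, value = thr$value,
             seed = thr$seed),
        file.path(outdir, "threshold.json"), auto_unbox = TRUE, digits = NA)
      paths$threshold <- file.path(outdir, "threshold.json")
      peaks <- find_peaks(scan, thr)
      paths$peaks <- write_tsv(peaks, file.path(outdir, "peaks.tsv"))
      top <- peaks[which.max(peaks$lod), ]
      summary$threshold <- thr$value
      summary$peaks <- peaks
      summary$top_peak <- list(chrom = top$chrom, cM = top$cM,
                                lod = top$lod,
                                significant = top$significant)
    })
  } else {
    # --- stability ----------------------------------------------------
    stage("stability", {
      tab <- population_table(pop, windows = FALSE)
      emap <- stats::setNames(est$value, est$sample_id)
      reps <- tab[!is.na(tab$replicate), ]
      rec <- data.frame(line = reps$lineage, generation = reps$generation,
                        replicate = reps$replicate,
                        value = emap[reps$id])
      paths$stability <- write_tsv(rec, file.path(outdir, "stability.tsv"))
      full <- fit_lmm(rec, c("line", "generation"))
      no_line <- fit_lmm(rec, "generation")
      no_gen <- fit_lmm(rec, "line")
      lrt_line <- lrt(full, no_line)
      lrt_gen <- lrt(full, no_gen)
      jsonlite::write_json(
        list(full_loglik = full$loglik,
             sigma2_rep = full$sigma2_rep, sigma2_e = full$sigma2_e,
             line = unclass(lrt_line), generation = unclass(lrt_gen)),
        file.path(outdir, "lrt.json"), auto_unbox = TRUE, digits = NA)
      paths$lrt <- file.path(outdir, "lrt.json")

      main <- tab[is.na(tab$replicate), ]
      cvdat <- data.frame(group = "founder_NOR_genotype",
                          generation = main$generation,
                          value = emap[main$id], method = "NGS")
      cv <- cv_by_generation(cvdat)
      paths$cv <- write_tsv(cv, file.path(outdir, "cv.tsv"))
      summary$lrt <- list(line = unclass(lrt_line),
                           generation = unclass(lrt_gen))
      summary$cv <- cv
    })
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths$summary <- file.path(outdir, "summary.json")
  manifest <- list(
    seed = seed, config = config,
    files = as.list(tools::md5sum(unlist(paths[names(paths) != "log"]))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$manifest <- file.path(outdir, "manifest.json")
  paths$log <- logf
  log("pipeline finished")
  invisible(list(paths = paths, summary = summary))
}
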