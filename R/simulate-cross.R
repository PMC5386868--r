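#' Simulation configuration for pedigree designs
#'
#' Bundles the parameters of a simulated cross: design, population size,
#' generations, parental NOR copy numbers, coverage model, window SNP-call
#' model, qPCR plate model and master seed. Defaults mirror the study
#' designs this package emulates: an F2 of 93 individuals from a ~500 x
#' ~2500 copies-per-haploid cross in which NOR2 carries all the segregating
#' variation, RILs with nine selfing generations since the F1, and MA lines
#' propagated by single-seed descent for 31 generations with replicate
#' sub-lineages measured in two consecutive generations (32 and 33).
#'
#' @param design one of "F2", "RIL", "MA".
#' @param n_individuals F2/RIL population size, or number of MA lines.
#' @param n_generations selfing generations since the F1 (RIL; the F2 itself
#'   counts as one), or generations of single-seed descent (MA).
#' @param parental_copies list with per-NOR vectors \code{c(parent1, parent2)}
#'   of copies per haploid genome; for MA only the first entry is used.
#' @param depth_mean,depth_dispersion coverage model: mean per-base baseline
#'   depth and negative-binomial dispersion (variance = mu(1+phi); 0 =
#'   deterministic).
#' @param snp_density expected segregating SNPs per 100-kb window.
#' @param low_diversity_rate,low_diversity_mean fraction of windows drawn as
#'   low-diversity and their mean segregating-SNP count (exercises the
#'   window discard rule downstream).
#' @param call_rate probability that a segregating SNP receives a call.
#' @param error_rate probability that a called SNP is assigned to a wrong
#'   class (split equally between the two wrong classes).
#' @param n_replicates MA design: replicate sub-lineages per line measured in
#'   the final two generations.
#' @param seed master seed; fixes the entire simulated output stream.
#' @return object of class \code{nor_sim_config}.
#' @export
sim_config <- function(design = c("F2", "RIL", "MA"),
                       n_individuals = 93,
                       n_generations = NULL,
                       parental_copies = list(NOR2 = c(500, 2500),
                                              NOR4 = c(300, 300)),
                       depth_mean = 20,
                       depth_dispersion = 0.5,
                       snp_density = 300,
                       low_diversity_rate = 0.05,
                       low_diversity_mean = 50,
                       call_rate = 0.9,
                       error_rate = 0.01,
                       n_replicates = 5,
                       seed = NULL) {
  design <- match.arg(design)
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (is.null(n_generations))
    n_generations <- switch(design, F2 = 1L, RIL = 9L, MA = 31L)
  rates <- c(low_diversity_rate, call_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  structure(list(design = design, n_individuals = as.integer(n_individuals),
                 n_generations = as.integer(n_generations),
                 parental_copies = parental_copies,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 snp_density = snp_density,
                 low_diversity_rate = low_diversity_rate,
                 low_diversity_mean = low_diversity_mean,
                 call_rate = call_rate, error_rate = error_rate,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "nor_sim_config")
}

#' Simulate a pedigree of NOR copy-number carriers
#'
#' F2: parent1 x parent2 -> F1, F1 selfed to give \code{n_individuals} F2s
#' (generation 2). RIL: each F2 advanced by single-seed descent until
#' \code{n_generations} selfing generations have elapsed since the F1.
#' MA: one homozygous founder (parent1 copy numbers) spawns
#' \code{n_individuals} independent single-seed-descent lineages followed for
#' \code{n_generations} generations; every generation is recorded, and each
#' line then produces \code{n_replicates} replicate sub-lineages measured in
#' the next two consecutive generations.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genome a \code{\link{genome_model}}.
#' @param mutation a \code{\link{mutation_model}}; the default (rate 0)
#'   conserves copy number exactly through the pedigree.
#' @return object of class \code{nor_population}: list with
#'   \code{individuals} (the design's focal individuals), \code{founders},
#'   \code{genome}, \code{config}.
#' @export
simulate_cross <- function(config, genome = genome_model(),
                           mutation = mutation_model(0, 0)) {
  stopifnot(inherits(config, "nor_sim_config"))
  if (!is.null(config$seed)) set.seed(derive_seed(config$seed, "pedigree"))

  cp <- config$parental_copies
  p1 <- founder_individual(genome, 1L, lapply(cp, `[`, 1L), "P1")
  founders <- list(P1 = p1)

  inds <- switch(config$design,
    F2 = , RIL = {
      p2 <- founder_individual(genome, 2L, lapply(cp, `[`, 2L), "P2")
      founders$P2 <- p2
      f1 <- fertilize(meiosis(p1, genome, mutation),
                      meiosis(p2, genome, mutation),
                      genome, "F1", 1L, "F1")
      founders$F1 <- f1
      pop <- lapply(seq_len(config$n_individuals), function(k)
        self_individual(f1, genome, mutation,
                        sprintf("S%03d", k), 2L, "F2"))
      if (config$design == "RIL") {
        extra <- config$n_generations - 1L # F1 -> F2 is the first selfing
        for (g in seq_len(max(0L, extra))) {
          pop <- lapply(pop, function(ind)
            self_individual(ind, genome, mutation, ind$id,
                            ind$generation + 1L, "RIL"))
        }
      }
      pop
    },
    MA = {
      all_inds <- list()
      for (l in seq_len(config$n_individuals)) {
        lid <- sprintf("L%02d", l)
        cur <- p1
        for (g in seq_len(config$n_generations)) {
          cur <- self_individual(cur, genome, mutation,
                                 sprintf("%s_g%02d", lid, g), g, "MA_line",
                                 lineage = lid)
          all_inds[[length(all_inds) + 1L]] <- cur
        }
        # replicate sub-lineages measured in two consecutive generations
        for (r in seq_len(config$n_replicates)) {
          rid <- sprintf("r%02d", r)
          g1 <- config$n_generations + 1L
          rep1 <- self_individual(cur, genome, mutation,
                                  sprintf("%s_%s_g%02d", lid, rid, g1),
                                  g1, "MA_line", lineage = lid, replicate = rid)
          rep2 <- self_individual(rep1, genome, mutation,
                                  sprintf("%s_%s_g%02d", lid, rid, g1 + 1L),
                                  g1 + 1L, "MA_line", lineage = lid,
                                  replicate = rid)
          all_inds[[length(all_inds) + 1L]] <- rep1
          all_inds[[length(all_inds) + 1L]] <- rep2
        }
      }
      all_inds
    })

  structure(list(individuals = inds, founders = founders,
                 genome = genome, config = config),
            class = "nor_population")
}

#' @export
print.nor_population <- function(x, ...) {
  cat("<nor_population>", length(x$individuals), x$config$design,
      "individuals\n")
  invisible(x)
}

#' Flatten a simulated population to its truth table
#'
#' One row per individual with pedigree metadata, per-haplotype NOR copy
#' counts, and (optionally) the true 0/1/2 diplotype of every window.
#'
#' @param pop a \code{nor_population}.
#' @param windows include per-window true diplotypes as extra columns.
#' @return data.frame.
#' @export
population_table <- function(pop, windows = TRUE) {
  g <- pop$genome
  base <- do.call(rbind, lapply(pop$individuals, function(ind) {
    row <- data.frame(id = ind$id, lineage = ind$lineage,
                      replicate = ind$replicate,
                      generation = ind$generation, role = ind$role,
                      stringsAsFactors = FALSE)
    for (nm in names(g$nor_positions)) {
      row[[paste0(tolower(nm), "_hap1")]] <- ind$nor[[nm]][1L]
      row[[paste0(tolower(nm), "_hap2")]] <- ind$nor[[nm]][2L]
    }
    row$total_copies <- total_nor_copies(ind)
    row
  }))
  if (!windows) return(base)
  dip <- t(vapply(pop$individuals, function(ind) {
    d <- true_diplotypes(ind, g)
    d$diplotype
  }, integer(sum(g$n_windows))))
  d0 <- true_diplotypes(pop$individuals[[1L]], g)
  colnames(dip) <- paste0(d0$chrom, ":", d0$window_index)
  cbind(base, as.data.frame(dip, check.names = FALSE))
}
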