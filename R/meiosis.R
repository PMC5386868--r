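#' Create a homozygous founder individual
#'
#' Founders are fully inbred: both haplotypes carry the same marker allele
#' on every window and the same NOR copy counts.
#'
#' @param genome a \code{\link{genome_model}}.
#' @param allele founder marker allele, 1 ("A", maternal founder) or
#'   2 ("B", paternal founder).
#' @param nor_copies named list/vector of copy counts per haploid genome for
#'   each NOR, e.g. \code{c(NOR2 = 500, NOR4 = 300)}.
#' @param id sample identifier.
#' @param generation integer generation index (founders are generation 0).
#' @param role pedigree role label.
#' @return An object of class \code{nor_individual}.
#' @export
founder_individual <- function(genome, allele, nor_copies, id,
                               generation = 0L, role = "parent") {
  stopifnot(allele %in% c(1L, 2L))
  nor_copies <- unlist(nor_copies)
  if (!all(names(genome$nor_positions) %in% names(nor_copies)))
    stop("nor_copies must name every NOR in the genome")
  if (any(nor_copies < 0)) stop("NOR copy numbers must be >= 0")
  alleles <- lapply(genome$n_windows, function(nw)
    matrix(as.integer(allele), nrow = 2, ncol = nw))
  nor <- lapply(names(genome$nor_positions), function(nm)
    rep(as.numeric(nor_copies[[nm]]), 2))
  names(nor) <- names(genome$nor_positions)
  new_individual(id, generation, role, alleles, nor)
}

new_individual <- function(id, generation, role, alleles, nor,
                           lineage = NA_character_, replicate = NA_character_) {
  structure(list(id = id, generation = as.integer(generation), role = role,
                 alleles = alleles, nor = nor,
                 lineage = lineage, replicate = replicate),
            class = "nor_individual")
}

#' Total diploid NOR copy number of an individual
#'
#' Sum over both haplotypes of both NOR loci; the per-haploid-genome copy
#' number targeted by depth-based estimation is half this value.
#'
#' @param ind a \code{nor_individual}.
#' @return numeric scalar.
#' @export
total_nor_copies <- function(ind) sum(unlist(ind$nor))

#' Simulate one meiosis and return a gamete haplotype
#'
#' Crossovers are placed under a no-interference (Haldane) model: the number
#' of crossovers per chromosome is Poisson with mean equal to the genetic
#' length in Morgans, positions uniform on the genetic map. Marker alleles
#' are read off window midpoints. The NOR allele and its copy count always
#' travel with the topmost window of their chromosome - NORs on homologous
#' chromosomes do not exchange repeats - and with probability
#' \code{mutation$jump_probability} the transmitted copy count is perturbed
#' by a rounded N(0, jump_sd) draw, floored at 0.
#'
#' @param parent a \code{nor_individual}.
#' @param genome a \code{\link{genome_model}}.
#' @param mutation a \code{\link{mutation_model}}.
#' @return list with per-chromosome allele vectors and per-NOR copy counts.
#' @export
meiosis <- function(parent, genome, mutation = mutation_model(0, 0)) {
  chroms <- genome$chromosomes
  gam_alleles <- vector("list", nrow(chroms))
  names(gam_alleles) <- chroms$name
  gam_nor <- numeric(0)
  nor_chrom <- genome$nor_positions # name -> chrom

  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]
    a <- parent$alleles[[cn]]
    L <- chroms$length_cM[i]
    homozygous <- all(a[1L, ] == a[2L, ])
    n_co <- stats::rpois(1L, L / 100)
    co <- if (n_co > 0) sort(stats::runif(n_co, 0, L)) else numeric(0)
    start <- sample.int(2L, 1L)
    seg <- findInterval(genome$win_cM[[cn]], co)
    hap <- 1L + (start - 1L + seg) %% 2L
    gam_alleles[[cn]] <- if (homozygous) a[1L, ] else
      ifelse(hap == 1L, a[1L, ], a[2L, ])

    for (nm in names(nor_chrom)[nor_chrom == cn]) {
      copies <- parent$nor[[nm]][hap[1L]]
      if (mutation$jump_probability > 0 &&
          stats::runif(1L) < mutation$jump_probability) {
        copies <- max(0, copies + round(stats::rnorm(1L, 0, mutation$jump_sd)))
      }
      gam_nor[nm] <- copies
    }
  }
  list(alleles = gam_alleles, nor = gam_nor)
}

# combine two gametes into a diploid individual
fertilize <- function(g1, g2, genome, id, generation, role,
                      lineage = NA_character_, replicate = NA_character_) {
  alleles <- lapply(genome$chromosomes$name, function(cn)
    rbind(g1$alleles[[cn]], g2$alleles[[cn]]))
  names(alleles) <- genome$chromosomes$name
  nor <- lapply(names(genome$nor_positions), function(nm)
    c(g1$nor[[nm]], g2$nor[[nm]]))
  names(nor) <- names(genome$nor_positions)
  new_individual(id, generation, role, alleles, nor, lineage, replicate)
}

self_individual <- function(ind, genome, mutation, id, generation, role,
                            lineage = NA_character_, replicate = NA_character_) {
  fertilize(meiosis(ind, genome, mutation), meiosis(ind, genome, mutation),
            genome, id, generation, role, lineage, replicate)
}

#' True window diplotype of an individual
#'
#' Codes each window 0 (homozygous maternal, "AA"), 1 (heterozygous) or
#' 2 (homozygous paternal, "BB").
#'
#' @param ind a \code{nor_individual}.
#' @param genome a \code{\link{genome_model}}.
#' @return data.frame with chrom, window_index (0-based), diplotype.
#' @export
true_diplotypes <- function(ind, genome) {
  out <- lapply(genome$chromosomes$name, function(cn) {
    a <- ind$alleles[[cn]]
    data.frame(chrom = cn,
               window_index = seq_len(ncol(a)) - 1L,
               diplotype = as.integer((a[1L, ] - 1L) + (a[2L, ] - 1L)))
  })
  do.call(rbind, out)
}
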