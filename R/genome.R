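#' Genome model for NOR copy-number simulations
#'
#' Describes the chromosome set over which pedigrees are simulated: physical
#' and genetic chromosome lengths, the window grid used for
#' genotyping-by-sequencing, the location of the two NOR loci (tandem 45S
#' rRNA gene arrays), and the single-copy baseline region used to normalize
#' sequencing depth.
#'
#' Defaults emulate the five Arabidopsis thaliana nuclear chromosomes (TAIR10
#' physical lengths, approximate genetic lengths), with NOR2 and NOR4 pinned
#' to the top (position 0) of chromosomes 2 and 4, and the depth baseline on
#' the first 10 Mb of chromosome 3, which carries neither NOR nor 5S arrays.
#' All coordinates are 0-based, half-open; windows are indexed from the
#' chromosome start and the last window may be truncated.
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length_bp},
#'   \code{length_cM}.
#' @param window_size_bp window width in bp for the genotyping grid.
#' @param nor_positions named character vector mapping NOR names to the
#'   chromosome whose top window carries them.
#' @param baseline_region list with \code{chrom}, \code{start}, \code{end}
#'   (bp, half-open) for the depth-normalization region.
#' @return An object of class \code{nor_genome}.
#' @examples
#' g <- genome_model()
#' g$chromosomes
#' @export
genome_model <- function(chromosomes = NULL,
                         window_size_bp = 1e5,
                         nor_positions = c(NOR2 = "chr2", NOR4 = "chr4"),
                         baseline_region = list(chrom = "chr3", start = 0, end = 1e7)) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(
      name = paste0("chr", 1:5),
      length_bp = c(30427671, 19698289, 23459830, 18585056, 26975502),
      length_cM = c(120, 80, 90, 80, 110)
    )
  }
  stopifnot(all(c("name", "length_bp", "length_cM") %in% names(chromosomes)))
  if (any(chromosomes$length_cM < 0)) stop("negative genetic lengths are not allowed")
  if (window_size_bp <= 0) stop("window_size_bp must be positive")
  if (!all(nor_positions %in% chromosomes$name))
    stop("NOR chromosomes must be part of the genome")
  if (baseline_region$chrom %in% nor_positions)
    stop("baseline region must not lie on a NOR chromosome")

  n_windows <- as.integer(ceiling(chromosomes$length_bp / window_size_bp))
  # midpoint of each window on the genetic map, assuming uniform cM/bp
  win_cM <- lapply(seq_len(nrow(chromosomes)), function(i) {
    nw <- n_windows[i]
    mid <- pmin((seq_len(nw) - 0.5) * window_size_bp, chromosomes$length_bp[i])
    mid / chromosomes$length_bp[i] * chromosomes$length_cM[i]
  })
  names(win_cM) <- chromosomes$name
  names(n_windows) <- chromosomes$name

  structure(list(
    chromosomes = chromosomes,
    window_size_bp = window_size_bp,
    nor_positions = nor_positions,
    baseline_region = baseline_region,
    n_windows = n_windows,
    win_cM = win_cM
  ), class = "nor_genome")
}

#' @export
print.nor_genome <- function(x, ...) {
  cat("<nor_genome>", nrow(x$chromosomes), "chromosomes,",
      sum(x$n_windows), "windows of", x$window_size_bp, "bp\n")
  cat("  NORs:", paste(names(x$nor_positions), x$nor_positions,
                       sep = "@", collapse = ", "), "\n")
  cat("  baseline:", x$baseline_region$chrom,
      sprintf("[%g, %g)\n", x$baseline_region$start, x$baseline_region$end))
  invisible(x)
}

#' Copy-number mutation model for NOR arrays
#'
#' Unequal crossing-over between misaligned sister repeats expands or
#' contracts tandem arrays. The simulator models this as a per-NOR,
#' per-meiosis Bernoulli event with probability \code{jump_probability}; when
#' it fires, the transmitted copy count is perturbed by a rounded draw from
#' N(0, \code{jump_sd}) and floored at zero. The rate and jump scale are free
#' parameters of the model; defaults are chosen so that excursions of one to
#' a few hundred copies become visible within tens of generations.
#'
#' @param jump_probability probability of a copy-number jump per NOR per
#'   meiosis, in [0, 1].
#' @param jump_sd standard deviation (in copies) of the symmetric jump.
#' @return An object of class \code{nor_mutation}.
#' @export
mutation_model <- function(jump_probability = 0.02, jump_sd = 100) {
  if (jump_probability < 0 || jump_probability > 1)
    stop("jump_probability must lie in [0, 1]")
  if (jump_sd < 0) stop("jump_sd must be >= 0")
  structure(list(jump_probability = jump_probability, jump_sd = jump_sd),
            class = "nor_mutation")
}
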