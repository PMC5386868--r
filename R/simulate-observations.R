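#' Simulate per-sample coverage summaries
#'
#' Emulates whole-genome sequencing depth at the two regions the NGS
#' copy-number estimator consumes: the annotated 18S interval of the rRNA
#' reference unit and the first 10 Mb of chromosome 3. The 18S mean depth
#' has expectation \code{depth_mean * C_total / 2} where C_total is the
#' individual's diploid total NOR copy number, so that the depth ratio
#' estimates copies per haploid genome. Noise is negative binomial per base
#' (variance mu(1+phi)); means are taken over the 1808 bases of the 18S
#' interval and over a 10,000-position subsample of the baseline region.
#' Dispersion 0 returns the deterministic expectations.
#'
#' @param pop a \code{nor_population}, or a list of \code{nor_individual}.
#' @param depth_mean mean per-base depth over the baseline region.
#' @param dispersion negative-binomial dispersion phi (0 = deterministic).
#' @param n_baseline_positions baseline positions sampled for the mean.
#' @return data.frame (CoverageSummary): sample_id, mean18S, meanBaseline.
#' @export
simulate_coverage <- function(pop, depth_mean = 20, dispersion = 0.5,
                              n_baseline_positions = 10000L) {
  inds <- if (inherits(pop, "nor_population")) pop$individuals else pop
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (dispersion < 0) stop("negative dispersion")
  n18 <- 4002L - 2195L + 1L # annotated 18S interval length
  out <- lapply(inds, function(ind) {
    mu18 <- depth_mean * total_nor_copies(ind) / 2
    data.frame(sample_id = ind$id,
               mean18S = mean(rdepth(n18, mu18, dispersion)),
               meanBaseline = mean(rdepth(n_baseline_positions, depth_mean,
                                          dispersion)))
  })
  do.call(rbind, out)
}

#' Simulate per-window SNP-call summaries
#'
#' For each 100-kb window the number of segregating parental SNPs is Poisson
#' around \code{snp_density} (a configurable fraction of windows is drawn as
#' low-diversity, with mean \code{low_diversity_mean}, to exercise the
#' downstream discard rule); calls are Binomial(n_segregating, call_rate);
#' each call reports the class implied by the individual's true window
#' diplotype (maternal for AA, paternal for BB, heterozygous for AB) and is
#' flipped to one of the two wrong classes with probability
#' \code{error_rate}.
#'
#' @param pop a \code{nor_population} or list of individuals.
#' @param genome genome model (taken from \code{pop} when available).
#' @param snp_density,low_diversity_rate,low_diversity_mean,call_rate,error_rate
#'   see \code{\link{sim_config}}.
#' @return data.frame (WindowCallSummary): sample_id, chrom, window_index,
#'   n_segregating, n_called, n_maternal, n_paternal, n_het.
#' @export
simulate_window_calls <- function(pop, genome = NULL, snp_density = 300,
                                  low_diversity_rate = 0.05,
                                  low_diversity_mean = 50,
                                  call_rate = 0.9, error_rate = 0.01) {
  if (inherits(pop, "nor_population")) {
    genome <- pop$genome
    inds <- pop$individuals
  } else inds <- pop
  if (is.null(genome)) stop("genome required")
  rates <- c(low_diversity_rate, call_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")

  grid <- true_diplotypes(inds[[1L]], genome)[, c("chrom", "window_index")]
  nw <- nrow(grid)
  out <- vector("list", length(inds))
  for (k in seq_along(inds)) {
    ind <- inds[[k]]
    dip <- true_diplotypes(ind, genome)$diplotype
    lam <- ifelse(stats::runif(nw) < low_diversity_rate,
                  low_diversity_mean, snp_density)
    n_seg <- stats::rpois(nw, lam)
    n_called <- stats::rbinom(nw, n_seg, call_rate)
    # class probabilities per window given true diplotype
    p_mat <- ifelse(dip == 0L, 1 - error_rate, error_rate / 2)
    p_pat <- ifelse(dip == 2L, 1 - error_rate, error_rate / 2)
    n_mat <- stats::rbinom(nw, n_called, p_mat)
    n_pat <- stats::rbinom(nw, n_called - n_mat,
                           ifelse(p_mat >= 1, 0, p_pat / (1 - p_mat)))
    out[[k]] <- data.frame(sample_id = ind$id, chrom = grid$chrom,
                           window_index = grid$window_index,
                           n_segregating = n_seg, n_called = n_called,
                           n_maternal = n_mat, n_paternal = n_pat,
                           n_het = n_called - n_mat - n_pat)
  }
  do.call(rbind, out)
}

#' Simulate qPCR threshold-cycle tables
#'
#' Each sample is measured against the single-copy reference gene ACT2
#' (At3g18780) in \code{n_replicates} technical replicates per plate. The
#' noiseless cycle values satisfy
#' \code{Ct(18S) = Ct(ACT2) - log2(copies)}, so that
#' \code{2^(Ct(ACT2) - Ct(18S))} recovers the copy number. Observed Ct adds
#' a shared per-plate offset (cancels in the difference), an optional
#' target-specific plate offset (does not cancel; corrected by control
#' standardization), and N(0, replicate_sd) noise per technical replicate.
#' A common control sample is placed on every plate.
#'
#' @param samples data.frame with \code{sample_id} and \code{copies} (true
#'   copy number on the relative scale measured by qPCR).
#' @param n_plates number of plates; samples are distributed round-robin.
#' @param control_id,control_copies common control present on all plates.
#' @param plate_offset_sd sd (cycles) of the shared per-plate offset.
#' @param target_offset_sd sd (cycles) of the per-plate, per-target offset.
#' @param replicate_sd sd (cycles) of technical-replicate noise.
#' @param n_replicates technical replicates per (sample, plate, target).
#' @param base_ct noiseless ACT2 threshold cycle.
#' @return data.frame (CtRecord): sample_id, plate_id, target, replicate, ct.
#' @export
simulate_qpcr <- function(samples, n_plates = 14, control_id = "control",
                          control_copies = 500,
                          plate_offset_sd = 0.3, target_offset_sd = 0,
                          replicate_sd = 0.038, n_replicates = 4,
                          base_ct = 25) {
  stopifnot(all(c("sample_id", "copies") %in% names(samples)))
  if (any(samples$copies <= 0)) stop("copies must be positive")
  plate_of <- rep(seq_len(n_plates), length.out = nrow(samples))
  off_shared <- stats::rnorm(n_plates, 0, plate_offset_sd)
  off_18s <- stats::rnorm(n_plates, 0, target_offset_sd)
  off_act2 <- stats::rnorm(n_plates, 0, target_offset_sd)

  layout <- rbind(
    data.frame(sample_id = samples$sample_id, copies = samples$copies,
               plate = plate_of),
    data.frame(sample_id = control_id, copies = control_copies,
               plate = seq_len(n_plates)))

  rows <- lapply(seq_len(nrow(layout)), function(i) {
    p <- layout$plate[i]
    ct18_true <- base_ct - log2(layout$copies[i])
    data.frame(
      sample_id = layout$sample_id[i],
      plate_id = sprintf("plate%02d", p),
      target = rep(c("18S", "ACT2"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2L),
      ct = c(ct18_true + off_shared[p] + off_18s[p] +
               stats::rnorm(n_replicates, 0, replicate_sd),
             base_ct + off_shared[p] + off_act2[p] +
               stats::rnorm(n_replicates, 0, replicate_sd)))
  })
  do.call(rbind, rows)
}
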