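# two-locus F2 joint genotype probabilities under recombination fraction r;
# rows/cols indexed 0/1/2 (copies of the paternal allele), flattened
# column-major 9-vector; closed form of the two-independent-gametes model
f2_joint_probs <- function(r) {
  s2 <- (1 - r)^2 / 4
  r2 <- r^2 / 4
  rs <- r * (1 - r) / 2
  c(s2, rs, r2,
    rs, (1 - r)^2 / 2 + r^2 / 2, rs,
    r2, rs, s2)
}

# ML estimate of r between two F2 marker columns coded 0/1/2
estimate_r_f2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  counts <- tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
  negll <- function(r) -sum(counts * log(pmax(f2_joint_probs(r), 1e-300)))
  stats::optimize(negll, c(1e-6, 0.5), tol = 1e-6)$minimum
}

# RIL (selfed to fixation): observed recombinant fraction R relates to the
# per-meiosis r through R = 2r / (1 + 2r)
estimate_r_ril <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2) & g1 != 1L & g2 != 1L
  if (sum(ok) < 2) return(NA_real_)
  R <- mean(g1[ok] != g2[ok])
  R <- min(R, 0.49)
  R / (2 * (1 - R))
}

#' Estimate a genetic map from a window genotype matrix
#'
#' Adjacent-window recombination fractions are estimated by maximum
#' likelihood from the observed genotype transitions (for RILs the observed
#' fraction is first mapped back through R = 2r/(1+2r) to the per-meiosis
#' r), converted to distances with the Haldane map function
#' d = -50 ln(1 - 2r), and cumulated along each chromosome. F2 genotypes
#' use the full A/H/B coding (0/1/2); in RILs residual heterozygous calls
#' are treated as missing. Windows with a call rate below
#' \code{min_call_rate} are excluded from the map; adjacent pairs with
#' fewer than \code{min_pairs} jointly informative samples fall back to the
#' chromosome's median estimated distance. Estimates of r at or above 0.5
#' are capped with a warning.
#'
#' @param gm a \code{\link{genotype_population}} matrix.
#' @param design "F2" or "RIL".
#' @param min_call_rate minimum per-window call rate to enter the map.
#' @param min_pairs minimum jointly informative samples per adjacent pair.
#' @param window_size_bp window width in bp (for physical positions).
#' @return object of class \code{nor_genetic_map}: data.frame chrom,
#'   window_index, bp, cM with attributes \code{design} and
#'   \code{map_function = "haldane"}.
#' @export
build_genetic_map <- function(gm, design = c("F2", "RIL"),
                              min_call_rate = 0.5, min_pairs = 20,
                              window_size_bp = 1e5) {
  design <- match.arg(design)
  keep <- gm$windows$call_rate >= min_call_rate
  wins <- gm$windows[keep, , drop = FALSE]
  calls <- gm$calls[, keep, drop = FALSE]
  G <- matrix(NA_integer_, nrow(calls), ncol(calls))
  G[calls == "A"] <- 0L
  G[calls == "B"] <- 2L
  if (design == "F2") G[calls == "H"] <- 1L

  est_r <- if (design == "F2") estimate_r_f2 else estimate_r_ril
  pieces <- lapply(unique(wins$chrom), function(ch) {
    jc <- which(wins$chrom == ch)
    if (length(jc) < 2)
      stop("need >= 2 informative windows on chromosome ", ch)
    r <- rep(NA_real_, length(jc) - 1L)
    for (k in seq_along(r)) {
      g1 <- G[, jc[k]]; g2 <- G[, jc[k + 1L]]
      if (sum(!is.na(g1) & !is.na(g2)) >= min_pairs)
        r[k] <- est_r(g1, g2)
    }
    if (all(is.na(r))) stop("no informative adjacent pairs on ", ch)
    fallback <- stats::median(r, na.rm = TRUE)
    r[is.na(r)] <- fallback
    if (any(r >= 0.5)) {
      warning("recombination fraction >= 0.5 capped on ", ch)
      r <- pmin(r, 0.4999)
    }
    data.frame(chrom = ch,
               window_index = wins$window_index[jc],
               bp = wins$window_index[jc] * window_size_bp,
               cM = cumsum(c(0, haldane_d(r))))
  })
  map <- do.call(rbind, pieces)
  structure(map, class = c("nor_genetic_map", "data.frame"),
            design = design, map_function = "haldane")
}
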