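# transition probability along one gamete: stay (same allele) or switch
tr_prob <- function(same, r) ifelse(same, 1 - r, r)

# phased allele pairs consistent with an unordered genotype 0/1/2
geno_configs <- function(g) {
  switch(as.character(g),
         "0" = list(c(0L, 0L)),
         "1" = list(c(0L, 1L), c(1L, 0L)),
         "2" = list(c(1L, 1L)))
}

# P(genotype at t | flanking genotypes) for an F2, two independent gametes,
# Markov allele process (Haldane). d* are map distances in cM.
cond_probs_f2 <- function(gL, gR, dLt, dtR) {
  if (is.na(gL) && is.na(gR)) return(c(0.25, 0.5, 0.25))
  if (is.na(gR)) return(cond_probs_f2_one(gL, dLt))
  if (is.na(gL)) return(cond_probs_f2_one(gR, dtR))
  rLt <- haldane_r(dLt); rtR <- haldane_r(dtR); rLR <- haldane_r(dLt + dtR)
  tot <- c(0, 0, 0)
  for (cl in geno_configs(gL)) for (cr in geno_configs(gR)) {
    wu <- tr_prob(cl[1L] == cr[1L], rLR)
    wv <- tr_prob(cl[2L] == cr[2L], rLR)
    if (wu == 0 || wv == 0) next
    pAu <- tr_prob(cl[1L] == 0L, rLt) * tr_prob(cr[1L] == 0L, rtR) / wu
    pAv <- tr_prob(cl[2L] == 0L, rLt) * tr_prob(cr[2L] == 0L, rtR) / wv
    w <- wu * wv
    tot <- tot + w * c(pAu * pAv,
                       pAu * (1 - pAv) + (1 - pAu) * pAv,
                       (1 - pAu) * (1 - pAv))
  }
  tot / sum(tot)
}

# single observed flank at map distance d
cond_probs_f2_one <- function(g, d) {
  r <- haldane_r(d)
  pA_each <- switch(as.character(g),
                    "0" = c(1 - r, 1 - r),
                    "1" = c(1 - r, r), # phase arbitrary; symmetrized below
                    "2" = c(r, r))
  if (g == 1L) {
    # average the two phase assignments
    p1 <- pA_each[1L]; p2 <- pA_each[2L]
    0.5 * c(p1 * p2, p1 * (1 - p2) + (1 - p1) * p2, (1 - p1) * (1 - p2)) +
      0.5 * c(p2 * p1, p2 * (1 - p1) + (1 - p2) * p1, (1 - p2) * (1 - p1))
  } else {
    pA <- pA_each[1L]
    c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  }
}

# RIL: fixed lines, single two-state chain with effective transition
# probability R = 2r/(1+2r)
ril_R <- function(d) {
  r <- haldane_r(d)
  2 * r / (1 + 2 * r)
}

cond_probs_ril <- function(gL, gR, dLt, dtR) {
  if (is.na(gL) && is.na(gR)) return(c(0.5, 0, 0.5))
  if (is.na(gR)) {
    R <- ril_R(dLt)
    pA <- if (gL == 0L) 1 - R else R
    return(c(pA, 0, 1 - pA))
  }
  if (is.na(gL)) {
    R <- ril_R(dtR)
    pA <- if (gR == 0L) 1 - R else R
    return(c(pA, 0, 1 - pA))
  }
  RL <- ril_R(dLt); RR <- ril_R(dtR)
  wA <- tr_prob(gL == 0L, RL) * tr_prob(gR == 0L, RR)
  wB <- tr_prob(gL == 2L, RL) * tr_prob(gR == 2L, RR)
  c(wA, 0, wB) / (wA + wB)
}

#' Genotype probabilities on a pseudomarker grid
#'
#' At every mapped window and every \code{step_cM} pseudomarker, computes
#' P(AA), P(AB), P(BB) for each individual by conditioning on the nearest
#' informative flanking markers under Haldane recombination (gametes
#' independent and Markov along the chromosome; missing markers are skipped
#' as flanks). At an observed marker the probability is 1 on the observed
#' state. For RILs P(AB) = 0 everywhere and heterozygous calls are treated
#' as missing.
#'
#' @param gm a \code{\link{genotype_population}} matrix.
#' @param map a \code{\link{build_genetic_map}} result covering the matrix.
#' @param step_cM pseudomarker spacing in cM.
#' @param design "F2" or "RIL".
#' @return object of class \code{nor_genoprob}: list with \code{grid}
#'   (data.frame chrom, cM, is_marker), matrices \code{pAA}, \code{pAB},
#'   \code{pBB} (individuals x positions), \code{samples}, \code{design}.
#' @export
genotype_probabilities <- function(gm, map, step_cM = 2,
                                   design = c("F2", "RIL")) {
  design <- match.arg(design)
  key_mat <- paste(gm$windows$chrom, gm$windows$window_index)
  key_map <- paste(map$chrom, map$window_index)
  idx <- match(key_map, key_mat)
  if (anyNA(idx)) stop("map refers to windows absent from the matrix")
  raw <- gm$calls[, idx, drop = FALSE]
  G <- matrix(NA_integer_, nrow(raw), ncol(raw))
  G[raw == "A"] <- 0L
  G[raw == "B"] <- 2L
  if (design == "F2") G[raw == "H"] <- 1L
  n <- nrow(G)
  cond <- if (design == "F2") cond_probs_f2 else cond_probs_ril

  grids <- list(); PAs <- list(); PHs <- list(); PBs <- list()
  for (ch in unique(map$chrom)) {
    if (!any(map$chrom == ch)) stop("empty chromosome ", ch)
    jc <- which(map$chrom == ch)
    mpos <- map$cM[jc]
    Gc <- G[, jc, drop = FALSE]
    tpos <- sort(unique(c(mpos, seq(0, max(mpos), by = step_cM))))
    npos <- length(tpos)
    PA <- matrix(NA_real_, n, npos); PH <- PA; PB <- PA

    # per-individual left/right informative flank (global marker index)
    ML <- matrix(NA_integer_, n, npos); MR <- ML
    for (i in seq_len(n)) {
      inf <- which(!is.na(Gc[i, ]))
      if (!length(inf)) next
      L <- findInterval(tpos, mpos[inf])
      lm <- ifelse(L == 0L, NA_integer_, inf[pmax(L, 1L)])
      rm_ <- ifelse(L >= length(inf), NA_integer_, inf[pmin(L + 1L, length(inf))])
      exact <- !is.na(lm) & mpos[lm] == tpos
      rm_[exact] <- lm[exact]
      ML[i, ] <- lm
      MR[i, ] <- rm_
    }

    for (j in seq_len(npos)) {
      lm <- ML[, j]; rm_ <- MR[, j]
      gL <- Gc[cbind(seq_len(n), lm)]
      gR <- Gc[cbind(seq_len(n), rm_)]
      dL <- tpos[j] - mpos[lm]
      dR <- mpos[rm_] - tpos[j]
      obs <- !is.na(lm) & !is.na(rm_) & lm == rm_
      if (any(obs)) {
        PA[obs, j] <- as.numeric(gL[obs] == 0L)
        PH[obs, j] <- as.numeric(gL[obs] == 1L)
        PB[obs, j] <- as.numeric(gL[obs] == 2L)
      }
      rest <- which(!obs)
      if (length(rest)) {
        key <- paste(lm[rest], rm_[rest], gL[rest], gR[rest])
        for (uk in unique(key)) {
          rows <- rest[key == uk]
          i0 <- rows[1L]
          p <- cond(gL[i0], gR[i0],
                    if (is.na(lm[i0])) NA_real_ else dL[i0],
                    if (is.na(rm_[i0])) NA_real_ else dR[i0])
          PA[rows, j] <- p[1L]; PH[rows, j] <- p[2L]; PB[rows, j] <- p[3L]
        }
      }
    }
    grids[[ch]] <- data.frame(chrom = ch, cM = tpos,
                              is_marker = tpos %in% mpos)
    PAs[[ch]] <- PA; PHs[[ch]] <- PH; PBs[[ch]] <- PB
  }
  structure(list(grid = do.call(rbind, grids),
                 pAA = do.call(cbind, PAs),
                 pAB = do.call(cbind, PHs),
                 pBB = do.call(cbind, PBs),
                 samples = gm$samples, design = design),
            class = "nor_genoprob")
}

#' @export
print.nor_genoprob <- function(x, ...) {
  cat("<nor_genoprob>", length(x$samples), "individuals x",
      nrow(x$grid), "positions (", x$design, ")\n")
  invisible(x)
}
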