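# Orthonormal bases for the per-position Haley-Knott design matrices.
# Returns Qt (stacked transposed Q blocks) plus a row -> position index,
# so that RSS1_j(y) = y'y - sum over rows of block j of (Qt y)^2.
hk_basis <- function(probs, use) {
  add <- probs$pAB[use, , drop = FALSE] + 2 * probs$pBB[use, , drop = FALSE]
  dom <- probs$pAB[use, , drop = FALSE]
  n <- length(use)
  npos <- ncol(add)
  qts <- vector("list", npos)
  for (j in seq_len(npos)) {
    X <- if (probs$design == "F2") cbind(1, add[, j], dom[, j])
         else cbind(1, add[, j])
    qd <- qr(X)
    qts[[j]] <- t(qr.Q(qd)[, seq_len(qd$rank), drop = FALSE])
  }
  ranks <- vapply(qts, nrow, integer(1))
  list(Qt = do.call(rbind, qts), row_pos = rep(seq_len(npos), ranks), n = n)
}

lod_from_rss <- function(n, rss0, rss1, cap = 300) {
  if (rss0 <= 0) return(rep(0, length(rss1)))
  perfect <- rss1 <= rss0 * 1e-12 # RSS1 ~ 0: report the cap, flagged below
  lod <- (n / 2) * log10(rss0 / pmax(rss1, rss0 * 1e-300))
  lod[perfect] <- cap
  pmin(pmax(lod, 0), cap)
}

match_phenotype <- function(probs, phenotype) {
  if (!is.null(names(phenotype))) {
    y <- phenotype[match(probs$samples, names(phenotype))]
  } else {
    if (length(phenotype) != length(probs$samples))
      stop("phenotype length does not match individuals")
    y <- phenotype
  }
  use <- which(is.finite(y))
  list(y = unname(y[use]), use = use)
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At each grid position the phenotype is regressed on the expected
#' genotype dosages (additive + dominance for F2; additive for RIL), and
#' the LOD score is \code{(n/2) log10(RSS0/RSS1)} with RSS0 from the
#' intercept-only fit. Individuals with missing phenotype are dropped;
#' zero phenotypic variance yields an all-zero scan with a warning; a
#' perfect fit (RSS1 = 0) is capped at LOD 300.
#'
#' @param probs a \code{\link{genotype_probabilities}} object.
#' @param phenotype numeric copy-number values, named by sample id (or in
#'   the order of \code{probs$samples}).
#' @return object of class \code{nor_scan}: data.frame chrom, cM, lod with
#'   attributes \code{n} and \code{model = "SIM"}.
#' @export
scan_sim <- function(probs, phenotype) {
  mp <- match_phenotype(probs, phenotype)
  y <- mp$y
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  if (rss0 <= 0) warning("zero phenotypic variance: all-LOD-zero scan")
  hb <- hk_basis(probs, mp$use)
  qty <- hb$Qt %*% y
  rss1 <- as.vector(sum(y^2) - rowsum(qty^2, hb$row_pos))
  out <- data.frame(chrom = probs$grid$chrom, cM = probs$grid$cM,
                    lod = lod_from_rss(n, rss0, rss1))
  structure(out, class = c("nor_scan", "data.frame"),
            n = n, model = "SIM")
}

#' Genome-wide maximum LOD for a matrix of phenotypes
#'
#' Shared machinery for permutation thresholds and calibration studies:
#' scans every column of \code{Y} and returns its genome-wide maximum LOD.
#' Columns are processed in chunks to bound memory.
#'
#' @param probs a \code{\link{genotype_probabilities}} object.
#' @param Y numeric matrix, individuals x phenotypes (rows in the order of
#'   \code{probs$samples}, already restricted to complete phenotypes).
#' @param chunk number of columns per block.
#' @return numeric vector of max LOD, one per column of \code{Y}.
#' @export
scan_max_lod <- function(probs, Y, chunk = 2000L) {
  n <- nrow(Y)
  if (n != length(probs$samples))
    stop("Y rows must match probs individuals")
  hb <- hk_basis(probs, seq_len(n))
  npos <- nrow(probs$grid)
  out <- numeric(ncol(Y))
  for (s in seq(1L, ncol(Y), by = chunk)) {
    cols <- s:min(s + chunk - 1L, ncol(Y))
    Yb <- Y[, cols, drop = FALSE]
    yty <- colSums(Yb^2)
    rss0 <- yty - n * colMeans(Yb)^2
    qty <- hb$Qt %*% Yb
    rss1 <- rowsum(qty^2, hb$row_pos)
    rss1 <- sweep(-rss1, 2, yty, `+`)
    lodm <- (n / 2) * (log10(matrix(rss0, npos, length(cols), byrow = TRUE)) -
                         log10(pmax(rss1, 1e-300)))
    lodm[, rss0 <= 0] <- 0
    out[cols] <- pmin(apply(lodm, 2, max), 300)
  }
  out
}

#' Permutation-based genome-wide LOD threshold
#'
#' The phenotype is permuted \code{n_perm} times, each permutation is
#' scanned genome-wide, and the threshold is the empirical (1 - alpha)
#' quantile (type 7) of the per-permutation maximum LOD.
#'
#' @param probs a \code{\link{genotype_probabilities}} object.
#' @param phenotype numeric phenotype (named or ordered as the samples).
#' @param alpha genome-wide significance level.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional seed fixing the permutation stream.
#' @return object of class \code{nor_threshold}: list with alpha, n_perm,
#'   value, seed, and the vector of permutation max LODs.
#' @export
permutation_threshold <- function(probs, phenotype, alpha = 0.05,
                                  n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  mp <- match_phenotype(probs, phenotype)
  if (length(mp$use) < length(probs$samples))
    stop("permutation scan requires complete phenotypes")
  y <- mp$y
  Y <- vapply(seq_len(n_perm), function(k) sample(y), numeric(length(y)))
  maxlod <- scan_max_lod(probs, Y)
  structure(list(alpha = alpha, n_perm = n_perm,
                 value = unname(stats::quantile(maxlod, 1 - alpha, type = 7)),
                 seed = seed, max_lods = maxlod),
            class = "nor_threshold")
}

#' @export
print.nor_threshold <- function(x, ...) {
  cat(sprintf("<nor_threshold> alpha=%g, %d permutations, LOD >= %.3f\n",
              x$alpha, x$n_perm, x$value))
  invisible(x)
}

#' Cofactor-adjusted genome scan (CIM-style approximation of MQM)
#'
#' Haley-Knott regression in which the dosages of selected cofactor markers
#' are included as covariates, except cofactors lying within
#' \code{exclusion_window_cM} of the test position on the same chromosome.
#' The LOD compares the position model against the cofactor-only model at
#' that position. Collinear cofactor columns are dropped by the QR
#' decomposition. With no cofactors the scan reduces exactly to
#' \code{\link{scan_sim}}.
#'
#' @param probs a \code{\link{genotype_probabilities}} object.
#' @param phenotype numeric phenotype (named or ordered as the samples).
#' @param cofactors data.frame with chrom and cM of cofactor positions
#'   (matched to the nearest grid position), or NULL.
#' @param exclusion_window_cM half-width of the cofactor exclusion window.
#' @return a \code{nor_scan} with \code{model = "cofactor"}.
#' @export
scan_cofactor <- function(probs, phenotype, cofactors = NULL,
                          exclusion_window_cM = 10) {
  if (is.null(cofactors) || nrow(cofactors) == 0) {
    out <- scan_sim(probs, phenotype)
    attr(out, "model") <- "cofactor"
    return(out)
  }
  mp <- match_phenotype(probs, phenotype)
  y <- mp$y
  n <- length(y)
  add <- probs$pAB[mp$use, , drop = FALSE] + 2 * probs$pBB[mp$use, , drop = FALSE]
  dom <- probs$pAB[mp$use, , drop = FALSE]
  grid <- probs$grid

  cof_idx <- vapply(seq_len(nrow(cofactors)), function(k) {
    on_chr <- which(grid$chrom == cofactors$chrom[k])
    if (!length(on_chr)) stop("cofactor chromosome not in grid")
    on_chr[which.min(abs(grid$cM[on_chr] - cofactors$cM[k]))]
  }, integer(1))

  rss_of <- function(X) {
    qd <- qr(X)
    q <- qr.Q(qd)[, seq_len(qd$rank), drop = FALSE]
    sum(y^2) - sum(as.vector(crossprod(q, y))^2)
  }
  lod <- numeric(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    active <- cof_idx[!(grid$chrom[cof_idx] == grid$chrom[j] &
                          abs(grid$cM[cof_idx] - grid$cM[j]) <
                            exclusion_window_cM)]
    X0 <- cbind(1, add[, active, drop = FALSE],
                if (probs$design == "F2") dom[, active, drop = FALSE])
    X1 <- cbind(X0, add[, j],
                if (probs$design == "F2") dom[, j])
    lod[j] <- lod_from_rss(n, rss_of(X0), rss_of(X1))
  }
  out <- data.frame(chrom = grid$chrom, cM = grid$cM, lod = lod)
  structure(out, class = c("nor_scan", "data.frame"),
            n = n, model = "cofactor")
}

#' Per-chromosome scan peaks
#'
#' @param scan a \code{nor_scan}.
#' @param threshold optional \code{nor_threshold}; adds a significance flag.
#' @return data.frame: chrom, cM, lod, significant.
#' @export
find_peaks <- function(scan, threshold = NULL) {
  pieces <- lapply(unique(scan$chrom), function(ch) {
    sc <- scan[scan$chrom == ch, ]
    sc[which.max(sc$lod), ]
  })
  out <- do.call(rbind, pieces)
  out$significant <- if (is.null(threshold)) NA else out$lod > threshold$value
  rownames(out) <- NULL
  out
}
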