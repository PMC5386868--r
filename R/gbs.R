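#' Thresholds for window genotype classification
#'
#' The classification operates on 100-kb windows of SNP calls at sites
#' segregating between the parental accessions. Windows with fewer than
#' \code{min_segregating} segregating SNPs (low parental diversity) or fewer
#' than \code{min_called} calls (poor read support) are discarded. A window
#' is "A" (maternal) or "B" (paternal) when more than
#' \code{homozygous_fraction} of its calls favour that parent; it is "H"
#' (heterozygous) when more than \code{het_fraction} of calls are
#' heterozygous, or when the absolute difference between maternal and
#' paternal call fractions falls below \code{parental_diff_fraction}. All
#' comparisons are strict, and all fractions are of the called-SNP count.
#'
#' @param min_segregating,min_called count thresholds (windows below either
#'   are discarded).
#' @param homozygous_fraction,het_fraction,parental_diff_fraction fractions
#'   in (0, 1).
#' @param window_size_bp window width in bp.
#' @return object of class \code{nor_gbs_thresholds}.
#' @export
genotyper_thresholds <- function(min_segregating = 100, min_called = 40,
                                 homozygous_fraction = 0.90,
                                 het_fraction = 0.25,
                                 parental_diff_fraction = 0.30,
                                 window_size_bp = 1e5) {
  fr <- c(homozygous_fraction, het_fraction, parental_diff_fraction)
  if (any(fr <= 0 | fr >= 1)) stop("fractions must lie in (0, 1)")
  if (min_segregating <= 0 || min_called <= 0) stop("counts must be positive")
  structure(list(min_segregating = min_segregating, min_called = min_called,
                 homozygous_fraction = homozygous_fraction,
                 het_fraction = het_fraction,
                 parental_diff_fraction = parental_diff_fraction,
                 window_size_bp = window_size_bp),
            class = "nor_gbs_thresholds")
}

validate_window_counts <- function(ws) {
  cnt <- c(ws$n_segregating, ws$n_called, ws$n_maternal, ws$n_paternal,
           ws$n_het)
  if (any(cnt < 0)) stop("window counts must be >= 0")
  if (any(ws$n_maternal + ws$n_paternal + ws$n_het > ws$n_called))
    stop("class counts exceed n_called")
  if (any(ws$n_called > ws$n_segregating))
    stop("n_called exceeds n_segregating")
  invisible(TRUE)
}

#' Classify window call summaries into A/B/H genotypes
#'
#' Vectorized over the rows of a WindowCallSummary table. Windows failing
#' the segregating-SNP or called-SNP minimum are NA; otherwise "A" when the
#' maternal call fraction strictly exceeds the homozygous threshold, "B"
#' likewise for paternal, then "H" when the heterozygous fraction strictly
#' exceeds its threshold or the absolute maternal-paternal difference falls
#' strictly below the parental-difference threshold; NA when no rule fires.
#' A/B are tested before H.
#'
#' @param ws data.frame with n_segregating, n_called, n_maternal,
#'   n_paternal, n_het.
#' @param thresholds a \code{\link{genotyper_thresholds}}.
#' @return character vector of "A", "B", "H" or NA, one per row.
#' @export
call_windows <- function(ws, thresholds = genotyper_thresholds()) {
  t <- thresholds
  validate_window_counts(ws)
  n <- ws$n_called
  keep <- ws$n_segregating >= t$min_segregating & n >= t$min_called
  fm <- ifelse(n > 0, ws$n_maternal / n, 0)
  fp <- ifelse(n > 0, ws$n_paternal / n, 0)
  fh <- ifelse(n > 0, ws$n_het / n, 0)
  fd <- ifelse(n > 0, abs(ws$n_maternal - ws$n_paternal) / n, 0)
  call <- rep(NA_character_, nrow(ws))
  is_a <- keep & fm > t$homozygous_fraction
  is_b <- keep & !is_a & fp > t$homozygous_fraction
  is_h <- keep & !is_a & !is_b &
    (fh > t$het_fraction | fd < t$parental_diff_fraction)
  call[is_a] <- "A"
  call[is_b] <- "B"
  call[is_h] <- "H"
  call
}

#' Classify a single window
#'
#' Scalar convenience wrapper around \code{\link{call_windows}}.
#'
#' @param n_segregating,n_called,n_maternal,n_paternal,n_het window counts.
#' @param thresholds a \code{\link{genotyper_thresholds}}.
#' @return "A", "B", "H" or NA.
#' @export
call_window <- function(n_segregating, n_called, n_maternal, n_paternal,
                        n_het, thresholds = genotyper_thresholds()) {
  call_windows(data.frame(n_segregating = n_segregating, n_called = n_called,
                          n_maternal = n_maternal, n_paternal = n_paternal,
                          n_het = n_het), thresholds)
}

#' Assemble per-sample window genotypes into a matrix
#'
#' Requires a consistent (chrom, window_index) grid across samples; applies
#' \code{\link{call_windows}} to every row and reshapes to a samples x
#' windows character matrix. No imputation is applied.
#'
#' @param summaries WindowCallSummary data.frame for all samples.
#' @param thresholds a \code{\link{genotyper_thresholds}}.
#' @return object of class \code{nor_geno_matrix}: list with \code{calls}
#'   (character matrix, rownames = samples), \code{windows} (data.frame
#'   chrom, window_index, call_rate), \code{samples}.
#' @export
genotype_population <- function(summaries,
                                thresholds = genotyper_thresholds()) {
  if (nrow(summaries) == 0) {
    return(structure(list(calls = matrix(character(0), 0, 0),
                          windows = data.frame(chrom = character(0),
                                               window_index = integer(0),
                                               call_rate = numeric(0)),
                          samples = character(0)),
                     class = "nor_geno_matrix"))
  }
  samples <- unique(summaries$sample_id)
  key <- paste(summaries$chrom, summaries$window_index, sep = ":")
  wkeys <- unique(key[summaries$sample_id == samples[1L]])
  per_sample <- split(key, summaries$sample_id)
  if (!all(vapply(per_sample, function(k) identical(sort(k), sort(wkeys)),
                  logical(1))))
    stop("inconsistent window grids across samples")

  calls <- call_windows(summaries, thresholds)
  m <- matrix(NA_character_, nrow = length(samples), ncol = length(wkeys),
              dimnames = list(samples, wkeys))
  m[cbind(match(summaries$sample_id, samples), match(key, wkeys))] <- calls

  first <- summaries[summaries$sample_id == samples[1L], ]
  ord <- order(match(first$chrom, unique(summaries$chrom)),
               first$window_index)
  wkeys_ord <- paste(first$chrom, first$window_index, sep = ":")[ord]
  m <- m[, wkeys_ord, drop = FALSE]
  windows <- data.frame(chrom = first$chrom[ord],
                        window_index = first$window_index[ord],
                        call_rate = colMeans(!is.na(m)))
  structure(list(calls = m, windows = windows, samples = samples),
            class = "nor_geno_matrix")
}

#' @export
print.nor_geno_matrix <- function(x, ...) {
  cat("<nor_geno_matrix>", length(x$samples), "samples x",
      nrow(x$windows), "windows\n")
  invisible(x)
}

#' Aggregate VCF genotype calls into window call summaries
#'
#' Reads a VCF of per-sample genotype calls made at sites known to
#' segregate between the parental accessions, classifies every called
#' genotype as maternal-homozygous, paternal-homozygous or heterozygous
#' according to the parental allele map, and aggregates counts per 100-kb
#' window (0-based, half-open on POS-1). Missing genotypes (./.) are not
#' counted as called; VCF sites absent from the parental map are ignored;
#' sites whose VCF alleles do not match the map are skipped and counted in
#' the \code{"skipped_sites"} attribute. The per-window segregating-SNP
#' count comes from the parental map itself.
#'
#' @param vcf_path path to a VCF (v4.x) file.
#' @param parental_map data.frame: chrom, pos (1-based),
#'   maternal_allele, paternal_allele.
#' @param window_size_bp window width in bp.
#' @return WindowCallSummary data.frame as from
#'   \code{\link{simulate_window_calls}}.
#' @export
ingest_vcf <- function(vcf_path, parental_map, window_size_bp = 1e5) {
  need <- c("chrom", "pos", "maternal_allele", "paternal_allele")
  stopifnot(all(need %in% names(parental_map)))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  samples <- colnames(gt)

  site_key <- paste(fix$CHROM, fix$POS)
  map_key <- paste(parental_map$chrom, parental_map$pos)
  mi <- match(site_key, map_key)
  usable <- !is.na(mi)
  skipped <- 0L

  # which GT allele index (0 = REF, 1 = ALT) is the maternal allele
  mat_idx <- rep(NA_integer_, nrow(fix))
  for (j in which(usable)) {
    mm <- parental_map[mi[j], ]
    ref <- fix$REF[j]; alt <- fix$ALT[j]
    if (ref == mm$maternal_allele && alt == mm$paternal_allele) {
      mat_idx[j] <- 0L
    } else if (ref == mm$paternal_allele && alt == mm$maternal_allele) {
      mat_idx[j] <- 1L
    } else {
      skipped <- skipped + 1L
      usable[j] <- FALSE
    }
  }
  if (skipped > 0)
    warning(skipped, " site(s) with alleles not in the parental map skipped")

  # segregating-site count per window from the parental map
  wmap <- data.frame(chrom = parental_map$chrom,
                     window_index = (parental_map$pos - 1) %/% window_size_bp)
  seg <- stats::aggregate(rep(1L, nrow(wmap)),
                          by = list(chrom = wmap$chrom,
                                    window_index = wmap$window_index),
                          FUN = sum)
  names(seg)[3] <- "n_segregating"

  widx <- (as.numeric(fix$POS) - 1) %/% window_size_bp
  out <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    g <- gt[, s]
    called <- usable & !is.na(g) & !grepl("\\.", g)
    alle <- strsplit(gsub("\\|", "/", g[called]), "/", fixed = TRUE)
    a1 <- as.integer(vapply(alle, `[`, "", 1L))
    a2 <- as.integer(vapply(alle, `[`, "", 2L))
    n_mat_allele <- (a1 == mat_idx[called]) + (a2 == mat_idx[called])
    cls <- ifelse(n_mat_allele == 2L, "mat",
                  ifelse(n_mat_allele == 0L, "pat", "het"))
    df <- data.frame(chrom = fix$CHROM[called], window_index = widx[called],
                     cls = cls, stringsAsFactors = FALSE)
    segkey <- paste(seg$chrom, seg$window_index)
    count_cls <- function(cl) {
      sub <- df[df$cls == cl, , drop = FALSE]
      if (!nrow(sub)) return(rep(0L, nrow(seg)))
      t <- tapply(rep(1L, nrow(sub)),
                  paste(sub$chrom, sub$window_index), sum)
      v <- t[segkey]
      as.integer(ifelse(is.na(v), 0L, v))
    }
    n_mat <- count_cls("mat")
    n_pat <- count_cls("pat")
    n_het <- count_cls("het")
    out[[s]] <- data.frame(sample_id = samples[s], chrom = seg$chrom,
                           window_index = seg$window_index,
                           n_segregating = seg$n_segregating,
                           n_called = n_mat + n_pat + n_het,
                           n_maternal = n_mat, n_paternal = n_pat,
                           n_het = n_het, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "skipped_sites") <- skipped
  res[order(res$sample_id, res$chrom, res$window_index), ]
}
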