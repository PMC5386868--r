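#' Estimate rRNA gene copy number from sequencing depth
#'
#' Copies per haploid genome are estimated as the ratio of the mean per-base
#' depth over the annotated 18S interval of the rRNA reference unit to the
#' mean depth over the first 10 Mb of chromosome 3 (a region free of
#' centromeres and of 5S/45S arrays). The estimator is scale-invariant in
#' overall sequencing effort: multiplying both means by any positive
#' constant leaves it unchanged.
#'
#' @param cov data.frame with columns sample_id, mean18S, meanBaseline.
#' @return data.frame (CopyNumberEstimate): sample_id, value, method,
#'   standardized.
#' @examples
#' estimate_ngs(data.frame(sample_id = "s1", mean18S = 1500, meanBaseline = 1))
#' @export
estimate_ngs <- function(cov) {
  stopifnot(all(c("sample_id", "mean18S", "meanBaseline") %in% names(cov)))
  if (any(cov$mean18S < 0) || any(cov$meanBaseline < 0))
    stop("coverage means must be >= 0")
  bad <- cov$meanBaseline <= 0
  if (any(bad))
    stop("baseline coverage is zero for sample(s): ",
         paste(cov$sample_id[bad], collapse = ", "))
  data.frame(sample_id = cov$sample_id,
             value = cov$mean18S / cov$meanBaseline,
             method = "NGS", standardized = FALSE,
             stringsAsFactors = FALSE)
}

#' Compute coverage summaries from a per-base depth table
#'
#' Means include zero-depth bases: the denominator is the full interval
#' length, and positions absent from the table count as depth 0. Positions
#' are 1-based; the baseline interval is 0-based half-open in bp.
#'
#' @param depth data.frame with columns chrom, pos (1-based), depth.
#' @param sample_id sample identifier for the output row.
#' @param unit_chrom name of the rRNA reference-unit sequence.
#' @param subunit_interval 1-based inclusive coordinates of the 18S subunit
#'   on the reference unit.
#' @param baseline_chrom,baseline_interval baseline region (bp, half-open).
#' @return one-row data.frame: sample_id, mean18S, meanBaseline.
#' @export
coverage_from_depth <- function(depth, sample_id,
                                unit_chrom = "rDNA_unit",
                                subunit_interval = c(2195, 4002),
                                baseline_chrom = "chr3",
                                baseline_interval = c(0, 1e7)) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)))
  in18 <- depth$chrom == unit_chrom &
    depth$pos >= subunit_interval[1] & depth$pos <= subunit_interval[2]
  len18 <- subunit_interval[2] - subunit_interval[1] + 1
  inb <- depth$chrom == baseline_chrom &
    depth$pos > baseline_interval[1] & depth$pos <= baseline_interval[2]
  lenb <- baseline_interval[2] - baseline_interval[1]
  data.frame(sample_id = sample_id,
             mean18S = sum(depth$depth[in18]) / len18,
             meanBaseline = sum(depth$depth[inb]) / lenb)
}

#' Estimate relative rRNA gene abundance from qPCR threshold cycles
#'
#' Relative copy number is \code{2^(Ct(ACT2) - Ct(18S))}: each cycle by
#' which the 18S amplicon crosses threshold earlier than the single-copy
#' ACT2 (At3g18780) reference doubles the estimated abundance. Depends only
#' on the Ct difference, so additive shifts common to both targets cancel.
#'
#' @param ct_18s,ct_act2 mean threshold cycles (vectorized).
#' @return numeric vector of relative copy numbers.
#' @examples
#' estimate_qpcr(15, 25) # 2^10 = 1024
#' @export
estimate_qpcr <- function(ct_18s, ct_act2) {
  if (any(!is.finite(ct_18s)) || any(!is.finite(ct_act2)))
    stop("Ct means must be finite")
  2^(ct_act2 - ct_18s)
}

#' Build a per-plate estimate table from raw Ct records
#'
#' Averages technical replicates per (sample, plate, target) and applies the
#' delta-Ct formula, giving one raw estimate per sample per plate.
#'
#' @param ct_records data.frame: sample_id, plate_id, target ("18S"/"ACT2"),
#'   replicate, ct.
#' @return data.frame (PlateTable): sample_id, plate_id, value.
#' @export
qpcr_estimates <- function(ct_records) {
  need <- c("sample_id", "plate_id", "target", "ct")
  stopifnot(all(need %in% names(ct_records)))
  if (any(ct_records$ct <= 0)) stop("ct values must be > 0")
  agg <- stats::aggregate(ct ~ sample_id + plate_id + target,
                          data = ct_records, FUN = mean)
  w18 <- agg[agg$target == "18S", c("sample_id", "plate_id", "ct")]
  wa <- agg[agg$target == "ACT2", c("sample_id", "plate_id", "ct")]
  m <- merge(w18, wa, by = c("sample_id", "plate_id"),
             suffixes = c("_18s", "_act2"))
  if (nrow(m) < max(nrow(w18), nrow(wa)))
    stop("missing replicate group: every (sample, plate) needs both targets")
  out <- data.frame(sample_id = m$sample_id, plate_id = m$plate_id,
                    value = estimate_qpcr(m$ct_18s, m$ct_act2),
                    stringsAsFactors = FALSE)
  out[order(out$plate_id, out$sample_id), , drop = FALSE]
}

#' Standardize per-plate estimates across plates
#'
#' Two schemes. \code{control}: a common DNA control present on every plate
#' anchors the plates - each plate's values are divided by that plate's
#' control estimate over the grand mean of the control across plates, which
#' leaves the control's own corrected values equal everywhere.
#' \code{regression}: multiplicative per-plate factors are fitted by least
#' squares on the log2 scale (model log2(value) = sample effect + plate
#' factor) using samples replicated across plates as links; the first plate
#' is the reference (factor 1). Plates with no replicate links to the rest
#' make the design singular and raise an error.
#'
#' @param plate_table data.frame: sample_id, plate_id, value.
#' @param mode "control" or "regression".
#' @param control_sample sample_id of the common control (control mode).
#' @return data.frame like the input with corrected values and a
#'   \code{standardized = TRUE} column; fitted per-plate factors are
#'   attached as attribute \code{"plate_factors"}.
#' @export
standardize_plates <- function(plate_table,
                               mode = c("control", "regression"),
                               control_sample = "control") {
  mode <- match.arg(mode)
  stopifnot(all(c("sample_id", "plate_id", "value") %in% names(plate_table)))
  plates <- unique(plate_table$plate_id)

  if (mode == "control") {
    ctrl <- plate_table[plate_table$sample_id == control_sample, ]
    if (!all(plates %in% ctrl$plate_id))
      stop("control sample '", control_sample, "' missing from plate(s): ",
           paste(setdiff(plates, ctrl$plate_id), collapse = ", "))
    ctrl_val <- tapply(ctrl$value, ctrl$plate_id, mean)
    factors <- ctrl_val / mean(ctrl_val)
  } else {
    # connectivity: every plate must share at least one sample with another
    tab <- table(plate_table$sample_id, plate_table$plate_id) > 0
    linked <- rownames(tab)[rowSums(tab) >= 2]
    if (length(linked) < 1)
      stop("singular design: need cross-plate technical replicate pairs")
    reach <- plates[1L]
    repeat {
      more <- unique(unlist(lapply(linked, function(s) {
        p <- colnames(tab)[tab[s, ]]
        if (any(p %in% reach)) p else NULL
      })))
      new <- setdiff(more, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    if (!all(plates %in% reach))
      stop("singular design: plate(s) with no replicate links to the rest: ",
           paste(setdiff(plates, reach), collapse = ", "))
    df <- plate_table
    df$sample_id <- factor(df$sample_id)
    df$plate_id <- factor(df$plate_id, levels = plates)
    fit <- stats::lm(log2(value) ~ 0 + sample_id + plate_id, data = df)
    cf <- stats::coef(fit)
    pf <- cf[paste0("plate_id", plates)]
    pf[is.na(pf)] <- 0 # reference plate absorbed into sample effects
    factors <- 2^pf
    names(factors) <- plates
  }

  out <- plate_table
  out$value <- as.numeric(out$value /
                            factors[match(out$plate_id, names(factors))])
  out$standardized <- TRUE
  attr(out, "plate_factors") <- factors
  out
}

#' Average corrected plate estimates to one value per sample
#'
#' @param plate_table output of \code{\link{standardize_plates}} (or a raw
#'   plate table).
#' @return data.frame: sample_id, value, n_plates.
#' @export
aggregate_estimates <- function(plate_table) {
  agg <- stats::aggregate(value ~ sample_id, data = plate_table, FUN = mean)
  n <- stats::aggregate(value ~ sample_id, data = plate_table, FUN = length)
  data.frame(sample_id = agg$sample_id, value = agg$value,
             n_plates = n$value, stringsAsFactors = FALSE)
}

#' FISH signal-area ratio
#'
#' Ratio of two fluorescence signal areas (pixel counts), reported at the
#' two-decimal precision used for cytology figures: the quotient is
#' truncated toward zero at the second decimal, matching how such ratios
#' are conventionally printed (e.g. 299.64/125.27 -> 2.39 and
#' 106.5/71.17 -> 1.49).
#'
#' @param area_a,area_b signal areas in pixels; \code{area_b} must be > 0.
#' @return numeric ratio with two decimals.
#' @examples
#' signal_ratio(299.64, 125.27)
#' @export
signal_ratio <- function(area_a, area_b) {
  if (any(area_b <= 0)) stop("area_b must be > 0")
  if (any(area_a < 0)) stop("area_a must be >= 0")
  trunc(area_a / area_b * 100 + 1e-9) / 100
}
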