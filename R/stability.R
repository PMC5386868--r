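#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Model: value = fixed effects + replicate random intercept + residual,
#' with replicates nested within lines (one random intercept per
#' line:replicate combination). The likelihood is maximized by profiling
#' the fixed effects and the residual variance out analytically and
#' optimizing the variance ratio lambda = sigma2_rep / sigma2_e in one
#' dimension: a bracketing grid on log10(lambda), refined by
#' golden-section search (\code{stats::optimize}) to tolerance 1e-8.
#' Likelihoods are full ML (not REML) so that fits with different fixed
#' structures are comparable in likelihood-ratio tests.
#'
#' @param data data.frame with columns \code{line}, \code{generation},
#'   \code{replicate}, \code{value}.
#' @param fixed character vector of fixed-effect terms (columns of
#'   \code{data}, modeled as factors); may be empty for an intercept-only
#'   model.
#' @return object of class \code{nor_lmm}: loglik, beta, sigma2_e,
#'   sigma2_rep, lambda, p (fixed-effect parameter count), n, fixed.
#' @export
fit_lmm <- function(data, fixed = c("line", "generation")) {
  need <- c("line", "generation", "replicate", "value")
  stopifnot(all(need %in% names(data)))
  y <- data$value
  n <- length(y)
  for (f in fixed)
    if (length(unique(data[[f]])) < 2)
      stop("fixed term '", f, "' has a single level: inestimable")
  grp <- interaction(data$line, data$replicate, drop = TRUE)
  if (!any(table(grp) >= 2))
    stop("need at least one replicate with >= 2 observations")

  fd <- data
  for (f in fixed) fd[[f]] <- factor(fd[[f]])
  X <- stats::model.matrix(
    if (length(fixed)) stats::reformulate(fixed) else ~1, data = fd)
  p <- ncol(X)

  # per-group sufficient statistics
  gi <- split(seq_len(n), grp)
  ng <- lengths(gi)
  M1 <- vapply(gi, function(ii) colSums(X[ii, , drop = FALSE]), numeric(p))
  y1 <- vapply(gi, function(ii) sum(y[ii]), numeric(1))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  profile_ll <- function(lambda) {
    cg <- lambda / (1 + ng * lambda)
    XtVX <- XtX - M1 %*% (cg * t(M1))
    XtVy <- Xty - M1 %*% (cg * y1)
    yVy <- yty - sum(cg * y1^2)
    beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf))
    rss <- max(yVy - sum(beta * XtVy), .Machine$double.eps)
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log1p(ng * lambda)) + n)
    list(ll = ll, beta = beta, s2 = s2)
  }

  grid <- c(0, 10^seq(-6, 6, by = 0.25))
  ll_grid <- vapply(grid, function(l) profile_ll(l)$ll, numeric(1))
  b <- which.max(ll_grid)
  if (b == 1L || b == 2L) {
    opt <- stats::optimize(function(lg) profile_ll(10^lg)$ll,
                           c(-9, log10(grid[3L])), maximum = TRUE,
                           tol = 1e-8)
    lambda <- if (ll_grid[1L] >= opt$objective) 0 else 10^opt$maximum
  } else {
    lo <- log10(grid[b - 1L])
    hi <- log10(grid[min(b + 1L, length(grid))])
    opt <- stats::optimize(function(lg) profile_ll(10^lg)$ll, c(lo, hi),
                           maximum = TRUE, tol = 1e-8)
    lambda <- 10^opt$maximum
  }
  fit <- profile_ll(lambda)
  structure(list(loglik = fit$ll, beta = drop(fit$beta),
                 sigma2_e = fit$s2, sigma2_rep = lambda * fit$s2,
                 lambda = lambda, p = p, n = n, fixed = fixed),
            class = "nor_lmm")
}

#' @export
print.nor_lmm <- function(x, ...) {
  cat(sprintf(
    "<nor_lmm> fixed: %s | logLik %.4f | sigma2_rep %.4g | sigma2_e %.4g\n",
    if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "(intercept)",
    x$loglik, x$sigma2_rep, x$sigma2_e))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' chi-square = 2 (logLik_full - logLik_reduced), floored at 0; degrees of
#' freedom are the difference in fixed-effect parameter counts of the two
#' design matrices; the p-value is the upper tail of the corresponding
#' chi-square distribution. Both fits must be ML fits of nested fixed
#' structures on the same data.
#'
#' @param full,reduced \code{nor_lmm} fits.
#' @return object of class \code{nor_lrt}: chi_square, df, p_value.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "nor_lmm"), inherits(reduced, "nor_lmm"))
  if (!all(reduced$fixed %in% full$fixed))
    stop("models are not nested: reduced terms must be a subset of full")
  if (full$n != reduced$n) stop("fits use different data")
  chi <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$p - reduced$p
  if (df < 0) stop("models are not nested: reduced has more parameters")
  p <- if (df == 0) as.numeric(chi <= 1e-8) else
    stats::pchisq(chi, df, lower.tail = FALSE)
  structure(list(chi_square = chi, df = df, p_value = p),
            class = "nor_lrt")
}

#' @export
print.nor_lrt <- function(x, ...) {
  cat(sprintf("<nor_lrt> chi^2(%d) = %.4g, p = %.4g\n",
              x$df, x$chi_square, x$p_value))
  invisible(x)
}

#' Coefficient of variation of copy number by generations since divergence
#'
#' For sets of individuals sharing the same genotypes at both NOR loci,
#' computes per group, generation (and method) the coefficient of variation
#' CV = sample sd (n-1 denominator) / mean of the copy-number values.
#' Groups with fewer than two values are dropped; a zero mean yields NA
#' with a warning.
#'
#' @param data data.frame with columns \code{group},
#'   \code{generation}, \code{value} and optionally \code{method}.
#' @return data.frame (CVSeries): group, generation, method, cv, n.
#' @export
cv_by_generation <- function(data) {
  stopifnot(all(c("group", "generation", "value") %in% names(data)))
  if (is.null(data$method)) data$method <- "NGS"
  keys <- interaction(data$group, data$generation, data$method, drop = TRUE)
  pieces <- lapply(split(data, keys), function(d) {
    if (nrow(d) < 2) return(NULL)
    m <- mean(d$value)
    cv <- if (m == 0) NA_real_ else stats::sd(d$value) / m
    data.frame(group = d$group[1L], generation = d$generation[1L],
               method = d$method[1L], cv = cv, n = nrow(d))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    stop("every group needs at least 2 values")
  if (anyNA(out$cv)) warning("zero-mean group(s): CV undefined, set to NA")
  rownames(out) <- NULL
  out[order(out$group, out$generation), ]
}

#' Simulate stability records under the mixed-model view
#'
#' Generates copy-number measurements for MA-style lines directly from the
#' random-intercept model: value = baseline + line effect (+ generation
#' effect) + replicate intercept + residual. Used for calibration studies
#' of the likelihood-ratio test where the generating model must match the
#' fitted one exactly.
#'
#' @param n_lines,n_replicates,generations design dimensions; generations
#'   is a vector of generation labels at which every replicate is measured.
#' @param baseline grand mean copy number.
#' @param line_sd,rep_sd,resid_sd standard deviations of the line effects,
#'   replicate intercepts, and residuals.
#' @param generation_effect additive shift per successive generation
#'   (0 = null of the generation test).
#' @return StabilityRecord data.frame: line, generation, replicate, value.
#' @export
simulate_stability_records <- function(n_lines = 10, n_replicates = 5,
                                       generations = c(32, 33),
                                       baseline = 500, line_sd = 75,
                                       rep_sd = 10, resid_sd = 10,
                                       generation_effect = 0) {
  lines <- sprintf("L%02d", seq_len(n_lines))
  le <- stats::rnorm(n_lines, 0, line_sd)
  out <- list()
  for (l in seq_len(n_lines)) for (r in seq_len(n_replicates)) {
    u <- stats::rnorm(1, 0, rep_sd)
    for (gi in seq_along(generations)) {
      out[[length(out) + 1L]] <- data.frame(
        line = lines[l], generation = generations[gi],
        replicate = sprintf("r%02d", r),
        value = baseline + le[l] + generation_effect * (gi - 1L) + u +
          stats::rnorm(1, 0, resid_sd))
    }
  }
  do.call(rbind, out)
}
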