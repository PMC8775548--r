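#' Parametric distribution specification
#'
#' A `dist_spec` describes one of the two families used throughout the risk
#' assessment: a normal distribution (body weight, inhalation rate) or a
#' base-10 log-normal (air concentrations, creatinine-corrected urinary
#' biomarkers). For `"normal"`, `a` is the arithmetic mean and `b` the
#' standard deviation of the variate. For `"lognormal10"`, `a` is the mean
#' and `b` the standard deviation of the base-10 logarithms of the variate,
#' so the variate itself is `10^N(a, b)` and is strictly positive.
#'
#' @param family `"normal"` or `"lognormal10"`.
#' @param a Location parameter (mean on the modelling scale).
#' @param b Scale parameter (standard deviation on the same scale); must be
#'   non-negative.
#' @param unit Free-text unit of the untransformed variate, e.g.
#'   `"ug/m3"`, `"kg"`, `"m3/day"`, `"ug/g crt"`.
#' @param provenance `"configured"` (taken from a parameter table) or
#'   `"fitted"` (estimated from data or quantiles).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal10", 0.321, 0.426, unit = "ug/m3")
#' @export
dist_spec <- function(family = c("normal", "lognormal10"), a, b,
                      unit = "", provenance = c("configured", "fitted")) {
  family <- match.arg(family)
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (b < 0) {
    stop("scale parameter 'b' must be >= 0, got ", b, call. = FALSE)
  }
  structure(
    list(family = family, a = as.numeric(a), b = as.numeric(b),
         unit = as.character(unit), provenance = provenance),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(a = %g, b = %g)%s [%s]\n",
              x$family, x$a, x$b,
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
              x$provenance))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Fit a normal distribution to a set of quantiles
#'
#' Fits mean and standard deviation by ordinary least squares of the observed
#' quantile values on the corresponding standard-normal scores
#' \eqn{\Phi^{-1}(p)} (Q-Q regression). This is exact when the supplied
#' points are true quantiles of a normal distribution, and is how population
#' body-weight and inhalation-rate distributions are derived from the
#' quartiles and medians published in exposure-factor handbooks.
#'
#' @param probabilities Quantile probabilities, distinct values in (0, 1).
#' @param values Observed quantile values, same length.
#' @param unit Unit of the variate.
#' @param sigma_tolerance If the fitted slope (sigma) is negative but its
#'   absolute value is below this tolerance, it is clamped to `abs(sigma)`
#'   with a warning; a larger negative slope is an error (the quantiles are
#'   decreasing and cannot come from a distribution).
#' @return A `dist_spec` with `family = "normal"`, `provenance = "fitted"`.
#' @examples
#' fit_normal_quantiles(c(0.25, 0.5, 0.75),
#'                      61.04 + 12.26 * qnorm(c(0.25, 0.5, 0.75)), unit = "kg")
#' @export
fit_normal_quantiles <- function(probabilities, values, unit = "",
                                 sigma_tolerance = 1e-8) {
  if (length(probabilities) != length(values)) {
    stop("'probabilities' and 'values' must have equal length", call. = FALSE)
  }
  if (length(probabilities) < 2L) {
    stop("at least 2 quantile points are required to fit a normal",
         call. = FALSE)
  }
  if (any(probabilities <= 0 | probabilities >= 1)) {
    stop("quantile probabilities must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (anyDuplicated(probabilities)) {
    stop("quantile probabilities must be distinct", call. = FALSE)
  }
  z <- stats::qnorm(probabilities)
  fit <- stats::lm(values ~ z)
  mu <- unname(stats::coef(fit)[1L])
  sigma <- unname(stats::coef(fit)[2L])
  if (sigma < 0) {
    if (abs(sigma) < sigma_tolerance) {
      warning("fitted sigma slightly negative (", signif(sigma, 3),
              "); clamped to its absolute value", call. = FALSE)
      sigma <- abs(sigma)
    } else {
      stop("fitted sigma is negative (", signif(sigma, 3),
           "): quantile values decrease with probability", call. = FALSE)
    }
  }
  dist_spec("normal", mu, sigma, unit = unit, provenance = "fitted")
}

#' Fit a base-10 log-normal distribution to positive samples
#'
#' Location is the arithmetic mean of `log10(values)`; scale is their sample
#' standard deviation (n - 1 denominator). This is the parameterisation used
#' for measured air concentrations and corrected biomarker levels.
#'
#' @param values Strictly positive sample values, length >= 2.
#' @param unit Unit of the variate.
#' @return A `dist_spec` with `family = "lognormal10"`,
#'   `provenance = "fitted"`.
#' @examples
#' fit_lognormal10(c(1, 10, 100))  # a = 1, b = 1
#' @export
fit_lognormal10 <- function(values, unit = "") {
  if (length(values) < 2L) {
    stop("at least 2 values are required", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    stop("all values must be positive and finite; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  lx <- log10(values)
  dist_spec("lognormal10", mean(lx), stats::sd(lx),
            unit = unit, provenance = "fitted")
}

#' Expected value of a distribution specification
#'
#' Closed-form mean: `a` for a normal; `10^a * exp((ln(10) * b)^2 / 2)` for a
#' base-10 log-normal.
#'
#' @param dist A `dist_spec`.
#' @return The arithmetic mean of the variate, in its own units.
#' @export
dist_mean <- function(dist) {
  stopifnot(is_dist_spec(dist))
  switch(dist$family,
         normal = dist$a,
         lognormal10 = 10^dist$a * exp((log(10) * dist$b)^2 / 2))
}

#' Cumulative distribution function of a distribution specification
#'
#' @param dist A `dist_spec`.
#' @param q Quantile(s) on the variate scale.
#' @return `P(X <= q)`, vectorised over `q`.
#' @export
dist_cdf <- function(dist, q) {
  stopifnot(is_dist_spec(dist))
  if (dist$b == 0) {
    med <- if (dist$family == "normal") dist$a else 10^dist$a
    return(as.numeric(q >= med))
  }
  switch(dist$family,
         normal = stats::pnorm(q, dist$a, dist$b),
         lognormal10 = ifelse(q <= 0, 0,
                              stats::pnorm(log10(pmax(q, .Machine$double.xmin)),
                                           dist$a, dist$b)))
}

#' Analytic exceedance probability P(X > threshold)
#'
#' The upper-tail probability of the modelled exposure exceeding a
#' regulatory threshold (an RfC for air concentrations, a BEI for urinary
#' biomarkers). A degenerate scale (`b = 0`) is handled by direct comparison.
#'
#' @param dist A `dist_spec`.
#' @param threshold Threshold on the variate scale; must be positive for a
#'   log-normal variate.
#' @return A probability in \[0, 1\].
#' @examples
#' # residential benzene vs its reference concentration of 30 ug/m3
#' dist_exceedance(dist_spec("lognormal10", 0.321, 0.426), 30)
#' @export
dist_exceedance <- function(dist, threshold) {
  stopifnot(is_dist_spec(dist), is.numeric(threshold), length(threshold) == 1L)
  if (dist$family == "lognormal10" && threshold <= 0) {
    stop("threshold must be > 0 for a lognormal10 variate", call. = FALSE)
  }
  if (dist$b == 0) {
    point <- if (dist$family == "normal") dist$a else 10^dist$a
    return(as.numeric(point > threshold))
  }
  z <- switch(dist$family,
              normal = (threshold - dist$a) / dist$b,
              lognormal10 = (log10(threshold) - dist$a) / dist$b)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Draw random samples from a distribution specification
#'
#' Log-normal draws are `10^x` for `x ~ N(a, b)`. With
#' `truncate_positive = TRUE`, non-positive normal draws are rejected and
#' redrawn; the number of rejected draws is attached as attribute
#' `"n_rejected"`. Sequences are reproducible for a given `seed`.
#'
#' @param dist A `dist_spec`.
#' @param n Number of draws, >= 1.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @param truncate_positive Reject non-positive normal draws (no effect on
#'   log-normal draws, which are always positive).
#' @param max_rounds Safety cap on rejection rounds.
#' @return Numeric vector of length `n` with attribute `n_rejected`.
#' @export
dist_sample <- function(dist, n, seed = NULL, truncate_positive = FALSE,
                        max_rounds = 100L) {
  stopifnot(is_dist_spec(dist), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_rejected <- 0L
  if (dist$family == "lognormal10") {
    out <- 10^stats::rnorm(n, dist$a, dist$b)
  } else {
    out <- stats::rnorm(n, dist$a, dist$b)
    if (truncate_positive) {
      rounds <- 0L
      while (any(bad <- out <= 0)) {
        rounds <- rounds + 1L
        if (rounds > max_rounds) {
          stop("rejection sampling failed to produce positive draws after ",
               max_rounds, " rounds for ", dist$family,
               "(", dist$a, ", ", dist$b, ")", call. = FALSE)
        }
        n_rejected <- n_rejected + sum(bad)
        out[bad] <- stats::rnorm(sum(bad), dist$a, dist$b)
      }
    }
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' One-sample Kolmogorov-Smirnov statistic
#'
#' The two-sided statistic `D = sup |F_n(x) - F(x)|`, evaluated at both step
#' edges of the empirical CDF at every sample point, against the model CDF of
#' a `dist_spec`. Used to check whether measured concentrations are
#' adequately described by the fitted normal or base-10 log-normal model.
#' The optional p-value uses the asymptotic Kolmogorov distribution
#' `P(sqrt(n) D > x) = 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 x^2)`.
#'
#' @param values Sample values, n >= 1.
#' @param dist A `dist_spec`.
#' @param p_value Also compute the asymptotic p-value.
#' @return A list with `statistic`, `n`, and (if requested) `p_value`.
#' @export
ks_statistic <- function(values, dist, p_value = FALSE) {
  stopifnot(is_dist_spec(dist), length(values) >= 1L)
  n <- length(values)
  x <- sort(values)
  fx <- dist_cdf(dist, x)
  d_plus <- max(seq_len(n) / n - fx)
  d_minus <- max(fx - (seq_len(n) - 1L) / n)
  d <- max(d_plus, d_minus)
  out <- list(statistic = d, n = n)
  if (p_value) {
    x0 <- sqrt(n) * d
    k <- seq_len(100L)
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x0^2))
    out$p_value <- min(1, max(0, p))
  }
  out
}

#' Serialize / deserialize a distribution specification
#'
#' `dist_to_list()` returns the plain-list form used in the packaged JSON
#' configuration (`{"family", "a", "b", "unit", "provenance"}`);
#' `dist_from_list()` inverts it exactly (the round trip preserves family and
#' both parameters bit-for-bit).
#'
#' @param dist A `dist_spec`.
#' @param x A list with fields `family`, `a`, `b` and optionally `unit`,
#'   `provenance`.
#' @return A list, or a `dist_spec`.
#' @export
dist_to_list <- function(dist) {
  stopifnot(is_dist_spec(dist))
  list(family = dist$family, a = dist$a, b = dist$b,
       unit = dist$unit, provenance = dist$provenance)
}

#' @rdname dist_to_list
#' @export
dist_from_list <- function(x) {
  dist_spec(x$family, x$a, x$b,
            unit = if (is.null(x$unit)) "" else x$unit,
            provenance = if (is.null(x$provenance)) "configured"
                         else x$provenance)
}
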