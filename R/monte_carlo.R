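#' Monte Carlo configuration
#'
#' @param n_iterations Number of iterations (default 10,000).
#' @param seed Integer seed; every simulation is reproducible given the seed.
#' @param risk_lines Ascending positive LCR thresholds whose exceedance
#'   fractions are reported; defaults to the US EPA conventions of 1e-6
#'   (acceptable) and 1e-4 (serious).
#' @param truncate_positive Reject non-positive normal IR/BW draws.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 10000L, seed = 1L,
                      risk_lines = c(acceptable = 1e-6, serious = 1e-4),
                      truncate_positive = TRUE) {
  stopifnot(n_iterations >= 1, all(risk_lines > 0),
            !is.unsorted(risk_lines, strictly = TRUE))
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 risk_lines = risk_lines,
                 truncate_positive = isTRUE(truncate_positive)),
            class = "mc_config")
}

draw_component <- function(x, n, truncate_positive) {
  if (is_dist_spec(x)) {
    dist_sample(x, n, seed = NULL, truncate_positive = truncate_positive)
  } else {
    rep(as.numeric(x), n)
  }
}

#' Monte Carlo simulation of lifetime cancer risk
#'
#' Propagates the concentration, inhalation-rate and body-weight
#' distributions through `LCR = SF x C x IR x EF x ED / (BW x AT) x 1e-3`,
#' drawing the three variates independently at each iteration. Returns the
#' mean, requested percentiles, the fraction of iterations exceeding each
#' configured risk line, and Spearman rank correlations of each sampled
#' parameter with the simulated LCR (the sensitivity ranking).
#'
#' @param conc_dist [dist_spec] for the air concentration (ug/m3).
#' @param scenario [exposure_scenario]; `ir` and `bw` are typically
#'   `dist_spec`s (fixed values are also accepted and held constant).
#' @param sf Cancer slope factor, >= 0.
#' @param cfg An [mc_config].
#' @param percentiles Probabilities of the reported percentiles.
#' @param keep_draws Attach the per-iteration LCR vector (`$draws`).
#' @return An object of class `lcr_summary`: list with `group_label`,
#'   `mean`, `percentiles`, `exceedance`, `sensitivity`, `n_iterations`,
#'   `seed`, `n_rejected`.
#' @examples
#' male <- exposure_scenario(ir = dist_spec("normal", 17.02, 2.96),
#'                           bw = dist_spec("normal", 61.04, 12.26),
#'                           group_label = "male")
#' simulate_lcr(dist_spec("lognormal10", 0.321, 0.426), male, sf = 0.029,
#'              cfg = mc_config(n_iterations = 1000, seed = 42))$mean
#' @export
simulate_lcr <- function(conc_dist, scenario, sf,
                         cfg = mc_config(),
                         percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                         keep_draws = FALSE) {
  stopifnot(is_dist_spec(conc_dist),
            inherits(scenario, "exposure_scenario"),
            inherits(cfg, "mc_config"), sf >= 0)
  set.seed(cfg$seed)
  n <- cfg$n_iterations
  conc <- dist_sample(conc_dist, n, seed = NULL,
                      truncate_positive = cfg$truncate_positive)
  ir <- draw_component(scenario$ir, n, cfg$truncate_positive)
  bw <- draw_component(scenario$bw, n, cfg$truncate_positive)
  n_rejected <- sum(attr(conc, "n_rejected") %||% 0L,
                    attr(ir, "n_rejected") %||% 0L,
                    attr(bw, "n_rejected") %||% 0L)
  k <- 1e-3 * scenario$ef * scenario$ed / scenario$at
  lcr <- sf * k * as.numeric(conc) * as.numeric(ir) / as.numeric(bw)
  draws <- cbind(concentration = as.numeric(conc), ir = as.numeric(ir),
                 bw = as.numeric(bw))
  pct <- stats::quantile(lcr, probs = percentiles, names = FALSE)
  names(pct) <- paste0("p", formatC(100 * percentiles, format = "fg"))
  exc <- vapply(cfg$risk_lines, function(line) mean(lcr > line), numeric(1))
  out <- list(group_label = scenario$group_label,
              mean = mean(lcr),
              percentiles = pct,
              exceedance = exc,
              risk_lines = cfg$risk_lines,
              sensitivity = sensitivity_ranks(draws, lcr),
              n_iterations = n,
              seed = cfg$seed,
              n_rejected = n_rejected)
  if (keep_draws) out$draws <- lcr
  structure(out, class = "lcr_summary")
}

#' @export
print.lcr_summary <- function(x, ...) {
  cat(sprintf("<lcr_summary> %s: mean LCR = %.3g (n = %d, seed = %d)\n",
              if (nzchar(x$group_label)) x$group_label else "(unnamed)",
              x$mean, x$n_iterations, x$seed))
  cat("  exceedance:",
      paste(sprintf("P(>%.0e) = %.3g", x$risk_lines, x$exceedance),
            collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic mean lifetime cancer risk (deterministic oracle)
#'
#' Under independence of C, IR and BW,
#' `E[LCR] = SF x k x E[C] x E[IR] x E[1/BW]` with
#' `k = 1e-3 x EF x ED / AT`. `E[C]` uses the closed-form log-normal mean;
#' `E[IR]` and `E[1/BW]` are taken over the positively-truncated normal
#' (truncated mean in closed form, `E[1/BW]` by adaptive quadrature). For
#' degenerate inputs this collapses exactly to the deterministic
#' CDI-then-LCR path.
#'
#' @inheritParams simulate_lcr
#' @return The expected LCR, a single number.
#' @export
analytic_mean_lcr <- function(conc_dist, scenario, sf) {
  stopifnot(is_dist_spec(conc_dist),
            inherits(scenario, "exposure_scenario"), sf >= 0)
  trunc_mean <- function(x) {
    if (!is_dist_spec(x)) return(as.numeric(x))
    if (x$b == 0 || x$family == "lognormal10") return(dist_mean(x))
    a <- -x$a / x$b
    x$a + x$b * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  }
  mean_inverse <- function(x) {
    if (!is_dist_spec(x)) return(1 / as.numeric(x))
    if (x$b == 0) {
      point <- if (x$family == "normal") x$a else 10^x$a
      return(1 / point)
    }
    if (x$family == "lognormal10") {
      # 1/X is lognormal10(-a, b)
      return(dist_mean(dist_spec("lognormal10", -x$a, x$b)))
    }
    zc <- stats::pnorm(0, x$a, x$b, lower.tail = FALSE)
    stats::integrate(function(v) stats::dnorm(v, x$a, x$b) / v,
                     lower = .Machine$double.eps^0.5, upper = Inf,
                     rel.tol = 1e-10)$value / zc
  }
  k <- 1e-3 * scenario$ef * scenario$ed / scenario$at
  sf * k * dist_mean(conc_dist) * trunc_mean(scenario$ir) *
    mean_inverse(scenario$bw)
}

#' Spearman sensitivity ranks of Monte Carlo parameters
#'
#' Spearman rank correlation (Pearson correlation of average ranks) of each
#' sampled parameter with the per-iteration LCR. A constant column cannot be
#' ranked against the output; its correlation is reported as 0 and its name
#' is returned in the `"constant"` attribute.
#'
#' @param draws Numeric matrix, one column per parameter, one row per
#'   iteration.
#' @param lcr Per-iteration LCR vector, same number of rows.
#' @return Named numeric vector of rank correlations, with attribute
#'   `constant` naming any flagged columns.
#' @export
sensitivity_ranks <- function(draws, lcr) {
  draws <- as.matrix(draws)
  stopifnot(nrow(draws) == length(lcr), nrow(draws) >= 10L)
  rl <- rank(lcr)
  flagged <- character()
  rho <- vapply(seq_len(ncol(draws)), function(j) {
    col <- draws[, j]
    if (stats::var(col) == 0 || stats::var(lcr) == 0) {
      flagged <<- c(flagged, colnames(draws)[j] %||% as.character(j))
      return(0)
    }
    stats::cor(rank(col), rl)
  }, numeric(1))
  names(rho) <- colnames(draws)
  attr(rho, "constant") <- flagged
  rho
}
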