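# Shared fixtures and independent oracles used across the suite.

study_cfg <- function() default_study_config()

# Independent ray-casting point-in-polygon oracle (crossing count), kept
# deliberately separate from the package's winding-number implementation.
raycast_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  # boundary counts as inside (package convention)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i])
    if (abs(cross) < 1e-12 &&
        px >= min(vx[i], vx[j]) - 1e-12 && px <= max(vx[i], vx[j]) + 1e-12 &&
        py >= min(vy[i], vy[j]) - 1e-12 && py <= max(vy[i], vy[j]) + 1e-12) {
      return(TRUE)
    }
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((vy[i] > py) != (vy[j] > py)) {
      x_int <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < x_int) inside <- !inside
    }
  }
  inside
}

# same planar embedding the package uses, recomputed independently
ternary_xy <- function(b, t, e) {
  s <- b + t + e
  c(x = (t + 0.5 * e) / s, y = (sqrt(3) / 2) * e / s)
}

# one-line deterministic LCR oracle: sf * k * c * ir / bw
lcr_oracle <- function(c, ir, bw, ef, ed, at, sf) {
  sf * (c * 1e-3 * ir * ef * ed / (bw * at))
}

# moment-matched lognormal approximation of P(LCR > line) under the product
# model LCR = sf * k * C * IR * (1/BW), all factors independent
lognormal_product_exceedance <- function(conc, ir, bw, sf, ef, ed, at, line) {
  ln_match <- function(m, v) {
    s2 <- log(1 + v / m^2)
    c(mu = log(m) - s2 / 2, s2 = s2)
  }
  trunc_m <- function(mu, s) {
    a <- -mu / s
    mu + s * dnorm(a) / (1 - pnorm(a))
  }
  trunc_v <- function(mu, s) {
    a <- -mu / s
    lam <- dnorm(a) / (1 - pnorm(a))
    s^2 * (1 + a * lam - lam^2)
  }
  inv_moment <- function(mu, s, p) {
    zc <- 1 - pnorm(0, mu, s)
    lo <- max(0.5, mu - 10 * s)
    integrate(function(x) dnorm(x, mu, s) / x^p, lo, Inf,
              rel.tol = 1e-10)$value / zc
  }
  k <- 1e-3 * ef * ed / at
  m_c <- 10^conc$a * exp((log(10) * conc$b)^2 / 2)
  v_c <- m_c^2 * (exp((log(10) * conc$b)^2) - 1)
  lc <- ln_match(m_c, v_c)
  li <- ln_match(trunc_m(ir$a, ir$b), trunc_v(ir$a, ir$b))
  m_inv <- inv_moment(bw$a, bw$b, 1)
  lb <- ln_match(m_inv, inv_moment(bw$a, bw$b, 2) - m_inv^2)
  mu <- log(sf * k) + lc["mu"] + li["mu"] + lb["mu"]
  s <- sqrt(lc["s2"] + li["s2"] + lb["s2"])
  unname(1 - pnorm((log(line) - mu) / s))
}
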