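# Shared helpers for cross-validation against independent numerical routes.

# trapezoidal rule (kept local so tests do not depend on package internals)
trapz_ <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# plain bisection root finder, independent of stats::uniroot
bisect_ <- function(f, lo, hi, tol = 1e-12, maxit = 200L) {
  flo <- f(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# window mean of an sdd_profile at one time, by trapezoid on the node grid
window_mean_ <- function(profile, tv, d, h) {
  s <- profile[profile$tau == tv & profile$epsilon >= d & profile$epsilon <= d + h, ]
  trapz_(s$epsilon, s$C) / (max(s$epsilon) - min(s$epsilon))
}

# time at which a recovery curve first reaches `frac` of its plateau,
# by linear interpolation on the sampled curve
time_to_fraction_ <- function(taus, values, plateau, frac = 0.95) {
  target <- values[1] + frac * (plateau - values[1])
  stats::approx(values, taus, xout = target, ties = "ordered")$y
}
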