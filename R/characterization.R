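#' Gradient-shape statistic: the 10% decay position
#'
#' `eps10` is the nondimensional position at which the steady concentration
#' has fallen to 10% of its value at the origin — a scale-free descriptor of
#' gradient shape. For the infinite-domain exponential gradient it is exactly
#' `ln 10 ~ 2.30`.
#'
#' @return For `eps10_infinite()`, a geometric mark: list with `eps10 = ln 10`
#'   and `defined = TRUE`, class `"sdd_mark"`.
#' @seealso [eps10_steady()], [eps10_transient()]
#' @export
eps10_infinite <- function() {
  new_mark(log(10))
}

new_mark <- function(eps10, defined = TRUE) {
  structure(list(eps10 = eps10, defined = defined), class = "sdd_mark")
}

#' @export
print.sdd_mark <- function(x, ...) {
  if (x$defined) cat(sprintf("<sdd_mark> eps10 = %.6f\n", x$eps10))
  else cat("<sdd_mark> undefined (profile never falls to 10% of origin)\n")
  invisible(x)
}

#' Steady-state eps10 for a finite tissue
#'
#' For a sink tip the closed form `eps10 = R - asinh(sinh(R)/10)` is used
#' (evaluated asymptotically for large `R`, where it tends to `ln 10`); in
#' the small-tissue limit it behaves as `0.9 R`. For a no-flux tip no closed
#' form is exposed, and the mark is found by bracketed root-finding on the
#' steady profile; it is *undefined* when the tip concentration never falls
#' to 10% of the origin value, which happens exactly when `cosh(R) < 10`
#' (i.e. `R < acosh(10) ~ 2.99`).
#'
#' @param dom A finite [sdd_domain()].
#' @param tol Root-finding tolerance (no-flux branch). Default 1e-10.
#' @return A geometric mark (class `"sdd_mark"`): `eps10`, `defined`.
#' @examples
#' eps10_steady(sdd_domain(1, "sink"))    # ~ 0.8827
#' eps10_steady(sdd_domain(2, "no_flux")) # undefined: cosh(2) < 10
#' @export
eps10_steady <- function(dom, tol = 1e-10) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) return(eps10_infinite())
  R <- dom$R
  if (dom$bc == "sink") {
    return(new_mark(eps10_sink_closed(R)))
  }
  # no-flux: ratio C(eps)/C(0) = cosh(R - eps)/cosh(R), minimal at the tip
  ratio <- function(e) steady_finite(e, dom) / steady_finite(0, dom)
  if (ratio(R) > 0.1) return(new_mark(NA_real_, defined = FALSE))
  root <- stats::uniroot(function(e) ratio(e) - 0.1, c(0, R), tol = tol)
  new_mark(root$root)
}

# closed form R - asinh(sinh(R)/10), with the large-R asymptote
# ln(10) - log1p(-exp(-2R)) used where sinh(R) would overflow
eps10_sink_closed <- function(R) {
  if (abs(R) > 30) {
    sign(R) * (log(10) - log1p(-exp(-2 * abs(R))))
  } else {
    R - asinh(sinh(R) / 10)
  }
}

#' Transient eps10 at a fixed time
#'
#' Position where the loading gradient `C(eps, tau)` has fallen to 10% of its
#' current origin value. Non-decreasing in `tau`; plateaus at the steady-state
#' mark. Undefined (flagged, not an error) when the whole profile stays above
#' 10% of the origin value, as happens early on under a no-flux tip.
#'
#' @param dom An [sdd_domain()] (finite or infinite).
#' @param tau Time, > 0.
#' @param ctrl A [series_control()].
#' @param tol Root tolerance. Default 1e-10.
#' @return A geometric mark (class `"sdd_mark"`).
#' @export
eps10_transient <- function(dom, tau, ctrl = series_control(), tol = 1e-10) {
  dom <- as_sdd_domain(dom)
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a single positive time", call. = FALSE)
  }
  cfun <- if (is_finite_domain(dom)) {
    function(e) conc_finite(e, tau, dom, ctrl)
  } else {
    function(e) conc_infinite(e, tau)
  }
  c0 <- cfun(0)
  if (c0 <= 0) stop("origin concentration is not positive at this tau", call. = FALSE)
  target <- 0.1 * c0
  if (is_finite_domain(dom)) {
    hi <- dom$R
    if (cfun(hi) > target) return(new_mark(NA_real_, defined = FALSE))
  } else {
    hi <- 2 * log(10)
    while (cfun(hi) > target) hi <- 2 * hi  # C <= exp(-eps), so this terminates
  }
  root <- stats::uniroot(function(e) cfun(e) - target, c(0, hi), tol = tol)
  new_mark(root$root)
}

#' Crossover tissue size between reaction-diffusion regimes
#'
#' For the sink tip, `eps10(R)` grows linearly (`~ 0.9 R`) for small tissues
#' and saturates at `ln 10` for large ones. The crossover `R_c` is defined by
#' Taylor-expanding `eps10(R)` about `R = 0` and finding the size at which the
#' second non-zero term (the cubic; the quadratic vanishes by symmetry)
#' reaches a given fraction (default 20%) of the linear term. The Taylor
#' coefficients are re-derived numerically by Richardson-extrapolated central
#' differences, not hard-coded. With `fraction = 0.2` the result is
#' `sqrt(0.2 * c1 / |c3|) ~ 3.3`, i.e. about three characteristic lengths.
#'
#' For the no-flux tip, `eps10` does not exist at all below the tissue size
#' where the tip concentration first reaches 10% of the origin value, so the
#' crossover is reported as that onset, `acosh(10) ~ 2.99` (the `fraction`
#' argument does not enter); see the package vignette for the rationale.
#'
#' @param fraction Ratio criterion in (0, 1); default 0.2.
#' @param bc `"sink"` or `"no_flux"`.
#' @return List of class `"sdd_crossover"`: `R_c`, `fraction`, `bc`, and for
#'   the sink branch the derived Taylor coefficients `c1`, `c2`, `c3`.
#' @examples
#' crossover_Rc()$R_c          # ~ 3.3, "about three lambda"
#' crossover_Rc(bc = "no_flux")$R_c
#' @export
crossover_Rc <- function(fraction = 0.2, bc = c("sink", "no_flux")) {
  bc <- match.arg(bc)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction >= 1) {
    stop("fraction must be a single number in (0, 1)", call. = FALSE)
  }
  if (bc == "no_flux") {
    return(structure(list(R_c = acosh(10), fraction = fraction, bc = bc),
                     class = "sdd_crossover"))
  }
  co <- taylor_eps10_sink()
  R_c <- sqrt(fraction * co[["c1"]] / abs(co[["c3"]]))
  structure(list(R_c = R_c, fraction = fraction, bc = bc,
                 c1 = co[["c1"]], c2 = co[["c2"]], c3 = co[["c3"]]),
            class = "sdd_crossover")
}

# Taylor coefficients of eps10(R) = R - asinh(sinh(R)/10) about R = 0, by
# Richardson-extrapolated central differences (the function is analytic and
# odd, so central stencils at +-h, +-2h are exact in parity).
taylor_eps10_sink <- function() {
  g <- eps10_sink_closed
  d1 <- function(h) (g(h) - g(-h)) / (2 * h)
  d2 <- function(h) (g(h) - 2 * g(0) + g(-h)) / h^2
  d3 <- function(h) (g(2 * h) - 2 * g(h) + 2 * g(-h) - g(-2 * h)) / (2 * h^3)
  rich <- function(f, h) {
    r1 <- (4 * f(h / 2) - f(h)) / 3
    r2 <- (4 * f(h / 4) - f(h / 2)) / 3
    (16 * r2 - r1) / 15
  }
  c(c1 = rich(d1, 0.2), c2 = rich(d2, 0.2), c3 = rich(d3, 0.2) / 6)
}

#' @export
print.sdd_crossover <- function(x, ...) {
  cat(sprintf("<sdd_crossover> R_c = %.4f (bc = %s, fraction = %g)\n",
              x$R_c, x$bc, x$fraction))
  invisible(x)
}

# Moment series sum_j (2/R) cos(w_j eps) / (w_j^2 + 1)^power, including the
# no-flux constant mode 1/R. power = 2 gives the numerator of mu_tau,
# power = 3 half the numerator of the second moment.
moment_series <- function(eps, dom, power, ctrl = series_control()) {
  R <- dom$R
  bc <- dom$bc
  acc <- if (bc == "sink") 0 else 1 / R
  j0 <- if (bc == "sink") 0L else 1L
  block <- 1024L
  j_next <- j0
  repeat {
    if (j_next - j0 >= ctrl$max_terms) {
      warning(warningCondition(
        sprintf("moment series not converged within %d terms", ctrl$max_terms),
        class = "sdd_convergence_warning"))
      break
    }
    j_hi <- min(j_next + block - 1L, j0 + ctrl$max_terms - 1L)
    j <- seq.int(j_next, j_hi)
    w <- eigen_freq(j, R, bc)
    acc <- acc + sum((2 / R) * cos(w * eps) / (w * w + 1)^power)
    j_next <- j_hi + 1L
    tail_bound <- (2 / R) * (R / pi)^(2 * power) /
      ((2 * power - 1) * max(j_next - 0.5, 0.5)^(2 * power - 1))
    if (tail_bound <= ctrl$tol * max(abs(acc), .Machine$double.xmin)) break
  }
  acc
}

#' Mean time to reach the steady state
#'
#' Uses the relaxation-function method: the deficit
#' `rho(eps, tau) = 1 - C(eps, tau)/C_ss(eps)` decays from 1 to 0, and
#' `-d rho/d tau` is treated as the probability density of the local
#' accumulation time. For the infinite domain the mean is `(eps + 1)/2`;
#' for finite tissues it is an eigenvalue series divided by the local steady
#' state, and it converges to the infinite-domain value as `R` grows.
#'
#' @param eps Position, in `[0, R]`.
#' @param dom An [sdd_domain()] (finite or infinite).
#' @param ctrl A [series_control()].
#' @return Mean accumulation time `mu_tau` (nondimensional).
#' @examples
#' mean_time(0, sdd_domain(Inf))         # 1/2
#' mean_time(0, sdd_domain(1, "sink"))   # < 1/2: absorbing tip speeds loading
#' @export
mean_time <- function(eps, dom, ctrl = series_control()) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) {
    if (any(eps < 0)) stop("eps must be >= 0", call. = FALSE)
    return((eps + 1) / 2)
  }
  check_eps_range(eps, dom$R)
  vapply(eps, function(e) {
    moment_series(e, dom, power = 2, ctrl) / steady_finite(e, dom)
  }, numeric(1))
}

#' Standard deviation of the time to reach the steady state
#'
#' Companion to [mean_time()]: the spread of the local accumulation-time
#' density. For the infinite domain it is `sqrt(eps + 2)/2` (so `sqrt(2)/2`
#' at the origin); for finite tissues the second moment is an eigenvalue
#' series (`2 * sum / C_ss`) from which the variance follows.
#'
#' @inheritParams mean_time
#' @return `sigma_tau` (nondimensional time).
#' @examples
#' std_time(0, sdd_domain(Inf))  # sqrt(2)/2
#' @export
std_time <- function(eps, dom, ctrl = series_control()) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) {
    if (any(eps < 0)) stop("eps must be >= 0", call. = FALSE)
    return(sqrt(eps + 2) / 2)
  }
  check_eps_range(eps, dom$R)
  vapply(eps, function(e) {
    css <- steady_finite(e, dom)
    mu <- moment_series(e, dom, power = 2, ctrl) / css
    m2 <- 2 * moment_series(e, dom, power = 3, ctrl) / css
    v <- m2 - mu * mu
    if (v < 0) {
      stop(sprintf("negative variance (%.3e) from series truncation; tighten series_control", v),
           call. = FALSE)
    }
    sqrt(v)
  }, numeric(1))
}

#' Accumulation-time moments by direct quadrature (numerical oracle)
#'
#' Independent route to the mean and SD of the time to steady state: builds
#' the relaxation function `rho(tau) = 1 - C(eps, tau)/C_ss(eps)` from the
#' concentration evaluators and integrates `mu = int rho dtau` and
#' `m2 = 2 int tau rho dtau` on an adaptive horizon (doubled until
#' `rho < 1e-10`, with the next doubling integrated as a tail check). Agrees
#' with the closed-form series of [mean_time()]/[std_time()]; exists so the
#' two can cross-validate.
#'
#' @inheritParams mean_time
#' @return List with `mu_tau`, `sigma_tau`, `defined`. At a sink tip
#'   (`eps = R`) the steady state is 0 and the moments are flagged undefined.
#' @export
relaxation_moments <- function(eps, dom, ctrl = series_control()) {
  dom <- as_sdd_domain(dom)
  finite <- is_finite_domain(dom)
  if (finite) check_eps_range(eps, dom$R) else if (eps < 0)
    stop("eps must be >= 0", call. = FALSE)
  css <- if (finite) steady_finite(eps, dom) else steady_infinite(eps)
  if (css <= 0) {
    return(list(mu_tau = NA_real_, sigma_tau = NA_real_, defined = FALSE))
  }
  rho <- function(tau) {
    cc <- if (finite) conc_finite(rep(eps, length(tau)), tau, dom, ctrl)
          else conc_infinite(eps, tau)
    1 - cc / css
  }
  H <- 10
  while (rho(H) > 1e-10 && H < 1e4) H <- 2 * H
  iq <- function(f, lo, hi) {
    stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-12,
                     subdivisions = 400L)$value
  }
  mu <- iq(rho, 0, H) + iq(rho, H, 2 * H)
  m2 <- 2 * (iq(function(t) t * rho(t), 0, H) +
             iq(function(t) t * rho(t), H, 2 * H))
  list(mu_tau = mu, sigma_tau = sqrt(max(m2 - mu * mu, 0)), defined = TRUE)
}
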