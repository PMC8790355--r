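#' Transient concentration, infinite domain
#'
#' Closed-form solution of the nondimensional synthesis-diffusion-degradation
#' model on the half-line: diffusion with unit flux injected at the origin and
#' first-order degradation, starting from an empty domain,
#' \deqn{C(\varepsilon,\tau) = e^{-\varepsilon}\left[1
#'   - \tfrac12\,\mathrm{erfc}\!\left(\sqrt{\tau}-\tfrac{\varepsilon}{2\sqrt{\tau}}\right)
#'   - \tfrac12\,e^{2\varepsilon}\,
#'     \mathrm{erfc}\!\left(\sqrt{\tau}+\tfrac{\varepsilon}{2\sqrt{\tau}}\right)\right].}
#' The second erfc term is evaluated in scaled form (via the scaled
#' complementary error function), so the expression is stable for large
#' `eps`. At `tau = 0` the initial condition 0 is returned exactly; as
#' `tau` grows the profile loads monotonically toward `exp(-eps)`.
#'
#' @param eps Nondimensional position(s), >= 0 (units of the characteristic
#'   length `lambda`).
#' @param tau Nondimensional time(s), >= 0 (units of `1/k`). Recycled against
#'   `eps`.
#' @return Nondimensional concentration(s) (units of `S = q/sqrt(D k)`).
#' @seealso [conc_finite()], [steady_infinite()]
#' @examples
#' conc_infinite(0.5, 1)
#' conc_infinite(0, 100)  # ~ 1, the steady origin value
#' @export
conc_infinite <- function(eps, tau) {
  n <- max(length(eps), length(tau))
  eps <- rep_len(as.numeric(eps), n)
  tau <- rep_len(as.numeric(tau), n)
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("eps must be finite and >= 0", call. = FALSE)
  }
  if (any(is.na(tau)) || any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  out <- numeric(n)
  pos <- tau > 0
  if (any(pos)) {
    e <- eps[pos]
    t <- tau[pos]
    inf_t <- is.infinite(t)
    st <- sqrt(t)
    a <- st - e / (2 * st)
    b <- st + e / (2 * st)
    val <- exp(-e) * (1 - 0.5 * erfc(a)) - 0.5 * exp_erfc(e, b)
    val[inf_t] <- exp(-e[inf_t])
    out[pos] <- val
  }
  out
}

#' Steady-state concentration, infinite domain
#'
#' The familiar exponential morphogen gradient `exp(-eps)`.
#'
#' @inheritParams conc_infinite
#' @return `exp(-eps)`.
#' @export
steady_infinite <- function(eps) {
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("eps must be finite and >= 0", call. = FALSE)
  }
  exp(-eps)
}

#' Steady-state concentration, finite domain
#'
#' Closed forms for the steady gradient on a tissue of nondimensional size `R`:
#' `sinh(R - eps)/cosh(R)` for an absorbing tip (sink) and
#' `cosh(R - eps)/sinh(R)` for a reflecting tip (no flux). Both are evaluated
#' in an exponential rescaling,
#' `exp(-eps) (1 -+ exp(-2(R - eps))) / (1 +- exp(-2R))`, which avoids
#' overflow of `cosh(R)` and remains accurate for `R` up to several hundred.
#' Both converge to `exp(-eps)` as `R -> Inf`; for small `R` the sink form
#' degenerates to the linear ramp `R - eps` and the no-flux form to the
#' uniform level `~ 1/R`.
#'
#' @inheritParams conc_infinite
#' @param dom A finite [sdd_domain()].
#' @return Steady concentration(s).
#' @examples
#' steady_finite(0.5, sdd_domain(1, "sink"))
#' steady_finite(0, sdd_domain(0.05, "sink"))  # ~ R at the origin
#' @export
steady_finite <- function(eps, dom) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) {
    stop("dom must be finite; use steady_infinite() for the infinite domain",
         call. = FALSE)
  }
  check_eps_range(eps, dom$R)
  R <- dom$R
  if (dom$bc == "sink") {
    exp(-eps) * (1 - exp(-2 * (R - eps))) / (1 + exp(-2 * R))
  } else {
    exp(-eps) * (1 + exp(-2 * (R - eps))) / (1 - exp(-2 * R))
  }
}

check_eps_range <- function(eps, R) {
  if (any(!is.finite(eps)) || any(eps < 0) || any(eps > R)) {
    stop(sprintf("eps must lie in [0, R] = [0, %g]", R), call. = FALSE)
  }
  invisible(TRUE)
}

# Eigenvalues of the spatial operator on [0, R]: cos(mu_j eps) with
# mu_j = (j + 1/2) pi / R (sink, j >= 0) or nu_j = j pi / R (no flux, j >= 0,
# j = 0 being the constant mode). Decay rates are mu^2 + 1.
eigen_freq <- function(j, R, bc) {
  if (bc == "sink") (j + 0.5) * pi / R else j * pi / R
}

# Transient deficit T(eps, tau) with C(eps, tau) = C_ss(eps) - T(eps, tau).
# Sink:    sum_{j>=0} (2/R) cos(mu_j eps) / (mu_j^2+1) exp(-(mu_j^2+1) tau)
# No flux: exp(-tau)/R +
#          sum_{j>=1} (2/R) cos(nu_j eps) / (nu_j^2+1) exp(-(nu_j^2+1) tau)
# Summed blockwise; the tail after index J is bounded by
# (2R/pi^2) exp(-(freq_J^2+1) tau) / (J - 1/2), a p-series/integral bound.
transient_deficit <- function(eps, tau, dom, ctrl = series_control()) {
  R <- dom$R
  bc <- dom$bc
  acc <- if (bc == "sink") numeric(length(eps)) else exp(-tau) / R
  j0 <- if (bc == "sink") 0L else 1L
  block <- 1024L
  j_next <- j0
  achieved <- Inf
  repeat {
    if (j_next - j0 >= ctrl$max_terms) {
      warning(warningCondition(
        sprintf(paste0("transient series not converged within %d terms ",
                       "(tail bound %.3e); result returned as-is"),
                ctrl$max_terms, achieved),
        class = "sdd_convergence_warning"))
      break
    }
    j_hi <- min(j_next + block - 1L, j0 + ctrl$max_terms - 1L)
    j <- seq.int(j_next, j_hi)
    w <- eigen_freq(j, R, bc)
    lam <- w * w + 1
    coef <- (2 / R) * exp(-lam * tau) / lam
    acc <- acc + drop(cos(outer(eps, w)) %*% coef)
    j_next <- j_hi + 1L
    w_next <- eigen_freq(j_next, R, bc)
    achieved <- (2 * R / pi^2) * exp(-(w_next^2 + 1) * tau) /
      max(j_next - 0.5, 0.5)
    if (achieved <= ctrl$tol * max(1, max(abs(acc)))) break
  }
  acc
}

#' Transient concentration, finite domain
#'
#' Exact eigenfunction-series solution on a tissue of size `R`: the steady
#' state minus a transient deficit summed over the cosine eigenbasis of the
#' tip boundary condition,
#' \deqn{C(\varepsilon,\tau) = C_{ss}(\varepsilon) - \sum_j \frac{2/R}{\mu_j^2+1}
#'   \cos(\mu_j \varepsilon)\, e^{-(\mu_j^2+1)\tau},}
#' with `mu_j = (j + 1/2) pi / R` for a sink tip and, for a no-flux tip, the
#' constant mode `exp(-tau)/R` plus `nu_j = j pi / R` cosines. Truncation is
#' governed by `ctrl`; at `tau = 0` the series identity makes the result 0 up
#' to truncation error (term decay is only `1/j^2` there, so convergence is
#' slow and a looser tolerance applies — see the package vignette).
#'
#' @inheritParams conc_infinite
#' @param dom A finite [sdd_domain()].
#' @param ctrl A [series_control()].
#' @return Concentration(s), recycled over `eps` and `tau`. Values are
#'   reported raw (not clipped), so a truncated series may dip below zero by
#'   O(`tol`).
#' @examples
#' conc_finite(0.5, 1, sdd_domain(1, "sink"))
#' @export
conc_finite <- function(eps, tau, dom, ctrl = series_control()) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) {
    stop("dom must be finite; use conc_infinite() for the infinite domain",
         call. = FALSE)
  }
  n <- max(length(eps), length(tau))
  eps <- rep_len(as.numeric(eps), n)
  tau <- rep_len(as.numeric(tau), n)
  check_eps_range(eps, dom$R)
  if (any(is.na(tau)) || any(tau < 0)) stop("tau must be >= 0", call. = FALSE)
  css <- steady_finite(eps, dom)
  out <- numeric(n)
  for (tv in unique(tau)) {
    idx <- which(tau == tv)
    if (is.infinite(tv)) {
      out[idx] <- css[idx]
    } else {
      out[idx] <- css[idx] - transient_deficit(eps[idx], tv, dom, ctrl)
    }
  }
  out
}

#' Total steady-state morphogen mass
#'
#' Quadrature of the finite-domain steady state over the tissue,
#' `N_ss = integral of C_ss over [0, R]`. Under the no-flux tip condition the
#' constant unit influx at the origin must balance the integrated linear
#' degradation, so `N_ss = 1` at every tissue size; under the sink condition
#' part of the flux leaves through the tip and the mass is `1 - 1/cosh(R)`,
#' approaching 1 as `R` grows.
#'
#' @param dom A finite [sdd_domain()].
#' @return The integrated mass (dimensionless).
#' @examples
#' total_steady_mass(sdd_domain(5, "no_flux"))  # 1, independent of R
#' @export
total_steady_mass <- function(dom) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) stop("dom must be finite", call. = FALSE)
  stats::integrate(function(e) steady_finite(e, dom), 0, dom$R,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Evaluate a concentration profile on a space-time grid
#'
#' Convenience wrapper building a long-format profile over an ascending
#' position grid and a set of times, for either model variant.
#'
#' @param dom An [sdd_domain()]; `R = Inf` selects the infinite-domain
#'   closed form.
#' @param eps Ascending positions; defaults to 201 points spanning `[0, R]`
#'   (or `[0, 3 * ln 10]` for the infinite domain).
#' @param taus Times at which to evaluate.
#' @param ctrl A [series_control()] (finite domain only).
#' @return A `data.frame` with columns `epsilon`, `tau`, `C`, `source`
#'   (`"analytic_infinite"` or `"analytic_finite"`), of class `"sdd_profile"`.
#' @examples
#' head(sdd_profile(sdd_domain(1, "sink"), taus = c(0.1, 1, 10)))
#' @export
sdd_profile <- function(dom, eps = NULL, taus = c(0.1, 1, 10),
                        ctrl = series_control()) {
  dom <- as_sdd_domain(dom)
  if (is.null(eps)) {
    hi <- if (is_finite_domain(dom)) dom$R else 3 * log(10)
    eps <- seq(0, hi, length.out = 201)
  }
  if (is.unsorted(eps)) stop("eps grid must be ascending", call. = FALSE)
  grid <- expand.grid(epsilon = eps, tau = taus, KEEP.OUT.ATTRS = FALSE)
  if (is_finite_domain(dom)) {
    grid$C <- conc_finite(grid$epsilon, grid$tau, dom, ctrl)
    grid$source <- "analytic_finite"
  } else {
    grid$C <- conc_infinite(grid$epsilon, grid$tau)
    grid$source <- "analytic_infinite"
  }
  class(grid) <- c("sdd_profile", "data.frame")
  grid
}
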