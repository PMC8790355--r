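#' Physical model parameters
#'
#' Bundle the dimensional parameters of the synthesis-diffusion-degradation
#' model: a morphogen is produced by a constant flux `q` at the tissue origin,
#' diffuses with coefficient `D` and is degraded linearly at rate `k` inside a
#' tissue of length `L`.
#'
#' @param D Diffusion coefficient (length^2/time), > 0.
#' @param k Linear degradation rate (1/time), > 0.
#' @param q Source flux at the origin (concentration * length / time), > 0.
#' @param L Tissue length (length), > 0.
#'
#' @return An object of class `"sdd_physical"`: a named list with fields
#'   `D`, `k`, `q`, `L`.
#' @seealso [nondimensionalize()]
#' @examples
#' physical_params(D = 36, k = 1, q = 1, L = 50)
#' @export
physical_params <- function(D, k, q, L) {
  vals <- c(D = D, k = k, q = q, L = L)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical parameters (D, k, q, L) must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(D = D, k = k, q = q, L = L), class = "sdd_physical")
}

#' Domain specification: tissue size and tip boundary condition
#'
#' The nondimensional tissue size `R = L / lambda` (tissue length in units of
#' the characteristic reaction-diffusion length `lambda = sqrt(D/k)`) is the
#' finite-domain model's only free parameter. `R = Inf` selects the
#' infinite-domain model, for which the tip boundary condition is immaterial.
#'
#' @param R Nondimensional tissue size, > 0, or `Inf` for the infinite domain.
#' @param bc Tip boundary condition at `eps = R`: `"sink"` (concentration held
#'   at zero, absorbing tip) or `"no_flux"` (zero gradient, reflecting tip).
#'
#' @return An object of class `"sdd_domain"`: list with fields `R`, `bc`.
#' @examples
#' sdd_domain(1, "sink")
#' sdd_domain(Inf)
#' @export
sdd_domain <- function(R = Inf, bc = c("sink", "no_flux")) {
  bc <- match.arg(bc)
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0) {
    stop("R must be a single positive number (or Inf)", call. = FALSE)
  }
  structure(list(R = R, bc = bc), class = "sdd_domain")
}

is_finite_domain <- function(dom) is.finite(dom$R)

as_sdd_domain <- function(dom) {
  if (inherits(dom, "sdd_domain")) return(dom)
  stop("expected an 'sdd_domain' object; see sdd_domain()", call. = FALSE)
}

#' Series truncation control
#'
#' Governs evaluation of the transient eigenfunction series: terms are summed
#' until an analytic bound on the remaining tail drops below
#' `tol * max(1, |running value|)`, or `max_terms` terms have been used (in
#' which case a convergence warning carrying the achieved bound is emitted).
#'
#' @param max_terms Cap on the series index, >= 1. Default 1e5.
#' @param tol Relative truncation tolerance, >= 0. Default 1e-10.
#'
#' @return Object of class `"sdd_series_control"`.
#' @export
series_control <- function(max_terms = 1e5, tol = 1e-10) {
  if (!is.numeric(max_terms) || length(max_terms) != 1L || max_terms < 1) {
    stop("max_terms must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1L || is.na(tol) || tol < 0) {
    stop("tol must be a single non-negative number", call. = FALSE)
  }
  structure(list(max_terms = as.integer(max_terms), tol = tol),
            class = "sdd_series_control")
}

#' Nondimensionalize physical parameters
#'
#' Computes the characteristic reaction-diffusion length `lambda = sqrt(D/k)`,
#' the concentration scale `S = q / sqrt(D*k)` and the time scale `1/k`, and
#' the reduced tissue size `R = L / lambda`. The dimensional concentration is
#' recovered as `C1(x, t) = S * C(x/lambda, k*t)`.
#'
#' @param p An [physical_params()] object.
#' @param bc Tip boundary condition passed through to the returned domain.
#'
#' @return A list with components
#'   \describe{
#'     \item{scale}{class `"sdd_scale"`: `lambda`, `S`, `tau_scale`.}
#'     \item{domain}{an [sdd_domain()] with `R = L/lambda`.}
#'   }
#' @examples
#' # Wg in the Drosophila wing disc: lambda ~ 6 um in a ~50 um tissue
#' nondimensionalize(physical_params(D = 36, k = 1, q = 1, L = 50))$domain$R
#' @export
nondimensionalize <- function(p, bc = c("sink", "no_flux")) {
  bc <- match.arg(bc)
  if (!inherits(p, "sdd_physical")) p <- do.call(physical_params, as.list(p))
  lambda <- sqrt(p$D / p$k)
  S <- p$q / sqrt(p$D * p$k)
  scale <- structure(list(lambda = lambda, S = S, tau_scale = 1 / p$k),
                     class = "sdd_scale")
  list(scale = scale, domain = sdd_domain(p$L / lambda, bc))
}

#' @export
print.sdd_domain <- function(x, ...) {
  if (is.finite(x$R)) {
    cat(sprintf("<sdd_domain> finite tissue, R = %g, tip bc = %s\n", x$R, x$bc))
  } else {
    cat("<sdd_domain> infinite domain\n")
  }
  invisible(x)
}

#' @export
print.sdd_scale <- function(x, ...) {
  cat(sprintf("<sdd_scale> lambda = %g, S = %g, tau_scale = %g\n",
              x$lambda, x$S, x$tau_scale))
  invisible(x)
}
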