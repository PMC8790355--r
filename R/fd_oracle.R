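#' Finite-difference grid specification
#'
#' Discretization controls for the numerical oracle: `n_x` equally spaced
#' nodes on `[0, R]` and a fixed time step `dt`. The explicit (forward Euler)
#' scheme is conditionally stable and requires
#' `dt <= deps^2 / (2 + deps^2)` (diffusion CFL tightened by the reaction
#' term); Crank-Nicolson is unconditionally stable and second-order in time.
#'
#' @param n_x Number of spatial nodes, >= 3.
#' @param dt Time step (nondimensional), > 0.
#' @param scheme `"crank_nicolson"` (default) or `"explicit"`.
#' @return Object of class `"sdd_grid"`.
#' @export
grid_spec <- function(n_x, dt, scheme = c("crank_nicolson", "explicit")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_x) || length(n_x) != 1L || n_x < 3) {
    stop("n_x must be a single integer >= 3", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  structure(list(n_x = as.integer(n_x), dt = dt, scheme = scheme),
            class = "sdd_grid")
}

# Second-difference operator with ghost-node Neumann closures, as a list of
# diagonals (lower, main, upper) of A where dC/dtau = A C + s.
# Node 0 carries the unit source flux via a centered ghost node
# (C_{-1} = C_1 + 2*deps), contributing s_0 = 2/deps; the tip node is either
# eliminated (sink, C = 0) or closed with a reflecting ghost (no flux).
fd_operator <- function(R, n_x, bc) {
  deps <- R / (n_x - 1)
  n <- if (bc == "sink") n_x - 1L else n_x  # unknown nodes
  main <- rep(-2 / deps^2 - 1, n)
  lower <- rep(1 / deps^2, n - 1)
  upper <- rep(1 / deps^2, n - 1)
  upper[1] <- 2 / deps^2                     # source-side ghost: C_{-1} = C_1 + 2 deps
  if (bc == "no_flux") lower[n - 1] <- 2 / deps^2  # tip ghost: C_{n+1} = C_{n-1}
  s <- numeric(n)
  s[1] <- 2 / deps
  list(lower = lower, main = main, upper = upper, s = s, deps = deps, n = n)
}

tridiag_mult <- function(op, x, scale = 1, shift = 0) {
  n <- length(x)
  y <- (shift + scale * op$main) * x
  y[-n] <- y[-n] + scale * op$upper * x[-1]
  y[-1] <- y[-1] + scale * op$lower * x[-n]
  y
}

tridiag_dense <- function(op, scale = 1, shift = 0) {
  n <- op$n
  M <- diag(shift + scale * op$main, n)
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- scale * op$upper
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- scale * op$lower
  M
}

#' Finite-difference solution of the reaction-diffusion model
#'
#' Independent numerical oracle for the finite-domain model: marches
#' `dC/dtau = d2C/deps2 - C` on `[0, R]` with unit influx at the origin
#' (centered ghost-node discretization of the flux condition, preserving
#' second-order spatial accuracy) and a sink or no-flux tip. Used throughout
#' the test suite to validate the analytic series solutions; it shares no
#' code with them.
#'
#' @param dom A finite [sdd_domain()].
#' @param grid A [grid_spec()].
#' @param times Ascending times (> 0) at which snapshots are returned. The
#'   step is shortened locally so every requested time is hit exactly.
#' @param init Initial values: `NULL` (empty tissue), a function of `eps`, or
#'   a numeric vector on the node grid.
#' @param flux Source flux at the origin (default 1; 0 gives null forcing).
#' @return A `data.frame` (class `"sdd_profile"`) with columns
#'   `epsilon`, `tau`, `C`, `source = "numeric"`.
#' @examples
#' p <- solve_fd(sdd_domain(1, "sink"), grid_spec(101, 1e-3), times = 10)
#' max(abs(p$C - steady_finite(p$epsilon, sdd_domain(1, "sink"))))
#' @export
solve_fd <- function(dom, grid, times, init = NULL, flux = 1) {
  dom <- as_sdd_domain(dom)
  if (!is_finite_domain(dom)) stop("dom must be finite", call. = FALSE)
  if (!inherits(grid, "sdd_grid")) stop("grid must be a grid_spec()", call. = FALSE)
  times <- sort(as.numeric(times))
  if (any(times <= 0)) stop("snapshot times must be > 0", call. = FALSE)
  op <- fd_operator(dom$R, grid$n_x, dom$bc)
  if (grid$scheme == "explicit") {
    dt_max <- op$deps^2 / (2 + op$deps^2)
    if (grid$dt > dt_max) {
      stop(sprintf("explicit scheme unstable: dt = %g exceeds bound %g",
                   grid$dt, dt_max), call. = FALSE)
    }
  }
  eps_grid <- seq(0, dom$R, length.out = grid$n_x)
  C <- init_values(init, eps_grid)
  u <- if (dom$bc == "sink") C[-grid$n_x] else C
  s <- flux / 1 * op$s
  # Crank-Nicolson: (I - dt/2 A) u' = (I + dt/2 A) u + dt s; the implicit
  # matrix depends only on dt, so its inverse is cached per distinct step.
  inv_cache <- list()
  cn_inv <- function(dt) {
    key <- format(dt, digits = 17)
    if (is.null(inv_cache[[key]])) {
      inv_cache[[key]] <<- solve(tridiag_dense(op, scale = -dt / 2, shift = 1))
    }
    inv_cache[[key]]
  }
  step <- function(u, dt) {
    if (grid$scheme == "explicit") {
      u + dt * (tridiag_mult(op, u) + s)
    } else {
      rhs <- tridiag_mult(op, u, scale = dt / 2, shift = 1) + dt * s
      drop(cn_inv(dt) %*% rhs)
    }
  }
  out <- vector("list", length(times))
  t_now <- 0
  for (i in seq_along(times)) {
    span <- times[i] - t_now
    n_full <- floor(span / grid$dt + 1e-12)
    for (m in seq_len(n_full)) u <- step(u, grid$dt)
    rem <- span - n_full * grid$dt
    if (rem > 1e-12 * max(1, times[i])) u <- step(u, rem)
    t_now <- times[i]
    C_out <- if (dom$bc == "sink") c(u, 0) else u
    out[[i]] <- data.frame(epsilon = eps_grid, tau = times[i], C = C_out,
                           source = "numeric")
  }
  res <- do.call(rbind, out)
  class(res) <- c("sdd_profile", "data.frame")
  res
}

init_values <- function(init, eps_grid) {
  if (is.null(init)) return(numeric(length(eps_grid)))
  if (is.function(init)) return(init(eps_grid))
  if (is.numeric(init) && length(init) == length(eps_grid)) return(as.numeric(init))
  stop("init must be NULL, a function of eps, or a vector on the node grid",
       call. = FALSE)
}
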