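test_that("nondimensionalization produces lambda, S and R from physical inputs", {
  # identity scales
  nd <- nondimensionalize(physical_params(1, 1, 1, 1))
  expect_equal(nd$scale$lambda, 1)
  expect_equal(nd$scale$S, 1)
  expect_equal(nd$domain$R, 1)

  # Wg in the wing disc: lambda ~ 6 um, tissue ~ 50 um
  nd <- nondimensionalize(physical_params(D = 36, k = 1, q = 1, L = 50))
  expect_equal(nd$scale$lambda, 6)
  expect_equal(nd$domain$R, 50 / 6, tolerance = 1e-12)

  # hand-computed case: lambda = sqrt(4/1) = 2, S = 2/sqrt(4) = 1, R = 10/2
  nd <- nondimensionalize(physical_params(D = 4, k = 1, q = 2, L = 10))
  expect_equal(nd$scale$lambda, 2)
  expect_equal(nd$scale$S, 1)
  expect_equal(nd$domain$R, 5)

  expect_error(physical_params(-1, 1, 1, 1), "positive")
  expect_error(physical_params(1, 0, 1, 1), "positive")
  expect_error(sdd_domain(-2), "positive")
})

test_that("infinite-domain transient has the right limits and domain errors", {
  expect_identical(conc_infinite(0.7, 0), 0)          # empty initial tissue
  expect_equal(conc_infinite(0, 1e6), 1)              # steady origin value
  expect_equal(conc_infinite(c(0.5, 2), Inf), exp(-c(0.5, 2)))
  # origin loading is erf(sqrt(tau)), an independent closed form
  tt <- c(0.1, 0.5, 1, 4)
  expect_equal(conc_infinite(0, tt), 2 * pnorm(sqrt(2 * tt)) - 1,
               tolerance = 1e-12)
  # stable far from the source
  expect_true(all(is.finite(conc_infinite(c(50, 200, 700), 1))))
  expect_error(conc_infinite(-0.1, 1), "eps")
  expect_error(conc_infinite(1, -1), "tau")
})

test_that("steady states take their closed-form values and limits", {
  expect_equal(steady_infinite(0), 1)
  expect_equal(steady_infinite(log(10)), 0.1)
  expect_equal(steady_infinite(2), exp(-2))

  dom <- sdd_domain(1, "sink")
  expect_equal(steady_finite(1, dom), 0)                       # absorbing tip
  expect_equal(steady_finite(0.4, dom), sinh(1 - 0.4) / cosh(1),
               tolerance = 1e-14)                              # literal form
  domn <- sdd_domain(1, "no_flux")
  expect_equal(steady_finite(0.4, domn), cosh(1 - 0.4) / sinh(1),
               tolerance = 1e-14)
  # reflecting tip: zero slope, by central difference
  dh <- 1e-6
  slope <- (steady_finite(1, domn) - steady_finite(1 - dh, domn)) / dh
  expect_lt(abs(slope), 1e-5)

  # small tissue degenerates to the linear ramp R - eps
  doms <- sdd_domain(0.05, "sink")
  eps <- c(0, 0.01, 0.03)
  expect_equal(steady_finite(eps, doms), 0.05 - eps, tolerance = 2e-3)

  # large-R convergence to the exponential, both tips
  expect_equal(steady_finite(1, sdd_domain(30, "sink")), exp(-1),
               tolerance = 1e-9)
  expect_equal(steady_finite(1, sdd_domain(30, "no_flux")), exp(-1),
               tolerance = 1e-9)
  # no overflow at very large tissue sizes
  expect_true(is.finite(steady_finite(350, sdd_domain(700, "sink"))))
  expect_true(is.finite(steady_finite(0, sdd_domain(700, "no_flux"))))

  expect_error(steady_finite(1.2, dom), "0, R")
})

test_that("unit source flux is carried by every variant", {
  dh <- 1e-5
  num_slope <- function(f) (f(dh) - f(0)) / dh
  expect_equal(num_slope(steady_infinite), -1, tolerance = 1e-4)
  for (bc in c("sink", "no_flux")) {
    dom <- sdd_domain(1.5, bc)
    expect_equal(num_slope(function(e) steady_finite(e, dom)), -1,
                 tolerance = 1e-4)
    expect_equal(num_slope(function(e) conc_finite(e, 1, dom)), -1,
                 tolerance = 1e-3)
  }
  expect_equal(num_slope(function(e) conc_infinite(e, 1)), -1, tolerance = 1e-3)
})

test_that("steady mass balances the source flux", {
  # no-flux tip: influx 1 balances integrated degradation at every R
  for (R in c(0.5, 1, 5)) {
    expect_equal(total_steady_mass(sdd_domain(R, "no_flux")), 1,
                 tolerance = 1e-8)
  }
  # sink tip: quadrature matches the closed form 1 - 1/cosh(R)
  for (R in c(0.5, 2)) {
    expect_equal(total_steady_mass(sdd_domain(R, "sink")), 1 - 1 / cosh(R),
                 tolerance = 1e-8)
  }
  # and approaches 1 (the half-line mass) for large tissues
  expect_equal(total_steady_mass(sdd_domain(40, "sink")), 1, tolerance = 1e-8)
})

test_that("finite-domain series honours its boundary, initial and long-time contracts", {
  eps <- seq(0, 1, length.out = 11)
  for (bc in c("sink", "no_flux")) {
    dom <- sdd_domain(1, bc)
    # series identity at tau = 0: concentration vanishes (slow 1/j^2 tail)
    v0 <- suppressWarnings(conc_finite(eps, 0, dom,
                                       series_control(max_terms = 2e5)))
    expect_lt(max(abs(v0)), 1e-4)
    # long time recovers the steady state
    expect_equal(conc_finite(eps, 30, dom), steady_finite(eps, dom),
                 tolerance = 1e-12)
  }
  # absorbing tip pinned at zero for all times
  dom <- sdd_domain(1, "sink")
  expect_lt(max(abs(conc_finite(1, c(0.1, 1, 10), dom))), 1e-12)
  # tissues above the crossover are indistinguishable from the half-line
  dom5 <- sdd_domain(5, "sink")
  eps5 <- seq(0, 4, length.out = 9)
  for (tv in c(0.1, 1, 10)) {
    expect_lt(max(abs(conc_finite(eps5, tv, dom5) - conc_infinite(eps5, tv))),
              1e-2)
  }
  expect_error(conc_finite(2, 1, sdd_domain(1, "sink")), "0, R")
  expect_warning(conc_finite(0.5, 0, dom, series_control(max_terms = 50)),
                 class = "sdd_convergence_warning")
})

test_that("gradients load monotonically and tip conditions order the models", {
  taus <- c(0.05, 0.2, 1, 3, 10)
  eps <- seq(0, 2, length.out = 21)
  doms <- sdd_domain(2, "sink")
  domn <- sdd_domain(2, "no_flux")
  Cs <- sapply(taus, function(tv) conc_finite(eps, tv, doms))
  Cn <- sapply(taus, function(tv) conc_finite(eps, tv, domn))
  Ci <- sapply(taus, function(tv) conc_infinite(eps, tv))
  slack <- 1e-9
  # non-decreasing in tau at every position
  expect_true(all(diff(t(Cs)) >= -slack))
  expect_true(all(diff(t(Cn)) >= -slack))
  expect_true(all(diff(t(Ci)) >= -slack))
  # non-increasing in eps at every time
  expect_true(all(diff(Cs) <= slack))
  expect_true(all(diff(Cn) <= slack))
  expect_true(all(diff(Ci) <= slack))
  # absorbing <= half-line <= reflecting, everywhere
  expect_true(all(Cs <= Ci + slack))
  expect_true(all(Ci <= Cn + slack))
})

test_that("finite steady profiles converge uniformly (and monotonically) to the half-line", {
  Rs <- c(1, 2, 4, 8, 16)
  sup_gap <- sapply(Rs, function(R) {
    eps <- seq(0, R, length.out = 201)
    max(abs(steady_finite(eps, sdd_domain(R, "sink")) - steady_infinite(eps)))
  })
  expect_true(all(diff(sup_gap) < 0))
  expect_lt(sup_gap[length(Rs)], 2 * exp(-16))  # tip mismatch decays as e^-R
})
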