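test_that("Naka-Rushton transfer has its defining values", {
  expect_equal(naka_rushton(0, 100, 300, 2), 0)
  expect_equal(naka_rushton(300, 100, 300, 2), 50)   # semi-saturation
  expect_equal(naka_rushton(0.5, 75, 0.5, 4), 37.5)
  # negative net input is rectified
  expect_equal(naka_rushton(-10, 100, 300, 2), 0)
  expect_lt(naka_rushton(1e9, 100, 300, 2), 100)
})

test_that("weight kernels integrate and shape as configured", {
  p <- rate_params()
  k <- weight_kernel("ei", p)
  rho_A_peak <- p$rho_i * p$A_ei * 0.39
  expect_equal(sum(k$w) * p$dx, rho_A_peak * 92 * sqrt(2 * pi),
               tolerance = 1e-3)
  # box family: constant on support, zero outside
  kb <- weight_kernel("ei", rate_params(kernel_family = "box"))
  on <- kb$w[abs(kb$x) <= 92 * sqrt(3) - 5]
  expect_true(all(abs(on - max(kb$w)) < 1e-12))
  expect_true(all(kb$w[abs(kb$x) > 92 * sqrt(3) + 5] == 0))
  # zero unitary strength gives a zero kernel
  k0 <- weight_kernel("ee", rate_params(A_ee = 0))
  expect_true(all(k0$w == 0))
  expect_error(rate_params(kernel_family = "triangle"))
})

test_that("rate fields stay bounded and zero drive is a fixed point", {
  p <- rate_params()
  s0 <- rate_sim(p, n_max = 0, sigma = 40, duration = 20)
  expect_true(all(s0$f_exc == 0) && all(s0$f_inh == 0))
  s <- rate_sim(p, n_max = 25, sigma = 60, duration = 60)
  expect_true(all(s$f_exc >= 0 & s$f_exc <= p$nr_exc$M))
  expect_true(all(s$f_inh >= 0 & s$f_inh <= p$nr_inh$M))
  expect_error(rate_sim(p, 20, 40, dt = 2), "dt")
})

test_that("uncoupled model settles on the pointwise transfer fixed point", {
  p <- rate_params(A_ee = 0, A_ie = 0, A_ei = 0)
  s <- rate_sim(p, n_max = 20, sigma = 60, duration = 120)
  thal <- p$w_thal_e * p$f_thal * 20 * exp(-s$x^2 / (2 * 60^2))
  want <- naka_rushton(thal, p$nr_exc$M, p$nr_exc$theta, p$nr_exc$n)
  expect_equal(s$f_exc[, ncol(s$f_exc)], want, tolerance = 1e-3)
})

test_that("narrow input sustains firing, broad input makes it transient", {
  p <- rate_params()
  s40 <- rate_sim(p, 20, 40, duration = 100)
  s120 <- rate_sim(p, 20, 120, duration = 100)
  ic <- which.min(abs(s40$x))
  at50 <- which.min(abs(s40$t - 50))
  expect_gte(s40$f_exc[ic, at50], 0.5 * max(s40$f_exc[ic, ]))
  expect_lt(s120$f_exc[ic, at50], 0.5 * max(s120$f_exc[ic, ]))
})

test_that("mean rate falls with input width, rises with input strength, and the width ratio crosses 1", {
  surf <- rate_surfaces(rate_params(), n_max = 20, sigma = seq(20, 160, 20))
  expect_true(all(diff(surf$mean_rate) < 0))
  expect_true(any(surf$ratio > 1) && any(surf$ratio < 1))
  surf_n <- rate_surfaces(rate_params(), n_max = c(8, 14, 20, 26),
                          sigma = c(40, 145))
  for (sg in unique(surf_n$sigma)) {
    sub <- surf_n[surf_n$sigma == sg, ]
    expect_true(all(diff(sub$mean_rate) > -1e-6))
  }
})

test_that("the co-tuning transition survives non-Gaussian connectivity kernels", {
  for (fam in c("box", "quadratic", "binomial")) {
    surf <- rate_surfaces(rate_params(kernel_family = fam), n_max = 20,
                          sigma = seq(40, 200, 32))
    expect_true(any(surf$ratio > 1) && any(surf$ratio < 1),
                label = paste("crossing with", fam, "kernel"))
  }
})

test_that("halving the time step changes the mean center rate by under 1%", {
  p <- rate_params()
  r1 <- mean_center_rate(rate_sim(p, 20, 60, duration = 55, dt = 0.25))
  r2 <- mean_center_rate(rate_sim(p, 20, 60, duration = 55, dt = 0.125))
  expect_lt(abs(r1 - r2) / r1, 0.01)
})

test_that("intensity trajectories classify as the input spread dictates", {
  p <- rate_params(w_thal_e = 0.02, w_thal_i = 0.02)
  narrow <- intensity_response(p, intensity_transfer())
  broad <- intensity_response(p, intensity_transfer(sigma_offset = 75))
  expect_equal(narrow$class, "non-monotonic")
  expect_equal(broad$class, "monotonic-increasing")
  # constant transfer: flat curve, monotonic by convention
  const <- intensity_transfer(nmax = list(M = 1e-9, theta = 0.5, n = 2),
                              sigma = list(M = 1e-9, theta = 0.5, n = 2),
                              sigma_offset = 60)
  flat <- intensity_response(rate_params(), const,
                             intensities = seq(0, 1, 0.25))
  expect_equal(flat$class, "monotonic-increasing")
  expect_lt(max(flat$curve$rate) - min(flat$curve$rate), 1e-6)
})

test_that("surface interpolation matches direct evaluation and guards its domain", {
  p <- rate_params(w_thal_e = 0.02, w_thal_i = 0.02)
  surf <- rate_surfaces(p, n_max = seq(0, 1000, by = 125),
                        sigma = seq(5, 160, by = 15.5))
  tr <- intensity_transfer()
  direct <- intensity_response(p, tr, intensities = seq(0, 1, 0.1))
  interp <- intensity_response(p, tr, intensities = seq(0, 1, 0.1),
                               surface = surf)
  expect_equal(interp$class, direct$class)
  expect_equal(interp$curve$rate, direct$curve$rate, tolerance = 0.15)
  small <- rate_surfaces(p, n_max = c(0, 100), sigma = c(20, 40))
  expect_error(intensity_response(p, tr, surface = small), "surface")
})
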