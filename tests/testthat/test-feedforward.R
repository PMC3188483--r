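test_that("excitatory profile is the thalamic Gaussian", {
  p <- ff_params(sigma_thal = 2, i_max = 3, theta = 1)
  pe <- ff_excitatory_profile(p)
  expect_equal(max(pe$value), 3)
  expect_equal(pe$value[which.min(abs(pe$x))], 3)
  # even in position
  expect_equal(pe$value, rev(pe$value))
  # FWHM of a Gaussian = 2 sigma sqrt(2 ln 2)
  expect_equal(half_width(pe), 2 * 2 * sqrt(2 * log(2)), tolerance = 1e-3)
})

test_that("sub-threshold input produces no inhibition", {
  p <- ff_params(sigma_thal = 1.5, i_max = 0.8, theta = 1)
  pinh <- ff_inhibitory_profile(p)
  expect_true(all(pinh$value == 0))
  expect_true(is.na(ff_width_ratio(p)$ratio))
})

test_that("threshold-free width ratio matches the Gaussian-convolution closed form", {
  # oracle: FWHM(I_inh)/FWHM(I_exc) = sqrt(sigma_thal^2 + sigma_inh^2)/sigma_thal
  for (s in c(0.5, 1, 2, 5, 20)) {
    p <- ff_params(sigma_thal = s, i_max = 2, theta = 0, sigma_inh = 1)
    r <- ff_width_ratio(p)$ratio
    expect_equal(r, sqrt(1 + 1 / s^2), tolerance = 1e-3)
    expect_gt(r, 1)
  }
  # asymptote: ratio approaches 1 from above as sigma_thal grows
  r_wide <- ff_width_ratio(ff_params(sigma_thal = 100, i_max = 2,
                                     theta = 0))$ratio
  expect_equal(r_wide, sqrt(1 + 1e-4), tolerance = 1e-3)
})

test_that("the iceberg effect narrows the thresholded rate profile", {
  p <- ff_params(sigma_thal = 2, i_max = 2, theta = 1)
  x <- seq(-12, 12, by = 0.02)
  i_thal <- 2 * exp(-x^2 / 8)
  f_inh <- pmax(i_thal - 1, 0)
  w_rate <- fwhm_linear(x, f_inh)
  w_thal <- fwhm_linear(x, i_thal)
  expect_lt(w_rate, w_thal)
})

test_that("width-ratio surface shows lateral inhibition, a co-tuning crossing, and grid stability", {
  surf <- ff_surface(i_max_norm = 3, sigma_norm = seq(0.25, 4, by = 0.25),
                     theta = 1)
  # narrow input: lateral inhibition
  expect_gt(surf$ratio[1], 1)
  # ratio vs sigma decreases monotonically and crosses 1
  expect_true(all(diff(surf$ratio) < 0))
  expect_true(any(surf$ratio < 1))
  ct <- cotuning_contour(surf)
  expect_equal(nrow(ct), 1)
  expect_true(ct$sigma_norm > 0.25 && ct$sigma_norm < 4)
  # lattice refinement: halving dx moves any ratio by < 1e-3
  p1 <- ff_params(sigma_thal = 1.5, i_max = 3, theta = 1, dx = 1 / 50)
  p2 <- ff_params(sigma_thal = 1.5, i_max = 3, theta = 1, dx = 1 / 100)
  expect_equal(ff_width_ratio(p1)$ratio, ff_width_ratio(p2)$ratio,
               tolerance = 1e-3)
})

test_that("peak-current surfaces behave as inherited and thresholded profiles", {
  surf <- ff_surface(i_max_norm = c(1.5, 2.5, 3.5),
                     sigma_norm = c(0.5, 1, 2), theta = 1)
  # peak excitatory current is i_max, independent of width
  expect_equal(surf$peak_exc, surf$i_max_norm, tolerance = 1e-12)
  # peak inhibitory current non-decreasing in i_max at fixed width
  for (s in unique(surf$sigma_norm)) {
    sub <- surf[surf$sigma_norm == s, ]
    expect_true(all(diff(sub$peak_inh) > 0))
  }
  # below-threshold input: zero inhibitory peak
  s0 <- ff_surface(i_max_norm = 0.9, sigma_norm = 1, theta = 1)
  expect_equal(s0$peak_inh, 0)
})

test_that("unequal E/I input widths shift the co-tuning contour as expected", {
  sg <- seq(0.25, 8, by = 0.25)
  s_eq <- ff_surface(i_max_norm = 3, sigma_norm = sg, theta = 1, r_ei = 1)
  s_wide <- ff_surface(i_max_norm = 3, sigma_norm = sg, theta = 1, r_ei = 1.15)
  s_nar <- ff_surface(i_max_norm = 3, sigma_norm = sg, theta = 1, r_ei = 0.85)
  c_eq <- cotuning_contour(s_eq)$sigma_norm
  c_wide <- cotuning_contour(s_wide)$sigma_norm
  c_nar <- cotuning_contour(s_nar)$sigma_norm
  # broader input to inhibitory cells moves exact co-tuning to larger sigma
  expect_gt(c_wide, c_eq)
  expect_lt(c_nar, c_eq)
  # r_ei = 1 reduces to the standard surface
  expect_equal(s_eq$ratio,
               ff_surface(i_max_norm = 3, sigma_norm = sg, theta = 1)$ratio)
})

test_that("a too-narrow lattice is rejected", {
  p <- ff_params(sigma_thal = 4, i_max = 3, theta = 0.1, span = 5)
  expect_error(ff_inhibitory_profile(p), "lattice too narrow")
})
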