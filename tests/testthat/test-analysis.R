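fake_spikes <- function(t, x = 0, y = 0, sweep = 1, pop = "P") {
  tibble::tibble(sweep = sweep, pop = pop, cell = 1L, x = x, y = y, t = t)
}

test_that("psth conserves counts and handles empty input", {
  sp <- fake_spikes(c(1, 6, 7, 42, 49.9), sweep = c(1, 1, 2, 2, 2))
  h <- psth(sp, bin_width = 10, n_sweeps = 2, t_max = 50)
  expect_equal(sum(h$count) * 2, 5)
  h0 <- psth(sp[0, ], bin_width = 10, n_sweeps = 2, t_max = 50)
  expect_true(all(h0$count == 0))
  expect_equal(nrow(h0), 5)
})

test_that("count_window averages spikes per cell over sweeps", {
  coords <- tibble::tibble(cell = 1:4, x = c(0, 10, 20, 30), y = 0)
  sp <- tibble::tibble(sweep = c(1, 1, 2, 2), pop = "P",
                       cell = c(1L, 1L, 1L, 3L), x = 0, y = 0,
                       t = c(5, 60, 10, 20))
  cw <- count_window(sp, window = c(0, 50), n_sweeps = 2, coords = coords)
  expect_equal(cw$count, c(1, 0, 0.5, 0))
  # full-span window counts everything
  cw2 <- count_window(sp, window = c(0, 100), n_sweeps = 2, coords = coords)
  expect_equal(sum(cw2$count) * 2, 4)
  # empty events give zero counts
  cw0 <- count_window(sp[0, ], window = c(0, 50), n_sweeps = 2,
                      coords = coords)
  expect_true(all(cw0$count == 0))
})

test_that("radial binning recovers analytic fields", {
  g <- expand.grid(x = seq(-300, 300, 7.5), y = seq(-300, 300, 7.5))
  # constant field -> flat profile
  flat <- radial_profile(tibble::tibble(x = g$x, y = g$y, value = 2),
                         bin_width = 15)
  expect_true(all(abs(flat$value - 2) < 1e-12))
  # isotropic Gaussian field: binned profile matches exp(-r^2/(2 s^2))
  s <- 80
  prof <- radial_profile(tibble::tibble(x = g$x, y = g$y,
                                        value = exp(-(g$x^2 + g$y^2) / (2 * s^2))),
                         bin_width = 15)
  keep <- prof$r < 250
  expect_equal(prof$value[keep], exp(-prof$r[keep]^2 / (2 * s^2)),
               tolerance = 0.02)
  # half-width of the binned Gaussian ~ 2.3548 s
  expect_equal(half_width(prof), 2 * sqrt(2 * log(2)) * s, tolerance = 0.02)
})

test_that("half-width is amplitude invariant and scales like the profile", {
  x <- seq(-400, 400, 2)
  p1 <- tibble::tibble(x = x, value = exp(-x^2 / (2 * 60^2)))
  p2 <- tibble::tibble(x = x, value = 7 * exp(-x^2 / (2 * 60^2)))
  p3 <- tibble::tibble(x = x, value = exp(-x^2 / (2 * 120^2)))
  expect_equal(half_width(p1), half_width(p2))
  expect_equal(half_width(p3) / half_width(p1), 2, tolerance = 1e-3)
  # a profile that never falls below half maximum is an error
  expect_error(half_width(tibble::tibble(x = x, value = 1 + 0.1 * cos(x / 400))),
               "half maximum")
})

test_that("ei_width_ratio agrees with the feedforward model on injected analytic profiles", {
  # cross-tier oracle: push the reduced model's profiles through the
  # simulation-analysis path and compare the two ratio computations
  p <- ff_params(sigma_thal = 60, sigma_inh = 92, i_max = 2, theta = 1,
                 dx = 2)
  pe <- ff_excitatory_profile(p)
  pinh <- ff_inhibitory_profile(p)
  n <- length(pe$x)
  coords <- tibble::tibble(cell = seq_len(n), x = pe$x, y = 0)
  rec <- structure(list(
    cond = list(times = 0,
                thal = matrix(pe$value, n, 1),
                rec = matrix(0, n, 1),
                inh = matrix(pinh$value, n, 1)),
    p_coords = coords, center = c(0, 0), n_sweeps = 1),
    class = "sim_record")
  got <- ei_width_ratio(rec, window = c(0, 0), bin_width = 2)
  want <- ff_width_ratio(p)
  expect_equal(got$ratio, want$ratio, tolerance = 1e-3)
})

test_that("two-tone bookkeeping validates conditions and orders separations", {
  base <- structure(list(
    spikes = tibble::tibble(sweep = 1, pop = "P", cell = 1L, x = 0, y = 0,
                            t = 10),
    p_coords = tibble::tibble(cell = 1:2, x = c(0, 100), y = 0),
    center = c(0, 0), n_sweeps = 1,
    drive = thalamic_drive(60, 40)), class = "sim_record")
  tt <- base
  tt$drive <- two_tone_drive(thalamic_drive(60, 40), 80)
  curve <- two_tone_curve(list(tt, base), base)
  expect_equal(curve$delta_x, c(0, 80))
  expect_true(all(curve$baseline == 1))
  bad <- tt
  bad$drive <- two_tone_drive(thalamic_drive(100, 40), 80)
  expect_error(two_tone_curve(list(bad), base), "match")
})

test_that("gain summary separates slope changes from onset shifts", {
  nmx <- seq(10, 60, by = 10)
  mk <- function(slope, onset) {
    tibble::tibble(n_max = nmx, count = pmax(0, slope * (nmx - onset)))
  }
  counts <- dplyr::bind_rows(
    dplyr::mutate(mk(0.10, 20), sigma = 40),
    dplyr::mutate(mk(0.05, 20), sigma = 75),
    dplyr::mutate(mk(0.02, 20), sigma = 110))
  gs <- gain_summary(counts)
  expect_true(gs$divisive)
  expect_equal(gs$summary$onset, rep(30, 3))  # first nonzero grid point
  expect_gt(gs$summary$slope[gs$summary$sigma == 40],
            gs$summary$slope[gs$summary$sigma == 110])
  # identical curves: equal slopes, no divisive flag
  same <- dplyr::bind_rows(
    dplyr::mutate(mk(0.1, 20), sigma = 40),
    dplyr::mutate(mk(0.1, 20), sigma = 110))
  expect_false(gain_summary(same)$divisive)
  # degenerate all-zero curve is flagged
  zero <- dplyr::bind_rows(
    dplyr::mutate(tibble::tibble(n_max = nmx, count = 0), sigma = 40),
    dplyr::mutate(mk(0.1, 20), sigma = 110))
  expect_true(any(gain_summary(zero)$summary$degenerate))
})
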