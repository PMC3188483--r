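test_that("spatial envelope is a radially symmetric Gaussian with the right peak", {
  d <- thalamic_drive(n_max = 60, sigma = 40, f_max = 50)
  expect_equal(spatial_envelope(d, 0, 0, "count"), 60)
  expect_equal(spatial_envelope(d, 0, 0, "rate"), 50)
  # closed-form value one standard deviation out
  expect_equal(spatial_envelope(d, 40, 0, "count"), 60 * exp(-1 / 2),
               tolerance = 1e-12)
  # radial symmetry: reflections and rotations about the center agree
  pts <- cbind(c(30, -30, 0, 21.2), c(10, -10, sqrt(1000), -21.2))
  v <- spatial_envelope(d, pts[, 1], pts[, 2], "rate")
  r <- sqrt(rowSums(pts^2))
  expect_equal(v, 50 * exp(-r^2 / (2 * 40^2)), tolerance = 1e-12)
})

test_that("envelope mass scales with n_max and sigma^2 (2-D Gaussian normalization)", {
  g <- expand.grid(x = seq(-600, 600, 4), y = seq(-600, 600, 4))
  mass <- function(n_max, sigma) {
    d <- thalamic_drive(n_max, sigma)
    sum(spatial_envelope(d, g$x, g$y, "count")) * 16
  }
  expect_equal(mass(60, 40), 2 * pi * 60 * 40^2, tolerance = 1e-3)
  expect_equal(mass(120, 40) / mass(60, 40), 2, tolerance = 1e-6)
  expect_equal(mass(60, 80) / mass(60, 40), 4, tolerance = 1e-3)
})

test_that("two-tone composites superpose count envelopes", {
  d <- thalamic_drive(60, 40)
  # zero separation doubles the count envelope everywhere
  d0 <- two_tone_drive(d, 0)
  x <- c(0, 25, 60, -80)
  expect_equal(spatial_envelope(d0, x, x, "count"),
               2 * spatial_envelope(d, x, x, "count"))
  # large separation: count at the S1 center approaches n_max
  dfar <- two_tone_drive(d, 2000)
  expect_equal(spatial_envelope(dfar, 0, 0, "count"), 60, tolerance = 1e-6)
  # closed-form midpoint value at separation sigma
  ds <- two_tone_drive(d, 40)
  expect_equal(spatial_envelope(ds, 20, 0, "count"), 2 * 60 * exp(-1 / 8),
               tolerance = 1e-12)
})

test_that("jittered trains reproduce the renewal statistics of the drive", {
  # independent oracle: direct cumulative-sum renewal process at rate 50 Hz
  set.seed(421)
  n_or <- 4000
  counts <- integer(n_or)
  vk3 <- numeric(n_or)
  for (i in seq_len(n_or)) {
    isi <- rnorm(12, 20, 5)
    while (any(isi <= 0)) isi[isi <= 0] <- rnorm(sum(isi <= 0), 20, 5)
    tt <- cumsum(isi)
    counts[i] <- sum(tt <= 100)
    vk3[i] <- tt[3]
  }
  tr <- generate_trains(rate = 50, duration = 100, n_trains = 10000, seed = 77)
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$t >= 0 & tr$t <= 100))
  # strictly increasing within each train
  expect_true(all(unlist(tapply(tr$t, tr$train, function(v) diff(v) > 0))))
  # Monte-Carlo mean spikes per train matches the oracle
  expect_equal(nrow(tr) / 10000, mean(counts), tolerance = 0.03)
  # jitter accumulation: variance of the 3rd spike time ~ 3 * (0.25/rate)^2
  third <- tapply(tr$t, tr$train, function(v) if (length(v) >= 3) v[3] else NA)
  expect_equal(var(third, na.rm = TRUE), var(vk3), tolerance = 0.1)
  expect_equal(var(vk3), 3 * 25, tolerance = 0.1)
})

test_that("train generation handles edge cases and rejects bad parameters", {
  expect_error(generate_trains(-5, 100, 10), "rate")
  expect_error(generate_trains(50, 0, 10), "duration")
  # a duration shorter than typical first latency can give empty trains
  tr <- generate_trains(rate = 50, duration = 2, n_trains = 200, seed = 3)
  expect_lt(length(unique(tr$train)), 200)
})

test_that("drive realization rounds counts half-up and is deterministic under a seed", {
  coords <- tibble::tibble(cell = 1:3, x = c(0, 40, 300), y = 0)
  d <- thalamic_drive(60, 40)
  r1 <- realize_drive(d, coords, seed = 11)
  r2 <- realize_drive(d, coords, seed = 11)
  expect_identical(r1, r2)
  # center cell receives exactly n_max afferents
  expect_equal(length(unique(r1$train[r1$cell == 1])), 60)
  # cell at one sigma: round(60 * exp(-1/2)) = 36
  expect_equal(length(unique(r1$train[r1$cell == 2])), 36)
  # zero-amplitude drive realizes no trains
  r0 <- realize_drive(thalamic_drive(0, 40), coords, seed = 1)
  expect_equal(nrow(r0), 0)
})

test_that("population activity of realized trains is phasic-tonic", {
  # onset synchrony: the histogram peak sits near the mean first-spike
  # latency (1/F) and exceeds the desynchronized tail
  tr <- generate_trains(rate = 50, duration = 200, n_trains = 3000, seed = 9)
  h <- psth(tibble::tibble(sweep = 1, pop = "P", x = 0, y = 0, t = tr$t),
            bin_width = 5, n_sweeps = 3000, t_max = 200)
  peak_bin <- h$t[which.max(h$count)]
  expect_lt(peak_bin, 30)           # peak within the onset volley
  tail_rate <- mean(h$count[h$t > 120])
  expect_gt(max(h$count), 1.3 * tail_rate)
})
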