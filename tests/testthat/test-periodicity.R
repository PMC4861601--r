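# Windowed profiles, zero-phase Butterworth smoothing, peak/trough calling
# and expression grouping.

test_that("a point mass of guides fills exactly one window of centers", {
  act <- data.frame(rel_pos = rep(0L, 10), activity = rep(1, 10))
  pr <- windowed_profile(act, window = 50, min_n = 10, range = c(-40, 40))
  # 0 is in [d-25, d+25) iff d in (-25, 25]
  expect_equal(pr$value[pr$rel_pos %in% -24:25], rep(1, 50))
  expect_true(all(is.na(pr$value[pr$rel_pos <= -25 | pr$rel_pos > 25])))
})

test_that("positions below the min_n support are missing", {
  act <- data.frame(rel_pos = rep(0L, 9), activity = rep(1, 9))
  pr <- windowed_profile(act, window = 50, min_n = 10, range = c(-40, 40))
  expect_true(all(is.na(pr$value)))
})

test_that("window means combine groups inside one window", {
  act <- data.frame(rel_pos = rep(c(-10L, 10L), each = 10),
                    activity = rep(c(0, 1), each = 10))
  pr <- windowed_profile(act, window = 50, min_n = 10, range = c(-5, 5))
  expect_equal(pr$value[pr$rel_pos == 0], 0.5)
})

test_that("windowed profile matches a brute-force double loop", {
  set.seed(31)
  for (rep in 1:10) {
    act <- data.frame(rel_pos = sample(-300:300, 200, replace = TRUE),
                      activity = rnorm(200))
    pr <- windowed_profile(act, window = 50, min_n = 5, range = c(-250, 250))
    br <- brute_windowed(act, window = 50, min_n = 5, range = c(-250, 250))
    expect_equal(pr$value, br$value)
    expect_equal(pr$n_sgrnas, br$n_sgrnas)
  }
})

test_that("smoothing a constant profile returns the same constant", {
  pr <- data.frame(rel_pos = -200:200, value = rep(3.7, 401))
  sm <- smooth_profile(pr)
  expect_equal(sm$smoothed, rep(3.7, 401), tolerance = 1e-9)
})

test_that("smoothing is linear", {
  set.seed(13)
  n <- 400
  x <- rnorm(n)
  y <- rnorm(n)
  mk <- function(v) data.frame(rel_pos = seq_len(n), value = v)
  sxy <- smooth_profile(mk(2 * x - 5 * y))$smoothed
  expect_equal(sxy, 2 * smooth_profile(mk(x))$smoothed -
                 5 * smooth_profile(mk(y))$smoothed, tolerance = 1e-8)
})

test_that("passband attenuation matches the analytic Butterworth response", {
  d <- -1000:1000
  per <- 190
  pr <- smooth_profile(data.frame(rel_pos = d, value = sin(2 * pi * d / per)))
  idx <- which(abs(d) <= 800)
  amp <- function(v) 2 * abs(mean(v[idx] * exp(-2i * pi * d[idx] / per)))
  measured <- amp(pr$smoothed) / amp(pr$value)
  # two zero-phase passes of an order-4 filter: |H|^2 = 1/(1+(f/fc)^8)
  analytic <- 1 / (1 + ((1 / per) / 0.015)^8)
  expect_lt(abs(measured - analytic) / analytic, 0.05)
  expect_gt(measured, 0.9)
})

test_that("stopband sinusoids are attenuated as the filter predicts", {
  d <- -1000:1000
  per <- 20
  pr <- smooth_profile(data.frame(rel_pos = d, value = sin(2 * pi * d / per)))
  idx <- which(abs(d) <= 800)
  amp <- function(v) 2 * abs(mean(v[idx] * exp(-2i * pi * d[idx] / per)))
  measured <- amp(pr$smoothed) / amp(pr$value)
  expect_lt(measured, 0.01)   # far below 1% of the input amplitude
  # exact magnitude response of the digital (bilinear, prewarped) design
  warped <- 1 / (1 + (tan(pi * (1 / per)) / tan(pi * 0.015))^8)
  expect_lt(abs(measured - warped) / warped, 0.05)
})

test_that("smoothing is zero-phase: in-band peaks shift by at most 1 bp", {
  d <- -500:1500
  pr <- smooth_profile(data.frame(rel_pos = d,
                                  value = cos(2 * pi * d / 190)))
  pk <- find_peaks_troughs(pr)
  interior <- pk$peaks$rel_pos[pk$peaks$rel_pos <= 1300]  # clear of the edge
  offs <- interior %% 190
  expect_true(all(pmin(offs, 190 - offs) <= 1))
})

test_that("interior gaps are interpolated before smoothing", {
  d <- -200:200
  v <- sin(2 * pi * d / 150)
  v[90:110] <- NA
  sm <- smooth_profile(data.frame(rel_pos = d, value = v))
  expect_false(anyNA(sm$smoothed))
  full <- smooth_profile(data.frame(rel_pos = d,
                                    value = sin(2 * pi * d / 150)))
  expect_equal(sm$smoothed[1:50], full$smoothed[1:50], tolerance = 1e-2)
})

test_that("degenerate profiles are rejected by the smoother", {
  expect_error(smooth_profile(data.frame(rel_pos = 1:10, value = rep(NA_real_, 10))),
               "missing")
  expect_error(smooth_profile(data.frame(rel_pos = 1:10, value = rnorm(10))),
               "warm-up")
})

test_that("cosine extrema are recovered in closed form", {
  d <- -400:600
  pr <- data.frame(rel_pos = d, value = cos(2 * pi * d / 190))
  pk <- find_peaks_troughs(pr)
  expect_equal(pk$peaks$rel_pos[1:2], c(0, 190))
  expect_equal(pk$troughs$rel_pos[1:2], c(95, 285))
  expect_equal(pk$amplitudes[1], 2, tolerance = 1e-3)
  expect_true(all(pk$troughs$rel_pos > pk$peaks$rel_pos[seq_len(nrow(pk$troughs))]))
})

test_that("a strictly monotone profile has no local maximum", {
  expect_error(find_peaks_troughs(data.frame(rel_pos = 1:50,
                                             value = seq(5, 1, length.out = 50))),
               "no local maximum")
})

test_that("equidistant equal maxima break ties downstream", {
  d <- -60:60
  v <- -(abs(d) - 30)^2          # equal maxima at -30 and +30
  pk <- find_peaks_troughs(data.frame(rel_pos = d, value = v))
  expect_equal(pk$peaks$rel_pos[1], 30)
})

test_that("plateau extrema collapse to their central position", {
  v <- c(0, 1, 2, 3, 3, 3, 2, 1, 0)
  pk <- find_peaks_troughs(data.frame(rel_pos = 1:9, value = v))
  expect_equal(pk$peaks$rel_pos, 5)
  v4 <- c(0, 1, 3, 3, 3, 3, 1, 0)   # even-length plateau: floor of midpoint
  pk4 <- find_peaks_troughs(data.frame(rel_pos = 1:8, value = v4))
  expect_equal(pk4$peaks$rel_pos, 4)
})

test_that("genes are grouped by their highest-expressed transcript", {
  fpkm <- data.frame(gene = c("a", "a", "b", "c"),
                     fpkm = c(2, 7, 0.1, 100))
  gr <- group_by_expression(fpkm, thresholds = c(1, 50))
  expect_equal(gr$fpkm[gr$gene == "a"], 7)
  expect_equal(as.character(gr$group), c("mid", "low", "high"))
  # boundary value goes to the upper bin
  at_t1 <- group_by_expression(data.frame(gene = "x", fpkm = 1),
                               thresholds = c(1, 50))
  expect_equal(as.character(at_t1$group), "mid")
  expect_error(group_by_expression(data.frame(gene = "x", fpkm = -1)),
               "negative")
})
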