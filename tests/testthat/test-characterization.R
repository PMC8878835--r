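test_that("sawtooth non-peak scans give noise exactly 10", {
  y <- rep(c(0, 10), 20)[1:39]
  tr <- ion_trace(1:39, y)
  N <- estimate_noise(tr, NULL)
  expect_equal(as.numeric(N), 10)
  expect_false(attr(N, "fallback"))
})

test_that("constant baselines fall back to the robust scale, flagged", {
  tr <- ion_trace(1:50, rep(100, 50))
  N <- estimate_noise(tr, NULL)
  expect_equal(as.numeric(N), 0)
  expect_true(attr(N, "fallback"))
})

test_that("white-noise estimate agrees with the independent extrema oracle", {
  set.seed(21)
  y <- pmax(rnorm(500, 1000, 50), 0)
  tr <- ion_trace(1:500, y)
  N <- estimate_noise(tr, NULL)
  expect_equal(as.numeric(N), oracle_noise(y), tolerance = 0.2)
})

test_that("peak regions are excluded from the noise estimate", {
  set.seed(22)
  y <- rnorm(300, 100, 5)
  y[140:160] <- y[140:160] + 5000 * exp(-((140:160) - 150)^2 / 18)
  tr <- ion_trace(1:300, pmax(y, 0))
  N_all <- estimate_noise(tr, NULL)
  N_masked <- estimate_noise(tr, data.frame(left_idx = 130, right_idx = 170))
  expect_gt(as.numeric(N_all), as.numeric(N_masked))
  expect_equal(as.numeric(N_masked),
               oracle_noise(y[c(1:129, 171:300)]), tolerance = 0.25)
})

test_that("triangle peak area and S/N identity are exact", {
  tr <- ion_trace(c(0, 1, 2), c(0, 100, 0))
  s <- list(rt = tr$rt, y_raw = tr$intensity, y = tr$intensity,
            d1 = c(100, 0, -100), d2 = c(0, -200, 0), window_used = 3L)
  class(s) <- "SmoothedTrace"
  bnd <- data.frame(left_idx = 1L, right_idx = 3L, baseline_left_y = 0,
                    baseline_right_y = 0)
  cand <- data.frame(apex_idx = 2L, left_inf_idx = 1L, right_inf_idx = 3L)
  ch <- characterize_peak(tr, s, bnd, cand, 100)
  expect_equal(ch$area_cpc, 100)      # trapezoid of (0,100,0) on dt=1
  expect_equal(ch$height_cpc, 100)
  expect_equal(ch$sn_cpc, 2 * 100 / 100)
})

full_characterize <- function(tr, win = 9) {
  s <- smooth_trace(tr, smoother_config(), window = win)
  cand <- detect_apices(s)
  stopifnot(nrow(cand) >= 1)
  ci <- which.max(s$y[cand$apex_idx])
  b <- expand_baseline(s, cand[ci, ], expansion_config(0, 0.5))
  N <- estimate_noise(tr, b)
  list(ch = characterize_peak(tr, s, b, cand[ci, ], N), s = s,
       cand = cand[ci, ], b = b)
}

test_that("a noiseless Gaussian has tailing factor 1 and the analytic FWHM", {
  tr <- gaussian_trace(A = 1e4, mu = 100, sigma = 5, dt = 0.5)
  res <- full_characterize(tr)
  expect_equal(res$ch$tailing_factor, 1, tolerance = 0.02)
  expect_equal(res$ch$fwhm, 2 * sqrt(2 * log(2)) * 5, tolerance = 0.02)
  expect_equal(res$ch$area_cpc, 1e4 * 5 * sqrt(2 * pi), tolerance = 0.02)
  # s/n identity holds exactly as emitted
  expect_equal(res$ch$sn_cpc, 2 * res$ch$height_cpc / res$ch$noise)
})

test_that("EMG peaks tail: tailing factor matches the analytic oracle", {
  sigma <- 5; tau <- 5
  rt <- seq(0, 200, 0.5)
  tr <- ion_trace(rt, emg_profile(rt, 80, sigma, tau, 5000))
  res <- full_characterize(tr, win = 11)
  mix <- emg_mix_fun(data.frame(mu = 80, sigma = sigma, tau = tau,
                                amplitude = 5000))
  w10 <- oracle_widths(mix$f, 0, 200, 0.10)
  tf_oracle <- (w10$right - w10$apex) / (w10$apex - w10$left)
  expect_gt(res$ch$tailing_factor, 1)
  expect_equal(res$ch$tailing_factor, tf_oracle, tolerance = 0.05)
})

test_that("width metrics are ordered fwhm <= w10 <= w05 <= w_base", {
  set.seed(31)
  for (k in 1:8) {
    sigma <- runif(1, 2, 8)
    tau <- if (k %% 2) 0 else runif(1, 0.3, 1.2) * sigma
    rt <- seq(0, 60 * sigma, 0.5)
    y <- emg_profile(rt, 25 * sigma, sigma, tau, 10^runif(1, 3, 4.5)) +
      rnorm(length(rt), 0, 10)
    res <- full_characterize(ion_trace(rt, pmax(y, 0)),
                             win = auto_window(sigma / 0.5,
                                               smoother_config()))
    ch <- res$ch
    expect_true(ch$fwhm <= ch$w10 + 1e-9)
    expect_true(ch$w10 <= ch$w05 + 1e-9)
    expect_true(ch$w05 <= ch$w_base + 1e-9)
    # front + tail half-widths recompose the 10% width
    expect_equal(ch$front_a + ch$tail_b, ch$w10, tolerance = 1e-8)
    expect_equal(ch$sn_cpc, 2 * ch$height_cpc / ch$noise)
  }
})

test_that("trapezoid area is additive under any interior split", {
  tr <- gaussian_trace(A = 5000, mu = 50, sigma = 4, dt = 0.5)
  res <- full_characterize(tr)
  b <- res$b
  idx <- b$left_idx:b$right_idx
  rt <- tr$rt[idx]
  base <- b$baseline_left_y + (b$baseline_right_y - b$baseline_left_y) *
    (rt - rt[1]) / (rt[length(rt)] - rt[1])
  yv <- pmax(tr$intensity[idx] - base, 0)
  full <- pracma::trapz(rt, yv)
  for (cut in c(5, 20, 35)) {
    part <- pracma::trapz(rt[1:cut], yv[1:cut]) +
      pracma::trapz(rt[cut:length(rt)], yv[cut:length(rt)])
    expect_equal(part, full, tolerance = 1e-12)
  }
  expect_equal(res$ch$area_cpc, full)
})

test_that("mirroring a trace inverts the tailing factor", {
  rt <- seq(0, 150, 0.5)
  y <- emg_profile(rt, 50, 4, 6, 8000)
  fwd <- full_characterize(ion_trace(rt, y), win = 11)$ch
  rev_tr <- ion_trace(rt, rev(y))
  bwd <- full_characterize(rev_tr, win = 11)$ch
  expect_equal(bwd$tailing_factor, 1 / fwd$tailing_factor, tolerance = 0.02)
})

test_that("estimated S/N is monotone in amplitude over fixed noise", {
  set.seed(41)
  rt <- seq(0, 120, 0.5)
  noise <- rnorm(length(rt), 200, 40)
  sn <- vapply(10^(2:5), function(A) {
    y <- pmax(A * exp(-(rt - 60)^2 / (2 * 16)) + noise, 0)
    full_characterize(ion_trace(rt, y), win = 9)$ch$sn_cpc
  }, numeric(1))
  expect_true(all(diff(sn) > 0))
})
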