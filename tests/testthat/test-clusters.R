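two_peak_setup <- function(h1 = 1000, h2 = 1000, delta = 60,
                           sigma = 10, n = 400, win = 9) {
  x <- 1:n
  c1 <- (n - delta) / 2
  c2 <- c1 + delta
  y <- h1 * exp(-(x - c1)^2 / (2 * sigma^2)) +
    h2 * exp(-(x - c2)^2 / (2 * sigma^2))
  s <- smooth_trace(ion_trace(x, y), smoother_config(), window = win)
  cand <- detect_apices(s)
  bounds <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    expand_baseline(s, cand[i, ], expansion_config(0, 0.5),
                    left_stop = if (i > 1) cand$right_inf_idx[i - 1] else 1L,
                    right_stop = if (i < nrow(cand))
                      cand$left_inf_idx[i + 1] else length(s$y))))
  list(s = s, cand = cand, bounds = bounds, c1 = c1, c2 = c2)
}

test_that("disjoint peaks form singleton clusters; overlap and chains merge", {
  s <- smooth_trace(ion_trace(1:100, rep(10, 100)), smoother_config(),
                    window = 5)
  b <- data.frame(left_idx = c(5, 30, 70), right_idx = c(20, 45, 90))
  cl <- group_clusters(b, s)
  expect_length(cl, 3)
  expect_equal(sapply(cl, function(x) length(x$members)), c(1, 1, 1))

  b2 <- data.frame(left_idx = c(10, 40), right_idx = c(50, 90))
  cl2 <- group_clusters(b2, s)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$left_idx, 10)
  expect_equal(cl2[[1]]$right_idx, 90)

  # chain overlap: A overlaps B, B overlaps C, A does not reach C
  b3 <- data.frame(left_idx = c(10, 35, 60), right_idx = c(40, 70, 95))
  expect_length(group_clusters(b3, s), 1)
})

test_that("equal Gaussians 6 sigma apart get a valley separator at the midpoint", {
  tp <- two_peak_setup(delta = 60)
  expect_equal(nrow(tp$cand), 2)
  cl <- group_clusters(tp$bounds, tp$s)
  expect_length(cl, 1)
  rcl <- resolve_separators(cl[[1]], tp$s, tp$cand)
  expect_equal(rcl$separators$type, "valley")
  expect_lte(abs(rcl$separators$idx - (tp$c1 + tp$c2) / 2), 1)
  # separator strictly between the apices
  expect_gt(rcl$separators$idx, tp$cand$apex_idx[1])
  expect_lt(rcl$separators$idx, tp$cand$apex_idx[2])
})

test_that("a 4:1 pair at 2.6 sigma has no valley and separates at the d2 maximum", {
  tp <- two_peak_setup(h1 = 4000, h2 = 1000, delta = 26)
  expect_equal(nrow(tp$cand), 2)
  # brute force: the summed analytic curve descends monotonically between
  # the apices (no valley)
  x <- seq_len(400)
  y <- 4000 * exp(-(x - tp$c1)^2 / 200) + 1000 * exp(-(x - tp$c2)^2 / 200)
  a1 <- tp$cand$apex_idx[1]; a2 <- tp$cand$apex_idx[2]
  expect_true(all(diff(y[a1:a2]) < 0))
  cl <- group_clusters(tp$bounds, tp$s)
  rcl <- resolve_separators(cl[[1]], tp$s, tp$cand)
  expect_true(rcl$separators$type %in% c("shoulder", "rounded"))
  # d2 maximum between the two d2 minima, located by brute force
  k_oracle <- which.max(tp$s$d2[tp$cand$d2_min_idx[1]:
                                  tp$cand$d2_min_idx[2]]) +
    tp$cand$d2_min_idx[1] - 1L
  expect_equal(rcl$separators$idx, k_oracle)
})

test_that("too-thin shoulder members merge into the taller peak, idempotently", {
  tp <- two_peak_setup(h1 = 4000, h2 = 1000, delta = 26)
  cl <- group_clusters(tp$bounds, tp$s)
  strict <- resolve_separators(cl[[1]], tp$s, tp$cand,
                               min_shoulder_pts = 50, min_rounded_pts = 50)
  expect_length(strict$members, 1)
  # survivor is the taller apex
  expect_equal(strict$members,
               which.max(tp$s$y[tp$cand$apex_idx]))
  expect_equal(nrow(strict$separators), 0)
  again <- resolve_separators(strict, tp$s, tp$cand,
                              min_shoulder_pts = 50, min_rounded_pts = 50)
  expect_equal(again$members, strict$members)
  expect_equal(again$separators, strict$separators)
})

test_that("separator partition conserves the cluster area", {
  tp <- two_peak_setup(delta = 40)   # overlapping pair, valley or shoulder
  cl <- group_clusters(tp$bounds, tp$s)
  expect_length(cl, 1)
  rcl <- resolve_separators(cl[[1]], tp$s, tp$cand)
  mb <- member_bounds(rcl, tp$s, tp$bounds)
  tr <- ion_trace(1:400, tp$s$y_raw)
  N <- 1
  areas <- vapply(seq_len(nrow(mb)), function(i)
    characterize_peak(tr, tp$s, mb[i, ], tp$cand[mb$member[i], ],
                      N)$area_cpc, numeric(1))
  # whole-cluster area above the cluster baseline
  idx <- rcl$left_idx:rcl$right_idx
  base <- seq(rcl$baseline_left_y, rcl$baseline_right_y,
              length.out = length(idx))
  total <- pracma::trapz(as.numeric(idx), pmax(tp$s$y_raw[idx] - base, 0))
  expect_equal(sum(areas), total, tolerance = 0.005)
})

test_that("EMG deconvolution recovers known parameters", {
  set.seed(9)
  rt <- seq(0, 200, 0.5)
  spec <- data.frame(mu = 90, sigma = 5, tau = 4, amplitude = 2000)
  y <- emg_profile(rt, 90, 5, 4, 2000)
  y <- y + rnorm(length(rt), 0, 20)   # 1% of amplitude
  tr <- ion_trace(rt, pmax(y, 0))
  s <- smooth_trace(tr, smoother_config(), window = 11)
  cand <- detect_apices(s)
  b <- expand_baseline(s, cand[1, ], expansion_config(0, 0.5))
  cl <- group_clusters(b, s)[[1]]
  cl <- resolve_separators(cl, s, cand)
  fit <- deconvolve_emg(cl, tr, s, cand)
  expect_true(fit$converged)
  expect_equal(fit$params$mu, 90, tolerance = 0.05 * 90)
  expect_equal(fit$params$sigma, 5, tolerance = 0.05 * 5)
  expect_equal(fit$params$area, 2000 * 5 * sqrt(2 * pi),
               tolerance = 0.05 * 2000 * 5 * sqrt(2 * pi))
})

test_that("two valley-separated EMG components recover their areas", {
  set.seed(10)
  rt <- seq(0, 300, 0.5)
  y <- emg_profile(rt, 120, 6, 3, 3000) + emg_profile(rt, 165, 6, 3, 1500) +
    rnorm(length(rt), 0, 15)
  tr <- ion_trace(rt, pmax(y, 0))
  s <- smooth_trace(tr, smoother_config(), window = 11)
  cand <- detect_apices(s)
  expect_equal(nrow(cand), 2)
  bounds <- do.call(rbind, lapply(1:2, function(i)
    expand_baseline(s, cand[i, ], expansion_config(0, 0.5),
                    left_stop = if (i > 1) cand$right_inf_idx[1] else 1L,
                    right_stop = if (i < 2) cand$left_inf_idx[2]
                    else length(s$y))))
  cl <- group_clusters(bounds, s)
  expect_length(cl, 1)
  cl <- resolve_separators(cl[[1]], s, cand)
  fit <- deconvolve_emg(cl, tr, s, cand)
  expect_true(fit$converged)
  truth <- c(3000, 1500) * 6 * sqrt(2 * pi)
  expect_equal(sort(fit$params$area, decreasing = TRUE), truth,
               tolerance = 0.10)
})

test_that("deconvolution of a flat trace reports non-convergence", {
  tr <- ion_trace(1:100, rep(50, 100))
  s <- smooth_trace(tr, smoother_config(), window = 5)
  cl <- list(members = 1L, left_idx = 10L, right_idx = 90L,
             baseline_left_y = 50, baseline_right_y = 50)
  cand <- data.frame(apex_idx = 50L, left_inf_idx = 40L,
                     right_inf_idx = 60L, d2_min = -1, d2_min_idx = 50L)
  fit <- deconvolve_emg(cl, tr, s, cand)
  expect_false(fit$converged)
})
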