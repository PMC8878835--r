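mk_chars <- function(sn = 50, area = 5000, n_pts = 20L, n_inf = 8L,
                     tf = 1.1, fwhm = 8, valid = TRUE) {
  data.frame(noise = 10, height_cpc = sn * 10 / 2, sn_cpc = sn,
             area_cpc = area, w_base = 20, fwhm = fwhm, w05 = 15, w10 = 12,
             front_a = 6, tail_b = 6, tailing_factor = tf,
             front_a5 = 7.5, tail_b5 = 7.5, n_points = n_pts,
             n_inf_points = n_inf, apex_rt = 100, width_capped = FALSE,
             noise_fallback = FALSE, valid = valid)
}

test_that("single violations produce exactly their reason code", {
  d <- apply_filters(mk_chars(sn = 4), filter_config())
  expect_false(d$keep)
  expect_equal(d$filter_reasons, "min_sn")
  expect_equal(apply_filters(mk_chars(area = 100))$filter_reasons,
               "min_intensity")
  expect_equal(apply_filters(mk_chars(n_pts = 3L))$filter_reasons,
               "min_pts")
  expect_equal(apply_filters(mk_chars(n_inf = 2L))$filter_reasons,
               "min_inf_width")
  expect_equal(apply_filters(mk_chars(tf = 5),
                             filter_config(interval_tf = c(0.5, 2)))$
                 filter_reasons, "tailing_factor")
  expect_equal(apply_filters(mk_chars(fwhm = 1),
                             filter_config(min_fwhm = 3))$filter_reasons,
               "min_fwhm")
})

test_that("all violated criteria are reported together", {
  d <- apply_filters(mk_chars(sn = 2, area = 50, n_pts = 3L))
  expect_setequal(strsplit(d$filter_reasons, ";")[[1]],
                  c("min_sn", "min_intensity", "min_pts"))
})

test_that("missing peak signature dominates", {
  d <- apply_filters(NULL)
  expect_false(d$keep)
  expect_equal(d$filter_reasons, "no_peak_signature")
  d2 <- apply_filters(mk_chars(valid = FALSE))
  expect_equal(d2$filter_reasons, "no_peak_signature")
})

test_that("comparisons are strict: exactly at the minimum is kept", {
  expect_true(apply_filters(mk_chars(sn = 10))$keep)
  expect_false(apply_filters(mk_chars(sn = 9.999))$keep)
  expect_true(apply_filters(mk_chars(area = 2000))$keep)
  expect_true(apply_filters(mk_chars(n_pts = 7L))$keep)
  expect_true(apply_filters(mk_chars(n_inf = 3L))$keep)
})

test_that("disabled thresholds keep any valid peak", {
  cfg <- filter_config(min_pts = 0, min_inf_width = 0, min_sn = 0,
                       min_intensity = 0)
  expect_true(apply_filters(mk_chars(sn = 0.01, area = 1, n_pts = 1L,
                                     n_inf = 1L), cfg)$keep)
})

test_that("filter_table partitions preserving order with summary counts", {
  tab <- data.frame(peak_id = sprintf("p%02d", 1:10), x = 1:10)
  dec <- data.frame(keep = rep(c(TRUE, FALSE), c(7, 3)),
                    filter_reasons = c(rep("", 7), "min_sn",
                                       "min_sn;min_intensity", "min_pts"))
  out <- filter_table(tab, dec)
  expect_equal(nrow(out$kept), 7)
  expect_equal(nrow(out$removed), 3)
  expect_equal(out$summary$removed_fraction, 0.3)
  expect_equal(out$summary$reason_counts$min_sn, 2L)
  expect_equal(out$summary$reason_counts$min_intensity, 1L)
  expect_equal(c(out$kept$peak_id, out$removed$peak_id),
               c(sprintf("p%02d", 1:7), sprintf("p%02d", 8:10)))
  # partition: disjoint and complete
  expect_setequal(c(out$kept$x, out$removed$x), tab$x)
  expect_error(filter_table(tab, dec[1:5, ]), "one decision")
  all_keep <- filter_table(tab, data.frame(keep = rep(TRUE, 10),
                                           filter_reasons = ""))
  expect_equal(nrow(all_keep$removed), 0)
})

test_that("raising any threshold never increases the kept count", {
  set.seed(51)
  chars <- lapply(1:40, function(i)
    mk_chars(sn = runif(1, 1, 60), area = runif(1, 100, 10000),
             n_pts = sample(3:30, 1), n_inf = sample(2:12, 1)))
  kept_count <- function(cfg) sum(vapply(chars, function(ch)
    apply_filters(ch, cfg)$keep, logical(1)))
  for (param in c("min_sn", "min_pts", "min_intensity", "min_inf_width")) {
    vals <- switch(param, min_sn = c(0, 5, 10, 20, 50),
                   min_pts = c(0, 5, 10, 20), min_intensity = c(0, 1000, 5000),
                   min_inf_width = c(0, 3, 6, 10))
    counts <- vapply(vals, function(v) {
      args <- setNames(list(v), param)
      kept_count(do.call(filter_config, args))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("filtering is deterministic", {
  ch <- mk_chars(sn = 9)
  d1 <- apply_filters(ch)
  d2 <- apply_filters(ch)
  expect_identical(d1, d2)
})
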