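# scaled complementary error function, stable over the whole real line
# (pracma::erfcx overflows to NaN beyond ~27; use the asymptotic series)
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  big <- x > 20
  if (any(big)) {
    xb <- x[big]
    out[big] <- (1 - 1 / (2 * xb^2) + 3 / (4 * xb^4)) / (xb * sqrt(pi))
  }
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  out
}

#' Exponentially modified Gaussian peak profile
#'
#' EMG with Gaussian core (`mu`, `sigma`), exponential decay constant `tau`
#' (rate `1/tau`) and pre-convolution Gaussian amplitude `amplitude`, so the
#' area is `amplitude * sigma * sqrt(2*pi)` for every `tau`. `tau = 0`
#' degenerates to the pure Gaussian by an explicit branch. Evaluated in a
#' numerically stable form using the scaled complementary error function on
#' the leading flank and the exponential-tail expansion on the far tail.
#'
#' @param t Time points (seconds).
#' @param mu Gaussian center (seconds).
#' @param sigma Gaussian width (seconds, > 0).
#' @param tau Exponential decay time (seconds, >= 0).
#' @param amplitude Gaussian amplitude (counts, > 0).
#' @return Intensity vector.
#' @export
emg_profile <- function(t, mu, sigma, tau, amplitude = 1) {
  stopifnot(sigma > 0, tau >= 0)
  z <- (t - mu) / sigma
  if (tau < 1e-8 * sigma) return(amplitude * exp(-z^2 / 2))
  a <- sigma / tau
  arg <- (a - z) / sqrt(2)
  out <- numeric(length(t))
  lead <- arg > -20
  if (any(lead))
    out[lead] <- amplitude * a * sqrt(pi / 2) *
      exp(-z[lead]^2 / 2) * erfcx_stable(arg[lead])
  if (any(!lead))    # far tail: erfc ~ 2, pure exponential decay
    out[!lead] <- amplitude * a * sqrt(pi / 2) * 2 *
      exp(a^2 / 2 - a * z[!lead])
  out
}

# Closed-form / fine-grid ground truth for one peak spec.
peak_truth <- function(mu, sigma, tau, amplitude) {
  area <- amplitude * sigma * sqrt(2 * pi)
  if (tau < 1e-8 * sigma) {
    return(data.frame(mu = mu, sigma = sigma, tau = tau,
                      amplitude = amplitude, area = area,
                      height = amplitude, apex_rt = mu,
                      fwhm = 2 * sqrt(2 * log(2)) * sigma,
                      tailing_factor = 1))
  }
  tg <- seq(mu - 6 * sigma, mu + 6 * sigma + 10 * tau,
            by = min(sigma, tau) / 50)
  yv <- emg_profile(tg, mu, sigma, tau, amplitude)
  ai <- which.max(yv)
  h <- yv[ai]
  crossings <- function(f) {
    lev <- f * h
    li <- max(which(yv[1:ai] <= lev))
    ri <- ai - 1L + min(which(yv[ai:length(yv)] <= lev))
    cl <- tg[li] + (lev - yv[li]) / (yv[li + 1L] - yv[li]) * diff(tg[1:2])
    cr <- tg[ri - 1L] + (yv[ri - 1L] - lev) / (yv[ri - 1L] - yv[ri]) *
      diff(tg[1:2])
    c(cl, cr)
  }
  c50 <- crossings(0.5); c10 <- crossings(0.10)
  data.frame(mu = mu, sigma = sigma, tau = tau, amplitude = amplitude,
             area = area, height = h, apex_rt = tg[ai],
             fwhm = c50[2] - c50[1],
             tailing_factor = (c10[2] - tg[ai]) / (tg[ai] - c10[1]))
}

#' Generate a synthetic ion trace with known ground truth
#'
#' Builds a chromatogram as the sum of EMG-shaped peaks on a noise model
#' comprising a constant baseline, a slow linear drift, a periodic
#' low-amplitude ripple (emulating pump-stroke baseline artifacts) and
#' white Gaussian noise; intensities are clipped at zero.
#'
#' @param peaks Data.frame (or list of lists) with columns `mu`, `sigma`,
#'   `tau`, `amplitude` and optionally `mz`; may have zero rows.
#' @param noise List with `white_sd`, `baseline_level`, `drift_slope`
#'   (counts/second), `ripple_amplitude`, `ripple_period` (seconds) and
#'   `seed`; any field may be omitted (defaults 0; seed default 1).
#' @param rt_grid Increasing retention-time vector (seconds).
#' @return A list with `trace` (an `IonTrace`) and `truth` (a data.frame
#'   with per-peak analytic `area`, `height`, `apex_rt`, `fwhm`,
#'   `tailing_factor`).
#' @export
gen_trace <- function(peaks, noise = list(), rt_grid) {
  stopifnot(all(diff(rt_grid) > 0))
  g <- function(nm, d = 0) if (is.null(noise[[nm]])) d else noise[[nm]]
  peaks <- as.data.frame(peaks)
  y <- rep(g("baseline_level"), length(rt_grid)) +
    g("drift_slope") * rt_grid
  if (g("ripple_amplitude") > 0)
    y <- y + g("ripple_amplitude") *
      sin(2 * pi * rt_grid / g("ripple_period", 1))
  if (nrow(peaks) > 0L) for (i in seq_len(nrow(peaks)))
    y <- y + emg_profile(rt_grid, peaks$mu[i], peaks$sigma[i],
                         peaks$tau[i], peaks$amplitude[i])
  if (g("white_sd") > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(g("seed", 1))
    y <- y + stats::rnorm(length(rt_grid), 0, g("white_sd"))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  truth <- if (nrow(peaks) > 0L)
    do.call(rbind, lapply(seq_len(nrow(peaks)), function(i)
      peak_truth(peaks$mu[i], peaks$sigma[i], peaks$tau[i],
                 peaks$amplitude[i])))
  else peak_truth(0, 1, 0, 1)[0, ]
  list(trace = new_ion_trace(rt_grid, pmax(y, 0),
                             mz_target = if (!is.null(peaks$mz) &&
                                             nrow(peaks) > 0L) peaks$mz[1]
                                         else NA_real_,
                             ppm = NA_real_),
       truth = truth)
}

# Noise level of a signal as seen by the alternating-extrema estimator.
measure_noise_level <- function(y) {
  ext <- segment_extrema(y)
  if (length(ext) < 2L) return(0)
  mean(abs(diff(y[ext])))
}

#' Generate a labeled synthetic benchmark run
#'
#' Emulates a picked-peak table over raw data with known truth: `n_true`
#' EMG peaks whose signal-to-noise ratios are stratified over
#' `sn_strata` (each channel's amplitude is calibrated against the realized
#' noise of that channel, measured with the same alternating-extrema rule
#' used by the noise estimator, so the stated S/N is true by construction),
#' and `n_false` peak-table rows pointing at noise: ripple crests of a
#' strong periodic baseline artifact (odd false rows) and white-noise
#' excursions (even false rows), both with true S/N < 5. Every entry lives
#' on its own m/z channel (2 Da apart) so ion-trace extraction is
#' exercised; all channels share one scan grid and are written into one
#' MS1 spectrum per scan.
#'
#' @param n_true,n_false Number of true / false entries (>= 1).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param rt_max Run length in seconds (default 600).
#' @param scan_dt Scan spacing in seconds (default 0.5).
#' @param white_sd White-noise standard deviation (default 50 counts).
#' @param baseline_level Constant baseline (default 200 counts).
#' @param ripple_amplitude Ripple amplitude on ripple-false channels
#'   (default 100 counts; true channels use 30).
#' @param ripple_period Ripple period (default 25 s).
#' @param sn_strata True-peak S/N targets (default `c(15, 30, 60, 120)`),
#'   cycled over the true entries.
#' @return List with `run` (a `RawRun`), `peaks` (a chromPeaks-convention
#'   data.frame), `labels` (data.frame: `peak_id`, `label`, `class`,
#'   `sn_target`) and `truth` (per true peak).
#' @export
gen_benchmark <- function(n_true = 100L, n_false = 100L, seed = 42L,
                          rt_max = 600, scan_dt = 0.5, white_sd = 50,
                          baseline_level = 200, ripple_amplitude = 100,
                          ripple_period = 25,
                          sn_strata = c(15, 30, 60, 120)) {
  stopifnot(n_true >= 1L, n_false >= 1L)
  rt <- seq(0, rt_max, by = scan_dt)
  n_chan <- n_true + n_false
  mz <- 200 + (seq_len(n_chan) - 1L) * 2
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  sigma <- stats::runif(n_true, 2.5, 5)
  tau <- ifelse(stats::runif(n_true) < 0.5, 0,
                stats::runif(n_true, 0.2, 1.2) * sigma)
  mu <- stats::runif(n_true, 80, rt_max - 100)
  drift <- stats::runif(n_chan, -0.1, 0.1)
  sn_target <- rep_len(sn_strata, n_true)
  chan_seed <- seed %% 100000L + seq_len(n_chan) * 101L
  spike_rt <- stats::runif(n_false, 100, rt_max - 100)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  intens <- matrix(0, nrow = length(rt), ncol = n_chan)
  peaks <- vector("list", n_chan)
  labels <- vector("list", n_chan)
  truth <- vector("list", n_true)
  for (i in seq_len(n_chan)) {
    is_true <- i <= n_true
    ripple_class <- !is_true && ((i - n_true) %% 2L == 1L)
    noise <- list(white_sd = white_sd, baseline_level = baseline_level,
                  drift_slope = drift[i],
                  ripple_amplitude = if (is_true) 30
                                     else if (ripple_class) ripple_amplitude
                                     else 0,
                  ripple_period = ripple_period, seed = chan_seed[i])
    bg <- gen_trace(peaks = data.frame(mu = numeric(0), sigma = numeric(0),
                                       tau = numeric(0),
                                       amplitude = numeric(0)),
                    noise = noise, rt_grid = rt)
    if (is_true) {
      Nlvl <- measure_noise_level(bg$trace$intensity)
      amp <- sn_target[i] * Nlvl / 2
      tr <- peak_truth(mu[i], sigma[i], tau[i], amp)
      intens[, i] <- pmax(bg$trace$intensity +
        emg_profile(rt, mu[i], sigma[i], tau[i], amp), 0)
      truth[[i]] <- cbind(peak_id = sprintf("P%04d", i), tr,
                          stringsAsFactors = FALSE)
      peaks[[i]] <- data.frame(
        peak_id = sprintf("P%04d", i), mz = mz[i],
        mzmin = mz[i] * (1 - 25e-6), mzmax = mz[i] * (1 + 25e-6),
        rt = tr$apex_rt, rtmin = tr$apex_rt - 2 * sigma[i],
        rtmax = tr$apex_rt + 2 * sigma[i],
        into = tr$area, maxo = tr$height, sn = sn_target[i],
        sample = "synth1", stringsAsFactors = FALSE)
      labels[[i]] <- data.frame(peak_id = sprintf("P%04d", i), label = TRUE,
                                class = "emg", sn_target = sn_target[i],
                                stringsAsFactors = FALSE)
    } else {
      intens[, i] <- bg$trace$intensity
      if (ripple_class) {
        # nearest ripple crest to a random position
        k <- round((spike_rt[i - n_true] / ripple_period) - 0.25)
        crest <- ripple_period * (k + 0.25)
        pseudo_sigma <- ripple_period / 8
        cls <- "ripple"
      } else {
        # strongest white-noise excursion in the central region
        sel <- which(rt >= 100 & rt <= rt_max - 100)
        crest <- rt[sel[which.max(intens[sel, i])]]
        pseudo_sigma <- 1.5
        cls <- "spike"
      }
      peaks[[i]] <- data.frame(
        peak_id = sprintf("P%04d", i), mz = mz[i],
        mzmin = mz[i] * (1 - 25e-6), mzmax = mz[i] * (1 + 25e-6),
        rt = crest, rtmin = crest - 2 * pseudo_sigma,
        rtmax = crest + 2 * pseudo_sigma,
        into = NA_real_, maxo = NA_real_, sn = NA_real_,
        sample = "synth1", stringsAsFactors = FALSE)
      labels[[i]] <- data.frame(peak_id = sprintf("P%04d", i), label = FALSE,
                                class = cls, sn_target = NA_real_,
                                stringsAsFactors = FALSE)
    }
  }
  spectra <- lapply(seq_along(rt), function(si)
    cbind(mz = mz, intensity = intens[si, ]))
  list(run = new_raw_run(rt, spectra, run_id = sprintf("synth_seed%d", seed)),
       peaks = do.call(rbind, peaks),
       labels = do.call(rbind, labels),
       truth = do.call(rbind, truth))
}
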