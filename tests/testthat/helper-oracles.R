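# Independent oracle implementations used to cross-check the package.

# plain-loop alternating-extrema noise estimate (mean |peak-to-peak|)
oracle_noise <- function(y) {
  ext <- c()
  dir <- 0
  for (i in 2:length(y)) {
    d <- y[i] - y[i - 1]
    if (d == 0) next
    nd <- sign(d)
    if (dir != 0 && nd != dir) ext <- c(ext, i - 1)
    dir <- nd
  }
  if (length(ext) < 2) return(NA_real_)
  mean(abs(diff(y[ext])))
}

# brute-force baseline-expansion stepper, written independently of the
# package: works on a sampled trace, takes tangent slopes from plain
# central finite differences (not SG filters), and applies the rule (move
# the side with the larger normalized slope excess one scan outward until
# below the liftoff/touchdown fraction of the initial slope difference)
# in a direct loop.
oracle_expand <- function(yv, left0, right0,
                          liftoff = 0, touchdown = 0.5) {
  n <- length(yv)
  g <- function(i) {
    if (i <= 1) return(yv[2] - yv[1])
    if (i >= n) return(yv[n] - yv[n - 1])
    (yv[i + 1] - yv[i - 1]) / 2
  }
  L <- left0; R <- right0
  m0 <- (yv[R] - yv[L]) / (R - L)
  df0 <- g(L) - m0
  dt0 <- m0 - g(R)
  Tf <- liftoff / 100 * df0
  Tt <- touchdown / 100 * dt0
  fa <- df0 > 0; ta <- dt0 > 0
  for (step in seq_len(2 * n)) {
    m <- (yv[R] - yv[L]) / (R - L)
    df <- g(L) - m
    dtl <- m - g(R)
    if (fa && df <= Tf) fa <- FALSE
    if (ta && dtl <= Tt) ta <- FALSE
    if (!fa && !ta) break
    front <- if (fa && ta) (df / df0) >= (dtl / dt0) else fa
    if (front) {
      if (L <= 1) fa <- FALSE else L <- L - 1
    } else {
      if (R >= n) ta <- FALSE else R <- R + 1
    }
  }
  c(L, R)
}

# analytic derivative of a sum of EMG components, by numeric differentiation
# of the closed-form profile on a fine step (the profile itself is exact)
emg_mix_fun <- function(specs) {
  f <- function(t) {
    out <- 0
    for (i in seq_len(nrow(specs)))
      out <- out + emg_profile(t, specs$mu[i], specs$sigma[i],
                               specs$tau[i], specs$amplitude[i])
    out
  }
  d1 <- function(t) (f(t + 1e-4) - f(t - 1e-4)) / 2e-4
  list(f = f, d1 = d1)
}

# widths of an analytic profile at a height fraction, by fine-grid bisection
oracle_widths <- function(f, lo, hi, frac) {
  tg <- seq(lo, hi, length.out = 200001)
  yv <- f(tg)
  ai <- which.max(yv)
  lev <- frac * yv[ai]
  li <- max(which(yv[1:ai] <= lev))
  ri <- ai - 1 + min(which(yv[ai:length(yv)] <= lev))
  cl <- approx(yv[c(li, li + 1)], tg[c(li, li + 1)], xout = lev)$y
  cr <- approx(yv[c(ri - 1, ri)], tg[c(ri - 1, ri)], xout = lev)$y
  list(left = cl, right = cr, apex = tg[ai], width = cr - cl)
}
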