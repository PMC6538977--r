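# Brute-force / closed-form oracles and fixture builders shared by the tests.
# Each oracle is an independent re-implementation of the definition, kept
# deliberately naive (loops) so it cannot share bugs with the package code.

# O(n^2) sample entropy by direct pairwise template counting
sampen_bruteforce <- function(x, m = 2, r, tau = 1) {
  n <- length(x)
  N <- n - m * tau
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      db <- max(abs(x[i + (0:(m - 1)) * tau] - x[j + (0:(m - 1)) * tau]))
      if (db <= r) {
        B <- B + 1
        da <- max(db, abs(x[i + m * tau] - x[j + m * tau]))
        if (da <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# O(n^2) negative-peak prominence scan (the MUA definition, scanned naively)
mua_bruteforce <- function(x, fs, k_sd = 5) {
  s <- stats::sd(x); thr <- -k_sd * s; n <- length(x)
  out <- numeric(0)
  for (i in 2:(n - 1)) {
    if (x[i] < thr && x[i] < x[i - 1] && x[i] <= x[i + 1]) {
      h <- -x[i]
      lmin <- h; j <- i - 1
      while (j >= 1 && -x[j] <= h) { lmin <- min(lmin, -x[j]); j <- j - 1 }
      rmin <- h; j <- i + 1
      while (j <= n && -x[j] <= h) { rmin <- min(rmin, -x[j]); j <- j + 1 }
      if (h - max(lmin, rmin) > h / 2) out <- c(out, (i - 1) / fs)
    }
  }
  out
}

# unit-SD Gaussian noise with injected biphasic negative spikes of amplitude
# `amp` (in SD units); returns the trace and the true peak positions
inject_spikes <- function(n, fs, n_spk, amp, seed,
                          margin = max(200L, round(0.05 * n))) {
  set.seed(seed)
  x <- stats::rnorm(n)
  pos <- sort(sample(seq(margin, n - margin), n_spk))
  pos <- pos[c(TRUE, diff(pos) > 0.01 * fs)]
  w <- round(-0.0004 * fs):round(0.0004 * fs)
  shape <- -exp(-(w / (0.00015 * fs))^2) * cos(pi * w / (0.0008 * fs))
  for (p in pos) x[p + w] <- x[p + w] + amp * shape
  list(x = x, pos = pos)
}

# quick feature_table from a plain data frame of features + labels
toy_feature_table <- function(features, concentration, subject_id = "s1",
                              age_months = NA_real_) {
  meta <- data.frame(minute = seq_len(nrow(features)),
                     concentration = concentration,
                     subject_id = subject_id, age_months = age_months)
  anesdepth:::new_feature_table(meta, features)
}

# separable two-class toy table: features shift with the binary label
toy_separable_table <- function(n = 120, seed = 1) {
  set.seed(seed)
  conc <- sample(c(0, 0, 1, 2, 3), n, replace = TRUE)
  f <- data.frame(a = conc + stats::rnorm(n, 0, 0.15),
                  b = stats::rnorm(n),
                  c = sqrt(conc) + stats::rnorm(n, 0, 0.2))
  toy_feature_table(f, conc)
}

expected_ppc <- function(kappa) (besselI(kappa, 1) / besselI(kappa, 0))^2

# von Mises phases mapped onto an integer number of cycles of a `f0` Hz
# sinusoid: spike times whose field phase equals the drawn phases
phases_to_spike_times <- function(phases, f0, n_cycles, margin_cycles = 5) {
  cyc <- sample(margin_cycles:(n_cycles - margin_cycles), length(phases),
                replace = TRUE)
  (cyc + (phases %% (2 * pi)) / (2 * pi)) / f0
}
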