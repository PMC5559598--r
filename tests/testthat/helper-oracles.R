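# Independent oracles used by the tests. These are deliberately written
# against different representations than the package code paths they
# check (isochromat Bloch vs configuration states; closed-form OLS vs
# lm; two-pass sd vs vectorized stats).

# Brute-force isochromat Bloch simulation of the inversion-prepared FISP
# sequence: nspins spins with per-TR dephasing increments uniformly
# spanning one full cycle; the recorded sample is the mean transverse
# magnetization at the echo time after each pulse.
bloch_fisp <- function(T1, T2, fa_deg, tr, ti, te, inv_eff = 1,
                       nspins = 2001) {
  th <- 2 * pi * (seq_len(nspins) - 0.5) / nspins
  Mx <- rep(0, nspins); My <- rep(0, nspins); Mz <- rep(-inv_eff, nspins)
  relax <- function(dt) {
    e1 <- exp(-dt / T1); e2 <- exp(-dt / T2)
    Mx <<- Mx * e2; My <<- My * e2; Mz <<- 1 + (Mz - 1) * e1
  }
  relax(ti)
  out <- complex(length(fa_deg))
  for (j in seq_along(fa_deg)) {
    a <- fa_deg[j] * pi / 180
    My2 <- cos(a) * My - sin(a) * Mz
    Mz <- sin(a) * My + cos(a) * Mz
    My <- My2
    relax(te)
    out[j] <- mean(complex(real = Mx, imaginary = My))
    relax(tr[j] - te)
    Mx2 <- Mx * cos(th) - My * sin(th)
    My <- Mx * sin(th) + My * cos(th)
    Mx <- Mx2
  }
  out
}

rel_rms <- function(a, b) sqrt(mean(Mod(a - b)^2)) / sqrt(mean(Mod(b)^2))

# textbook OLS slope/intercept
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# two-pass standard deviation
sd_two_pass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# hand-coded unpaired equal-variance t statistic
t_two_sample <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# is `match` within one local grid step of `truth` on an axis?
within_one_step <- function(truth, match, axis) {
  i <- findInterval(truth, axis)
  lo <- axis[pmax(i, 1L)]
  hi <- axis[pmin(i + 1L, length(axis))]
  abs(match - truth) <= (hi - lo) + 1e-9
}
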