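## Simulators and fits for the reference relaxometry experiments:
## inversion-recovery spin-echo T1 and CPMG (or multi-TE spin-echo) T2.

## Evaluate an expression with a locally seeded RNG, restoring the
## caller's RNG state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

dcmrf_fit_failure <- function(msg, diagnostics = list()) {
  structure(class = c("dcmrf_fit_failure", "error", "condition"),
            list(message = msg, call = sys.call(-1),
                 diagnostics = diagnostics))
}

#' Simulate inversion-recovery signals
#'
#' Signed inversion-recovery spin-echo signal
#' \deqn{S(TI) = M_0 (1 - 2\beta e^{-TI/T1})}
#' with \eqn{\beta} the inversion efficiency, sampled at the schedule's
#' inversion times, optionally with additive zero-mean Gaussian noise of
#' standard deviation \code{noise_sd * M0} (the standard thermal-noise
#' model).
#'
#' @param T1 longitudinal relaxation time, ms (> 0).
#' @param sched an \code{\link{IRSchedule}}.
#' @param M0 equilibrium signal amplitude (arbitrary units).
#' @param noise_sd noise standard deviation as a fraction of \code{M0}.
#' @param seed integer seed for the noise draw (NULL = use current RNG).
#' @return numeric vector, one signed value per inversion time.
#' @export
simulateIRSignal <- function(T1, sched, M0 = 1, noise_sd = 0, seed = NULL) {
  stopifnot(is(sched, "IRSchedule"))
  if (!.scalar_ok(T1) || T1 <= 0) stop("'T1' must be finite and > 0")
  if (!.scalar_ok(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  ti <- sched@inversionTimes
  s <- M0 * (1 - 2 * sched@inversionEfficiency * exp(-ti / T1))
  if (noise_sd > 0)
    s <- s + with_seed(seed, rnorm(length(ti), sd = noise_sd * M0))
  s
}

#' Fit T1 from inversion-recovery signals
#'
#' Nonlinear least-squares fit of the signed three-parameter model
#' \eqn{S(TI) = a - b\, e^{-TI/T1}} (so \eqn{M_0 = a},
#' \eqn{\beta = b / 2a}). A coarse profile search over log-spaced T1
#' candidates (with the linear parameters solved exactly at each
#' candidate) provides the start, refined by Levenberg-Marquardt.
#'
#' @param signal signed IR signals, one per inversion time.
#' @param sched the \code{\link{IRSchedule}} used.
#' @param full if TRUE return a list with \code{T1}, \code{M0},
#'   \code{beta} and the residual sum of squares; otherwise just T1.
#' @return fitted T1 in ms (or a list, see \code{full}).
#' @export
fitT1IR <- function(signal, sched, full = FALSE) {
  stopifnot(is(sched, "IRSchedule"))
  ti <- sched@inversionTimes
  signal <- as.numeric(signal)
  if (length(signal) != length(ti))
    stop("'signal' length must match the number of inversion times")
  if (length(ti) < 3L) stop("at least 3 inversion times are required")
  scl <- max(abs(signal))
  if (scl == 0 || diff(range(signal)) < 1e-12 * max(scl, 1))
    stop(dcmrf_fit_failure("constant IR signal: no decay information",
                           list(signal = signal)))
  ## profile the linear parameters over a T1 grid
  cand <- exp(seq(log(min(ti) / 3), log(max(ti) * 3), length.out = 60))
  best <- NULL
  for (t1 in cand) {
    X <- cbind(1, -exp(-ti / t1))
    cf <- tryCatch(qr.coef(qr(X), signal), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    rss <- sum((signal - X %*% cf)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(t1 = t1, a = cf[1], b = cf[2], rss = rss)
  }
  if (is.null(best))
    stop(dcmrf_fit_failure("IR profile search failed", list(signal = signal)))
  df <- data.frame(ti = ti, s = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ a - b * exp(-ti / T1), data = df,
                      start = list(a = best$a, b = best$b, T1 = best$t1),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop(dcmrf_fit_failure("IR nonlinear fit did not converge",
                           list(start = best, signal = signal)))
  cf <- coef(fit)
  out <- list(T1 = unname(cf["T1"]), M0 = unname(cf["a"]),
              beta = unname(cf["b"] / (2 * cf["a"])),
              rss = sum(stats::residuals(fit)^2))
  if (full) out else out$T1
}

#' Simulate a CPMG echo train
#'
#' Mono-exponential echo amplitudes
#' \eqn{S(k) = M_0 e^{-k\,\Delta t / T2}} for k = 1..n echoes with echo
#' spacing \eqn{\Delta t}, optionally with additive Gaussian noise.
#'
#' @param T2 transverse relaxation time, ms (> 0).
#' @param sched a \code{\link{CPMGSchedule}}.
#' @inheritParams simulateIRSignal
#' @return numeric vector of echo amplitudes.
#' @export
simulateCPMG <- function(T2, sched, M0 = 1, noise_sd = 0, seed = NULL) {
  stopifnot(is(sched, "CPMGSchedule"))
  if (!.scalar_ok(T2) || T2 <= 0) stop("'T2' must be finite and > 0")
  if (!.scalar_ok(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  t <- echoTimes(sched)
  s <- M0 * exp(-t / T2)
  if (noise_sd > 0)
    s <- s + with_seed(seed, rnorm(length(t), sd = noise_sd * M0))
  s
}

#' Fit T2 from a mono-exponential decay
#'
#' Log-linear least squares on \eqn{\log S = \log M_0 - t/T2} when all
#' amplitudes are positive; falls back to a nonlinear
#' Levenberg-Marquardt fit of \eqn{S = M_0 e^{-t/T2}} when any
#' amplitude is non-positive (as happens with noisy late echoes).
#' Works for CPMG echo trains and for multi-TE single-echo spin-echo
#' series alike; pass the echo times explicitly for the latter.
#'
#' @param amplitudes echo amplitudes.
#' @param times echo times in ms (e.g. \code{echoTimes(sched)}); must
#'   contain at least two distinct values.
#' @param full if TRUE return a list with \code{T2}, \code{M0} and the
#'   mode used; otherwise just T2.
#' @return fitted T2 in ms (or a list, see \code{full}).
#' @export
fitT2Mono <- function(amplitudes, times, full = FALSE) {
  if (is(times, "CPMGSchedule")) times <- echoTimes(times)
  amplitudes <- as.numeric(amplitudes)
  times <- as.numeric(times)
  if (length(amplitudes) != length(times))
    stop("'amplitudes' and 'times' must have equal length")
  if (length(unique(times)) < 2L)
    stop("at least 2 distinct echo times are required")
  if (diff(range(amplitudes)) <= 0)
    stop(dcmrf_fit_failure("constant echo amplitudes: no decay information",
                           list(amplitudes = amplitudes)))
  if (all(amplitudes > 0)) {
    cf <- coef(lm(log(amplitudes) ~ times))
    out <- list(T2 = -1 / unname(cf[2]), M0 = exp(unname(cf[1])),
                mode = "log-linear")
    if (out$T2 > 0) return(if (full) out else out$T2)
    ## growing "decay" (heavy noise): fall through to nonlinear fit
  }
  keep <- amplitudes > 0
  if (sum(keep) < 2L)
    stop(dcmrf_fit_failure("too few positive amplitudes for a T2 start",
                           list(amplitudes = amplitudes)))
  cf0 <- coef(lm(log(amplitudes[keep]) ~ times[keep]))
  t2_0 <- if (cf0[2] < 0) unname(-1 / cf0[2]) else max(times)
  df <- data.frame(t = times, s = amplitudes)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ M0 * exp(-t / T2), data = df,
                      start = list(M0 = exp(unname(cf0[1])), T2 = t2_0),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop(dcmrf_fit_failure("T2 nonlinear fit did not converge",
                           list(amplitudes = amplitudes)))
  cf <- coef(fit)
  out <- list(T2 = unname(cf["T2"]), M0 = unname(cf["M0"]), mode = "nonlinear")
  if (full) out else out$T2
}

#' Run a simulated relaxometry study
#'
#' Simulates the reference-relaxometry arm of a phantom study: per
#' sample, \code{t1_repeats} independent IR measurements and
#' \code{t2_repeats} independent CPMG measurements are simulated at the
#' sample's true (T1, T2) and fitted; repeated fits are averaged into a
#' single T1 and T2 per sample.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{T1},
#'   \code{T2} (ms) and optionally \code{t1_repeats} (default 2) and
#'   \code{t2_repeats} (default 3).
#' @param ir_sched an \code{\link{IRSchedule}}.
#' @param cpmg_sched a \code{\link{CPMGSchedule}}.
#' @param noise_sd Gaussian noise sd as a fraction of M0.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return data.frame with columns \code{sample_id}, \code{T1_ms},
#'   \code{T2_ms}, \code{T1_sd}, \code{T2_sd} (sd across repeats, NA for
#'   a single repeat).
#' @export
runRelaxometryStudy <- function(samples, ir_sched, cpmg_sched,
                                noise_sd = 0, seed = NULL) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) stop("'samples' must be non-empty")
  need <- c("sample_id", "T1", "T2")
  if (!all(need %in% names(samples)))
    stop("'samples' needs columns: ", paste(need, collapse = ", "))
  if (is.null(samples$t1_repeats)) samples$t1_repeats <- 2L
  if (is.null(samples$t2_repeats)) samples$t2_repeats <- 3L
  if (any(samples$t1_repeats < 1L) || any(samples$t2_repeats < 1L))
    stop("repeat counts must be >= 1")
  with_seed(seed, {
    res <- lapply(seq_len(nrow(samples)), function(i) {
      row <- samples[i, ]
      t1s <- tryCatch(
        vapply(seq_len(row$t1_repeats), function(r)
          fitT1IR(simulateIRSignal(row$T1, ir_sched, noise_sd = noise_sd),
                  ir_sched), numeric(1)),
        error = function(e)
          stop("T1 fit failed for sample '", row$sample_id, "': ",
               conditionMessage(e), call. = FALSE))
      t2s <- tryCatch(
        vapply(seq_len(row$t2_repeats), function(r)
          fitT2Mono(simulateCPMG(row$T2, cpmg_sched, noise_sd = noise_sd),
                    echoTimes(cpmg_sched)), numeric(1)),
        error = function(e)
          stop("T2 fit failed for sample '", row$sample_id, "': ",
               conditionMessage(e), call. = FALSE))
      data.frame(sample_id = row$sample_id,
                 T1_ms = mean(t1s), T2_ms = mean(t2s),
                 T1_sd = if (length(t1s) > 1) sd(t1s) else NA_real_,
                 T2_sd = if (length(t2s) > 1) sd(t2s) else NA_real_)
    })
    do.call(rbind, res)
  })
}
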