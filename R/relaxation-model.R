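## Linear dual-agent relaxation model, its closed-form inversion, and
## relaxivity calibration.

#' Forward dual-agent relaxation model
#'
#' Post-contrast relaxation times of a solution containing two
#' paramagnetic agents under the linear relaxivity model
#' \deqn{1/T1 = 1/T1_0 + r_{1A} [A] + r_{1B} [B]}
#' \deqn{1/T2 = 1/T2_0 + r_{2A} [A] + r_{2B} [B]}
#' The model assumes the two agents shorten relaxation independently
#' (no agent-agent interaction), which holds at moderate concentrations.
#'
#' @param baseline \code{\link{BaselineRelaxation}} of the solvent.
#' @param agentA,agentB \code{\link{AgentRelaxivity}} of the two agents.
#'   \code{agentB} may be \code{NULL} for a single-agent solution.
#' @param concA,concB concentrations in mM; vectors are recycled to a
#'   common length. Must be finite and non-negative.
#' @return data.frame with columns \code{T1}, \code{T2} (ms).
#' @examples
#' water <- BaselineRelaxation(4250, 2760)
#' gd <- AgentRelaxivity("Gd", 0.0040, 0.0048)
#' mn <- AgentRelaxivity("Mn", 0.0054, 0.0652)
#' forwardRelaxation(water, gd, mn, concA = 0.2, concB = 0.1)
#' @seealso \code{\link{invertDualAgent}} for the closed-form inverse.
#' @export
forwardRelaxation <- function(baseline, agentA, agentB = NULL,
                              concA, concB = 0) {
  stopifnot(is(baseline, "BaselineRelaxation"), is(agentA, "AgentRelaxivity"))
  if (is.null(agentB)) {
    agentB <- AgentRelaxivity("none", 1e-9, 1e-9)
    if (any(concB != 0)) stop("concB must be 0 when agentB is NULL")
  }
  stopifnot(is(agentB, "AgentRelaxivity"))
  n <- max(length(concA), length(concB))
  concA <- rep_len(as.numeric(concA), n)
  concB <- rep_len(as.numeric(concB), n)
  if (any(!is.finite(concA)) || any(!is.finite(concB)))
    stop("concentrations must be finite")
  if (any(concA < 0) || any(concB < 0))
    stop("concentrations must be non-negative")
  R1 <- 1 / baseline@T1 + agentA@r1 * concA + agentB@r1 * concB
  R2 <- 1 / baseline@T2 + agentA@r2 * concA + agentB@r2 * concB
  data.frame(T1 = 1 / R1, T2 = 1 / R2)
}

#' Relaxivity determinant of a dual-agent system
#'
#' The denominator of the closed-form inversion,
#' \code{r2A * r1B - r1A * r2B} (mM^-2 ms^-2). Two agents with
#' proportional relaxivity pairs give a vanishing determinant and an
#' unsolvable system.
#'
#' @inheritParams forwardRelaxation
#' @return a single number.
#' @export
relaxivityDeterminant <- function(agentA, agentB) {
  stopifnot(is(agentA, "AgentRelaxivity"), is(agentB, "AgentRelaxivity"))
  agentA@r2 * agentB@r1 - agentA@r1 * agentB@r2
}

#' Closed-form dual-agent inversion
#'
#' Solves the linear dual-agent relaxation model for the two
#' concentrations given measured post-contrast T1 and T2:
#' \deqn{[A] = (\Delta R2\, r_{1B} - \Delta R1\, r_{2B}) /
#'             (r_{2A} r_{1B} - r_{1A} r_{2B})}
#' \deqn{[B] = (\Delta R2 - r_{2A} [A]) / r_{2B}}
#' with \eqn{\Delta R1 = 1/T1 - 1/T1_0} and
#' \eqn{\Delta R2 = 1/T2 - 1/T2_0}. Agent A plays the Gd role and agent
#' B the Mn role of a Gd/Mn pair.
#'
#' Noisy measurements can yield (slightly) negative concentrations;
#' these are returned as-is. Clamping at zero is a map-level option of
#' \code{\link{concentrationMaps}}, not part of the inversion.
#'
#' @inheritParams forwardRelaxation
#' @param T1,T2 measured post-contrast relaxation times, ms (vectors are
#'   recycled to a common length).
#' @param det_tol singularity guard: if the absolute relaxivity
#'   determinant is below this threshold (mM^-2 ms^-2) the system is
#'   treated as degenerate and an error is raised.
#' @return data.frame with columns \code{concA}, \code{concB} (mM).
#' @examples
#' water <- BaselineRelaxation(4250, 2760)
#' gd <- AgentRelaxivity("Gd", 0.0040, 0.0048)
#' mn <- AgentRelaxivity("Mn", 0.0054, 0.0652)
#' tt <- forwardRelaxation(water, gd, mn, 0.2, 0.1)
#' invertDualAgent(water, gd, mn, tt$T1, tt$T2)  # recovers 0.2, 0.1
#' @export
invertDualAgent <- function(baseline, agentA, agentB, T1, T2,
                            det_tol = 1e-12) {
  stopifnot(is(baseline, "BaselineRelaxation"),
            is(agentA, "AgentRelaxivity"), is(agentB, "AgentRelaxivity"))
  det <- relaxivityDeterminant(agentA, agentB)
  if (!is.finite(det) || abs(det) < det_tol)
    stop("singular dual-agent model: |r2A*r1B - r1A*r2B| = ",
         format(abs(det)), " < det_tol; the two agents' relaxivities are ",
         "too similar to separate")
  n <- max(length(T1), length(T2))
  T1 <- rep_len(as.numeric(T1), n)
  T2 <- rep_len(as.numeric(T2), n)
  if (any(!is.finite(T1)) || any(!is.finite(T2)) ||
      any(T1 <= 0) || any(T2 <= 0))
    stop("measured T1 and T2 must be finite and > 0")
  dR1 <- 1 / T1 - 1 / baseline@T1
  dR2 <- 1 / T2 - 1 / baseline@T2
  concA <- (dR2 * agentB@r1 - dR1 * agentB@r2) / det
  concB <- (dR2 - agentA@r2 * concA) / agentB@r2
  data.frame(concA = concA, concB = concB)
}

#' Relaxivity calibration by ordinary least squares
#'
#' Fits \code{rate ~ concentration} by OLS; the slope is the agent's
#' relaxivity when \code{rate} is R1 or R2 in ms^-1 and concentration is
#' in mM. The intercept is fitted freely (it estimates the solvent's
#' baseline rate); \code{r_squared} is the squared Pearson correlation
#' and the two-tailed p-value comes from the t statistic of the
#' correlation with n - 2 degrees of freedom.
#'
#' @param concentration concentrations, mM; at least two distinct values.
#' @param rate relaxation rates, ms^-1; same length as
#'   \code{concentration}.
#' @return a \code{\link{CalibrationFit}}.
#' @examples
#' conc <- c(0.05, 0.1, 0.2, 0.35, 0.5)
#' fitRelaxivity(conc, 1 / 4250 + 0.0040 * conc)  # slope 0.0040, R^2 = 1
#' @export
fitRelaxivity <- function(concentration, rate) {
  concentration <- as.numeric(concentration)
  rate <- as.numeric(rate)
  if (length(concentration) != length(rate))
    stop("'concentration' and 'rate' must have equal length")
  if (length(concentration) < 2L)
    stop("at least 2 points are required")
  if (any(!is.finite(concentration)) || any(!is.finite(rate)))
    stop("inputs must be finite")
  if (length(unique(concentration)) < 2L)
    stop("degenerate design: all concentrations identical")
  fit <- lm(rate ~ concentration)
  n <- length(rate)
  if (sd(rate) == 0) {
    r2 <- NA_real_; p <- NA_real_
  } else {
    r <- stats::cor(concentration, rate)
    r2 <- r * r
    p <- if (n >= 3L) {
      if (1 - r2 <= 0) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r2))
        2 * pt(-abs(tstat), df = n - 2)
      }
    } else NA_real_
  }
  new("CalibrationFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      rSquared = r2, pValue = p, n = as.integer(n))
}
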