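## Built-in reference parameters for the gadobenate dimeglumine (Gd) /
## MnCl2 (Mn) agent pair in deionized water, the system the package's
## default phantoms emulate.

.relaxivity_table <- data.frame(
  agent   = rep(c("Gd", "Mn"), each = 3),
  context = rep(c("60MHz", "3T_SE", "3T_MRF"), 2),
  r1      = c(0.0040, 0.0051, 0.0056, 0.0054, 0.0068, 0.0067),
  r2      = c(0.0048, 0.0060, 0.0076, 0.0652, 0.1079, 0.1144),
  stringsAsFactors = FALSE
)

#' Reference relaxivities of the Gd/Mn agent pair
#'
#' Relaxivities (mM^-1 ms^-1) of gadobenate dimeglumine ("Gd") and
#' manganese chloride ("Mn") in deionized water, per measurement
#' context: a 60 MHz relaxometer at 37 C (\code{"60MHz"}), conventional
#' 3 T spin-echo relaxometry at room temperature (\code{"3T_SE"}), and
#' 3 T MRF at room temperature (\code{"3T_MRF"}).
#'
#' @param agent \code{"Gd"} or \code{"Mn"}; if missing, the full table
#'   is returned.
#' @param context one of \code{"60MHz"}, \code{"3T_SE"}, \code{"3T_MRF"}.
#' @return an \code{\link{AgentRelaxivity}}, or the full data.frame when
#'   \code{agent} is missing.
#' @examples
#' referenceRelaxivities()               # full table
#' referenceRelaxivities("Gd", "60MHz")  # r1 = 0.0040, r2 = 0.0048
#' @export
referenceRelaxivities <- function(agent, context = c("60MHz", "3T_SE", "3T_MRF")) {
  if (missing(agent)) return(.relaxivity_table)
  context <- match.arg(context)
  row <- .relaxivity_table[.relaxivity_table$agent == agent &
                           .relaxivity_table$context == context, ]
  if (nrow(row) != 1L) stop("unknown agent '", agent, "'")
  AgentRelaxivity(agent, row$r1, row$r2)
}

#' Reference deionized-water baselines
#'
#' Pre-contrast relaxation times of deionized water: (4250, 2760) ms at
#' 60 MHz / 37 C and (2897, 946) ms measured by MRF at 3 T / room
#' temperature. The 3 T values serve both spin-echo and MRF contexts.
#'
#' @param context \code{"60MHz"} or \code{"3T"}.
#' @return a \code{\link{BaselineRelaxation}}.
#' @export
referenceBaseline <- function(context = c("60MHz", "3T")) {
  context <- match.arg(context)
  switch(context,
         "60MHz" = BaselineRelaxation(4250, 2760),
         "3T"    = BaselineRelaxation(2897, 946))
}
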