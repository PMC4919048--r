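## Pathway kinetics: flux-force efficacy, BRENDA-style specific-activity
## aggregation, and pathway specific activity.

#' Flux-Force Efficacy
#'
#' Fraction of the total flux through the thermodynamic bottleneck reaction
#' that runs forward, \eqn{(e^{B/RT} - 1)/(e^{B/RT} + 1)} with B the
#' driving force (the pathway MDF). Strictly increasing and odd in B, with
#' values in (-1, 1).
#'
#' @param mdf driving force in kJ/mol (scalar or vector).
#' @param settings a [thermo_settings()]; the default evaluates at
#'   298.15 K.
#' @return dimensionless efficacy.
#' @export
#' @examples
#' ffe(5.66)  # ~0.81
ffe <- function(mdf, settings = thermo_settings()) {
  x <- exp(mdf / settings$RT)
  (x - 1) / (x + 1)
}

#' Aggregate specific-activity observations
#'
#' The working estimate for an enzyme's specific activity from a BRENDA-style
#' collection: sort ascending, discard the lower 50\% and the upper 10\%
#' (counts rounded down, so at least one value is always retained), and
#' average the rest. The trim suppresses unnaturally low or high activities
#' from non-representative in vitro conditions.
#'
#' @param values positive activities (umol/mg protein/min).
#' @return the trimmed mean.
#' @export
#' @examples
#' aggregate_specific_activity(1:10)  # mean of 6,7,8,9 = 7.5
aggregate_specific_activity <- function(values) {
  if (length(values) == 0L) stop("no specific-activity observations")
  if (any(!is.finite(values) | values <= 0))
    stop("specific activities must be positive")
  v <- sort(values)
  n <- length(v)
  lo <- floor(0.5 * n)
  hi <- floor(0.1 * n)
  mean(v[(lo + 1):(n - hi)])
}

#' Pathway Specific Activity
#'
#' Upper-limit pathway flux carried by 1 mg of total pathway protein,
#' \eqn{PSA = 1 / \sum_i w_i / V_i}, with \eqn{w_i} the stoichiometric
#' coefficient of enzyme i per mole of end product (pyruvate) and
#' \eqn{V_i} its specific activity. Never exceeds \eqn{\min_i V_i/w_i},
#' with equality only for a single-enzyme pathway.
#'
#' @param kinetics a data.frame with columns \code{w} and
#'   \code{specific_activity} (e.g. [kinetics_table()]), or a pathway
#'   token.
#' @return umol pyruvate/mg pathway protein/min.
#' @export
#' @examples
#' psa("rtca")
psa <- function(kinetics) {
  if (is.character(kinetics)) kinetics <- kinetics_table(kinetics)
  w <- kinetics$w
  V <- kinetics$specific_activity
  if (any(!is.finite(w) | w <= 0)) stop("w coefficients must be positive")
  if (any(!is.finite(V) | V <= 0)) stop("specific activities must be positive")
  1 / sum(w / V)
}
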