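#' Triage tool classification
#'
#' Applies a triage tool (combined tool + paramedic judgement) to patients.
#' A patient with ISS >= 16 is classified positive (sent to the MTC) with
#' probability equal to the tool's sensitivity; a patient with ISS < 16 is
#' classified positive with probability 1 - specificity. Vectorised;
#' `u` supplies the uniform draws so common random numbers can be shared
#' across tools.
#'
#' @param iss_ge16 Logical vector: ISS >= 16.
#' @param sensitivity,specificity Tool operating characteristics in \[0,1\].
#' @param u Uniform(0,1) draws, one per patient.
#' @return Logical vector: tool positive.
#' @export
classify_triage <- function(iss_ge16, sensitivity, specificity, u) {
  stopifnot(length(u) == length(iss_ge16), all(u >= 0 & u < 1))
  ifelse(iss_ge16, u < sensitivity, u < (1 - specificity))
}

#' Assign the care pathway after triage
#'
#' Implements the decision tree. Tool-positive patients always receive MTC
#' care (`ever_mtc`); with probability `tp` (true positives) or `fp` (false
#' positives) they are first stabilised at a local hospital and then
#' transferred, incurring the transfer cost. Tool-negative patients start
#' at a local hospital and are transferred onwards with probability `fn`
#' (ISS >= 16) or `tn` (ISS < 16); only transferred negatives ever reach
#' the MTC.
#'
#' @param tool_positive Logical vector from [classify_triage()].
#' @param iss_ge16 Logical vector: ISS >= 16.
#' @param transfers Named list with probabilities `tp`, `fn`, `tn`, `fp`
#'   (secondary transfer by triage category).
#' @param u Uniform(0,1) draws, one per patient.
#' @return Data frame with logical columns `tool_positive`, `local_first`,
#'   `transferred`, `ever_mtc`.
#' @export
assign_pathway <- function(tool_positive, iss_ge16, transfers, u) {
  stopifnot(length(u) == length(tool_positive), all(u >= 0 & u < 1))
  p_transfer <- ifelse(tool_positive,
                       ifelse(iss_ge16, transfers$tp, transfers$fp),
                       ifelse(iss_ge16, transfers$fn, transfers$tn))
  transferred <- u < p_transfer
  data.frame(
    tool_positive = tool_positive,
    local_first = !tool_positive | transferred,
    transferred = transferred,
    ever_mtc = tool_positive | transferred
  )
}

#' Expected MTC flows (analytic, no simulation)
#'
#' Closed-form expected number of patients ever treated at an MTC, split by
#' severity, given the tool's operating characteristics and the secondary
#' transfer probabilities:
#' `E[ISS>=16 at MTC] = n16 * (sens + (1 - sens) * fn)` and
#' `E[ISS<16 at MTC] = nLT16 * ((1 - spec) + spec * tn)`.
#' Serves as the exact oracle for the Monte-Carlo engine's flow outputs.
#'
#' @param sensitivity,specificity Tool operating characteristics.
#' @param n_iss16,n_issLT16 Patient counts in each severity stratum.
#' @param transfers Transfer probability list (`tp`, `fn`, `tn`, `fp`).
#' @return Data frame with `mtc_iss16`, `mtc_issLT16`, `mtc_total`.
#' @export
#' @examples
#' p <- default_parameters()
#' expected_flows(0.284, 0.886, 8916, 91084, p$clinical$transfer)
expected_flows <- function(sensitivity, specificity, n_iss16, n_issLT16,
                           transfers) {
  stopifnot(n_iss16 >= 0, n_issLT16 >= 0)
  m16 <- n_iss16 * (sensitivity + (1 - sensitivity) * transfers$fn)
  mlt <- n_issLT16 * ((1 - specificity) + specificity * transfers$tn)
  data.frame(mtc_iss16 = m16, mtc_issLT16 = mlt, mtc_total = m16 + mlt)
}
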