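# General solubility equation (GSE): links intrinsic aqueous solubility to
# the melting point and the octanol/water partition coefficient.

#' Intrinsic log molar solubility from the general solubility equation
#'
#' `logS = 0.5 - 0.01 (MP - 25) - logP`, with MP in degrees Celsius.
#' Liquids (MP below 25 degrees C) are conventionally entered with
#' MP = 25, making the MP term vanish; `logp` is an input, measured or
#' externally predicted.
#'
#' @param mp_c melting point(s), degrees Celsius (> -273.15).
#' @param logp octanol/water partition coefficient(s).
#' @return log10 molar intrinsic solubility.
#' @examples
#' gse_logs(25, 0)    # 0.5
#' gse_logs(125, 2.3)
#' @export
gse_logs <- function(mp_c, logp) {
  stopifnot(all(mp_c > -273.15))
  0.5 - 0.01 * (mp_c - 25) - logp
}

#' Solubility-error contribution of a melting-point model
#'
#' Through the GSE's MP coefficient of 0.01 log units per degree C, a
#' melting-point prediction error of `mp_rmse` degrees C propagates to
#' `0.01 * mp_rmse` log units of solubility error.
#'
#' @param mp_rmse melting-point RMSE in degrees C (non-negative).
#' @return solubility error contribution in log units.
#' @examples
#' gse_error_contribution(30)  # 0.3
#' @export
gse_error_contribution <- function(mp_rmse) {
  stopifnot(all(mp_rmse >= 0))
  0.01 * mp_rmse
}
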