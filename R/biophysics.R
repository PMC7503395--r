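# Derived quantities linking AIS morphology and physiology.

#' AIS capacitance from cylinder geometry
#'
#' Open-cylinder lateral area `pi * d * L` times the specific membrane
#' capacitance (default 1 uF/cm^2 = 0.01 pF/um^2); no end caps.
#'
#' @param length_um AIS length, um.
#' @param diameter_um AIS diameter, um.
#' @param specific_capacitance Specific membrane capacitance, uF/cm^2.
#' @return An object of class `"ais_capacitance"`: `c_ais` (pF),
#'   `area_um2`, inputs echoed.
#' @export
ais_capacitance <- function(length_um, diameter_um,
                            specific_capacitance = 1.0) {
  if (any(c(length_um, diameter_um, specific_capacitance) <= 0)) {
    stop("parameter error: geometry and specific capacitance must be > 0",
         call. = FALSE)
  }
  area <- pi * diameter_um * length_um
  structure(list(c_ais = area * specific_capacitance * 0.01,
                 area_um2 = area, length_um = length_um,
                 diameter_um = diameter_um,
                 specific_capacitance = specific_capacitance),
            class = "ais_capacitance")
}

#' Estimated AIS inward current
#'
#' `I = C * dV/dt`: the AIS capacitance times the initial-segment component
#' of the phase plot; pF times V/s gives pA.
#'
#' @param c_ais AIS capacitance, pF (number or [ais_capacitance()]).
#' @param is_component IS component, V/s.
#' @return List of class `"estimated_ais_current"`: `i_in_ais` (pA),
#'   `c_ais`, `is_component`.
#' @export
estimate_ais_current <- function(c_ais, is_component) {
  if (inherits(c_ais, "ais_capacitance")) c_ais <- c_ais$c_ais
  if (c_ais <= 0 || is_component < 0) {
    stop("parameter error: c_ais must be > 0 and is_component >= 0",
         call. = FALSE)
  }
  structure(list(i_in_ais = c_ais * is_component, c_ais = c_ais,
                 is_component = is_component),
            class = "estimated_ais_current")
}

#' Fit the rheobase-input-resistance hyperbola (Ohm's law)
#'
#' Least-squares fit in current space of `rheobase = V / Rin` over all
#' cells, with the single free parameter `V` (the depolarization needed to
#' reach threshold). The closed-form solution is
#' `V = sum(I_i / R_i) / sum(1 / R_i^2)`.
#'
#' @param rin_mohm Input resistances, MOhm (> 0).
#' @param rheobase_pa Rheobase currents, pA.
#' @return An object of class `"hyperbola_fit"`: `V` (mV), `rss` (pA^2),
#'   `n`.
#' @export
fit_rheobase_hyperbola <- function(rin_mohm, rheobase_pa) {
  if (length(rin_mohm) != length(rheobase_pa)) {
    stop("rin and rheobase must have equal length", call. = FALSE)
  }
  if (length(rin_mohm) < 2L) {
    stop("fit error: at least 2 (Rin, rheobase) pairs are required",
         call. = FALSE)
  }
  if (any(rin_mohm <= 0)) stop("Rin must be > 0", call. = FALSE)
  v_pa_mohm <- sum(rheobase_pa / rin_mohm) / sum(1 / rin_mohm^2)
  resid <- rheobase_pa - v_pa_mohm / rin_mohm
  structure(list(V = v_pa_mohm / 1000,   # pA*MOhm -> mV
                 rss = sum(resid^2), n = length(rin_mohm)),
            class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat(sprintf("<hyperbola_fit> V = %.2f mV (n = %d, rss = %.3g pA^2)\n",
              x$V, x$n, x$rss))
  invisible(x)
}

#' Depolarization at rheobase
#'
#' The empirical estimate of the voltage term of the rheobase hyperbola:
#' the difference between AP threshold and resting potential.
#'
#' @param erest Resting potential, mV.
#' @param threshold AP threshold, mV (must not lie below `erest`).
#' @return `threshold - erest`, mV; a zero difference is flagged with a
#'   warning.
#' @export
depolarization_at_rheobase <- function(erest, threshold) {
  if (threshold < erest) {
    stop("sign error: threshold lies below Erest", call. = FALSE)
  }
  if (threshold == erest) {
    warning("threshold equals Erest: zero depolarization at rheobase")
  }
  threshold - erest
}
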