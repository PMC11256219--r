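# Analytic quartz-crystal-microbalance (QCM-D) support calculations: the
# shear-wave penetration depth that sets the technique's depth sensitivity,
# and the Sauerbrey mass-frequency relation for thin rigid films.

#' Properties of water for QCM calculations
#'
#' Dynamic viscosity and density of pure water at the measurement
#' temperature. The 38 degree C defaults (0.681 mPa s, 992.6 kg m^-3) are
#' standard-table values; both are overridable.
#'
#' @param temperature Label only (stored, not used in a correlation).
#' @param viscosity Pa s.
#' @param density kg m^-3.
#' @return A list with `viscosity`, `density`, `temperature`.
#' @export
water_properties <- function(temperature = 38, viscosity = 6.81e-4,
                             density = 992.6) {
  if (viscosity <= 0 || density <= 0) {
    stop("viscosity and density must be positive", call. = FALSE)
  }
  list(viscosity = viscosity, density = density, temperature = temperature)
}

#' Shear-wave penetration depth
#'
#' \eqn{\delta = \sqrt{\eta / (\pi \rho f_0 n)}}: the decay length of the
#' evanescent shear wave launched into the liquid by a quartz sensor of
#' fundamental frequency \eqn{f_0} driven at odd overtone \eqn{n}. The depth
#' sensitivity of QCM-D is inversely proportional to the overtone:
#' \eqn{\delta(n)/\delta(3) = \sqrt{3/n}}.
#'
#' @param overtone Odd overtone number(s), `>= 1`. Vectorised.
#' @param fundamental Fundamental frequency in Hz (default 5 MHz).
#' @param fluid A [water_properties()] list.
#' @return Penetration depth(s) in nm.
#' @examples
#' penetration_depth(c(3, 5, 7))   # ~120, 94, 79 nm in water at 38 C
#' @export
penetration_depth <- function(overtone = c(3, 5, 7), fundamental = 5e6,
                              fluid = water_properties()) {
  if (any(overtone < 1) || any(overtone %% 2 != 1)) {
    stop("overtones must be odd integers >= 1", call. = FALSE)
  }
  if (fundamental <= 0) stop("fundamental frequency must be positive",
                             call. = FALSE)
  delta_m <- sqrt(fluid$viscosity /
                    (pi * fluid$density * fundamental * overtone))
  delta_m * 1e9
}

#' Sauerbrey frequency shift
#'
#' \eqn{\Delta f_n = -m_A / C}: the overtone-normalised frequency shift of a
#' thin rigid film of areal mass \eqn{m_A}, with mass-sensitivity constant
#' `C` (17.7 ng cm^-2 Hz^-1 for a 5 MHz sensor).
#'
#' @param areal_mass Areal mass in ng cm^-2, `>= 0`. Vectorised.
#' @param mass_sensitivity ng cm^-2 Hz^-1.
#' @return Normalised frequency shift in Hz (negative for added mass).
#' @examples
#' sauerbrey_shift(478)   # ~ -27 Hz, a typical lipid bilayer
#' @export
sauerbrey_shift <- function(areal_mass, mass_sensitivity = 17.7) {
  if (any(areal_mass < 0)) stop("areal mass must be >= 0", call. = FALSE)
  -areal_mass / mass_sensitivity
}

#' Penetration-depth table
#'
#' Tidy per-overtone summary of the QCM-D depth sensitivity.
#'
#' @inheritParams penetration_depth
#' @return Tibble `overtone`, `frequency_mhz`, `depth_nm`.
#' @examples
#' qcm_depth_table()
#' @export
qcm_depth_table <- function(overtone = c(3, 5, 7), fundamental = 5e6,
                            fluid = water_properties()) {
  tibble(overtone = overtone,
         frequency_mhz = fundamental * overtone / 1e6,
         depth_nm = penetration_depth(overtone, fundamental, fluid))
}
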