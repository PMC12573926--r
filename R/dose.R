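#' Beam specification
#'
#' Photon bookkeeping for one exposure: a reference flux measured at a
#' reference ring current, linear scaling to the actual current, an
#' exposure time and an attenuation transmission. For an XFEL the flux
#' scaling is irrelevant - set `current = ref_current` and fold the pulse
#' energy into `flux_at_ref * exposure`.
#'
#' @param flux_at_ref photons/second at the sample for `ref_current`
#' @param ref_current reference ring current (mA)
#' @param current actual ring current (mA)
#' @param exposure exposure time (seconds)
#' @param photon_energy photon energy (keV)
#' @param beam_area beam cross-section (micrometre^2)
#' @param attenuation_transmission transmission in (0, 1]
#' @return list of class `beam_spec`
#' @export
beam_spec <- function(flux_at_ref, ref_current = 200, current = ref_current,
                      exposure, photon_energy = 12, beam_area = 8,
                      attenuation_transmission = 1) {
  vals <- c(flux_at_ref, ref_current, current, photon_energy,
            beam_area, attenuation_transmission)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all beam parameters must be positive and finite")
  if (!is.finite(exposure) || exposure < 0) stop("exposure must be >= 0")
  if (attenuation_transmission > 1) stop("transmission must be <= 1")
  structure(list(flux_at_ref = flux_at_ref, ref_current = ref_current,
                 current = current, exposure = exposure,
                 photon_energy = photon_energy, beam_area = beam_area,
                 attenuation_transmission = attenuation_transmission),
            class = "beam_spec")
}

#' Photons delivered in one exposure
#'
#' `flux_at_ref * (current / ref_current) * exposure * transmission`,
#' i.e. linear ring-current scaling of the reference flux.
#'
#' @param beam a [beam_spec()]
#' @return photon count
#' @examples
#' # 1.6e15 ph/s at 200 mA, ring at 68 mA, 90 us exposure -> 4.90e10
#' id29 <- beam_spec(flux_at_ref = 1.6e15, ref_current = 200, current = 68,
#'                   exposure = 90e-6, photon_energy = 11.56)
#' photons_per_pulse(id29)
#' @export
photons_per_pulse <- function(beam) {
  stopifnot(inherits(beam, "beam_spec"))
  beam$flux_at_ref * (beam$current / beam$ref_current) * beam$exposure *
    beam$attenuation_transmission
}

#' Dose rate with unit-aware formatting
#'
#' @param dose absorbed dose (Gy)
#' @param exposure exposure time (seconds), > 0
#' @return list of class `dose_rate`: `gy_per_s` (numeric) and `formatted`
#'   (string in Gy/s, kGy/s, MGy/s or GGy/s as appropriate)
#' @examples
#' dose_rate(0.88e6, 90e-6)   # ~9.8 GGy/s
#' dose_rate(33e3, 10e-3)     # 3.3 MGy/s
#' @export
dose_rate <- function(dose, exposure) {
  if (exposure <= 0) stop("exposure must be > 0")
  if (dose < 0) stop("dose must be >= 0")
  r <- dose / exposure
  units <- c("Gy/s" = 1, "kGy/s" = 1e3, "MGy/s" = 1e6, "GGy/s" = 1e9)
  pick <- max(1, sum(r >= units))
  structure(list(gy_per_s = r,
                 formatted = sprintf("%.3g %s", r / units[pick], names(units)[pick])),
            class = "dose_rate")
}

#' @export
print.dose_rate <- function(x, ...) {
  cat("dose rate:", x$formatted, "\n")
  invisible(x)
}

#' Absorber specification for the simple dose model
#'
#' @param thickness absorber (sample) thickness (micrometre)
#' @param density density (kg/m^3)
#' @param absorption_coefficient linear absorption coefficient (1/m) at the
#'   beam's photon energy
#' @return list of class `absorber_spec`
#' @export
absorber_spec <- function(thickness, density = 1060,
                          absorption_coefficient = 270) {
  vals <- c(thickness, density, absorption_coefficient)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("absorber parameters must be >= 0")
  structure(list(thickness = thickness, density = density,
                 absorption_coefficient = absorption_coefficient),
            class = "absorber_spec")
}

KEV_TO_JOULE <- 1.602176634e-16

#' Simple top-surface absorbed-dose estimate
#'
#' First-principles uniform-beam estimate
#' `dose = n_photons * E_photon * (1 - exp(-mu t)) / (beam_area * t * rho)`,
#' the absorbed energy divided by the mass of the column the beam
#' traverses. This deliberately ignores diffraction weighting, beam
#' profile, fluorescence and photoelectron escape; published
#' diffraction-weighted doses are authoritative inputs, never recomputed
#' here.
#'
#' @param beam a [beam_spec()]
#' @param absorber an [absorber_spec()]
#' @return absorbed dose (Gy)
#' @export
simple_absorbed_dose <- function(beam, absorber) {
  stopifnot(inherits(beam, "beam_spec"), inherits(absorber, "absorber_spec"))
  t <- absorber$thickness * 1e-6                   # m
  if (t == 0) return(0)
  n <- photons_per_pulse(beam)
  e <- beam$photon_energy * KEV_TO_JOULE           # J
  absorbed <- n * e * (1 - exp(-absorber$absorption_coefficient * t))
  mass <- beam$beam_area * 1e-12 * t * absorber$density   # kg
  absorbed / mass
}
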