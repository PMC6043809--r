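# gas constant, L atm mol^-1 K^-1; atomic mass of carbon, g mol^-1
.R_GAS <- 0.0820574
.C_MASS <- 12.011

#' CO2-C emission per enclosure from headspace concentrations
#'
#' Converts the blank-corrected headspace CO2 excess to mineralized
#' carbon per gram of dry soil via the ideal gas law:
#' `n = (sample - blank) 1e-6 * P V / (R T)` moles CO2, times 12.011
#' g C per mole, per gram of soil. Negative blank-corrected differences
#' are floored at zero with a warning.
#'
#' @param samplePpm Headspace CO2 after enclosure, ppm.
#' @param blankPpm Blank (empty container) CO2 of the same date, ppm.
#' @param headspaceMl Headspace volume, ml.
#' @param tempC Incubation temperature, degrees C.
#' @param pressureAtm Pressure, atm.
#' @param soilG Soil dry mass, g.
#' @return Micrograms C per gram soil released during the enclosure.
#' @export
#' @examples
#' co2Flux(1420, 420, headspaceMl = 59, tempC = 18, soilG = 1.5)
co2Flux <- function(samplePpm, blankPpm, headspaceMl, tempC,
                    pressureAtm = 1, soilG = 1) {
  if (any(is.na(blankPpm))) stop("missing blank measurement")
  stopifnot(all(headspaceMl > 0), all(tempC > -273.15),
            all(pressureAtm > 0), all(soilG > 0))
  excess <- samplePpm - blankPpm
  if (any(excess < 0)) {
    warning("negative blank-corrected CO2 floored at zero")
    excess <- pmax(excess, 0)
  }
  mol <- excess * 1e-6 * pressureAtm * (headspaceMl / 1000) /
    (.R_GAS * (tempC + 273.15))
  mol * .C_MASS * 1e6 / soilG
}

# midpoint-to-midpoint integration bounds for a sampling schedule
.interval_hours <- function(days) {
  bounds <- c(0, (days[-length(days)] + days[-1]) / 2, days[length(days)])
  diff(bounds) * 24
}

#' Cumulative carbon mineralization
#'
#' The emission rate measured during each enclosure (flux divided by
#' enclosure duration) is assumed to hold from the midpoint of the
#' previous sampling interval to the midpoint of the next (day 0 to the
#' first sampling day for the first measurement; the series ends at the
#' final sampling day). The cumulative sum of rate times interval gives
#' mineralized C per date.
#'
#' @param fluxUgPerG Per-enclosure emissions from [co2Flux()], ug C g^-1.
#' @param days Sampling days, strictly increasing.
#' @param enclosureH Enclosure durations, hours (scalar or per date).
#' @return data.frame: day, flux_ug_per_g, rate_ug_per_g_h, interval_h,
#'   cumulative_ug_per_g.
#' @export
cumulativeCmin <- function(fluxUgPerG, days, enclosureH) {
  stopifnot(length(days) >= 1L, length(fluxUgPerG) == length(days))
  if (any(diff(days) <= 0)) stop("sampling days must be strictly increasing")
  if (any(enclosureH <= 0)) stop("enclosure durations must be positive")
  enclosureH <- rep_len(enclosureH, length(days))
  rate <- fluxUgPerG / enclosureH
  intervalH <- .interval_hours(days)
  data.frame(day = days, flux_ug_per_g = fluxUgPerG,
             rate_ug_per_g_h = rate, interval_h = intervalH,
             cumulative_ug_per_g = cumsum(rate * intervalH))
}

#' Net and relative carbon mineralization
#'
#' Net Cmin is the amended-minus-control cumulative series; the
#' relative fraction is the final net Cmin as a percentage of the
#' substrate carbon added.
#'
#' @param amended,control data.frames from [cumulativeCmin()] with
#'   matching days.
#' @param substrateCAddedUgPerG Substrate carbon added, ug C g^-1 soil.
#' @return List: `net` (data.frame day, net_cumulative_ug_per_g) and
#'   `relative_pct`.
#' @export
netRelativeCmin <- function(amended, control, substrateCAddedUgPerG) {
  if (!isTRUE(all.equal(amended$day, control$day)))
    stop("amended and control series must share sampling days")
  if (substrateCAddedUgPerG <= 0)
    stop("substrate carbon added must be positive")
  net <- amended$cumulative_ug_per_g - control$cumulative_ug_per_g
  list(net = data.frame(day = amended$day, net_cumulative_ug_per_g = net),
       relative_pct = 100 * net[length(net)] / substrateCAddedUgPerG)
}

#' Substrate carbon added per gram of soil
#'
#' Unit bookkeeping helper: application rate (g substrate per g soil)
#' times the substrate's carbon content gives ug C g^-1 soil. Grass in
#' the study contains 42.3% C, sawdust 44.8% C.
#'
#' @param applicationRateGPerG Substrate application rate, g g^-1 soil.
#' @param carbonPct Substrate carbon content, percent.
#' @return Substrate carbon added, ug C g^-1 soil.
#' @export
substrateCarbonAdded <- function(applicationRateGPerG, carbonPct) {
  stopifnot(applicationRateGPerG >= 0, carbonPct >= 0, carbonPct <= 100)
  applicationRateGPerG * carbonPct / 100 * 1e6
}

#' Water-filled pore space
#'
#' `WFPS% = 100 * volumetric water / total porosity` with volumetric
#' water = gravimetric water times bulk density (water density 1
#' g cm^-3) and total porosity `1 - BD/PD`. The incubations used a
#' fixed bulk density of 1.26 g cm^-3 and moisture levels of 25 and
#' 50% WFPS.
#'
#' @param gravimetricWater Water content, g per g dry soil.
#' @param bulkDensity Bulk density, g cm^-3 (default 1.26).
#' @param particleDensity Particle density, g cm^-3 (default 2.65).
#' @return WFPS in percent.
#' @export
#' @examples
#' wfps(0.1041) # ~25%
wfps <- function(gravimetricWater, bulkDensity = 1.26,
                 particleDensity = 2.65) {
  stopifnot(all(gravimetricWater >= 0), bulkDensity > 0,
            bulkDensity < particleDensity)
  porosity <- 1 - bulkDensity / particleDensity
  out <- 100 * gravimetricWater * bulkDensity / porosity
  if (any(out > 100)) stop("WFPS above 100%: over-saturated input")
  out
}

#' Synthetic headspace CO2 incubation series
#'
#' Forward model for the incubation pipeline: a known emission-rate
#' profile is converted to headspace ppm excesses through the same
#' ideal-gas arithmetic that [co2Flux()] inverts, on the study's
#' 128-day sampling schedule. The true cumulative C release implied by
#' the midpoint integration rule is recorded, so the downstream
#' pipeline can be checked against it (exactly, at zero noise).
#'
#' @param days Sampling days (default: the 22-date, 128-day schedule).
#' @param rateUgPerGPerH Emission rate at each sampling day, ug C
#'   g^-1 h^-1; either a vector or a function of day.
#' @param blankPpm Ambient (blank) CO2, ppm.
#' @param noiseSd Gaussian noise s.d. on sample and blank ppm.
#' @param enclosureH,headspaceMl,tempC,pressureAtm,soilG Enclosure
#'   parameters (recycled per date).
#' @param seed RNG seed.
#' @return data.frame (class `IncubationRecord`): day, sample_ppm,
#'   blank_ppm, enclosure_h, headspace_ml, temp_c, pressure_atm,
#'   soil_g; the truth is in `attr(x, "truth")` (rates and cumulative
#'   series).
#' @export
generateIncubationSeries <- function(days = c(1, 3, 6, 10, 13, 15, 17, 19,
                                              22, 25, 28, 31, 35, 40, 47,
                                              54, 64, 74, 86, 100, 114, 128),
                                     rateUgPerGPerH = function(d) 0.8 * exp(-0.03 * d),
                                     blankPpm = 420, noiseSd = 0,
                                     enclosureH = 12, headspaceMl = 59,
                                     tempC = 18, pressureAtm = 1,
                                     soilG = 1.5, seed = 1L) {
  stopifnot(length(days) >= 1L, all(diff(days) > 0))
  set.seed(seed)
  rate <- if (is.function(rateUgPerGPerH)) rateUgPerGPerH(days)
          else rep_len(rateUgPerGPerH, length(days))
  stopifnot(all(rate >= 0))
  n <- length(days)
  enclosureH <- rep_len(enclosureH, n)
  headspaceMl <- rep_len(headspaceMl, n)
  tempC <- rep_len(tempC, n)
  pressureAtm <- rep_len(pressureAtm, n)
  soilG <- rep_len(soilG, n)
  ugC <- rate * enclosureH                       # per enclosure, per g
  mol <- ugC * soilG / (.C_MASS * 1e6)
  excessPpm <- mol * .R_GAS * (tempC + 273.15) /
    (pressureAtm * headspaceMl / 1000) * 1e6
  blank <- blankPpm + if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
  sample <- blankPpm + excessPpm + if (noiseSd > 0) rnorm(n, 0, noiseSd) else 0
  intervalH <- .interval_hours(days)
  out <- data.frame(day = days, sample_ppm = sample, blank_ppm = blank,
                    enclosure_h = enclosureH, headspace_ml = headspaceMl,
                    temp_c = tempC, pressure_atm = pressureAtm,
                    soil_g = soilG)
  class(out) <- c("IncubationRecord", "data.frame")
  attr(out, "truth") <- list(rate_ug_per_g_h = rate,
                             cumulative_ug_per_g = cumsum(rate * intervalH))
  out
}
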