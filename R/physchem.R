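# Partition-coefficient estimation and three-phase equilibrium uptake for
# headspace SPME. The model treats a vial as three phases at equilibrium:
# a liquid polymeric fiber coating (volume V1), the aqueous sample (V2)
# and the headspace above it (V3). K1 = coating/headspace and
# K2 = headspace/liquid partition coefficients; K = K1*K2 is the overall
# coating/liquid coefficient, approximated by the octanol-water Kow.

#' Universal gas constant in m^3 atm / (mol K)
#'
#' The value used throughout the headspace partition calculations.
#' @export
GAS_CONSTANT_ATM <- 8.2054e-5

# Gas constant in J/(mol K), used by the van't Hoff slope.
GAS_CONSTANT_J <- 8.314

#' Convert degrees Celsius to Kelvin
#'
#' @param celsius temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' Standard atomic weights for common elements
#'
#' Conventional IUPAC standard atomic weights, sufficient for small-molecule
#' formulas encountered in GC-MS work.
#' @keywords internal
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403,
  Na = 22.98977, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.0983, Br = 79.904, I = 126.90447
)

#' Molecular weight from a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. `"C11H14O2"`) and sums
#' standard atomic weights.
#'
#' @param formula character molecular formula.
#' @return Molecular weight in g/mol.
#' @examples
#' formula_weight("C11H14O2") # the acetylated 2-phenyl-2-propanol derivative
#' @export
formula_weight <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse molecular formula: ", formula, call. = FALSE)
  }
  w <- 0
  for (tok in tokens) {
    el <- sub("\\d+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(.atomic_weights)) {
      stop("unknown element in formula: ", el, call. = FALSE)
    }
    w <- w + .atomic_weights[[el]] * n
  }
  w
}

#' Physicochemical property record for one analyte
#'
#' Bundles the constants needed by the partition and uptake models. The
#' Henry constant and log Kow are temperature-specific: tag them with the
#' temperature they were established at.
#'
#' @param name compound name.
#' @param molecular_formula molecular formula; used to derive
#'   `molecular_weight` when that is not given.
#' @param molecular_weight g/mol; computed from the formula if `NULL`.
#' @param log_kow log10 octanol-water partition coefficient.
#' @param henry_constant Henry's law constant, atm m^3/mol.
#' @param heat_of_vaporization J/mol.
#' @param vapor_pressure Pa.
#' @param activity_coefficient dimensionless solute activity coefficient.
#' @param temperature Kelvin tag for the temperature-dependent properties.
#' @return An object of class `analyte_properties`.
#' @export
analyte_properties <- function(name, molecular_formula = NULL,
                               molecular_weight = NULL, log_kow = NULL,
                               henry_constant = NULL,
                               heat_of_vaporization = NULL,
                               vapor_pressure = NULL,
                               activity_coefficient = NULL,
                               temperature = NULL) {
  if (is.null(molecular_weight)) {
    if (is.null(molecular_formula)) {
      stop("need molecular_weight or molecular_formula", call. = FALSE)
    }
    molecular_weight <- formula_weight(molecular_formula)
  }
  if (molecular_weight <= 0) stop("molecular_weight must be > 0", call. = FALSE)
  if (!is.null(henry_constant) && henry_constant <= 0) {
    stop("henry_constant must be > 0", call. = FALSE)
  }
  if (!is.null(vapor_pressure) && vapor_pressure <= 0) {
    stop("vapor_pressure must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, molecular_formula = molecular_formula,
         molecular_weight = molecular_weight, log_kow = log_kow,
         henry_constant = henry_constant,
         heat_of_vaporization = heat_of_vaporization,
         vapor_pressure = vapor_pressure,
         activity_coefficient = activity_coefficient,
         temperature = temperature),
    class = "analyte_properties"
  )
}

#' Read analyte property records from a YAML config file
#'
#' The file holds one compound record with keys matching the
#' [analyte_properties()] fields; temperature-dependent constants live
#' under `by_temperature`, one entry per sampling temperature (given in
#' degrees Celsius as `temperature_c`).
#'
#' @param path path to the YAML file.
#' @return A list of `analyte_properties`, one per temperature entry,
#'   named by the Celsius temperature.
#' @export
read_analyte_properties <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$name))
  entries <- cfg$by_temperature
  if (is.null(entries)) entries <- list(list(temperature_c = NA_real_))
  out <- lapply(entries, function(e) {
    analyte_properties(
      name = cfg$name,
      molecular_formula = cfg$molecular_formula,
      molecular_weight = cfg$molecular_weight,
      log_kow = e$log_kow,
      henry_constant = e$henry_constant,
      heat_of_vaporization = e$heat_of_vaporization,
      vapor_pressure = e$vapor_pressure,
      activity_coefficient = e$activity_coefficient,
      temperature = if (!is.null(e$temperature_c)) {
        celsius_to_kelvin(e$temperature_c)
      }
    )
  })
  names(out) <- vapply(entries, function(e) {
    as.character(e$temperature_c %||% NA)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Three-phase system geometry for a headspace SPME vial
#'
#' @param v_coating fiber coating volume V1, mL.
#' @param v_liquid liquid (sample) phase volume V2, mL.
#' @param v_headspace headspace volume V3, mL.
#' @param temperature sampling temperature.
#' @param unit unit of `temperature`: `"K"` (default) or `"C"`.
#' @param gas_constant gas constant in m^3 atm/(mol K).
#' @return An object of class `phase_system`.
#' @export
phase_system <- function(v_coating, v_liquid, v_headspace, temperature,
                         unit = c("K", "C"),
                         gas_constant = GAS_CONSTANT_ATM) {
  unit <- match.arg(unit)
  if (unit == "C") temperature <- celsius_to_kelvin(temperature)
  if (any(c(v_coating, v_liquid, v_headspace) < 0)) {
    stop("phase volumes must be >= 0", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  structure(
    list(v_coating = v_coating, v_liquid = v_liquid,
         v_headspace = v_headspace, temperature = temperature,
         gas_constant = gas_constant),
    class = "phase_system"
  )
}

#' Nominal PDMS coating volume for a 1-cm fiber
#'
#' Vendor-nominal coating volumes for the common 1-cm PDMS fiber
#' thicknesses; overridable wherever a coating volume is consumed.
#'
#' @param thickness_um coating thickness in micrometres (7, 30 or 100).
#' @return Coating volume in mL.
#' @export
pdms_coating_volume <- function(thickness_um) {
  vols_ul <- c(`7` = 0.026, `30` = 0.132, `100` = 0.612)
  key <- as.character(thickness_um)
  if (!key %in% names(vols_ul)) {
    stop("no nominal coating volume for thickness ", thickness_um,
         " um; supply v_coating directly", call. = FALSE)
  }
  vols_ul[[key]] * 1e-3
}

#' Headspace/liquid partition coefficient from Henry's law constant
#'
#' K2 = K_H / (R T): the dimensionless air-water partition coefficient
#' obtained by dividing the Henry constant by the gas constant times the
#' absolute temperature.
#'
#' @param henry_constant atm m^3/mol.
#' @param temperature Kelvin.
#' @param gas_constant m^3 atm/(mol K).
#' @return Dimensionless K2.
#' @examples
#' k2_from_henry(5.25e-4, 333.15) # ~1.92e-2 at 60 degrees C
#' @export
k2_from_henry <- function(henry_constant, temperature,
                          gas_constant = GAS_CONSTANT_ATM) {
  if (henry_constant <= 0) stop("henry_constant must be > 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (gas_constant <= 0) stop("gas_constant must be > 0", call. = FALSE)
  henry_constant / (gas_constant * temperature)
}

#' Coating/liquid partition coefficient from log Kow
#'
#' The overall coating/liquid coefficient K = K1*K2 of an absorptive PDMS
#' coating is approximated by the octanol-water partition coefficient.
#'
#' @param log_kow log10 Kow.
#' @return Dimensionless K.
#' @export
k_from_kow <- function(log_kow) {
  stopifnot(is.finite(log_kow))
  10^log_kow
}

#' Coating/headspace partition coefficient from log Kow and K2
#'
#' K1 = Kow / K2 = 10^log_kow / K2.
#'
#' @param log_kow log10 Kow.
#' @param k2 dimensionless headspace/liquid coefficient.
#' @return Dimensionless K1.
#' @export
k1_from_kow_k2 <- function(log_kow, k2) {
  if (k2 <= 0) stop("k2 must be > 0", call. = FALSE)
  10^log_kow / k2
}

#' LTPRI-to-K1 correlation
#'
#' Log-linear correlation between the coating/headspace partition
#' coefficient of a compound on a PDMS phase and its linear
#' temperature-programmed retention index:
#' log10 K1 = slope * LTPRI + intercept.
#'
#' @param slope per index unit.
#' @param intercept dimensionless.
#' @return An object of class `ltpri_correlation`.
#' @export
ltpri_correlation <- function(slope = 0.0042, intercept = -0.188) {
  if (slope == 0) stop("correlation slope must be nonzero", call. = FALSE)
  structure(list(slope = slope, intercept = intercept),
            class = "ltpri_correlation")
}

#' Coating/headspace partition coefficient from a retention index
#'
#' @param ltpri linear temperature-programmed retention index.
#' @param correlation an [ltpri_correlation()].
#' @return Dimensionless K1.
#' @examples
#' k1_from_ltpri(1384) # ~4.2e5
#' @export
k1_from_ltpri <- function(ltpri, correlation = ltpri_correlation()) {
  stopifnot(ltpri > 0)
  10^(correlation$slope * ltpri + correlation$intercept)
}

#' van't Hoff parameters for the temperature dependence of K1
#'
#' Parameters of log10 K1 = a / T + b, the van't Hoff (reciprocal
#' temperature) linearity, with a = dHv / (2.303 R_J) in Kelvin and R_J =
#' 8.314 J/(mol K).
#'
#' @param a slope term, Kelvin.
#' @param b dimensionless intercept.
#' @param reference_temperature Kelvin at which the parameters were
#'   established.
#' @return An object of class `vant_hoff_params`.
#' @export
vant_hoff_params <- function(a, b, reference_temperature = 298.15) {
  if (reference_temperature <= 0) {
    stop("reference_temperature must be > 0", call. = FALSE)
  }
  structure(list(a = a, b = b,
                 reference_temperature = reference_temperature),
            class = "vant_hoff_params")
}

#' van't Hoff slope from a heat of vaporization
#'
#' a = dHv / (2.303 * R_J) with R_J = 8.314 J/(mol K).
#'
#' @param heat_of_vaporization J/mol.
#' @return Slope in Kelvin.
#' @export
vant_hoff_slope <- function(heat_of_vaporization) {
  heat_of_vaporization / (2.303 * GAS_CONSTANT_J)
}

#' Temperature-corrected K1 from van't Hoff parameters
#'
#' Evaluates log10 K1 = a / T + b. For a positive slope (exothermic
#' absorption), K1 increases as the sampling temperature drops, which is
#' the rationale for cooled headspace sampling.
#'
#' @param params a [vant_hoff_params()].
#' @param temperature Kelvin.
#' @return Dimensionless K1.
#' @export
k1_vant_hoff <- function(params, temperature) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  10^(params$a / temperature + params$b)
}

#' Bundle of the three partition coefficients
#'
#' @param k1 coating/headspace coefficient.
#' @param k2 headspace/liquid coefficient.
#' @param provenance how K1 was obtained: one of `"from_kow"`,
#'   `"from_ltpri"`, `"from_vant_hoff"`, `"user"`.
#' @return An object of class `partition_set` with `k = k1 * k2`.
#' @export
partition_set <- function(k1, k2,
                          provenance = c("user", "from_kow", "from_ltpri",
                                         "from_vant_hoff")) {
  provenance <- match.arg(provenance)
  if (k1 <= 0 || k2 <= 0) stop("partition coefficients must be > 0",
                               call. = FALSE)
  structure(list(k1 = k1, k2 = k2, k = k1 * k2, provenance = provenance),
            class = "partition_set")
}

#' Equilibrium mass of analyte absorbed by the fiber coating
#'
#' Three-phase equilibrium model: the mass on the coating once
#' coating/headspace/liquid equilibrium is reached is
#' \deqn{n = \frac{C_0 V_1 V_2 K_1 K_2}{K_1 K_2 V_1 + K_2 V_3 + V_2}}
#' with C0 the initial liquid-phase concentration. Bounded above by the
#' total analyte mass C0*V2 (extraction is never exhaustive).
#'
#' @param system a [phase_system()].
#' @param c0 initial liquid concentration, mg/L.
#' @param partitions a [partition_set()].
#' @return Mass on the coating at equilibrium, ng.
#' @export
equilibrium_uptake <- function(system, c0, partitions) {
  stopifnot(inherits(system, "phase_system"),
            inherits(partitions, "partition_set"))
  if (c0 < 0) stop("c0 must be >= 0", call. = FALSE)
  k1 <- partitions$k1
  k2 <- partitions$k2
  denom <- k1 * k2 * system$v_coating + k2 * system$v_headspace +
    system$v_liquid
  if (denom == 0) stop("degenerate phase system: all volumes zero",
                       call. = FALSE)
  # mg/L == ug/mL, volumes in mL -> ug; x1000 -> ng
  n_ug <- c0 * system$v_coating * system$v_liquid * k1 * k2 / denom
  n_ug * 1000
}

#' First-order uptake profile towards equilibrium
#'
#' Exponential approach n(t) = n_eq (1 - exp(-k t)). The rate constant is
#' derived from the observed equilibration time via the convention that
#' `equilibrium_time` is when the fiber holds `equilibrium_fraction`
#' (default 95%) of the equilibrium mass.
#'
#' @param mass_equilibrium equilibrium mass n_eq, ng.
#' @param equilibrium_time minutes to reach `equilibrium_fraction` of n_eq.
#' @param equilibrium_fraction fraction of n_eq defining "equilibrium".
#' @return An object of class `uptake_prediction` carrying the implied
#'   first-order rate constant (1/min).
#' @export
uptake_prediction <- function(mass_equilibrium, equilibrium_time,
                              equilibrium_fraction = 0.95) {
  stopifnot(mass_equilibrium >= 0, equilibrium_time > 0,
            equilibrium_fraction > 0, equilibrium_fraction < 1)
  rate <- -log(1 - equilibrium_fraction) / equilibrium_time
  structure(
    list(mass_equilibrium = mass_equilibrium,
         equilibrium_time = equilibrium_time,
         equilibrium_fraction = equilibrium_fraction,
         rate_constant = rate),
    class = "uptake_prediction"
  )
}

#' Mass on the fiber at a given sampling time
#'
#' @param prediction an [uptake_prediction()].
#' @param time minutes since the fiber was exposed; vectorized.
#' @return Mass on the fiber, ng.
#' @export
uptake_at_time <- function(prediction, time) {
  stopifnot(inherits(prediction, "uptake_prediction"))
  if (any(time < 0)) stop("time must be >= 0", call. = FALSE)
  prediction$mass_equilibrium * (1 - exp(-prediction$rate_constant * time))
}

#' Sample-preparation protocol (ordered reagent additions)
#'
#' @param additions data.frame with columns `volume` (mL) and `role`
#'   (one of sample, internal_standard, acid, base, catalyst,
#'   derivatizing_agent).
#' @param vial_volume total vial volume, mL.
#' @return An object of class `prep_protocol`.
#' @export
prep_protocol <- function(additions, vial_volume = 20) {
  roles <- c("sample", "internal_standard", "acid", "base", "catalyst",
             "derivatizing_agent")
  stopifnot(is.data.frame(additions),
            all(c("volume", "role") %in% names(additions)),
            all(additions$volume > 0),
            all(additions$role %in% roles))
  if (sum(additions$volume) > vial_volume) {
    stop("additions exceed the vial volume", call. = FALSE)
  }
  structure(list(additions = additions, vial_volume = vial_volume),
            class = "prep_protocol")
}

#' The default urine derivatization protocol
#'
#' 2 mL urine + 150 uL internal standard + 200 uL HCl + 400 uL NaOH +
#' 100 uL pyridine + 50 uL acetic anhydride in a 20-mL headspace vial,
#' for a final liquid volume of 2.9 mL and headspace of 17.1 mL.
#'
#' @return A [prep_protocol()].
#' @export
default_prep_protocol <- function() {
  prep_protocol(data.frame(
    volume = c(2, 0.15, 0.2, 0.4, 0.1, 0.05),
    role = c("sample", "internal_standard", "acid", "base", "catalyst",
             "derivatizing_agent")
  ), vial_volume = 20)
}

#' Total liquid volume of a prep protocol
#' @param protocol a [prep_protocol()].
#' @return mL of liquid phase after all additions.
#' @export
liquid_volume <- function(protocol) {
  stopifnot(inherits(protocol, "prep_protocol"))
  sum(protocol$additions$volume)
}

#' Headspace volume left in the vial
#' @param protocol a [prep_protocol()].
#' @return mL of headspace.
#' @export
headspace_volume <- function(protocol) {
  protocol$vial_volume - liquid_volume(protocol)
}

#' Effective initial concentration after dilution and derivatization
#'
#' Converts a spike concentration in the sample aliquot to the effective
#' concentration of the derivative in the final liquid phase: dilution by
#' the ratio of sample to total liquid volume and 1:1 molar conversion to
#' the derivative (scaled by the molecular-weight ratio), times an
#' optional derivatization yield.
#'
#' @param protocol a [prep_protocol()].
#' @param spike_concentration mg/L of the parent analyte in the sample
#'   aliquot.
#' @param analyte_mw parent molecular weight, g/mol.
#' @param derivative_mw derivative molecular weight, g/mol.
#' @param yield molar derivatization yield (default 1, quantitative).
#' @return Effective derivative concentration in the final liquid, mg/L.
#' @export
effective_c0 <- function(protocol, spike_concentration, analyte_mw,
                         derivative_mw, yield = 1) {
  stopifnot(inherits(protocol, "prep_protocol"),
            analyte_mw > 0, derivative_mw > 0, yield >= 0, yield <= 1)
  sample_vol <- sum(protocol$additions$volume[
    protocol$additions$role == "sample"])
  if (sample_vol == 0) stop("protocol has no sample aliquot", call. = FALSE)
  total <- liquid_volume(protocol)
  if (total == 0) stop("zero total liquid volume", call. = FALSE)
  spike_concentration * (sample_vol / total) * (derivative_mw / analyte_mw) *
    yield
}
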