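#' Coolant mass passed through the vessel during an ablation
#'
#' @param flow_ml_min Flow rate in ml/min (>= 0).
#' @param duration_s Ablation duration in s (>= 0).
#' @param density_g_ml Coolant density in g/ml (default 1.0, water).
#' @return Mass in kg (vectorised).
#' @examples
#' coolant_mass(500, 300) # 2.5 kg
#' @export
coolant_mass <- function(flow_ml_min, duration_s, density_g_ml = 1.0) {
  check_nonneg(flow_ml_min, "flow_ml_min")
  check_nonneg(duration_s, "duration_s")
  check_nonneg(density_g_ml, "density_g_ml")
  flow_ml_min * (duration_s / 60) * density_g_ml / 1000
}

#' Energy absorbed by the coolant
#'
#' The calorimetric energy balance `dQ = m * c * dT`: the heat carried away
#' by the perfusate over one ablation, from its mass, specific heat and
#' end-to-end temperature rise.
#'
#' @param mass_kg Coolant mass in kg (>= 0).
#' @param c_kJ_kgK Specific heat capacity in kJ/(kg K); default 4.186
#'   (water).
#' @param delta_T_K Temperature rise in K (>= 0; the coolant cannot leave
#'   colder than it entered in this model).
#' @return Absorbed energy in kJ (vectorised).
#' @examples
#' energy_loss(0.5, 4.186, 0.6) # 1.256 kJ
#' @export
energy_loss <- function(mass_kg, c_kJ_kgK = 4.186, delta_T_K) {
  check_nonneg(mass_kg, "mass_kg")
  check_nonneg(c_kJ_kgK, "c_kJ_kgK")
  check_nonneg(delta_T_K, "delta_T_K")
  mass_kg * c_kJ_kgK * delta_T_K
}

#' Coolant-absorbed fraction of the applied microwave energy
#'
#' @param delta_Q_kJ Energy absorbed by the coolant in kJ (>= 0).
#' @param power_W Generator power in W (> 0).
#' @param duration_s Ablation duration in s (> 0).
#' @return Percentage of the applied energy (vectorised).
#' @examples
#' absorbed_fraction(1.256, 100, 300) # 4.19 %
#' @export
absorbed_fraction <- function(delta_Q_kJ, power_W, duration_s) {
  check_nonneg(delta_Q_kJ, "delta_Q_kJ")
  if (any(!is.finite(power_W)) || any(power_W <= 0) ||
      any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop_parameter("`power_W` and `duration_s` must be > 0")
  }
  100 * delta_Q_kJ / (power_W * duration_s / 1000)
}

#' Full coolant energy balance per run
#'
#' Combines [coolant_mass()], [energy_loss()] and [absorbed_fraction()]
#' into one tidy table, one row per run.
#'
#' @param flow_ml_min Flow rate(s) in ml/min.
#' @param delta_T_K Measured coolant temperature rise(s) in K.
#' @param power_W,duration_s Generator settings (defaults 100 W, 300 s).
#' @param density_g_ml Coolant density (g/ml).
#' @param c_kJ_kgK Specific heat capacity (kJ/(kg K)).
#' @return A tibble with columns `flow_ml_min`, `duration_s`, `delta_T_K`,
#'   `coolant_density_g_ml`, `specific_heat_kJ_kgK`, `mass_kg`,
#'   `delta_Q_kJ`, `applied_energy_kJ`, `absorbed_fraction_pct`.
#' @examples
#' energy_balance(c(100, 500), c(0.6, 0.55))
#' @export
energy_balance <- function(flow_ml_min, delta_T_K, power_W = 100,
                           duration_s = 300, density_g_ml = 1.0,
                           c_kJ_kgK = 4.186) {
  m <- coolant_mass(flow_ml_min, duration_s, density_g_ml)
  dq <- energy_loss(m, c_kJ_kgK, delta_T_K)
  tibble(
    flow_ml_min = flow_ml_min,
    duration_s = duration_s,
    delta_T_K = delta_T_K,
    coolant_density_g_ml = density_g_ml,
    specific_heat_kJ_kgK = c_kJ_kgK,
    mass_kg = m,
    delta_Q_kJ = dq,
    applied_energy_kJ = power_W * duration_s / 1000,
    absorbed_fraction_pct = absorbed_fraction(dq, power_W, duration_s)
  )
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_parameter(sprintf("`%s` must be finite and >= 0", name))
  }
  invisible(x)
}
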