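#' Chip geometry
#'
#' Physical dimensions of the microfluidic chip: cylindrical medium
#' reservoirs (two per side) and the hydrogel channel they perfuse.
#' Defaults describe a commercial chip with a 1.3 mm wide, 250 um high
#' gel channel flanked by medium channels, where the effective hydrogel
#' cross-section seen by the interstitial flow is 10.8 mm x 250 um.
#'
#' @param reservoir_diameter_mm Reservoir diameter (mm).
#' @param reservoirs_per_side Number of reservoirs feeding each side.
#' @param gel_cross_section_width_mm Width of the hydrogel cross-section
#'   perpendicular to the flow (mm).
#' @param gel_cross_section_height_um Height of the hydrogel cross-section
#'   (um).
#' @param gel_channel_width_mm Width of the gel channel (mm).
#' @return An object of class `chip_geometry`.
#' @examples
#' geom <- chip_geometry()
#' reservoir_area_mm2(geom) # pi * 5^2 / 4
#' @export
chip_geometry <- function(reservoir_diameter_mm = 5,
                          reservoirs_per_side = 2,
                          gel_cross_section_width_mm = 10.8,
                          gel_cross_section_height_um = 250,
                          gel_channel_width_mm = 1.3) {
  if (!is.numeric(reservoir_diameter_mm) || reservoir_diameter_mm <= 0)
    stop("invalid geometry: reservoir diameter must be > 0", call. = FALSE)
  dims <- c(reservoirs_per_side, gel_cross_section_width_mm,
            gel_cross_section_height_um, gel_channel_width_mm)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid geometry: all dimensions must be positive", call. = FALSE)
  structure(list(reservoir_diameter_mm = reservoir_diameter_mm,
                 reservoirs_per_side = reservoirs_per_side,
                 gel_cross_section_width_mm = gel_cross_section_width_mm,
                 gel_cross_section_height_um = gel_cross_section_height_um,
                 gel_channel_width_mm = gel_channel_width_mm),
            class = "chip_geometry")
}

#' @rdname chip_geometry
#' @param geom A `chip_geometry`.
#' @export
reservoir_area_mm2 <- function(geom) {
  pi * geom$reservoir_diameter_mm^2 / 4
}

#' Hydrogel cross-sectional area in mm^2
#'
#' @param geom A `chip_geometry`.
#' @return Cross-section (mm^2) used to convert interstitial velocity to
#'   flow rate; 2.7 mm^2 for the default geometry.
#' @export
gel_cross_section_mm2 <- function(geom) {
  geom$gel_cross_section_width_mm * geom$gel_cross_section_height_um / 1000
}

#' Fluid constants
#'
#' Medium is treated as water-like at 37 C: the viscosity is that of
#' water at 37 C and the density is taken as 1000 kg/m^3 (flow duration
#' is independent of density, which cancels between pressure and
#' resistance; pressure reporting needs a convention). `k_p` is the
#' Darcy permeability of the fibrin hydrogel.
#'
#' @param rho Density (kg/m^3).
#' @param g Gravitational acceleration (m/s^2).
#' @param mu Dynamic viscosity (Pa s).
#' @param k_p Darcy permeability (m^2).
#' @return An object of class `fluid_constants`.
#' @export
fluid_constants <- function(rho = 1000, g = 9.81, mu = 0.6913e-3,
                            k_p = 6.67e-12) {
  v <- c(rho = rho, g = g, mu = mu, k_p = k_p)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("fluid constants must be strictly positive", call. = FALSE)
  structure(as.list(v), class = "fluid_constants")
}

#' Reservoir volume condition
#'
#' Volumes pipetted into each reservoir of the inlet and outlet side.
#' The daily medium change uses 90 ul per inlet reservoir and 50 ul per
#' outlet reservoir, written \[(90+90)+(50+50)\] ul.
#'
#' @param inlet_volume_each_ul Volume per inlet reservoir (ul).
#' @param outlet_volume_each_ul Volume per outlet reservoir (ul).
#' @return An object of class `volume_condition`.
#' @export
volume_condition <- function(inlet_volume_each_ul = 90,
                             outlet_volume_each_ul = 50) {
  if (inlet_volume_each_ul < 0 || outlet_volume_each_ul < 0)
    stop("volumes must be non-negative", call. = FALSE)
  if (inlet_volume_each_ul < outlet_volume_each_ul)
    stop("inlet volume must be >= outlet volume for forward flow",
         call. = FALSE)
  structure(list(inlet_volume_each_ul = inlet_volume_each_ul,
                 outlet_volume_each_ul = outlet_volume_each_ul),
            class = "volume_condition")
}

#' Initial liquid-plug height difference between inlet and outlet
#'
#' With equal cylindrical reservoirs on each side, the height difference
#' is the per-reservoir volume difference divided by the single-reservoir
#' cross-sectional area A = pi d^2 / 4.
#'
#' @param vol A [volume_condition()].
#' @param geom A [chip_geometry()].
#' @return Height difference in mm.
#' @examples
#' height_difference(volume_condition(90, 50), chip_geometry()) # 2.037 mm
#' @export
height_difference <- function(vol, geom = chip_geometry()) {
  a_mm2 <- reservoir_area_mm2(geom)
  (vol$inlet_volume_each_ul - vol$outlet_volume_each_ul) / a_mm2
}

#' Hydrostatic pressure from a plug height difference
#'
#' dp = rho * g * dh, the pressure head driving the interstitial flow.
#'
#' @param dh_mm Height difference (mm); must be non-negative.
#' @param consts A [fluid_constants()].
#' @return Pressure in Pa.
#' @export
hydrostatic_pressure <- function(dh_mm, consts = fluid_constants()) {
  if (any(dh_mm < 0)) stop("height difference must be >= 0", call. = FALSE)
  consts$rho * consts$g * dh_mm * 1e-3
}

#' Calibrate the hydraulic resistance from an initial flow measurement
#'
#' R_hyd = dp(0) / Q(0), assumed constant over the drainage. Returned in
#' SI units (Pa s / m^3).
#'
#' @param q0_ul_min Measured initial flow rate (ul/min); must be > 0.
#' @param dp0_pa Initial hydrostatic pressure (Pa).
#' @return Hydraulic resistance in Pa s / m^3.
#' @export
calibrate_resistance <- function(q0_ul_min, dp0_pa) {
  if (!is.finite(q0_ul_min) || q0_ul_min <= 0)
    stop("calibration requires a positive initial flow rate", call. = FALSE)
  q0_si <- q0_ul_min * 1e-9 / 60     # ul/min -> m^3/s
  dp0_pa / q0_si
}

# drainage time constant in minutes: tau = A * dh(0) / Q(0)
# (equals the inlet-outlet volume difference over Q(0))
drainage_tau_min <- function(q0_ul_min, vol, geom = chip_geometry()) {
  reservoir_area_mm2(geom) * height_difference(vol, geom) / q0_ul_min
}

#' Closed-form drainage flow rate
#'
#' With constant hydraulic resistance the flow obeys
#' Q(t) = dh(t)/dh(0) * Q(0), and with each reservoir pair draining or
#' filling uniformly the height difference decays as
#' d(dh)/dt = -Q/A (A the single-reservoir area), so
#' Q(t) = Q(0) exp(-t / tau) with tau = A dh(0) / Q(0). This closed form
#' is the analytic oracle for [simulate_drainage()].
#'
#' @param q0_ul_min Initial flow rate (ul/min), > 0.
#' @param vol A [volume_condition()].
#' @param geom A [chip_geometry()].
#' @param t_min Times (minutes) at which to evaluate Q.
#' @return Flow rate(s) in ul/min at `t_min`; identically 0 when the
#'   initial height difference is 0.
#' @export
drainage_closed_form <- function(q0_ul_min, vol, geom = chip_geometry(),
                                 t_min) {
  if (!is.finite(q0_ul_min) || q0_ul_min <= 0)
    stop("q0 must be > 0", call. = FALSE)
  dh0 <- height_difference(vol, geom)
  if (dh0 == 0) return(rep(0, length(t_min)))
  tau <- drainage_tau_min(q0_ul_min, vol, geom)
  q0_ul_min * exp(-t_min / tau)
}

#' Simulate the gravity-driven reservoir drainage
#'
#' Numerically integrates the coupled reservoir-volume / flow system:
#' each inlet reservoir loses volume at rate Q/2 and each outlet
#' reservoir gains Q/2 (two reservoirs per side share the flow), the
#' height difference follows from the reservoir area, and
#' Q = Q(0) dh/dh(0). Integration uses `deSolve::lsoda` evaluated on a
#' fixed time grid; the simulation ends when Q first drops below
#' `q_min_ul_min`, the threshold standing in for the small friction
#' losses that stop the flow in practice.
#'
#' @param q0_ul_min Initial (calibrating) flow rate, ul/min.
#' @param vol A [volume_condition()].
#' @param geom A [chip_geometry()].
#' @param consts A [fluid_constants()] (used to report pressure).
#' @param q_min_ul_min Stop threshold (ul/min), default 0.02.
#' @param dt_min Time step of the reporting grid (minutes); defaults to
#'   tau/1000.
#' @return A `flow_series`: a data frame with columns `t_min`,
#'   `q_ul_min`, `dh_mm`, `dp_pa`, truncated at the stop time, with
#'   attributes `duration_min`, `tau_min`, `r_hyd_si`, `q0_ul_min`,
#'   `q_min_ul_min`, and the full reservoir volume trajectories
#'   `v_in_each_ul`, `v_out_each_ul` as columns.
#' @examples
#' fs <- simulate_drainage(3.1)
#' attr(fs, "duration_min") / 60  # about 1.08 h
#' @export
simulate_drainage <- function(q0_ul_min,
                              vol = volume_condition(),
                              geom = chip_geometry(),
                              consts = fluid_constants(),
                              q_min_ul_min = 0.02,
                              dt_min = NULL) {
  if (!is.finite(q0_ul_min) || q0_ul_min <= 0)
    stop("q0 must be > 0", call. = FALSE)
  dh0 <- height_difference(vol, geom)
  a_mm2 <- reservoir_area_mm2(geom)
  if (q0_ul_min <= q_min_ul_min || dh0 <= 0) {
    warning("initial flow rate at or below the stop threshold; duration 0")
    out <- data.frame(t_min = 0, q_ul_min = q0_ul_min * (dh0 > 0), dh_mm = dh0,
                      dp_pa = hydrostatic_pressure(dh0, consts),
                      v_in_each_ul = vol$inlet_volume_each_ul,
                      v_out_each_ul = vol$outlet_volume_each_ul)
    return(new_flow_series(out, duration_min = 0, tau_min = NA_real_,
                           q0_ul_min = q0_ul_min, q_min_ul_min = q_min_ul_min,
                           r_hyd_si = calibrate_resistance(
                             q0_ul_min, hydrostatic_pressure(dh0, consts))))
  }
  tau <- drainage_tau_min(q0_ul_min, vol, geom)
  if (is.null(dt_min)) dt_min <- tau / 1000
  t_end <- tau * log(q0_ul_min / q_min_ul_min)
  times <- seq(0, t_end * 1.05 + 5 * dt_min, by = dt_min)

  deriv <- function(t, state, parms) {
    dh <- (state[["v_in"]] - state[["v_out"]]) / a_mm2
    q <- q0_ul_min * dh / dh0                        # ul/min
    n <- geom$reservoirs_per_side
    list(c(v_in = -q / n, v_out = q / n))
  }
  sol <- deSolve::lsoda(
    y = c(v_in = vol$inlet_volume_each_ul, v_out = vol$outlet_volume_each_ul),
    times = times, func = deriv, parms = NULL, rtol = 1e-10, atol = 1e-10)

  dh <- (sol[, "v_in"] - sol[, "v_out"]) / a_mm2
  q <- q0_ul_min * dh / dh0
  stop_idx <- which(q < q_min_ul_min)[1]
  if (is.na(stop_idx)) stop_idx <- length(q)     # grid covers the crossing
  keep <- seq_len(stop_idx)
  out <- data.frame(t_min = sol[keep, "time"],
                    q_ul_min = q[keep],
                    dh_mm = dh[keep],
                    dp_pa = hydrostatic_pressure(pmax(dh[keep], 0), consts),
                    v_in_each_ul = sol[keep, "v_in"],
                    v_out_each_ul = sol[keep, "v_out"])
  new_flow_series(out,
                  duration_min = unname(sol[stop_idx, "time"]),
                  tau_min = tau,
                  q0_ul_min = q0_ul_min,
                  q_min_ul_min = q_min_ul_min,
                  r_hyd_si = calibrate_resistance(
                    q0_ul_min, hydrostatic_pressure(dh0, consts)))
}

new_flow_series <- function(df, duration_min, tau_min, q0_ul_min,
                            q_min_ul_min, r_hyd_si) {
  structure(df, duration_min = duration_min, tau_min = tau_min,
            q0_ul_min = q0_ul_min, q_min_ul_min = q_min_ul_min,
            r_hyd_si = r_hyd_si, class = c("flow_series", "data.frame"))
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf(
    "Gravity-driven drainage: Q(0) = %.3g ul/min, tau = %.4g min,\n",
    attr(x, "q0_ul_min"), attr(x, "tau_min")))
  cat(sprintf("  stop threshold %.3g ul/min, duration %.4g min (%.3g h)\n",
              attr(x, "q_min_ul_min"), attr(x, "duration_min"),
              attr(x, "duration_min") / 60))
  cat(sprintf("  R_hyd = %.4g Pa s/m^3; %d time points\n",
              attr(x, "r_hyd_si"), nrow(x)))
  invisible(x)
}

#' Total flow duration until the stop threshold
#'
#' @param fs A `flow_series` from [simulate_drainage()].
#' @param unit `"min"` or `"h"`; `"h"` divides by 60.
#' @param round_hours Round to the nearest whole hour (the reporting
#'   granularity used for daily medium changes). Only applies to `"h"`.
#' @return Duration as a number.
#' @export
flow_duration <- function(fs, unit = c("min", "h"), round_hours = FALSE) {
  unit <- match.arg(unit)
  d <- attr(fs, "duration_min")
  if (unit == "min") return(d)
  if (round_hours) round(d / 60) else d / 60
}

#' Interstitial shear stress from a Darcy permeability estimate
#'
#' tau = mu * v / sqrt(K_p): the wall shear an interstitial velocity v
#' exerts inside a porous matrix of Darcy permeability K_p
#' (Darcy-Brinkman boundary-layer estimate).
#'
#' @param v_mm_s Interstitial flow velocity (mm/s), non-negative.
#' @param consts A [fluid_constants()].
#' @return Shear stress in Pa.
#' @examples
#' interstitial_shear(0.024)  # ~0.0064 Pa, physiological interstitial range
#' @export
interstitial_shear <- function(v_mm_s, consts = fluid_constants()) {
  if (any(v_mm_s < 0)) stop("velocity must be >= 0", call. = FALSE)
  consts$mu * (v_mm_s * 1e-3) / sqrt(consts$k_p)
}
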