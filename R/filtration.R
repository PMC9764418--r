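#' Operating conditions for filtration and washing
#'
#' @param pressure_drop Driving pressure difference, Pa; > 0.
#' @param filter_diameter Filter medium diameter, m; > 0.
#' @param media_resistance Filter-medium resistance R_m, m^-1; >= 0.
#' @param temperature Temperature, degrees C.
#' @param endpoint_mode Filtration endpoint: `"dryland"` stops when the free
#'   slurry liquid is exhausted and the cake is fully saturated with mother
#'   liquor; `"breakthrough"` additionally removes pore liquor until only
#'   `breakthrough_residual_fraction` of the void volume holds liquid
#'   (bookkeeping only: no capillary or multiphase-flow physics).
#' @param breakthrough_residual_fraction Fraction of the void volume still
#'   liquid-filled at breakthrough, in (0, 1); default 0.10 (90% of the
#'   mother liquor removed).
#' @param settling_enabled Apply Richardson-Zaki hindered settling to
#'   pre-concentrate the depositing cake (off by default).
#' @param settling_exponent Richardson-Zaki exponent n; default 4.65.
#' @return An object of class `operating_conditions`.
#' @export
operating_conditions <- function(pressure_drop, filter_diameter,
                                 media_resistance,
                                 temperature = 25,
                                 endpoint_mode = c("dryland", "breakthrough"),
                                 breakthrough_residual_fraction = 0.10,
                                 settling_enabled = FALSE,
                                 settling_exponent = 4.65) {
  endpoint_mode <- match.arg(endpoint_mode)
  if (pressure_drop <= 0) stop("pressure_drop must be > 0 (Pa)")
  if (filter_diameter <= 0) stop("filter_diameter must be > 0 (m)")
  if (media_resistance < 0) stop("media_resistance must be >= 0 (m^-1)")
  if (breakthrough_residual_fraction <= 0 ||
      breakthrough_residual_fraction >= 1)
    stop("breakthrough_residual_fraction must lie in (0, 1)")
  structure(list(pressure_drop = pressure_drop,
                 filter_diameter = filter_diameter,
                 media_resistance = media_resistance,
                 temperature = temperature,
                 endpoint_mode = endpoint_mode,
                 breakthrough_residual_fraction =
                   breakthrough_residual_fraction,
                 settling_enabled = settling_enabled,
                 settling_exponent = settling_exponent),
            class = "operating_conditions")
}

#' Suspension (slurry) state fed to the filter
#'
#' @param solid_mass Suspended solid mass, kg; > 0.
#' @param psd A [psd()] describing the solid.
#' @param liquid A [liquid_state()]: the mother liquor.
#' @param cake_porosity Porosity of the cake the suspension forms, in (0, 1).
#'   An empirical input; it is not predicted from the PSD.
#' @return An object of class `suspension_state`.
#' @export
suspension_state <- function(solid_mass, psd, liquid, cake_porosity) {
  stopifnot(inherits(psd, "psd"), inherits(liquid, "liquid_state"))
  if (solid_mass <= 0) stop("solid_mass must be > 0")
  if (cake_porosity <= 0 || cake_porosity >= 1)
    stop("cake_porosity must lie in (0, 1)")
  structure(list(solid_mass = solid_mass, psd = psd, liquid = liquid,
                 cake_porosity = cake_porosity),
            class = "suspension_state")
}

#' Carman-Kozeny specific (mass-based) cake resistance
#'
#' alpha = 180 (1 - eps) / (rho_s x_sv^2 eps^3): positive and strictly
#' decreasing in porosity.
#'
#' @param eps Cake porosity, in (0, 1).
#' @param x_sv Sauter mean diameter (sphericity-scaled), m; > 0.
#' @param rho_s Crystal density, kg m^-3; > 0.
#' @return Specific cake resistance, m kg^-1.
#' @export
carman_kozeny_alpha <- function(eps, x_sv, rho_s) {
  if (any(eps <= 0 | eps >= 1)) stop("porosity must lie in (0, 1)")
  if (any(x_sv <= 0)) stop("x_sv must be > 0")
  if (any(rho_s <= 0)) stop("rho_s must be > 0")
  180 * (1 - eps) / (rho_s * x_sv^2 * eps^3)
}

#' Cake permeability from the specific cake resistance
#'
#' k = 1 / (alpha rho_s (1 - eps)).
#'
#' @param alpha Specific cake resistance, m kg^-1; > 0.
#' @inheritParams carman_kozeny_alpha
#' @return Permeability, m^2.
#' @export
permeability_from_alpha <- function(alpha, eps, rho_s) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(eps >= 1)) stop("porosity must be < 1")
  1 / (alpha * rho_s * (1 - eps))
}

#' Richardson-Zaki hindered settling velocity
#'
#' u = u_Stokes (1 - phi_v)^n with u_Stokes = (rho_s - rho_l) g d^2 / (18 mu).
#'
#' @param d Particle diameter, m.
#' @param rho_s,rho_l Solid and liquid densities, kg m^-3.
#' @param mu Liquid viscosity, Pa s.
#' @param phi_v Solid volume fraction of the suspension, in \[0, 1).
#' @param n Richardson-Zaki exponent; default 4.65.
#' @return Settling velocity, m s^-1 (positive downward for rho_s > rho_l).
#' @export
hindered_settling_velocity <- function(d, rho_s, rho_l, mu, phi_v,
                                       n = 4.65) {
  if (any(phi_v < 0 | phi_v >= 1)) stop("phi_v must lie in [0, 1)")
  (rho_s - rho_l) * 9.80665 * d^2 / (18 * mu) * (1 - phi_v)^n
}

new_cake_state <- function(layers, area, height, saturation) {
  structure(list(layers = layers, area = area, height = height,
                 n_layers = length(layers), saturation = saturation),
            class = "cake_state")
}

#' @export
print.cake_state <- function(x, ...) {
  cat(sprintf("<cake_state> %d layer(s), A = %.4g m^2, L = %.4g mm, solid %.5g g\n",
              x$n_layers, x$area, x$height * 1e3,
              1e3 * sum(vapply(x$layers, `[[`, numeric(1), "solid_mass"))))
  invisible(x)
}

cake_void_volume <- function(cake) {
  sum(vapply(cake$layers, function(l) {
    vs <- l$solid_mass / l$rho_s
    vs / (1 - l$porosity) * l$porosity
  }, numeric(1)))
}

cake_solid_mass <- function(cake)
  sum(vapply(cake$layers, `[[`, numeric(1), "solid_mass"))

cake_liquid_mass <- function(cake) {
  m <- Reduce(`+`, lapply(cake$layers, function(l) l$liquid$mass))
  m
}

#' Constant-pressure dead-end cake filtration
#'
#' Integrates Darcy's law for constant-pressure cake filtration,
#' dV/dt = dP A^2 / (mu (alpha w V + R_m A)), with w the dry cake mass
#' deposited per unit filtrate volume, from V = 0 to the endpoint: *dryland*
#' (all free suspension liquid is either filtrate or held saturating the cake
#' voids) or *breakthrough* (pore liquor further reduced to
#' `breakthrough_residual_fraction` of the void volume at unchanged
#' composition). The specific resistance comes from [carman_kozeny_alpha()]
#' at the supplied porosity and the PSD's sphericity-scaled Sauter mean.
#'
#' @param suspension A [suspension_state()].
#' @param conditions An [operating_conditions()].
#' @param materials A [material_set()].
#' @param n_samples Number of trajectory samples; default 201.
#' @return A list with components `result` (class `filtration_result`:
#'   trajectory `t`, `V`, `Q`; `filtration_time`; `alpha`; `cake_volume`;
#'   `cake_height`; `residual_liquid_volume`; `residual_liquid`) and `cake`
#'   (a single-layer `cake_state` ready for washing).
#' @export
constant_pressure_filtration <- function(suspension, conditions, materials,
                                         n_samples = 201L) {
  stopifnot(inherits(suspension, "suspension_state"),
            inherits(conditions, "operating_conditions"),
            inherits(materials, "material_set"))
  rho_s <- materials$solute$crystal_density
  phi <- materials$solute$sphericity
  eps <- suspension$cake_porosity
  A <- pi * (conditions$filter_diameter / 2)^2
  dP <- conditions$pressure_drop
  Rm <- conditions$media_resistance

  mu <- mixture_viscosity(suspension$liquid, materials)
  rho_l <- mixture_density(suspension$liquid, materials)
  M_s <- suspension$solid_mass
  M_l <- sum(suspension$liquid$mass)
  V_liq <- M_l / rho_l
  if (V_liq <= 0) stop("suspension carries no liquid")

  V_solid <- M_s / rho_s
  cake_volume <- V_solid / (1 - eps)
  void_volume <- cake_volume * eps
  L <- cake_volume / A
  V_dry <- V_liq - void_volume
  if (V_dry <= 0)
    stop("degenerate suspension: liquid volume does not exceed cake voids")

  x_sv <- sauter_mean(suspension$psd, phi)
  alpha <- carman_kozeny_alpha(eps, x_sv, rho_s)
  w <- M_s / V_dry

  if (isTRUE(conditions$settling_enabled)) {
    d_sv <- sauter_mean(suspension$psd, 1)
    phi_v <- V_solid / (V_solid + V_liq)
    u_h <- hindered_settling_velocity(d_sv, rho_s, rho_l, mu, phi_v,
                                      conditions$settling_exponent)
    Q0 <- if (Rm > 0) dP * A / (mu * Rm) else Inf
    if (is.finite(Q0) && u_h > 0) w <- w * (1 + u_h * A / Q0)
  }

  # integrate dt/dV (monotone V as independent variable)
  dtdV <- function(V, t, parms)
    list(mu * (alpha * w * V + Rm * A) / (dP * A^2))
  Vgrid <- seq(0, V_dry, length.out = n_samples)
  sol <- deSolve::ode(y = c(t = 0), times = Vgrid, func = dtdV, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-14)
  tgrid <- sol[, "t"]
  Qgrid <- dP * A^2 / (mu * (alpha * w * Vgrid + Rm * A))

  saturation <- 1
  residual_volume <- void_volume
  if (conditions$endpoint_mode == "breakthrough") {
    f_b <- conditions$breakthrough_residual_fraction
    dV_b <- (1 - f_b) * void_volume
    R_cake <- alpha * M_s / A
    Q_b <- dP * A / (mu * (R_cake + Rm))
    Vb <- seq(V_dry, V_dry + dV_b, length.out = 51L)[-1L]
    tb <- tgrid[length(tgrid)] + (Vb - V_dry) / Q_b
    Vgrid <- c(Vgrid, Vb)
    tgrid <- c(tgrid, tb)
    Qgrid <- c(Qgrid, rep(Q_b, length(Vb)))
    saturation <- f_b
    residual_volume <- f_b * void_volume
  }

  frac <- mass_fractions(suspension$liquid)
  res_mass <- residual_volume * rho_l
  residual_liquid <- liquid_state(
    solute = res_mass * frac[["solute"]],
    crystallization_solvent = res_mass * frac[["crystallization_solvent"]],
    wash_solvent = res_mass * frac[["wash_solvent"]],
    temperature = suspension$liquid$temperature)

  layer <- list(solid_mass = M_s, psd = suspension$psd,
                liquid = residual_liquid, porosity = eps, rho_s = rho_s)
  cake <- new_cake_state(list(layer), area = A, height = L,
                         saturation = saturation)

  result <- structure(list(
    filtration_time = tgrid[length(tgrid)],
    trajectory = data.frame(t = tgrid, V = Vgrid, Q = Qgrid),
    specific_cake_resistance = alpha,
    cake_volume = cake_volume,
    cake_height = L,
    void_volume = void_volume,
    residual_liquid_volume = residual_volume,
    residual_liquid = residual_liquid,
    filtrate_volume = Vgrid[length(Vgrid)],
    suspension_liquid_volume = V_liq,
    cake_deposition_concentration = w,
    viscosity = mu,
    liquid_density = rho_l,
    sauter_diameter = x_sv,
    area = A), class = "filtration_result")
  list(result = result, cake = cake)
}

#' @export
print.filtration_result <- function(x, ...) {
  cat(sprintf(paste0("<filtration_result> t = %.4g s, alpha = %.4g m/kg, ",
                     "L = %.4g mm, residual liquid %.4g mL\n"),
              x$filtration_time, x$specific_cake_resistance,
              x$cake_height * 1e3, x$residual_liquid_volume * 1e6))
  invisible(x)
}

#' Split the filtered cake into equal layers for washing
#'
#' Splits the cake into `n_layers` equal-thickness layers with equal solid
#' mass and copies of the PSD; the residual mother liquor is distributed
#' uniformly; the saturation (1 at dryland, the breakthrough residual
#' fraction otherwise) is inherited from the filtration endpoint. Layer 1 is
#' the top of the cake (wash inlet), layer `n_layers` adjoins the filter
#' medium.
#'
#' @param filtration The list returned by [constant_pressure_filtration()].
#' @param n_layers Number of layers; >= 1.
#' @return A `cake_state` with `n_layers` layers.
#' @export
make_initial_wash_cake <- function(filtration, n_layers = 10L) {
  stopifnot(n_layers >= 1L)
  cake <- filtration$cake
  if (cake$n_layers != 1L)
    stop("make_initial_wash_cake expects the single-layer filtration cake")
  l0 <- cake$layers[[1L]]
  liq <- l0$liquid
  layers <- lapply(seq_len(n_layers), function(i) {
    list(solid_mass = l0$solid_mass / n_layers,
         psd = psd(l0$psd$edges, l0$psd$mass / n_layers),
         liquid = liquid_state(
           solute = liq$mass[["solute"]] / n_layers,
           crystallization_solvent =
             liq$mass[["crystallization_solvent"]] / n_layers,
           wash_solvent = liq$mass[["wash_solvent"]] / n_layers,
           temperature = liq$temperature),
         porosity = l0$porosity, rho_s = l0$rho_s)
  })
  new_cake_state(layers, area = cake$area, height = cake$height,
                 saturation = cake$saturation)
}
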