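#' Wash protocol
#'
#' Operating description of one washing step. All results are reported
#' against the wash ratio on a fixed grid (`wr_step`), so the curves are
#' independent of the absolute flow rate; the flow rate (Darcy at constant
#' pressure, or a prescribed constant flow) sets the physical time axis and
#' the time step seen by finite-rate dissolution kinetics.
#'
#' @param wash_ratio_max Final wash ratio W_r; > 0. Default 2.
#' @param flow_mode `"constant_pressure"` (Darcy with the evolving mixture
#'   viscosity; needs [operating_conditions()] at run time) or
#'   `"constant_flow"`.
#' @param wash_flow_rate Wash volumetric flow, m^3 s^-1 (constant_flow mode).
#' @param n_layers Default cascade depth for the tanks-in-series models.
#' @param molecular_diffusivity Molecular diffusivity D, m^2 s^-1;
#'   default 1e-9.
#' @param dispersion_model `"fixed_D"` (axial dispersion = D) or
#'   `"correlation"` (packed-bed estimate D + 0.5 u_s d_p).
#' @param outflow_matched Exit flow equals wash inflow (the default; the
#'   holdup volume stays constant).
#' @param wr_step Reporting grid spacing in wash ratio; default 0.01.
#' @param internal_wr_step Operator-splitting step of the case-2 engine.
#' @param checkpoints Wash ratios at which layer-wise PSD/porosity snapshots
#'   are stored; default every 0.25.
#' @param equilibrium_tol Maximum |sigma| tolerated on an accepted case-2
#'   run; default 1e-3.
#' @return An object of class `wash_protocol`.
#' @export
wash_protocol <- function(wash_ratio_max = 2,
                          flow_mode = c("constant_pressure", "constant_flow"),
                          wash_flow_rate = NULL,
                          n_layers = 10L,
                          molecular_diffusivity = 1e-9,
                          dispersion_model = c("fixed_D", "correlation"),
                          outflow_matched = TRUE,
                          wr_step = 0.01,
                          internal_wr_step = 0.005,
                          checkpoints = NULL,
                          equilibrium_tol = 1e-3) {
  flow_mode <- match.arg(flow_mode)
  dispersion_model <- match.arg(dispersion_model)
  if (wash_ratio_max <= 0) stop("wash_ratio_max must be > 0")
  if (molecular_diffusivity <= 0) stop("molecular_diffusivity must be > 0")
  if (is.null(checkpoints))
    checkpoints <- unique(c(seq(0, wash_ratio_max, by = 0.25),
                            wash_ratio_max))
  structure(list(wash_ratio_max = wash_ratio_max, flow_mode = flow_mode,
                 wash_flow_rate = wash_flow_rate, n_layers = n_layers,
                 molecular_diffusivity = molecular_diffusivity,
                 dispersion_model = dispersion_model,
                 outflow_matched = outflow_matched,
                 wr_step = wr_step, internal_wr_step = internal_wr_step,
                 checkpoints = checkpoints,
                 equilibrium_tol = equilibrium_tol),
            class = "wash_protocol")
}

#' Wash ratio
#'
#' W_r = V_w / V_v: wash volume fed over the cake void volume.
#'
#' @param V_w Wash volume fed, m^3.
#' @param V_v Cake void volume, m^3; > 0.
#' @return Dimensionless wash ratio.
#' @export
wash_ratio <- function(V_w, V_v) {
  if (any(V_v <= 0)) stop("degenerate cake: void volume must be > 0")
  V_w / V_v
}

#' @rdname wash_ratio
#' @param t Time since wash start, s.
#' @param u_s Superficial wash velocity, m s^-1.
#' @param L Cake height, m.
#' @param eps Cake porosity.
#' @export
wr_from_time <- function(t, u_s, L, eps) {
  if (any(L <= 0) || any(eps <= 0)) stop("degenerate cake geometry")
  u_s * t / (eps * L)
}

#' Axial dispersion coefficient
#'
#' `"fixed_D"` returns the molecular diffusivity unchanged; `"correlation"`
#' adds the standard packed-bed mechanical-dispersion estimate
#' 0.5 u_s d_p.
#'
#' @param u_s Superficial velocity, m s^-1; >= 0.
#' @param d_p Particle diameter, m.
#' @param D Molecular diffusivity, m^2 s^-1.
#' @param mode `"fixed_D"` or `"correlation"`.
#' @return Axial dispersion coefficient, m^2 s^-1.
#' @export
axial_dispersion_coefficient <- function(u_s, d_p, D,
                                         mode = c("fixed_D",
                                                  "correlation")) {
  mode <- match.arg(mode)
  if (any(u_s < 0)) stop("u_s must be >= 0")
  if (mode == "fixed_D") D else D + 0.5 * u_s * d_p
}

#' Nernst-Brunner dissolution rate
#'
#' dm/dt = (D / delta) A_total (c_sat - c) with the total crystal surface
#' area from [specific_surface_area()] and both concentrations on a
#' mass-per-liquid-volume basis. Positive = dissolution (solid to liquid),
#' negative = deposition; zero at saturation.
#'
#' @param liquid A [liquid_state()].
#' @param x A [psd()].
#' @param curve A [solubility_curve()].
#' @param D Molecular diffusivity, m^2 s^-1.
#' @param boundary_layer Diffusion boundary-layer thickness delta, m; > 0.
#' @param solid_mass Solid mass carrying the surface area, kg.
#' @param materials A [material_set()].
#' @return Rate of solid dissolution, kg s^-1.
#' @export
nernst_brunner_rate <- function(liquid, x, curve, D, boundary_layer,
                                solid_mass, materials) {
  if (boundary_layer <= 0) stop("boundary_layer must be > 0")
  rho_s <- materials$solute$crystal_density
  phi <- materials$solute$sphericity
  A_tot <- specific_surface_area(x, phi, rho_s) * solid_mass
  V_liq <- sum(liquid$mass / c(rho_s,
                               materials$crystallization_solvent$density,
                               materials$wash_solvent$density))
  if (V_liq <= 0) stop("degenerate liquid state: zero volume")
  solv <- sum(liquid$mass[c("crystallization_solvent", "wash_solvent")])
  c_now <- liquid$mass[["solute"]] / V_liq
  c_sat <- csat_lookup(curve, wash_solvent_fraction(liquid)) * solv / V_liq
  (D / boundary_layer) * A_tot * (c_sat - c_now)
}

# ---- shared helpers ------------------------------------------------------

species_names <- c("solute", "crystallization_solvent", "wash_solvent")

cake_layer_void <- function(l) l$solid_mass / l$rho_s / (1 - l$porosity) *
  l$porosity

liquid_from_vec <- function(m, temperature = 25) {
  # absorb solver-level negative roundoff (washed-out species)
  tiny <- m < 0 & m > -1e-9 * max(m, 1e-30)
  m[tiny] <- 0
  liquid_state(m[1L], m[2L], m[3L], temperature)
}

cake_liquid_matrix <- function(cake)
  t(vapply(cake$layers, function(l) unname(l$liquid$mass), numeric(3)))

#' @keywords internal
wash_flow_rate_now <- function(cake, materials, protocol, conditions,
                               liquid_masses) {
  if (protocol$flow_mode == "constant_flow") {
    if (is.null(protocol$wash_flow_rate))
      stop("constant_flow mode needs protocol$wash_flow_rate")
    return(protocol$wash_flow_rate)
  }
  if (is.null(conditions)) {
    # no hydraulic information: nominal one void volume per minute
    return(sum(vapply(cake$layers, cake_layer_void, numeric(1))) / 60)
  }
  mu <- mixture_viscosity(liquid_from_vec(colSums(liquid_masses)), materials)
  A <- cake$area
  R_cake <- sum(vapply(cake$layers, function(l) {
    x_sv <- sauter_mean(l$psd, materials$solute$sphericity)
    carman_kozeny_alpha(l$porosity, x_sv, l$rho_s) * l$solid_mass / A
  }, numeric(1)))
  conditions$pressure_drop * A / (mu * (R_cake + conditions$media_resistance))
}

new_wash_curve <- function(model, wash_ratio, filtrate_fraction, c_over_c0,
                           cum_filtrate, solid_dmass, fed_wash, final_cake,
                           snapshots, diagnostics, time = NULL) {
  colnames(filtrate_fraction) <- species_names
  colnames(cum_filtrate) <- species_names
  structure(list(model = model, wash_ratio = wash_ratio,
                 filtrate_fraction = filtrate_fraction,
                 c_over_c0 = c_over_c0, cum_filtrate = cum_filtrate,
                 solid_dmass = solid_dmass, fed_wash = fed_wash,
                 final_cake = final_cake, snapshots = snapshots,
                 diagnostics = diagnostics, time = time),
            class = "wash_curve")
}

#' @export
print.wash_curve <- function(x, ...) {
  n <- length(x$wash_ratio)
  cat(sprintf(paste0("<wash_curve> model %s: W_r 0..%.3g, final c/c0 = %.4g, ",
                     "solid mass change %+.4g mg\n"),
              x$model, x$wash_ratio[n], x$c_over_c0[n],
              1e6 * x$solid_dmass[n]))
  if (!is.null(x$diagnostics$max_sigma) &&
      is.finite(x$diagnostics$max_sigma))
    cat(sprintf("  max |sigma| = %.3g\n", x$diagnostics$max_sigma))
  invisible(x)
}

layer_snapshot <- function(cake_area, cake_height, n_layers, solid, psds,
                           M, layers_meta, materials, wr) {
  V_layer <- cake_area * cake_height / n_layers
  rho <- c(materials$solute$crystal_density,
           materials$crystallization_solvent$density,
           materials$wash_solvent$density)
  do.call(rbind, lapply(seq_len(n_layers), function(i) {
    q <- if (sum(psds[[i]]$mass) > 0)
      quantile(psds[[i]], c(0.1, 0.5, 0.9)) else rep(NA_real_, 3)
    solid_vol <- solid[i] / layers_meta[[i]]$rho_s
    porosity <- 1 - solid_vol / V_layer
    liq_vol <- sum(M[i, ] / rho)
    void <- V_layer - solid_vol
    data.frame(wash_ratio = wr, layer = i,
               D10 = q[1L], D50 = q[2L], D90 = q[3L],
               porosity = porosity,
               saturation = if (void > 0) liq_vol / void else NA_real_,
               w_wash = if (sum(M[i, 2:3]) > 0)
                 M[i, 3L] / sum(M[i, 2:3]) else NA_real_)
  }))
}

# ---- model 1a / 2a: pure displacement ------------------------------------

#' Displacement washing (models 1a and 2a)
#'
#' Plug displacement of the pore liquor by an immiscible wash solvent: the
#' filtrate keeps the mother-liquor composition until exactly one void volume
#' has been displaced (W_r = 1) and is the wash input thereafter. With
#' `dissolve = TRUE` (model 2a) the wash liquor traverses the cake and leaves
#' saturated at csat(w_wash = 1), dissolving solid homogeneously across the
#' cake at a rate of csat(1) per unit mass of wash solvent fed
#' ([uniform_dissolve()] on every layer).
#'
#' @param cake A `cake_state` saturated with mother liquor (dryland feed).
#' @param materials A [material_set()].
#' @param protocol A [wash_protocol()].
#' @param curve A [solubility_curve()] (required when `dissolve = TRUE`).
#' @param dissolve Model 2a when `TRUE`, 1a when `FALSE`.
#' @return A `wash_curve`.
#' @export
wash_displacement <- function(cake, materials, protocol, curve = NULL,
                              dissolve = FALSE) {
  stopifnot(inherits(cake, "cake_state"), inherits(protocol, "wash_protocol"))
  if (abs(cake$saturation - 1) > 1e-9)
    stop("displacement washing needs a dryland (fully saturated) feed cake")
  if (dissolve && is.null(curve))
    stop("model 2a needs a solubility curve")

  wr <- seq(0, protocol$wash_ratio_max, by = protocol$wr_step)
  V_v <- sum(vapply(cake$layers, cake_layer_void, numeric(1)))
  rho_w <- materials$wash_solvent$density
  ml <- colSums(cake_liquid_matrix(cake))
  rho_ml <- mixture_density(liquid_from_vec(ml), materials)
  fr_ml <- ml / sum(ml)
  c0 <- ml[1L] / V_v

  csat1 <- if (dissolve) csat_lookup(curve, 1) else 0
  m_wash_per_wr <- rho_w * V_v          # wash solvent mass per unit W_r
  diss_per_wr <- csat1 * m_wash_per_wr  # solid dissolved per unit W_r
  solid0 <- cake_solid_mass(cake)
  total_diss <- diss_per_wr * protocol$wash_ratio_max
  if (total_diss > solid0)
    stop("infeasible dissolution: wash would dissolve more than the cake")

  pre <- wr < 1
  x_out_sat <- c(csat1, 0, 1) / (1 + csat1)
  filtrate_fraction <- rbind(
    matrix(fr_ml, sum(pre), 3, byrow = TRUE),
    matrix(x_out_sat, sum(!pre), 3, byrow = TRUE))
  c_over_c0 <- ifelse(pre, 1, (csat1 * rho_w) / c0)

  cum_filtrate <- matrix(0, length(wr), 3)
  for (j in 1:3) {
    ml_part <- pmin(wr, 1) * V_v * rho_ml * fr_ml[j]
    wash_part <- pmax(wr - 1, 0) * m_wash_per_wr *
      (if (j == 1L) csat1 else if (j == 3L) 1 else 0)
    cum_filtrate[, j] <- ml_part + wash_part
  }
  solid_dmass <- -diss_per_wr * wr
  fed_wash <- cbind(solute = 0, crystallization_solvent = 0,
                    wash_solvent = m_wash_per_wr * wr)

  # final cake: top fraction min(wr_max,1) of layers hold saturated wash
  wr_end <- protocol$wash_ratio_max
  n <- cake$n_layers
  final_layers <- lapply(seq_len(n), function(i) {
    l <- cake$layers[[i]]
    void <- cake_layer_void(l)
    washed <- min(max(wr_end * n - (i - 1), 0), 1) # fraction displaced
    m_ws <- washed * void * rho_w
    m_res <- (1 - washed) * void * rho_ml
    l$liquid <- liquid_state(
      solute = m_ws * csat1 + m_res * fr_ml[1L],
      crystallization_solvent = m_res * fr_ml[2L],
      wash_solvent = m_ws + m_res * fr_ml[3L],
      temperature = l$liquid$temperature)
    diss_i <- total_diss * l$solid_mass / solid0
    l$psd <- uniform_dissolve(l$psd, diss_i)
    l$solid_mass <- l$solid_mass - diss_i
    l
  })
  final_cake <- new_cake_state(final_layers, cake$area, cake$height,
                               saturation = 1)

  snaps <- NULL
  new_wash_curve(model = if (dissolve) "2a" else "1a",
                 wash_ratio = wr, filtrate_fraction = filtrate_fraction,
                 c_over_c0 = c_over_c0, cum_filtrate = cum_filtrate,
                 solid_dmass = solid_dmass, fed_wash = fed_wash,
                 final_cake = final_cake, snapshots = snaps,
                 diagnostics = list(max_sigma = NA_real_, peclet = NA_real_))
}

# ---- tanks-in-series engine (models 1b, 2b, 1c-cascade, 2c) --------------

cascade_case1 <- function(cake, materials, protocol, wr, V_L, c_in, c0) {
  N <- cake$n_layers
  M0 <- cake_liquid_matrix(cake)
  y0 <- c(as.vector(t(M0)), rep(0, 3))
  m_in <- c_in * V_L
  deriv <- function(wrx, y, parms) {
    M <- matrix(y[seq_len(3 * N)], nrow = N, byrow = TRUE)
    up <- rbind(m_in, M[-N, , drop = FALSE])
    dM <- N * (up - M)
    dF <- N * M[N, ]
    list(c(as.vector(t(dM)), dF))
  }
  sol <- deSolve::ode(y = y0, times = wr, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-11, atol = 1e-14,
                      jactype = "bandint", bandup = 0, banddown = 3)
  idxN <- 3 * (N - 1) + 1:3 + 1  # +1 for the time column
  mN <- sol[, idxN, drop = FALSE]
  Fcum <- sol[, 3 * N + 1:3 + 1, drop = FALSE]
  list(sol = sol, mN = mN, Fcum = Fcum)
}

equilibrate_layer <- function(m, solid, p, kinetics, curve, dt, tol) {
  # m: liquid species masses; p: psd; returns updated (m, solid, p, sigma)
  solv <- m[2L] + m[3L]
  if (solv <= 0 || solid < 0)
    return(list(m = m, solid = solid, psd = p, sigma = 0))
  csat <- csat_lookup(curve, m[3L] / solv)
  c_now <- m[1L] / solv
  delta <- (csat - c_now) * solv          # >0 dissolve, <0 deposit
  if (delta > 0) delta <- min(delta, solid)
  scale <- max(solid + m[1L], 1e-30)
  sigma_of <- function(mm) {
    cs <- csat_lookup(curve, mm[3L] / (mm[2L] + mm[3L]))
    cn <- mm[1L] / (mm[2L] + mm[3L])
    if (cs == 0) { if (cn > 0) Inf else 0 } else cn / cs - 1
  }
  if (abs(delta) < 1e-16 * scale)
    return(list(m = m, solid = solid, psd = p, sigma = sigma_of(m)))
  if (sum(p$mass) <= 0 && delta > 0)      # nothing left to dissolve
    return(list(m = m, solid = solid, psd = p, sigma = sigma_of(m)))

  if (kinetics$mode == "instantaneous_flash") {
    dL <- psd_delta_for_mass(p, delta)
  } else {
    sig <- if (csat == 0) { if (c_now > 0) Inf else 0 } else c_now / csat - 1
    G <- if (is.infinite(sig)) -sign(delta) * kinetics$rate_constant else
      sign(sig) * kinetics$rate_constant * abs(sig)^kinetics$exponent
    dL <- G * dt
    # dissolution: sigma<0 -> G<0 -> dL<0 matches delta>0; clip at flash
    would <- psd_shift_mass_change(p, dL)
    if (abs(would) > abs(delta) || sign(would) != sign(delta))
      dL <- psd_delta_for_mass(p, delta)
  }
  sh <- psd_shift(p, dL)
  ex <- sh$mass_exchanged                  # >0 dissolved
  m[1L] <- m[1L] + ex
  solid <- solid - ex
  list(m = m, solid = solid, psd = sh$psd, sigma = sigma_of(m))
}

cascade_case2 <- function(cake, materials, protocol, kinetics, curve,
                          conditions, wr, V_L, V_v, c_in, c0) {
  N <- cake$n_layers
  h <- protocol$internal_wr_step
  n_report <- length(wr)
  M <- cake_liquid_matrix(cake)
  Fcum <- rep(0, 3)
  solid <- vapply(cake$layers, `[[`, numeric(1), "solid_mass")
  psds <- lapply(cake$layers, `[[`, "psd")
  solid0 <- sum(solid)
  m_in <- c_in * V_L

  flow_deriv <- function(M, Fc) {
    up <- rbind(m_in, M[-N, , drop = FALSE])
    list(dM = N * (up - M), dF = N * M[N, ])
  }
  rk4_step <- function(M, Fc, h) {
    k1 <- flow_deriv(M, Fc)
    k2 <- flow_deriv(M + h / 2 * k1$dM, Fc)
    k3 <- flow_deriv(M + h / 2 * k2$dM, Fc)
    k4 <- flow_deriv(M + h * k3$dM, Fc)
    list(M = M + h / 6 * (k1$dM + 2 * k2$dM + 2 * k3$dM + k4$dM),
         Fc = Fc + h / 6 * (k1$dF + 2 * k2$dF + 2 * k3$dF + k4$dF))
  }

  out_frac <- matrix(NA_real_, n_report, 3)
  out_c <- numeric(n_report)
  out_F <- matrix(NA_real_, n_report, 3)
  out_dm <- numeric(n_report)
  out_t <- numeric(n_report)
  snaps <- list()
  record <- function(k) {
    tot <- sum(M[N, ])
    out_frac[k, ] <<- if (tot > 0) M[N, ] / tot else rep(NA_real_, 3)
    out_c[k] <<- (M[N, 1L] / V_L) / c0
    out_F[k, ] <<- Fcum
    out_dm[k] <<- sum(solid) - solid0
  }
  maybe_snapshot <- function(w) {
    if (any(abs(protocol$checkpoints - w) < 1e-9)) {
      snaps[[length(snaps) + 1L]] <<-
        layer_snapshot(cake$area, cake$height, N, solid, psds, M,
                       cake$layers, materials, w)
    }
  }

  max_sigma <- 0
  record(1L); maybe_snapshot(0)
  t_now <- 0
  n_steps <- round(protocol$wash_ratio_max / h)
  report_every <- max(1L, round(protocol$wr_step / h))
  k_rep <- 1L
  for (s in seq_len(n_steps)) {
    Q <- wash_flow_rate_now(cake, materials, protocol, conditions, M)
    dt <- h * V_v / Q
    st <- rk4_step(M, Fcum, h)
    M <- st$M; Fcum <- st$Fc
    for (i in seq_len(N)) {
      eq <- equilibrate_layer(M[i, ], solid[i], psds[[i]], kinetics, curve,
                              dt, protocol$equilibrium_tol)
      M[i, ] <- eq$m; solid[i] <- eq$solid; psds[[i]] <- eq$psd
      if (is.finite(eq$sigma)) max_sigma <- max(max_sigma, abs(eq$sigma))
      else max_sigma <- max(max_sigma, Inf)
    }
    t_now <- t_now + dt
    if (s %% report_every == 0L) {
      k_rep <- k_rep + 1L
      record(k_rep)
      out_t[k_rep] <- t_now
      maybe_snapshot(s * h)
    }
  }

  final_layers <- lapply(seq_len(N), function(i) {
    l <- cake$layers[[i]]
    l$solid_mass <- solid[i]
    l$psd <- psds[[i]]
    l$liquid <- liquid_from_vec(M[i, ], l$liquid$temperature)
    V_layer <- cake$area * cake$height / N
    l$porosity <- 1 - (solid[i] / l$rho_s) / V_layer
    l
  })
  list(filtrate_fraction = out_frac, c_over_c0 = out_c, cum_filtrate = out_F,
       solid_dmass = out_dm, time = out_t, snapshots = snaps,
       max_sigma = max_sigma,
       final_cake = new_cake_state(final_layers, cake$area, cake$height,
                                   saturation = cake$saturation))
}

#' Tanks-in-series (CSTR cascade) washing: models 1c-cascade and 2c
#'
#' The cake void volume is a cascade of `n_layers` equal well-mixed holdups:
#' layer 1 receives fresh wash, each layer feeds the next, layer N feeds the
#' filtrate (Levenspiel compartment approximation of axial dispersion). With
#' `kinetics` and a solubility `curve`, every layer independently exchanges
#' solid mass with its liquid at the local supersaturation against the binary
#' solubility curve; k_g is auto-escalated (x10) until the run stays within
#' the equilibrium tolerance, or the algebraic `"instantaneous_flash"` mode
#' equilibrates exactly each step.
#'
#' With `n_layers = 1` and no kinetics this is exactly the perfectly mixed
#' dilution model; as `n_layers` grows the cascade converges to the
#' displacement step at W_r = 1.
#'
#' @param cake A `cake_state` (its `n_layers` sets the cascade depth).
#' @param materials A [material_set()].
#' @param protocol A [wash_protocol()].
#' @param kinetics A [dissolution_kinetics()] or `NULL` (case 1).
#' @param curve A [solubility_curve()] (required with kinetics).
#' @param conditions Optional [operating_conditions()] for constant-pressure
#'   wash hydraulics (sets the physical time axis).
#' @return A `wash_curve`.
#' @export
wash_cstr_cascade <- function(cake, materials, protocol, kinetics = NULL,
                              curve = NULL, conditions = NULL) {
  stopifnot(inherits(cake, "cake_state"), inherits(protocol, "wash_protocol"))
  if (!is.null(kinetics) && is.null(curve))
    stop("case-2 washing needs a solubility curve")
  N <- cake$n_layers
  V_v <- sum(vapply(cake$layers, cake_layer_void, numeric(1)))
  V_L <- V_v / N
  rho_w <- materials$wash_solvent$density
  ml <- colSums(cake_liquid_matrix(cake))
  c0 <- ml[1L] / (V_v * cake$saturation)

  # breakthrough feed: rewet the voids with fresh wash before any outflow
  wr_offset <- 0
  if (cake$saturation < 1 - 1e-9) {
    deficit <- (1 - cake$saturation) * V_L
    for (i in seq_len(N)) {
      l <- cake$layers[[i]]
      m <- unname(l$liquid$mass)
      m[3L] <- m[3L] + deficit * rho_w
      cake$layers[[i]]$liquid <- liquid_from_vec(m, l$liquid$temperature)
    }
    wr_offset <- 1 - cake$saturation
    cake$saturation <- 1
  }

  wr <- seq(0, protocol$wash_ratio_max, by = protocol$wr_step)
  c_in <- c(0, 0, rho_w)

  if (is.null(kinetics)) {
    cs <- cascade_case1(cake, materials, protocol, wr, V_L, c_in, c0)
    frac <- cs$mN / rowSums(cs$mN)
    c_over_c0 <- (cs$mN[, 1L] / V_L) / c0
    sol_last <- cs$sol[nrow(cs$sol), 1 + seq_len(3 * N)]
    Mend <- matrix(sol_last, nrow = N, byrow = TRUE)
    final_layers <- lapply(seq_len(N), function(i) {
      l <- cake$layers[[i]]
      l$liquid <- liquid_from_vec(Mend[i, ], l$liquid$temperature)
      l
    })
    final_cake <- new_cake_state(final_layers, cake$area, cake$height,
                                 saturation = 1)
    snaps <- lapply(protocol$checkpoints, function(w) {
      k <- which.min(abs(wr - w))
      Mk <- matrix(cs$sol[k, 1 + seq_len(3 * N)], nrow = N, byrow = TRUE)
      layer_snapshot(cake$area, cake$height, N,
                     vapply(cake$layers, `[[`, numeric(1), "solid_mass"),
                     lapply(cake$layers, `[[`, "psd"), Mk, cake$layers,
                     materials, wr[k])
    })
    out <- new_wash_curve(model = if (N == 1L) "1b" else "1c",
                          wash_ratio = wr, filtrate_fraction = frac,
                          c_over_c0 = c_over_c0, cum_filtrate = cs$Fcum,
                          solid_dmass = rep(0, length(wr)),
                          fed_wash = cbind(solute = 0,
                                           crystallization_solvent = 0,
                                           wash_solvent =
                                             rho_w * V_v * (wr + wr_offset)),
                          final_cake = final_cake,
                          snapshots = do.call(rbind, snaps),
                          diagnostics = list(max_sigma = NA_real_,
                                             n_layers = N,
                                             wr_offset = wr_offset))
    return(out)
  }

  run_once <- function(kin) {
    cascade_case2(cake, materials, protocol, kin, curve, conditions,
                  wr, V_L, V_v, c_in, c0)
  }
  kin <- kinetics
  n_escal <- 0L
  res <- run_once(kin)
  if (kin$mode == "kinetic") {
    while (res$max_sigma > protocol$equilibrium_tol && n_escal < 6L) {
      n_escal <- n_escal + 1L
      kin$rate_constant <- kin$rate_constant * 10
      res <- run_once(kin)
    }
    if (res$max_sigma > protocol$equilibrium_tol)
      warning(sprintf(
        "equilibrium tolerance violated at final k_g = %.3g: max |sigma| = %.3g",
        kin$rate_constant, res$max_sigma))
  }

  new_wash_curve(model = if (N == 1L) "2b" else "2c",
                 wash_ratio = wr, filtrate_fraction = res$filtrate_fraction,
                 c_over_c0 = res$c_over_c0, cum_filtrate = res$cum_filtrate,
                 solid_dmass = res$solid_dmass,
                 fed_wash = cbind(solute = 0, crystallization_solvent = 0,
                                  wash_solvent =
                                    rho_w * V_v * (wr + wr_offset)),
                 final_cake = res$final_cake,
                 snapshots = do.call(rbind, res$snapshots),
                 diagnostics = list(max_sigma = res$max_sigma,
                                    rate_constant = kin$rate_constant,
                                    escalations = n_escal, n_layers = N,
                                    wr_offset = wr_offset),
                 time = res$time)
}

#' Perfectly mixed dilution washing: models 1b and 2b
#'
#' Treats the entire cake pore liquid as one well-mixed holdup with matched
#' inlet and outlet flows, so the species balances reduce to an exponential
#' washout (c/c0 = exp(-W_r) for an inert solute). A single-layer call into
#' the same engine as [wash_cstr_cascade()]; with `kinetics` and a `curve`
#' this is model 2b, where the holdup exchanges mass with the solid at the
#' local supersaturation. Breakthrough-fed cakes are first rewetted to full
#' saturation before any outflow starts.
#'
#' @inheritParams wash_cstr_cascade
#' @param cake A single-layer `cake_state` (use
#'   [make_initial_wash_cake()] with `n_layers = 1`).
#' @return A `wash_curve`.
#' @export
wash_dilution <- function(cake, materials, protocol, kinetics = NULL,
                          curve = NULL, conditions = NULL) {
  if (cake$n_layers != 1L)
    stop("dilution washing treats the cake as one holdup; build the cake ",
         "with make_initial_wash_cake(n_layers = 1)")
  wash_cstr_cascade(cake, materials, protocol, kinetics, curve, conditions)
}

# ---- model 1c, plug-flow (advection-dispersion PDE) form -----------------

#' Diffusion-dispersion washing as a 1-D advection-dispersion PDE (model 1c)
#'
#' Solves dc/dt = D_L d2c/dz2 - u dc/dz on the cake height by a conservative
#' finite-volume method of lines: Dirichlet wash inlet with no dispersive
#' flux at the top of the cake, zero-gradient outlet, initial condition
#' c = c0 everywhere; the filtrate concentration is read at the medium
#' (z = L). Central differencing of advection, switching automatically to
#' upwinding when the cell Peclet number exceeds 2 (with a notice). The
#' solid is inert (case 1) and the feed must be a dryland cake.
#'
#' @inheritParams wash_cstr_cascade
#' @param n_nodes Number of finite-volume cells (>= 100); default 200.
#' @return A `wash_curve`; `diagnostics$peclet` holds the column Peclet
#'   number u L / D_L.
#' @export
wash_dispersion_pde <- function(cake, materials, protocol, conditions = NULL,
                                n_nodes = 200L) {
  stopifnot(inherits(cake, "cake_state"), n_nodes >= 100L)
  if (abs(cake$saturation - 1) > 1e-9)
    stop("dispersion washing needs a dryland (fully saturated) feed cake")
  N <- n_nodes
  V_v <- sum(vapply(cake$layers, cake_layer_void, numeric(1)))
  eps_bar <- V_v / (cake$area * cake$height)
  M0 <- cake_liquid_matrix(cake)
  ml <- colSums(M0)
  rho_w <- materials$wash_solvent$density

  Q <- wash_flow_rate_now(cake, materials, protocol, conditions, M0)
  u_s <- Q / cake$area
  u <- u_s / eps_bar
  d_p <- sauter_mean(cake$layers[[1L]]$psd, materials$solute$sphericity)
  D_L <- axial_dispersion_coefficient(u_s, d_p,
                                      protocol$molecular_diffusivity,
                                      protocol$dispersion_model)
  Pe <- u * cake$height / D_L
  hz <- 1 / N
  upwind <- (Pe * hz) > 2
  if (upwind)
    message(sprintf(
      "cell Peclet %.3g > 2 at %d nodes: switching advection to upwinding",
      Pe * hz, N))

  # dimensionless unit-step scalar s: s(z,0)=1, inlet s=0, ds/dz(1)=0;
  # finite-volume faces 1..N+1, face 1 = inlet (advective only, the top
  # boundary carries no dispersive flux), face N+1 = zero-gradient outlet
  deriv <- function(wrx, y, parms) {
    s <- y[seq_len(N)]
    adv_int <- if (upwind) s[-N] else (s[-N] + s[-1L]) / 2
    dsp_int <- -(s[-1L] - s[-N]) / (Pe * hz)
    flux <- c(0, adv_int + dsp_int, s[N])
    ds <- (flux[seq_len(N)] - flux[-1L]) / hz
    list(c(ds, s[N]))            # last state: integral of outlet flux
  }
  wr <- seq(0, protocol$wash_ratio_max, by = protocol$wr_step)
  y0 <- c(rep(1, N), 0)
  sol <- deSolve::ode(y = y0, times = wr, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12,
                      jactype = "bandint", bandup = 1, banddown = 1)
  S <- sol[, 1 + seq_len(N), drop = FALSE]
  s_out <- S[, N]
  s_int <- sol[, N + 2L]                # integral of s at outlet over Wr
  s_mean <- rowMeans(S)

  c_over_c0 <- s_out
  cum_filtrate <- cbind(ml[1L] * s_int,
                        ml[2L] * s_int,
                        rho_w * V_v * (wr - s_int))
  inst <- cbind(ml[1L] * s_out, ml[2L] * s_out, rho_w * V_v * (1 - s_out))
  frac <- inst / rowSums(inst)

  s_end_mean <- s_mean[length(wr)]
  n_cake <- cake$n_layers
  # holdup profile averaged onto the cake's layers
  final_layers <- lapply(seq_len(n_cake), function(i) {
    l <- cake$layers[[i]]
    sel <- seq.int(floor((i - 1) * N / n_cake) + 1L, floor(i * N / n_cake))
    s_i <- min(max(mean(S[length(wr), sel]), 0), 1)
    void <- cake_layer_void(l)
    l$liquid <- liquid_state(
      solute = ml[1L] * s_i / n_cake,
      crystallization_solvent = ml[2L] * s_i / n_cake,
      wash_solvent = rho_w * void * (1 - s_i),
      temperature = l$liquid$temperature)
    l
  })
  final_cake <- new_cake_state(final_layers, cake$area, cake$height,
                               saturation = 1)

  new_wash_curve(model = "1c", wash_ratio = wr, filtrate_fraction = frac,
                 c_over_c0 = c_over_c0, cum_filtrate = cum_filtrate,
                 solid_dmass = rep(0, length(wr)),
                 fed_wash = cbind(solute = 0, crystallization_solvent = 0,
                                  wash_solvent = rho_w * V_v * wr),
                 final_cake = final_cake, snapshots = NULL,
                 diagnostics = list(max_sigma = NA_real_, peclet = Pe,
                                    upwind = upwind, n_nodes = N,
                                    dispersion_coefficient = D_L,
                                    superficial_velocity = u_s,
                                    holdup_solute = ml[1L] * s_mean))
}

# ---- bookkeeping ---------------------------------------------------------

#' Species-wise mass balance audit of a completed wash
#'
#' For each species checks
#' initial (solid + cake liquid) + fed wash = final (solid + cake liquid) +
#' cumulative filtrate, and reports the relative residuals.
#'
#' @param curve A `wash_curve`.
#' @param initial_cake The `cake_state` the wash started from.
#' @param materials A [material_set()] (unused for the balance itself; kept
#'   for interface symmetry).
#' @return A data.frame with one row per species and a `residual_rel`
#'   column; attribute `max_residual` carries the largest relative residual.
#' @export
mass_balance_audit <- function(curve, initial_cake, materials = NULL) {
  stopifnot(inherits(curve, "wash_curve"),
            inherits(initial_cake, "cake_state"))
  n <- length(curve$wash_ratio)
  init_liq <- colSums(cake_liquid_matrix(initial_cake))
  init_solid <- c(cake_solid_mass(initial_cake), 0, 0)
  fed <- curve$fed_wash[n, ]
  fin_liq <- colSums(cake_liquid_matrix(curve$final_cake))
  fin_solid <- c(cake_solid_mass(curve$final_cake), 0, 0)
  filt <- curve$cum_filtrate[n, ]
  lhs <- init_liq + init_solid + fed
  rhs <- fin_liq + fin_solid + filt
  res <- (lhs - rhs) / pmax(lhs, 1e-30)
  out <- data.frame(species = species_names,
                    initial = unname(init_liq + init_solid),
                    fed_wash = unname(fed),
                    final = unname(fin_liq + fin_solid),
                    filtrate = unname(filt),
                    residual_rel = unname(res))
  attr(out, "max_residual") <- max(abs(res))
  out
}
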