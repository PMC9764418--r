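#' Solvent specification
#'
#' Pure-component solvent properties at the (isothermal) run temperature.
#'
#' @param name Solvent name.
#' @param density Density, kg m^-3. Must be positive.
#' @param viscosity Dynamic viscosity, Pa s. Must be positive.
#' @param role One of `"crystallization"` or `"wash"`.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(name, density, viscosity,
                         role = c("crystallization", "wash")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("solvent density must be a single positive number (kg m^-3)")
  if (!is.numeric(viscosity) || length(viscosity) != 1L || viscosity <= 0)
    stop("solvent viscosity must be a single positive number (Pa s)")
  structure(list(name = name, density = density, viscosity = viscosity,
                 role = role),
            class = "solvent_spec")
}

#' Solute (crystal) specification
#'
#' @param name Solute name.
#' @param crystal_density Crystal density, kg m^-3.
#' @param sphericity Particle sphericity in (0, 1]; scales the Sauter mean
#'   diameter used by the Carman-Kozeny resistance and the specific surface
#'   area used for dissolution.
#' @return An object of class `solute_spec`.
#' @export
solute_spec <- function(name, crystal_density, sphericity = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(crystal_density) || crystal_density <= 0)
    stop("crystal_density must be positive (kg m^-3)")
  if (!is.numeric(sphericity) || sphericity <= 0 || sphericity > 1)
    stop("sphericity must lie in (0, 1]")
  structure(list(name = name, crystal_density = crystal_density,
                 sphericity = sphericity),
            class = "solute_spec")
}

#' Bundle of the materials present in one isolation run
#'
#' @param solute A [solute_spec()].
#' @param crystallization_solvent,wash_solvent [solvent_spec()] objects.
#' @return An object of class `material_set`.
#' @export
material_set <- function(solute, crystallization_solvent, wash_solvent) {
  stopifnot(inherits(solute, "solute_spec"),
            inherits(crystallization_solvent, "solvent_spec"),
            inherits(wash_solvent, "solvent_spec"))
  structure(list(solute = solute,
                 crystallization_solvent = crystallization_solvent,
                 wash_solvent = wash_solvent),
            class = "material_set")
}

#' Liquid-phase state
#'
#' Species masses of a liquid holdup. The three species are the dissolved
#' solute, the crystallization solvent, and the wash solvent.
#'
#' @param solute,crystallization_solvent,wash_solvent Species masses, kg
#'   (all non-negative).
#' @param temperature Temperature, degrees C (carried, kinetics are
#'   isothermal).
#' @return An object of class `liquid_state`.
#' @export
liquid_state <- function(solute = 0, crystallization_solvent = 0,
                         wash_solvent = 0, temperature = 25) {
  m <- c(solute = solute, crystallization_solvent = crystallization_solvent,
         wash_solvent = wash_solvent)
  if (any(!is.finite(m)) || any(m < 0))
    stop("all species masses must be finite and >= 0")
  structure(list(mass = m, temperature = temperature),
            class = "liquid_state")
}

#' @export
print.liquid_state <- function(x, ...) {
  tot <- sum(x$mass)
  cat(sprintf("<liquid_state> total %.6g kg at %.4g degC\n", tot,
              x$temperature))
  if (tot > 0) {
    fr <- x$mass / tot
    cat(sprintf("  %s: %.6g kg (w = %.4f)\n", names(x$mass), x$mass, fr),
        sep = "")
  }
  invisible(x)
}

#' Species mass fractions of a liquid state
#'
#' @param liquid A [liquid_state()].
#' @return Named numeric vector of mass fractions summing to 1.
#' @export
mass_fractions <- function(liquid) {
  tot <- sum(liquid$mass)
  if (tot <= 0) stop("degenerate liquid state: zero total mass")
  liquid$mass / tot
}

#' Wash-solvent mass fraction of the solute-free solvent mixture
#'
#' @param liquid A [liquid_state()].
#' @return Fraction in \[0, 1\].
#' @export
wash_solvent_fraction <- function(liquid) {
  solv <- liquid$mass[["crystallization_solvent"]] +
    liquid$mass[["wash_solvent"]]
  if (solv <= 0) stop("degenerate liquid state: zero solvent mass")
  liquid$mass[["wash_solvent"]] / solv
}

#' Ideal mixture density of a liquid state
#'
#' Mass-weighted inverse-specific-volume (ideal volume-additive) blend of the
#' pure-component densities. Dissolved solute contributes at its crystal
#' density. The result is bounded by the smallest and largest component
#' density present.
#'
#' @param liquid A [liquid_state()].
#' @param materials A [material_set()].
#' @return Density, kg m^-3.
#' @export
mixture_density <- function(liquid, materials) {
  tot <- sum(liquid$mass)
  if (tot <= 0) stop("degenerate liquid state: zero total mass")
  rho <- c(materials$solute$crystal_density,
           materials$crystallization_solvent$density,
           materials$wash_solvent$density)
  tot / sum(liquid$mass / rho)
}

#' Mixture viscosity of a liquid state
#'
#' Log-linear (Arrhenius-type) blend of the two solvent viscosities on a
#' solute-free mass-fraction basis; the dissolved solute is not counted.
#' Bounded by the two component viscosities.
#'
#' @inheritParams mixture_density
#' @return Dynamic viscosity, Pa s.
#' @export
mixture_viscosity <- function(liquid, materials) {
  if (sum(liquid$mass) <= 0) stop("degenerate liquid state: zero total mass")
  w <- wash_solvent_fraction(liquid)
  exp((1 - w) * log(materials$crystallization_solvent$viscosity) +
        w * log(materials$wash_solvent$viscosity))
}

infer_curve_shape <- function(csat) {
  d <- diff(csat)
  rng <- diff(range(csat))
  if (rng <= 1e-12 * max(csat, 1e-300)) return("flat")
  tol <- 1e-12 * max(abs(csat))
  if (all(d <= tol)) return("monotone_decreasing")
  if (all(d >= -tol)) return("monotone_increasing")
  imax <- which.max(csat)
  if (imax > 1L && imax < length(csat) &&
      all(d[seq_len(imax - 1L)] >= -tol) && all(d[imax:length(d)] <= tol))
    return("maximum")
  stop("solubility curve is neither monotone, flat, nor single-maximum")
}

#' Binary-solvent solubility curve
#'
#' Saturation solubility of the solute, in g solute per g of solute-free
#' solvent mixture, as a function of the wash-solvent mass fraction of that
#' mixture. This is the binary plot that drives all case-2 dissolution and
#' antisolvent-deposition behaviour.
#'
#' @param w_grid Wash-solvent mass fractions, strictly ascending with
#'   endpoints 0 and 1.
#' @param csat_grid Saturation solubilities, g/g, all >= 0.
#' @param shape_tag Optional: one of `"maximum"`, `"monotone_decreasing"`,
#'   `"monotone_increasing"`, `"flat"`. Verified against the data; inferred
#'   when omitted.
#' @return An object of class `solubility_curve`.
#' @export
solubility_curve <- function(w_grid, csat_grid, shape_tag = NULL) {
  stopifnot(is.numeric(w_grid), is.numeric(csat_grid),
            length(w_grid) == length(csat_grid), length(w_grid) >= 2L)
  if (any(diff(w_grid) <= 0)) stop("w_grid must be strictly ascending")
  if (abs(w_grid[1L]) > 1e-12 || abs(w_grid[length(w_grid)] - 1) > 1e-12)
    stop("w_grid must span [0, 1] with endpoints 0 and 1")
  if (any(csat_grid < 0)) stop("csat_grid must be >= 0")
  inferred <- infer_curve_shape(csat_grid)
  if (!is.null(shape_tag)) {
    shape_tag <- match.arg(shape_tag, c("maximum", "monotone_decreasing",
                                        "monotone_increasing", "flat"))
    if (shape_tag != inferred)
      stop(sprintf("shape_tag '%s' inconsistent with data (inferred '%s')",
                   shape_tag, inferred))
  }
  structure(list(w_grid = as.numeric(w_grid),
                 csat_grid = as.numeric(csat_grid),
                 shape_tag = inferred),
            class = "solubility_curve")
}

#' @export
print.solubility_curve <- function(x, ...) {
  cat(sprintf("<solubility_curve> %d nodes, shape '%s', csat(0) = %.4g, csat(1) = %.4g g/g\n",
              length(x$w_grid), x$shape_tag, x$csat_grid[1L],
              x$csat_grid[length(x$csat_grid)]))
  invisible(x)
}

#' Saturation-solubility lookup
#'
#' Piecewise-linear interpolation of the binary solubility curve; exact at
#' grid nodes, no extrapolation outside \[0, 1\].
#'
#' @param curve A [solubility_curve()].
#' @param w_wash Wash-solvent mass fraction(s) of the solvent mixture, in
#'   \[0, 1\].
#' @return Saturation solubility(ies), g solute per g solvent mixture.
#' @export
csat_lookup <- function(curve, w_wash) {
  stopifnot(inherits(curve, "solubility_curve"))
  if (any(w_wash < -1e-12 | w_wash > 1 + 1e-12))
    stop("w_wash outside [0, 1]: no extrapolation of the solubility curve")
  w_wash <- pmin(pmax(w_wash, 0), 1)
  approx(curve$w_grid, curve$csat_grid, xout = w_wash, method = "linear",
         rule = 1)$y
}

#' Relative supersaturation of a liquid against the binary solubility curve
#'
#' Returns sigma = c/c_sat - 1 where c is the solute concentration on a
#' g-per-g-solvent-mixture basis and c_sat comes from [csat_lookup()] at the
#' liquid's wash-solvent fraction. Positive sigma drives deposition, negative
#' sigma drives dissolution. sigma is intensive: scaling all masses by a
#' positive factor leaves it unchanged.
#'
#' @param liquid A [liquid_state()].
#' @param curve A [solubility_curve()].
#' @return Dimensionless supersaturation; `Inf` when the liquid carries solute
#'   but the local saturation solubility is zero.
#' @export
supersaturation <- function(liquid, curve) {
  solv <- liquid$mass[["crystallization_solvent"]] +
    liquid$mass[["wash_solvent"]]
  if (solv <= 0) stop("degenerate liquid state: zero solvent mass")
  c_j <- liquid$mass[["solute"]] / solv
  c_sat <- csat_lookup(curve, wash_solvent_fraction(liquid))
  if (c_sat == 0) {
    if (c_j > 0) return(Inf)
    return(-1)
  }
  c_j / c_sat - 1
}

#' Read / write a solubility curve as a two-column CSV
#'
#' File format: header `w_wash,csat_g_per_g`, dot decimal separator, UTF-8.
#'
#' @param path File path.
#' @return `read_solubility_curve()` returns a [solubility_curve()];
#'   `write_solubility_curve()` returns `path` invisibly.
#' @export
read_solubility_curve <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("w_wash", "csat_g_per_g") %in% names(d)))
    stop("solubility curve file needs columns 'w_wash' and 'csat_g_per_g'")
  solubility_curve(d$w_wash, d$csat_g_per_g)
}

#' @rdname read_solubility_curve
#' @param curve A [solubility_curve()].
#' @export
write_solubility_curve <- function(curve, path) {
  write.csv(data.frame(w_wash = curve$w_grid,
                       csat_g_per_g = curve$csat_grid),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a material property table
#'
#' CSV with columns `name,density_kg_m3,viscosity_Pa_s,role`.
#'
#' @param path File path.
#' @return A list of [solvent_spec()] objects keyed by name.
#' @export
read_solvent_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "density_kg_m3", "viscosity_Pa_s", "role")
  if (!all(need %in% names(d)))
    stop("solvent table needs columns ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(d)), function(i)
    solvent_spec(d$name[i], d$density_kg_m3[i], d$viscosity_Pa_s[i],
                 d$role[i]))
  names(out) <- d$name
  out
}
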