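# shared fixtures, memoized across test files (heavy washing runs are reused)

.cw_cache <- new.env(parent = emptyenv())

cw_memo <- function(key, expr) {
  if (!exists(key, envir = .cw_cache))
    assign(key, expr, envir = .cw_cache)
  get(key, envir = .cw_cache)
}

cw_fixture <- function(kind)
  cw_memo(paste0("fx_", kind), generate_fixture(kind))

cw_filtration <- function(kind) {
  fx <- cw_fixture(kind)
  cw_memo(paste0("filt_", kind),
          constant_pressure_filtration(fx$suspension, fx$conditions,
                                       fx$materials))
}

cw_cake <- function(kind, n_layers = 1L)
  make_initial_wash_cake(cw_filtration(kind), n_layers)

cw_wash <- function(key, expr) cw_memo(paste0("wash_", key), expr)

# small controlled system with round-number properties for analytic checks
cw_simple_materials <- function()
  material_set(solute_spec("crystal", 1200, 1),
               solvent_spec("liqA", 800, 1e-3, "crystallization"),
               solvent_spec("liqB", 1000, 2e-3, "wash"))

cw_simple_case <- function() {
  cw_memo("simple_case", {
    mats <- cw_simple_materials()
    p <- psd(c(50e-6, 150e-6), 0.01)   # single-bin, midpoint 100 um
    liq <- liquid_state(solute = 0.001, crystallization_solvent = 0.02)
    susp <- suspension_state(0.01, p, liq, 0.5)
    cond <- operating_conditions(5e4, 0.02, 1e9)
    filt <- constant_pressure_filtration(susp, cond, mats)
    list(materials = mats, suspension = susp, conditions = cond,
         filtration = filt, cake = make_initial_wash_cake(filt, 1L))
  })
}

erfc <- function(x) 2 * pnorm(-x * sqrt(2))

flash_kinetics <- function() dissolution_kinetics(mode = "instantaneous_flash")
kinetic_kinetics <- function(k = 1e-2) dissolution_kinetics(k, 1, "kinetic")
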