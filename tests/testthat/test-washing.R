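test_that("wash ratio definitions behave", {
  expect_equal(wash_ratio(2e-6, 2e-6), 1)
  expect_equal(wash_ratio(0, 2e-6), 0)
  expect_equal(wash_ratio(4e-6, 2e-6), 2)
  expect_error(wash_ratio(1e-6, 0), "degenerate")
  expect_equal(wr_from_time(10, 1e-4, 0.01, 0.5), 1e-3 / (0.5 * 0.01))
})

test_that("displacement washing is the piecewise mother-liquor/wash step", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  w <- wash_displacement(cake, fx$materials, fx$protocol)
  pre <- w$wash_ratio < 1
  expect_true(all(abs(w$filtrate_fraction[pre, 1] - 0.12) < 1e-12))
  expect_true(all(w$filtrate_fraction[!pre, 1] == 0))
  expect_equal(w$wash_ratio[which(w$filtrate_fraction[, 1] == 0)[1]], 1)
  expect_true(all(w$solid_dmass == 0))
  expect_lt(attr(mass_balance_audit(w, cake), "max_residual"), 1e-10)
  # a breakthrough-fed cake is rejected
  sc <- cw_simple_case()
  cond_b <- operating_conditions(5e4, 0.02, 1e9,
                                 endpoint_mode = "breakthrough")
  fb <- constant_pressure_filtration(sc$suspension, cond_b, sc$materials)
  expect_error(wash_displacement(make_initial_wash_cake(fb, 1L),
                                 sc$materials, fx$protocol), "dryland")
})

test_that("displacement with a zero-solubility wash reduces to model 1a", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  zero <- solubility_curve(c(0, 1), c(0.12 / 0.88, 0))
  w1 <- wash_displacement(cake, fx$materials, fx$protocol)
  w2 <- wash_displacement(cake, fx$materials, fx$protocol, curve = zero,
                          dissolve = TRUE)
  expect_equal(w2$c_over_c0, w1$c_over_c0)
  expect_equal(w2$solid_dmass, w1$solid_dmass)
  expect_equal(w2$cum_filtrate, w1$cum_filtrate)
})

test_that("displacement with dissolution leaves saturated wash filtrate", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  w <- wash_displacement(cake, fx$materials, fx$protocol, curve = fx$curve,
                         dissolve = TRUE)
  csat1 <- csat_lookup(fx$curve, 1)
  n <- length(w$wash_ratio)
  # filtrate past one void volume is wash saturated at csat(1)
  expect_equal(unname(w$filtrate_fraction[n, 1]), csat1 / (1 + csat1),
               tolerance = 1e-12)
  # dissolution linear in the wash fed; solid loss negative
  V_v <- cw_filtration("pcm_water")$result$void_volume
  expect_equal(w$solid_dmass[n], -csat1 * 997 * V_v * 2, tolerance = 1e-12)
  expect_lt(attr(mass_balance_audit(w, cake), "max_residual"), 1e-10)
  # the solid PSD shrank homogeneously
  d50_0 <- quantile(cake$layers[[1]]$psd, 0.5)
  expect_lt(quantile(w$final_cake$layers[[1]]$psd, 0.5), d50_0)
})

test_that("dilution washing matches the exponential washout closed form", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  w <- cw_wash("1b_water",
               wash_dilution(cake, fx$materials, fx$protocol,
                             conditions = fx$conditions))
  expect_lt(max(abs(w$c_over_c0 - exp(-w$wash_ratio))), 1e-8)
  # W_r = 0 filtrate is the mother liquor
  expect_equal(unname(w$filtrate_fraction[1, ]), c(0.12, 0.88, 0),
               tolerance = 1e-9)
  # removal is incomplete at two cake volumes
  expect_equal(w$c_over_c0[w$wash_ratio == 2], exp(-2), tolerance = 1e-8)
  expect_gt(w$c_over_c0[w$wash_ratio == 2], 0.01)
  expect_lt(attr(mass_balance_audit(w, cake), "max_residual"), 1e-8)
  # multi-layer cakes are rejected: the holdup must be single
  expect_error(wash_dilution(cw_cake("pcm_water", 10L), fx$materials,
                             fx$protocol), "one holdup")
})

test_that("a single-tank cascade is identical to dilution washing", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  wd <- cw_wash("1b_water",
                wash_dilution(cake, fx$materials, fx$protocol,
                              conditions = fx$conditions))
  wc <- wash_cstr_cascade(cake, fx$materials, fx$protocol,
                          conditions = fx$conditions)
  expect_equal(wc$c_over_c0, wd$c_over_c0, tolerance = 1e-10)
  expect_equal(wc$cum_filtrate, wd$cum_filtrate, tolerance = 1e-10)
})

test_that("the cascade converges to the displacement step as N grows", {
  fx <- cw_fixture("pcm_water")
  step <- function(wr) ifelse(wr < 1, 1, 0)
  l1 <- vapply(c(5L, 20L, 80L), function(N) {
    w <- wash_cstr_cascade(cw_cake("pcm_water", N), fx$materials,
                           fx$protocol, conditions = fx$conditions)
    mean(abs(w$c_over_c0 - step(w$wash_ratio)))
  }, numeric(1))
  expect_true(all(diff(l1) < 0))        # L1 distance decreasing in N
  wbig <- wash_cstr_cascade(cw_cake("pcm_water", 200L), fx$materials,
                            fx$protocol, conditions = fx$conditions)
  # pointwise convergence away from the jump
  expect_gt(wbig$c_over_c0[wbig$wash_ratio == 0.5], 0.999)
  expect_lt(wbig$c_over_c0[wbig$wash_ratio == 1.5], 1e-3)
})

test_that("the ten-tank cascade shows the three washing stages", {
  fx <- cw_fixture("pcm_water")
  w <- cw_wash("1c_cascade10",
               wash_cstr_cascade(cw_cake("pcm_water", 10L), fx$materials,
                                 fx$protocol, conditions = fx$conditions))
  cc <- w$c_over_c0; wr <- w$wash_ratio
  # constant-rate plateau, steep intermediate fall, long diffusive tail
  expect_gt(cc[wr == 0.5], 0.95)
  expect_true(cc[wr == 1.0] > 0.2 && cc[wr == 1.0] < 0.8)
  expect_true(cc[wr == 1.5] > 1e-4 && cc[wr == 1.5] < 0.2)
  expect_true(all(diff(cc) <= 1e-12))   # non-increasing wash curve
})

test_that("the dispersion PDE matches the erfc breakthrough closed form", {
  sc <- cw_simple_case()
  cake <- sc$cake
  r <- sc$filtration$result
  eps <- 0.5
  Q <- 1e-8
  u <- Q / (r$area * eps)
  Pe_target <- 200
  D <- u * r$cake_height / Pe_target
  prot <- wash_protocol(wash_ratio_max = 2, flow_mode = "constant_flow",
                        wash_flow_rate = Q, molecular_diffusivity = D)
  w <- wash_dispersion_pde(cake, sc$materials, prot, n_nodes = 400L)
  Pe <- w$diagnostics$peclet
  expect_equal(Pe, Pe_target, tolerance = 1e-9)
  tau <- w$wash_ratio[-1]
  # two-term constant-coefficient step-inlet solution at the outlet
  arg1 <- (1 - tau) / (2 * sqrt(tau / Pe))
  arg2 <- (1 + tau) / (2 * sqrt(tau / Pe))
  t2 <- 0.5 * exp(Pe - arg2^2) / (arg2 * sqrt(pi))   # asymptotic, Pe large
  s_exact <- 1 - (0.5 * erfc(arg1) + t2)
  expect_lt(max(abs(w$c_over_c0[-1] - s_exact)), 1e-3)
})

test_that("the dispersion PDE conserves solute at every output step", {
  sc <- cw_simple_case()
  prot <- wash_protocol(wash_ratio_max = 2, flow_mode = "constant_flow",
                        wash_flow_rate = 1e-8, molecular_diffusivity = 2e-9)
  w <- wash_dispersion_pde(sc$cake, sc$materials, prot, n_nodes = 200L)
  m0 <- sum(cakewash:::cake_liquid_matrix(sc$cake))
  sol0 <- cakewash:::cake_liquid_matrix(sc$cake)[1, 1]
  resid <- abs(w$diagnostics$holdup_solute + w$cum_filtrate[, 1] - sol0) /
    sol0
  expect_lt(max(resid), 1e-8)
  expect_lt(attr(mass_balance_audit(w, sc$cake), "max_residual"), 1e-8)
})

test_that("vanishing dispersion recovers the displacement step", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  # the fixed 1e-9 m2/s diffusivity at the benchmark flow is advection-
  # dominated: expect upwinding and a near-step breakthrough at W_r = 1
  expect_message(
    w <- wash_dispersion_pde(cake, fx$materials, fx$protocol,
                             conditions = fx$conditions, n_nodes = 400L),
    "upwind")
  cc <- w$c_over_c0; wr <- w$wash_ratio
  expect_gt(cc[wr == 0.5], 0.98)
  expect_lt(cc[wr == 1.5], 0.02)
  expect_gt(cc[wr == 0.9], 0.5)
  expect_lt(cc[wr == 1.1], 0.5)
})

test_that("Nernst-Brunner rate is zero at saturation and linear in area", {
  mats <- cw_simple_materials()
  cur <- solubility_curve(c(0, 1), c(0.10, 0.02))
  p <- psd(c(90e-6, 110e-6), 1e-3)
  sat <- liquid_state(0.10, 1, 0)
  expect_equal(nernst_brunner_rate(sat, p, cur, 1e-9, 10e-6, 1e-3, mats), 0,
               tolerance = 1e-15)
  under <- liquid_state(0.05, 1, 0)
  r1 <- nernst_brunner_rate(under, p, cur, 1e-9, 10e-6, 1e-3, mats)
  expect_gt(r1, 0)                       # dissolution-driving
  # doubling the solid mass doubles the surface area and the rate
  r2 <- nernst_brunner_rate(under, p, cur, 1e-9, 10e-6, 2e-3, mats)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  # hand evaluation
  A_tot <- specific_surface_area(p, 1, 1200) * 1e-3
  V_liq <- 0.05 / 1200 + 1 / 800
  hand <- (1e-9 / 10e-6) * A_tot * (0.10 * 1 / V_liq - 0.05 / V_liq)
  expect_equal(r1, hand, tolerance = 1e-12)
})

test_that("axial dispersion coefficient modes", {
  expect_equal(axial_dispersion_coefficient(0, 50e-6, 1e-9, "correlation"),
               1e-9)
  expect_equal(axial_dispersion_coefficient(1e-4, 50e-6, 1e-9, "fixed_D"),
               1e-9)
  u <- c(1e-5, 1e-4, 1e-3)
  DL <- axial_dispersion_coefficient(u, 50e-6, 1e-9, "correlation")
  expect_true(all(diff(DL) > 0))
  expect_equal(DL[2], 1e-9 + 0.5 * 1e-4 * 50e-6)
})

test_that("case-2 dilution stays at equilibrium and loses mass on a maximum-type curve", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  wf <- cw_wash("2b_water_flash",
                wash_dilution(cake, fx$materials, fx$protocol,
                              kinetics = flash_kinetics(), curve = fx$curve,
                              conditions = fx$conditions))
  expect_lt(wf$diagnostics$max_sigma, 1e-3)
  n <- length(wf$wash_ratio)
  expect_lt(wf$solid_dmass[n], 0)                    # net dissolution
  ipeak <- which.min(wf$solid_dmass)
  expect_lt(wf$wash_ratio[ipeak], 1)                 # interior peak
  expect_gt(wf$wash_ratio[ipeak], 0.2)
  expect_gt(-min(wf$solid_dmass), -wf$solid_dmass[n]) # partial redeposition
  expect_lt(attr(mass_balance_audit(wf, cake), "max_residual"), 1e-8)
})

test_that("kinetic relaxation agrees with the instantaneous flash oracle", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  wf <- cw_wash("2b_water_flash",
                wash_dilution(cake, fx$materials, fx$protocol,
                              kinetics = flash_kinetics(), curve = fx$curve,
                              conditions = fx$conditions))
  wk <- cw_wash("2b_water_kinetic",
                wash_dilution(cake, fx$materials, fx$protocol,
                              kinetics = kinetic_kinetics(), curve = fx$curve,
                              conditions = fx$conditions))
  expect_lt(wk$diagnostics$max_sigma, 1e-3)
  n <- length(wf$wash_ratio)
  expect_lt(abs(wk$solid_dmass[n] - wf$solid_dmass[n]) /
              abs(wf$solid_dmass[n]), 0.01)
})

test_that("a monotone-decreasing curve drives antisolvent deposition", {
  fh <- cw_fixture("pcm_heptane")
  cakeh <- cw_cake("pcm_heptane", 1L)
  w <- cw_wash("2b_heptane_flash",
               wash_dilution(cakeh, fh$materials, fh$protocol,
                             kinetics = flash_kinetics(), curve = fh$curve,
                             conditions = fh$conditions))
  n <- length(w$wash_ratio)
  expect_gt(w$solid_dmass[n], 0)                     # net deposition
  # deposition concentrated before one void volume
  expect_gt(w$solid_dmass[w$wash_ratio == 1], 0.8 * max(w$solid_dmass))
  expect_lt(w$diagnostics$max_sigma, 1e-3)
  expect_lt(attr(mass_balance_audit(w, cakeh), "max_residual"), 1e-8)
})

test_that("layered case-2 washing raises D50 most in the upper layers", {
  fx <- cw_fixture("pcm_water")
  cakeN <- cw_cake("pcm_water", 10L)
  w <- cw_wash("2c_water_flash",
               wash_cstr_cascade(cakeN, fx$materials, fx$protocol,
                                 kinetics = flash_kinetics(),
                                 curve = fx$curve,
                                 conditions = fx$conditions))
  expect_lt(w$diagnostics$max_sigma, 1e-3)
  expect_lt(attr(mass_balance_audit(w, cakeN), "max_residual"), 1e-8)
  snap <- w$snapshots
  s0 <- snap[snap$wash_ratio == 0, ]
  s2 <- snap[abs(snap$wash_ratio - 2) < 1e-9, ]
  dd50 <- s2$D50 - s0$D50
  expect_true(all(dd50 > 0))                 # larger in all layers
  expect_gt(mean(dd50[1:5]), mean(dd50[6:10]))  # most in layers 1-5
  # porosity rises where solid mass fell (inverse coupling)
  dpor <- s2$porosity - s0$porosity
  expect_true(all(dpor > 0))
  dsolid <- vapply(seq_len(10), function(i)
    w$final_cake$layers[[i]]$solid_mass - cakeN$layers[[i]]$solid_mass,
    numeric(1))
  expect_true(all(sign(dpor) == -sign(dsolid)))
})

test_that("breakthrough-fed dilution rewets the cake before outflow", {
  sc <- cw_simple_case()
  cond_b <- operating_conditions(5e4, 0.02, 1e9,
                                 endpoint_mode = "breakthrough")
  fb <- constant_pressure_filtration(sc$suspension, cond_b, sc$materials)
  cakeb <- make_initial_wash_cake(fb, 1L)
  prot <- wash_protocol(wash_ratio_max = 1, flow_mode = "constant_flow",
                        wash_flow_rate = 1e-8)
  w <- wash_dilution(cakeb, sc$materials, prot)
  # the rewetting charge appears in the fed wash beyond the wash ratio
  expect_equal(w$diagnostics$wr_offset, 0.9, tolerance = 1e-9)
  expect_lt(attr(mass_balance_audit(w, cakeb), "max_residual"), 1e-8)
  # the holdup starts diluted by the rewetting charge
  expect_lt(w$c_over_c0[1], 0.2)
})

test_that("case-1 audits close exactly (no solid exchange)", {
  fx <- cw_fixture("pcm_water")
  cake <- cw_cake("pcm_water", 1L)
  for (w in list(cw_wash("1b_water",
                         wash_dilution(cake, fx$materials, fx$protocol,
                                       conditions = fx$conditions)),
                 wash_displacement(cake, fx$materials, fx$protocol))) {
    aud <- mass_balance_audit(w, cake)
    expect_equal(cakewash:::cake_solid_mass(w$final_cake),
                 cakewash:::cake_solid_mass(cake))
    expect_lt(attr(aud, "max_residual"), 1e-10)
  }
})
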