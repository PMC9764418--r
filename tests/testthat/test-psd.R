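test_that("lognormal fit hits the requested number-weighted moments", {
  p <- fit_lognormal_psd(77e-6, 174e-6, n_bins = 80L)
  mid <- (p$edges[-1] + p$edges[-length(p$edges)]) / 2
  n <- p$mass / mid^3
  n <- n / sum(n)
  mean_r <- sum(n * mid)
  std_r <- sqrt(sum(n * (mid - mean_r)^2))
  expect_lt(abs(mean_r / 77e-6 - 1), 0.02)
  expect_lt(abs(std_r / 174e-6 - 1), 0.02)
  expect_equal(sum(p$mass), 1)
})

test_that("lognormal fit hits the requested volume median in mass weighting", {
  p <- fit_lognormal_psd(77e-6, 174e-6, weighting = "mass",
                         total_mass = 5.895e-3)
  expect_lt(abs(quantile(p, 0.5) / 77e-6 - 1), 0.02)
  expect_equal(sum(p$mass), 5.895e-3)
})

test_that("vanishing std concentrates all mass in the bin holding the mean", {
  p <- fit_lognormal_psd(77e-6, 1e-7, n_bins = 80L)
  i <- which(p$mass > 0)
  expect_length(i, 1L)
  expect_lte(p$edges[i], 77e-6)
  expect_gte(p$edges[i + 1L], 77e-6)
})

test_that("discretized moments agree with dense quadrature at 500 bins", {
  # a lognormal comfortably inside the grid, so truncation is negligible
  mu <- log(77e-6); sd <- 0.45
  dg <- exp(seq(log(0.1e-6), log(1000e-6), length.out = 20001))
  fg <- diff(plnorm(dg, mu, sd))
  mg <- (dg[-1] + dg[-length(dg)]) / 2
  fg <- fg / sum(fg)
  mean_q <- sum(fg * mg)
  std_q <- sqrt(sum(fg * (mg - mean_q)^2))

  p <- fit_lognormal_psd(mean_q, std_q, n_bins = 500L)
  mid <- (p$edges[-1] + p$edges[-length(p$edges)]) / 2
  n <- p$mass / mid^3; n <- n / sum(n)
  mean_r <- sum(n * mid)
  std_r <- sqrt(sum(n * (mid - mean_r)^2))
  expect_lt(abs(mean_r / mean_q - 1), 1e-3)
  expect_lt(abs(std_r / std_q - 1), 1e-3)
  # third moment (mass mean) against quadrature
  m3_q <- sum(fg * mg^3 * mg) / sum(fg * mg^3)
  m3_r <- sum(p$mass * mid) / sum(p$mass)
  expect_lt(abs(m3_r / m3_q - 1), 1e-3)
})

test_that("mass-weighted quantiles interpolate and are monotone", {
  # single-bin PSD: quantile stays inside the bin for all p
  p1 <- psd(c(10e-6, 20e-6), 1)
  for (q in c(0.1, 0.5, 0.9)) {
    expect_gte(quantile(p1, q), 10e-6)
    expect_lte(quantile(p1, q), 20e-6)
  }
  # symmetric two-bin PSD: median at the shared edge
  p2 <- psd(c(10e-6, 20e-6, 30e-6), c(0.5, 0.5))
  expect_equal(quantile(p2, 0.5), 20e-6)
  # monotone in p, D10 <= D50 <= D90
  set.seed(42)
  for (i in 1:10) {
    edges <- sort(runif(21, 1e-6, 500e-6))
    p <- psd(edges, runif(20))
    q <- quantile(p, c(0.1, 0.5, 0.9))
    expect_true(all(diff(q) >= 0))
    # refined-grid oracle: cumulative scan on a 10x finer grid
    fine_edges <- unlist(lapply(seq_len(20), function(j)
      seq(edges[j], edges[j + 1], length.out = 11)[-11]))
    fine_edges <- c(fine_edges, edges[21])
    fine_mass <- rep(p$mass / 10, each = 10)
    cum <- cumsum(fine_mass) / sum(fine_mass)
    fine_width <- diff(fine_edges)
    for (k in 1:3) {
      j <- which(cum >= c(0.1, 0.5, 0.9)[k])[1]
      # brute-force scan lands within one fine-bin width of the quantile
      expect_lt(abs(q[k] - fine_edges[j + 1]), fine_width[j] + 1e-12)
    }
  }
})

test_that("Sauter mean is the sphericity-scaled harmonic mass mean", {
  p <- psd(c(90e-6, 110e-6), 1)     # midpoint 100 um
  expect_equal(sauter_mean(p, 1), 100e-6)
  expect_equal(sauter_mean(p, 0.5), 50e-6)
  # bimodal hand evaluation
  pb <- psd(c(10e-6, 30e-6, 90e-6, 110e-6), c(0.3, 0, 0.7))
  hand <- (0.3 + 0.7) / (0.3 / 20e-6 + 0.7 / 100e-6)
  expect_equal(sauter_mean(pb, 1), hand, tolerance = 1e-12)
  expect_error(sauter_mean(psd(c(1e-6, 2e-6), 0), 1), "degenerate")
})

test_that("specific surface area follows the sphere formula and scaling", {
  p <- psd(c(90e-6, 110e-6), 1)
  expect_equal(specific_surface_area(p, 1, 1200), 6 / (1200 * 100e-6))
  half <- psd(c(45e-6, 55e-6), 1)
  expect_equal(specific_surface_area(half, 1, 1200),
               2 * specific_surface_area(p, 1, 1200))
  pb <- psd(c(10e-6, 30e-6, 90e-6, 110e-6), c(0.3, 0.1, 0.6))
  hand <- sum(6 * c(0.3, 0.1, 0.6) /
                (1200 * c(20e-6, 60e-6, 100e-6) * 0.5)) / 1
  expect_equal(specific_surface_area(pb, 0.5, 1200), hand,
               tolerance = 1e-12)
})

test_that("uniform dissolution is shape-preserving and mass-exact", {
  p <- fit_lognormal_psd(77e-6, 30e-6, total_mass = 5.895e-3)
  d50 <- quantile(p, 0.5)
  # zero dissolution leaves the PSD and its D50 untouched
  expect_equal(uniform_dissolve(p, 0), p)
  expect_equal(quantile(uniform_dissolve(p, 0), 0.5), d50)
  # 7/8 of the mass gone halves every diameter
  ph <- uniform_dissolve(p, 7 / 8 * sum(p$mass))
  expect_equal(ph$edges, p$edges / 2, tolerance = 1e-12)
  expect_equal(quantile(ph, 0.5), d50 / 2, tolerance = 1e-12)
  # mass balance and preserved bin ratios on random feasible masses
  set.seed(7)
  for (i in 1:10) {
    dm <- runif(1) * sum(p$mass)
    pu <- uniform_dissolve(p, dm)
    expect_equal(sum(pu$mass), sum(p$mass) - dm, tolerance = 1e-12)
    keep <- p$mass > 0
    expect_equal(pu$mass[keep] / p$mass[keep],
                 rep((sum(p$mass) - dm) / sum(p$mass), sum(keep)),
                 tolerance = 1e-12)
  }
  expect_error(uniform_dissolve(p, 2 * sum(p$mass)), "infeasible")
})

test_that("power-law growth/dissolution matches the shrinking sphere", {
  kin <- dissolution_kinetics(2e-6, 1)
  p <- psd(c(90e-6, 110e-6), 1e-3)
  # sigma = 0 is the identity
  id <- advance_growth_dissolution(p, kin, 0, 10)
  expect_identical(id$psd, p)
  expect_identical(id$mass_exchanged, 0)
  # one step of linear shrinkage: analytic mass of a shrinking sphere
  sigma <- -0.5; dt <- 1
  dL <- -kin$rate_constant * abs(sigma) * dt     # -1e-6 m
  out <- advance_growth_dissolution(p, kin, sigma, dt)
  m_analytic <- 1e-3 * ((100e-6 + dL) / 100e-6)^3
  expect_equal(sum(out$psd$mass), m_analytic, tolerance = 1e-10)
  expect_equal(out$mass_exchanged, 1e-3 - m_analytic, tolerance = 1e-10)
})

test_that("sustained dissolution removes fines first and raises D50", {
  p <- fit_lognormal_psd(77e-6, 174e-6, weighting = "mass", total_mass = 1)
  kin <- dissolution_kinetics(1e-6, 1)
  cur <- p
  d50_0 <- quantile(cur, 0.5)
  mid <- (p$edges[-1] + p$edges[-length(p$edges)]) / 2
  tot <- sum(p$mass)
  dmin0 <- min(mid[p$mass > 1e-9 * tot])
  for (i in 1:10) cur <- advance_growth_dissolution(cur, kin, -1, 1)$psd
  # the smallest occupied sizes are gone and the mass median moved right
  expect_gt(min(mid[cur$mass > 1e-9 * tot]), dmin0)
  expect_gt(quantile(cur, 0.5), d50_0)
})

test_that("every PSD update conserves mass and respects the sigma sign", {
  set.seed(23)
  p0 <- fit_lognormal_psd(77e-6, 174e-6, weighting = "mass", total_mass = 1)
  kin <- dissolution_kinetics(1e-5, 1.3)
  for (i in 1:20) {
    sigma <- runif(1, -2, 2)
    dt <- runif(1, 0.1, 5)
    out <- advance_growth_dissolution(p0, kin, sigma, dt)
    expect_equal(sum(out$psd$mass) + out$mass_exchanged, sum(p0$mass),
                 tolerance = 1e-10)
    if (sigma < 0) expect_lte(sum(out$psd$mass), sum(p0$mass) + 1e-15)
    if (sigma > 0) expect_gte(sum(out$psd$mass), sum(p0$mass) - 1e-15)
    expect_true(all(out$psd$mass >= 0))
  }
})

test_that("the mass-targeted diameter shift reproduces its target exactly", {
  set.seed(5)
  p <- fit_lognormal_psd(50e-6, 60e-6, weighting = "mass", total_mass = 2e-3)
  for (target in c(1e-5, 5e-4, -1e-5, -5e-4, 1.9e-3)) {
    dL <- cakewash:::psd_delta_for_mass(p, target)
    got <- cakewash:::psd_shift(p, dL)$mass_exchanged
    expect_equal(got, target, tolerance = 1e-9)
  }
})

test_that("PSD files round-trip through CSV", {
  p <- fit_lognormal_psd(77e-6, 40e-6, n_bins = 20L, total_mass = 3e-3)
  path <- tempfile(fileext = ".csv")
  write_psd(p, path)
  back <- read_psd(path, total_mass = 3e-3)
  expect_equal(back$edges, p$edges, tolerance = 1e-9)
  expect_equal(back$mass, p$mass, tolerance = 1e-9)
})
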