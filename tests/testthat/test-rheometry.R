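test_that("moduli extraction is exact on synthetic sinusoids", {
  w <- 0.05
  gamma0 <- 0.5
  A <- 2.5
  tt <- seq(0, 4 * 2 * pi / w, length.out = 4 * 64 + 1)

  g <- extract_moduli(tt, A * sin(w * tt), omega = w, gamma0 = gamma0)
  expect_equal(g[["Gp"]], A / gamma0, tolerance = 1e-10)
  expect_lt(abs(g[["Gpp"]]), 1e-10)

  g <- extract_moduli(tt, A * cos(w * tt), omega = w, gamma0 = gamma0)
  expect_lt(abs(g[["Gp"]]), 1e-10)
  expect_equal(g[["Gpp"]], A / gamma0, tolerance = 1e-10)

  # pi/4 phase split, cross-checked against a least-squares sinusoid fit
  sig <- A * sin(w * tt + pi / 4)
  g <- extract_moduli(tt, sig, omega = w, gamma0 = gamma0)
  expect_equal(g[["Gp"]], A / (gamma0 * sqrt(2)), tolerance = 1e-10)
  expect_equal(g[["Gpp"]], A / (gamma0 * sqrt(2)), tolerance = 1e-10)
  fit <- stats::lm(sig ~ 0 + sin(w * tt) + cos(w * tt))
  expect_equal(unname(stats::coef(fit)) / gamma0, unname(g), tolerance = 1e-8)

  expect_error(extract_moduli(tt, sig, omega = w, gamma0 = 0), "undefined")
})

test_that("scenario assembly matches its bonding contracts", {
  base <- list(n_elements = 120, seed = 6)
  sph <- build_scenario(do.call(scenario_spec,
                                c(list(kind = "frictional_spheres"), base)))
  expect_equal(nrow(sph$bonds), 0)

  blk <- build_scenario(do.call(scenario_spec,
                                c(list(kind = "bulk_crosslinked"), base)))
  expect_equal(nrow(blk$bonds), nrow(find_contacts(blk)))

  dense <- build_scenario(do.call(scenario_spec,
    c(list(kind = "dense_irregular", particles_target = 10), base)))
  loose <- build_scenario(do.call(scenario_spec,
    c(list(kind = "loose_porous", particles_target = 10,
           internal_bond_fraction = 0.3), base)))
  # same packing and partition: strict bond-count inequality
  expect_identical(dense$assignment, loose$assignment)
  expect_lt(nrow(loose$bonds), nrow(dense$bonds))
  # free intra-particle contacts remain in the loose scenario
  ct <- find_contacts(loose)
  a <- loose$assignment
  n_intra <- sum(a[ct$i] == a[ct$j])
  expect_gte(n_intra - nrow(loose$bonds), 1)
})

test_that("amplitude sweeps are deterministic and internally consistent", {
  sp <- scenario_spec("frictional_spheres", n_elements = 60, seed = 8)
  pr <- shear_protocol(n_cycles_total = 3, n_cycles_discard = 1)
  amps <- c(0.01, 0.05, 0.2)
  c1 <- amplitude_sweep(sp, amps, pr)
  c2 <- amplitude_sweep(sp, amps, pr)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(c1$gamma0, amps)
  expect_equal(c1$tau0, c1$gamma0 * sqrt(c1$Gp^2 + c1$Gpp^2), tolerance = 1e-12)
})

test_that("joint stiffness scaling multiplies the moduli and collapses master curves", {
  # frictional packing at the default drive rate, stick-dominated amplitudes
  amps <- c(0.004, 0.01)
  pr <- shear_protocol(n_cycles_total = 4, n_cycles_discard = 2)
  base <- amplitude_sweep(scenario_spec("frictional_spheres", n_elements = 80,
                                        E = 1, seed = 9), amps, pr)
  scaled <- amplitude_sweep(scenario_spec("frictional_spheres", n_elements = 80,
                                          E = 3, seed = 9), amps, pr)
  expect_equal(scaled$Gp, 3 * base$Gp, tolerance = 0.02)
  expect_equal(scaled$Gpp, 3 * base$Gpp, tolerance = 0.02)
  # master curves collapse pointwise (shape unchanged by stiffness scaling)
  nb <- normalize_master(base)
  ns <- normalize_master(scaled)
  expect_equal(ns$Gp, nb$Gp, tolerance = 0.02)
  expect_equal(ns$tau0, nb$tau0, tolerance = 0.02)

  # bonded network, deep quasi-static drive (inertial ringing suppressed)
  pr2 <- shear_protocol(n_cycles_total = 4, n_cycles_discard = 2, omega = 0.01)
  amps2 <- c(0.004, 0.01)
  b2 <- amplitude_sweep(scenario_spec("bulk_crosslinked", n_elements = 80,
                                      E = 1, seed = 9), amps2, pr2)
  s2 <- amplitude_sweep(scenario_spec("bulk_crosslinked", n_elements = 80,
                                      E = 3, seed = 9), amps2, pr2)
  expect_equal(s2$Gp, 3 * b2$Gp, tolerance = 0.02)
  expect_equal(s2$Gpp, 3 * b2$Gpp, tolerance = 0.02)
})

test_that("bonded structures respond as elastic solids at small strain", {
  # fully bonded network, deep quasi-static drive: stress sinusoidal and in
  # phase with the imposed strain
  net <- build_scenario(scenario_spec("bulk_crosslinked", n_elements = 48,
                                      seed = 4))
  w <- 0.006
  s <- run_oscillation(net, shear_protocol(gamma0 = 0.005, omega = w,
                                           n_cycles_total = 4,
                                           n_cycles_discard = 2))
  g <- extract_moduli(s)
  expect_gt(g[["Gp"]], 0)
  phase_deg <- atan2(g[["Gpp"]], g[["Gp"]]) * 180 / pi
  expect_lt(phase_deg, 1)
  # first harmonic carries the signal: residual of the sinusoid fit is small
  keep <- s$measure
  fit <- g[["Gp"]] * 0.005 * sin(w * s$time[keep]) +
    g[["Gpp"]] * 0.005 * cos(w * s$time[keep])
  expect_lt(sd(s$sxy[keep] - fit), 0.05 * sd(s$sxy[keep]))

  # full cross-linked network: storage modulus flat (within 10%) over a
  # decade of small amplitudes, loss modulus well below it
  ens <- build_scenario(scenario_spec("bulk_crosslinked", n_elements = 80,
                                      seed = 4))
  amps <- c(0.002, 0.0045, 0.009, 0.02)
  cv <- amplitude_sweep(ens, amps, shear_protocol(n_cycles_total = 4,
                                                  n_cycles_discard = 2))
  expect_lt(diff(range(cv$Gp)) / mean(cv$Gp), 0.10)
  expect_true(all(cv$Gpp < 0.15 * cv$Gp))
})
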