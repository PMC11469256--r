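mk_curve <- function(gamma0, Gp, Gpp, tau0 = NULL) {
  df <- data.frame(gamma0 = gamma0, Gp = Gp, Gpp = Gpp)
  if (!is.null(tau0)) df$tau0 <- tau0
  rheology_curve(df)
}

test_that("low-strain plateau follows the prefix rule", {
  flat <- mk_curve(c(0.01, 0.02, 0.04, 0.08), rep(5, 4), rep(0.1, 4))
  expect_equal(low_strain_plateau(flat), 5)

  cv <- mk_curve(c(0.01, 0.02, 0.04, 0.08), c(5.0, 4.9, 3.0, 1.0), rep(0.1, 4))
  expect_equal(low_strain_plateau(cv), mean(c(5.0, 4.9)))

  collapsing <- mk_curve(c(0.01, 0.02, 0.04), c(5, 3, 1), rep(0.1, 3))
  expect_true(is.na(low_strain_plateau(collapsing)))

  expect_error(low_strain_plateau(flat[0, ]), "empty")
})

test_that("yield location: log-linear interpolation, exact hits, and no-yield flag", {
  cv <- mk_curve(c(0.1, 0.4, 0.8), c(2, 2, 1), c(0.5, 1, 2))
  # G'/G'' = 2 at 0.4 and 0.5 at 0.8 -> geometric midpoint
  y <- find_yield(cv)
  expect_equal(y$yield_strain, sqrt(0.4 * 0.8), tolerance = 1e-12)

  solid <- mk_curve(c(0.1, 1, 3), c(5, 5, 6), c(0.2, 0.2, 0.3))
  y <- find_yield(solid)
  expect_true(is.na(y$yield_strain) && is.na(y$yield_stress))

  # an exact G' = G'' point is itself the crossover
  eq <- mk_curve(c(0.1, 1, 2), c(2, 1, 0.2), c(0.5, 1, 1))
  expect_equal(find_yield(eq)$yield_strain, 1)

  # agreement with a dense brute-force scan of the interpolated difference
  set.seed(31)
  for (rep in 1:5) {
    g <- exp(seq(log(0.01), log(3), length.out = 9))
    gp <- 2 * exp(-cumsum(abs(rnorm(9, 0.5, 0.2))))
    gpp <- seq(0.2 * gp[1], 2 * gp[9], length.out = 9)
    cv <- mk_curve(g, gp, gpp)
    y <- find_yield(cv)
    if (is.na(y$yield_strain)) next
    dense <- exp(seq(log(g[1]), log(g[9]), length.out = 5000))
    lr <- stats::approx(log(g), log(gp / gpp), xout = log(dense))$y
    zero <- dense[which.min(abs(lr))]
    k <- findInterval(y$yield_strain, g)
    expect_gte(zero, g[max(1, k - 1)])
    expect_lte(zero, g[min(length(g), k + 2)])
  }
})

test_that("softening detection: onset, plateau, depth, and flags", {
  flat <- mk_curve(exp(seq(log(0.01), log(1), length.out = 5)),
                   rep(5, 5), rep(0.1, 5))
  s <- detect_softening(flat)
  expect_true(is.na(s$softening_onset_strain))

  g <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
  gp <- c(10, 10, 4, 4, 4, 0.5)
  gpp <- c(1, 1, 1, 1, 1, 2)
  cv <- mk_curve(g, gp, gpp)
  s <- detect_softening(cv)
  expect_equal(s$softening_onset_strain, 0.05)
  expect_equal(s$softening_depth, 10 / 4, tolerance = 1e-12)
  expect_equal(s$soft_plateau_Gp, 4)
  # soft plateau stress read at the plateau midpoint
  expect_equal(s$soft_plateau_stress, cv$tau0[4], tolerance = 1e-12)
})

test_that("the Hookean reference curve has relative yield stress exactly its yield strain", {
  hk <- hookean_curve(G0 = 1, yield_strain = 1)
  f <- extract_features(hk)
  expect_identical(f$G0p, 1)
  expect_identical(f$yield_strain, 1)
  expect_identical(f$relative_yield_stress, 1)

  hk2 <- hookean_curve(G0 = 4, yield_strain = 0.5)
  f2 <- extract_features(hk2)
  expect_equal(f2$relative_yield_stress, 0.5, tolerance = 1e-12)
})

test_that("feature extraction is scale equivariant", {
  g <- exp(seq(log(0.005), log(2), length.out = 8))
  gp <- c(8, 8, 7.8, 4, 3.8, 2, 0.8, 0.1)
  gpp <- c(0.4, 0.4, 0.5, 0.8, 1.0, 1.4, 1.2, 0.9)
  cv <- mk_curve(g, gp, gpp)
  f1 <- extract_features(cv)
  c_scale <- 7.3
  f2 <- extract_features(mk_curve(g, c_scale * gp, c_scale * gpp))
  expect_equal(f2$G0p, c_scale * f1$G0p, tolerance = 1e-12)
  expect_equal(f2$soft_plateau_stress, c_scale * f1$soft_plateau_stress,
               tolerance = 1e-12)
  expect_equal(f2$yield_stress, c_scale * f1$yield_stress, tolerance = 1e-12)
  expect_equal(f2$yield_strain, f1$yield_strain, tolerance = 1e-12)
  expect_equal(f2$softening_depth, f1$softening_depth, tolerance = 1e-12)
  expect_equal(f2$relative_yield_stress, f1$relative_yield_stress,
               tolerance = 1e-12)
})

test_that("relative yield stress of softening curves sits below the Hookean bound", {
  set.seed(91)
  tested <- 0
  for (rep in 1:8) {
    # finely resolved curves so that grid interpolation error is negligible
    npt <- 60
    g <- exp(seq(log(0.005), log(3), length.out = npt))
    # non-increasing G' with a linear-regime prefix and a guaranteed crossover
    gp <- 10 * exp(-cumsum(c(0, 0.002,
                             abs(rnorm(npt - 2, 0.4, 0.3)) * 8 / npt)))
    gpp <- exp(seq(log(0.05 * gp[1]), log(5 * gp[npt]), length.out = npt))
    cv <- mk_curve(g, gp, gpp)
    f <- extract_features(cv)
    if (is.na(f$relative_yield_stress)) next
    tested <- tested + 1
    g_at_cross <- exp(stats::approx(log(g), log(gp),
                                    xout = log(f$yield_strain))$y)
    # equality holds exactly at the crossover; the yield stress and G' are
    # interpolated on the grid independently, hence the small residual slack
    expect_lte(f$relative_yield_stress,
               f$yield_strain * g_at_cross / f$G0p * sqrt(2) * 1.01)
  }
  expect_gte(tested, 3)
})

test_that("normalization to the plateau is exact and idempotent", {
  flat <- mk_curve(c(0.01, 0.02, 0.04), rep(5, 3), rep(0.5, 3))
  nm <- normalize_master(flat)
  expect_equal(nm$Gp, rep(1, 3))
  expect_identical(low_strain_plateau(nm), 1)
  collapsing <- mk_curve(c(0.01, 0.02, 0.04), c(5, 3, 1), rep(0.1, 3))
  expect_error(normalize_master(collapsing), "undefined")
})

test_that("sweep tables round-trip losslessly with descriptive parse errors", {
  d <- withr::local_tempdir()
  g <- exp(seq(log(0.01), log(2), length.out = 6))
  cv <- mk_curve(g, 5 * exp(-g), 0.3 + g / 10)
  f <- file.path(d, "sweep.csv")
  write_sweep(cv, f)
  back <- read_sweep(f)
  expect_equal(back$Gp, cv$Gp, tolerance = 0)
  expect_equal(back$gamma0, cv$gamma0, tolerance = 0)

  # unsorted input is sorted, content preserved
  shuffled <- as.data.frame(cv)[c(3, 1, 6, 2, 5, 4), ]
  utils::write.csv(shuffled, f, row.names = FALSE)
  back <- read_sweep(f)
  expect_equal(back$gamma0, sort(cv$gamma0), tolerance = 1e-12)
  expect_equal(back[order(back$gamma0), "Gp"], cv$Gp, tolerance = 1e-12)

  # tau0 reconstructed when absent
  utils::write.csv(shuffled[, c("gamma0", "Gp", "Gpp")], f, row.names = FALSE)
  back <- read_sweep(f)
  expect_equal(back$tau0, back$gamma0 * sqrt(back$Gp^2 + back$Gpp^2),
               tolerance = 1e-12)

  utils::write.csv(shuffled[, c("gamma0", "Gp")], f, row.names = FALSE)
  expect_error(read_sweep(f), "Gpp")

  bad <- shuffled
  bad$Gp[2] <- "oops"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_sweep(f), "non-numeric")

  dup <- shuffled
  dup$gamma0[2] <- dup$gamma0[1]
  utils::write.csv(dup, f, row.names = FALSE)
  expect_error(read_sweep(f), "duplicate")
})
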