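test_that("packing obeys the area identity, seeded determinism, and feasibility guard", {
  # single element: box area follows directly from the area fraction
  e1 <- generate_packing(1, phi_target = 0.5, seed = 1)
  expect_equal(prod(e1$box), pi * e1$elements$r[1]^2 / 0.5, tolerance = 1e-12)

  ens <- generate_packing(120, size_ratio = 1.4, phi_target = 0.90, seed = 7)
  phi_direct <- sum(pi * ens$elements$r^2) / prod(ens$box)
  expect_lt(abs(phi_direct - 0.90) / 0.90, 0.01)

  ens2 <- generate_packing(120, size_ratio = 1.4, phi_target = 0.90, seed = 7)
  expect_identical(ens$elements, ens2$elements)
  expect_identical(ens$box, ens2$box)

  expect_error(generate_packing(50, phi_target = 0.95), "feasible")

  # below jamming the relaxed packing is essentially overlap free
  soft <- generate_packing(120, phi_target = 0.80, seed = 3)
  ct <- find_contacts(soft)
  if (nrow(ct) > 0)
    expect_lt(max(ct$delta / pmin(soft$elements$r[ct$i],
                                  soft$elements$r[ct$j])), 0.05)

  # disc inertia convention
  expect_equal(ens$elements$inertia,
               0.5 * ens$elements$m * ens$elements$r^2, tolerance = 1e-12)
})

test_that("contact detection matches brute-force enumeration, including sheared images", {
  # two-element trivial cases
  el <- data.frame(x = c(2, 4.5), y = c(2, 2), r = 1)
  far <- make_ensemble(el, box = c(10, 10))
  expect_equal(nrow(find_contacts(far)), 0)

  el$x <- c(2, 3.9)
  near <- make_ensemble(el, box = c(10, 10))
  ct <- find_contacts(near)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$delta, 0.1, tolerance = 1e-12)

  # 50-element packing vs all-pairs oracle, at rest and under boundary strain
  ens <- generate_packing(50, phi_target = 0.88, seed = 11)
  for (g in c(0, 0.37)) {
    ens$strain <- g
    got <- find_contacts(ens)
    ref <- bf_contacts(ens)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got[, c("i", "j")], ref[, c("i", "j")],
                 ignore_attr = TRUE)
    expect_equal(got$delta, ref$delta, tolerance = 1e-12)
  }
})

test_that("partitioning gives exactly the requested number of contiguous particles", {
  ens <- generate_packing(200, phi_target = 0.90, seed = 5)

  expect_identical(partition_particles(ens, 200, seed = 1), 1:200)
  expect_true(all(partition_particles(ens, 1, seed = 1) == 1L))
  expect_error(partition_particles(ens, 300, seed = 1), "between 1 and")

  a <- partition_particles(ens, 12, seed = 9)
  expect_length(a, 200)
  expect_equal(length(unique(a)), 12)
  ct <- find_contacts(ens)
  for (pid in unique(a)) {
    members <- which(a == pid)
    intra <- ct[a[ct$i] == pid & a[ct$j] == pid, ]
    expect_true(is_connected_subset(members, intra$i, intra$j))
  }
})

test_that("bond modes: counts, nesting, connectivity and free interfaces", {
  ens <- generate_packing(200, phi_target = 0.90, seed = 5)
  a <- partition_particles(ens, 12, seed = 9)
  ct <- find_contacts(ens)

  expect_equal(nrow(create_bonds(ens, mode = "none")), 0)

  bulk <- create_bonds(ens, mode = "bulk_all")
  expect_equal(nrow(bulk), nrow(ct))
  expect_true(all(bulk$i < bulk$j))

  intra <- create_bonds(ens, a, mode = "intra_all")
  n_intra_contacts <- sum(a[ct$i] == a[ct$j])
  expect_equal(nrow(intra), n_intra_contacts)

  expect_error(create_bonds(ens, NULL, mode = "intra_all"), "assignment")

  p <- 0.3
  frac <- create_bonds(ens, a, mode = "intra_fraction", p = p, seed = 2)
  # binomial bound on the sampled core (bridges only ever add bonds), and the
  # bridge additions cannot exceed the spanning-tree size
  sigma <- sqrt(n_intra_contacts * p * (1 - p))
  expect_gte(nrow(frac), p * n_intra_contacts - 3 * sigma)
  expect_lte(nrow(frac), p * n_intra_contacts + 3 * sigma + length(unique(a)) +
               length(a))
  # mode nesting for the same packing
  expect_gte(nrow(bulk), nrow(intra))
  expect_gte(nrow(intra), nrow(frac))

  for (pid in unique(a)) {
    members <- which(a == pid)
    bb <- frac[a[frac$i] == pid, ]
    expect_true(is_connected_subset(members, bb$i, bb$j))
    # free contact interfaces whenever the particle has spare (cycle) contacts
    nc <- sum(a[ct$i] == pid & a[ct$j] == pid)
    if (nc > length(members) - 1)
      expect_lt(nrow(bb), nc)
  }
})

test_that("ensemble serialization is lossless and byte stable; configs round-trip", {
  ens <- generate_packing(40, phi_target = 0.85, seed = 2)
  ens$bonds <- create_bonds(ens, mode = "bulk_all")
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a"); p2 <- file.path(d, "b")
  write_ensemble(ens, p1)
  write_ensemble(ens, p2)
  for (suf in c("_meta.json", "_elements.csv", "_bonds.csv"))
    expect_identical(readLines(paste0(p1, suf)), readLines(paste0(p2, suf)))
  back <- read_ensemble(p1)
  expect_equal(back$elements$x, ens$elements$x, tolerance = 0)
  expect_equal(back$bonds$rest_length, ens$bonds$rest_length, tolerance = 0)
  expect_equal(back$box, ens$box, tolerance = 0)

  cfg <- list(kind = "loose_porous", n_elements = 40L, phi = 0.871234567891234,
              mu = 0.3, E = 1.5, particles_target = 6L,
              internal_bond_fraction = 1 / 3, seed = 4L,
              amplitudes = c(0.01, 0.1, 1))
  f <- file.path(d, "cfg.yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_identical(back$phi, cfg$phi)
  expect_identical(back$internal_bond_fraction, cfg$internal_bond_fraction)
  expect_identical(as.numeric(back$amplitudes), cfg$amplitudes)
  f2 <- file.path(d, "cfg2.yaml")
  write_config(back, f2)
  expect_identical(readLines(f), readLines(f2))
})
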