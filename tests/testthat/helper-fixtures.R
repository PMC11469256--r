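# Fixtures built in code: tiny hand-placed ensembles and an independent
# all-pairs force oracle written in plain R against the scalar force laws.

make_ensemble <- function(elements, box, material = material_params(),
                          bonds = NULL, strain = 0, strain_rate = 0) {
  n <- nrow(elements)
  if (is.null(elements$vx)) elements$vx <- 0
  if (is.null(elements$vy)) elements$vy <- 0
  if (is.null(elements$omega)) elements$omega <- 0
  if (is.null(elements$m)) elements$m <- (elements$r / 0.5)^2
  if (is.null(elements$inertia)) elements$inertia <- 0.5 * elements$m * elements$r^2
  if (is.null(elements$id)) elements$id <- seq_len(n)
  structure(list(
    box = box,
    elements = elements[, c("id", "x", "y", "vx", "vy", "omega", "r", "m",
                            "inertia")],
    phi = sum(pi * elements$r^2) / prod(box),
    material = material,
    bonds = if (is.null(bonds)) rheodem:::empty_bonds() else bonds,
    assignment = seq_len(n),
    strain = strain, strain_rate = strain_rate,
    meta = list(seed = NA_integer_, kind = "fixture")
  ), class = "dem_ensemble")
}

# two discs bonded at stretched separation: a harmonic oscillator
make_bonded_pair <- function(dist = 1.5, rest = 1.2, k = 1, box = c(8, 8),
                             material = material_params(eta_scale = 0, drag = 0,
                                                        mu = 0)) {
  el <- data.frame(x = c(box[1] / 2 - dist / 2, box[1] / 2 + dist / 2),
                   y = box[2] / 2, r = 0.5)
  make_ensemble(el, box, material,
                bonds = data.frame(i = 1L, j = 2L, rest_length = rest,
                                   k_bond = k))
}

# Lees-Edwards minimum image in plain R; returns c(bx, by, n_images)
le_min_image <- function(bx, by, Lx, Ly, gamma) {
  nimg <- round(by / Ly)
  by <- by - nimg * Ly
  bx <- bx - nimg * gamma * Ly
  bx <- bx - Lx * round(bx / Lx)
  c(bx, by, nimg)
}

# Independent brute-force oracle: all-pairs forces and torques assembled in R
# from the exported scalar force laws. states: data.frame(i, j, xi).
bf_forces <- function(ens, states = NULL, dt = 0.05, gdot = 0) {
  e <- ens$elements
  n <- nrow(e)
  mat <- ens$material
  eff <- rheodem:::effective_params(mat)
  Lx <- ens$box[1]; Ly <- ens$box[2]; g <- ens$strain
  fx <- numeric(n); fy <- numeric(n); tq <- numeric(n)
  xi_of <- function(i, j) {
    if (is.null(states)) return(0)
    hit <- which((states$i == i & states$j == j) |
                 (states$i == j & states$j == i))
    if (length(hit)) states$xi[hit[1]] else 0
  }
  bkey <- paste(ens$bonds$i, ens$bonds$j)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      b <- le_min_image(e$x[i] - e$x[j], e$y[i] - e$y[j], Lx, Ly, g)
      d <- sqrt(b[1]^2 + b[2]^2)
      bonded <- paste(i, j) %in% bkey
      delta <- e$r[i] + e$r[j] - d
      if (!bonded && delta <= 0) next
      nx <- -b[1] / d; ny <- -b[2] / d
      tx <- -ny; ty <- nx
      vrx <- e$vx[j] + b[3] * gdot * Ly - e$vx[i]
      vry <- e$vy[j] - e$vy[i]
      vn <- -(vrx * nx + vry * ny)
      ai <- e$r[i] - delta / 2; aj <- e$r[j] - delta / 2
      vt <- vrx * tx + vry * ty - (e$omega[i] * ai + e$omega[j] * aj)
      ft <- 0
      if (bonded) {
        bd <- ens$bonds[bkey == paste(i, j), ]
        Fn <- bond_force(bd, d, E = mat$E) + eff$eta * vn
        # cross-links bind tangentially: uncapped spring, fresh in a one-shot
        if (eff$kt > 0) ft <- eff$kt * (0 + vt * dt)
      } else {
        Fn <- normal_force(delta, vn, mat)
        if (delta > 0 && eff$mu > 0)
          ft <- tangential_update(xi_of(i, j), vt, dt, Fn, mat)$force
      }
      fjx <- Fn * nx - ft * tx
      fjy <- Fn * ny - ft * ty
      fx[j] <- fx[j] + fjx; fy[j] <- fy[j] + fjy
      fx[i] <- fx[i] - fjx; fy[i] <- fy[i] - fjy
      tq[i] <- tq[i] + ai * ft; tq[j] <- tq[j] + aj * ft
    }
  }
  list(force = cbind(fx, fy), torque = tq)
}

# brute-force contact enumeration in R
bf_contacts <- function(ens) {
  e <- ens$elements
  n <- nrow(e)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      b <- le_min_image(e$x[i] - e$x[j], e$y[i] - e$y[j],
                        ens$box[1], ens$box[2], ens$strain)
      d <- sqrt(b[1]^2 + b[2]^2)
      if (d < e$r[i] + e$r[j])
        out <- rbind(out, data.frame(i = i, j = j,
                                     delta = e$r[i] + e$r[j] - d))
    }
  }
  out
}

# BFS connectivity of a vertex subset within an edge list
is_connected_subset <- function(members, edges_i, edges_j) {
  if (length(members) <= 1) return(TRUE)
  keep <- edges_i %in% members & edges_j %in% members
  ei <- edges_i[keep]; ej <- edges_j[keep]
  visited <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nb <- c(ej[ei %in% frontier], ei[ej %in% frontier])
    frontier <- setdiff(nb, visited)
    visited <- union(visited, frontier)
  }
  length(setdiff(members, visited)) == 0
}

# softening depth with a conservative fallback: when the low-strain plateau
# prefix is undefined, use the smallest-amplitude G' as a lower bound on G0'
# (underestimates the depth of continuously softening curves)
softening_depth_bounded <- function(curve) {
  G0p <- low_strain_plateau(curve)
  if (is.na(G0p)) G0p <- curve$Gp[1]
  s <- detect_softening(curve, G0p = G0p)
  if (is.na(s$softening_depth)) 1 else s$softening_depth
}
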