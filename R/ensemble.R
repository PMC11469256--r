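#' Generate a seeded bidisperse packing of circular elements
#'
#' Builds a dense 2D packing in a periodic box: elements are inserted by random
#' sequential insertion at a low area fraction, then the box is shrunk
#' isotropically in stages with damped (FIRE) relaxation to the target area
#' fraction. Radii are bidisperse 50/50 at ratio `size_ratio` (suppresses
#' crystallization); the mean small-element diameter defines the length unit,
#' the small-element mass the mass unit. Masses scale with element area,
#' inertia follows the disc convention \eqn{I = m r^2 / 2}.
#'
#' Above the 2D jamming point (area fraction about 0.84) the relaxed packing
#' necessarily carries finite overlaps set by the confining pressure; below it
#' the protocol relaxes to an essentially overlap-free state.
#'
#' @param n_elements number of elements, `>= 1`.
#' @param size_ratio large/small radius ratio, `>= 1`.
#' @param phi_target target area fraction in `(0, 0.92]`.
#' @param box_aspect ratio Lx/Ly of the periodic box.
#' @param seed integer seed; the packing is a deterministic function of the
#'   arguments.
#' @param material a [material_params()] object attached to the ensemble.
#' @return an object of class `dem_ensemble`: list with `box` (Lx, Ly),
#'   `elements` data frame (`id, x, y, vx, vy, omega, r, m, inertia`), measured
#'   `phi`, `material`, `bonds`, per-element particle `assignment`, boundary
#'   `strain` and `strain_rate`.
#' @export
generate_packing <- function(n_elements, size_ratio = 1.4, phi_target = 0.90,
                             box_aspect = 1, seed = 1,
                             material = material_params()) {
  stopifnot(n_elements >= 1, size_ratio >= 1, box_aspect > 0)
  if (phi_target <= 0 || phi_target > 0.92)
    stop("phi_target = ", phi_target,
         " is outside the geometrically feasible range (0, 0.92] for 2D disks")
  n <- as.integer(n_elements)
  set.seed(as.integer(seed))
  rs <- 0.5
  rl <- 0.5 * size_ratio
  radii <- sample(rep(c(rs, rl), length.out = n))
  area_el <- sum(pi * radii^2)
  area_box <- area_el / phi_target
  Lx <- sqrt(area_box * box_aspect)
  Ly <- area_box / Lx

  # random sequential insertion at a dilute fraction, then compress
  phi_init <- min(0.35, phi_target)
  s0 <- sqrt(phi_target / phi_init)   # initial box inflation factor
  Lx0 <- Lx * s0
  Ly0 <- Ly * s0
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(50000L)) {
      px <- runif(1, 0, Lx0); py <- runif(1, 0, Ly0)
      ok <- TRUE
      if (i > 1) {
        dx <- x[seq_len(i - 1)] - px
        dy <- y[seq_len(i - 1)] - py
        dy <- dy - Ly0 * round(dy / Ly0)
        dx <- dx - Lx0 * round(dx / Lx0)
        ok <- all(dx * dx + dy * dy >= (radii[seq_len(i - 1)] + radii[i])^2)
      }
      if (ok) { x[i] <- px; y[i] <- py; placed <- TRUE; break }
    }
    if (!placed)
      stop("random sequential insertion failed at element ", i,
           "; initial area fraction too high")
  }

  pk <- dem_pack(x, y, radii, Lx0, Ly0, phi_target,
                 kn = 1, stage_ratio = 1.02,
                 max_iter_stage = 2000L, max_iter_final = 40000L,
                 tol_stage = 1e-8, tol_final = 1e-11)
  elements <- data.frame(id = seq_len(n), x = pk$x, y = pk$y,
                         vx = 0, vy = 0, omega = 0,
                         r = radii, m = (radii / rs)^2,
                         inertia = 0.5 * (radii / rs)^2 * radii^2)
  ens <- structure(list(
    box = c(pk$Lx, pk$Ly),
    elements = elements,
    phi = area_el / (pk$Lx * pk$Ly),
    material = material,
    bonds = empty_bonds(),
    assignment = seq_len(n),
    strain = 0,
    strain_rate = 0,
    meta = list(seed = as.integer(seed), size_ratio = size_ratio,
                phi_target = phi_target, box_aspect = box_aspect,
                residual_force = pk$fmax, kind = NA_character_)
  ), class = "dem_ensemble")
  ens
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0),
             rest_length = numeric(0), k_bond = numeric(0))
}

#' @export
print.dem_ensemble <- function(x, ...) {
  cat(sprintf("dem_ensemble: %d elements in %.3g x %.3g box (phi = %.4f)\n",
              nrow(x$elements), x$box[1], x$box[2], x$phi))
  cat(sprintf("  %d bonds, %d particles, boundary strain %.4g\n",
              nrow(x$bonds), length(unique(x$assignment)), x$strain))
  cat(sprintf("  mu = %g, E = %g, compression law: %s\n",
              x$material$mu, x$material$E, x$material$compression_law))
  invisible(x)
}

elem_matrix <- function(ens) {
  as.matrix(ens$elements[, c("x", "y", "vx", "vy", "omega", "r", "m", "inertia")])
}

# bond stiffness scales with the constituent stiffness multiplier E,
# like every other spring constant
bond_matrix <- function(ens) {
  b <- ens$bonds
  if (nrow(b) == 0) return(matrix(numeric(0), ncol = 4))
  m <- as.matrix(b[, c("i", "j", "rest_length", "k_bond")])
  m[, 4] <- m[, 4] * ens$material$E
  m
}

#' List overlapping element pairs
#'
#' Exact all-pairs contact detection under the sheared (Lees-Edwards) periodic
#' minimum image. A pair (i, j) is listed once, with overlap
#' `delta = r_i + r_j - distance > 0` and the unit normal pointing from i to j.
#'
#' @param ensemble a `dem_ensemble`.
#' @return data frame with columns `i, j, delta, nx, ny, dist`.
#' @export
find_contacts <- function(ensemble) {
  e <- ensemble$elements
  m <- dem_contacts(e$x, e$y, e$r, ensemble$box[1], ensemble$box[2],
                    ensemble$strain)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             delta = m[, 3], nx = m[, 4], ny = m[, 5], dist = m[, 6])
}

min_image_dist <- function(dx, dy, Lx, Ly, gamma) {
  n <- round(dy / Ly)
  dy <- dy - n * Ly
  dx <- dx - n * gamma * Ly
  dx <- dx - Lx * round(dx / Lx)
  sqrt(dx * dx + dy * dy)
}

#' Partition a packing into contiguous super-particles
#'
#' Grows `particles_target` particles from seeded centers: seed elements are
#' drawn at random, and the remaining elements are attached one at a time by
#' nearest-center (minimum-image Euclidean) assignment, restricted to elements
#' in contact with the growing particle. Every particle is therefore connected
#' in the contact graph by construction.
#'
#' @param ensemble a `dem_ensemble`.
#' @param particles_target number of particles, in `[1, n_elements]`.
#' @param seed integer seed for the choice of centers.
#' @return integer vector: particle id (1-based) per element.
#' @export
partition_particles <- function(ensemble, particles_target, seed = 1) {
  n <- nrow(ensemble$elements)
  particles_target <- as.integer(particles_target)
  if (particles_target < 1 || particles_target > n)
    stop("particles_target must be between 1 and the number of elements (", n, ")")
  if (particles_target == n) return(seq_len(n))
  set.seed(as.integer(seed))
  centers_id <- sample.int(n, particles_target)
  e <- ensemble$elements
  Lx <- ensemble$box[1]; Ly <- ensemble$box[2]; g <- ensemble$strain

  contacts <- find_contacts(ensemble)
  adj <- vector("list", n)
  for (k in seq_len(nrow(contacts))) {
    i <- contacts$i[k]; j <- contacts$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }

  assignment <- integer(n)
  assignment[centers_id] <- seq_len(particles_target)
  cx <- e$x[centers_id]; cy <- e$y[centers_id]

  # candidate pool: unassigned elements adjacent to an assigned one, keyed by
  # distance to the adjacent particle's center
  repeat {
    un <- which(assignment == 0L)
    if (length(un) == 0) break
    best_el <- 0L; best_p <- 0L; best_d <- Inf
    for (el in un) {
      ps <- unique(assignment[adj[[el]]])
      ps <- ps[ps > 0L]
      if (length(ps) == 0) next
      d <- min_image_dist(e$x[el] - cx[ps], e$y[el] - cy[ps], Lx, Ly, g)
      kmin <- which.min(d)
      if (d[kmin] < best_d) { best_d <- d[kmin]; best_el <- el; best_p <- ps[kmin] }
    }
    if (best_el == 0L) {
      # isolated elements (no contact to any particle): nearest center directly
      for (el in un) {
        d <- min_image_dist(e$x[el] - cx, e$y[el] - cy, Lx, Ly, g)
        assignment[el] <- which.min(d)
      }
      break
    }
    assignment[best_el] <- best_p
  }
  assignment
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) { uf[i] <- uf[uf[i]]; i <- uf[i] }
  i
}

#' Lay permanent cross-links on a packing
#'
#' Bonds are permanent central springs formed at the current contact geometry
#' (`rest_length` = center distance at formation, stiffness `k_bond = kn`,
#' scaled by the stiffness multiplier `E` during dynamics). Modes:
#' \describe{
#'   \item{none}{no bonds.}
#'   \item{bulk_all}{one bond per contacting pair regardless of assignment
#'     (a fully cross-linked bulk network).}
#'   \item{intra_all}{one bond per contacting pair sharing a particle
#'     (compact irregular particles).}
#'   \item{intra_fraction}{a seeded subsample of intra-particle contact pairs
#'     of expected fraction `p`; bridge bonds are re-added so each particle's
#'     bonded subgraph stays connected, and each particle with more contacts
#'     than its spanning tree keeps at least one free (unbonded) contact
#'     interface.}
#' }
#'
#' @param ensemble a `dem_ensemble`.
#' @param assignment integer particle id per element (required for `intra_*`).
#' @param mode bonding mode, see Details.
#' @param p expected bonded fraction of intra-particle contacts
#'   (`intra_fraction` only).
#' @param seed integer seed for the subsample.
#' @return a bond data frame (`i, j, rest_length, k_bond`), `i < j`.
#' @export
create_bonds <- function(ensemble, assignment = ensemble$assignment,
                         mode = c("none", "bulk_all", "intra_all",
                                  "intra_fraction"),
                         p = 1, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 1)
  if (mode == "none") return(empty_bonds())
  contacts <- find_contacts(ensemble)
  kb <- ensemble$material$kn
  if (mode == "bulk_all") {
    return(data.frame(i = contacts$i, j = contacts$j,
                      rest_length = contacts$dist, k_bond = kb))
  }
  if (is.null(assignment) || length(assignment) != nrow(ensemble$elements))
    stop("mode '", mode, "' requires a particle assignment for every element")
  intra <- contacts[assignment[contacts$i] == assignment[contacts$j], ,
                    drop = FALSE]
  if (mode == "intra_all") {
    return(data.frame(i = intra$i, j = intra$j,
                      rest_length = intra$dist, k_bond = kb))
  }
  # intra_fraction
  set.seed(as.integer(seed))
  keep <- runif(nrow(intra)) < p
  n <- nrow(ensemble$elements)
  sel <- intra[keep, , drop = FALSE]
  # connectivity repair per particle: add bridge bonds from unselected
  # intra-particle contacts until each particle's bonded subgraph is connected
  uf <- uf_new(n)
  if (nrow(sel) > 0) {
    for (k in seq_len(nrow(sel))) {
      a <- uf_find(uf, sel$i[k]); b <- uf_find(uf, sel$j[k])
      if (a != b) uf[a] <- b
    }
  }
  rest <- intra[!keep, , drop = FALSE]
  add <- logical(nrow(rest))
  if (nrow(rest) > 0) {
    for (k in seq_len(nrow(rest))) {
      a <- uf_find(uf, rest$i[k]); b <- uf_find(uf, rest$j[k])
      if (a != b) { uf[a] <- b; add[k] <- TRUE }
    }
  }
  bonds <- rbind(sel, rest[add, , drop = FALSE])
  # free-interface guarantee: a particle whose intra contacts all ended up
  # bonded, while having more contacts than a spanning tree needs, releases
  # one cycle bond (its removal keeps the particle connected)
  if (p < 1 && nrow(bonds) > 0) {
    for (pid in unique(assignment)) {
      members <- which(assignment == pid)
      ci <- intra[assignment[intra$i] == pid, , drop = FALSE]
      nb <- bonds[assignment[bonds$i] == pid, , drop = FALSE]
      if (nrow(ci) > length(members) - 1 && nrow(nb) == nrow(ci)) {
        for (k in seq_len(nrow(nb))) {
          uf2 <- uf_new(n)
          others <- nb[-k, , drop = FALSE]
          if (nrow(others) > 0) {
            for (q in seq_len(nrow(others))) {
              a <- uf_find(uf2, others$i[q]); b <- uf_find(uf2, others$j[q])
              if (a != b) uf2[a] <- b
            }
          }
          roots <- vapply(members, function(mm) uf_find(uf2, mm), 1L)
          if (length(unique(roots)) == 1) {
            drop_key <- paste(nb$i[k], nb$j[k])
            bonds <- bonds[paste(bonds$i, bonds$j) != drop_key, , drop = FALSE]
            break
          }
        }
      }
    }
  }
  bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
  rownames(bonds) <- NULL
  data.frame(i = bonds$i, j = bonds$j, rest_length = bonds$dist, k_bond = kb)
}

#' Serialize / restore an ensemble as plain-text artifacts
#'
#' Writes `<prefix>_meta.json` (box, area fraction, material, strain, particle
#' assignment), `<prefix>_elements.csv` and `<prefix>_bonds.csv`. Numeric
#' fields carry full double precision; writing the same ensemble twice yields
#' byte-identical files.
#'
#' @param ensemble a `dem_ensemble`.
#' @param prefix path prefix for the three files.
#' @return `write_ensemble` returns the file paths invisibly; `read_ensemble`
#'   returns the restored `dem_ensemble`.
#' @export
write_ensemble <- function(ensemble, prefix) {
  meta <- list(box = ensemble$box, phi = ensemble$phi,
               material = unclass(ensemble$material),
               strain = ensemble$strain, strain_rate = ensemble$strain_rate,
               assignment = ensemble$assignment, meta = ensemble$meta)
  paths <- paste0(prefix, c("_meta.json", "_elements.csv", "_bonds.csv"))
  jsonlite::write_json(meta, paths[1], auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  write_table_full(ensemble$elements, paths[2])
  write_table_full(ensemble$bonds, paths[3])
  invisible(paths)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  el <- utils::read.csv(paste0(prefix, "_elements.csv"))
  bd <- utils::read.csv(paste0(prefix, "_bonds.csv"))
  mat <- do.call(material_params,
                 meta$material[c("kn", "kt", "mu", "E", "eta_scale",
                                 "compression_law", "delta_max", "drag")])
  structure(list(box = meta$box, elements = el, phi = meta$phi,
                 material = mat,
                 bonds = if (nrow(bd)) bd else empty_bonds(),
                 assignment = as.integer(meta$assignment),
                 strain = meta$strain, strain_rate = meta$strain_rate,
                 meta = meta$meta),
            class = "dem_ensemble")
}

write_table_full <- function(df, path) {
  cols <- lapply(df, function(v)
    if (is.double(v)) sprintf("%.17g", v) else as.character(v))
  out <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(df), collapse = ","), out), path)
  invisible(path)
}
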