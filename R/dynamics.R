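#' Free time integration of an ensemble
#'
#' Velocity-Verlet integration with no imposed drive (the boundary strain is
#' held fixed). Used for relaxation, oscillator checks and energy bookkeeping.
#' Energy is reported for the linear contact law: kinetic + rotational +
#' normal, tangential and bond spring energies.
#'
#' @param ensemble a `dem_ensemble`.
#' @param n_steps number of time steps.
#' @param dt time step, `<= 0.1` (stability bound in natural units).
#' @param record_every record state and energy every this many steps.
#' @return list with `time`, `energy`, trajectory matrices `X, Y, VX, VY, OM`
#'   (one row per record), the final `ensemble`, and `cap_excess`.
#' @export
simulate_steps <- function(ensemble, n_steps, dt = 0.05, record_every = 1L) {
  stopifnot(n_steps >= 1, dt > 0, dt <= 0.1)
  res <- dem_steps(elem_matrix(ensemble), bond_matrix(ensemble),
                   effective_params(ensemble$material),
                   ensemble$box[1], ensemble$box[2], ensemble$strain,
                   as.integer(n_steps), dt, as.integer(record_every))
  if (!res$ok)
    stop("non-finite coordinates during free integration; state dumped")
  out_ens <- ensemble
  out_ens$elements[, c("x", "y", "vx", "vy", "omega")] <-
    res$elem[, 1:5, drop = FALSE]
  list(time = as.numeric(res$time), energy = as.numeric(res$energy),
       X = res$X, Y = res$Y, VX = res$VX, VY = res$VY, OM = res$OM,
       ensemble = out_ens, cap_excess = res$cap_excess)
}

#' Run an oscillatory simple-shear experiment
#'
#' Imposes \eqn{\gamma(t) = \gamma_0 \sin(\omega t)} through Lees-Edwards
#' boundary images plus per-step affine velocity kicks (element velocities are
#' initialized on the affine field at t = 0). The symmetric virial stress
#' tensor is sampled 64 times per cycle; the first `n_cycles_discard` cycles
#' are flagged as transient.
#'
#' @param ensemble a `dem_ensemble` (a fresh copy is used; the input is not
#'   modified).
#' @param protocol a [shear_protocol()].
#' @return data frame of stress samples (`time, strain, sxx, sxy, syy, cycle,
#'   measure`) with attributes `gamma0`, `omega`, `dt`, `cap_excess`,
#'   `stiff_warnings`.
#' @export
run_oscillation <- function(ensemble, protocol = shear_protocol()) {
  res <- dem_run(elem_matrix(ensemble), bond_matrix(ensemble),
                 effective_params(ensemble$material),
                 ensemble$box[1], ensemble$box[2], ensemble$strain,
                 protocol$gamma0, protocol$omega, protocol$dt,
                 protocol$n_cycles_total, protocol$samples_per_cycle)
  if (!res$ok)
    stop(sprintf(
      "oscillation unstable (energy divergence) at amplitude gamma0 = %g",
      protocol$gamma0))
  s <- res$samples
  period <- 2 * pi / protocol$omega
  cycle <- pmin(floor(s[, 1] / period * (1 + 1e-12)) + 1L,
                protocol$n_cycles_total)
  out <- data.frame(time = s[, 1], strain = s[, 2], sxx = s[, 3],
                    sxy = s[, 4], syy = s[, 5],
                    cycle = as.integer(cycle),
                    measure = cycle > protocol$n_cycles_discard)
  attr(out, "gamma0") <- protocol$gamma0
  attr(out, "omega") <- protocol$omega
  attr(out, "dt") <- res$dt
  attr(out, "n_cycles_discard") <- protocol$n_cycles_discard
  attr(out, "cap_excess") <- res$cap_excess
  attr(out, "stiff_warnings") <- res$stiff_warnings
  out
}

#' Symmetric virial stress tensor of the current configuration
#'
#' \deqn{\sigma = \frac{1}{A}\sum_{pairs} \mathrm{sym}(r_{ij} \otimes F_{ij})
#'   + \frac{1}{A}\sum_i m_i\, \mathrm{sym}(v'_i \otimes v'_i)}
#' with minimum-image branch vectors, the force transmitted across each pair,
#' and the non-affine (fluctuation) velocities \eqn{v'}. The convention is
#' tension-positive: a pair stretched along x contributes
#' \eqn{\sigma_{xx} = +F d / A}. The pair term is symmetrized, so
#' \eqn{\sigma_{xy} = \sigma_{yx}} exactly even with tangential forces; set
#' `symmetrize = FALSE` to inspect the raw (unsymmetrized) pair tensor.
#'
#' @param ensemble a `dem_ensemble`.
#' @param forces optional result of [total_forces()] for the current
#'   configuration (recomputed when omitted).
#' @param strain_rate boundary strain rate defining the affine field for the
#'   fluctuation velocities.
#' @param symmetrize if `FALSE`, return the unsymmetrized pair tensor.
#' @return symmetric 2x2 stress tensor.
#' @export
measure_stress <- function(ensemble, forces = NULL,
                           strain_rate = ensemble$strain_rate,
                           symmetrize = TRUE) {
  if (is.null(forces))
    forces <- total_forces(ensemble, strain_rate = strain_rate)
  A <- ensemble$box[1] * ensemble$box[2]
  sig <- forces$sigma_pairs
  if (!symmetrize && nrow(forces$pairs) > 0) {
    # rebuild unsymmetrized pair tensor from the pair table
    p <- forces$pairs
    e <- ensemble$elements
    sxx <- 0; sxy <- 0; syx <- 0; syy <- 0
    Lx <- ensemble$box[1]; Ly <- ensemble$box[2]; g <- ensemble$strain
    for (k in seq_len(nrow(p))) {
      i <- p$i[k]; j <- p$j[k]
      bx <- e$x[i] - e$x[j]; by <- e$y[i] - e$y[j]
      nimg <- round(by / Ly)
      by <- by - nimg * Ly; bx <- bx - nimg * g * Ly
      bx <- bx - Lx * round(bx / Lx)
      sxx <- sxx + bx * p$fx_on_j[k]; sxy <- sxy + bx * p$fy_on_j[k]
      syx <- syx + by * p$fx_on_j[k]; syy <- syy + by * p$fy_on_j[k]
    }
    sig <- matrix(c(sxx, syx, sxy, syy), 2, 2) / A
  }
  e <- ensemble$elements
  vpx <- e$vx - strain_rate * (e$y - ensemble$box[2] / 2)
  vpy <- e$vy
  kin <- matrix(c(sum(e$m * vpx * vpx), sum(e$m * vpx * vpy),
                  sum(e$m * vpx * vpy), sum(e$m * vpy * vpy)), 2, 2) / A
  sig + kin
}
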