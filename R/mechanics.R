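#' Normal contact force law
#'
#' Central elastic/dissipative force between two overlapping elements. With
#' the linear law the elastic part is Hookean in the overlap; the stiffening
#' law `kn * delta / (1 - delta/delta_max)` diverges as the overlap approaches
#' `delta_max`, emulating densification of a porous element under compression.
#' The total (elastic + dashpot) force is floored at zero: an unbonded contact
#' transmits no tension. For `delta >= delta_max` the stiffening law is capped
#' at a large finite value (integrator guard) with a warning.
#'
#' @param delta overlap `r_i + r_j - distance`; `<= 0` means no contact.
#' @param v_n relative normal approach speed (positive when approaching).
#' @param params a [material_params()] object.
#' @return signed scalar force along the contact normal (repulsion positive).
#' @export
normal_force <- function(delta, v_n = 0, params = material_params()) {
  if (delta <= 0) return(0)
  eff <- effective_params(params)
  fe <- if (eff$law == 0L) {
    eff$kn * delta
  } else {
    xf <- delta / eff$dmax
    if (xf >= 0.99) {
      warning("overlap ", signif(delta, 4), " at or beyond delta_max = ",
              eff$dmax, "; stiffening force capped")
      99 * eff$kn * eff$dmax
    } else {
      eff$kn * delta / (1 - xf)
    }
  }
  max(0, fe + eff$eta * v_n)
}

#' Tangential (Coulomb-capped) friction update
#'
#' Cundall-Strack tangential spring with Coulomb cap: the accumulated
#' tangential stretch grows with the relative surface velocity; the trial
#' force `kt * xi` is capped at `mu * Fn` and the spring is rescaled onto the
#' cap when slipping. With `mu = 0` the tangential force is exactly zero.
#'
#' @param xi accumulated tangential spring stretch.
#' @param v_t relative tangential surface velocity at the contact.
#' @param dt time step.
#' @param Fn current (non-negative) normal force.
#' @param params a [material_params()] object.
#' @return list with `force` (signed tangential force), updated `xi`, and
#'   logical `slipping`.
#' @export
tangential_update <- function(xi, v_t, dt, Fn, params = material_params()) {
  stopifnot(Fn >= 0, dt > 0)
  eff <- effective_params(params)
  if (eff$mu == 0 || eff$kt == 0)
    return(list(force = 0, xi = 0, slipping = FALSE))
  xi <- xi + v_t * dt
  trial <- eff$kt * xi
  cap <- eff$mu * Fn
  if (abs(trial) > cap) {
    force <- sign(trial) * cap
    list(force = force, xi = force / eff$kt, slipping = TRUE)
  } else {
    list(force = trial, xi = xi, slipping = FALSE)
  }
}

#' Permanent bond force
#'
#' Central linear spring active in both tension and compression:
#' `k_bond * E * (rest_length - distance)` along the pair normal (repulsion
#' positive). Bonds are permanent; the stiffness scales with the constituent
#' stiffness multiplier `E`.
#'
#' @param bond list or one-row data frame with `rest_length` and `k_bond`.
#' @param current_distance center distance, `> 0`.
#' @param E stiffness multiplier.
#' @return signed scalar force along the pair normal.
#' @export
bond_force <- function(bond, current_distance, E = 1) {
  stopifnot(current_distance > 0)
  E * bond$k_bond * (bond$rest_length - current_distance)
}

#' Total pairwise forces and torques on an ensemble
#'
#' One exact (all-pairs) force evaluation: contact normal forces, tangential
#' friction with spring memory, and permanent bond forces. Bonded pairs use
#' the bond spring only (no contact normal law on top); tangential friction
#' stays active while the surfaces overlap, capped by the overlap-based
#' interfacial normal load. The pairwise sum obeys
#' Newton's third law, so total force vanishes to round-off.
#'
#' @param ensemble a `dem_ensemble`.
#' @param contact_states data frame `i, j, xi` of tangential spring stretches
#'   carried into this evaluation for unbonded contacts (missing pairs start
#'   at zero; bonded-pair tangential memory is internal to time-stepped runs).
#' @param dt time step used to advance the tangential springs.
#' @param strain_rate boundary strain rate (corrects image velocities).
#' @return list with `force` (n x 2), `torque` (n), per-pair table `pairs`
#'   (`i, j, delta, nx, ny, fn, ft, fx_on_j, fy_on_j, xi, bonded`), the
#'   pairwise virial tensor `sigma_pairs`, and `cap_excess`, the maximum of
#'   `|Ft| - mu*Fn` over all contacts (never above round-off).
#' @export
total_forces <- function(ensemble, contact_states = NULL, dt = 0.05,
                         strain_rate = ensemble$strain_rate) {
  st <- if (is.null(contact_states) || nrow(contact_states) == 0) {
    matrix(numeric(0), ncol = 3)
  } else {
    as.matrix(contact_states[, c("i", "j", "xi")])
  }
  res <- dem_forces(elem_matrix(ensemble), bond_matrix(ensemble),
                    effective_params(ensemble$material),
                    ensemble$box[1], ensemble$box[2], ensemble$strain,
                    st, dt, strain_rate)
  p <- res$pairs
  colnames(p) <- c("i", "j", "delta", "nx", "ny", "fn", "ft",
                   "fx_on_j", "fy_on_j", "xi", "bonded")
  list(force = res$force, torque = as.numeric(res$torque),
       pairs = as.data.frame(p), sigma_pairs = res$sigma_pairs,
       cap_excess = res$cap_excess)
}
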