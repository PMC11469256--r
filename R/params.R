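#' Material parameters for the discrete-element model
#'
#' All quantities are nondimensional: lengths in units of the mean small-element
#' diameter \eqn{L_0}, masses in units of the small-element mass \eqn{M_0}, and
#' times in units of \eqn{T_0 = \sqrt{M_0/k_{n,\mathrm{ref}}}} with the
#' reference normal stiffness \code{kn = 1}. The constituent stiffness
#' multiplier \code{E} scales every spring constant (normal, tangential, bond)
#' and every damping coefficient jointly, so that the quasi-static stress
#' response is proportional to \code{E}.
#'
#' @param kn normal contact spring constant (reference scale, before `E`).
#' @param kt tangential spring constant; defaults to `kn/2`, a common granular
#'   choice.
#' @param mu Coulomb friction coefficient, `>= 0`.
#' @param E constituent Young's-modulus multiplier applied to `kn`, `kt`, bond
#'   stiffness and damping.
#' @param eta_scale pair dashpot per unit normal stiffness, in units of
#'   \eqn{T_0}. The default 0.84 gives a restitution coefficient of about 0.1
#'   for a reference small-element pair: heavily damped, quasi-static
#'   rheometry.
#' @param compression_law `"linear"` (Hookean overlap) or `"stiffening"`
#'   (`kn * delta / (1 - delta/delta_max)`, diverging as the overlap approaches
#'   `delta_max`; emulates densification of a porous element).
#' @param delta_max overlap scale of the stiffening law; must not exceed the
#'   smallest radius.
#' @param drag weak background drag (per unit `E`) toward the affine shear
#'   field; removes rigid-body drift. Much smaller than the contact damping.
#' @return an object of class `material_params`.
#' @export
material_params <- function(kn = 1, kt = kn / 2, mu = 0.3, E = 1,
                            eta_scale = 0.84,
                            compression_law = c("linear", "stiffening"),
                            delta_max = 0.3, drag = 0.05) {
  compression_law <- match.arg(compression_law)
  stopifnot(kn > 0, kt >= 0, mu >= 0, E > 0, eta_scale >= 0, drag >= 0)
  if (compression_law == "stiffening" && !(delta_max > 0))
    stop("delta_max must be positive for the stiffening law")
  structure(list(kn = kn, kt = kt, mu = mu, E = E, eta_scale = eta_scale,
                 compression_law = compression_law, delta_max = delta_max,
                 drag = drag),
            class = "material_params")
}

# Effective (E-scaled) parameter list handed to the compiled core.
effective_params <- function(mat) {
  kn_eff <- mat$kn * mat$E
  list(kn = kn_eff,
       kt = mat$kt * mat$E,
       mu = mat$mu,
       eta = mat$eta_scale * kn_eff,
       drag = mat$drag * mat$E,
       law = if (mat$compression_law == "stiffening") 1L else 0L,
       dmax = mat$delta_max)
}

#' Oscillatory shear protocol
#'
#' Strain-controlled drive \eqn{\gamma(t) = \gamma_0 \sin(\omega t)}. The time
#' step is adjusted downward so that a cycle is an exact multiple of 64 steps,
#' giving 64 stress samples per cycle. The defaults keep the drive quasi-static
#' (\eqn{\omega T_0 \le 0.05}) and the integration stable
#' (\eqn{dt \le 0.1 T_0}).
#'
#' @param gamma0 strain amplitude (dimensionless).
#' @param omega angular frequency in units of \eqn{1/T_0}.
#' @param n_cycles_total total number of oscillation cycles.
#' @param n_cycles_discard initial transient cycles excluded from the moduli.
#' @param dt target integration time step in units of \eqn{T_0}.
#' @return an object of class `shear_protocol`.
#' @export
shear_protocol <- function(gamma0 = 0.01, omega = 0.05, n_cycles_total = 6,
                           n_cycles_discard = 2, dt = 0.05) {
  stopifnot(gamma0 >= 0, omega > 0, dt > 0,
            n_cycles_discard < n_cycles_total, n_cycles_total >= 1)
  if (dt > 0.1)
    stop("dt exceeds the stability bound 0.1*sqrt(M0/kn)")
  if (omega > 0.05)
    stop("omega exceeds the quasi-static bound 0.05/sqrt(M0/kn)")
  structure(list(gamma0 = gamma0, omega = omega,
                 n_cycles_total = as.integer(n_cycles_total),
                 n_cycles_discard = as.integer(n_cycles_discard),
                 dt = dt, samples_per_cycle = 64L),
            class = "shear_protocol")
}

#' Scenario specification for the four prototype geometries
#'
#' The four canonical microstructures: a dense suspension of un-bonded
#' frictional spheres; a bulk network with every contacting pair cross-linked;
#' compact irregular particles with all intra-particle contacts cross-linked;
#' and loosely cross-linked porous particles that keep free (frictional)
#' contact interfaces inside each particle.
#'
#' @param kind one of `"frictional_spheres"`, `"bulk_crosslinked"`,
#'   `"dense_irregular"`, `"loose_porous"`.
#' @param n_elements number of discrete elements.
#' @param phi target area fraction.
#' @param mu Coulomb friction coefficient.
#' @param E constituent stiffness multiplier.
#' @param particles_target number of super-particles for the irregular kinds.
#' @param internal_bond_fraction fraction `p` of intra-particle contacts that
#'   receive a permanent cross-link (`loose_porous`); forced to 1 for
#'   `dense_irregular` and 0 for `frictional_spheres`.
#' @param size_ratio bidisperse 50/50 radius ratio.
#' @param compression_law,delta_max see [material_params()].
#' @param seed integer seed controlling packing, partition and bond sampling.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("frictional_spheres", "bulk_crosslinked",
                                   "dense_irregular", "loose_porous"),
                          n_elements = 400, phi = 0.90, mu = 0.3, E = 1,
                          particles_target = 25, internal_bond_fraction = 0.3,
                          size_ratio = 1.4,
                          compression_law = "linear", delta_max = 0.3,
                          seed = 1) {
  kind <- match.arg(kind)
  if (kind == "frictional_spheres") internal_bond_fraction <- 0
  if (kind == "dense_irregular") internal_bond_fraction <- 1
  stopifnot(n_elements >= 1, phi > 0, phi < 1,
            internal_bond_fraction >= 0, internal_bond_fraction <= 1)
  if (kind %in% c("dense_irregular", "loose_porous"))
    stopifnot(particles_target >= 1, particles_target <= n_elements)
  structure(list(kind = kind, n_elements = as.integer(n_elements), phi = phi,
                 mu = mu, E = E, particles_target = as.integer(particles_target),
                 internal_bond_fraction = internal_bond_fraction,
                 size_ratio = size_ratio, compression_law = compression_law,
                 delta_max = delta_max, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$kind, "\n")
  cat(sprintf("  n = %d elements, phi = %g, mu = %g, E = %g, seed = %d\n",
              x$n_elements, x$phi, x$mu, x$E, x$seed))
  if (x$kind %in% c("dense_irregular", "loose_porous"))
    cat(sprintf("  particles_target = %d, internal_bond_fraction = %g\n",
                x$particles_target, x$internal_bond_fraction))
  if (x$compression_law != "linear")
    cat(sprintf("  compression law: %s (delta_max = %g)\n",
                x$compression_law, x$delta_max))
  invisible(x)
}

fmt_num <- function(v) {
  if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v) else as.character(v)
}

#' Read and write scenario configuration files
#'
#' Flat YAML files describing a scenario plus (optionally) the shear protocol
#' and amplitude grid. Numeric values are written with full double precision so
#' a write/read round trip is bit exact.
#'
#' @param path file path.
#' @param config a named list (or `scenario_spec`) of configuration values.
#' @return `read_config` returns a named list; `write_config` returns `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kind)) stop("config is missing the 'kind' field")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  lines <- character(0)
  for (nm in names(config)) {
    v <- config[[nm]]
    if (length(v) == 1) {
      lines <- c(lines, paste0(nm, ": ", fmt_num(v)))
    } else {
      lines <- c(lines, paste0(nm, ": [", paste(vapply(v, fmt_num, ""),
                                                collapse = ", "), "]"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

config_to_spec <- function(cfg) {
  scenario_spec(kind = cfg$kind,
                n_elements = cfg$n_elements %||% 400,
                phi = cfg$phi %||% 0.90,
                mu = cfg$mu %||% 0.3,
                E = cfg$E %||% 1,
                particles_target = cfg$particles_target %||% 25,
                internal_bond_fraction = cfg$internal_bond_fraction %||% 0.3,
                size_ratio = cfg$size_ratio %||% 1.4,
                compression_law = cfg$compression_law %||% "linear",
                delta_max = cfg$delta_max %||% 0.3,
                seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
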