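#' Assemble one of the four canonical scenarios
#'
#' Builds the seeded packing and lays bonds according to the scenario kind:
#' `frictional_spheres` (no bonds), `bulk_crosslinked` (every contacting pair
#' bonded), `dense_irregular` (partition into super-particles, all
#' intra-particle contacts bonded), `loose_porous` (partition, seeded fraction
#' `p` of intra-particle contacts bonded, free contact interfaces retained).
#' Deterministic given the scenario seed.
#'
#' @param spec a [scenario_spec()].
#' @return a `dem_ensemble` ready for [run_oscillation()].
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  mat <- material_params(mu = spec$mu, E = spec$E,
                         compression_law = spec$compression_law,
                         delta_max = spec$delta_max)
  ens <- generate_packing(spec$n_elements, size_ratio = spec$size_ratio,
                          phi_target = spec$phi, seed = spec$seed,
                          material = mat)
  ens$meta$kind <- spec$kind
  if (spec$kind == "frictional_spheres") {
    return(ens)
  }
  if (spec$kind == "bulk_crosslinked") {
    ens$bonds <- create_bonds(ens, mode = "bulk_all")
    return(ens)
  }
  ens$assignment <- partition_particles(ens, spec$particles_target,
                                        seed = spec$seed)
  if (spec$kind == "dense_irregular") {
    ens$bonds <- create_bonds(ens, ens$assignment, mode = "intra_all")
  } else {
    ens$bonds <- create_bonds(ens, ens$assignment, mode = "intra_fraction",
                              p = spec$internal_bond_fraction, seed = spec$seed)
  }
  ens
}

#' Storage and loss moduli from a stress/strain time series
#'
#' First-harmonic Fourier projection of the shear stress onto the imposed
#' strain phase over the measurement cycles:
#' \deqn{G' = \frac{2}{\gamma_0 T_m}\int \sigma_{xy} \sin(\omega t)\,dt,\qquad
#'       G'' = \frac{2}{\gamma_0 T_m}\int \sigma_{xy} \cos(\omega t)\,dt}
#' evaluated by the trapezoid rule on the uniformly sampled series (exact to
#' round-off for pure first-harmonic signals sampled 64 times per cycle over
#' whole periods).
#'
#' @param samples data frame from [run_oscillation()], or a numeric time
#'   vector.
#' @param stress_xy,omega,gamma0 when `samples` is a bare time vector, supply
#'   the shear stress series, the angular frequency and the strain amplitude.
#' @param measure_only use only samples flagged as measurement cycles
#'   (ignored for bare vectors).
#' @return named vector `c(Gp, Gpp)`.
#' @export
extract_moduli <- function(samples, stress_xy = NULL, omega = NULL,
                           gamma0 = NULL, measure_only = TRUE) {
  if (is.data.frame(samples)) {
    omega <- omega %||% attr(samples, "omega")
    gamma0 <- gamma0 %||% attr(samples, "gamma0")
    keep <- if (measure_only && "measure" %in% names(samples)) {
      # include the boundary sample shared with the last discard cycle so the
      # window spans whole periods
      first <- match(TRUE, samples$measure)
      seq.int(max(1L, first - 1L), nrow(samples))
    } else {
      seq_len(nrow(samples))
    }
    tt <- samples$time[keep]
    ss <- samples$sxy[keep]
  } else {
    tt <- samples
    ss <- stress_xy
  }
  if (is.null(omega) || is.null(gamma0))
    stop("omega and gamma0 are required")
  if (gamma0 == 0)
    stop("moduli are undefined at zero strain amplitude")
  Tm <- tt[length(tt)] - tt[1]
  trap <- function(y) {
    n <- length(y)
    sum((y[-1] + y[-n]) / 2 * diff(tt))
  }
  Gp <- 2 / (gamma0 * Tm) * trap(ss * sin(omega * tt))
  Gpp <- 2 / (gamma0 * Tm) * trap(ss * cos(omega * tt))
  c(Gp = Gp, Gpp = Gpp)
}

#' Amplitude sweep: the in silico rheometer
#'
#' For each strain amplitude a fresh copy of the scenario ensemble is driven
#' through the oscillation protocol (independent sweeps, no history carried
#' between amplitudes, mirroring fresh-sample amplitude sweeps on a
#' laboratory rheometer) and the first-harmonic moduli are extracted from the
#' measurement cycles. The stress amplitude is reported as
#' \eqn{\tau_0 = \gamma_0 |G^*|}.
#'
#' @param spec a [scenario_spec()], or a prebuilt `dem_ensemble`.
#' @param amplitudes strictly increasing strain amplitudes (default: 10
#'   log-spaced points from 0.5% to 300%).
#' @param protocol a [shear_protocol()] template; its `gamma0` is replaced per
#'   amplitude.
#' @param label scenario label stored with the curve.
#' @return an object of class `rheology_curve`: data frame with columns
#'   `gamma0, tau0, Gp, Gpp, scenario, seed`, ordered by `gamma0`. Unstable
#'   amplitudes truncate the curve with a warning.
#' @export
amplitude_sweep <- function(spec, amplitudes = default_amplitudes(),
                            protocol = shear_protocol(),
                            label = NULL) {
  stopifnot(length(amplitudes) >= 1, all(diff(amplitudes) > 0),
            all(amplitudes > 0))
  if (inherits(spec, "scenario_spec")) {
    ens <- build_scenario(spec)
    label <- label %||% spec$kind
    seed <- spec$seed
  } else {
    stopifnot(inherits(spec, "dem_ensemble"))
    ens <- spec
    label <- label %||% (ens$meta$kind %||% "custom")
    seed <- ens$meta$seed %||% NA_integer_
  }
  rows <- vector("list", length(amplitudes))
  for (k in seq_along(amplitudes)) {
    pr <- protocol
    pr$gamma0 <- amplitudes[k]
    samples <- tryCatch(run_oscillation(ens, pr), error = identity)
    if (inherits(samples, "error")) {
      warning("sweep truncated: ", conditionMessage(samples))
      break
    }
    g <- extract_moduli(samples)
    rows[[k]] <- data.frame(gamma0 = amplitudes[k],
                            tau0 = amplitudes[k] * sqrt(sum(g^2)),
                            Gp = g[["Gp"]], Gpp = g[["Gpp"]])
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no stable amplitude in the sweep")
  out <- do.call(rbind, rows)
  out$scenario <- label
  out$seed <- seed
  rheology_curve(out)
}

#' Default log-spaced amplitude grid, 0.5% to 300% strain
#' @param n number of amplitudes.
#' @export
default_amplitudes <- function(n = 10) {
  exp(seq(log(0.005), log(3), length.out = n))
}

#' Construct a rheology curve
#'
#' Validates and orders an amplitude-indexed table of moduli. `tau0` is
#' reconstructed as \eqn{\gamma_0 |G^*|} when absent.
#'
#' @param df data frame with columns `gamma0, Gp, Gpp` and optionally `tau0`,
#'   `scenario`, `seed`.
#' @return a `rheology_curve` (data frame subclass) ordered by `gamma0`.
#' @export
rheology_curve <- function(df) {
  need <- c("gamma0", "Gp", "Gpp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gamma0))
    stop("duplicate gamma0 values in curve")
  df <- df[order(df$gamma0), , drop = FALSE]
  if (is.null(df$tau0)) df$tau0 <- df$gamma0 * sqrt(df$Gp^2 + df$Gpp^2)
  if (is.null(df$scenario)) df$scenario <- "unlabeled"
  if (is.null(df$seed)) df$seed <- NA_integer_
  df <- df[, c("gamma0", "tau0", "Gp", "Gpp", "scenario", "seed")]
  rownames(df) <- NULL
  class(df) <- c("rheology_curve", "data.frame")
  df
}

#' @export
print.rheology_curve <- function(x, ...) {
  cat(sprintf("rheology_curve: %d amplitudes (%.3g%% to %.3g%% strain), scenario '%s'\n",
              nrow(x), 100 * min(x$gamma0), 100 * max(x$gamma0),
              x$scenario[1]))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Plot an amplitude sweep (log-log moduli vs strain amplitude)
#' @param x a `rheology_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rheology_curve <- function(x, ...) {
  graphics::plot(x$gamma0, x$Gp, log = "xy", type = "b", pch = 16,
                 xlab = expression(gamma[0]), ylab = "modulus",
                 ylim = range(c(x$Gp, x$Gpp)[c(x$Gp, x$Gpp) > 0]), ...)
  graphics::lines(x$gamma0, x$Gpp, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomleft", legend = c("G'", "G''"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
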