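#' Low-strain plateau modulus
#'
#' Mean storage modulus over the largest low-amplitude prefix of the curve in
#' which consecutive `G'` values differ by less than `tol` (relative). `NA`
#' (undefined) when no such prefix of length >= 2 exists, e.g. when the curve
#' collapses from its first point.
#'
#' @param curve a `rheology_curve`.
#' @param tol relative tolerance between consecutive plateau points.
#' @return scalar `G0'` or `NA`.
#' @export
low_strain_plateau <- function(curve, tol = 0.10) {
  if (nrow(curve) == 0) stop("empty curve")
  gp <- curve$Gp
  len <- 1L
  while (len < length(gp) &&
         abs(gp[len + 1] - gp[len]) < tol * abs(gp[len])) {
    len <- len + 1L
  }
  if (len < 2L) return(NA_real_)
  mean(gp[seq_len(len)])
}

#' Yield point from the G' = G'' crossover
#'
#' Locates the first bracketing pair where the response turns from solid-like
#' to liquid-like (`G' - G''` changes sign from positive to negative) and
#' interpolates `log(G'/G'')` linearly against `log(gamma0)` to zero; the
#' yield stress is interpolated on the same log abscissa from `tau0`. A point
#' with exactly `G' = G''` is itself the crossover. Liquid-to-solid crossings
#' (which arise at vanishing amplitudes where the stress signal falls below
#' the measurement floor) are not yield points. Curves that stay solid-like
#' (`G' > G''` everywhere) have no yield in range: both values are `NA`.
#'
#' @param curve a `rheology_curve`.
#' @return list with `yield_strain`, `yield_stress` (both `NA` when no
#'   crossover exists).
#' @export
find_yield <- function(curve) {
  gp <- curve$Gp; gpp <- curve$Gpp; g0 <- curve$gamma0; tau <- curve$tau0
  diffv <- gp - gpp
  eq <- which(diffv == 0)
  if (length(eq) > 0) {
    k <- eq[1]
    return(list(yield_strain = g0[k], yield_stress = tau[k]))
  }
  n <- length(diffv)
  cross <- which(diffv[-n] > 0 & diffv[-1] < 0)
  if (length(cross) == 0)
    return(list(yield_strain = NA_real_, yield_stress = NA_real_))
  k <- cross[1]
  lr1 <- log(gp[k] / gpp[k]); lr2 <- log(gp[k + 1] / gpp[k + 1])
  lg1 <- log(g0[k]); lg2 <- log(g0[k + 1])
  f <- lr1 / (lr1 - lr2)
  lgy <- lg1 + f * (lg2 - lg1)
  lty <- log(tau[k]) + f * (log(tau[k + 1]) - log(tau[k]))
  list(yield_strain = exp(lgy), yield_stress = exp(lty))
}

#' Elastic softening transition
#'
#' The softening onset is the first amplitude where `G'` falls below
#' `onset_frac * G0'` while the response is still solid-like (`G' > G''`) —
#' elastic softening, distinct from yielding. A transition additionally
#' requires the softened solid state to persist: at least two consecutive
#' solid-like amplitudes from the onset (a single grid point passed on the
#' way to yield is not a soft plateau). The soft plateau is the mean `G'`
#' over the longest such run whose consecutive ratios vary by less than
#' `plateau_tol`; the soft plateau stress is `tau0` at that run's midpoint.
#' All values are `NA` (flagged) when no amplitude satisfies the onset
#' condition before the crossover — the criterion separating softening from
#' non-softening materials.
#'
#' @param curve a `rheology_curve`.
#' @param onset_frac onset threshold as a fraction of `G0'`.
#' @param plateau_tol relative tolerance between consecutive plateau points.
#' @param G0p precomputed plateau modulus (otherwise [low_strain_plateau()]).
#' @return list with `softening_onset_strain`, `softening_depth`
#'   (`G0'/soft-plateau G'`, >= 1), `soft_plateau_Gp`, `soft_plateau_stress`.
#' @export
detect_softening <- function(curve, onset_frac = 0.8, plateau_tol = 0.2,
                             G0p = NULL) {
  none <- list(softening_onset_strain = NA_real_, softening_depth = NA_real_,
               soft_plateau_Gp = NA_real_, soft_plateau_stress = NA_real_)
  G0p <- G0p %||% low_strain_plateau(curve)
  if (is.na(G0p)) return(none)
  gp <- curve$Gp; gpp <- curve$Gpp
  onset_idx <- which(gp < onset_frac * G0p & gp > gpp)
  if (length(onset_idx) == 0) return(none)
  onset_idx <- onset_idx[1]
  # contiguous solid-like stretch from the onset
  solid <- onset_idx
  k <- onset_idx
  while (k + 1 <= nrow(curve) && gp[k + 1] > gpp[k + 1]) {
    k <- k + 1
    solid <- c(solid, k)
  }
  # the softened solid state must persist over at least two amplitudes
  if (length(solid) < 2) return(none)
  # longest run with consecutive ratio within plateau_tol (first on ties)
  best <- c(onset_idx, onset_idx)
  run_start <- solid[1]
  for (q in seq_along(solid)) {
    if (q > 1) {
      ok <- abs(gp[solid[q]] / gp[solid[q - 1]] - 1) < plateau_tol
      if (!ok) run_start <- solid[q]
    }
    if (solid[q] - run_start > best[2] - best[1])
      best <- c(run_start, solid[q])
  }
  idx <- seq.int(best[1], best[2])
  plateau <- mean(gp[idx])
  mid <- idx[ceiling(length(idx) / 2)]
  list(softening_onset_strain = curve$gamma0[onset_idx],
       softening_depth = G0p / plateau,
       soft_plateau_Gp = plateau,
       soft_plateau_stress = curve$tau0[mid])
}

#' Full rheological signature of an amplitude sweep
#'
#' Combines the low-strain plateau, the elastic softening transition and the
#' yield point into the characteristic feature set of an injectable granular
#' material, including the relative yield stress \eqn{\tau_y / G_0'} (the
#' balance between injectability and stiffness; a Hookean solid yielding at
#' 100% strain has value 1). Undefined features are `NA`.
#'
#' @param curve a `rheology_curve`.
#' @param onset_frac,plateau_tol,prefix_tol thresholds passed through to the
#'   component extractors.
#' @return object of class `rheo_features`.
#' @export
extract_features <- function(curve, onset_frac = 0.8, plateau_tol = 0.2,
                             prefix_tol = 0.1) {
  stopifnot(inherits(curve, "rheology_curve") || is.data.frame(curve))
  if (nrow(curve) < 4)
    warning("curve has fewer than 4 points; features may be undefined")
  G0p <- low_strain_plateau(curve, tol = prefix_tol)
  soft <- detect_softening(curve, onset_frac, plateau_tol, G0p = G0p)
  yld <- find_yield(curve)
  rel <- if (!is.na(G0p) && !is.na(yld$yield_stress))
    yld$yield_stress / G0p else NA_real_
  structure(c(list(G0p = G0p), soft, yld,
              list(relative_yield_stress = rel,
                   scenario = curve$scenario[1], seed = curve$seed[1])),
            class = "rheo_features")
}

#' @export
print.rheo_features <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4g", v)
  cat("Rheological features (scenario '", x$scenario, "'):\n", sep = "")
  cat("  G0' (low-strain plateau):     ", fmt(x$G0p), "\n")
  cat("  softening onset strain:       ", fmt(x$softening_onset_strain), "\n")
  cat("  softening depth (G0'/Gsoft'): ", fmt(x$softening_depth), "\n")
  cat("  soft plateau stress:          ", fmt(x$soft_plateau_stress), "\n")
  cat("  yield strain (G'=G''):        ", fmt(x$yield_strain), "\n")
  cat("  yield stress:                 ", fmt(x$yield_stress), "\n")
  cat("  relative yield stress:        ", fmt(x$relative_yield_stress), "\n")
  invisible(x)
}

#' Normalize a sweep to its low-strain plateau (master curve)
#'
#' Divides `G'`, `G''` and `tau0` by the low-strain plateau modulus `G0'`, so
#' the normalized storage modulus tends to 1 at small amplitude. Master curves
#' from stiffness-scaled copies of the same geometry collapse onto each other.
#'
#' @param curve a `rheology_curve`.
#' @return normalized `rheology_curve`.
#' @export
normalize_master <- function(curve) {
  G0p <- low_strain_plateau(curve)
  if (is.na(G0p))
    stop("low-strain plateau undefined; cannot normalize")
  curve$Gp <- curve$Gp / G0p
  curve$Gpp <- curve$Gpp / G0p
  curve$tau0 <- curve$tau0 / G0p
  curve
}

#' Read / write amplitude-sweep tables
#'
#' CSV schema `gamma0,tau0,Gp,Gpp` (plus optional `scenario`, `seed`);
#' `tau0` is reconstructed as \eqn{\gamma_0|G^*|} when absent. Rows are sorted
#' by `gamma0` on read; values round-trip losslessly (better than 12
#' significant digits). Missing required columns, non-numeric cells and
#' duplicate amplitudes raise descriptive errors.
#'
#' @param path CSV file path.
#' @param curve a `rheology_curve`.
#' @return `read_sweep` returns a `rheology_curve`; `write_sweep` returns
#'   `path` invisibly.
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) stop("sweep table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gamma0", "Gp", "Gpp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sweep table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  for (nm in intersect(c("gamma0", "tau0", "Gp", "Gpp"), names(df))) {
    v <- df[[nm]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v))
      stop("non-numeric values in column '", nm, "' of ", path)
    df[[nm]] <- v
  }
  if (anyDuplicated(df$gamma0))
    stop("duplicate gamma0 values in ", path)
  rheology_curve(df)
}

#' @rdname read_sweep
#' @export
write_sweep <- function(curve, path) {
  write_table_full(as.data.frame(curve), path)
  invisible(path)
}

#' Synthetic Hookean (linear-elastic) amplitude sweep
#'
#' Idealized reference curve: constant storage modulus `G0` and negligible
#' loss below the imposed yield strain, with `G' = G'' = G0/sqrt(2)` exactly
#' at yield so that the complex modulus (and hence `tau0 = gamma0 |G*|`)
#' follows the Hookean line through the yield point: the relative yield
#' stress equals the yield strain.
#'
#' @param G0 plateau modulus.
#' @param yield_strain imposed yield strain.
#' @param n_below points below yield.
#' @return a `rheology_curve`.
#' @export
hookean_curve <- function(G0 = 1, yield_strain = 1, n_below = 6) {
  g_below <- exp(seq(log(yield_strain / 100), log(yield_strain / 1.5),
                     length.out = n_below))
  g <- c(g_below, yield_strain, yield_strain * 2)
  Gp <- c(rep(G0, n_below), G0 / sqrt(2), G0 / 10)
  Gpp <- c(rep(0, n_below), G0 / sqrt(2), G0 / 2)
  # tau0 follows the Hookean line tau = G0 * gamma exactly up to yield
  tau0 <- G0 * g
  tau0[length(g)] <- g[length(g)] * sqrt(Gp[length(g)]^2 + Gpp[length(g)]^2)
  rheology_curve(data.frame(gamma0 = g, Gp = Gp, Gpp = Gpp, tau0 = tau0,
                            scenario = "hookean", seed = NA_integer_))
}
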