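#' Kinetic parameters of a glucose-limited retentostat
#'
#' Bundles the constants of the maintenance-energy biomass balance
#' \deqn{dC_x/dt = Y_{sx}^{max} (D (C_{s,in} - C_s) - m_s C_x)}
#' where biomass accumulates until the glucose feed only covers maintenance.
#'
#' @param D dilution rate (h^-1).
#' @param Cs_in glucose concentration in the feed (g L^-1).
#' @param Cs residual glucose concentration (g L^-1); effectively zero in
#'   glucose-limited cultures (three orders of magnitude below the feed).
#' @param ms_mmol maintenance coefficient (mmol glucose g biomass^-1 h^-1).
#' @param Ysx_max maximum biomass yield on glucose (g g^-1).
#' @param Cx0 biomass concentration when the retentostat is started
#'   (g L^-1). Defaults to the steady state of a chemostat run at mu = D,
#'   see [chemostat_steady_state_biomass()].
#' @param mw_glucose molar mass of glucose (g mmol^-1).
#'
#' @return An object of class `retentostat_params`: the arguments plus
#'   `ms_g`, the maintenance coefficient converted to g glucose g^-1 h^-1.
#' @examples
#' p <- retentostat_params()
#' p$ms_g            # 0.50 mmol g-1 h-1 as g g-1 h-1
#' @export
retentostat_params <- function(D = 0.025, Cs_in = 50, Cs = 0,
                               ms_mmol = 0.50, Ysx_max = 0.097,
                               Cx0 = NULL, mw_glucose = 0.18016) {
  vals <- c(D = D, Cs_in = Cs_in, Cs = Cs, ms_mmol = ms_mmol,
            Ysx_max = Ysx_max, mw_glucose = mw_glucose)
  if (any(!is.finite(vals)))
    stop("retentostat parameters must be finite numbers")
  if (D <= 0 || Cs_in <= 0 || ms_mmol <= 0 || Ysx_max <= 0 || mw_glucose <= 0)
    stop("retentostat parameters must be positive (Cs may be zero)")
  if (Cs < 0) stop("residual glucose Cs must be >= 0")
  if (Cs >= Cs_in) stop("residual glucose Cs must be below the feed Cs_in")
  p <- list(D = D, Cs_in = Cs_in, Cs = Cs, ms_mmol = ms_mmol,
            Ysx_max = Ysx_max, mw_glucose = mw_glucose,
            ms_g = ms_mmol * mw_glucose)
  p$Cx0 <- if (is.null(Cx0)) chemostat_steady_state_biomass_(p) else Cx0
  if (!is.finite(p$Cx0) || p$Cx0 <= 0) stop("Cx0 must be a positive number")
  class(p) <- "retentostat_params"
  p
}

#' @export
print.retentostat_params <- function(x, ...) {
  cat("Retentostat parameters\n")
  cat(sprintf("  D        %.4g h-1\n", x$D))
  cat(sprintf("  Cs_in    %.4g g/L   Cs %.4g g/L\n", x$Cs_in, x$Cs))
  cat(sprintf("  ms       %.4g mmol/g/h (%.4g g/g/h)\n", x$ms_mmol, x$ms_g))
  cat(sprintf("  Ysx_max  %.4g g/g\n", x$Ysx_max))
  cat(sprintf("  Cx0      %.4g g/L\n", x$Cx0))
  invisible(x)
}

chemostat_steady_state_biomass_ <- function(params) {
  params$Cs_in / (1 / params$Ysx_max + params$ms_g / params$D)
}

#' Steady-state biomass of a chemostat at mu = D
#'
#' Maintenance-corrected (Pirt) yield: 1/Y_obs = 1/Ysx_max + ms/D, so the
#' steady-state biomass is Cs_in * Y_obs. Used to initialise the
#' retentostat trajectory at the biomass of the parent chemostat.
#'
#' @param params a [retentostat_params()] object.
#' @return biomass concentration (g L^-1).
#' @export
chemostat_steady_state_biomass <- function(params) {
  stopifnot(inherits(params, "retentostat_params"))
  if (params$D <= 0) stop("chemostat steady state requires D > 0")
  chemostat_steady_state_biomass_(params)
}

#' Ideal retentostat biomass accumulation
#'
#' Closed-form solution of the maintenance-energy biomass balance:
#' \deqn{C_x(t) = C_{x,\infty} + (C_{x,0} - C_{x,\infty}) e^{-k t}}
#' with \eqn{k = m_s Y_{sx}^{max}} and
#' \eqn{C_{x,\infty} = D (C_{s,in} - C_s)/m_s}, the steady state at which
#' the entire glucose supply is spent on maintenance and growth ceases.
#'
#' @param params a [retentostat_params()] object.
#' @param t time since the switch to retentostat mode (h); vectorised.
#' @return biomass concentration (g L^-1) at each `t`.
#' @examples
#' p <- retentostat_params()
#' predict_biomass(p, c(0, 528))
#' @export
predict_biomass <- function(params, t) {
  stopifnot(inherits(params, "retentostat_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  k <- params$ms_g * params$Ysx_max
  Cx_inf <- params$D * (params$Cs_in - params$Cs) / params$ms_g
  decay <- exp(-k * t)
  params$Cx0 * decay + Cx_inf * (1 - decay)  # exact at t = 0
}

#' Biomass / viability time series
#'
#' @param time_h sampling times (h), strictly increasing.
#' @param cx_total total biomass concentration (g L^-1), viable plus
#'   non-viable cells.
#' @param viability viable fraction in `[0, 1]` at each time.
#' @return a `biomass_series` object (data.frame backed).
#' @export
biomass_series <- function(time_h, cx_total, viability = rep(1, length(time_h))) {
  if (length(time_h) != length(cx_total) || length(time_h) != length(viability))
    stop("time_h, cx_total and viability must have equal length")
  if (any(!is.finite(time_h)) || any(diff(time_h) <= 0))
    stop("time_h must be finite and strictly increasing")
  if (any(!is.finite(cx_total)) || any(cx_total <= 0))
    stop("cx_total must be finite and positive")
  if (any(viability < 0 | viability > 1))
    stop("viability must lie in [0, 1]")
  structure(data.frame(time_h = time_h, cx_total = cx_total,
                       viability = viability),
            class = c("biomass_series", "data.frame"))
}

#' Read a biomass series from a delimited file
#'
#' Expects a header with columns `time_h`, `cx_total_g_per_l` and
#' `viability_fraction` (TSV or CSV, sniffed from the extension).
#'
#' @param path file path.
#' @return a [biomass_series()] object.
#' @export
read_biomass_series <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("time_h", "cx_total_g_per_l", "viability_fraction")
  if (!all(need %in% names(d)))
    stop("biomass series file must have columns: ", paste(need, collapse = ", "))
  biomass_series(d$time_h, d$cx_total_g_per_l, d$viability_fraction)
}

#' Fit A e^(B t) + C to a biomass trajectory
#'
#' Least-squares fit of the three-parameter exponential that shares the
#' shape of the ideal retentostat solution, by derivative-free simplex
#' (Nelder-Mead) search on the sum of squared residuals. Initialisation:
#' C0 = 1.05 max(Cx), A0 = Cx(0) - C0, B0 = -0.01 h^-1; the search is
#' restarted once from its own optimum to polish the simplex.
#'
#' @param series a [biomass_series()] object (>= 4 points).
#' @param init optional numeric `c(A, B, C)` starting values.
#' @return a `biomass_fit` list: `A`, `B`, `C`, `sse`, `converged`, `n`.
#'   Non-convergence is reported through `converged = FALSE` with the
#'   best values found, not an error.
#' @export
fit_biomass_curve <- function(series, init = NULL) {
  stopifnot(inherits(series, "biomass_series"))
  t <- series$time_h; y <- series$cx_total
  if (length(t) < 4)
    stop("fit_biomass_curve needs at least 4 time points, got ", length(t))
  if (is.null(init)) {
    C0 <- max(y) * 1.05
    init <- c(A = y[1] - C0, B = -0.01, C = C0)
  }
  sse_fun <- function(p) {
    r <- y - (p[1] * exp(p[2] * t) + p[3])
    s <- sum(r * r)
    if (!is.finite(s)) 1e300 else s
  }
  ctrl <- list(maxit = 10000, reltol = 1e-12, abstol = 1e-14)
  o <- stats::optim(init, sse_fun, method = "Nelder-Mead", control = ctrl)
  o2 <- stats::optim(o$par, sse_fun, method = "Nelder-Mead", control = ctrl)
  if (o2$value < o$value) o <- o2
  structure(list(A = unname(o$par[1]), B = unname(o$par[2]),
                 C = unname(o$par[3]), sse = o$value,
                 converged = (o$convergence == 0), n = length(t)),
            class = "biomass_fit")
}

#' @export
print.biomass_fit <- function(x, ...) {
  cat(sprintf("Cx(t) = %.4g * exp(%.4g t) + %.4g   (sse %.3g, %s)\n",
              x$A, x$B, x$C, x$sse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Viability-corrected specific growth rate
#'
#' Differentiates the fitted biomass curve analytically
#' (dCx/dt = A B e^(B t)) and attributes all biomass formation to the
#' viable cells: mu(t) = (dCx/dt) / (viability(t) * Cx_fit(t)), assuming
#' no lysis. Viability between sampling points is linearly interpolated.
#' Negative fitted derivatives (which would violate the no-lysis
#' assumption) are clipped to mu = 0 and flagged.
#'
#' @param fit a [fit_biomass_curve()] result.
#' @param series the [biomass_series()] carrying viability measurements.
#' @param times evaluation times (h); defaults to the series' times.
#' @return data.frame with `time_h`, `cx_fit`, `dcx_dt`, `viability`,
#'   `cx_viable`, `mu`, `clipped`.
#' @export
specific_growth_rate <- function(fit, series, times = series$time_h) {
  stopifnot(inherits(fit, "biomass_fit"), inherits(series, "biomass_series"))
  if (!fit$converged)
    warning("biomass fit did not converge; growth rates may be unreliable")
  v <- stats::approx(series$time_h, series$viability, xout = times,
                     rule = 2)$y
  if (any(v == 0))
    stop("viability is zero at t = ",
         paste(times[v == 0], collapse = ", "), " h; mu undefined there")
  cx_fit <- fit$A * exp(fit$B * times) + fit$C
  dcx <- fit$A * fit$B * exp(fit$B * times)
  mu <- dcx / (v * cx_fit)
  clipped <- mu < 0
  mu[clipped] <- 0
  if (any(clipped))
    warning("negative fitted dCx/dt at ", sum(clipped),
            " time point(s); mu clipped to 0")
  data.frame(time_h = times, cx_fit = cx_fit, dcx_dt = dcx, viability = v,
             cx_viable = v * cx_fit, mu = mu, clipped = clipped)
}

#' Doubling time from a specific growth rate
#'
#' ln(2)/mu; `+Inf` for mu <= 0 (a non-growing culture never doubles).
#'
#' @param mu specific growth rate (h^-1); vectorised.
#' @return doubling time in hours.
#' @examples
#' doubling_time(0.005)  # ~139 h
#' @export
doubling_time <- function(mu) {
  out <- rep(Inf, length(mu))
  pos <- is.finite(mu) & mu > 0
  out[pos] <- log(2) / mu[pos]
  out
}

#' Partition glucose consumption between maintenance and growth
#'
#' Maintenance demand is ms * Cx_viable and growth demand is
#' mu * Cx_viable / Ysx_max (both in g glucose L^-1 h^-1); the fractions
#' are each flux over their sum.
#'
#' @param params a [retentostat_params()] object.
#' @param Cx_viable viable biomass concentration (g L^-1); vectorised.
#' @param mu specific growth rate (h^-1), same length as `Cx_viable`.
#' @return data.frame with `maintenance_flux`, `growth_flux`,
#'   `frac_maintenance`, `frac_growth`, `degenerate` (TRUE where both
#'   fluxes are zero and the fractions are undefined, reported as NA).
#' @export
glucose_partition <- function(params, Cx_viable, mu) {
  stopifnot(inherits(params, "retentostat_params"))
  if (any(Cx_viable < 0) || any(mu < 0))
    stop("Cx_viable and mu must be >= 0")
  maint <- params$ms_g * Cx_viable
  growth <- mu * Cx_viable / params$Ysx_max
  tot <- maint + growth
  degenerate <- tot == 0
  fm <- ifelse(degenerate, NA_real_, maint / tot)
  data.frame(maintenance_flux = maint, growth_flux = growth,
             frac_maintenance = fm, frac_growth = 1 - fm,
             degenerate = degenerate)
}

#' Residual glucose under Monod-type uptake kinetics
#'
#' The specific glucose consumption rate implied by a growth rate,
#' qs = mu/(Ysx_max * mw) + ms (mmol g^-1 h^-1), is inverted through the
#' Monod relation qs = qs_max * Cs/(Ks + Cs), giving
#' Cs = Ks * qs/(qs_max - qs). Because maintenance keeps qs positive as
#' mu tends to 0, the residual glucose levels off at a positive floor
#' instead of vanishing. The default kinetic constants keep the relation
#' unsaturated up to mu = 0.2 h^-1 and place the near-zero-growth floor
#' at ~0.13 mM.
#'
#' @param mu specific growth rate (h^-1); vectorised.
#' @param qs_max maximum specific glucose uptake rate (mmol g^-1 h^-1).
#' @param Ks Monod affinity constant (mM).
#' @param params a [retentostat_params()] supplying ms and Ysx_max.
#' @return residual glucose concentration (mM).
#' @export
residual_glucose_monod <- function(mu, qs_max = 15, Ks = 3.8,
                                   params = retentostat_params()) {
  stopifnot(inherits(params, "retentostat_params"))
  if (any(mu < 0)) stop("mu must be >= 0")
  qs <- mu / (params$Ysx_max * params$mw_glucose) + params$ms_mmol
  if (any(qs >= qs_max))
    stop("implied glucose uptake reaches qs_max; Monod relation saturates")
  Ks * qs / (qs_max - qs)
}
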