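# Two-state stability-curve thermodynamics with a constant-dCp
# Gibbs-Helmholtz free energy of unfolding. All internal temperatures are
# kelvin; user-facing reports are Celsius.

#' Gas constant in kcal mol-1 K-1
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

#' Celsius offset (K at 0 degrees C)
#' @export
KELVIN_OFFSET <- 273.15

# Floor of the physical temperature range: below this the constant-dCp
# model is declared non-physical rather than extrapolated.
COLD_SEARCH_FLOOR_K <- 200

#' Two-state stability parameters
#'
#' Bundle of the three parameters that define a constant-heat-capacity
#' stability curve: the van't Hoff unfolding enthalpy at the melting
#' temperature, the heat-capacity change of unfolding, and the melting
#' (heat-denaturation) temperature itself.
#'
#' @param dH unfolding enthalpy at `Tm`, kcal mol-1 (must be > 0)
#' @param dCp heat-capacity change of unfolding, kcal K-1 mol-1 (> 0)
#' @param Tm heat-denaturation midpoint. Interpreted in kelvin unless
#'   `celsius = TRUE`.
#' @param celsius logical; if `TRUE`, `Tm` is given in degrees Celsius.
#' @return An object of class `stability_params` (a named list with
#'   elements `dH`, `dCp`, `Tm` in kelvin).
#' @examples
#' wt <- stability_params(dH = 19.2, dCp = 2.24, Tm = 33.6, celsius = TRUE)
#' delta_g(298.15, wt)
#' @export
stability_params <- function(dH, dCp, Tm, celsius = FALSE) {
  if (celsius) Tm <- Tm + KELVIN_OFFSET
  stopifnot(is.numeric(dH), is.numeric(dCp), is.numeric(Tm),
            length(dH) == 1L, length(dCp) == 1L, length(Tm) == 1L)
  if (!is.finite(dH) || dH <= 0) stop("dH must be a positive finite number (kcal/mol)")
  if (!is.finite(dCp) || dCp <= 0) stop("dCp must be a positive finite number (kcal/K/mol)")
  if (!is.finite(Tm) || Tm <= 0) stop("Tm must be positive (kelvin)")
  structure(list(dH = dH, dCp = dCp, Tm = Tm), class = "stability_params")
}

#' @export
print.stability_params <- function(x, ...) {
  cat(sprintf(
    "Two-state stability parameters:\n  dH  = %.3g kcal/mol\n  dCp = %.3g kcal/K/mol\n  Tm  = %.2f K (%.2f C)\n",
    x$dH, x$dCp, x$Tm, x$Tm - KELVIN_OFFSET))
  invisible(x)
}

as_stability_params <- function(x) {
  if (inherits(x, "stability_params")) return(x)
  stability_params(x[["dH"]], x[["dCp"]], x[["Tm"]])
}

#' Free energy of unfolding at temperature T
#'
#' Evaluates the constant-dCp stability curve
#' \deqn{\Delta G(T) = \Delta H (1 - T/T_m) + \Delta C_p [(T - T_m) - T \ln(T/T_m)]}
#' Positive values mean the folded state is favoured. The curve is concave
#' in T, zero at `Tm`, and (when dCp is large enough) zero again at a lower
#' cold-denaturation temperature.
#'
#' @param T temperature(s) in kelvin; must be > 0.
#' @param params a [stability_params] object.
#' @return unfolding free energy in kcal mol-1, same length as `T`.
#' @export
delta_g <- function(T, params) {
  params <- as_stability_params(params)
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be positive (kelvin)")
  params$dH * (1 - T / params$Tm) +
    params$dCp * ((T - params$Tm) - T * log(T / params$Tm))
}

#' Unfolding entropy at the melting temperature
#'
#' At the midpoint \eqn{\Delta G(T_m) = 0}, so \eqn{\Delta S = \Delta H / T_m}.
#'
#' @inheritParams delta_g
#' @return entropy change of unfolding in kcal K-1 mol-1.
#' @export
entropy_at_tm <- function(params) {
  params <- as_stability_params(params)
  params$dH / params$Tm
}

#' Temperature of maximal stability
#'
#' The stability curve peaks where its derivative vanishes, which has the
#' closed form \eqn{T_s = T_m \exp(-\Delta H / (\Delta C_p T_m))}. At `Ts`
#' the unfolding entropy is zero and the protein is maximally stable;
#' `Tc < Ts < Tm` whenever a cold transition exists.
#'
#' @inheritParams delta_g
#' @return `Ts` in kelvin.
#' @export
max_stability_temp <- function(params) {
  params <- as_stability_params(params)
  params$Tm * exp(-params$dH / (params$dCp * params$Tm))
}

#' Cold-denaturation temperature
#'
#' Finds the low-temperature zero of the stability curve by bracketed
#' (Brent) root-finding on `[floor, Ts]`. The solver is deterministic and
#' the returned root satisfies |dG(Tc)| < 1e-9 kcal/mol. An unbracketed
#' Newton step is deliberately avoided: the curve is nearly flat around its
#' maximum.
#'
#' @inheritParams delta_g
#' @param floor lower end of the search bracket in kelvin; below this the
#'   constant-dCp model is considered non-physical (default 200 K).
#' @return `Tc` in kelvin.
#' @export
cold_denaturation_temp <- function(params, floor = COLD_SEARCH_FLOOR_K) {
  params <- as_stability_params(params)
  Ts <- max_stability_temp(params)
  if (Ts <= floor)
    stop("no cold transition in range: stability maximum below the search floor",
         call. = FALSE)
  g_ts <- delta_g(Ts, params)
  if (g_ts <= 0)
    stop("invalid parameters: stability curve never positive (dG(Ts) <= 0)",
         call. = FALSE)
  g_lo <- delta_g(floor, params)
  if (g_lo >= 0)
    stop("no cold transition in range: dG does not change sign above the 200 K floor",
         call. = FALSE)
  r <- stats::uniroot(function(T) delta_g(T, params), lower = floor, upper = Ts,
                      f.lower = g_lo, f.upper = g_ts, tol = 1e-12)
  # polish with bisection until the FUNCTION value meets tolerance
  Tc <- r$root
  lo <- floor; hi <- Ts
  while (abs(delta_g(Tc, params)) > 1e-9 && (hi - lo) > 1e-13 * Ts) {
    if (delta_g(Tc, params) < 0) lo <- Tc else hi <- Tc
    Tc <- (lo + hi) / 2
  }
  Tc
}

#' Equilibrium fraction folded
#'
#' Two-state folded population \eqn{f = K/(1+K)} with
#' \eqn{K = \exp(\Delta G_{unf}/(RT))} the folded/unfolded ratio. Equal to
#' 0.5 exactly at both zeros of the stability curve and above 0.5 strictly
#' between them.
#'
#' @inheritParams delta_g
#' @return fraction folded in (0, 1), same length as `T`.
#' @export
fraction_folded <- function(T, params) {
  params <- as_stability_params(params)
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be positive (kelvin)")
  # logistic form is overflow-safe for large |dG|
  stats::plogis(delta_g(T, params) / (GAS_CONSTANT_KCAL * T))
}

#' Full stability report for one parameter set
#'
#' Derives every downstream quantity of the stability curve from the
#' (dH, dCp, Tm) triple: unfolding entropy, temperature of maximal
#' stability, cold-denaturation temperature and the folded percentage at
#' `Ts`. Temperatures are reported in Celsius. If no cold root exists above
#' the 200 K floor, `Tc_C` is `NA` and a warning is raised.
#'
#' @inheritParams delta_g
#' @param construct optional label for the protein construct.
#' @return A one-row `data.frame` with columns `construct`, `dH_kcal_mol`,
#'   `dCp_kcal_K_mol`, `dS_kcal_K_mol`, `Tm_C`, `Tc_C`, `Ts_C`,
#'   `folding_pct`.
#' @examples
#' stability_report(stability_params(19.2, 2.24, 33.6, celsius = TRUE), "Wt")
#' @export
stability_report <- function(params, construct = NA_character_) {
  params <- as_stability_params(params)
  Ts <- max_stability_temp(params)
  Tc <- tryCatch(cold_denaturation_temp(params), error = function(e) {
    if (grepl("no cold transition", conditionMessage(e))) {
      warning("no cold transition above 200 K for construct '", construct,
              "'; Tc reported as NA", call. = FALSE)
      NA_real_
    } else stop(e)
  })
  data.frame(
    construct = construct,
    dH_kcal_mol = params$dH,
    dCp_kcal_K_mol = params$dCp,
    dS_kcal_K_mol = entropy_at_tm(params),
    Tm_C = params$Tm - KELVIN_OFFSET,
    Tc_C = Tc - KELVIN_OFFSET,
    Ts_C = Ts - KELVIN_OFFSET,
    folding_pct = 100 * fraction_folded(Ts, params),
    stringsAsFactors = FALSE
  )
}

#' Write a stability report table to CSV and/or JSON
#'
#' @param report a `data.frame` as returned by [stability_report()] (rows
#'   may be stacked with `rbind`).
#' @param csv,json output paths; either may be `NULL` to skip.
#' @return the report, invisibly.
#' @export
write_stability_report <- function(report, csv = NULL, json = NULL) {
  stopifnot(is.data.frame(report))
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(report)
}

#' Reference thermodynamic parameters for yeast frataxin constructs
#'
#' Loads the bundled table of published (dH, dCp, Tm) triples for wild-type
#' Yfh1 and its three single charge-neutralising mutants (E89S, E112S,
#' E103S). Only the fitted inputs are bundled; every derived quantity (Tc,
#' dS, folded fraction) is recomputed by this package.
#'
#' @return `data.frame` with columns `construct`, `dH`, `dCp`, `Tm_C`.
#' @export
yfh1_reference_params <- function() {
  path <- system.file("extdata", "yfh1_params.csv", package = "coldcurve",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
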