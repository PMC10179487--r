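# Substrate scans, Michaelis-constant and turnover-number extraction, ROS
# flux reporting with unit conversion, oxidation-degree and tunnel-diode
# (monotonicity) diagnostics.

default_scan_grid <- function(substrate) {
  if (substrate %in% c("QH2", "Q")) {
    exp(seq(log(0.01), log(1e4), length.out = 25))
  } else {
    # dicarboxylates: up to 2 mM, the upper end of the physiological
    # fumarate/succinate range the model is exercised over (co-substrates
    # saturate at 1 mM)
    exp(seq(log(0.1), log(2e3), length.out = 25))
  }
}

#' Steady-state substrate scan
#'
#' Solves one steady state per grid point with the chosen substrate
#' clamped at each value, and extracts the saturation-curve summary
#' (Vmax, Km, plateau quality, monotonicity).  The operating mode is set
#' from the substrate: `QH2` scans run in reverse with free QH2 clamped
#' (free Q dynamic, drained by the recycling reaction); `Q` scans run
#' forward with free Q clamped; `fum`/`suc` scans run on a conserved
#' quinone pool (default total 500 uM) in reverse/forward operation.  The
#' co-substrate is clamped at `co_substrate` (default 1000 uM for the
#' dicarboxylate partner of a quinone scan; dicarboxylate scans keep the
#' preset quinone pool and clamp the product dicarboxylate at 0).
#'
#' @param params A [cii_parameters()] object (typically a `fig*` preset or
#'   a `kd_*` preset plus [set_keq1()]).
#' @param substrate One of `"QH2"`, `"Q"`, `"fum"`, `"suc"`.
#' @param grid Strictly increasing vector of >= 12 substrate
#'   concentrations (uM) spanning at least three decades; default 25
#'   log-spaced points over \[0.01, 1e4\] (quinones) or \[0.1, 1e4\]
#'   (dicarboxylates).
#' @param co_substrate Co-substrate clamp (uM), or `NULL` for the default.
#' @param q_total Quinone pool total for dicarboxylate scans (uM),
#'   default 500.
#' @param refine_km Refine the Km estimate by bisection with fresh
#'   steady-state solves (default TRUE).
#' @param ... Passed to [integrate_to_steady_state()].
#' @return A `cii_michaelis_fit` object: `curve` (data frame with columns
#'   `substrate`, `rate`), `vmax`, `km`, `plateau`, `monotonic`,
#'   `substrate_name`, `params`.
#' @export
substrate_scan <- function(params, substrate = c("QH2", "Q", "fum", "suc"),
                           grid = NULL, co_substrate = NULL, q_total = 500,
                           refine_km = TRUE, ...) {
  substrate <- match.arg(substrate)
  if (is.null(grid)) grid <- default_scan_grid(substrate)
  if (length(grid) < 12 || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with at least 12 points")
  if (log10(max(grid) / min(grid)) < 3)
    stop("grid must span at least three decades")
  params <- configure_scan_mode(params, substrate, co_substrate, q_total)
  clamp_key <- substrate
  solve_at <- function(s) {
    p <- modify_parameters(params,
                           list(clamp = stats::setNames(s, clamp_key)))
    r <- integrate_to_steady_state(p, ...)
    if (!startsWith(r$status, "converged"))
      stop("steady state did not converge at ", substrate, " = ", s,
           " uM (residual ", signif(r$residual, 3), ")")
    r$net_flux
  }
  rates <- vapply(grid, solve_at, numeric(1))
  curve <- data.frame(substrate = grid, rate = rates)
  fit <- michaelis_from_curve(curve,
                              refine = if (refine_km) solve_at else NULL)
  fit$substrate_name <- substrate
  fit$params <- params
  fit
}

# Set clamping/pool mode appropriate for a scanned substrate.
configure_scan_mode <- function(params, substrate, co_substrate, q_total) {
  upd <- switch(substrate,
    QH2 = list(mode = list(direction = "reverse", quinone = "clamped-QH2"),
               clamp = c(fum = if (is.null(co_substrate)) 1000
                         else co_substrate)),
    Q = list(mode = list(direction = "forward", quinone = "clamped-Q"),
             clamp = c(suc = if (is.null(co_substrate)) 1000
                       else co_substrate)),
    fum = list(mode = list(direction = "reverse",
                           quinone = "conserved-pool"),
               pools = c(q = q_total),
               clamp = c(suc = if (is.null(co_substrate)) 0
                         else co_substrate)),
    suc = list(mode = list(direction = "forward",
                           quinone = "conserved-pool"),
               pools = c(q = q_total),
               clamp = c(fum = if (is.null(co_substrate)) 0
                         else co_substrate))
  )
  modify_parameters(params, upd)
}

#' Extract Vmax and Km from a saturation curve
#'
#' When the curve has genuinely saturated within the scanned range
#' (relative rate change below 0.5% over the top decade of substrate),
#' `Vmax` is the rate at the top grid point and `Km` is the substrate
#' concentration at which the rate crosses `Vmax/2`, located by monotone
#' log-linear interpolation between the bracketing grid points and, when a
#' `refine` callback is supplied, polished by bisection on fresh
#' steady-state solves to 0.5% precision.
#'
#' When the plateau check fails, the top grid point underestimates the
#' true plateau and a grid-dependent `Vmax` would distort `Km`; the
#' saturation parameters are instead estimated by a nonlinear
#' least-squares fit of the Michaelis equation `v = Vmax*S/(Km+S)` over
#' the scanned points, and the `plateau` flag is set to `FALSE` to mark
#' the extrapolation.
#'
#' For a non-monotonic curve (see [tunnel_diode_check()]) `Km` is
#' undefined (`NA`) and flagged.
#'
#' @param curve Data frame with columns `substrate` and `rate` (uM, uM/s),
#'   substrate strictly increasing.
#' @param refine Optional function `function(substrate) rate` used for
#'   bisection refinement.
#' @return A `cii_michaelis_fit` object (see [substrate_scan()]).
#' @examples
#' s <- exp(seq(log(0.01), log(1e4), length.out = 25))
#' fit <- michaelis_from_curve(data.frame(substrate = s,
#'                                        rate = 100 * s / (5 + s)))
#' c(fit$vmax, fit$km)  # ~ (100, 5)
#' @export
michaelis_from_curve <- function(curve, refine = NULL) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 12,
            all(diff(curve$substrate) > 0))
  s <- curve$substrate; v <- curve$rate
  n <- length(s)
  vmax <- v[n]
  verdict <- tunnel_diode_check(curve)
  monotonic <- verdict$monotonic
  top_decade <- s >= s[n] / 10
  plateau <- monotonic && vmax > 0 &&
    (max(v[top_decade]) - min(v[top_decade])) / vmax < 0.005
  km <- NA_real_
  if (plateau) {
    half <- vmax / 2
    i <- findInterval(half, v)   # v non-decreasing (within tolerance)
    if (i >= 1 && i < n) {
      lo <- s[i]; hi <- s[i + 1]
      # log-linear interpolation seed
      km <- exp(log(lo) + (half - v[i]) / (v[i + 1] - v[i]) *
                  (log(hi) - log(lo)))
      if (!is.null(refine)) {
        for (it in 1:40) {
          if (hi / lo - 1 < 0.005) break
          mid <- sqrt(lo * hi)
          if (refine(mid) < half) lo <- mid else hi <- mid
        }
        km <- sqrt(lo * hi)
      }
    }
  } else if (monotonic && vmax > 0) {
    km0 <- s[which.min(abs(v - vmax / 2))]
    fit <- tryCatch(
      stats::nls(rate ~ Vm * substrate / (Km + substrate), data = curve,
                 start = list(Vm = vmax, Km = km0),
                 algorithm = "port", lower = c(Vm = 0, Km = 0)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      vmax <- unname(co[["Vm"]])
      km <- unname(co[["Km"]])
      if (km < min(s) || km > max(s)) km <- NA_real_
    }
  }
  structure(list(curve = curve, vmax = vmax, km = km, plateau = plateau,
                 monotonic = monotonic, peak = verdict$peak,
                 drop = verdict$drop),
            class = "cii_michaelis_fit")
}

#' Turnover number
#'
#' `kcat = Vmax / CII_tot`, the maximal rate per enzyme.
#'
#' @param vmax Maximal rate (uM/s).
#' @param cii_tot Total enzyme concentration (uM), default 235.
#' @return kcat in 1/s.
#' @export
turnover_number <- function(vmax, cii_tot = 235) {
  stopifnot(cii_tot > 0)
  vmax / cii_tot
}

#' Monotonicity (tunnel-diode) verdict for a rate curve
#'
#' A tunnel-diode (negative-resistance) characteristic would show the rate
#' dropping as the driving substrate concentration keeps increasing.  The
#' curve is called monotonic if every successive rate difference is above
#' `-0.001 * max(rate)` (a 0.1%-of-Vmax noise allowance); otherwise the
#' peak location and the fractional drop from peak to the curve's final
#' value are reported.
#'
#' @param curve Data frame with columns `substrate`, `rate` (>= 12 rows).
#' @return List with `monotonic` (logical), `peak` (substrate at the
#'   maximal rate; `NA` when monotonic) and `drop` (fractional rate drop
#'   after the peak; 0 when monotonic).
#' @export
tunnel_diode_check <- function(curve) {
  stopifnot(nrow(curve) >= 12)
  v <- curve$rate
  tol <- 0.001 * max(v, 0)
  if (all(diff(v) >= -tol))
    return(list(monotonic = TRUE, peak = NA_real_, drop = 0))
  ipk <- which.max(v)
  list(monotonic = FALSE, peak = curve$substrate[ipk],
       drop = (v[ipk] - v[length(v)]) / v[ipk])
}

#' Oxidation degree of the [3Fe-4S] cluster
#'
#' Fraction of the \[3Fe-4S\] pool in the oxidized state,
#' `[3Fe-4S] / ([3Fe-4S] + [3Fe-4S]-)`.  A tunnel-diode drop in reverse
#' turnover would require this fraction to exceed ~0.99 at high driving
#' force; reporting it alongside scans makes the monotonicity verdict
#' interpretable.
#'
#' @param result A `cii_steady_state` object (or a full state vector).
#' @return Fraction in \[0, 1\].
#' @export
oxidation_degree_3fe4s <- function(result) {
  st <- if (inherits(result, "cii_steady_state")) result$state else result
  st[["fes3_ox"]] / (st[["fes3_ox"]] + st[["fes3_red"]])
}

#' ROS flux report at steady state
#'
#' Extracts the reactive-oxygen-species fluxes of a converged steady
#' state: H2O2 production by FADH2 (`V22`), superoxide production by FADH2
#' (`V23`), the FADH radical (`V24`), reduced \[3Fe-4S\] (`V25`) and the
#' bound semiquinone anion (`V26`), superoxide dismutation (`V27`) and
#' H2O2 efflux (`V28`).  The total ROS production rate is `V28`, which at
#' steady state equals `V22 + V27` (H2O2 balance); the per-site
#' superoxide attribution shares are `V23..V26` over their sum.
#'
#' @param result A `cii_steady_state` object.
#' @param params Parameter set (default: the result's own).
#' @param tolerance Relative tolerance on the steady-state H2O2 balance
#'   `|V28 - (V22 + V27)|` (default 1e-4).
#' @return A `cii_ros_report` object: data frame `rates` (uM/s and
#'   pmol/min/mg), `total` (uM/s), `total_pmol_min_mg`, and named
#'   `site_shares` summing to 1.
#' @export
ros_report <- function(result, params = result$params, tolerance = 1e-4) {
  v <- result$fluxes
  ids <- c("22", "23", "24", "25", "26", "27", "28")
  total <- v[["28"]]
  balance <- abs(v[["28"]] - (v[["22"]] + v[["27"]]))
  if (balance > tolerance * max(total, 1e-12))
    stop("H2O2 balance V28 = V22 + V27 violated (|diff| = ",
         signif(balance, 3), " uM/s); state is not at steady state")
  so <- v[c("23", "24", "25", "26")]
  shares <- if (sum(so) > 0) so / sum(so) else so * 0
  names(shares) <- c("FADH2", "FADHr", "fes3_red", "CII.Qsn")
  rates <- data.frame(
    reaction = ids,
    site = c("FADH2 (H2O2)", "FADH2 (O2.-)", "FADH. (O2.-)",
             "[3Fe-4S]- (O2.-)", "CII.Q.- (O2.-)",
             "dismutation", "H2O2 efflux"),
    rate_uM_s = as.numeric(v[ids]),
    rate_pmol_min_mg = convert_rate(as.numeric(v[ids])))
  structure(list(rates = rates, total = total,
                 total_pmol_min_mg = convert_rate(total),
                 site_shares = shares),
            class = "cii_ros_report")
}

#' @export
print.cii_ros_report <- function(x, ...) {
  cat("<cii_ros_report> total ROS rate:", signif(x$total, 4), "uM/s =",
      signif(x$total_pmol_min_mg, 4), "pmol/min/mg\n")
  print(x$rates, digits = 4)
  cat("superoxide site shares:\n")
  print(round(x$site_shares, 4))
  invisible(x)
}

#' Convert concentrations between bookkeeping bases
#'
#' The model's concentrations are referred to the inner-membrane volume.
#' Protein-normalized contents convert at 273 uM (mitochondrial-volume
#' basis) per nmol/mg of protein; membrane-volume concentrations are the
#' mitochondrial-volume values divided by the membrane/mitochondrial
#' volume fraction `w_imb = 0.24`.
#'
#' @param value Numeric value(s) to convert.
#' @param from,to One of `"nmol_per_mg"`, `"uM_mito"`, `"uM_membrane"`.
#' @param per_nmol_mg uM (mitochondrial volume) per nmol/mg (default 273).
#' @param w_imb Membrane/mitochondrial volume ratio (default 0.24).
#' @return Converted value(s).
#' @examples
#' convert_concentration(1, "nmol_per_mg", "uM_mito")       # 273
#' convert_concentration(0.209, "nmol_per_mg", "uM_membrane")  # ~237
#' @export
convert_concentration <- function(value, from, to, per_nmol_mg = 273,
                                  w_imb = 0.24) {
  bases <- c("nmol_per_mg", "uM_mito", "uM_membrane")
  if (!from %in% bases || !to %in% bases)
    stop("unknown basis; use one of: ", paste(bases, collapse = ", "))
  # to mitochondrial-volume uM
  x <- switch(from, nmol_per_mg = value * per_nmol_mg, uM_mito = value,
              uM_membrane = value * w_imb)
  switch(to, nmol_per_mg = x / per_nmol_mg, uM_mito = x,
         uM_membrane = x / w_imb)
}

#' Convert a matrix-basis rate to protein-normalized units
#'
#' Converts a rate in uM/s (mitochondrial-matrix volume basis) to
#' pmol/min/mg of mitochondrial protein:
#' `rate * 60 / 273 * 1000`.
#'
#' @param rate Rate(s) in uM/s, non-negative.
#' @param per_nmol_mg uM per nmol/mg (default 273).
#' @return Rate(s) in pmol/min/mg.
#' @examples
#' convert_rate(1)  # ~219.8
#' @export
convert_rate <- function(rate, per_nmol_mg = 273) {
  stopifnot(all(rate >= 0))
  rate * 60 / per_nmol_mg * 1000
}

#' @export
print.cii_michaelis_fit <- function(x, ...) {
  cat("<cii_michaelis_fit>",
      if (!is.null(x$substrate_name)) paste0("substrate: ",
                                             x$substrate_name) else "", "\n")
  cat("  Vmax =", signif(x$vmax, 6), "uM/s",
      if (!x$plateau) "(fitted plateau; curve not saturated in range)"
      else "", "\n")
  cat("  Km   =", if (is.na(x$km)) "undefined" else
    paste(signif(x$km, 4), "uM"), "\n")
  cat("  monotonic:", x$monotonic,
      if (!x$monotonic) sprintf(" (peak at %.3g uM, drop %.1f%%)",
                                x$peak, 100 * x$drop) else "", "\n")
  invisible(x)
}
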