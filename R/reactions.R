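# The reaction network: rate laws, reaction ids, and the stoichiometry
# matrix.  Reaction ids follow the field's conventional numbering for this
# scheme, including the lettered flavin-site variants (8a, 8b, 16a, 16b,
# 17a, 21a).

#' Reaction identifiers of the complex II network
#'
#' @return Character vector of all reaction ids in canonical order:
#'   `"1"`..`"9"` with `"8a"`, `"8b"` (first electron transfer),
#'   `"10"`..`"16b"` (second electron transfer), `"17"`..`"21a"`
#'   (flavin-site dicarboxylate chemistry), `"22"`..`"26"` (ROS bypass),
#'   `"27"` (superoxide dismutation), `"28"` (H2O2 efflux), `"29"`
#'   (quinone recycling in the inner membrane).
#' @export
reaction_ids <- function() {
  c("1", "2", "3", "4", "5", "6", "7", "8", "8a", "8b", "9",
    "10", "11", "12", "13", "14", "15", "16", "16a", "16b",
    "17", "17a", "18", "19", "20", "21", "21a",
    "22", "23", "24", "25", "26", "27", "28", "29")
}

# Reaction definitions.  Each entry: substrates and products as named
# stoichiometry vectors, and the rate-law type:
#   "rev" reversible mass action  V = k * (prod(sub) - prod(prod)/Keq)
#   "mm"  irreversible Michaelis-Menten (superoxide dismutation)
#   "irr" irreversible first order
# Reaction 29 (quinone recycling) regenerates the substrate quinone species
# consumed by net turnover; its direction therefore depends on the
# operating direction of the enzyme.
reaction_table <- function(params = NULL) {
  direction <- if (is.null(params)) "reverse" else params$mode$direction
  r <- list(
    "1"  = list(sub = c(CII = 1, QH2 = 1), prod = c(CII.QH2 = 1)),
    "2"  = list(sub = c(CII.QH2 = 1), prod = c(CII.QHm = 1, H = 1)),
    "3"  = list(sub = c(CII.QHm = 1, fes3_ox = 1),
                prod = c(CII.QHr = 1, fes3_red = 1)),
    "4"  = list(sub = c(CII.QHm = 1, b_ox = 1),
                prod = c(CII.QHr = 1, b_red = 1)),
    "5"  = list(sub = c(fes3_ox = 1, b_red = 1),
                prod = c(fes3_red = 1, b_ox = 1)),
    "6"  = list(sub = c(fes4_ox = 1, fes3_red = 1),
                prod = c(fes4_red = 1, fes3_ox = 1)),
    "7"  = list(sub = c(fes2_ox = 1, fes4_red = 1),
                prod = c(fes2_red = 1, fes4_ox = 1)),
    "8"  = list(sub = c(FAD = 1, fes2_red = 1, H = 1),
                prod = c(FADHr = 1, fes2_ox = 1)),
    "8a" = list(sub = c(FAD.fum = 1, fes2_red = 1, H = 1),
                prod = c(FADHr.fum = 1, fes2_ox = 1)),
    "8b" = list(sub = c(FAD.suc = 1, fes2_red = 1, H = 1),
                prod = c(FADHr.suc = 1, fes2_ox = 1)),
    "9"  = list(sub = c(CII.QHr = 1), prod = c(CII.Qsn = 1, H = 1)),
    "10" = list(sub = c(CII.Qsn = 1, fes3_ox = 1),
                prod = c(CII.Q = 1, fes3_red = 1)),
    "11" = list(sub = c(CII.Q = 1), prod = c(CII = 1, Q = 1)),
    "12" = list(sub = c(CII.Qsn = 1, b_ox = 1),
                prod = c(CII.Q = 1, b_red = 1)),
    "13" = list(sub = c(fes3_ox = 1, b_red = 1),
                prod = c(fes3_red = 1, b_ox = 1)),
    "14" = list(sub = c(fes4_ox = 1, fes3_red = 1),
                prod = c(fes4_red = 1, fes3_ox = 1)),
    "15" = list(sub = c(fes2_ox = 1, fes4_red = 1),
                prod = c(fes2_red = 1, fes4_ox = 1)),
    "16" = list(sub = c(FADHr = 1, fes2_red = 1, H = 1),
                prod = c(FADH2 = 1, fes2_ox = 1)),
    "16a" = list(sub = c(FADHr.fum = 1, fes2_red = 1, H = 1),
                 prod = c(FADH2.fum = 1, fes2_ox = 1)),
    "16b" = list(sub = c(FADHr.suc = 1, fes2_red = 1, H = 1),
                 prod = c(FADH2.suc = 1, fes2_ox = 1)),
    "17"  = list(sub = c(FADH2 = 1, fum = 1), prod = c(FADH2.fum = 1)),
    "17a" = list(sub = c(FADHr = 1, fum = 1), prod = c(FADHr.fum = 1)),
    "18"  = list(sub = c(FADH2.fum = 1), prod = c(FAD.suc = 1)),
    "19"  = list(sub = c(FAD.suc = 1), prod = c(FAD = 1, suc = 1)),
    "20"  = list(sub = c(FAD = 1, fum = 1), prod = c(FAD.fum = 1)),
    "21"  = list(sub = c(FADH2.suc = 1), prod = c(FADH2 = 1, suc = 1)),
    "21a" = list(sub = c(FADHr.suc = 1), prod = c(FADHr = 1, suc = 1)),
    "22" = list(sub = c(FADH2 = 1, O2 = 1), prod = c(FAD = 1, H2O2 = 1)),
    "23" = list(sub = c(FADH2 = 1, O2 = 1),
                prod = c(FADHr = 1, O2sn = 1, H = 1)),
    "24" = list(sub = c(FADHr = 1, O2 = 1),
                prod = c(FAD = 1, O2sn = 1, H = 1)),
    "25" = list(sub = c(fes3_red = 1, O2 = 1),
                prod = c(fes3_ox = 1, O2sn = 1)),
    "26" = list(sub = c(CII.Qsn = 1, O2 = 1),
                prod = c(CII.Q = 1, O2sn = 1)),
    "27" = list(sub = c(O2sn = 2, H = 2), prod = c(O2 = 1, H2O2 = 1),
                type = "mm"),
    "28" = list(sub = c(H2O2 = 1), prod = stats::setNames(numeric(0), character(0)),
                type = "irr"),
    "29" = if (direction == "reverse")
      list(sub = c(Q = 1, H = 2), prod = c(QH2 = 1), type = "irr",
           rate_species = "Q")
    else
      list(sub = c(QH2 = 1), prod = c(Q = 1, H = 2), type = "irr",
           rate_species = "QH2")
  )
  for (i in seq_along(r)) if (is.null(r[[i]]$type)) r[[i]]$type <- "rev"
  r[["27"]]$rate_species <- "O2sn"
  r[["28"]]$rate_species <- "H2O2"
  r
}

#' Stoichiometry matrix of the network
#'
#' Signed species-by-reaction incidence matrix of the full network,
#' transcribed from the written reaction equations (protons appear as
#' written even though they are clamped in simulations).
#'
#' @param params Optional [cii_parameters()] object; determines the
#'   direction of the quinone-recycling reaction 29 (`Q -> QH2` in reverse
#'   operation, `QH2 -> Q` in forward operation).  Default: reverse.
#' @return Integer matrix, 31 species rows x 35 reaction columns, with
#'   `dimnames` over [species_names()] and [reaction_ids()].
#' @export
stoichiometry_matrix <- function(params = NULL) {
  rx <- reaction_table(params)
  sp <- species_names()
  S <- matrix(0L, nrow = length(sp), ncol = length(rx),
              dimnames = list(sp, names(rx)))
  for (j in names(rx)) {
    for (s in names(rx[[j]]$sub))  S[s, j] <- S[s, j] - as.integer(rx[[j]]$sub[[s]])
    for (s in names(rx[[j]]$prod)) S[s, j] <- S[s, j] + as.integer(rx[[j]]$prod[[s]])
  }
  S
}

#' Evaluate all reaction rates at a state
#'
#' Computes the 35 reaction rates of the network: reversible mass action
#' `V = k * (prod substrates - prod products / Keq)` for the
#' electron-transfer and binding reactions (the proton always enters as
#' written, at its clamped concentration), Michaelis-Menten dismutation of
#' superoxide (`V27 = Vmax27 * O2sn / (Km27 + O2sn)`), and first-order
#' irreversible H2O2 efflux (28) and quinone recycling (29).
#'
#' @param state Named numeric state vector over [species_names()] (uM).
#' @param params A [cii_parameters()] object.
#' @return Named numeric vector of rates (uM/s) over [reaction_ids()],
#'   class `cii_fluxes`.
#' @examples
#' p <- cii_preset("table2_base")
#' v <- compute_fluxes(initial_state(p, "fully-oxidized"), p)
#' @export
compute_fluxes <- function(state, params) {
  if (any(!is.finite(state)) || any(state < 0))
    stop("state must be finite and non-negative")
  rx <- reaction_table(params)
  v <- stats::setNames(numeric(length(rx)), names(rx))
  k <- params$k
  keq <- params$keq
  for (id in names(rx)) {
    r <- rx[[id]]
    if (r$type == "rev") {
      fwd <- prod(state[names(r$sub)]^r$sub)
      bwd <- prod(state[names(r$prod)]^r$prod)
      v[id] <- k[[id]] * (fwd - bwd / keq[[id]])
    } else if (r$type == "mm") {
      s <- state[[r$rate_species]]
      v[id] <- params$vmax27 * s / (params$km27 + s)
    } else {
      v[id] <- k[[id]] * state[[r$rate_species]]
    }
    if (!is.finite(v[id]))
      stop("non-finite rate for reaction ", id,
           "; check state and parameters")
  }
  structure(v, class = c("cii_fluxes", "numeric"))
}

#' @export
print.cii_fluxes <- function(x, ...) {
  cat("<cii_fluxes> reaction rates (uM/s)\n")
  print(data.frame(reaction = names(unclass(x)), rate = as.numeric(x),
                   row.names = NULL), digits = 6)
  invisible(x)
}
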