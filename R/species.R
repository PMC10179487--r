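# Species catalogue, display labels, moiety (conserved-pool) structure, and
# state constructors for the complex II kinetic model.

#' Species names of the complex II model
#'
#' The model tracks 31 named species: the six occupancy states of the
#' quinone-binding (Qp) site, the oxidized/reduced pairs of the four
#' one-electron relay centers (the \[3Fe-4S\], \[4Fe-4S\] and \[2Fe-2S\]
#' iron-sulfur clusters and heme b), the nine flavin states (FAD, FADH
#' radical and FADH2, each free or bound to fumarate or succinate), and the
#' membrane/matrix metabolites (ubiquinone Q, ubiquinol QH2, fumarate,
#' succinate, O2, superoxide, H2O2 and matrix protons).
#'
#' Canonical names are ASCII-safe identifiers; [species_labels()] maps them
#' to the conventional biochemical notation used in I/O and printing.
#'
#' @return Character vector of the 31 canonical species names, in the
#'   model's fixed order.
#' @seealso [species_labels()], [conservation_totals()]
#' @export
species_names <- function() {
  c(
    # Qp-site occupancy states
    "CII", "CII.QH2", "CII.QHm", "CII.QHr", "CII.Qsn", "CII.Q",
    # one-electron relay centers, oxidized / reduced
    "fes3_ox", "fes3_red",   # [3Fe-4S] / [3Fe-4S]-
    "b_ox", "b_red",         # heme b / b-
    "fes4_ox", "fes4_red",   # [4Fe-4S] / [4Fe-4S]-
    "fes2_ox", "fes2_red",   # [2Fe-2S] / [2Fe-2S]-
    # flavin states
    "FAD", "FADHr", "FADH2",
    "FAD.fum", "FADHr.fum", "FADH2.fum",
    "FAD.suc", "FADHr.suc", "FADH2.suc",
    # membrane / matrix metabolites
    "Q", "QH2", "fum", "suc", "O2", "O2sn", "H2O2", "H"
  )
}

#' Display labels for model species
#'
#' Maps the canonical ASCII species names to the conventional notation
#' (e.g. `"CII.Qsn"` is the bound semiquinone anion `"CII.Q.-"`,
#' `"fes3_red"` is `"[3Fe-4S]-"`).
#'
#' @return Named character vector: names are canonical identifiers, values
#'   the display labels.
#' @export
species_labels <- function() {
  c(
    CII = "CII", CII.QH2 = "CII.QH2", CII.QHm = "CII.QH-",
    CII.QHr = "CII.QH.", CII.Qsn = "CII.Q.-", CII.Q = "CII.Q",
    fes3_ox = "[3Fe-4S]", fes3_red = "[3Fe-4S]-",
    b_ox = "b", b_red = "b-",
    fes4_ox = "[4Fe-4S]", fes4_red = "[4Fe-4S]-",
    fes2_ox = "[2Fe-2S]", fes2_red = "[2Fe-2S]-",
    FAD = "FAD", FADHr = "FADH.", FADH2 = "FADH2",
    FAD.fum = "FAD.fum", FADHr.fum = "FADH..fum", FADH2.fum = "FADH2.fum",
    FAD.suc = "FAD.suc", FADHr.suc = "FADH..suc", FADH2.suc = "FADH2.suc",
    Q = "Q", QH2 = "QH2", fum = "fum", suc = "suc",
    O2 = "O2", O2sn = "O2.-", H2O2 = "H2O2", H = "H+"
  )
}

# Members of the seven conserved moieties.  The quinone pool counts every
# quinone-carrying species: free Q and QH2 plus the five occupied Qp-site
# states (free CII carries no quinone).
moiety_members <- function() {
  list(
    qsite  = c("CII", "CII.QH2", "CII.QHm", "CII.QHr", "CII.Qsn", "CII.Q"),
    fes3   = c("fes3_ox", "fes3_red"),
    b      = c("b_ox", "b_red"),
    fes4   = c("fes4_ox", "fes4_red"),
    fes2   = c("fes2_ox", "fes2_red"),
    flavin = c("FAD", "FADHr", "FADH2", "FAD.fum", "FADHr.fum", "FADH2.fum",
               "FAD.suc", "FADHr.suc", "FADH2.suc"),
    quinone = c("Q", "QH2", "CII.QH2", "CII.QHm", "CII.QHr", "CII.Qsn",
                "CII.Q")
  )
}

# Species eliminated (reconstructed from its pool total) per moiety.  The
# quinone-pool member depends on the operating direction: the species that
# the recycling reaction regenerates is reconstructed, so its value absorbs
# the closure of the pool.
moiety_eliminated <- function(direction = c("reverse", "forward")) {
  direction <- match.arg(direction)
  c(qsite = "CII", fes3 = "fes3_ox", b = "b_ox", fes4 = "fes4_ox",
    fes2 = "fes2_ox", flavin = "FAD",
    quinone = if (direction == "reverse") "QH2" else "Q")
}

#' Construct a species state vector
#'
#' @param ... Named concentrations in uM; species not mentioned are zero.
#' @param values Optionally, a named numeric vector instead of `...`.
#' @return A named numeric vector of length 31 (class `cii_state`) over
#'   [species_names()].
#' @examples
#' st <- cii_state(CII = 235, fes3_ox = 235, Q = 4541, H = 0.1)
#' @export
cii_state <- function(..., values = NULL) {
  x <- stats::setNames(numeric(31L), species_names())
  upd <- if (is.null(values)) unlist(list(...)) else values
  if (length(upd)) {
    bad <- setdiff(names(upd), names(x))
    if (length(bad))
      stop("unknown species name(s): ", paste(bad, collapse = ", "))
    x[names(upd)] <- as.numeric(upd)
  }
  if (any(!is.finite(x)) || any(x < 0))
    stop("species concentrations must be finite and non-negative")
  structure(x, class = c("cii_state", "numeric"))
}

#' Conserved moiety totals of a state
#'
#' Returns the seven conserved pool sums of the model: (1) Qp-site occupancy
#' (all six CII states), (2)-(5) oxidized+reduced sums for \[3Fe-4S\],
#' heme b, \[4Fe-4S\] and \[2Fe-2S\], (6) the nine-state flavin sum, and
#' (7) total quinone (free Q and QH2 plus Qp-site-bound quinone species).
#' These sums are invariant under every reaction of the network, which is
#' what reduces the dynamics to 20 independent ODEs.
#'
#' @param state Named numeric state vector over [species_names()].
#' @return Named numeric vector of length 7
#'   (`qsite`, `fes3`, `b`, `fes4`, `fes2`, `flavin`, `quinone`), in uM.
#' @export
conservation_totals <- function(state) {
  vapply(moiety_members(), function(m) sum(state[m]), numeric(1))
}

#' Deterministic initial state for steady-state runs
#'
#' Places each conserved pool entirely into one member: the free oxidized
#' species for `kind = "fully-oxidized"` (free CII, oxidized relay centers,
#' free FAD) or the reduced ones for `kind = "fully-reduced"` (free CII,
#' reduced centers, free FADH2).  The quinone pool starts as free Q
#' (fully-oxidized) or free QH2 (fully-reduced); in clamped-quinone modes
#' the clamped quinone species holds its configured value and the free
#' counterpart starts at zero.  Clamped metabolites take their configured
#' values.
#'
#' @param params A [cii_parameters()] object.
#' @param kind `"fully-oxidized"` or `"fully-reduced"`.
#' @return A `cii_state` vector satisfying the configured pool totals.
#' @export
initial_state <- function(params, kind = c("fully-oxidized", "fully-reduced")) {
  kind <- match.arg(kind)
  p <- params$pools
  x <- stats::setNames(numeric(31L), species_names())
  x["CII"] <- p[["qsite"]]
  if (kind == "fully-oxidized") {
    x[c("fes3_ox", "b_ox", "fes4_ox", "fes2_ox")] <-
      c(p[["fes3"]], p[["b"]], p[["fes4"]], p[["fes2"]])
    x["FAD"] <- p[["flavin"]]
  } else {
    x[c("fes3_red", "b_red", "fes4_red", "fes2_red")] <-
      c(p[["fes3"]], p[["b"]], p[["fes4"]], p[["fes2"]])
    x["FADH2"] <- p[["flavin"]]
  }
  qmode <- params$mode$quinone
  if (qmode == "conserved-pool") {
    if (kind == "fully-oxidized") x["Q"] <- p[["q"]] else x["QH2"] <- p[["q"]]
  } else if (qmode == "clamped-QH2") {
    x["QH2"] <- params$clamp[["QH2"]]
  } else {
    x["Q"] <- params$clamp[["Q"]]
  }
  for (s in c("fum", "suc", "O2", "H")) x[s] <- params$clamp[[s]]
  structure(x, class = c("cii_state", "numeric"))
}

#' Thermodynamic equilibrium state of the reversible subnetwork
#'
#' Solves, in log-concentration space, the linear system requiring every
#' reversible reaction of the electron-transfer core (reactions 1-21a) to
#' sit exactly at its equilibrium ratio, holding the clamped metabolites at
#' their configured values.  For a detailed-balanced parameter set the
#' system is consistent and every net reversible flux at the returned state
#' is zero; it is the natural reference state for zero-flux tests.  The ROS
#' and recycling reactions (22-29) are not constrained (their substrates
#' O2 and superoxide are left at zero / clamp values).
#'
#' @param params A [cii_parameters()] object.  Dicarboxylate clamps should
#'   be positive so the flavin-site binding reactions have a finite
#'   equilibrium point.
#' @param anchor Log10 concentration assigned to the gauge freedoms (one
#'   free scale per conserved moiety); default 0 (1 uM).
#' @return A `cii_state` vector at which all reversible net rates vanish.
#' @export
equilibrium_state <- function(params, anchor = 0) {
  rx <- reaction_table(params)
  # the reversible electron-transfer / binding core only
  rev_ids <- setdiff(names(rx),
                     c("22", "23", "24", "25", "26", "27", "28", "29"))
  sp <- species_names()
  clamped <- c("fum", "suc", "O2", "H")
  free_sp <- setdiff(unique(unlist(lapply(rx[rev_ids], function(r)
    c(names(r$sub), names(r$prod))))), clamped)
  # rows: log(prod products) - log(prod substrates) = log Keq
  A <- matrix(0, nrow = length(rev_ids), ncol = length(free_sp),
              dimnames = list(rev_ids, free_sp))
  b <- numeric(length(rev_ids))
  keq <- params$keq
  for (i in seq_along(rev_ids)) {
    r <- rx[[rev_ids[i]]]
    b[i] <- log(keq[[rev_ids[i]]])
    for (s in names(r$sub)) {
      if (s %in% clamped) b[i] <- b[i] + r$sub[[s]] * log(params$clamp[[s]])
      else A[i, s] <- A[i, s] - r$sub[[s]]
    }
    for (s in names(r$prod)) {
      if (s %in% clamped) b[i] <- b[i] - r$prod[[s]] * log(params$clamp[[s]])
      else A[i, s] <- A[i, s] + r$prod[[s]]
    }
  }
  # minimum-norm least-squares solution about the anchor point, via the
  # pseudoinverse (the system is rank-deficient: one gauge freedom per
  # conserved moiety)
  u0 <- rep(anchor * log(10), length(free_sp))
  sv <- svd(A)
  pos <- sv$d > 1e-10 * max(sv$d)
  u <- u0 + sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], b - A %*% u0)) / sv$d[pos])
  x <- stats::setNames(numeric(31L), sp)
  x[free_sp] <- exp(as.numeric(u))
  for (s in clamped) x[s] <- params$clamp[[s]]
  structure(x, class = c("cii_state", "numeric"))
}

#' @export
print.cii_state <- function(x, ...) {
  cat("<cii_state> 31 species (uM)\n")
  lab <- species_labels()[names(unclass(x))]
  df <- data.frame(species = lab, conc = as.numeric(x), row.names = NULL)
  print(df, digits = 6)
  invisible(x)
}
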