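# Assembly of the reduced ODE system: clamped species are held fixed, one
# species per conserved moiety is eliminated algebraically, and the
# remaining 20 concentrations are integrated.

# Compile the network into an indexed form for fast flux evaluation inside
# the ODE right-hand side.  Every reversible reaction involves at most
# three distinct species on each side with unit stoichiometry, so rates
# are triple products over padded index tables (index n_sp + 1 holds the
# constant 1).
compile_network <- function(params) {
  rx <- reaction_table(params)
  sp <- species_names()
  n <- length(rx)
  pad <- length(sp) + 1L
  sub_idx <- matrix(pad, n, 3); prod_idx <- matrix(pad, n, 3)
  kvec <- numeric(n); keqvec <- rep(Inf, n)
  type <- character(n)
  rate_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- rx[[i]]
    id <- names(rx)[i]
    type[i] <- r$type
    if (r$type == "rev") {
      si <- match(names(r$sub), sp); pi <- match(names(r$prod), sp)
      sub_idx[i, seq_along(si)] <- si
      prod_idx[i, seq_along(pi)] <- pi
      kvec[i] <- params$k[[id]]
      keqvec[i] <- params$keq[[id]]
    } else if (r$type == "irr") {
      kvec[i] <- params$k[[id]]
      rate_idx[i] <- match(r$rate_species, sp)
    } else {
      rate_idx[i] <- match(r$rate_species, sp)
    }
  }
  list(ids = names(rx), sub_idx = sub_idx, prod_idx = prod_idx,
       kvec = kvec, keqvec = keqvec, type = type, rate_idx = rate_idx,
       is_rev = type == "rev", is_irr = type == "irr",
       mm = which(type == "mm"),
       S = stoichiometry_matrix(params))
}

flux_eval <- function(net, x, params) {
  xp <- c(x, 1)
  v <- net$kvec *
    (xp[net$sub_idx[, 1]] * xp[net$sub_idx[, 2]] * xp[net$sub_idx[, 3]] -
     xp[net$prod_idx[, 1]] * xp[net$prod_idx[, 2]] * xp[net$prod_idx[, 3]] /
       net$keqvec)
  irr <- net$is_irr
  v[irr] <- net$kvec[irr] * x[net$rate_idx[irr]]
  s <- x[net$rate_idx[net$mm]]
  v[net$mm] <- params$vmax27 * s / (params$km27 + s)
  v
}

# Gross (one-way) rate magnitudes: forward + backward term of each
# reaction.  The per-species gross turnover |S| %*% gross sets the
# round-off floor of the net derivative: a species exchanged at 1e8 uM/s
# cannot have its net rate resolved below ~1e-8 uM/s in double precision.
flux_gross <- function(net, x, params) {
  xp <- c(x, 1)
  fwd <- net$kvec *
    xp[net$sub_idx[, 1]] * xp[net$sub_idx[, 2]] * xp[net$sub_idx[, 3]]
  bwd <- net$kvec *
    xp[net$prod_idx[, 1]] * xp[net$prod_idx[, 2]] * xp[net$prod_idx[, 3]] /
    net$keqvec
  irr <- net$is_irr
  fwd[irr] <- net$kvec[irr] * x[net$rate_idx[irr]]
  bwd[irr] <- 0
  s <- x[net$rate_idx[net$mm]]
  fwd[net$mm] <- params$vmax27 * s / (params$km27 + s)
  bwd[net$mm] <- 0
  abs(fwd) + abs(bwd)
}

#' Reduced ODE system for the complex II model
#'
#' Builds the machinery for simulating the model under the operating mode
#' encoded in `params`: the clamped species set (`fum`, `suc`, `O2`, `H+`,
#' plus the clamped quinone species in the clamped-quinone modes), the
#' active conserved moieties (the six enzyme pools, plus the quinone pool
#' in conserved-pool mode), the eliminated species reconstructed from each
#' pool total, and the resulting 20-dimensional right-hand side.
#'
#' @param params A [cii_parameters()] object.
#' @return List with elements `dynamic` (names of the 20 integrated
#'   species), `clamped`, `eliminated` (named by moiety), `totals`,
#'   `reconstruct(y)` (reduced vector to full 31-species state), `rhs(x)`
#'   (full-state derivative, clamps zeroed), and `rhs_reduced(t, y, ...)`
#'   in the form expected by [deSolve::ode()].
#' @export
cii_system <- function(params) {
  net <- compile_network(params)
  sp <- species_names()
  qmode <- params$mode$quinone
  clamped <- c("fum", "suc", "O2", "H",
               switch(qmode, "clamped-QH2" = "QH2", "clamped-Q" = "Q"))
  moieties <- moiety_members()
  active <- if (qmode == "conserved-pool") names(moieties) else
    setdiff(names(moieties), "quinone")
  elim <- moiety_eliminated(params$mode$direction)[active]
  dynamic <- setdiff(sp, c(clamped, elim))
  pool_key <- ifelse(active == "quinone", "q", active)
  totals <- stats::setNames(as.numeric(params$pools[pool_key]), active)
  dyn_ix <- match(dynamic, sp)
  clamp_ix <- match(clamped, sp)
  clamp_val <- params$clamp[clamped]
  elim_ix <- match(elim, sp)
  # per eliminated species: indices of the other pool members
  other_ix <- lapply(active, function(m)
    match(setdiff(moieties[[m]], elim[[m]]), sp))
  tot <- unname(totals)

  reconstruct <- function(y) {
    x <- numeric(31L)
    x[dyn_ix] <- y
    x[clamp_ix] <- clamp_val
    for (i in seq_along(elim_ix))
      x[elim_ix[i]] <- tot[i] - sum(x[other_ix[[i]]])
    names(x) <- sp
    x
  }
  rhs_full <- function(x) {
    v <- flux_eval(net, x, params)
    dx <- drop(net$S %*% v)
    dx[clamp_ix] <- 0
    dx
  }
  rhs_reduced <- function(t, y, parms = NULL) {
    x <- reconstruct(y)
    list(rhs_full(x)[dyn_ix])
  }
  absS <- abs(net$S)
  gross_reduced <- function(y) {
    x <- reconstruct(y)
    drop(absS %*% flux_gross(net, x, params))[dyn_ix]
  }
  list(dynamic = dynamic, clamped = clamped, eliminated = elim,
       totals = totals, net = net,
       reconstruct = reconstruct, rhs = rhs_full,
       rhs_reduced = rhs_reduced, gross_reduced = gross_reduced,
       dyn_ix = dyn_ix)
}

#' ODE right-hand side of the model
#'
#' Evaluates time derivatives at a full 31-species state under the
#' operating mode of `params`: clamped species have derivative exactly
#' zero, eliminated species are first reconstructed from their pool totals
#' (their derivatives are implied by the conservation laws), and all other
#' derivatives are the signed sums of reaction rates given by the
#' stoichiometry matrix.
#'
#' @param state Named full state vector (values of eliminated species are
#'   ignored and reconstructed from the pool totals in `params`).
#' @param params A [cii_parameters()] object.
#' @return Named numeric derivative vector (uM/s) over all 31 species.
#' @export
ode_rhs <- function(state, params) {
  sys <- cii_system(params)
  y <- state[sys$dynamic]
  x <- sys$reconstruct(as.numeric(y))
  bad <- x < -1e-6 * max(unlist(params$pools))
  if (any(bad))
    stop("pool inconsistency: reconstructed concentration negative for ",
         paste(names(x)[bad], collapse = ", "))
  dx <- sys$rhs(x)
  names(dx) <- species_names()
  dx
}
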