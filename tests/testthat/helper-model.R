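# Shared helpers: fast solve wrappers and small scan grids used across the
# test files.  All fixtures are built in code; the model is deterministic.

solve_ss <- function(params, ...) integrate_to_steady_state(params, ...)

# 13-point log grid (the minimum the scan contract allows) to keep test
# runtimes low; acceptance tests use the package default grids.
small_grid <- function(lo, hi) exp(seq(log(lo), log(hi), length.out = 13))

# a state whose moiety totals match the configured pools, but otherwise
# random; used for flux/RHS oracle checks
random_pool_state <- function(params) {
  x <- stats::setNames(stats::runif(31, 0.01, 50), species_names())
  mm <- getFromNamespace("moiety_members", "sdhkin")()
  pools <- params$pools
  pool_of <- c(qsite = "qsite", fes3 = "fes3", b = "b", fes4 = "fes4",
               fes2 = "fes2", flavin = "flavin", quinone = "q")
  for (m in setdiff(names(mm), "quinone")) {
    tot <- pools[[pool_of[[m]]]]
    x[mm[[m]]] <- x[mm[[m]]] * tot / sum(x[mm[[m]]])
  }
  # quinone moiety overlaps the Q-site moiety: rescale free Q/QH2 so the
  # quinone total also matches after the Q-site scaling
  bound <- sum(x[setdiff(mm$quinone, c("Q", "QH2"))])
  free_target <- max(pools[["q"]] - bound, 1)
  x[c("Q", "QH2")] <- x[c("Q", "QH2")] * free_target / sum(x[c("Q", "QH2")])
  for (s in c("fum", "suc", "O2", "H")) x[s] <- params$clamp[[s]]
  cii_state(values = x)
}
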