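# Rate laws, stoichiometry, moiety conservation, and the reduced ODE
# right-hand side.

test_that("rate laws evaluate exactly as written", {
  p <- cii_preset("table2_base")
  # reaction 1 at its equilibrium ratio has zero net rate
  st <- cii_state(CII = 2, QH2 = 3, CII.QH2 = 2 * 3 * p$keq[["1"]],
                  fum = 1, suc = 1, O2 = 30, H = 0.1)
  v <- compute_fluxes(st, p)
  expect_equal(unname(v[["1"]]), 0)
  # superoxide dismutation at half-saturation: Vmax27/2
  st2 <- cii_state(O2sn = 50, H = 0.1, O2 = 30)
  v2 <- compute_fluxes(st2, p)
  expect_equal(unname(v2[["27"]]), 2.8e4)
  # first-order H2O2 efflux
  st3 <- cii_state(H2O2 = 1, H = 0.1, O2 = 30)
  expect_equal(unname(compute_fluxes(st3, p)[["28"]]), 30)
  # non-finite state is rejected
  bad <- unclass(st3); bad["FAD"] <- NaN
  expect_error(compute_fluxes(bad, p), "finite")
})

test_that("stoichiometry matrix transcribes the written reactions", {
  S <- stoichiometry_matrix()
  expect_identical(dim(S), c(31L, 35L))
  # reaction 1: CII + QH2 = CII.QH2
  col1 <- S[, "1"]
  expect_identical(col1[c("CII", "QH2", "CII.QH2")], c(CII = -1L, QH2 = -1L,
                                                       CII.QH2 = 1L))
  expect_identical(sum(col1 != 0), 3L)
  # reaction 27: 2 O2.- + 2 H+ -> O2 + H2O2
  col27 <- S[, "27"]
  expect_identical(col27[c("O2sn", "H", "O2", "H2O2")],
                   c(O2sn = -2L, H = -2L, O2 = 1L, H2O2 = 1L))
  # recycling direction follows the operating mode
  expect_identical(S["Q", "29"], -1L)
  Sf <- stoichiometry_matrix(cii_preset("fig3a"))
  expect_identical(Sf["QH2", "29"], -1L)
  expect_identical(Sf["Q", "29"], 1L)
})

test_that("every reaction column conserves all seven moieties", {
  mm <- getFromNamespace("moiety_members", "sdhkin")()
  for (S in list(stoichiometry_matrix(), stoichiometry_matrix(cii_preset("fig3a")))) {
    for (m in names(mm)) {
      ind <- as.numeric(species_names() %in% mm[[m]])
      expect_identical(max(abs(as.numeric(ind %*% S))), 0)
    }
  }
})

test_that("conservation totals read off pool sums", {
  p <- cii_preset("table2_base")
  st <- initial_state(p, "fully-oxidized")
  tot <- conservation_totals(st)
  expect_equal(unname(tot["qsite"]), 235)
  expect_equal(unname(tot["fes3"]), 235)
  expect_equal(unname(tot["quinone"]), 4541)
  expect_identical(unname(conservation_totals(cii_state())), rep(0, 7))
})

test_that("one explicit Euler step leaves every moiety total unchanged", {
  p <- cii_preset("fig1b", keq1 = 10)
  p <- modify_parameters(p, list(clamp = c(fum = 500)))
  set.seed(11)
  for (i in 1:5) {
    st <- random_pool_state(p)
    d <- ode_rhs(st, p)
    # step small enough that the update does not lose the totals to
    # round-off (gross rates at random states reach ~1e11 uM/s)
    st2 <- unclass(st) + 1e-9 * d
    expect_equal(conservation_totals(st2), conservation_totals(st),
                 tolerance = 1e-12)
  }
})

test_that("reduced RHS equals stoichiometry times fluxes (oracle)", {
  p <- cii_preset("fig1b", keq1 = 10)
  p <- modify_parameters(p, list(clamp = c(fum = 250)))
  S <- stoichiometry_matrix(p)
  set.seed(23)
  for (i in 1:10) {
    st <- random_pool_state(p)
    d <- ode_rhs(st, p)
    oracle <- drop(S %*% as.numeric(compute_fluxes(st, p)))
    names(oracle) <- species_names()
    oracle[c("fum", "suc", "O2", "H")] <- 0
    expect_equal(d, oracle, tolerance = 1e-12)
  }
})

test_that("H2O2 balance is structural: d[H2O2]/dt = V22 + V27 - V28", {
  p <- cii_preset("fig1b", keq1 = 10)
  p <- modify_parameters(p, list(clamp = c(fum = 250)))
  set.seed(31)
  st <- random_pool_state(p)
  v <- compute_fluxes(st, p)
  d <- ode_rhs(st, p)
  expect_equal(unname(d[["H2O2"]]),
               unname(v[["22"]] + v[["27"]] - v[["28"]]))
})

test_that("the reduced system has exactly 20 dynamic species in every mode", {
  for (nm in c("fig1a", "fig1b", "fig3a", "fig3b")) {
    sys <- cii_system(cii_preset(nm))
    expect_length(sys$dynamic, 20L)
  }
})

test_that("constructed equilibrium state has zero net reversible flux", {
  p <- nernst_parameters(cii_preset("table2_base"))
  p <- modify_parameters(p, list(clamp = c(fum = 100, suc = 50)))
  eq <- equilibrium_state(p, anchor = -1)
  v <- compute_fluxes(eq, p)
  core <- setdiff(reaction_ids(), c("22", "23", "24", "25", "26",
                                    "27", "28", "29"))
  expect_lt(max(abs(v[core])), 1e-9 * max(p$k))
})

test_that("parameter validation names the offending key", {
  expect_error(cii_parameters(list(keq = c("99" = 1))), "keq.99")
  expect_error(cii_parameters(list(k = c("3" = -1))), "k.3")
  expect_error(cii_parameters(list(bogus_group = 1)), "bogus_group")
  p <- cii_preset("fig1b", keq1 = 10)
  p$keq[["11"]] <- 1   # break the linked relation behind the flag's back
  expect_error(validate_parameters(p), "Keq1\\*Keq11")
})
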