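# Nernst relations, pKa constants, derived cycle-closure constants,
# detailed balance, and the quinol-oxidation consistency adjustment.

test_that("Nernst equilibrium constants match hand-evaluated values", {
  # quinol semiquinone couple (190 mV) -> [3Fe-4S] (60 mV)
  expect_equal(keq_from_potentials(60, 190), 5.52e-3, tolerance = 1e-3)
  # two-electron overall quinol oxidation at E(Q/QH2) = 90 mV
  expect_equal(keq_from_potentials(60, 90, n = 2), exp(-2.4))
  expect_equal(keq_from_potentials(60, 90, n = 2), 0.09, tolerance = 0.01)
  # zero driving force
  expect_identical(keq_from_potentials(-50, -50, n = 3, rt_over_f = 26), 1)
})

test_that("keq_from_potentials reciprocal symmetry holds for any pair", {
  set.seed(7)
  for (i in 1:25) {
    a <- stats::runif(1, -400, 800); b <- stats::runif(1, -400, 800)
    n <- sample(1:3, 1)
    expect_equal(keq_from_potentials(a, b, n) * keq_from_potentials(b, a, n),
                 1, tolerance = 1e-12)
  }
})

test_that("pKa-derived deprotonation constants are in uM", {
  expect_equal(keq_from_pka(10.86), 1.38e-5, tolerance = 2e-3)
  expect_equal(keq_from_pka(5.31), 4.9, tolerance = 2e-3)
  expect_identical(keq_from_pka(0), 1e6)
})

test_that("derived flavin-site constants reproduce the cycle-closure values", {
  p <- cii_preset("table2_base")
  d <- derived_equilibrium_constants(p)
  expect_equal(unname(d[["18"]]), 2778, tolerance = 1e-3)
  expect_equal(unname(d[["8a"]]), 0.02987, tolerance = 1e-3)
  expect_equal(unname(d[["16a"]]), 0.289, tolerance = 1e-12)
  expect_equal(unname(d[["8b"]]), 3.75e-4, tolerance = 1e-12)
  # the closure value; a published compilation quotes 0.47 from an
  # inconsistent intermediate (see thermo_check docs)
  expect_equal(unname(d[["16b"]]), 0.30, tolerance = 1e-3)
})

test_that("detailed balance holds for tabulated constants within rounding", {
  p <- cii_preset("table2_base")
  cyc <- check_detailed_balance(p)
  expect_setequal(cyc$flagged, FALSE)
  # quinone-heme cycle product from the printed constants: 3.06e-7 * 1.8e4
  # / 5.52e-3
  e1 <- cyc$product[cyc$cycle == "qsite_heme_e1"]
  expect_equal(e1, 0.998, tolerance = 1e-3)
  # the flavin cycles are closed exactly by construction
  expect_lt(max(cyc$residual[startsWith(cyc$cycle, "flavin")]), 1e-12)
})

test_that("potential-generated parameter sets balance every cycle exactly", {
  p <- nernst_parameters(cii_preset("table2_base"))
  expect_lt(max(check_detailed_balance(p)$residual), 1e-12)
  # and stay balanced under dicarboxylate constant changes
  p2 <- nernst_parameters(cii_preset("kd_ref8"))
  expect_lt(max(check_detailed_balance(p2)$residual), 1e-12)
})

test_that("summed quinol-oxidation equilibrium constant and ratio chain", {
  p <- cii_preset("table2_base")
  qo <- keq_sum_quinol_oxidation(p)
  expect_equal(qo$keq_sum, 8.2e-4, tolerance = 5e-3)
  expect_equal(qo$ratio, 110, tolerance = 0.01)
  # scaling Keq3 to its adjusted value scales the sum by the same factor
  p3 <- modify_parameters(p, list(keq = c("3" = 0.027)))
  expect_equal(keq_sum_quinol_oxidation(p3)$keq_sum, 4.018e-3,
               tolerance = 5e-3)
  expect_equal(keq_sum_quinol_oxidation(p3)$ratio, 22.4, tolerance = 0.02)
  # all six constants at 1 -> product 1
  p1 <- modify_parameters(p, list(keq = c("1" = 1, "2" = 1, "3" = 1,
                                          "9" = 1, "10" = 1, "11" = 1)))
  expect_equal(keq_sum_quinol_oxidation(p1)$keq_sum, 1)
})

test_that("thermodynamic adjustment recomputes Keq3/Keq4 and links Keq1*Keq11", {
  p <- apply_thermodynamic_adjustment(cii_preset("table2_base"))
  expect_equal(p$keq[["3"]], 0.027, tolerance = 0.02)
  expect_equal(p$keq[["3"]], exp(-3.6))
  expect_equal(p$keq[["4"]], 1.5e-6, tolerance = 0.02)
  expect_true(p$flags$linked_q_binding)
  expect_equal(p$keq[["1"]] * p$keq[["11"]], 7.39)
  # the overall/summed ratio is restored to ~1
  expect_equal(keq_sum_quinol_oxidation(p)$ratio, 1, tolerance = 0.01)
  # any Keq1 on the linked line keeps the ratio
  p10 <- set_keq1(p, 10)
  expect_equal(keq_sum_quinol_oxidation(p10)$ratio, 1, tolerance = 0.01)
  expect_equal(p10$keq[["11"]], 0.739)
})

test_that("thermo_check reports Nernst deviations without repairing them", {
  tc <- thermo_check(cii_preset("table2_base"))
  k10 <- tc$nernst[tc$nernst$keq == "10", ]
  expect_equal(k10$tabulated, 6.67e3)
  expect_equal(k10$nernst, exp(223 / 25), tolerance = 1e-12)
  expect_lt(k10$rel_dev, 0)   # tabulated value is below the Nernst value
  expect_equal(tc$quinol_oxidation$ratio, 110, tolerance = 0.01)
})
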