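# Michaelis extraction, substrate scans, tunnel-diode diagnostics, ROS
# reporting and unit conversions.

test_that("Km/Vmax extraction recovers exact hyperbola parameters", {
  s <- exp(seq(log(0.01), log(1e4), length.out = 25))
  fit <- michaelis_from_curve(data.frame(substrate = s,
                                         rate = 100 * s / (5 + s)))
  expect_true(fit$plateau)
  expect_true(fit$monotonic)
  expect_equal(fit$vmax, 100, tolerance = 0.01)
  expect_equal(fit$km, 5, tolerance = 0.01)
  # bisection refinement against the analytic rate function
  fit2 <- michaelis_from_curve(data.frame(substrate = s,
                                          rate = 100 * s / (5 + s)),
                               refine = function(x) 100 * x / (5 + x))
  expect_equal(fit2$km, 5, tolerance = 5e-3)
})

test_that("non-plateaued curves fall back to a Michaelis fit", {
  s <- exp(seq(log(0.1), log(2e3), length.out = 25))
  # exact hyperbola with Km near the top of the grid: no plateau in range
  curve <- data.frame(substrate = s, rate = 50 * s / (400 + s))
  fit <- michaelis_from_curve(curve)
  expect_false(fit$plateau)
  expect_equal(fit$vmax, 50, tolerance = 0.01)
  expect_equal(fit$km, 400, tolerance = 0.01)
})

test_that("tunnel-diode verdicts on synthetic curves", {
  s <- 1:15
  up <- data.frame(substrate = s, rate = s / (5 + s))
  expect_true(tunnel_diode_check(up)$monotonic)
  peaked <- data.frame(substrate = s,
                       rate = c(seq(10, 100, length.out = 10),
                                seq(96, 80, length.out = 5)))
  td <- tunnel_diode_check(peaked)
  expect_false(td$monotonic)
  expect_equal(td$peak, 10)
  expect_equal(td$drop, 0.2)
})

test_that("turnover number is Vmax per enzyme", {
  expect_equal(turnover_number(237.7, 235), 1.011, tolerance = 1e-3)
  expect_identical(turnover_number(0, 235), 0)
  expect_identical(turnover_number(235, 235), 1)
})

test_that("volume/protein-basis conversions apply the 273 and 0.24 factors", {
  expect_equal(convert_concentration(1, "nmol_per_mg", "uM_mito"), 273)
  expect_equal(convert_concentration(0.209, "nmol_per_mg", "uM_membrane"),
               237.7, tolerance = 1e-3)
  expect_identical(convert_concentration(0, "uM_mito", "nmol_per_mg"), 0)
  expect_equal(convert_concentration(
    convert_concentration(42, "uM_membrane", "nmol_per_mg"),
    "nmol_per_mg", "uM_membrane"), 42)
  expect_error(convert_concentration(1, "mol_per_l", "uM_mito"), "basis")
})

test_that("rate conversion to pmol/min/mg", {
  expect_identical(convert_rate(0), 0)
  expect_equal(convert_rate(1), 219.78, tolerance = 1e-4)
  # 50 pmol/min/mg corresponds to ~0.2275 uM/s
  expect_equal(convert_rate(0.2275), 50.0, tolerance = 1e-3)
  expect_error(convert_rate(-1))
})

test_that("a reverse QH2 scan is monotonic with a defined Km", {
  p <- cii_preset("fig1a", keq1 = 10)
  fit <- substrate_scan(p, "QH2", grid = small_grid(0.01, 1e4),
                        refine_km = FALSE)
  expect_true(fit$monotonic)
  expect_true(fit$plateau)
  expect_gt(fit$vmax, 200)
  expect_false(is.na(fit$km))
  # scan-order invariance: fresh single-point solves reproduce the curve
  for (i in c(3, 7, 11)) {
    pq <- modify_parameters(p, list(clamp = c(QH2 = fit$curve$substrate[i])))
    expect_equal(solve_ss(pq)$net_flux, fit$curve$rate[i], tolerance = 1e-3)
  }
})

test_that("net flux vanishes without substrates", {
  p <- cii_preset("fig1b", keq1 = 10)   # fum = suc = 0 by default
  r <- solve_ss(p)
  expect_lt(abs(r$net_flux), 1e-6)
})

test_that("oxidation degree of [3Fe-4S] reads the cluster poise", {
  p <- cii_preset("fig1a", keq1 = 10)
  expect_identical(oxidation_degree_3fe4s(initial_state(p, "fully-oxidized")),
                   1)
  p <- modify_parameters(p, list(clamp = c(QH2 = 100)))
  r <- solve_ss(p)
  deg <- oxidation_degree_3fe4s(r)
  expect_gt(deg, 0)
  expect_lt(deg, 0.85)
})

test_that("ROS report decomposes the steady-state fluxes", {
  p <- cii_preset("fig1a", keq1 = 10)
  p <- modify_parameters(p, list(clamp = c(QH2 = 100)))
  r <- solve_ss(p)
  ros <- ros_report(r)
  expect_equal(ros$total, unname(r$fluxes[["28"]]))
  expect_equal(sum(ros$site_shares), 1, tolerance = 1e-9)
  expect_true(all(ros$rates$rate_uM_s >= 0))
  expect_equal(ros$total_pmol_min_mg, convert_rate(ros$total))
  # with O2 (effectively) absent all ROS rates vanish
  p0 <- modify_parameters(p, list(clamp = c(O2 = 0)))
  r0 <- solve_ss(p0)
  expect_lt(max(ros_report(r0)$rates$rate_uM_s), 1e-12)
})

test_that("forward turnover greatly exceeds reverse at shared presets", {
  rev_fit <- substrate_scan(cii_preset("fig1b", keq1 = 10), "fum",
                            grid = small_grid(0.1, 2e3), refine_km = FALSE)
  fwd_fit <- substrate_scan(cii_preset("fig3b", keq1 = 10), "suc",
                            grid = small_grid(0.1, 2e3), refine_km = FALSE)
  expect_gt(fwd_fit$vmax / rev_fit$vmax, 5)
})
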