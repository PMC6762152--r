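test_that("sweeps annotate monotonicity and interior kappa minima", {
  sr <- sweep_family(family_spec("ZA", N = 2), seq(0.5, 100, by = 0.5))
  expect_equal(sr$mcc_monotone, "decreasing")
  expect_true(all(diff(sr$results$mcc) < 0))
  expect_equal(sr$kappa_monotone, "non-monotone")
  expect_equal(sr$kappa_argmin, 1 + 2 * sqrt(2), tolerance = 0.2)

  s0 <- sweep_family(family_spec("C0", a = 1, d = 1),
                     exp(seq(log(0.1), log(100), length.out = 60)))
  expect_equal(s0$mcc_monotone, "decreasing")
  expect_equal(s0$kappa_monotone, "decreasing")
  expect_true(is.na(s0$kappa_argmin))
})

test_that("degenerate grid points are flagged, not dropped", {
  # b = 0 in [[1, b], [1, 0]] empties the second column
  sr <- sweep_family(family_spec("C1_zero_d", a = 1), c(0, 1, 2, 3))
  expect_equal(nrow(sr$results), 4)
  expect_true(sr$results$degenerate[1])
  expect_true(is.na(sr$results$kappa[1]))
  expect_false(any(sr$results$degenerate[-1]))
})

test_that("numerical kappa minimizers match the reconstructed closed forms", {
  cases <- list(family_spec("C1_equal_diag", a = 0.2),
                family_spec("C1_zero_d", a = 1),
                family_spec("C1_unit_d", a = 0.2),
                family_spec("ZA", N = 2),
                family_spec("ZA", N = 3))
  for (sp in cases) {
    found <- find_kappa_minimum(sp, c(0.05, 500))
    expect_equal(found, kappa_min_closed_form(sp), tolerance = 1e-6)
  }
  expect_equal(kappa_min_closed_form(family_spec("C1_equal_diag", a = 0.2)),
               0.2^2 + 1.2 * sqrt(0.2^2 + 1))
  expect_equal(kappa_min_closed_form(family_spec("C1_zero_d", a = 1)),
               sqrt(2))
  # kappa is monotone on C0: no interior minimum to find
  expect_error(find_kappa_minimum(family_spec("C0", a = 1, d = 1),
                                  c(0.1, 100)), "no interior minimum")
})

test_that("Z_A closed forms agree with direct evaluation and the reciprocal identity", {
  expect_equal(zA_closed_forms(2, 1), c(mcc = 0, kappa = 0))
  expect_equal(zA_closed_forms(3, 0), c(mcc = 1 / 14, kappa = 3 / 43))
  for (N in c(2, 3, 5, 10)) {
    for (A in c(0, 0.3, 1, 2.5, 10, 300)) {
      cf <- zA_closed_forms(N, A)
      cm <- make_zA(N, A)
      expect_equal(unname(cf["mcc"]), mcc_multiclass(cm),
                   tolerance = 1e-12)
      expect_equal(unname(cf["kappa"]), cohen_kappa(cm),
                   tolerance = 1e-12)
      if (A != 1)
        expect_equal(1 / cf[["mcc"]] - 1 / cf[["kappa"]], (A - 1) / N,
                     tolerance = 1e-9)
    }
    # limits: MCC -> -1/(2(N-1)) from above, K -> 0 from below
    far <- zA_closed_forms(N, 1e8)
    expect_equal(unname(far["mcc"]), -1 / (2 * (N - 1)),
                 tolerance = 1e-6)
    expect_lt(far[["kappa"]], 0)
    expect_gt(far[["kappa"]], -1e-6)
  }
  # small-A limits in the binary case: K -> 2/5, MCC -> 1/2
  near0 <- zA_closed_forms(2, 1e-6)
  expect_equal(unname(near0["kappa"]), 0.4, tolerance = 1e-3)
  expect_equal(unname(near0["mcc"]), 0.5, tolerance = 1e-3)
})

test_that("divergence |MCC - K| grows monotonically past the Z_A kappa minimum", {
  for (N in c(2, 3)) {
    astar <- kappa_min_closed_form(family_spec("ZA", N = N))
    A <- exp(seq(log(astar * 1.01), log(1e4), length.out = 80))
    gap <- vapply(A, function(a) {
      cf <- zA_closed_forms(N, a)
      abs(cf[["mcc"]] - cf[["kappa"]])
    }, 0)
    expect_true(all(diff(gap) > 0))
  }
})

test_that("MCC decreases monotonically in b on every C1 sub-family", {
  specs <- list(family_spec("C1_equal_diag", a = 0.2),
                family_spec("C1_zero_d", a = 1),
                family_spec("C1_unit_d", a = 0.2),
                family_spec("C1", a = 2, d = 3))
  for (sp in specs) {
    sr <- sweep_family(sp, exp(seq(log(0.01), log(1e4), length.out = 100)))
    expect_true(all(diff(sr$results$mcc) < 0))
  }
})

test_that("the C0 functional relation links kappa to MCC", {
  for (i in 1:30) {
    abd <- 0.2 + stats::runif(3) * 5
    cm <- make_binary(abd[1], abd[2], 0, abd[3])
    expect_equal(cohen_kappa(cm), c0_kappa_from_mcc(mcc_multiclass(cm)),
                 tolerance = 1e-12)
  }
  m <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(c0_kappa_from_mcc(m)) > 0))
  expect_equal(c0_kappa_from_mcc(1), 1)
  expect_error(c0_kappa_from_mcc(0), "\\(0, 1\\]")
  expect_error(c0_kappa_from_mcc(1.2), "\\(0, 1\\]")
})

test_that("the largest C0 gap is 0.13 at MCC 0.3", {
  g <- c0_max_gap()
  expect_equal(round(g[["gap"]], 2), 0.13)
  expect_equal(round(g[["argmax_mcc"]], 1), 0.3)
  # stationarity of m - 2m^2/(1+m^2): (1 + m*^2)^2 = 4 m*
  m <- g[["argmax_mcc"]]
  expect_equal((1 + m^2)^2, 4 * m, tolerance = 1e-6)
})

test_that("binary ordering chains hold in every branch", {
  r <- binary_ordering_check(0, 1, 0, case = "c1")
  expect_true(r$holds)
  expect_equal(r$kappa, -1); expect_equal(r$mcc, -1)
  r2 <- binary_ordering_check(0, 2, 0, case = "c1")
  expect_true(r2$holds)
  expect_equal(r2$mcc, -1)
  expect_equal(r2$kappa, -4 / 5)
  # ad = b: both zero
  r3 <- binary_ordering_check(2, 6, 3, case = "c1")
  expect_true(r3$holds)
  expect_equal(r3$kappa, 0, tolerance = 1e-12)
  # random matrices hit the four strict branches
  for (i in 1:40) {
    abd <- 0.3 + stats::runif(3) * c(4, 6, 4)
    expect_true(binary_ordering_check(abd[1], abd[2], abd[3],
                                      case = "c1")$holds)
    expect_true(binary_ordering_check(abd[1], abd[2], abd[3],
                                      case = "c0")$holds)
  }
  # b = 1 is a symmetric equality branch
  rb <- binary_ordering_check(2, 1, 3, case = "c1")
  expect_true(rb$holds)
  expect_match(rb$branch, "symmetric")
})

test_that("C1_equal_diag boundary roots put the marginal bound at -1", {
  for (a in c(0.05, 0.1, 0.15)) {
    roots <- c1_equal_diag_boundary_roots(a)
    expect_false(anyNA(roots))
    expect_lt(roots[["b1"]], roots[["b2"]])
    expect_lt(roots[["b2"]], 1)
    for (b in roots)
      expect_equal((a^2 - b) / (a + b)^2, -1, tolerance = 1e-9)
  }
  expect_true(anyNA(c1_equal_diag_boundary_roots(0.3)))
})

test_that("regime classification separates the eight families as summarized", {
  expected <- c(C0 = "agreement", C1 = "disagreement",
                ZA = "disagreement", M1 = "agreement",
                M2 = "disagreement", M3 = "agreement",
                M4 = "disagreement", M5 = "agreement")
  t3 <- reproduce_table("table3")
  expect_equal(stats::setNames(t3$label, t3$family), expected)
  # the disagreement rule is exactly "entropy decreasing to zero"
  expect_true(all((t3$label == "disagreement") ==
                  (t3$entropy_trend == "decreasing_to_zero")))
  expect_equal(t3$asymmetry_trend[t3$family == "M3"], "constant")
})

test_that("an inconclusive sweep tail is refused", {
  # M5's entropy still rises towards its interior maximum on this range
  sr <- sweep_family(family_spec("M5"),
                     exp(seq(log(1), log(300), length.out = 60)))
  expect_error(classify_regime(sr), "inconclusive")
})
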