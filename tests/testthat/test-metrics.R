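test_that("accuracy is trace over total", {
  expect_equal(accuracy(matrix(c(3, 0, 0, 3), 2)), 1)
  expect_equal(accuracy(matrix(1, 2, 2)), 0.5)
  expect_equal(accuracy(make_example_family("M2", 10)), 3 / 117)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("chance agreement is the marginal-product overlap", {
  expect_equal(chance_agreement(matrix(1, 2, 2)), 0.5)
  expect_equal(chance_agreement(diag(c(5, 5))), 0.5)
  # M2(10): row sums (12, 102, 3), col sums (3, 12, 102)
  expect_equal(chance_agreement(make_example_family("M2", 10)),
               1566 / 13689)
})

test_that("kappa matches its definition and known values", {
  m2 <- make_example_family("M2", 10)
  expect_equal(round(cohen_kappa(m2), 4), -0.1002)
  k <- cohen_kappa(m2)
  expect_equal(k, (accuracy(m2) - chance_agreement(m2)) /
                    (1 - chance_agreement(m2)))
  for (N in 2:5) expect_equal(cohen_kappa(matrix(1, N, N)), 0)
  # all mass in one diagonal cell: row/column sums degenerate
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
})

test_that("closed-form MCC reproduces known values and reduces to the binary formula", {
  expect_equal(round(mcc_multiclass(make_example_family("M2", 10)), 4),
               -0.3879)
  expect_equal(mcc_multiclass(diag(c(2, 3))), 1)
  expect_equal(mcc_multiclass(make_zA(3, 0)), 1 / 14)
  for (i in 1:25) {
    cm <- random_confusion(2, 60, seed = 400 + i)
    expect_equal(mcc_multiclass(cm),
                 mcc_binary_cells(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2]),
                 tolerance = 1e-12)
  }
  expect_error(mcc_multiclass(matrix(c(1, 1, 0, 0), 2, byrow = TRUE)),
               "degenerate")
})

test_that("simplified MCC numerator agrees with the literal triple sum", {
  for (cm in rand_cms(30, seed_base = 2000))
    expect_equal(mcc_multiclass(cm), mcc_triple_sum(cm),
                 tolerance = 1e-12)
})

test_that("indicator-matrix oracle equals the closed form", {
  expect_equal(mcc_indicator_oracle(make_binary(2, 1, 1, 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(mcc_indicator_oracle(diag(c(2, 3))), 1)
  for (cm in rand_cms(60, seed_base = 3000))
    expect_lt(abs(mcc_indicator_oracle(cm) - mcc_multiclass(cm)), 1e-10)
  expect_error(mcc_indicator_oracle(make_binary(0.5, 1, 1, 1)), "integer")
})

test_that("kappa and MCC coincide on symmetric matrices", {
  for (i in 1:60) {
    N <- 2 + (i %% 7)
    cm <- random_confusion(N, 40 + 3 * N^2, seed = 5000 + i,
                           symmetric = TRUE)
    expect_lt(abs(cohen_kappa(cm) - mcc_multiclass(cm)), 1e-10)
  }
})

test_that("alpha/beta decomposition: kappa harmonic, |MCC| geometric mean", {
  expect_equal(alpha_beta(matrix(1, 2, 2)), c(alpha = 0, beta = 0))
  ab <- alpha_beta(make_binary(2, 1, 1, 2))
  expect_equal(unname(ab), c(1 / 3, 1 / 3))
  for (i in 1:50) {
    cm <- random_confusion(2, 60, seed = 6000 + i)
    ab <- alpha_beta(cm)
    k <- cohen_kappa(cm)
    m <- mcc_multiclass(cm)
    det <- cm[1, 1] * cm[2, 2] - cm[1, 2] * cm[2, 1]
    if (det != 0) {
      expect_equal(k, 2 / (1 / ab[1] + 1 / ab[2]), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(abs(m), sqrt(prod(ab)), tolerance = 1e-12)
      # ordering: both between min and max of (alpha, beta), K on the
      # |.|-smaller side
      expect_gte(k + 1e-12, min(ab)); expect_lte(k - 1e-12, max(ab))
      expect_gte(m + 1e-12, min(ab)); expect_lte(m - 1e-12, max(ab))
      if (det > 0) { expect_gt(k, 0); expect_lte(k, m + 1e-12) }
      else         { expect_lt(k, 0); expect_lte(m, k + 1e-12) }
    } else {
      expect_equal(k, 0); expect_equal(m, 0)
    }
  }
  expect_error(alpha_beta(matrix(1, 3, 3)), "binary")
})

test_that("metrics are invariant under positive scaling and transpose", {
  for (i in 1:20) {
    cm <- random_confusion(2 + (i %% 4), 80, seed = 7000 + i)
    s <- exp(stats::runif(1, -2, 2))
    for (f in list(accuracy, chance_agreement, cohen_kappa,
                   mcc_multiclass)) {
      expect_equal(f(cm * s), f(cm), tolerance = 1e-12)
      expect_equal(f(t(cm)), f(cm), tolerance = 1e-12)
    }
  }
})

test_that("metric_report assembles all fields", {
  r <- metric_report(make_binary(2, 1, 1, 2))
  expect_named(r, c("acc", "pe", "kappa", "mcc", "alpha", "beta"))
  expect_equal(r$kappa, 1 / 3)
  r3 <- metric_report(make_zA(3, 2))
  expect_true(is.na(r3$alpha) && is.na(r3$beta))
})

test_that("real-valued entries are accepted by all metrics except the oracle", {
  cm <- make_binary(0.2, 5, 1, 0.2)
  expect_equal(cohen_kappa(cm), cohen_kappa(cm * 5), tolerance = 1e-12)
  expect_equal(mcc_multiclass(cm * 5),
               mcc_multiclass(matrix(c(1, 25, 5, 1), 2, byrow = TRUE)),
               tolerance = 1e-12)
})
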