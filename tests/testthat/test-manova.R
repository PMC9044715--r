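test_that("design construction: intercept, treatment coding, interactions, term map", {
  d4 <- data.frame(g = factor(c("a", "a", "b", "b")), x = c(1, 2, 3, 4))
  int_only <- build_design(d4, ~ 1)
  expect_equal(int_only$X, matrix(1, 4, 1), ignore_attr = TRUE)
  expect_equal(int_only$term_labels, "(Intercept)")
  one_fac <- build_design(d4, ~ g)
  expect_equal(one_fac$X, cbind(rep(1, 4), c(0, 0, 1, 1)), ignore_attr = TRUE)
  expect_equal(one_fac$assign, c(0L, 1L))
  inter <- build_design(d4, ~ g * x)
  expect_equal(ncol(inter$X), 4L)
  expect_equal(unname(inter$X[, 4]), c(0, 0, 1, 1) * d4$x)
  expect_equal(inter$term_labels, c("(Intercept)", "g", "x", "g:x"))
})

test_that("design construction rejects unknown columns, constant factors and aliasing", {
  d <- data.frame(g = factor(rep("a", 6)), x = 1:6)
  expect_error(build_design(d, ~ missing_col), "missing_col")
  expect_error(build_design(d, ~ g), "fewer than 2")
  d2 <- data.frame(x = 1:8, y = 2 * (1:8))
  des <- build_design(d2, ~ x + y)
  Y <- embed_angles(rad(seq(0.1, 2, length.out = 8)))
  expect_error(fit_mlm(des$X, Y, des$assign, des$term_labels),
               "rank deficient.*'y'")
})

test_that("cardinal points give a zero intercept SSCP and unit residual SSCP", {
  des <- build_design(data.frame(row.names = 1:4), ~ 1)
  Y <- embed_angles(deg(c(0, 90, 180, 270)))
  fit <- fit_mlm(des$X, Y, des$assign, des$term_labels)
  expect_lt(max(abs(fit$H[["(Intercept)"]])), 1e-24)
  expect_equal(fit$E, diag(c(2, 2)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$df_error, 3L)
})

test_that("identical angles are rejected as a degenerate response", {
  expect_error(circular_manova(rad(rep(1.2, 10))), "degenerate response")
})

test_that("sequential SSCP partition conserves the total uncorrected SSCP", {
  set.seed(42)
  for (rep in 1:5) {
    ds <- rand_dataset(n = 12, levels = 3)
    m <- circular_manova(rad(ds$theta), ~ g + x, ds$data)
    Y <- embed_angles(rad(ds$theta))
    total <- Reduce(`+`, m$fit$H) + m$fit$E
    expect_equal(total, crossprod(Y), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(m$fit$df_error + sum(m$fit$q), length(ds$theta))
  }
})

test_that("a zero hypothesis SSCP yields Pillai 0, F 0, p 1", {
  res <- pillai_term_test(matrix(0, 2, 2), diag(2), q = 1, df_error = 10)
  expect_equal(res$pillai, 0)
  expect_equal(res$approx_f, 0)
  expect_equal(res$p_theory, 1)
  expect_false(res$degenerate)
})

test_that("intercept-only Pillai F and p equal the one-sample Hotelling T-squared test", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    theta <- runif(n, 0, 2 * pi)
    m <- circular_manova(rad(theta))
    oracle <- hotelling_oracle(theta)
    expect_equal(m$table$approx_f, oracle$F, tolerance = 1e-9)
    expect_equal(m$table$p_theory, oracle$p, tolerance = 1e-9)
  }
})

test_that("per-term Pillai traces match brute-force nested-model differencing", {
  set.seed(42)
  for (rep in 1:20) {
    ds <- rand_dataset(n = sample(15:30, 1), levels = 3)
    m <- circular_manova(rad(ds$theta), ~ g + x, ds$data)
    oracle <- brute_pillai_traces(ds$theta, ~ g + x, ds$data)
    expect_equal(m$table$pillai, unname(oracle[m$table$term]),
                 tolerance = 1e-9)
  }
})

test_that("full table agrees with the base-R sequential MANOVA summary", {
  set.seed(42)
  ds <- rand_dataset(n = 28, levels = 3)
  Y <- cbind(cos(ds$theta), sin(ds$theta))
  ref <- summary(stats::manova(Y ~ g * x, data = ds$data),
                 test = "Pillai", intercept = TRUE)$stats
  m <- circular_manova(rad(ds$theta), ~ g * x, ds$data)
  k <- nrow(m$table)
  expect_equal(m$table$pillai, unname(ref[1:k, "Pillai"]), tolerance = 1e-8)
  expect_equal(m$table$approx_f, unname(ref[1:k, "approx F"]), tolerance = 1e-8)
  expect_equal(m$table$p_theory, unname(ref[1:k, "Pr(>F)"]), tolerance = 1e-8)
  expect_equal(m$table$df, unname(ref[1:k, "Df"]))
})

test_that("intercept-only Pillai and p are invariant under rotation of the sample", {
  set.seed(42)
  theta <- runif(30, 0, 2 * pi)
  m0 <- circular_manova(rad(theta))
  for (c_shift in c(0.7, 2.4, 5.1)) {
    mr <- circular_manova(rad((theta + c_shift) %% (2 * pi)))
    expect_equal(mr$table$pillai, m0$table$pillai, tolerance = 1e-9)
    expect_equal(mr$table$p_theory, m0$table$p_theory, tolerance = 1e-9)
  }
})

test_that("clustered and grouped scenarios are detected as expected", {
  set.seed(42)
  strong <- rcirc_vonmises(100, 1, 2)
  expect_lt(circular_manova(strong)$table$p_theory, 0.001)
  # two groups 180 degrees apart: pooled uniformity test blind, group term not
  theta <- c(rcirc_vonmises(50, 0, 2)$angles, rcirc_vonmises(50, pi, 2)$angles)
  d <- data.frame(g = factor(rep(c("a", "b"), each = 50)))
  m <- circular_manova(rad(theta), ~ g, d)
  expect_gt(m$table$p_theory[1], 0.05)
  expect_lt(m$table$p_theory[2], 0.01)
  expect_error(circular_manova(rad(theta), ~ g, d[1:10, , drop = FALSE]),
               "rows")
})

test_that("Monte-Carlo calibration ranks the observed p among uniform-null p-values", {
  set.seed(42)
  strong <- rcirc_vonmises(100, 1, 5)
  m <- mc_calibrated_manova(strong, B = 99)
  expect_equal(m$table$p_mc, 1 / 100)
  expect_error(mc_calibrated_manova(strong, B = 0), "at least 1")
})

test_that("the vectorized theory-p engine reproduces per-sample fits exactly", {
  set.seed(42)
  ds <- rand_dataset(n = 25, levels = 2)
  des <- build_design(ds$data, ~ g + x)
  basis_fit <- fit_mlm(des$X, embed_angles(rad(ds$theta)), des$assign,
                       des$term_labels)
  reps <- 30
  theta_mat <- matrix(runif(25 * reps, 0, 2 * pi), 25, reps)
  P <- circmanova:::.theory_p_matrix(basis_fit$Q, basis_fit$ranks,
                                     cos(theta_mat), sin(theta_mat),
                                     basis_fit$df_error)
  for (j in seq_len(reps)) {
    m <- circular_manova(rad(theta_mat[, j]), ~ g + x, ds$data)
    expect_equal(P[, j], m$table$p_theory, tolerance = 1e-12)
  }
})
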