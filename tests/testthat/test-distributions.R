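test_that("samplers are deterministic under a fixed seed", {
  draws <- function() list(
    u = rcirc_uniform(50)$angles,
    v = rcirc_vonmises(50, 1, 2)$angles,
    w = rcirc_wsn(50, 0, 2, 30)$angles,
    m = rcirc_mixture(vm_mixture(c(0, 180), 1), 50)$angles
  )
  set.seed(42); a <- draws()
  set.seed(42); b <- draws()
  expect_identical(a, b)
})

test_that("uniform draws have vanishing mean resultant and stay in range", {
  set.seed(42)
  s <- rcirc_uniform(1e5)
  expect_lt(mean_resultant(s)$rbar, 0.02)
  expect_true(all(s$angles >= 0 & s$angles < 2 * pi))
  expect_equal(rcirc_uniform(1)$n, 1L)
  expect_error(rcirc_uniform(0), "at least 1")
})

test_that("von Mises first moment matches the Bessel ratio and concentrates at mu", {
  set.seed(42)
  s <- rcirc_vonmises(1e5, mu = 0, kappa = 1)
  expect_equal(mean_resultant(s)$rbar, besselI(1, 1) / besselI(1, 0),
               tolerance = 0.01)
  expect_equal(mean_resultant(s)$mean_direction %% (2 * pi), 0,
               tolerance = 0.02)
  sharp <- rcirc_vonmises(1e4, mu = 2.5, kappa = 50)
  expect_equal(mean_resultant(sharp)$mean_direction, 2.5, tolerance = 0.02)
  expect_error(rcirc_vonmises(10, 0, -1), "nonnegative")
})

test_that("kappa = 0 von Mises degenerates to the circular uniform", {
  set.seed(42)
  s <- rcirc_vonmises(1e5, mu = 1, kappa = 0)
  expect_gt(rayleigh_test(s)$p.value, 0.001)
})

test_that("wrapped skew normal: alpha = 0 gives the wrapped normal moment, alpha = 30 is skewed", {
  set.seed(42)
  wn <- rcirc_wsn(1e5, xi = 0, omega = 0.5, alpha = 0)
  expect_equal(mean_resultant(wn)$rbar, exp(-0.5^2 / 2), tolerance = 0.01)
  skewed <- rcirc_wsn(1e5, xi = 0, omega = 2, alpha = 30)
  mu <- mean_resultant(skewed)$mean_direction
  # circular skewness: second moment about the mean direction is asymmetric
  b <- mean(sin(2 * (skewed$angles - mu)))
  expect_gt(abs(b), 0.1)
  expect_error(rcirc_wsn(10, 0, -2, 0), "positive")
})

test_that("a single-component mixture matches its component distribution", {
  set.seed(42)
  spec <- mixture_spec(list(list(family = "vonmises", weight = 1, mu = 1, kappa = 2)))
  mix <- rcirc_mixture(spec, 2e4)
  direct <- rcirc_vonmises(2e4, 1, 2)
  expect_equal(mean_resultant(mix)$rbar, mean_resultant(direct)$rbar,
               tolerance = 0.02)
  expect_equal(mean_resultant(mix)$mean_direction,
               mean_resultant(direct)$mean_direction, tolerance = 0.03)
})

test_that("symmetric mixtures cancel the mean resultant", {
  set.seed(42)
  bi <- rcirc_mixture(vm_mixture(c(0, 180), 1), 1e5)
  expect_lt(mean_resultant(bi)$rbar, 0.02)
  tri <- rcirc_mixture(vm_mixture(c(0, 120, 240), 1), 1e5)
  expect_lt(mean_resultant(tri)$rbar, 0.02)
})

test_that("mixture specs validate weights and parameters and round-trip via JSON", {
  expect_error(
    mixture_spec(list(list(family = "vonmises", weight = 0.7, mu = 0, kappa = 1),
                      list(family = "uniform", weight = 0.2))),
    "sum to 1"
  )
  expect_error(
    mixture_spec(list(list(family = "cauchy", weight = 1))), "family"
  )
  spec <- mixture_spec(list(
    list(family = "vonmises", weight = 0.5, mu = 0, kappa = 1),
    list(family = "wsn", weight = 0.3, xi = 0, omega = 2, alpha = 30),
    list(family = "uniform", weight = 0.2)
  ))
  back <- mixture_from_json(mixture_to_json(spec))
  expect_equal(back, spec)
  path <- withr::local_tempfile(fileext = ".json")
  mixture_to_json(spec, path)
  expect_equal(mixture_from_json(path), spec)
})
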