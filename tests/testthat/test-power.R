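test_that("scenario and design constructors validate their inputs", {
  expect_error(scenario("bad", NULL, c(10, 5)), "increasing")
  expect_error(scenario("bad", "not a spec", 10), "mixture_spec")
  expect_error(hypothetical_design(kappa1 = c(-1, 2)), "nonnegative")
  expect_error(
    run_hypothetical_suite(hypothetical_design(), n_total = 25, replicates = 1),
    "divisible by 10"
  )
})

test_that("a single replicate yields a degenerate rate and rates stay in [0, 1]", {
  set.seed(42)
  scn <- scenario("unif", NULL, c(10, 25), replicates = 1)
  r <- run_uniformity_suite(scn, tests = c("rayleigh", "manova"))
  expect_true(all(r$rate %in% c(0, 1)))
  scn2 <- scenario("vm", vm_mixture(0, 1), 25, replicates = 200)
  r2 <- run_uniformity_suite(scn2, tests = c("rayleigh", "manova"))
  expect_true(all(r2$rate >= 0 & r2$rate <= 1))
})

test_that("suite summaries carry binomial intervals that tighten with replication", {
  empty <- summarize_suite(data.frame())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("se", "ci_lo", "ci_hi") %in% names(empty)))
  tab <- data.frame(scenario = "s", test = "t", term = "intercept",
                    n = c(10, 10), replicates = c(100, 10000),
                    rate = c(0.05, 0.05))
  s <- summarize_suite(tab)
  width <- s$ci_hi - s$ci_lo
  expect_lt(width[s$replicates == 10000], width[s$replicates == 100])
  expect_true(all(s$ci_lo >= 0 & s$ci_hi <= 1))
})

test_that("power against unimodal alternatives is non-decreasing in n within MC error", {
  set.seed(42)
  scn <- scenario("vm", vm_mixture(0, 1), c(5, 10, 15, 25, 50, 100),
                  replicates = 2000)
  r <- run_uniformity_suite(scn, tests = c("rayleigh", "manova"))
  for (tst in c("rayleigh", "manova")) {
    rates <- r$rate[r$test == tst][order(r$n[r$test == tst])]
    se <- sqrt(rates * (1 - rates) / 2000)
    expect_true(all(diff(rates) >= -2 * (se[-length(se)] + se[-1])))
  }
})

test_that("binned data inflate the Hermans-Rasson type-I error with n but not the others", {
  set.seed(42)
  scn <- scenario("unif_binned", NULL, c(10, 100), binned = TRUE,
                  replicates = 3000)
  r <- run_uniformity_suite(scn, tests = c("hr", "rayleigh", "manova"))
  hr <- r[r$test == "hr", ]
  expect_gt(hr$rate[hr$n == 100], hr$rate[hr$n == 10])
  expect_gt(hr$rate[hr$n == 100], 0.05)
  others <- r[r$test != "hr" & r$n == 100, ]
  expect_true(all(abs(others$rate - 0.05) <= 0.015))
})

test_that("fully uniform group-by-age cells keep every term at its nominal level", {
  set.seed(42)
  des <- hypothetical_design(kappa1 = c(0, 0), kappa2 = c(0, 0))
  r <- run_hypothetical_suite(des, n_total = 50, replicates = 1500,
                              tests = c("manova", "rayleigh"))
  expect_true(all(abs(r$rate - 0.05) <= 0.02))
})

test_that("an age-driven concentration increase is seen by the age term, not the group term", {
  set.seed(42)
  des <- hypothetical_design(kappa1 = c(0, 2), kappa2 = c(0, 2))
  r <- run_hypothetical_suite(des, n_total = c(20, 100), replicates = 800,
                              tests = "manova")
  age <- r[r$term == "age", ]
  expect_gt(age$rate[age$n == 100], age$rate[age$n == 20] + 0.1)
  group <- r[r$term == "group", ]
  expect_true(all(abs(group$rate - 0.05) <= 0.025))
})

test_that("MC-calibrated rates from the harness match the per-sample calibrated test", {
  set.seed(42)
  # tiny paired check: identical seeds, one replicate, same decision
  theta <- rcirc_vonmises(20, 0, 3)$angles
  Q1 <- matrix(1 / sqrt(20), 20, 1)
  set.seed(99)
  rej <- circmanova:::.mc_calibrated_rejections(
    Q1, 1L, matrix(cos(theta)), matrix(sin(theta)), 19L, B = 199, alpha = 0.05
  )
  set.seed(99)
  m <- mc_calibrated_manova(rad(theta), B = 199)
  expect_equal(unname(rej[1, 1]), m$table$p_mc < 0.05)
})
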