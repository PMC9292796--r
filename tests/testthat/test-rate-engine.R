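test_that("Wigner transmission coefficient follows its closed form", {
  expect_identical(wigner_kappa(0), 1)
  expect_identical(wigner_kappa(NA_real_), 1)
  expect_equal(wigner_kappa(2000), 4.881, tolerance = 1e-3)
  expect_error(wigner_kappa(-100), "non-negative")
  # monotone in frequency, decreasing in temperature
  nu <- seq(0, 3500, by = 250)
  expect_true(all(diff(wigner_kappa(nu)) > 0))
  expect_true(wigner_kappa(2000, 350) < wigner_kappa(2000, 298.15))
})

test_that("Eyring rate hits the prefactor at zero barrier", {
  expect_equal(eyring_rate(0), 6.212e12, tolerance = 1e-3)
  expect_equal(eyring_rate(6.759), 6.9e7, tolerance = 0.02)
  expect_equal(eyring_rate(36.759), 7.1e-15, tolerance = 0.02)
  expect_error(eyring_rate(-1), ">= 0")
  expect_error(eyring_rate(5, kappa = 0.5), "kappa")
})

test_that("Eyring rate is log-linear in the barrier with slope -1/RT", {
  g <- seq(0, 40, by = 0.5)
  slope <- diff(log(eyring_rate(g))) / diff(g)
  expect_equal(slope, rep(-1 / RT298, length(slope)), tolerance = 1e-9)
})

test_that("Marcus barrier and region classification", {
  lam <- 12
  expect_equal(marcus_barrier(0, lam)$dG_act, lam / 4)
  expect_identical(marcus_barrier(0, lam)$region, "normal")
  # activationless point, boundary classified normal
  b <- marcus_barrier(-lam, lam)
  expect_equal(b$dG_act, 0)
  expect_identical(b$region, "normal")
  b <- marcus_barrier(-13.0, 10.911)
  expect_equal(b$dG_act, 0.10, tolerance = 0.02)
  expect_identical(b$region, "inverted")
  expect_error(marcus_barrier(-5, 0), "positive")
})

test_that("reorganization-energy inference returns the admissible roots", {
  roots <- infer_lambda(-13.0, 0.1)
  expect_equal(sort(roots$lambda), c(10.9109, 15.4891), tolerance = 1e-4)
  expect_identical(roots$region[order(roots$lambda)],
                   c("inverted", "normal"))
  expect_equal(infer_lambda(0, 5)$lambda, 20)
  expect_equal(infer_lambda(-10, 0)$lambda, 10)
  expect_identical(nrow(infer_lambda(10, 2)), 0L)  # barrier below |dG_r|
})

test_that("marcus_barrier composed with infer_lambda is the identity", {
  set.seed(42)
  for (i in 1:200) {
    g <- runif(1, -30, 20)
    a <- runif(1, max(g, 0) + 0.01, 40)
    roots <- infer_lambda(g, a)
    expect_gt(nrow(roots), 0)
    for (lam in roots$lambda) {
      expect_equal(marcus_barrier(g, lam)$dG_act, a, tolerance = 1e-9)
    }
  }
})

test_that("diffusion rate reduces to 8kBT N_A/(3 eta) for equal radii", {
  for (a in c(1e-10, 2.2e-10, 5e-10)) {
    expect_equal(diffusion_rate(a, a, 8.91e-4), 7.419e9, tolerance = 1e-3)
  }
  # inverse proportionality to viscosity
  expect_equal(diffusion_rate(2e-10, 3e-10, 2 * 8.91e-4),
               diffusion_rate(2e-10, 3e-10, 8.91e-4) / 2)
  # strongly asymmetric pairs diffuse faster than symmetric ones
  expect_gt(diffusion_rate(1e-10, 15e-10, 8.91e-4),
            diffusion_rate(4e-10, 4e-10, 8.91e-4))
  expect_error(diffusion_rate(-1e-10, 2e-10, 8.91e-4), "positive")
})

test_that("Collins-Kimball interpolates between the two regimes", {
  expect_equal(collins_kimball(1e15, 7.4e9), 7.4e9, tolerance = 1e-4)
  expect_equal(collins_kimball(1e3, 7.4e9), 1e3, tolerance = 1e-6)
  expect_identical(collins_kimball(5e9, 5e9), 2.5e9)
  expect_error(collins_kimball(0, 1e9), "positive")
})

test_that("k_app is bounded by both rates and monotone in each", {
  set.seed(11)
  k1 <- 10^runif(300, -20, 14)
  k2 <- 10^runif(300, -20, 14)
  kapp <- collins_kimball(k1, k2)
  expect_true(all(kapp <= pmin(k1, k2) * (1 + 1e-12)))
  expect_true(all(kapp > 0))
  # monotone non-decreasing in each argument over the full range (strictness
  # saturates below double precision deep in the diffusion limit) ...
  expect_true(all(collins_kimball(k1 * 1.5, k2) >= kapp * (1 - 1e-12)))
  expect_true(all(collins_kimball(k1, k2 * 1.5) >= kapp * (1 - 1e-12)))
  # ... and strictly increasing where both rates are comparable
  k1m <- 10^runif(100, 8, 11)
  k2m <- 10^runif(100, 8, 11)
  expect_true(all(collins_kimball(k1m * 1.5, k2m) >
                    collins_kimball(k1m, k2m)))
  expect_true(all(collins_kimball(k1m, k2m * 1.5) >
                    collins_kimball(k1m, k2m)))
})
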