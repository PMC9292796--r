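test_that("the generator is fully determined by its seed", {
  a <- generate_channels(generator_spec(seed = 123))
  b <- generate_channels(generator_spec(seed = 123))
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth, b$truth)
  c <- generate_channels(generator_spec(seed = 124))
  expect_false(identical(a$channels, c$channels))
  # no global RNG state leak
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_channels(generator_spec(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("generated tables have the structure of the curated data", {
  ds <- generate_channels(generator_spec(seed = 2))
  ch <- ds$channels
  expect_identical(nrow(validate_channels(ch)), 0L)
  amino <- ch$mechanism == "HAT" & ch$site == "1"
  expect_true(all(ch$dG_rxn_kcal[amino] < 0))
  peroxyl_arom <- ch$mechanism == "HAT" & ch$site != "1" &
    grepl("OO", ch$radical)
  expect_true(all(ch$dG_rxn_kcal[peroxyl_arom] > 0))
  expect_true(all(ch$sigma[ch$site %in% c("2", "2a", "3", "4", "5", "5a")]
                  == 2L))
  set <- ch[ch$mechanism == "SET", ]
  aqueous <- set$medium == "water"
  expect_true(all(set$dG_act_kcal[!aqueous] >= 40))
  expect_error(generate_channels(generator_spec(mechanisms = character(0))),
               "mechanisms")
})

test_that("every synthetic SET channel's lambda is recoverable", {
  ds <- generate_channels(generator_spec(seed = 31))
  set <- ds$channels[ds$channels$mechanism == "SET" &
                       !is.na(ds$channels$lambda_kcal), ]
  expect_gt(nrow(set), 10)
  for (i in seq_len(nrow(set))) {
    g <- set$dG_rxn_kcal[i]
    a_marcus <- marcus_barrier(g, set$lambda_kcal[i])$dG_act
    roots <- infer_lambda(g, a_marcus)
    expect_true(min(abs(roots$lambda - set$lambda_kcal[i])) < 1e-6)
  }
})

test_that("pipeline output equals the stored brute-force truth", {
  ds <- generate_channels(generator_spec(seed = 17, n_antioxidants = 15))
  expect_gt(nrow(ds$channels), 1000)
  rates <- channel_rates(ds$channels, ds$media, ds$species)
  expect_equal(rates$k_app, ds$truth$k_app_true, tolerance = 1e-12)
  # diffusion-capped channels never exceed the context diffusion rate
  capped <- !is.na(rates$k_D)
  expect_true(all(rates$k_app[capped] <= rates$k_D[capped]))
})

test_that("branching ratios on synthetic contexts sum to 100 pre-rounding", {
  ds <- generate_channels(generator_spec(seed = 9, n_antioxidants = 2))
  rep <- scavenging_report(channel_rates(ds$channels, ds$media, ds$species))
  mech <- rep[rep$mechanism != "overall" & !is.na(rep$gamma), ]
  sums <- tapply(mech$gamma,
                 paste(mech$antioxidant, mech$radical, mech$medium), sum)
  expect_equal(as.vector(sums), rep(100, length(sums)), tolerance = 1e-12)
})

test_that("input-rounding noise moves activation-controlled rates <= 1.088x", {
  ds <- generate_channels(generator_spec(seed = 4))
  pert <- perturb(ds, 0.05)
  rates0 <- channel_rates(ds$channels, ds$media, ds$species)
  rates1 <- channel_rates(pert$channels, pert$media, pert$species)
  # activation-controlled, away from the clamp so the perturbation is linear
  sel <- which(!rates0$diffusion_limited & rates0$dG_act_corrected > 1 &
                 rates0$k_app < 1e8)
  expect_gt(length(sel), 50)
  ratio <- rates1$k_app[sel] / rates0$k_app[sel]
  bound <- exp(0.05 / RT298)
  expect_true(all(ratio <= bound & ratio >= 1 / bound))
  expect_equal(bound, 1.088, tolerance = 1e-3)
  expect_identical(perturb(ds, 0), ds)
})

test_that("perturbation by RT moves rates by at most a factor e", {
  ds <- generate_channels(generator_spec(seed = 5, n_antioxidants = 1))
  pert <- perturb(ds, RT298)
  r0 <- channel_rates(ds$channels, ds$media, ds$species)
  r1 <- channel_rates(pert$channels, pert$media, pert$species)
  sel <- which(!r0$diffusion_limited & r0$dG_act_corrected > 1 &
                 r0$k_app < 1e8 & r1$dG_act_corrected > 0 &
                 !r1$diffusion_limited)
  ratio <- r1$k_app[sel] / r0$k_app[sel]
  expect_true(all(ratio <= exp(1) + 1e-9 & ratio >= exp(-1) - 1e-9))
})
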