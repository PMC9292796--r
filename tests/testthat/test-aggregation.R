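test_that("mechanism sums are degeneracy-weighted and context-checked", {
  ch <- demo_channel()
  rates <- channel_rates(ch, demo_media(), demo_species())
  s <- sum_mechanism(rates, "HAT")
  expect_equal(s$k_app_sum, rates$k_app)  # single sigma=1 channel unchanged

  # two identical sigma=2 channels double twice relative to one path
  two <- reaction_channel("PS", "HO", "RAF", c("2", "4"), "water",
                          dG_act_kcal = 25, dG_rxn_kcal = -10)
  one <- two[1, ]; one$sigma <- 1L
  r2 <- channel_rates(two, demo_media(), demo_species())
  r1 <- channel_rates(one, demo_media(), demo_species())
  expect_equal(sum_mechanism(r2, "RAF")$k_app_sum,
               4 * r1$k_app, tolerance = 1e-9)

  mixed <- rbind(demo_channel(),
                 reaction_channel("PS", "HOO", "HAT", "1", "water",
                                  dG_act_kcal = 0, dG_rxn_kcal = -7.6))
  rm <- channel_rates(mixed, demo_media(),
                      c(demo_species(),
                        list(HOO = species_spec("HOO", "radical",
                                                stokes_radius = 2.46e-10))))
  expect_error(sum_mechanism(rm, "HAT"), "mixed")
})

test_that("branching ratios recover the published percentages", {
  g <- branching_ratios(c(HAT = 2.61e9, RAF = 6.94e10, SET = 8.53e9))
  expect_equal(unname(round_half_away(g)), c(3, 86, 11))
  g <- branching_ratios(c(HAT = 1.96e9, SET = 6.76e9))
  expect_true(abs(g[["HAT"]] - 22.5) < 1 && abs(g[["SET"]] - 77.5) < 1)
  expect_identical(unname(branching_ratios(c(5e9, 0, 0))), c(100, 0, 0))
  expect_error(branching_ratios(c(0, 0)), "zero")
})

test_that("branching ratios are scale-invariant and ignore zero channels", {
  k <- c(2.61e9, 6.94e10, 8.53e9)
  expect_equal(branching_ratios(k), branching_ratios(k * 1e-7))
  expect_equal(unname(branching_ratios(c(k, 0))[1:3]),
               unname(branching_ratios(k)))
  expect_equal(sum(branching_ratios(k)), 100)
})

test_that("overall activity is the sum of mechanism sums", {
  expect_equal(overall_activity(c(1.96e9, 2.05e9 - 1.96e9)), 2.05e9)
  expect_identical(overall_activity(numeric(0)), 0)
})

test_that("report excludes direct oxidation from totals by default", {
  ch <- rbind(
    reaction_channel("PTE", "HOO", "HAT", "1", "water",
                     dG_act_kcal = 0, dG_rxn_kcal = -5.2),
    reaction_channel("PTE", "HOO", "OX", "none", "water",
                     dG_act_kcal = 12.2, dG_rxn_kcal = -18.4))
  sp <- list(PTE = species_spec("PTE", "antioxidant", 3.6e-10, "Te"),
             HOO = species_spec("HOO", "radical", 2.46e-10))
  rates <- channel_rates(ch, demo_media(), sp)
  rep <- scavenging_report(rates)
  expect_true(is.na(rep$gamma[rep$mechanism == "OX"]))
  expect_equal(rep$k_app_sum[rep$mechanism == "overall"],
               rep$k_app_sum[rep$mechanism == "HAT"])
  expect_equal(rep$gamma[rep$mechanism == "HAT"], 100)

  rep_ox <- scavenging_report(rates, rate_options(include_ox = TRUE))
  expect_false(is.na(rep_ox$gamma[rep_ox$mechanism == "OX"]))
  expect_equal(rep_ox$k_app_sum[rep_ox$mechanism == "overall"],
               sum(rates$k_app))
})

test_that("reported percentages round half away from zero", {
  expect_identical(round_half_away(c(86.5, 2.5, -2.5, 10.4)),
                   c(87, 3, -3, 10))
})
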