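test_that("the packaged dataset loads, validates, and is checksum-pinned", {
  fx <- cached_fixture()
  ch <- fx$channels
  expect_identical(nrow(ch), 228L)
  expect_identical(nrow(validate_channels(ch)), 0L)

  pick <- function(...) {
    sel <- ch[ch$antioxidant == ..1 & ch$radical == ..2 &
                ch$mechanism == ..3 & ch$site == ..4 & ch$medium == ..5, ]
    expect_identical(nrow(sel), 1L)
    sel
  }
  expect_identical(pick("PS", "HO", "HAT", "1", "water")$dG_rxn_kcal, -39.9)
  set_pte <- pick("PTE", "HOO", "SET", "none", "water")
  expect_identical(set_pte$dG_act_kcal, 7.4)
  expect_identical(set_pte$dG_rxn_kcal, 5.3)
  ox_pte <- pick("PTE", "HOO", "OX", "none", "water")
  expect_identical(ox_pte$dG_act_kcal, 12.2)
  expect_identical(ox_pte$dG_rxn_kcal, -18.4)

  # corrupted data must hard-fail the checksum pin
  tmp <- withr::local_tempdir()
  for (f in c("phenothiazine_channels.csv", "phenothiazine_config.yml",
              "printed_rate_table.csv")) {
    file.copy(system.file("extdata", f, package = "qmorsa"),
              file.path(tmp, f))
  }
  cat("x,y\n", file = file.path(tmp, "phenothiazine_channels.csv"),
      append = TRUE)
  expect_error(load_fixture(dir = tmp), "checksum")
})

test_that("site coverage matches the seven non-equivalent active sites", {
  ch <- cached_fixture()$channels
  expect_setequal(unique(ch$site[ch$mechanism == "HAT"]),
                  c("1", "2", "3", "4", "5"))
  expect_setequal(unique(ch$site[ch$mechanism == "RAF"]),
                  c("2", "2a", "3", "4", "5", "5a"))
  expect_true(all(ch$site[ch$mechanism %in% c("SET", "OX")] == "none"))
  ro <- ch[ch$ring_opening, ]
  expect_true(all(ro$antioxidant == "PTE" & ro$mechanism == "RAF" &
                    ro$site == "5a"))
  expect_identical(nrow(ro), 6L)  # 3 radicals x 2 media
})

test_that("inverted-region channels have lambda below |dG_rxn|", {
  rep <- cached_reproduction()
  inv <- rep$rates[rep$rates$marcus_region %in% "inverted", ]
  # the two hydroxyl-radical aqueous cases flagged in the source
  expect_setequal(paste(inv$antioxidant, inv$radical, inv$medium),
                  c("PSE HO water", "PTE HO water"))
  expect_true(all(inv$lambda_used < abs(inv$dG_rxn_kcal)))
  # and their barriers round-trip through the Marcus relation
  expect_equal(marcus_barrier(-13.0, inv$lambda_used[
    inv$antioxidant == "PSE"])$dG_act, 0.1, tolerance = 1e-9)
})

test_that("robust entries reproduce within the input-rounding budget", {
  cells <- cached_reproduction()$cells
  expect_true(all(c("robust", "calibrated", "not-reproducible") %in%
                    cells$class))
  robust <- cells[cells$class == "robust", ]
  expect_identical(nrow(robust), 13L)
  expect_true(all(robust$ratio > 1 / 1.2 & robust$ratio < 1.2))
  # mechanism-level calibrated entries match by construction; "overall"
  # rows inherit the 3-significant-figure rounding of the printed values
  calibrated <- cells[cells$class == "calibrated", ]
  mech_cal <- calibrated[calibrated$mechanism != "overall", ]
  expect_true(all(abs(mech_cal$ratio - 1) < 1e-6))
  expect_true(all(abs(calibrated$ratio - 1) < 5e-3))
  # every published entry appears exactly once
  expect_identical(anyDuplicated(cells[, c("medium", "mechanism",
                                           "radical", "antioxidant")]), 0L)
})

test_that("recomputed branching matches the printed integers within 1 point", {
  cells <- cached_reproduction()$cells
  have <- !is.na(cells$gamma_printed) & !is.na(cells$gamma_recomputed) &
    cells$class != "not-reproducible"
  expect_true(all(abs(cells$gamma_recomputed[have] -
                        cells$gamma_printed[have]) <= 1))
})

test_that("direct chalcogen oxidation is negligible even in its best case", {
  rates <- cached_reproduction()$rates
  best_ox <- rates[rates$antioxidant == "PTE" & rates$radical == "HOO" &
                     rates$mechanism == "OX" & rates$medium == "water", ]
  hat <- rates[rates$antioxidant == "PTE" & rates$radical == "HOO" &
                 rates$mechanism == "HAT" & rates$site == "1" &
                 rates$medium == "water", ]
  expect_lt(best_ox$k_app, 1e-2 * hat$k_app)
})
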