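presets_all <- expand.grid(
  modality = c("surface_erosion", "bulk", "bulk_autocatalytic"),
  speed = c("fast", "matched", "slow"), stringsAsFactors = FALSE)

test_that("analytic milestones reproduce the published calendar", {
  lay <- default_layout()
  m <- milestones(degradation_preset("exponential", "fast"), lay)
  expect_equal(m$erosion_onset_day_surface, 105)
  expect_equal(m$full_degradation_day, 115)
  m <- milestones(degradation_preset("exponential", "slow"), lay)
  expect_equal(m$erosion_onset_day_surface, 768)
  onset_s <- c(fast = 23, matched = 45, slow = 90)
  onset_b <- c(fast = 12, matched = 23, slow = 45)
  bulk_done <- c(fast = 13, matched = 25, slow = 50)
  for (speed in names(onset_s)) {
    m <- milestones(degradation_preset("bulk_autocatalytic", speed), lay)
    expect_equal(m$erosion_onset_day_surface, unname(onset_s[speed]))
    expect_equal(m$erosion_onset_day_bulk, unname(onset_b[speed]))
    expect_equal(m$bulk_complete_day, unname(bulk_done[speed]))
  }
  m <- milestones(degradation_preset("surface_erosion", "fast"), lay)
  expect_equal(m$first_surface_layer_complete_day, 13)
  expect_equal(m$full_degradation_day, 25)
  m <- milestones(degradation_preset("bulk", "slow"), lay)
  expect_equal(m$full_degradation_day, 100)
  # zero rates report the "never" sentinel
  m <- milestones(degradation_params("exponential", k_e = 0), lay)
  expect_true(is.infinite(m$erosion_onset_day_surface))
  m <- milestones(degradation_params("bulk", k_E = 0, k_N = 0), lay)
  expect_true(is.infinite(m$full_degradation_day))
})

test_that("daily stepping matches the analytic calendar for every preset", {
  lay <- default_layout()
  horizon <- list(surface_erosion = 110, bulk = 110,
                  bulk_autocatalytic = 110)
  for (r in seq_len(nrow(presets_all))) {
    p <- degradation_preset(presets_all$modality[r], presets_all$speed[r])
    an <- milestones(p, lay)
    st <- degrade_trajectory(p, lay, horizon[[p$modality]])$stepped_milestones
    for (nm in names(unclass(an))) {
      if (is.na(an[[nm]]) || is.infinite(an[[nm]])) next
      expect_equal(st[[nm]], an[[nm]],
                   info = sprintf("%s %s %s", p$modality,
                                  presets_all$speed[r], nm))
    }
  }
  for (speed in c("fast", "slow")) {
    p <- degradation_preset("exponential", speed)
    an <- milestones(p, lay)
    st <- degrade_trajectory(p, lay, 790)$stepped_milestones
    expect_equal(st$erosion_onset_day_surface, an$erosion_onset_day_surface)
    expect_equal(st$full_degradation_day, an$full_degradation_day)
  }
})

test_that("surface erosion erodes layer by layer with carryover", {
  lay <- default_layout()
  p <- degradation_preset("surface_erosion", "fast")   # k_N = 0.04
  st <- scaffold_state(lay, p)
  for (d in 1:12) st <- degrade_step(st)
  outer <- st$initial_label == "surface"
  expect_true(all(abs(st$N[outer] - 0.02) < 1e-12))
  expect_true(all(st$N[!outer] == p$N0))
  expect_true(all(st$E[!outer] == p$E0))     # bulk modulus untouched
  st <- degrade_step(st)                     # day 13: first layer done
  expect_true(all(st$N[outer] == 0))
  expect_true(all(st$E[outer] == 0))
  # carryover: the overshoot continued into the newly exposed columns
  expect_true(all(abs(st$N[!outer] - 0.48) < 1e-12))
  expect_true(all(st$label[!outer][st$N[!outer] > 0] == "surface"))
  for (d in 14:25) st <- degrade_step(st)
  expect_true(all(st$N == 0))                # full degradation at day 25
  # zero rate leaves the state unchanged
  st0 <- scaffold_state(lay, degradation_params("surface_erosion", k_N = 0))
  st1 <- st0
  for (d in 1:30) st1 <- degrade_step(st1)
  expect_equal(st1$N, st0$N)
  expect_equal(st1$E, st0$E)
})

test_that("bulk degradation follows the linear law with erosion onset", {
  lay <- default_layout()
  p <- degradation_preset("bulk", "matched")   # k_E = 20
  st <- scaffold_state(lay, p)
  expect_true(all(st$E == 1000) && all(st$N == 0.5))  # initial condition
  for (d in 1:44) st <- degrade_step(st)
  expect_true(all(st$E == 1000 - 20 * 44))
  expect_true(all(st$N == 0.5))              # onset crossed at t = 45.0
  st <- degrade_step(st)
  expect_true(all(st$E == 100))
  expect_true(all(st$N == 0.5))              # zero decrement on the onset day
  for (d in 46:50) st <- degrade_step(st)
  expect_true(all(st$N == 0) && all(st$E == 0))
})

test_that("exponential decay reproduces the published modulus values", {
  lay <- default_layout()
  tr <- degrade_trajectory(degradation_preset("exponential", "slow"), lay,
                           125)$trajectory
  expect_equal(round(tr$mean_E[tr$day == 125]), 687)
  expect_equal(tr$mean_E[tr$day == 125], 1000 * exp(-0.003 * 125),
               tolerance = 1e-12)
  expect_equal(tr$defect_volume_fraction_pct[tr$day == 125], 15)
  # zero rate: E stays at E0
  tr0 <- degrade_trajectory(degradation_params("exponential", k_e = 0),
                            lay, 50)$trajectory
  expect_true(all(tr0$mean_E == 1000))
})

test_that("trajectories are monotone and match the closed forms", {
  lay <- default_layout()
  for (r in seq_len(nrow(presets_all))) {
    p <- degradation_preset(presets_all$modality[r], presets_all$speed[r])
    tr <- degrade_trajectory(p, lay, 60)$trajectory
    expect_true(all(diff(tr$mean_E) <= 1e-12))
    expect_true(all(diff(tr$mean_N) <= 1e-12))
  }
  # linear bulk trajectory equals E0 - kE d exactly before clipping
  p <- degradation_preset("bulk", "slow")
  tr <- degrade_trajectory(p, lay, 80)$trajectory
  expect_equal(tr$mean_E, pmax(0, 1000 - 10 * tr$day))
  # exponential equals the closed form to full floating precision
  p <- degradation_preset("exponential", "fast")
  st <- scaffold_state(lay, p)
  for (d in 1:60) st <- degrade_step(st)
  expect_equal(st$E, rep(1000 * exp(-0.022 * 60), length(st$E)),
               tolerance = 1e-12)
})

test_that("modulus and volume fraction vanish together for all linear presets", {
  lay <- default_layout()
  for (speed in c("fast", "matched", "slow")) {
    for (mod in c("bulk", "bulk_autocatalytic")) {
      p <- degradation_preset(mod, speed)
      st <- scaffold_state(lay, p)
      day_E0 <- NA; day_N0 <- NA
      for (d in 1:110) {
        st <- degrade_step(st)
        if (is.na(day_E0) && all(st$E == 0)) day_E0 <- d
        if (is.na(day_N0) && all(st$N == 0)) day_N0 <- d
      }
      expect_equal(day_E0, day_N0, info = paste(mod, speed))
    }
  }
})

test_that("stepping rules reject a mismatched modality", {
  lay <- default_layout()
  st <- scaffold_state(lay, degradation_preset("bulk", "fast"))
  expect_error(step_surface_erosion(st, st$params), "modality")
  st2 <- scaffold_state(lay, degradation_preset("surface_erosion", "fast"))
  expect_error(step_exponential(st2, st2$params), "modality")
})
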