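make_event <- function(n_bites, dur_s = 30, fish = "f1", sp = "A",
                       x = NULL, t = NULL, mass = NULL) {
  df <- data.frame(fish_id = fish, species = sp, quadrat = "Q1", TL_mm = 110,
                   entry_s = 0, exit_s = dur_s,
                   t_s = if (is.null(t)) seq(1, dur_s - 1,
                                             length.out = n_bites) else t,
                   substrate = "rock",
                   x_cm = if (is.null(x)) rep(0, n_bites) else x,
                   y_cm = 0, z_cm = 0)
  if (!is.null(mass)) df$mass_g <- mass
  df
}

test_that("benthic cover turns cell counts into fractions", {
  expect_equal(unname(benthic_cover(c(rubble = 500, sand = 500))$cover),
               c(0.5, 0.5))
  expect_equal(unname(benthic_cover(c(rock = 123))$cover), 1)
  expect_equal(unname(benthic_cover(c(a = 700, b = 200, c = 100))$cover),
               c(0.7, 0.2, 0.1))
  expect_error(benthic_cover(c(a = -1, b = 2)), ">= 0")
  expect_error(benthic_cover(c(a = 0, b = 0)), "> 0")
  expect_error(substrate_profile(c(a = 0.6, b = 0.6)), "sum to 1")
})

test_that("bite rate standardizes counts by visit duration", {
  expect_equal(bite_rate(make_event(10, dur_s = 30)), 20)
  expect_equal(bite_rate(make_event(1, dur_s = 60)), 1)
  # duration-weighted mean of split-event rates equals the whole-event rate
  whole <- make_event(12, dur_s = 60)
  first <- whole[whole$t_s < 20, ]; first$exit_s <- 20
  second <- whole[whole$t_s >= 20, ]; second$entry_s <- 20
  weighted <- (bite_rate(first) * 20 + bite_rate(second) * 40) / 60
  expect_equal(weighted, bite_rate(whole))
  bad <- make_event(3); bad$exit_s <- bad$entry_s
  expect_error(bite_rate(bad), "duration")
})

test_that("mean bite distance averages consecutive distances in time order", {
  # collinear bites at 0, 30, 90 mm -> (30 + 60) / 2 = 45 mm
  ev <- make_event(3, x = c(0, 3, 9))
  expect_equal(mean_bite_distance(ev), 45)
  expect_equal(mean_bite_distance(make_event(4, x = rep(2, 4))), 0)
  # traversing the same positions in reverse order leaves the mean unchanged
  expect_equal(mean_bite_distance(make_event(3, x = c(9, 3, 0))), 45)
  # fewer than two positioned bites -> missing, not zero
  one <- make_event(2, x = c(1, NA))
  expect_true(is.na(mean_bite_distance(one)))
})

test_that("biomass counts each individual once per window", {
  two <- rbind(make_event(3, fish = "f1", mass = 50),
               make_event(4, fish = "f2", mass = 50))
  expect_equal(biomass_per_quadrat(two), 100)
  expect_equal(biomass_per_quadrat(two[0, ]), 0)
  # the same fish re-entering is not double-counted
  re <- rbind(make_event(3, fish = "f1", mass = 80),
              transform(make_event(2, fish = "f1", mass = 80),
                        entry_s = 100, exit_s = 130, t_s = t_s + 100))
  expect_equal(biomass_per_quadrat(re), 80)
})

test_that("feeding rate and pressure reproduce their unit arithmetic", {
  ev <- make_event(60, dur_s = 100, mass = 100)   # one 0.1 kg fish, 60 bites
  expect_equal(unname(feeding_rate(ev, window_min = 45, area_m2 = 1)), 80)
  expect_equal(unname(feeding_rate(ev, window_min = 90, area_m2 = 1)), 40)
  expect_equal(unname(feeding_pressure(ev, window_min = 45, area_m2 = 1)), 8)
  # two identical fish match one fish with double the bites (bilinearity)
  twofish <- rbind(make_event(30, fish = "f1", mass = 100),
                   make_event(30, fish = "f2", mass = 100))
  expect_equal(feeding_pressure(twofish, 45, 1), feeding_pressure(ev, 45, 1))
  # massless community exerts no pressure
  ev0 <- make_event(10, mass = 1e-12)
  expect_lt(unname(feeding_pressure(ev0, 45, 1)), 1e-10)
  expect_equal(length(feeding_rate(ev[0, ], 45, 1)), 0L)
  # consistency identity: pressure = rate x mass when all fish share a mass
  expect_equal(unname(feeding_pressure(ev, 45, 1)),
               unname(feeding_rate(ev, 45, 1)) * 0.1)
})

test_that("Manly ratios convert use and availability into preferences", {
  prof <- substrate_profile(c(rock = 0.5, sand = 0.5))
  neutral <- manly_ratios(c(rock = 20, sand = 20), prof)
  expect_equal(unname(neutral$w), c(1, 1))
  expect_equal(unname(neutral$preference_pct), c(50, 50))

  sel <- manly_ratios(c(rock = 30, sand = 10), prof)
  expect_equal(unname(sel$w), c(1.5, 0.5))
  expect_equal(unname(sel$preference_pct), c(75, 25))
  expect_equal(sum(sel$preference_pct), 100)

  # merging never-used categories leaves used-category preferences unchanged
  prof4 <- substrate_profile(c(rock = 0.4, sand = 0.3, coral = 0.2,
                               rubble = 0.1))
  prof3 <- substrate_profile(c(rock = 0.4, sand = 0.3, other = 0.3))
  a <- manly_ratios(c(rock = 30, sand = 10), prof4)
  b <- manly_ratios(c(rock = 30, sand = 10), prof3)
  expect_equal(a$preference_pct[c("rock", "sand")],
               b$preference_pct[c("rock", "sand")])

  expect_error(manly_ratios(c(rock = 1, lava = 2), prof), "lava")
  zero <- substrate_profile(c(rock = 1, sand = 0))
  expect_error(manly_ratios(c(rock = 1, sand = 2), zero), "zero availability")
})

test_that("per-fish and pooled Manly modes agree for identical fish", {
  prof <- substrate_profile(c(rock = 0.5, sand = 0.5))
  bites <- rbind(make_event(4, fish = "f1"), make_event(4, fish = "f2"))
  bites$substrate <- rep(c("rock", "rock", "rock", "sand"), 2)
  pooled <- manly_ratios(c(rock = 6, sand = 2), prof)
  perfish <- manly_ratios(bites, prof, mode = "per_fish")
  expect_equal(perfish$preference_pct, pooled$preference_pct)
})

test_that("metrics are invariant to row order", {
  prof <- substrate_profile(c(rock = 0.6, sand = 0.4))
  bites <- simulate_feeding_observations(prof, c(rock = 2, sand = 1),
                                         n_fish = 10, seed = 6)
  bites$mass_g <- mass_from_length(0.0206, 3.01, bites$TL_mm)
  set.seed(1)
  shuf <- bites[sample.int(nrow(bites)), ]
  expect_equal(feeding_rate(shuf), feeding_rate(bites))
  expect_equal(feeding_pressure(shuf), feeding_pressure(bites))
  expect_equal(biomass_per_quadrat(shuf), biomass_per_quadrat(bites))
})

test_that("model selection ranks structures by AIC with a deterministic tie-break", {
  td <- simulate_trait_observations(fish_sd = 0, quadrat_sd = 0, seed = 31)
  rk <- trait_model_selection(td, include_mass = FALSE)
  expect_equal(nrow(rk), 3L)
  expect_true(all(diff(rk$AIC) >= 0))
  expect_match(rk$model[1], "^lm: ")
  expect_true(any(rk$singular))   # boundary fits reported, not dropped

  strong <- simulate_trait_observations(fish_sd = 0.8, quadrat_sd = 0,
                                        resid_sd = 0.2, seed = 32)
  rk2 <- trait_model_selection(strong, include_mass = FALSE)
  expect_match(rk2$model[1], "lmm_fish")

  expect_error(trait_model_selection(transform(td, trait = trait - 100)),
               "positive")
})
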