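test_that("geometric ladders hit their endpoints with constant ratio", {
  l64 <- make_ladder(300, 455.95, 64)
  expect_length(l64$temperatures, 64L)
  expect_identical(l64$temperatures[1], 300)
  expect_identical(l64$temperatures[64], 455.95)
  expect_true(all(diff(l64$temperatures) > 0))

  l32 <- make_ladder(300, 452.32, 32)
  ratios <- l32$temperatures[-1] / l32$temperatures[-32]
  expect_lt(max(abs(ratios - (452.32 / 300)^(1 / 31))), 1e-9)
  # cumulative product route as an independent check on the closed form
  expect_equal(l32$temperatures,
               300 * cumprod(c(1, rep((452.32 / 300)^(1 / 31), 31))),
               tolerance = 1e-9)

  expect_equal(make_ladder(300, 300.0001, 2)$temperatures, c(300, 300.0001))
  expect_error(make_ladder(400, 300, 8), "T_max > T_min")
  expect_error(make_ladder(300, 400, 1), "at least 2")
})

test_that("ensemble specs validate weights and apply the glycosylation shift", {
  expect_error(residue_ensemble_spec(c(PPII = 0.6, beta = 0.6)), "sum to 1")
  expect_error(residue_ensemble_spec(c(PPII = 0.5, junk = 0.5)), "named after")
  sp <- residue_ensemble_spec(c(PPII = 0.45, alphaR = 0.35, beta = 0.2),
                              glycosylated = TRUE, glyco_weight_shift = 0.3)
  w <- sapply(sp$basins, `[[`, "weight")
  expect_equal(unname(w[sapply(sp$basins, `[[`, "name") == "PPII"]), 0.75)
  expect_equal(unname(w[sapply(sp$basins, `[[`, "name") == "alphaR"]), 0.05)
  expect_equal(sum(w), 1)
})

test_that("degenerate concentration collapses every draw onto the basin centre", {
  sp <- residue_ensemble_spec(c(PPII = 1), kappa = Inf)
  tr <- sample_ensemble(sp, 50, seed = 9)
  expect_true(all(tr$phi == -75))
  expect_true(all(tr$psi == 145))
})

test_that("sampled region populations match the closed-form mixture oracle", {
  n <- 20000
  for (kap in c(12, 50)) {
    sp <- residue_ensemble_spec(c(PPII = 0.7, alphaR = 0.3), kappa = kap)
    tr <- sample_ensemble(sp, n, seed = 100 + kap)
    emp <- residue_populations(tr)
    want <- oracle_region_probs(sp)
    for (lab in names(want)) {
      p <- want[[lab]]
      se <- sqrt(max(p * (1 - p), 1e-6) / n)
      expect_lt(abs(emp$fraction[emp$region == lab] - p), 3 * se + 1e-3)
    }
  }
})

test_that("the glycosylation shift empties alphaR in the sampled ensemble", {
  base <- c(PPII = 0.45, alphaR = 0.35, beta = 0.15, alphaL = 0.05)
  plain <- residue_ensemble_spec(base, kappa = 12)
  glyc <- residue_ensemble_spec(base, kappa = 12, glycosylated = TRUE,
                                glyco_weight_shift = 0.3)
  tp <- residue_populations(sample_ensemble(plain, 8000, seed = 51))
  tg <- residue_populations(sample_ensemble(glyc, 8000, seed = 52))
  expect_lt(tg$fraction[tg$region == "alphaR"],
            tp$fraction[tp$region == "alphaR"])
  expect_gt(tg$fraction[tg$region == "PPII"],
            tp$fraction[tp$region == "PPII"])
})

test_that("mixture energy: minimum at the centre, gauge freedom, closed-form differences", {
  sp <- residue_ensemble_spec(c(PPII = 1), kappa = 12)
  set.seed(61)
  phis <- runif(200, -180, 180); psis <- runif(200, -180, 180)
  e <- mixture_energy(phis, psis, sp)
  e0 <- mixture_energy(-75, 145, sp)
  expect_true(all(e >= e0))
  # energy differences equal -kB T ln(density ratio)
  d <- mixture_density(phis, psis, sp)
  expect_equal(e - e0,
               -k_boltzmann * 300 * log(d / mixture_density(-75, 145, sp)),
               tolerance = 1e-10)
  # periodic continuity across the +-180 seam
  psi_seq <- seq(-180, 180, by = 7.3)
  expect_lt(max(abs(mixture_energy(-180, psi_seq, sp) -
                    mixture_energy(180, psi_seq, sp))), 1e-9)
  expect_lt(max(abs(mixture_energy(psi_seq, -180, sp) -
                    mixture_energy(psi_seq, 180, sp))), 1e-9)
})

test_that("exchange probability follows the Metropolis closed form", {
  expect_equal(exchange_probability(5, 5, 300, 400), 1.0)
  expect_equal(exchange_probability(3, 7, 350, 350), 1.0)
  d_beta <- 1 / (k_boltzmann * 300) - 1 / (k_boltzmann * 400)
  # +1 kcal/mol on the colder replica: exp(d_beta * 1), capped for the
  # reversed sign
  expect_equal(exchange_probability(1, 2, 300, 400), exp(-d_beta))
  expect_equal(exchange_probability(2, 1, 300, 400), 1.0)  # Metropolis cap
  expect_error(exchange_probability(1, 2, -300, 400), "positive")
})

test_that("all sampler outputs live in [-180, 180)", {
  sp <- residue_ensemble_spec(c(PPII = 0.5, beta = 0.5), kappa = 2)
  tr <- sample_ensemble(list(sp, sp), 2000, seed = 77)
  expect_true(all(tr$phi >= -180 & tr$phi < 180))
  expect_true(all(tr$psi >= -180 & tr$psi < 180))
  run <- remd_run(sp, make_ladder(300, 455.95, 3), n_sweeps = 200, seed = 78)
  for (t in run$trajectories) {
    expect_true(all(t$phi >= -180 & t$phi < 180))
    expect_true(all(t$psi >= -180 & t$psi < 180))
  }
})

test_that("identical-temperature replicas always exchange", {
  sp <- residue_ensemble_spec(c(PPII = 1), kappa = 5)
  run <- remd_run(sp, make_ladder(300, 300 + 1e-9, 2), n_sweeps = 100,
                  exchange_interval = 5, seed = 13)
  att <- run$exchanges[run$exchanges$pair_i == 1, ]
  expect_gt(nrow(att), 0)
  expect_true(all(att$accepted))
})

test_that("fixed-temperature sampling matches grid-integrated Boltzmann weights", {
  sp <- residue_ensemble_spec(c(PPII = 1), kappa = 3)
  run <- remd_run(sp, make_ladder(300, 300.0001, 2), n_sweeps = 20000, seed = 7)
  tr <- run$trajectories[[1]]
  po <- oracle_boltzmann_bins(sp)
  pe <- empirical_bins(tr, frames = 2001:20000)
  expect_lt(tv_distance(po, pe), 0.05)
})

test_that("stretching the ladder lowers exchange acceptance", {
  specs <- ensemble_spec_for_model(tttt_model())
  narrow <- remd_run(specs, make_ladder(300, 455.95, 8), n_sweeps = 1500,
                     seed = 3)
  wide <- remd_run(specs, make_ladder(300, 900, 8), n_sweeps = 1500, seed = 3)
  expect_true(all(narrow$exchange_rates > 0 & narrow$exchange_rates <= 1))
  expect_lt(mean(wide$exchange_rates), mean(narrow$exchange_rates))
})

test_that("sampler rejects invalid arguments", {
  sp <- residue_ensemble_spec(c(PPII = 1))
  lad <- make_ladder(300, 455.95, 2)
  expect_error(remd_run(sp, lad, 10, proposal_step = 0, seed = 1), "positive")
  expect_error(remd_run(sp, lad, 10, exchange_interval = 0, seed = 1), ">= 1")
  expect_error(remd_run(sp, lad, 10), "seed")
  expect_error(sample_ensemble(sp, 10), "seed")
})
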