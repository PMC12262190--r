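test_that("2D histograms are normalised and localise degenerate ensembles", {
  sp <- residue_ensemble_spec(c(PPII = 1), kappa = Inf)
  tr <- sample_ensemble(sp, 100, seed = 1)
  h <- histogram2d(tr, n_bins = 72)
  expect_equal(sum(h$P), 1)
  expect_equal(max(h$P), 1)           # single bin holds everything
  expect_equal(sum(h$P > 0), 1L)

  sp2 <- residue_ensemble_spec(c(PPII = 0.6, beta = 0.4), kappa = 8)
  h2 <- histogram2d(sample_ensemble(sp2, 5000, seed = 2), n_bins = 36)
  expect_equal(sum(h2$P), 1)
  expect_error(histogram2d(tr, n_bins = 1), ">= 2")
})

test_that("free-energy surface follows the Boltzmann-inversion closed form", {
  # two-bin toy distribution: P = P_max / 2 must sit at kB*300*ln2
  P <- matrix(0, 72, 72)
  P[10, 10] <- 2 / 3
  P[20, 20] <- 1 / 3
  fes <- free_energy_surface(P, T = 300)
  expect_identical(fes$dG[10, 10], 0)
  expect_equal(fes$dG[20, 20], 0.0019872041 * 300 * log(2), tolerance = 1e-12)
  expect_equal(fes$dG[20, 20], 0.4132, tolerance = 1e-3)
  expect_true(all(is.infinite(fes$dG[P == 0])))

  fes2 <- free_energy_surface(P, T = 600)
  defined <- is.finite(fes$dG)
  expect_equal(fes2$dG[defined], 2 * fes$dG[defined], tolerance = 1e-12)
})

test_that("surface invariants: nonnegative, zero mode, exact inversion, duplication-stable", {
  sp <- residue_ensemble_spec(c(PPII = 0.5, alphaR = 0.3, beta = 0.2),
                              kappa = 10)
  tr <- sample_ensemble(list(sp, sp, sp), 3000, seed = 4)
  fes <- free_energy_surface(tr, T = 300)
  expect_true(all(fes$dG >= 0))
  expect_identical(min(fes$dG), 0)
  expect_equal(sum(fes$P), 1)
  defined <- is.finite(fes$dG)
  expect_lt(max(abs(exp(-fes$dG[defined] / (fes$k_B * fes$T)) * fes$P_max -
                    fes$P[defined])), 1e-12)
  # duplicating every frame leaves the surface unchanged
  tr2 <- dihedral_trajectory(rbind(tr$phi, tr$phi), rbind(tr$psi, tr$psi),
                             tr$residues)
  fes2 <- free_energy_surface(tr2, T = 300)
  expect_equal(fes2$dG, fes$dG)
  expect_error(free_energy_surface(matrix(0.5, 2, 1), T = -1), "positive")
})

test_that("classifier reproduces the printed worked examples", {
  expect_identical(classify(-75, 145), "PPII")
  expect_identical(classify(60, 45), "alphaL")
  expect_identical(classify(0, 0), "coil")
  expect_identical(classify(-100, -170), "beta")   # psi wraps: -170 == 190
  expect_identical(classify(-63, -60), "alphaR")
  # strict bounds: angles exactly on a printed bound fall to coil
  expect_identical(classify(-90, 145), "coil")
  expect_identical(classify(-75, 50), "coil")
})

test_that("classifier is total, single-valued and disjoint on a 1-degree torus scan", {
  g <- expand.grid(phi = seq(-180, 179, by = 1), psi = seq(-180, 179, by = 1))
  regions <- region_set()
  hits <- matrix(FALSE, nrow(g), nrow(regions))
  for (r in seq_len(nrow(regions)))
    hits[, r] <- ppiiens:::.in_circ(g$phi, regions$phi_lo[r], regions$phi_hi[r]) &
                 ppiiens:::.in_circ(g$psi, regions$psi_lo[r], regions$psi_hi[r])
  expect_true(all(rowSums(hits) <= 1))          # pairwise disjoint
  lab <- classify(g$phi, g$psi, regions)
  expect_false(anyNA(lab))                       # total
  expect_identical(lab[rowSums(hits) == 0], rep("coil", sum(rowSums(hits) == 0)))
  one <- rowSums(hits) == 1
  expect_identical(lab[one], regions$name[apply(hits[one, ], 1, which)])
})

test_that("overlapping region definitions are rejected", {
  bad <- data.frame(name = c("PPII", "beta"),
                    phi_lo = c(-90, -100), phi_hi = c(20, -80),
                    psi_lo = c(50, 50), psi_hi = c(240, 240))
  expect_error(region_set(bad), "overlap")
})

test_that("per-residue populations equal the time-average of classifier labels", {
  sp <- residue_ensemble_spec(c(PPII = 0.6, alphaR = 0.4), kappa = 15)
  tr <- sample_ensemble(list(sp, sp), 400, seed = 8)
  pops <- residue_populations(tr)
  for (j in 1:2) {
    lab <- classify(tr$phi[, j], tr$psi[, j])
    for (region in unique(pops$region)) {
      expect_equal(
        pops$fraction[pops$region == region][j],
        mean(lab == region))
    }
  }
  sums <- tapply(pops$fraction, pops$residue_number, sum)
  expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-9)
})

test_that("degenerate PPII ensemble has population 1 and CI [1, 1]", {
  sp <- residue_ensemble_spec(c(PPII = 1), kappa = Inf)
  tr <- sample_ensemble(sp, 300, seed = 10)
  ci <- population_ci(tr, block_length = 5, n_boot = 200, seed = 1)
  row <- ci$region == "PPII"
  expect_equal(ci$fraction[row], 1)
  expect_equal(ci$ci_low[row], 1)
  expect_equal(ci$ci_high[row], 1)
  expect_equal(ci$fraction[ci$region == "alphaR"], 0)
})

test_that("bootstrap CIs are deterministic under a fixed seed and shrink ~1/sqrt(n)", {
  sp <- residue_ensemble_spec(c(PPII = 0.6, alphaR = 0.4), kappa = 20)
  tr <- sample_ensemble(sp, 4000, seed = 12)
  ci_a <- population_ci(tr, n_boot = 300, seed = 99)
  ci_b <- population_ci(tr, n_boot = 300, seed = 99)
  expect_identical(ci_a$ci_low, ci_b$ci_low)
  expect_identical(ci_a$ci_high, ci_b$ci_high)

  small <- dihedral_trajectory(tr$phi[1:1000, , drop = FALSE],
                               tr$psi[1:1000, , drop = FALSE], tr$residues)
  ci_small <- population_ci(small, n_boot = 300, seed = 99)
  w_large <- ci_a$ci_high - ci_a$ci_low
  w_small <- ci_small$ci_high - ci_small$ci_low
  row <- ci_a$region == "PPII"
  expect_equal(w_small[row] / w_large[row], 2, tolerance = 0.35)
})

test_that("population CI validates its arguments", {
  sp <- residue_ensemble_spec(c(PPII = 1))
  tr <- sample_ensemble(sp, 100, seed = 1)
  expect_error(population_ci(tr, block_length = 100, n_boot = 200, seed = 1),
               "block_length")
  expect_error(population_ci(tr, n_boot = 50, seed = 1), "n_boot")
  expect_error(population_ci(tr, n_boot = 200), "seed")
})

test_that("identical ensembles show no significant population differences", {
  sp <- residue_ensemble_spec(c(PPII = 0.6, alphaR = 0.4), kappa = 15)
  tr <- sample_ensemble(list(sp, sp), 2000, seed = 21)
  cmp <- compare_populations(tr, tr, n_boot = 300, seed = 22)
  expect_false(any(cmp$significant))
  expect_true(all(cmp$delta == 0))
})

test_that("a constructed alphaR->PPII weight shift is detected with direction", {
  base <- c(PPII = 0.45, alphaR = 0.35, beta = 0.15, alphaL = 0.05)
  plain <- residue_ensemble_spec(base, kappa = 12)
  glyc <- residue_ensemble_spec(base, kappa = 12, glycosylated = TRUE,
                                glyco_weight_shift = 0.3)
  ta <- sample_ensemble(list(plain, plain), 20000, seed = 31)
  tb <- sample_ensemble(list(glyc, glyc), 20000, seed = 32)
  cmp <- compare_populations(ta, tb, n_boot = 300, seed = 33)
  ppii <- cmp[cmp$region == "PPII", ]
  ar <- cmp[cmp$region == "alphaR", ]
  expect_true(all(ppii$significant))
  expect_true(all(ppii$direction == "increase"))
  expect_true(all(ar$significant))
  expect_true(all(ar$direction == "decrease"))
})

test_that("comparison rejects mismatched residue labelling", {
  sp <- residue_ensemble_spec(c(PPII = 1))
  ta <- sample_ensemble(list(sp, sp), 50, seed = 1)
  tb <- sample_ensemble(list(sp), 50, seed = 2)
  expect_error(compare_populations(ta, tb, n_boot = 200, seed = 3),
               "residue")
})

test_that("null comparisons flag differences at about the nominal rate", {
  sp <- residue_ensemble_spec(c(PPII = 0.55, alphaR = 0.25, beta = 0.2),
                              kappa = 12)
  n_rep <- 30
  calls <- logical(0)
  for (r in seq_len(n_rep)) {
    ta <- sample_ensemble(sp, 1000, seed = 1000 + r)
    tb <- sample_ensemble(sp, 1000, seed = 2000 + r)
    cmp <- compare_populations(ta, tb, n_boot = 250, seed = 3000 + r)
    calls <- c(calls, cmp$significant)
  }
  rate <- mean(calls)
  # 150 label-level calls at alpha = 0.05: a generous binomial envelope
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.15)
})
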