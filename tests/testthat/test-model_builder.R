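test_that("glycosylation-site assignment finds threonines and honours exclusions", {
  expect_equal(assign_glyco_sites("PKEPAPTTTKEPAPTTPK", 393, exclude = 401),
               c(399L, 400L, 407L, 408L))
  expect_equal(assign_glyco_sites("AAAA", 1), integer(0))
  expect_equal(assign_glyco_sites("TTTT", 1), 1:4)
  expect_error(assign_glyco_sites("TTTT", 1, exclude = 9), "outside")
  expect_error(assign_glyco_sites("TATA", 1, exclude = 2), "not threonine")
  expect_error(assign_glyco_sites("TBXT", 1), "unknown residue")
})

test_that("site count equals threonine count minus exclusions (property)", {
  set.seed(11)
  for (i in 1:25) {
    seq <- paste(sample(c("T", "A", "P", "K", "S"), 30, replace = TRUE),
                 collapse = "")
    first <- sample(1:500, 1)
    thr <- which(strsplit(seq, "")[[1]] == "T") + first - 1L
    n_ex <- min(length(thr), sample(0:3, 1))
    ex <- if (n_ex) sample(thr, n_ex) else integer()
    got <- assign_glyco_sites(seq, first, exclude = ex)
    expect_length(got, length(thr) - n_ex)
    expect_true(all(got %in% thr))
  }
})

test_that("high-PPII-propensity residue counting", {
  expect_identical(count_high_ppii_residues("KEPAPTTP"), 5L)
  expect_identical(count_high_ppii_residues(""), 0L)
  expect_identical(count_high_ppii_residues("PPPP", "P"), 4L)
  expect_error(count_high_ppii_residues("PXZP"), "unknown residue")
})

test_that("peptide model validates glyco sites and numbering", {
  m <- mucin_model(glycosylated = TRUE)
  expect_equal(m$residues$number[m$residues$glycosylated],
               c(399L, 400L, 407L, 408L))
  expect_equal(m$residues$number, 393:410)
  expect_error(peptide_model("APA", glyco_sites = 2), "threonine or serine")
  expect_error(peptide_model("ATA", glyco_sites = 7), "numbering range")
})

test_that("backbone geometry rejects non-physical parameters", {
  expect_error(backbone_geometry(bond_n_ca = 2.5), "bond lengths")
  expect_error(backbone_geometry(angle_n_ca_c = 60), "bond angles")
  expect_error(backbone_geometry(masses = c(N = 14, CA = 12, C = 12, O = -1)),
               "masses")
})

test_that("build/measure round trip reproduces arbitrary dihedral assignments", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    m <- peptide_model(paste(sample(c("A", "P", "T", "K"), n, replace = TRUE),
                             collapse = ""),
                       phi = runif(n, -179, 179), psi = runif(n, -179, 179))
    dt <- compute_dihedrals(build_backbone(m))
    interior <- 2:(n - 1)
    expect_lt(max(abs(dt$phi[1, interior] - m$dihedrals$phi[interior])), 1e-6)
    expect_lt(max(abs(dt$psi[1, interior] - m$dihedrals$psi[interior])), 1e-6)
    # termini: undefined on the open end only
    expect_true(is.na(dt$phi[1, 1]) && is.na(dt$psi[1, n]))
  }
})

test_that("canonical PPII build measures back (-75, 145) at interior residues", {
  dt <- compute_dihedrals(build_backbone(mucin_model()))
  expect_lt(max(abs(dt$phi[1, 2:17] - (-75))), 1e-6)
  expect_lt(max(abs(dt$psi[1, 2:17] - 145)), 1e-6)
})

test_that("helix fit recovers canonical geometries", {
  ppii <- helix_parameters(build_backbone(mucin_model()))
  expect_equal(round(ppii$residues_per_turn), 3)
  expect_identical(ppii$handedness, "left")
  expect_lt(ppii$twist, 0)

  alpha <- helix_parameters(build_backbone(
    peptide_model(strrep("A", 18), phi = -57, psi = -47)))
  expect_equal(alpha$residues_per_turn, 3.6, tolerance = 0.03)
  expect_identical(alpha$handedness, "right")

  ext <- helix_parameters(build_backbone(
    peptide_model(strrep("A", 18), phi = -135, psi = 135)))
  expect_equal(ext$residues_per_turn, 2, tolerance = 0.05)
})

test_that("helix fit is invariant under rigid-body motion and rejects degenerate traces", {
  bb <- build_backbone(mucin_model())
  ca <- bb$coords[1, bb$atoms$atom == "CA", ]
  h0 <- helix_parameters(ca)
  for (s in 1:3) {
    h1 <- helix_parameters(random_rigid_motion(ca, seed = s))
    expect_equal(h1$twist, h0$twist, tolerance = 1e-9)
    expect_equal(h1$rise, h0$rise, tolerance = 1e-9)
  }
  line <- cbind(seq_len(8) * 3.0, 0, 0)
  expect_error(helix_parameters(line), "degenerate|collinear")
  expect_error(helix_parameters(ca[1:4, ]), "at least 6")
})

test_that("PDB writer emits one MODEL per frame and annotates glyco sites", {
  m <- mucin_model(glycosylated = TRUE)
  traj1 <- build_backbone(m)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(traj1, path)
  lines <- readLines(path)
  expect_length(grep("^MODEL", lines), 1L)
  expect_match(grep("REMARK 999", lines, value = TRUE)[1],
               "399 400 407 408")

  tr <- sample_ensemble(ensemble_spec_for_model(m), 10, seed = 5,
                        residues = m$residues)
  traj10 <- build_backbone_trajectory(tr)
  write_pdb(traj10, path)
  expect_length(grep("^MODEL", readLines(path)), 10L)
})
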