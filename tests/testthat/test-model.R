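# Interfacial model: slab rendering, volume-fraction and SLD profiles,
# membrane-to-SAM distance.

test_that("slab rendering produces the documented stack orderings", {
  u <- underlayers()
  bare <- render_slabs(u, NULL, "D2O")
  expect_equal(nrow(bare), 6)
  expect_equal(bare$layer,
               c("si", "sio2_permalloy_mix", "permalloy", "gold", "sam",
                 "solvent"))
  mem <- render_slabs(u, floating_membrane(), "D2O")
  expect_equal(nrow(mem), 11)
  expect_equal(mem$layer[6:10],
               c("interlayer", "inner_heads", "tails", "outer_heads",
                 "peripheral_protein"))
  # tails slab: 61% lipid tails, 24% protein, 15% D2O
  expect_equal(mem$sld[mem$layer == "tails"],
               0.61 * (-0.4) + 0.24 * 3.2 + 0.15 * 6.36, tolerance = 1e-12)
  # optional inner-protein layer appears only when given thickness
  mem12 <- render_slabs(u, floating_membrane(inner_protein_thickness = 10,
                                             inner_protein_fraction = 0.2),
                        "D2O")
  expect_equal(nrow(mem12), 12)
  expect_true("inner_protein" %in% mem12$layer)
})

test_that("a zero-coverage SAM is invisible at every contrast", {
  u0 <- underlayers(sam_coverage = 0)
  for (ct in c("D2O", "AuMW", "PrMW", "H2O")) {
    s <- render_slabs(u0, NULL, ct)
    expect_equal(s$sld[s$layer == "sam"], s$sld[s$layer == "solvent"],
                 tolerance = 1e-12)
  }
})

test_that("over-filled layer compositions are rejected at render time", {
  bad <- floating_membrane(tail_lipid = 0.8, tail_protein = 0.3)
  expect_error(render_slabs(underlayers(), bad, "D2O"), "sums to")
})

test_that("component fractions sum to one everywhere, across random draws", {
  set.seed(41)
  for (i in 1:20) {
    m <- floating_membrane(
      interlayer_thickness = runif(1, 0, 140),
      head_lipid = runif(1, 0, 0.6), head_protein = runif(1, 0, 0.4),
      tail_lipid = runif(1, 0, 0.7), tail_protein = runif(1, 0, 0.3),
      peripheral_protein = runif(1, 0, 0.5),
      bilayer_roughness = runif(1, 1, 70),
      peripheral_roughness = runif(1, 1, 70))
    prof <- component_profile(underlayers(), m)
    sums <- rowSums(prof[, setdiff(names(prof), "z")])
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-6)
  }
})

test_that("sharp-interface profiles match the layer table exactly", {
  u <- underlayers(si_roughness = 0, mix_roughness = 0, permalloy_roughness = 0,
                   gold_roughness = 0, sam_roughness = 0)
  m <- floating_membrane(bilayer_roughness = 0, peripheral_roughness = 0)
  prof <- component_profile(u, m)
  mid <- function(z) prof[which.min(abs(prof$z - z)), ]
  # midpoints: gold at 12+120+45; tails centre; peripheral centre
  expect_equal(mid(12 + 120 + 45)$gold, 1, tolerance = 1e-9)
  z_tails <- 12 + 120 + 90 + 25 + 11 + 8 + 15
  expect_equal(mid(z_tails)$lipid_tails, 0.61, tolerance = 1e-9)
  expect_equal(mid(z_tails)$protein, 0.24, tolerance = 1e-9)
  expect_equal(mid(z_tails)$water, 0.15, tolerance = 1e-9)
  z_per <- 12 + 120 + 90 + 25 + 11 + 8 + 30 + 8 + 25
  expect_equal(mid(z_per)$protein, 0.13, tolerance = 1e-9)
})

test_that("profile integrals equal the analytic layer sums", {
  u <- underlayers()
  m <- floating_membrane()
  prof <- component_profile(u, m, dz = 0.5)
  # trapezoid integral of the lipid fractions vs sum(fraction * thickness)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * 0.5
  lipid_analytic <- 0.42 * 8 + 0.61 * 30 + 0.42 * 8
  expect_equal(trap(prof$lipid_heads + prof$lipid_tails), lipid_analytic,
               tolerance = 1e-3)
  protein_analytic <- 0.24 * (8 + 30 + 8) + 0.13 * 50.5
  expect_equal(trap(prof$protein), protein_analytic, tolerance = 1e-3)
})

test_that("SLD profile has the right asymptotes and plateaus", {
  u <- underlayers()
  m <- floating_membrane()
  p <- sld_profile(u, m, "D2O")
  # far field tends to the solvent
  expect_equal(tail(p$sld, 1), 6.36, tolerance = 1e-3)
  expect_equal(head(p$sld, 1), 2.07, tolerance = 1e-3)
  # a sharp-interface variant shows the pure-D2O interlayer plateau
  u2 <- underlayers(sam_roughness = 1)
  m2 <- floating_membrane(bilayer_roughness = 1)
  p2 <- sld_profile(u2, m2, "D2O")
  z_inter <- 12 + 120 + 90 + 25 + 5.5
  i <- which.min(abs(p2$z - z_inter))
  expect_equal(p2$sld[i], 6.36, tolerance = 1e-3)
})

test_that("protein matched water flattens the protein-only regions", {
  mats <- default_materials()
  f_match <- 0.42
  mats$sld_h2o[mats$material == "protein"] <- water_sld(f_match)
  mats$sld_d2o[mats$material == "protein"] <- water_sld(f_match)
  u <- underlayers()
  m <- floating_membrane()
  p <- sld_profile(u, m, f_match, materials = mats)
  # peripheral layer (protein + water only) is indistinguishable from bulk
  z_per <- 12 + 120 + 90 + 25 + 11 + 8 + 30 + 8 + 25
  i <- which.min(abs(p$z - z_per))
  expect_equal(p$sld[i], water_sld(f_match), tolerance = 1e-4)
})

test_that("membrane-to-SAM distance is the interlayer thickness", {
  expect_equal(membrane_to_sam_distance(floating_membrane()), 11)
  expect_equal(membrane_to_sam_distance(
    floating_membrane(interlayer_thickness = 0)), 0)
  m <- floating_membrane()
  m$interlayer_thickness <- 26
  expect_equal(membrane_to_sam_distance(m), 26)
  expect_error(membrane_to_sam_distance(NULL), "bare")
})

test_that("microsliced SLD profile reproduces the slab model reflectivity", {
  # cross-module oracle: feed sld_profile slices to the kernel directly and
  # compare with render_slabs + microslice in the small-roughness regime
  u <- underlayers(si_roughness = 2, mix_roughness = 2, permalloy_roughness = 2,
                   gold_roughness = 2, sam_roughness = 2)
  q <- default_q(80)
  s <- render_slabs(u, NULL, "D2O")
  r_slab <- abeles_reflectivity(s, q, "microslice", dz = 0.25, merge_tol = 0)
  p <- sld_profile(u, NULL, "D2O", dz = 0.25)
  manual <- tibble::tibble(
    thickness = c(0, rep(0.25, nrow(p)), 0),
    sld = c(2.07, p$sld, 6.36), roughness = 0)
  r_prof <- abeles_reflectivity(manual, q)
  expect_equal(r_prof, r_slab, tolerance = 5e-3)
  # and both agree with Nevot-Croce here
  r_nc <- abeles_reflectivity(s, q, "nevot_croce")
  expect_lt(max(abs(r_nc - r_slab) / r_nc), 5e-3)
})

test_that("an empty membrane is indistinguishable from the bare surface", {
  u <- underlayers()
  empty <- floating_membrane(interlayer_thickness = 0, head_lipid = 0,
                             head_protein = 0, tail_lipid = 0,
                             tail_protein = 0, peripheral_protein = 0,
                             head_thickness = 0, tail_thickness = 0,
                             peripheral_thickness = 0,
                             bilayer_roughness = 9, peripheral_roughness = 9)
  q <- default_q(60)
  for (ct in c("D2O", "H2O")) {
    r_bare <- abeles_reflectivity(render_slabs(u, NULL, ct), q, "microslice")
    r_mem <- abeles_reflectivity(render_slabs(u, empty, ct), q, "microslice")
    expect_equal(r_mem, r_bare, tolerance = 1e-6)
  }
})
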