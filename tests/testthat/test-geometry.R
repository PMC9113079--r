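test_that("concentric cross-section areas follow the squared-diameter law", {
  expect_equal(csa_concentric(0, 3.5), 9.62112750161874)
  expect_equal(csa_concentric(0.5, 3.5), 2.40528187540469)
  # area stenosis identity 1 - (1 - ds)^2, exact over a severity grid
  ds <- seq(0, 0.95, by = 0.05)
  ref <- csa_concentric(0, 3.5)
  expect_equal(1 - csa_concentric(ds, 3.5) / ref, 1 - (1 - ds)^2)
  expect_equal(csa_concentric(0.8, 3.5), 0.38484510006475)
  expect_error(csa_concentric(1, 3.5), "occluded")
  expect_error(csa_concentric(-0.1, 3.5), "invalid lesion")
})

test_that("eccentric cross-sections are circle segments (flat-plaque model)", {
  ref <- csa_concentric(0, 3.5)
  expect_equal(csa_eccentric(0, 3.5), ref)
  # 50% DS puts the chord through the centre: exactly half the lumen
  expect_equal(csa_eccentric(0.5, 3.5), ref / 2)
  # frozen value, cross-checked against strip quadrature of the truncated circle
  expect_equal(csa_eccentric(0.8, 3.5), 1.36984160512994)
  expect_equal(csa_eccentric(0.8, 3.5),
               oracle_truncated_circle_area(0.2 * 3.5, 3.5),
               tolerance = 1e-6)
  # eccentric narrowing is always milder in area than concentric, except at 0
  ds <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(csa_eccentric(ds, 3.5) > csa_concentric(ds, 3.5)))
})

test_that("lesion shape functions honour their boundary definitions", {
  foc <- std_lesion(0.7, 5, center = 25)
  expect_equal(lesion_shape_function(foc, 25), 0.7)     # peak at mid-lesion
  expect_equal(lesion_shape_function(foc, c(22.5, 27.5)), c(0, 0))
  expect_equal(lesion_shape_function(foc, c(10, 40)), c(0, 0))  # outside

  rect <- std_lesion(0.7, 5, profile = "rectangular", center = 25)
  expect_equal(lesion_shape_function(rect, c(22.6, 25, 27.4)), rep(0.7, 3))

  unif <- std_lesion(0.7, 30, taper = "uniform", center = 50)
  x <- seq(36, 64, by = 0.01)      # inside the 28 mm plateau (1 mm shoulders)
  expect_equal(lesion_shape_function(unif, x), rep(0.7, length(x)))
  expect_equal(lesion_shape_function(unif, c(35, 65)), c(0, 0))
  expect_lt(lesion_shape_function(unif, 35.5), 0.7)
})

test_that("area profiles compose lesions onto the reference lumen", {
  ref <- csa_concentric(0, 3.5)
  empty <- std_profile(L = 50)
  expect_equal(unique(empty$area_mm2), ref)

  one <- std_profile(list(std_lesion(0.7, 5)), L = 50)
  expect_equal(one$min_area_mm2, 0.865901475145687, tolerance = 1e-10)
  expect_equal(one$min_area_x_mm, 25)
  outside <- one$x_mm < 22.5 | one$x_mm > 27.5
  expect_equal(unique(one$area_mm2[outside]), ref)

  two <- std_profile(rep(list(std_lesion(0.7, 5)), 2), L = 100)
  centers <- sapply(two$segment$lesions, `[[`, "center_mm")
  expect_equal(diff(centers), 15)   # 10 mm edge-to-edge gap for 5 mm lesions
  # full recovery to the reference area between the two minima
  between <- two$x_mm > centers[1] + 2.5 & two$x_mm < centers[2] - 2.5
  expect_equal(unique(two$area_mm2[between]), ref)
  # two distinct local minima at the two lesion centres
  expect_equal(two$area_mm2[two$x_mm %in% centers], rep(two$min_area_mm2, 2))
})

test_that("invalid lesion layouts are rejected with informative errors", {
  expect_error(
    segment_spec(3.5, 50, list(std_lesion(center = 10),
                               std_lesion(center = 13))),
    "lesions 1 and 2 overlap")
  expect_error(segment_spec(3.5, 50, std_lesion(center = 1)),
               "outside the segment")
  expect_error(segment_spec(3.5, 20, rep(list(std_lesion()), 3)),
               "exceeds segment length")
  expect_error(lesion_spec(0.7, -5), "length_mm")
})

test_that("halving the grid step changes min area and the viscous integral by < 0.5%", {
  cases <- sweep_cases()
  fl <- fluid_properties()
  for (i in seq_len(nrow(cases))) {
    seg <- case_segment(cases[i, ])
    coarse <- build_area_profile(seg, 0.1)
    fine <- build_area_profile(seg, 0.05)
    expect_lt(abs(fine$min_area_mm2 - coarse$min_area_mm2) /
                fine$min_area_mm2, 0.005)
    rv_c <- viscous_resistance(coarse, fl)
    rv_f <- viscous_resistance(fine, fl)
    expect_lt(abs(rv_f - rv_c) / rv_f, 0.005)
  }
})

test_that("geometry specs round-trip through JSON", {
  seg <- std_vessel(list(std_lesion(0.7, 5, "eccentric", taper = "uniform")),
                    L = 100)
  p <- withr::local_tempfile(fileext = ".json")
  write_spec(seg, p)
  expect_equal(read_spec(p), seg)

  bif <- bifurcation_spec(pmb = segment_spec(3.5, 25, std_lesion()),
                          dmb = segment_spec(2.8, 25), law = "finet")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_spec(bif, p2)
  expect_equal(read_spec(p2), bif)
})

test_that("exported surfaces agree with the area profile station by station", {
  seg <- std_vessel(list(std_lesion(0.5, 5, "eccentric")), L = 20)
  prof <- build_area_profile(seg)
  p <- withr::local_tempfile(fileext = ".stl")
  export_surface(prof, p, "stl")
  txt <- readLines(p)
  expect_identical(txt[1], "solid lumen")
  expect_gt(sum(grepl("facet normal", txt)), 100)

  # slice-and-integrate: polygon area matches A(x) within 1% at every station
  sev <- stenoflow:::segment_severity(seg, prof$x_mm)
  for (i in seq(1, length(prof$x_mm), by = 25)) {
    poly <- stenoflow:::cross_section_polygon(3.5, sev$severity[i],
                                              sev$cross_section[i], n = 256)
    expect_equal(stenoflow:::polygon_area(poly), prof$area_mm2[i],
                 tolerance = 0.01)
  }
  # eccentric lesion is flat-sided on one side only: boundary stays clear of
  # the intact wall's opposite pole
  mid <- stenoflow:::cross_section_polygon(3.5, 0.5, "eccentric", n = 128)
  expect_lt(max(mid[, 2]), 0 + 1e-9)      # chord at the centreline for 50%
  expect_equal(min(mid[, 2]), -1.75, tolerance = 1e-3)  # polygon vertex gap

  p2 <- withr::local_tempfile(fileext = ".vtk")
  export_surface(prof, p2, "vtk")
  expect_identical(readLines(p2, n = 1), "# vtk DataFile Version 3.0")
})
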