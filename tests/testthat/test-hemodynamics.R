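fl <- fluid_properties()
bc <- boundary_conditions()
lp <- loss_model_params()

test_that("viscous resistance reproduces closed-form Poiseuille tubes", {
  prof100 <- std_profile(L = 100)
  expect_equal(viscous_resistance(prof100, fl),
               oracle_tube_resistance(3.5e-3, 0.1), tolerance = 1e-9)
  # halving the diameter multiplies the resistance by 16
  prof_half <- std_profile(L = 100, D = 1.75)
  expect_equal(viscous_resistance(prof_half, fl) /
                 viscous_resistance(prof100, fl), 16, tolerance = 1e-9)
  # piecewise-constant profile equals the sum of per-piece closed forms
  seg <- std_vessel(list(std_lesion(0.6, 10, profile = "rectangular",
                                    center = 25)), L = 50)
  prof <- build_area_profile(seg)
  d_throat <- 0.4 * 3.5e-3
  expected <- oracle_tube_resistance(3.5e-3, 0.04) +
    oracle_tube_resistance(d_throat, 0.01)
  expect_equal(viscous_resistance(prof, fl), expected, tolerance = 0.005)
})

test_that("expansion losses vanish without narrowing or flow and follow Q|Q|", {
  prof <- std_profile(list(std_lesion(0.7, 5)))
  les <- prof$segment$lesions[[1]]
  expect_equal(expansion_loss(prof, les, lp, fl, 0), 0)
  none <- std_lesion(0, 5, center = 25)
  expect_equal(expansion_loss(std_profile(), none, lp, fl, 1e-6), 0)
  dp1 <- expansion_loss(prof, les, lp, fl, 1e-6)
  dp2 <- expansion_loss(prof, les, lp, fl, 2e-6)
  expect_equal(dp2 / dp1, 4)
  # sign follows the flow direction
  expect_equal(expansion_loss(prof, les, lp, fl, -1e-6), -dp1)
})

test_that("total pressure drop is additive and matches the fine-grid oracle", {
  q <- 1.4e-6
  free <- std_profile(L = 50)
  rv <- viscous_resistance(free, fl)
  expect_equal(total_pressure_drop(free, flow_m3_s = q), rv * q)

  one <- std_profile(list(std_lesion()), L = 100)
  two <- std_profile(rep(list(std_lesion()), 2), L = 100)
  exp1 <- total_pressure_drop(one, flow_m3_s = q) -
    viscous_resistance(one, fl) * q
  exp2 <- total_pressure_drop(two, flow_m3_s = q) -
    viscous_resistance(two, fl) * q
  expect_equal(exp2, 2 * exp1)

  # oracle equivalence across the study archetypes, written first and kept
  # on an independent code path (strict 1% criterion)
  cases <- sweep_cases()
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    prof <- build_area_profile(case_segment(cc))
    got <- total_pressure_drop(prof, flow_m3_s = q)
    want <- oracle_pressure_drop(3.5, cc$L, case_oracle_lesions(cc), q)
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("solve_flow honours the closed-form linear limits", {
  # lesion-free vessel: vFFR equals the resistance ratio Rmv / (Rmv + Rv)
  prof <- std_profile(L = 100)
  sol <- solve_flow(prof, params = lp, fluid = fl, bc = bc)
  expect_equal(sol$vffr, 0.989220888709051, tolerance = 1e-10)
  expect_equal(sol$flow_m3_s, sol$q_normal_m3_s, tolerance = 1e-10)

  # Kt = 0 collapses any lesioned vessel to the same closed form, to 1e-10
  prof2 <- std_profile(list(std_lesion(0.7, 5)), L = 100)
  k0 <- loss_model_params(expansion_coefficient = 0)
  rv <- viscous_resistance(prof2, fl)
  want <- bc$outlet_mvr_Pa_s_m3 / (bc$outlet_mvr_Pa_s_m3 + rv)
  got <- solve_flow(prof2, params = k0, fluid = fl, bc = bc)$vffr
  expect_equal(got, want, tolerance = 1e-10)

  # zero-resistance limit: vFFR identically 1
  tiny <- build_area_profile(segment_spec(3.5, 0.1))
  expect_equal(solve_flow(tiny, params = lp, fluid = fl, bc = bc)$vffr, 1,
               tolerance = 1e-4)
})

test_that("converged solutions satisfy the pressure balance and monotone curve", {
  for (les in list(list(std_lesion(0.8, 5)),
                   rep(list(std_lesion(0.7, 5, taper = "uniform")), 3))) {
    prof <- std_profile(les, L = 100)
    sol <- solve_flow(prof, params = lp, fluid = fl, bc = bc)
    expect_true(sol$converged)
    expect_lt(abs(sol$residual) / bc$inlet_pressure_Pa, 1e-8)
    expect_gt(sol$vffr, 0)
    expect_lte(sol$vffr, 1)
    p <- sol$pressure_curve$pressure_Pa
    expect_true(all(diff(p) <= 1e-9))
    expect_equal(p[1], bc$inlet_pressure_Pa)
    # the curve ends at the outlet pressure that defines the vFFR
    expect_equal(p[length(p)], sol$outlet_pressure_Pa, tolerance = 1e-6)
  }
})

test_that("vFFR falls monotonically with severity and lesion burden", {
  vffr_of <- function(...) {
    solve_flow(std_profile(list(std_lesion(...)), L = 100),
               params = lp, fluid = fl, bc = bc)$vffr
  }
  sev <- seq(0.3, 0.9, by = 0.1)
  v <- vapply(sev, function(d) vffr_of(d, 5), numeric(1))
  expect_true(all(diff(v) < 0))
  # length, uniform taper: longer throat, lower vFFR
  lens <- c(5, 10, 20, 30)
  vl <- vapply(lens, function(L) vffr_of(0.7, L, taper = "uniform"),
               numeric(1))
  expect_true(all(diff(vl) < 0))
})

test_that("matched-pair shape orderings hold", {
  vffr_seg <- function(les, L = 100) {
    solve_flow(std_profile(les, L = L), params = lp, fluid = fl, bc = bc)$vffr
  }
  for (ds in c(0.5, 0.7, 0.8)) {
    rect <- vffr_seg(list(std_lesion(ds, 5, profile = "rectangular")))
    round_f <- vffr_seg(list(std_lesion(ds, 5)))
    expect_lte(rect, round_f)
    unif <- vffr_seg(list(std_lesion(ds, 10, taper = "uniform")))
    foc <- vffr_seg(list(std_lesion(ds, 10)))
    expect_lte(unif, foc)
    ecc <- vffr_seg(list(std_lesion(ds, 5, "eccentric")))
    conc <- vffr_seg(list(std_lesion(ds, 5)))
    expect_gte(ecc, conc)
  }
})

test_that("serial lesions show diminishing incremental effect", {
  v <- vapply(1:3, function(n) {
    solve_flow(std_profile(rep(list(std_lesion()), n), L = 100),
               params = lp, fluid = fl, bc = bc)$vffr
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_gte((v[1] - v[2]), (v[2] - v[3]))
})

test_that("vFFR is invariant to axial lesion position (lumped model)", {
  at <- function(center) {
    solve_flow(std_profile(list(std_lesion(center = center)), L = 100),
               params = lp, fluid = fl, bc = bc)$vffr
  }
  positions <- c(10, 30, 50, 70, 90)
  v <- vapply(positions, at, numeric(1))
  expect_lt(max(v) - min(v), 1e-6)
})

test_that("vFFR rises with microvascular resistance", {
  prof <- std_profile(list(std_lesion()), L = 50)
  tri <- vffr_sensitivity_mvr(prof, params = lp, fluid = fl, bc = bc,
                              delta_mvr = 2e9)
  expect_lt(tri[["low"]], tri[["standard"]])
  expect_lt(tri[["standard"]], tri[["high"]])
  same <- vffr_sensitivity_mvr(prof, params = lp, fluid = fl, bc = bc,
                               delta_mvr = 0)
  expect_equal(unname(same), rep(same[["standard"]], 3))
  expect_error(vffr_sensitivity_mvr(prof, bc = bc, delta_mvr = 9e9))
})
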