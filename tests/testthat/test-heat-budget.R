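test_that("whole-body convection is antisymmetric in the temperature excess", {
  A_b <- 1.637e-4
  v0 <- tiny_visits(T_a = 25, T_hd = 25, T_th = 25, T_ab = 25, G = 10)
  expect_equal(convection_simple(v0, h_b = 12.14393, A_b = A_b), 0)
  # hand evaluation with the published whole-body coefficient
  v10 <- tiny_visits(T_a = 25, T_hd = 35, T_th = 35, T_ab = 35, G = 10)
  expect_equal(convection_simple(v10, 12.14393, A_b), 0.01987961341,
    tolerance = 1e-10
  )
  vm10 <- tiny_visits(T_a = 25, T_hd = 15, T_th = 15, T_ab = 15, G = 10)
  expect_equal(
    convection_simple(vm10, 12.14393, A_b),
    -convection_simple(v10, 12.14393, A_b)
  )
})

test_that("per-segment convection evaluates each part term as written", {
  areas <- body_surface()
  t2a <- coef_preset("table2a")
  v0 <- tiny_visits(T_a = 25, T_hd = 25, T_th = 25, T_ab = 25, G = 10)
  expect_equal(convection_per_part(v0, t2a, areas), 0)
  # thorax-only record: (a_hth + b_hth * 25) * A_th * 10
  v_th <- tiny_visits(T_a = 25, T_hd = 25, T_th = 35, T_ab = 25, G = 10)
  expect_equal(convection_per_part(v_th, t2a, areas), 0.07575461664,
    tolerance = 1e-10
  )
  expect_error(
    convection_per_part(v_th, coef_preset("table3a"), areas), "variant"
  )
})

test_that("eq13 with a zero abdomen slope reproduces eq14 exactly", {
  areas <- body_surface()
  t2b <- coef_preset("table2b")
  k <- coef(t2b)
  nested <- coefficient_set("advanced_eq13",
    r_l = k[["r_l"]], r_g = k[["r_g"]], e_lev = k[["e_lev"]],
    a_hhd = k[["a_hhd"]], b_hhd = k[["b_hhd"]],
    a_hth = k[["a_hth"]], b_hth = k[["b_hth"]],
    a_hab = k[["h_ab"]], b_hab = 0
  )
  v <- tiny_visits()
  expect_identical(
    convection_per_part(v, nested, areas),
    convection_per_part(v, t2b, areas)
  )
  # same nesting for the three-compartment pair
  t3b <- coef_preset("table3b")
  k3 <- coef(t3b)
  nested3 <- coefficient_set("three_comp_eq15",
    r_l = k3[["r_l"]], r_g = k3[["r_g"]], e_lev = k3[["e_lev"]],
    a_hthhd = k3[["a_hthhd"]], b_hthhd = k3[["b_hthhd"]],
    a_hth = k3[["a_hth"]], b_hth = k3[["b_hth"]],
    a_hthab = k3[["h_thab"]], b_hthab = 0
  )
  expect_identical(
    convection_three_compartment(v, nested3, areas),
    convection_three_compartment(v, t3b, areas)
  )
})

test_that("three-compartment convection matches its hand evaluation", {
  areas <- body_surface()
  t3b <- coef_preset("table3b")
  v0 <- tiny_visits(T_a = 25, T_hd = 25, T_th = 25, T_ab = 25, G = 10)
  expect_equal(convection_three_compartment(v0, t3b, areas), 0)
  # T_th - T_hd = 5, T_th - T_a = 10, T_th - T_ab = 12 at T_a = 25
  v <- tiny_visits(T_a = 25, T_hd = 30, T_th = 35, T_ab = 23, G = 10)
  expect_equal(
    convection_three_compartment(v, t3b, areas), 0.058845493392,
    tolerance = 1e-10
  )
  expect_error(
    convection_three_compartment(v, coef_preset("table2a"), areas), "variant"
  )
  # the internal-difference basis is an exact linear combination of the
  # per-part excess basis
  v2 <- tiny_visits()
  expect_equal(
    (v2$T_th_C - v2$T_hd_C),
    (v2$T_th_C - v2$T_a_C) - (v2$T_hd_C - v2$T_a_C)
  )
})

test_that("full equilibrium leaves only the evaporative term", {
  cs <- coefficient_set("simple_eq7",
    r_l = 1, r_g = 1, e_lev = 2, h_b = 5
  )
  cst <- thermal_constants() # alpha_bIR = epsilon_b
  v <- tiny_visits(T_a = 30, T_hd = 30, T_th = 30, T_ab = 30, G = 0)
  p <- predict_metabolism(v, cs, constants = cst)
  expect_equal(p$M_W, 2 * cst$E_ev)
})

test_that("prediction components decompose exactly and match a term-by-term
           hand evaluation", {
  areas <- body_surface()
  cst <- thermal_constants()
  for (preset in preset_names()) {
    v <- simulate_visits(synthetic_config(n_visits = 40), seed = 9)
    p <- predict_metabolism(v, coef_preset(preset), areas, cst)
    expect_identical(
      p$M_W,
      p$term_rloss_W + p$term_rgain_W + p$term_ecv_W + p$term_eev_W
    )
    expect_identical(p$M_mW, p$M_W * 1000)
  }
  # independent arithmetic for table2b on one fixed record
  v1 <- tiny_visits(T_a = 25, T_hd = 31, T_th = 37, T_ab = 27, G = 400)
  T_b <- (31 + 37 + 27) / 3
  sb <- 0.97 * 5.669e-8
  rloss <- sb * (T_b + 273.15)^4 * 163.7e-6
  rgain <- sb * (25 + 273.15)^4 * 163.7e-6 +
    0.825 * 400 * 163.7e-6 / 2
  ecv <- (55.80168 - 8.71008 * 25) * 30.80e-6 * 6 +
    (26.57184 + 5.28199 * 25) * 47.78e-6 * 12 +
    (-22.66916) * 85.91e-6 * 2
  M_hand <- 0.33816 * rloss - 0.06758 * rgain + ecv + (-7.80027) * 0.004
  expect_equal(
    predict_metabolism(v1, coef_preset("table2b"))$M_W, M_hand,
    tolerance = 1e-12
  )
})

test_that("the evaporative term is the product of its published factors", {
  t2a <- coef_preset("table2a")
  v <- tiny_visits(T_a = 20, T_hd = 26, T_th = 30, T_ab = 22, G = 50)
  p <- predict_metabolism(v, t2a)
  expect_equal(p$term_eev_W, -0.03444572, tolerance = 1e-12)
})

test_that("conductance estimate is M over the temperature excess", {
  expect_equal(conductance_estimate(50, 35, 25), 5)
  expect_equal(conductance_estimate(0, 35, 25), 0)
  expect_equal(
    conductance_estimate(50, 30, 25), 2 * conductance_estimate(50, 35, 25)
  )
  expect_warning(out <- conductance_estimate(50, 25, 25), "undefined")
  expect_true(is.na(out))
})

test_that("coefficient sets enforce their variant schema", {
  expect_error(
    coefficient_set("advanced_eq13", r_l = 1, r_g = 1, e_lev = 1),
    "exactly the coefficients"
  )
  expect_error(
    coefficient_set("simple_eq7",
      r_l = 1, r_g = 1, e_lev = 1, h_b = NA_real_
    ),
    "finite"
  )
  expect_length(coef(coef_preset("table2a")), 9)
  expect_length(coef(coef_preset("table2b")), 8)
  expect_length(coef(coef_preset("table3a")), 9)
  expect_length(coef(coef_preset("table3b")), 8)
  expect_length(coef(coef_preset("simple")), 4)
})

test_that("presets round-trip bit-stably through their file format", {
  p <- coef_preset("table3a")
  f <- withr::local_tempfile(fileext = ".json")
  write_preset(p, f)
  q <- read_preset(f)
  expect_identical(coef(q), coef(p))
  expect_identical(q$variant, p$variant)
})
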