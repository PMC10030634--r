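test_that("design matrices have the variant's dimensions and column order", {
  v <- simulate_visits(synthetic_config(n_visits = 60), seed = 4)
  d13 <- build_design_matrix(v, "advanced_eq13")
  expect_identical(dim(d13$X), c(60L, 9L))
  expect_identical(colnames(d13$X), coefficient_names("advanced_eq13"))
  d16 <- build_design_matrix(v, "three_comp_eq16")
  expect_identical(dim(d16$X), c(60L, 8L))
  expect_identical(d13$y, v$M_mW / 1000)
})

test_that("visits without measured M are excluded with a count", {
  v <- simulate_visits(synthetic_config(n_visits = 30), seed = 4)
  v$M_mW[c(3, 17)] <- NA
  expect_message(
    d <- build_design_matrix(v, "advanced_eq14"), "2 visit"
  )
  expect_identical(d$N, 28L)
  expect_identical(d$n_excluded, 2L)
  v$M_mW <- NULL
  expect_error(build_design_matrix(v, "advanced_eq14"), "M_mW")
})

test_that("constant air temperature makes slope columns collinear", {
  v <- simulate_visits(synthetic_config(n_visits = 40), seed = 4)
  v$T_a_C <- 25
  d <- build_design_matrix(v, "advanced_eq13")
  expect_error(fit_linear(d), "collinear")
  expect_error(fit_iterative(d), "collinear")
})

test_that("noise-free data from a known coefficient set is recovered exactly", {
  gen <- coef_preset("table2a")
  v <- simulate_visits(
    synthetic_config(n_visits = 200, noise_sd_mW = 0),
    seed = 8
  )
  f <- fit_linear(build_design_matrix(v, "advanced_eq13"))
  expect_lt(rel_diff(coef(f), coef(gen)), 1e-6)
  expect_equal(f$adj_R2, 1, tolerance = 1e-9)
})

test_that("degrees of freedom decrease by one per added coefficient", {
  v <- simulate_visits(synthetic_config(n_visits = 100), seed = 5)
  f13 <- fit_variant(v, "advanced_eq13", method = "linear")
  f14 <- fit_variant(v, "advanced_eq14", method = "linear")
  expect_identical(f13$df, f13$N - 9L)
  # dropping the abdomen slope frees one degree of freedom
  expect_identical(f14$df, f13$df + 1L)
})

test_that("the iterative fit agrees with the closed-form solution for every
           variant and start", {
  v <- simulate_visits(synthetic_config(n_visits = 150), seed = 6)
  for (vr in model_variants()) {
    d <- build_design_matrix(v, vr)
    fl <- fit_linear(d)
    fi <- fit_iterative(d)
    expect_true(fi$converged)
    expect_lt(rel_diff(coef(fi), coef(fl)), 1e-6)
    expect_equal(fi$SD_res_mW, fl$SD_res_mW, tolerance = 1e-8)
  }
  # convexity: the optimum does not depend on the start
  d <- build_design_matrix(v, "advanced_eq13")
  f0 <- fit_iterative(d, init = rep(0, 9))
  f1 <- fit_iterative(d, init = rep(1, 9))
  expect_lt(rel_diff(coef(f0), coef(f1)), 1e-8)
})

test_that("the iterative fit agrees with an external Levenberg-Marquardt
           implementation", {
  v <- simulate_visits(synthetic_config(n_visits = 200), seed = 12)
  d <- build_design_matrix(v, "advanced_eq14")
  fi <- fit_iterative(d)
  s <- sqrt(colSums(d$X^2))
  Xs <- sweep(d$X, 2, s, "/")
  rv <- minpack.lm::nls.lm(
    par = rep(1, ncol(Xs)),
    fn = function(p) d$y - drop(Xs %*% p),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15)
  )
  expect_lt(rel_diff(coef(fi), coef(rv) / s), 1e-5)
})

test_that("fit statistics follow their defining identities", {
  set.seed(1)
  y <- rnorm(50, 0.03, 0.017)
  res <- rnorm(50, 0, 0.005)
  st <- fit_statistics(res, 4, y)
  expect_identical(st$df, 46)
  expect_equal(st$SD_res, sqrt(sum(res^2) / 46))
  expect_equal(st$SEM_res, st$SD_res / sqrt(50))
  # perfect fit
  st0 <- fit_statistics(rep(0, 50), 4, y)
  expect_equal(st0$SD_res, 0)
  expect_equal(st0$adj_R2, 1)
  # null model: residuals are the centred response
  stn <- fit_statistics(y - mean(y), 1, y)
  expect_equal(stn$adj_R2, 0, tolerance = 1e-12)
  expect_error(fit_statistics(res, 50, y), "degrees of freedom")
})

test_that("coefficient t statistics and two-sided P values are coherent", {
  v <- simulate_visits(synthetic_config(n_visits = 120), seed = 13)
  f <- fit_variant(v, "advanced_eq14", method = "linear")
  expect_equal(f$table$t_value, f$table$value / f$table$se)
  expect_equal(
    f$table$p_gt_t, 2 * pt(-abs(f$table$t_value), df = f$df)
  )
  expect_true(all(f$table$p_gt_t >= 0 & f$table$p_gt_t <= 1))
})

test_that("equal-span variants give identical residuals; nesting can only
           help", {
  v <- simulate_visits(synthetic_config(n_visits = 180), seed = 14)
  cmp <- compare_variants(
    v, c("simple_eq7", "advanced_eq13", "advanced_eq14",
         "three_comp_eq15", "three_comp_eq16"),
    method = "linear"
  )
  fits <- attr(cmp, "fits")
  scale_W <- sd(v$M_mW) / 1000
  expect_lt(
    max(abs(residuals(fits$advanced_eq13) -
              residuals(fits$three_comp_eq15))) / scale_W,
    1e-8
  )
  expect_lt(
    max(abs(residuals(fits$advanced_eq14) -
              residuals(fits$three_comp_eq16))) / scale_W,
    1e-8
  )
  # nested models cannot beat their parents in residual sum of squares
  rss <- vapply(fits, function(f) sum(residuals(f)^2), 0)
  expect_gte(rss[["simple_eq7"]], rss[["advanced_eq13"]])
  expect_gte(rss[["advanced_eq14"]], rss[["advanced_eq13"]])
  expect_gte(rss[["three_comp_eq16"]], rss[["three_comp_eq15"]])
  expect_error(compare_variants(v, "advanced_eq13"), "at least two")
})

test_that("equal-span coefficient vectors map onto each other by the exact
           basis change", {
  # eq15 head term h*(T_th - T_hd) contributes +h/A_th to the thorax excess
  # column and -h/A_hd to the head excess column of the eq13 basis
  v <- simulate_visits(synthetic_config(n_visits = 180), seed = 15)
  areas <- body_surface()
  f13 <- fit_variant(v, "advanced_eq13", method = "linear")
  f15 <- fit_variant(v, "three_comp_eq15", method = "linear")
  k15 <- coef(f15)
  mapped <- c(
    a_hhd = -k15[["a_hthhd"]] / areas$A_hd,
    b_hhd = -k15[["b_hthhd"]] / areas$A_hd,
    a_hth = k15[["a_hth"]] +
      (k15[["a_hthhd"]] + k15[["a_hthab"]]) / areas$A_th,
    b_hth = k15[["b_hth"]] +
      (k15[["b_hthhd"]] + k15[["b_hthab"]]) / areas$A_th,
    a_hab = -k15[["a_hthab"]] / areas$A_ab,
    b_hab = -k15[["b_hthab"]] / areas$A_ab
  )
  expect_equal(coef(f13)[names(mapped)], mapped, tolerance = 1e-6)
})
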