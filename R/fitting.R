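#' Build the linear design matrix of a model variant
#'
#' Every heat-budget variant is exactly linear in its free coefficients:
#' each term of the energy balance is a coefficient times a quantity
#' computable from the visit record (radiative loss, radiative gain, the
#' evaporative constant, and the variant's convection basis).  This function
#' assembles that design matrix, one row per visit with measured energy
#' turnover, one column per coefficient in the order of
#' [coefficient_names()]:
#' * `r_l` — the radiative-loss column \eqn{R_{loss}} (W),
#' * `r_g` — the negated radiative-gain column \eqn{-R_{gain}} (W),
#' * `e_lev` — the constant evaporative column \eqn{E_{ev}} (W),
#' * convection columns, e.g. for `advanced_eq13`:
#'   \eqn{A_{hd}(T_{hd}-T_a)}, \eqn{T_a A_{hd}(T_{hd}-T_a)}, and likewise
#'   for thorax and abdomen; for the three-compartment variants the head and
#'   abdomen columns are \eqn{(T_{th}-T_{hd})} and \eqn{(T_{th}-T_{ab})}
#'   (optionally times \eqn{T_a}) without an area factor.
#'
#' Visits lacking `M_mW` are excluded with a message stating the count.
#'
#' @param visits A visit table with measured `M_mW`.
#' @param variant One of [model_variants()].
#' @param areas A [body_surface()] object.
#' @param constants A [thermal_constants()] object.
#' @param T_surround Radiant surround temperature, degC; default air
#'   temperature (see [ir_gain()]).
#' @return An object of class `"design_matrix"`: list with matrix `X`
#'   (colnames = coefficient names), response `y` (measured M in W),
#'   `variant`, `N`, and `n_excluded`.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 50), seed = 1)
#' d <- build_design_matrix(v, "advanced_eq13")
#' dim(d$X)
#' @export
build_design_matrix <- function(visits, variant, areas = body_surface(),
                                constants = thermal_constants(),
                                T_surround = NULL) {
  visits <- as_visits(visits)
  variant <- match.arg(variant, model_variants())
  if (is.null(visits$M_mW)) {
    stop("fitting requires a measured M_mW column", call. = FALSE)
  }
  usable <- !is.na(visits$M_mW)
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    message(n_excluded, " visit(s) without measured M_mW excluded from fit")
  }
  visits <- visits[usable, , drop = FALSE]
  if (nrow(visits) == 0) {
    stop("no visits with measured energy turnover", call. = FALSE)
  }
  if (is.null(T_surround)) T_surround <- visits$T_a_C

  T_a <- visits$T_a_C
  T_b <- mean_body_temperature(visits)
  rad <- radiation_budget(
    T_b = T_b, T_surround = T_surround, G = visits$G_Wm2,
    A_b = areas$A_b, constants = constants
  )
  d_hd <- areas$A_hd * (visits$T_hd_C - T_a)
  d_th <- areas$A_th * (visits$T_th_C - T_a)
  d_ab <- areas$A_ab * (visits$T_ab_C - T_a)
  d_thhd <- visits$T_th_C - visits$T_hd_C
  d_thab <- visits$T_th_C - visits$T_ab_C

  conv <- switch(variant,
    simple_eq7 = cbind(h_b = areas$A_b * (T_b - T_a)),
    advanced_eq13 = cbind(
      a_hhd = d_hd, b_hhd = T_a * d_hd,
      a_hth = d_th, b_hth = T_a * d_th,
      a_hab = d_ab, b_hab = T_a * d_ab
    ),
    advanced_eq14 = cbind(
      a_hhd = d_hd, b_hhd = T_a * d_hd,
      a_hth = d_th, b_hth = T_a * d_th,
      h_ab = d_ab
    ),
    three_comp_eq15 = cbind(
      a_hthhd = d_thhd, b_hthhd = T_a * d_thhd,
      a_hth = d_th, b_hth = T_a * d_th,
      a_hthab = d_thab, b_hthab = T_a * d_thab
    ),
    three_comp_eq16 = cbind(
      a_hthhd = d_thhd, b_hthhd = T_a * d_thhd,
      a_hth = d_th, b_hth = T_a * d_th,
      h_thab = d_thab
    )
  )
  X <- cbind(r_l = rad$R_loss, r_g = -rad$R_gain, e_lev = constants$E_ev, conv)
  stopifnot(identical(colnames(X), coefficient_names(variant)))
  structure(
    list(
      X = X, y = visits$M_mW / 1000, variant = variant,
      N = nrow(X), n_excluded = n_excluded
    ),
    class = "design_matrix"
  )
}

check_full_rank <- function(X) {
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  qx
}

#' Residual and goodness-of-fit statistics
#'
#' Computes the accuracy currency of the model fits from a residual vector:
#' * `SD_res` — standard deviation of residuals, \eqn{\sqrt{RSS/df}} with
#'   `df = N - n_coefficients` (the df-denominator convention, consistent
#'   with reporting R^2 adjusted for df),
#' * `SEM_res` — \eqn{SD_{res}/\sqrt{N}},
#' * `adj_R2` — \eqn{1 - (RSS/df) / (TSS/(N-1))} with `TSS` centred on the
#'   response mean,
#' * `F_value` — overall regression F under the no-intercept (uncentred)
#'   ANOVA convention, \eqn{((\sum y^2 - RSS)/p)/(RSS/df)}.  Fit F-values
#'   are convention-sensitive across statistics packages; this package's
#'   convention is fixed and documented here.
#'
#' Statistics are returned in the units of the residuals supplied (the
#' model fits use W and convert to mW for reporting).
#'
#' @param residuals Residual vector (response minus fitted).
#' @param n_coefficients Number of free coefficients.
#' @param response The response vector the residuals refer to.
#' @return List with `SD_res`, `SEM_res`, `adj_R2`, `F_value`, `df`, `N`.
#' @examples
#' fit_statistics(residuals = rnorm(100, 0, 0.005), n_coefficients = 9,
#'                response = rnorm(100, 0.03, 0.017))
#' @export
fit_statistics <- function(residuals, n_coefficients, response) {
  N <- length(residuals)
  stopifnot(length(response) == N)
  df <- N - n_coefficients
  if (df <= 0) {
    stop("non-positive residual degrees of freedom (N <= n_coefficients)",
      call. = FALSE
    )
  }
  RSS <- sum(residuals^2)
  TSS <- sum((response - mean(response))^2)
  TSS_u <- sum(response^2)
  SD_res <- sqrt(RSS / df)
  list(
    SD_res = SD_res,
    SEM_res = SD_res / sqrt(N),
    adj_R2 = 1 - (RSS / df) / (TSS / (N - 1)),
    F_value = ((TSS_u - RSS) / n_coefficients) / (RSS / df),
    df = df,
    N = N
  )
}

finish_fit <- function(design, beta, qx, method, converged = TRUE,
                       n_iterations = 0L) {
  X <- design$X
  y <- design$y
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  stats <- fit_statistics(resid, ncol(X), y)
  # per-coefficient SE from the unbiased residual variance and (X'X)^-1
  R <- qr.R(qx)
  XtX_inv <- chol2inv(R)
  sigma2 <- sum(resid^2) / stats$df
  se <- sqrt(diag(XtX_inv) * sigma2)
  t_value <- beta / se
  p_gt_t <- 2 * stats::pt(-abs(t_value), df = stats$df)
  coeffs <- coefficient_set(design$variant,
    values = stats::setNames(beta, colnames(X)),
    name = paste0("fit_", design$variant)
  )
  structure(
    list(
      coefficients = coeffs,
      table = data.frame(
        coefficient = colnames(X), value = beta, se = se,
        t_value = t_value, p_gt_t = p_gt_t, row.names = NULL
      ),
      SD_res_mW = stats$SD_res * 1000,
      SEM_res_mW = stats$SEM_res * 1000,
      adj_R2 = stats$adj_R2,
      F_value = stats$F_value,
      df = stats$df, N = stats$N,
      n_excluded = design$n_excluded,
      method = method, converged = converged,
      n_iterations = n_iterations,
      reduced_chi2 = sum(resid^2) / stats$df,
      fitted_W = fitted, residuals_W = resid
    ),
    class = "heat_fit"
  )
}

#' Closed-form linear least-squares fit
#'
#' Because every model variant is linear in its coefficients, ordinary
#' least squares via a QR decomposition gives the exact optimum in one
#' step.  This is the reference implementation against which the iterative
#' Levenberg-Marquardt route ([fit_iterative()]) is checked: on any
#' full-rank input the two must agree to high relative precision.
#'
#' @param design A [build_design_matrix()] result.
#' @return An object of class `"heat_fit"`: fitted [coefficient_set()], a
#'   per-coefficient table (value, SE, t, two-sided P>|t|), `SD_res_mW`,
#'   `SEM_res_mW`, `adj_R2`, `F_value`, `df`, `N`, convergence info and
#'   residuals.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 100), seed = 1)
#' fit_linear(build_design_matrix(v, "advanced_eq14"))
#' @export
fit_linear <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  qx <- check_full_rank(design$X)
  beta <- drop(qr.coef(qx, design$y))
  finish_fit(design, beta, qx, method = "linear")
}

#' Iterative Levenberg-Marquardt fit
#'
#' Minimises the residual sum of squares by the Levenberg-Marquardt
#' algorithm, the iterative procedure used to calibrate the published
#' coefficient sets: damped normal-equation steps
#' \eqn{(J^TJ + \lambda\,\mathrm{diag}(J^TJ))\,\delta = J^Tr}
#' with the damping \eqn{\lambda} shrunk tenfold after every accepted step
#' and grown tenfold after a rejected one.  Convergence is declared when
#' an accepted step changes the reduced Chi^2 (RSS/df) by less than `tol`
#' (default 1e-9).  Columns are normalised internally so the damping acts
#' on a well-conditioned system; coefficients are returned on the original
#' scale.
#'
#' The model is linear in its coefficients, so the problem is convex with
#' a unique optimum and a single start (all coefficients 1) suffices; the
#' result must agree with [fit_linear()] on every full-rank input.
#'
#' @param design A [build_design_matrix()] result.
#' @param init Initial coefficient vector (default all ones).
#' @param tol Reduced-Chi^2 convergence tolerance (default 1e-9).
#' @param max_iterations Iteration cap (default 1000); if reached the result
#'   is returned with `converged = FALSE`.
#' @return An object of class `"heat_fit"`; see [fit_linear()].
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 100), seed = 1)
#' f <- fit_iterative(build_design_matrix(v, "advanced_eq14"))
#' f$converged
#' @export
fit_iterative <- function(design, init = NULL, tol = 1e-9,
                          max_iterations = 1000L) {
  stopifnot(inherits(design, "design_matrix"), tol > 0)
  qx <- check_full_rank(design$X)
  p <- ncol(design$X)
  if (is.null(init)) init <- rep(1, p)
  stopifnot(length(init) == p)
  df <- length(design$y) - p

  # column-normalised working copy; beta_s = beta * scale
  scale <- sqrt(colSums(design$X^2))
  Xs <- sweep(design$X, 2, scale, "/")
  y <- design$y
  A <- crossprod(Xs)
  D <- diag(diag(A), p)
  beta <- init * scale
  rss <- sum((y - Xs %*% beta)^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    g <- crossprod(Xs, y - Xs %*% beta)
    delta <- solve(A + lambda * D, g)
    rss_new <- sum((y - Xs %*% (beta + delta))^2)
    if (rss_new <= rss) {
      accepted_change <- (rss - rss_new) / df
      step_rel <- sqrt(sum(delta^2)) / max(sqrt(sum((beta + delta)^2)), 1e-300)
      beta <- beta + delta
      rss <- rss_new
      lambda <- lambda / 10
      # the chi^2-change test is only meaningful once the damping no longer
      # dominates the step (lambda shrinks tenfold per accepted step) or the
      # step itself has become negligible
      if (accepted_change < tol && (lambda < 1e-8 || step_rel < 1e-10)) {
        converged <- TRUE
        break
      }
    } else {
      # for this convex problem a damped step always descends in exact
      # arithmetic; a rejection at heavy damping means the round-off floor
      # of the optimum has been reached
      lambda <- lambda * 10
      if (lambda > 1e3) {
        converged <- TRUE
        break
      }
    }
  }
  beta <- drop(beta) / scale
  finish_fit(design, stats::setNames(beta, colnames(design$X)), qx,
    method = "levenberg_marquardt", converged = converged,
    n_iterations = iter
  )
}

#' @export
print.heat_fit <- function(x, digits = 5, ...) {
  cat(sprintf(
    "Heat-budget model fit (%s, %s)\n",
    x$coefficients$variant, x$method
  ))
  cat(sprintf(
    "  N = %d, df = %d%s\n", x$N, x$df,
    if (x$n_excluded > 0) sprintf(" (%d excluded)", x$n_excluded) else ""
  ))
  tab <- x$table
  tab$value <- signif(tab$value, digits)
  tab$se <- signif(tab$se, digits)
  tab$t_value <- signif(tab$t_value, digits)
  tab$p_gt_t <- signif(tab$p_gt_t, 3)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "  SD_res = %.3f mW, SEM_res = %.4f mW, adj. R2 = %.5f, F = %.2f\n",
    x$SD_res_mW, x$SEM_res_mW, x$adj_R2, x$F_value
  ))
  if (x$method != "linear") {
    cat(sprintf(
      "  converged: %s after %d iteration(s)\n",
      x$converged, x$n_iterations
    ))
  }
  invisible(x)
}

#' @export
coef.heat_fit <- function(object, ...) object$coefficients$values

#' @export
residuals.heat_fit <- function(object, ...) object$residuals_W

#' @export
fitted.heat_fit <- function(object, ...) object$fitted_W

#' Fit a model variant to visit data
#'
#' Convenience wrapper: builds the design matrix and fits it, iteratively
#' (the default, matching the published calibration procedure) or by the
#' closed-form least-squares route.
#'
#' @inheritParams build_design_matrix
#' @param method `"iterative"` (Levenberg-Marquardt) or `"linear"`.
#' @param ... Passed on to [fit_iterative()].
#' @return A `"heat_fit"` object.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 100), seed = 1)
#' fit_variant(v, "three_comp_eq16")
#' @export
fit_variant <- function(visits, variant, areas = body_surface(),
                        constants = thermal_constants(), T_surround = NULL,
                        method = c("iterative", "linear"), ...) {
  method <- match.arg(method)
  design <- build_design_matrix(visits, variant, areas, constants, T_surround)
  if (method == "linear") fit_linear(design) else fit_iterative(design, ...)
}

#' Fit several model variants to the same data
#'
#' Fits each requested variant on identical visits and reports their
#' accuracy side by side.  Nested variants (the constant-abdomen forms) can
#' never beat their parents; the per-segment and three-compartment bases of
#' equal size span the same linear space, so their residuals are identical
#' even though the coefficient vectors differ.
#'
#' @inheritParams fit_variant
#' @param variants Character vector of at least two of [model_variants()].
#' @return A data.frame with one row per variant (`variant`, `n_coef`,
#'   `df`, `SD_res_mW`, `adj_R2`, `converged`); the full `"heat_fit"`
#'   objects are attached as attribute `"fits"`.
#' @examples
#' v <- simulate_visits(synthetic_config(n_visits = 100), seed = 1)
#' compare_variants(v, c("simple_eq7", "advanced_eq13", "three_comp_eq15"))
#' @export
compare_variants <- function(visits, variants = model_variants(),
                             areas = body_surface(),
                             constants = thermal_constants(),
                             T_surround = NULL,
                             method = c("iterative", "linear")) {
  method <- match.arg(method)
  variants <- vapply(variants, match.arg, "", choices = model_variants())
  if (length(variants) < 2) {
    stop("compare_variants() needs at least two variants", call. = FALSE)
  }
  fits <- lapply(variants, function(vr) {
    fit_variant(visits, vr,
      areas = areas, constants = constants,
      T_surround = T_surround, method = method
    )
  })
  names(fits) <- variants
  out <- data.frame(
    variant = variants,
    n_coef = vapply(fits, function(f) length(coef(f)), 0L),
    df = vapply(fits, function(f) f$df, 0L),
    SD_res_mW = vapply(fits, function(f) f$SD_res_mW, 0),
    adj_R2 = vapply(fits, function(f) f$adj_R2, 0),
    converged = vapply(fits, function(f) f$converged, TRUE),
    row.names = NULL
  )
  attr(out, "fits") <- fits
  out
}
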