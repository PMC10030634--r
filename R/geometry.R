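#' Surface area of a sphere from its diameter
#'
#' The thorax is approximated as a sphere; its surface area is
#' \eqn{\pi d^2}.
#'
#' @param diameter Sphere diameter, mm. Must be strictly positive.
#' @return Surface area, mm^2.
#' @examples
#' sphere_surface_area(3.90) # honeybee thorax, ~47.78 mm^2
#' @export
sphere_surface_area <- function(diameter) {
  if (!is.numeric(diameter) || any(diameter <= 0)) {
    stop("sphere diameter must be strictly positive", call. = FALSE)
  }
  pi * diameter^2
}

#' Surface area of an oblate rotational ellipsoid
#'
#' The head is approximated as an oblate spheroid (flattened along its
#' rotation axis).  For equatorial semi-axis `a` and polar semi-axis
#' `c <= a`, with eccentricity \eqn{e = \sqrt{1 - c^2/a^2}},
#' \deqn{S = 2\pi a^2 \left(1 + \frac{1-e^2}{e}\,\mathrm{atanh}(e)\right).}
#' The sphere limit `a = c` is handled exactly (returns \eqn{4\pi a^2}).
#'
#' @param a Equatorial semi-axis, mm.
#' @param c Polar semi-axis, mm; requires `c <= a`.
#' @return Surface area, mm^2.
#' @examples
#' oblate_ellipsoid_area(5, 3)
#' oblate_ellipsoid_area(3, 3) # sphere: 4*pi*9
#' @export
oblate_ellipsoid_area <- function(a, c) {
  if (!is.numeric(a) || !is.numeric(c) || any(c <= 0) || any(a <= 0)) {
    stop("ellipsoid semi-axes must be strictly positive", call. = FALSE)
  }
  if (any(c > a)) {
    stop("oblate spheroid requires polar semi-axis c <= equatorial a",
      call. = FALSE
    )
  }
  e <- sqrt(pmax(0, 1 - c^2 / a^2))
  out <- ifelse(e == 0,
    4 * pi * a^2,
    2 * pi * a^2 * (1 + ((1 - e^2) / ifelse(e == 0, 1, e)) * atanh(e))
  )
  out
}

#' Surface area of a prolate rotational ellipsoid
#'
#' The abdomen is approximated as a prolate spheroid (elongated along its
#' rotation axis).  For long semi-axis `a` and short semi-axis `b <= a`,
#' with eccentricity \eqn{e = \sqrt{1 - b^2/a^2}},
#' \deqn{S = 2\pi b^2 \left(1 + \frac{a}{b\,e}\,\mathrm{asin}(e)\right).}
#' The sphere limit `a = b` is handled exactly.
#'
#' @param a Long semi-axis, mm.
#' @param b Short semi-axis, mm; requires `b <= a`.
#' @return Surface area, mm^2.
#' @examples
#' prolate_ellipsoid_area(5, 3)
#' @export
prolate_ellipsoid_area <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(b <= 0) || any(a <= 0)) {
    stop("ellipsoid semi-axes must be strictly positive", call. = FALSE)
  }
  if (any(b > a)) {
    stop("prolate spheroid requires short semi-axis b <= long a",
      call. = FALSE
    )
  }
  e <- sqrt(pmax(0, 1 - b^2 / a^2))
  ifelse(e == 0,
    4 * pi * a^2,
    2 * pi * b^2 * (1 + (a / (b * ifelse(e == 0, 1, e))) * asin(e))
  )
}

#' Morphometric body dimensions of a honeybee forager
#'
#' Container for the five linear dimensions the surface-area geometry needs:
#' head width (equatorial diameter of the oblate head) and depth (polar
#' diameter), thorax diameter (sphere), abdomen length (long diameter of the
#' prolate abdomen) and width (short diameter).  All in mm.
#'
#' The defaults are a synthetic reference morphometry back-solved from the
#' published part areas (head 30.80, thorax 47.78, abdomen 85.91 mm^2), not
#' measured values; they reproduce those areas to better than 0.01 mm^2.
#'
#' @param head_width,head_depth Oblate head diameters, mm (`width >= depth`).
#' @param thorax_diameter Sphere diameter, mm.
#' @param abdomen_length,abdomen_width Prolate abdomen diameters, mm
#'   (`length >= width`).
#' @return An object of class `"body_dimensions"`.
#' @examples
#' body_dimensions()
#' @export
body_dimensions <- function(head_width = 3.40,
                            head_depth = 2.6037,
                            thorax_diameter = 3.90,
                            abdomen_length = 6.00,
                            abdomen_width = 4.8539) {
  d <- list(
    head_width = head_width, head_depth = head_depth,
    thorax_diameter = thorax_diameter,
    abdomen_length = abdomen_length, abdomen_width = abdomen_width
  )
  if (!all(vapply(d, function(x) is.numeric(x) && length(x) == 1 && x > 0, TRUE))) {
    stop("all body dimensions must be single strictly positive numbers",
      call. = FALSE
    )
  }
  if (head_depth > head_width) {
    stop("oblate head requires head_depth <= head_width", call. = FALSE)
  }
  if (abdomen_width > abdomen_length) {
    stop("prolate abdomen requires abdomen_width <= abdomen_length",
      call. = FALSE
    )
  }
  structure(d, class = "body_dimensions")
}

#' @export
print.body_dimensions <- function(x, ...) {
  cat("Honeybee body dimensions (mm):\n")
  cat(sprintf(
    "  head %.3f x %.3f | thorax diameter %.3f | abdomen %.3f x %.3f\n",
    x$head_width, x$head_depth, x$thorax_diameter,
    x$abdomen_length, x$abdomen_width
  ))
  invisible(x)
}

MM2_TO_M2 <- 1e-6

#' Body-part surface areas of a honeybee forager
#'
#' Assembles head (oblate spheroid), thorax (sphere) and abdomen (prolate
#' spheroid) surface areas, without wings and legs, and converts them to m^2.
#'
#' Two modes exist.  With `dims = NULL` (the default) the published constant
#' areas are used verbatim: A_hd = 30.80, A_th = 47.78, A_ab = 85.91 mm^2.
#' In that mode the published whole-body area A_b = 163.7 mm^2 is carried as
#' printed even though the three parts sum to 164.49 mm^2 — a 0.79 mm^2
#' discrepancy in the source values that is deliberately not "corrected";
#' set `total = "sum"` to use the component sum instead.  With explicit
#' `dims`, areas are computed from the geometry and A_b is always the sum.
#'
#' @param dims A [body_dimensions()] object, or `NULL` for the published
#'   constant areas.
#' @param total For the constant mode: `"printed"` (A_b = 163.7 mm^2, the
#'   default) or `"sum"` (A_b = 164.49 mm^2).
#' @return An object of class `"body_surface"`: list with `A_hd`, `A_th`,
#'   `A_ab`, `A_b` in m^2, plus the `dims` used (or `NULL`) and the `total`
#'   mode.
#' @examples
#' body_surface() # published constants
#' body_surface(body_dimensions())
#' @export
body_surface <- function(dims = NULL, total = c("printed", "sum")) {
  total <- match.arg(total)
  if (is.null(dims)) {
    A_hd <- 30.80
    A_th <- 47.78
    A_ab <- 85.91
    A_b <- if (total == "printed") 163.7 else A_hd + A_th + A_ab
  } else {
    if (!inherits(dims, "body_dimensions")) {
      stop("`dims` must be a body_dimensions object or NULL", call. = FALSE)
    }
    A_hd <- oblate_ellipsoid_area(dims$head_width / 2, dims$head_depth / 2)
    A_th <- sphere_surface_area(dims$thorax_diameter)
    A_ab <- prolate_ellipsoid_area(
      dims$abdomen_length / 2,
      dims$abdomen_width / 2
    )
    A_b <- A_hd + A_th + A_ab
    total <- "sum"
  }
  structure(
    list(
      A_hd = A_hd * MM2_TO_M2, A_th = A_th * MM2_TO_M2,
      A_ab = A_ab * MM2_TO_M2, A_b = A_b * MM2_TO_M2,
      dims = dims, total = total
    ),
    class = "body_surface"
  )
}

#' @export
print.body_surface <- function(x, ...) {
  cat("Honeybee body-part surface areas (without wings and legs):\n")
  part <- function(name, A) {
    cat(sprintf("  %-8s %8.2f mm^2  (%.4e m^2)\n", name, A / MM2_TO_M2, A))
  }
  part("head", x$A_hd)
  part("thorax", x$A_th)
  part("abdomen", x$A_ab)
  part("body", x$A_b)
  if (is.null(x$dims)) {
    cat(sprintf(
      "  (published constants; whole-body total mode: %s)\n", x$total
    ))
  }
  invisible(x)
}
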