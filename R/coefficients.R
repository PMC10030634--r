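# Convection-coefficient names per model variant.  eq13/eq14 coefficients are
# per-area (W m-2 degC-1 and W m-2 degC-2); eq15/eq16 head and abdomen terms
# carry no area factor, so their coefficients are absolute (W degC-1,
# W degC-2).  The variant tag travels with the set so the two unit systems
# can never be mixed.
VARIANT_CONV <- list(
  simple_eq7      = c("h_b"),
  advanced_eq13   = c("a_hhd", "b_hhd", "a_hth", "b_hth", "a_hab", "b_hab"),
  advanced_eq14   = c("a_hhd", "b_hhd", "a_hth", "b_hth", "h_ab"),
  three_comp_eq15 = c("a_hthhd", "b_hthhd", "a_hth", "b_hth", "a_hthab", "b_hthab"),
  three_comp_eq16 = c("a_hthhd", "b_hthhd", "a_hth", "b_hth", "h_thab")
)

#' Model variants
#'
#' Names of the five supported convection variants:
#' * `simple_eq7` — one whole-body convection coefficient `h_b`.
#' * `advanced_eq13` — per-segment coefficients, each a linear function of
#'   air temperature (`a + b * T_a`).
#' * `advanced_eq14` — as eq13 but with a constant abdomen coefficient.
#' * `three_comp_eq15` — thorax-to-head and thorax-to-abdomen temperature
#'   differences replace the head and abdomen excess over air.
#' * `three_comp_eq16` — as eq15 but with a constant thorax-abdomen
#'   coefficient.
#'
#' @return Character vector of variant names.
#' @examples
#' model_variants()
#' @export
model_variants <- function() names(VARIANT_CONV)

#' Coefficient names of a variant
#'
#' Full ordered coefficient vector of a variant: the three radiative/
#' evaporative weights `r_l`, `r_g`, `e_lev` followed by the variant's
#' convection coefficients.
#'
#' @param variant One of [model_variants()].
#' @return Character vector of coefficient names.
#' @examples
#' coefficient_names("advanced_eq13")
#' @export
coefficient_names <- function(variant) {
  variant <- match.arg(variant, model_variants())
  c("r_l", "r_g", "e_lev", VARIANT_CONV[[variant]])
}

#' Construct a coefficient set for a model variant
#'
#' Bundles the correlative weights of a heat-budget model variant: the
#' radiative-loss and radiative-gain weights `r_l` and `r_g`, the
#' evaporative weight `e_lev`, and the variant's convection coefficients.
#' Negative values are accepted without complaint — fitted sets include
#' negative head/abdomen coefficients, interpreted as those body parts on
#' average receiving more heat (from the thorax via haemolymph and
#' ventilation, and from the sun) than they emit.
#'
#' @param variant One of [model_variants()].
#' @param ... Named coefficients; must be exactly the set returned by
#'   [coefficient_names()] for the variant (order free).  Alternatively a
#'   single named vector/list may be supplied as `values`.
#' @param values Optional named numeric vector or list of all coefficients.
#' @param name Optional label (e.g. a preset name).
#' @param note Optional free-text provenance/caveat note.
#' @return An object of class `"coefficient_set"`.
#' @examples
#' coefficient_set("simple_eq7",
#'   r_l = 0.68114, r_g = 0.30352, e_lev = 1.82501, h_b = 12.14393
#' )
#' @export
coefficient_set <- function(variant, ..., values = NULL, name = NULL,
                            note = NULL) {
  variant <- match.arg(variant, model_variants())
  wanted <- coefficient_names(variant)
  vals <- if (is.null(values)) list(...) else as.list(values)
  if (!setequal(names(vals), wanted)) {
    stop(
      sprintf(
        "variant '%s' needs exactly the coefficients: %s",
        variant, paste(wanted, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  vals <- vapply(vals[wanted], as.numeric, numeric(1))
  if (any(!is.finite(vals))) {
    stop("all coefficients must be finite numbers", call. = FALSE)
  }
  structure(
    list(
      variant = variant, values = vals,
      name = name, note = note
    ),
    class = "coefficient_set"
  )
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf(
    "Heat-budget coefficient set%s (variant %s):\n",
    if (is.null(x$name)) "" else paste0(" '", x$name, "'"), x$variant
  ))
  print(x$values)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.coefficient_set <- function(object, ...) object$values

#' Load a published coefficient preset
#'
#' The package ships the fitted coefficient sets of the five model variants
#' as JSON files under `inst/extdata/presets/`, entered digit-for-digit as
#' published:
#' * `"simple"` — whole-body model (`simple_eq7`),
#' * `"table2a"` — advanced per-segment model (`advanced_eq13`),
#' * `"table2b"` — simplified per-segment model (`advanced_eq14`),
#' * `"table3a"` — three-compartment model (`three_comp_eq15`),
#' * `"table3b"` — simplified three-compartment model (`three_comp_eq16`).
#'
#' Each file carries a `note` flagging known ambiguities in the published
#' tables (see the preset metadata).
#'
#' @param name Preset name; see [preset_names()].
#' @return A [coefficient_set()].
#' @examples
#' coef_preset("table2a")
#' @export
coef_preset <- function(name) {
  name <- match.arg(name, preset_names())
  path <- system.file("extdata", "presets", paste0(name, ".json"),
    package = "beeheat", mustWork = TRUE
  )
  read_preset(path)
}

#' @rdname coef_preset
#' @export
preset_names <- function() {
  c("simple", "table2a", "table2b", "table3a", "table3b")
}

#' Read / write a coefficient preset file
#'
#' Preset files are JSON with fields `name`, `variant`, `coefficients`
#' (name-to-value map), and optional `note` and `units` strings.  A loaded
#' preset re-serialises bit-stably (numbers are written with full precision).
#'
#' @param path File path.
#' @return `read_preset()`: a [coefficient_set()]. `write_preset()`: the
#'   path, invisibly.
#' @examples
#' p <- coef_preset("table2b")
#' f <- tempfile(fileext = ".json")
#' write_preset(p, f)
#' identical(coef(read_preset(f)), coef(p))
#' @export
read_preset <- function(path) {
  if (!file.exists(path)) stop("preset file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("variant", "coefficients")) {
    if (is.null(j[[field]])) {
      stop("preset file lacks required field '", field, "': ", path,
        call. = FALSE
      )
    }
  }
  coefficient_set(j$variant,
    values = unlist(j$coefficients),
    name = j$name, note = j$note
  )
}

#' @rdname read_preset
#' @param coeffs A [coefficient_set()] to serialise.
#' @export
write_preset <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  out <- list(
    name = coeffs$name, variant = coeffs$variant,
    coefficients = as.list(coeffs$values), note = coeffs$note
  )
  out <- out[!vapply(out, is.null, TRUE)]
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
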