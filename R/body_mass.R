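#' Estimate mean individual body mass from length (and width) measurements
#'
#' Applies a group-specific allometric regression to each measured individual
#' and averages the resulting masses (mass of each individual, then the mean —
#' not the mass of the mean length). Log-scale regressions are back-transformed
#' per individual before averaging.
#'
#' Supported forms:
#' \describe{
#'   \item{`"power"`}{M = a L^b, length only}
#'   \item{`"length_width"`}{M = a (L W^2)^b, body approximated as a cylinder;
#'     widths required, one per length}
#'   \item{`"log10"`}{log10 M = a + b log10 L}
#' }
#'
#' @param lengths numeric vector of body lengths (mm); may be empty when
#'   `fixed_body_mass` is supplied.
#' @param widths numeric vector of body widths (mm), required by the
#'   `"length_width"` form.
#' @param form regression form id (see Details), or `NA` when
#'   `fixed_body_mass` is used.
#' @param a,b regression coefficients.
#' @param fixed_body_mass fallback mass in mg used when no measurements are
#'   available (reference-table masses, e.g. nematode genera).
#' @return Mean individual body mass in mg.
#' @export
#' @examples
#' estimate_body_mass(c(1, 3), form = "power", a = 1, b = 2) # mean(1, 9) = 5
estimate_body_mass <- function(lengths = numeric(), widths = NULL,
                               form = NA_character_, a = NA_real_,
                               b = NA_real_, fixed_body_mass = NA_real_) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) == 0) {
    if (is.na(fixed_body_mass)) {
      abort("no measurements and no fixed_body_mass fallback")
    }
    return(fixed_body_mass)
  }
  if (any(lengths < 0)) abort("negative body length")
  if (is.na(form)) {
    if (is.na(fixed_body_mass)) abort("no regression form and no fixed mass")
    return(fixed_body_mass)
  }
  masses <- switch(form,
    power = a * lengths^b,
    length_width = {
      if (is.null(widths)) abort("length_width regression requires widths")
      widths <- widths[!is.na(widths)]
      if (length(widths) != length(lengths)) {
        abort("lengths and widths must pair one-to-one")
      }
      if (any(widths < 0)) abort("negative body width")
      a * (lengths * widths^2)^b
    },
    log10 = 10^(a + b * log10(lengths)),
    abort(paste0("unknown regression form: ", form))
  )
  mean(masses)
}
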