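# Assay arithmetic: DPPH radical scavenging and HPLC peak quantitation.

#' DPPH radical-scavenging percentage
#'
#' Antioxidant activity from a DPPH assay:
#' `100 * (A_control - A_sample) / A_control`, the standard convention in
#' which a fully scavenged radical (sample absorbance 0) gives 100 %.
#' Some sources print the formula with the opposite sign,
#' `(A_sample - A_control) / A_control * 100`, which is negative for any
#' scavenging sample; that literal form is available with
#' `as_printed = TRUE` but is almost certainly a typographical variant.
#'
#' @param a_control Control absorbance(s); must be positive.
#' @param a_sample Sample absorbance(s).
#' @param as_printed Use the sign-flipped literal form? Default `FALSE`.
#' @return Scavenging percentage(s).
#' @examples
#' dpph_scavenging(1.0, 0.4) # 60
#' @export
dpph_scavenging <- function(a_control, a_sample, as_printed = FALSE) {
  if (any(!is.finite(a_control)) || any(a_control <= 0)) {
    stop("Control absorbance must be positive (zero control makes the ",
         "assay undefined).", call. = FALSE)
  }
  if (any(a_sample < 0)) {
    stop("Absorbances cannot be negative.", call. = FALSE)
  }
  out <- 100 * (a_control - a_sample) / a_control
  if (as_printed) -out else out
}

#' Concentration of a compound from an HPLC peak
#'
#' External-standard single-point quantitation:
#' `conc = area_sample / area_std * conc_std` (ppm), linear in both the
#' sample area and the standard concentration.
#'
#' @param area_sample Peak area of the compound in the sample.
#' @param area_std Peak area of the standard; must be positive.
#' @param conc_std Concentration of the standard (ppm); must be positive.
#' @return Concentration(s) in ppm.
#' @examples
#' peak_concentration(50, 100, 10) # 5
#' @export
peak_concentration <- function(area_sample, area_std, conc_std) {
  if (any(!is.finite(area_std)) || any(area_std <= 0)) {
    stop("Standard peak area must be positive.", call. = FALSE)
  }
  if (any(conc_std <= 0)) {
    stop("Standard concentration must be positive.", call. = FALSE)
  }
  if (any(area_sample < 0)) {
    stop("Peak areas cannot be negative.", call. = FALSE)
  }
  area_sample / area_std * conc_std
}
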