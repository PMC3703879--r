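#' @include classes.R
NULL

#' The eleven-implant catalogue
#'
#' Returns the full labelled set of implants compared in the design study:
#' ten threaded, bevelled, helically milled implants spanning D in
#' \{3.6, 4.3\} mm, L in \{5.5, 9\} mm, thread profiles T0/30 and T10/30,
#' truncations ST/DT and millings SM/LM, plus the commercial-style stand-in
#' "A" (D = 3.5 mm, L = 11 mm, no milling, no bevel).  Label assignments keep
#' every documented pairwise comparison single-factor where the notation
#' allows it: 1 vs 2 and 7 vs 8 differ only in thread shape, 4 vs 5 and
#' 8 vs 9 only in milling, 5 vs 6 and 9 vs 10 only in truncation.
#'
#' @return named list of 11 \code{\link{implantSpec}} objects
#' @examples
#' cat11 <- implantCatalogue()
#' names(cat11)
#' cat11[["A"]]@L_mm
#' @export
implantCatalogue <- function() {
  t0 <- function(trunc) threadSpec("T0_30_sawtooth", trunc)
  t10 <- function(trunc) threadSpec("T10_30_trapezoid", trunc)
  specs <- list(
    "1" = implantSpec("1", 3.6, 5.5, t0("DT"), millingSpec("SM")),
    "2" = implantSpec("2", 3.6, 5.5, t10("DT"), millingSpec("SM")),
    "3" = implantSpec("3", 4.3, 5.5, t10("DT"), millingSpec("SM")),
    "4" = implantSpec("4", 4.3, 9, t10("DT"), millingSpec("SM")),
    "5" = implantSpec("5", 4.3, 9, t10("DT"), millingSpec("LM")),
    "6" = implantSpec("6", 4.3, 9, t10("ST"), millingSpec("LM")),
    "7" = implantSpec("7", 3.6, 9, t0("DT"), millingSpec("SM")),
    "8" = implantSpec("8", 3.6, 9, t10("DT"), millingSpec("SM")),
    "9" = implantSpec("9", 3.6, 9, t10("DT"), millingSpec("LM")),
    "10" = implantSpec("10", 3.6, 9, t10("ST"), millingSpec("LM")),
    "A" = implantSpec("A", 3.5, 11, t10("ST"), millingSpec("none"),
                      has_lead_in_bevel = FALSE))
  specs
}
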