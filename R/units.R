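#' Unit conversion helpers
#'
#' All internal state is SI (m, Pa, s, m^3/s). Literature transport
#' coefficients for tissue are tabulated in cm / mmHg units and vessel
#' diameters in micrometres; these helpers convert at the boundary of the
#' system.
#'
#' @param x numeric value(s) to convert.
#' @return converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

# L_p tabulated as cm/(mmHg s) -> m/(Pa s)
lp_cgs_to_si <- function(x) x * 1e-2 / 133.322

# K tabulated as cm^2/(mmHg s) -> m^2/(Pa s)
k_cgs_to_si <- function(x) x * 1e-4 / 133.322

# S/V tabulated as 1/cm -> 1/m
sv_cgs_to_si <- function(x) x * 100
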