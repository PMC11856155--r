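# Unit conversions at the clinical/user boundary. Geometry is carried in mm,
# morphometric outputs in cm/cm^2 (clinical convention); all physics runs in SI.

#' Unit conversion helpers
#'
#' The package carries surface geometry in millimetres, reports morphometry in
#' centimetres (clinical convention), and runs all physics in SI units.
#' Pressures cross the user boundary in mmHg at 133.322 Pa/mmHg; flows in mL/s.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @name units
NULL

PA_PER_MMHG <- 133.322

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * PA_PER_MMHG

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / PA_PER_MMHG

#' @rdname units
#' @export
mL_s_to_m3_s <- function(x) x * 1e-6

#' @rdname units
#' @export
m3_s_to_mL_s <- function(x) x * 1e6

# mm^2 -> m^2
mm2_to_m2 <- function(x) x * 1e-6
# mm -> m
mm_to_m <- function(x) x * 1e-3
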