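#' Unit conversions
#'
#' All internal computations use SI units (m, s, Pa, kg). Conversions happen at
#' I/O boundaries only. The mmHg conversion constant is fixed at 133.322 Pa.
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @examples
#' mmHg_to_Pa(10) # 1333.22
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname mmHg_to_Pa
#' @export
mL_to_m3 <- function(x) x * 1e-6

#' @rdname mmHg_to_Pa
#' @export
m3_to_mL <- function(x) x * 1e6
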