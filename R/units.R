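# Unit conversions between clinical I/O units and internal SI.
# Internal units are always SI: m, m^3/s, Pa, Pa.s/m^3. Conversion happens
# only at I/O boundaries so the solver never sees mixed units.

MMHG_PA <- 133.322            # Pa per mmHg
MLMIN_M3S <- 1e-6 / 60        # m^3/s per mL/min
WU_SI <- MMHG_PA / (1e-3 / 60)  # Pa.s/m^3 per Wood unit (mmHg.min/L)

#' Convert millimetres to metres
#' @param x numeric, mm
#' @return numeric, m
#' @keywords internal
mm_to_m <- function(x) x * 1e-3

#' @rdname mm_to_m
#' @keywords internal
m_to_mm <- function(x) x * 1e3

#' Convert aortic pressure in mmHg to Pa
#' @param x numeric, mmHg
#' @return numeric, Pa
#' @keywords internal
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname mmhg_to_pa
#' @keywords internal
pa_to_mmhg <- function(x) x / MMHG_PA

#' Convert flow in mL/min to m^3/s
#' @param x numeric, mL/min
#' @return numeric, m^3/s
#' @keywords internal
mlmin_to_m3s <- function(x) x * MLMIN_M3S

#' @rdname mlmin_to_m3s
#' @keywords internal
m3s_to_mlmin <- function(x) x / MLMIN_M3S

#' Convert microvascular resistance in Wood units to Pa.s/m^3
#'
#' One Wood unit is 1 mmHg per L/min of flow.
#' @param x numeric, Wood units
#' @return numeric, Pa.s/m^3
#' @keywords internal
wu_to_si <- function(x) x * WU_SI

#' @rdname wu_to_si
#' @keywords internal
si_to_wu <- function(x) x / WU_SI
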