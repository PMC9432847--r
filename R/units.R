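## Internal unit system is CGS: lengths in cm, pressures in dyn/cm^2,
## flows in cm^3/s, viscosity in poise, oxygen amounts in cm^3 O2.
## The user-facing interface keeps diameters in um, pressures in mmHg and
## oxygen demand in cm^3 O2/100 cm^3/min, the conventional units of the field.

#' Unit conversion constants
#'
#' `MMHG_TO_DYN` converts mmHg to dyn/cm^2 (1 mmHg = 1333.22 dyn/cm^2);
#' `UM_TO_CM` converts micrometres to centimetres; `CP_TO_POISE` converts
#' centipoise to poise; `M0_TO_CGS` converts an oxygen demand expressed in
#' cm^3 O2/100 cm^3 tissue/min to cm^3 O2/cm^3 tissue/s.
#'
#' @name units
#' @keywords internal
NULL

MMHG_TO_DYN <- 1333.22
UM_TO_CM <- 1e-4
CP_TO_POISE <- 1e-2
M0_TO_CGS <- 1 / (100 * 60)

mmHg_to_cgs <- function(p) p * MMHG_TO_DYN
cgs_to_mmHg <- function(p) p / MMHG_TO_DYN
um_to_cm <- function(d) d * UM_TO_CM
cm_to_um <- function(d) d / UM_TO_CM
cP_to_poise <- function(mu) mu * CP_TO_POISE
demand_to_cgs <- function(m0) m0 * M0_TO_CGS

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
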