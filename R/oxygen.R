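#' Oxygen transport parameters
#'
#' Bundles the scalar constants of the oxygen model. `d_diff_alpha` is the
#' product of tissue oxygen diffusivity and solubility (cm^3 O2/cm/s/mmHg);
#' `m0` is the maximal tissue oxygen demand in the conventional
#' cm^3 O2/100 cm^3 tissue/min; `p0` the Michaelis constant (mmHg) at which
#' consumption is half-maximal; `p50` and `n_hill` the half-saturation pressure
#' and exponent of the oxyhemoglobin dissociation curve; `c0` the oxygen
#' binding capacity of fully saturated red cells (cm^3 O2/cm^3 RBC); `alpha_b`
#' the effective solubility of dissolved oxygen in blood (cm^3 O2/cm^3/mmHg);
#' `inflow_po2` the arterial inflow oxygen tension (mmHg).
#'
#' @param m0 oxygen demand, cm^3 O2/100 cm^3/min.
#' @param p0 Michaelis constant, mmHg.
#' @param p50 hemoglobin half-saturation pressure, mmHg.
#' @param n_hill Hill exponent (> 1).
#' @param d_diff_alpha diffusivity-solubility product, cm^3 O2/cm/s/mmHg.
#' @param c0 red-cell oxygen binding capacity, cm^3 O2/cm^3.
#' @param alpha_b blood oxygen solubility, cm^3 O2/cm^3/mmHg.
#' @param inflow_po2 arterial inflow PO2, mmHg.
#' @param include_dissolved logical; carry the dissolved term `alpha_b * P_b`
#'   in the convective flux during compartment marching (default `TRUE`).
#' @return list of class `oxygen_params`.
#' @export
oxygen_params <- function(m0 = 1, p0 = 10, p50 = 26, n_hill = 2.7,
                          d_diff_alpha = 6e-10, c0 = 0.5, alpha_b = 3.1e-5,
                          inflow_po2 = 84.4, include_dissolved = TRUE) {
  vals <- c(m0 = m0, p0 = p0, p50 = p50, n_hill = n_hill,
            d_diff_alpha = d_diff_alpha, c0 = c0, alpha_b = alpha_b,
            inflow_po2 = inflow_po2)
  if (any(!is.finite(vals)) || any(vals[names(vals) != "m0"] <= 0) || m0 < 0)
    stop_invalid("oxygen parameters must be positive (m0 >= 0)")
  if (n_hill <= 1) stop_invalid("Hill exponent must exceed 1")
  structure(list(m0 = m0, p0 = p0, p50 = p50, n_hill = n_hill,
                 d_diff_alpha = d_diff_alpha, c0 = c0, alpha_b = alpha_b,
                 inflow_po2 = inflow_po2,
                 include_dissolved = isTRUE(include_dissolved)),
            class = "oxygen_params")
}

#' Michaelis-Menten oxygen consumption
#'
#' `M = M0 * PO2 / (P0 + PO2)`: half-maximal at `PO2 = P0`, saturating at the
#' demand `M0`. Units of the result follow the units of `m0`.
#'
#' @param po2 tissue oxygen tension, mmHg (>= 0).
#' @param m0 maximal demand.
#' @param p0 Michaelis constant, mmHg.
#' @export
michaelis_menten <- function(po2, m0, p0 = 10) {
  if (any(po2 < 0)) stop_invalid("po2 must be non-negative")
  m0 * po2 / (p0 + po2)
}

#' Oxyhemoglobin saturation (Hill equation)
#'
#' `S = P^n / (P^n + P50^n)`, strictly increasing in `P`.
#'
#' @param pb blood oxygen tension, mmHg (>= 0).
#' @param p50 half-saturation pressure, mmHg.
#' @param n_hill Hill exponent.
#' @export
hill_saturation <- function(pb, p50 = 26, n_hill = 2.7) {
  if (any(pb < 0)) stop_invalid("pb must be non-negative")
  pb^n_hill / (pb^n_hill + p50^n_hill)
}

#' Invert the Hill saturation curve
#'
#' @param s saturation in `[0, 1)`.
#' @inheritParams hill_saturation
#' @return blood PO2, mmHg.
#' @export
hill_inverse <- function(s, p50 = 26, n_hill = 2.7) {
  if (any(s < 0) || any(s >= 1)) stop_invalid("saturation must be in [0, 1)")
  p50 * (s / (1 - s))^(1 / n_hill)
}

#' Convective oxygen flux along a vessel
#'
#' `f(P_b) = Q * (H_D * C0 * S(P_b) + alpha_b * P_b)`: hemoglobin-bound plus
#' dissolved oxygen carried per unit time, cm^3 O2/s.
#'
#' @param q blood flow, cm^3/s (>= 0).
#' @param hd discharge hematocrit.
#' @param pb blood PO2, mmHg.
#' @param params an [oxygen_params()].
#' @export
convective_flux <- function(q, hd, pb, params = oxygen_params()) {
  if (any(q < 0)) stop_invalid("flow must be non-negative")
  q * oxygen_content(pb, hd, params)
}

## Oxygen content per unit blood volume, cm^3 O2/cm^3.
oxygen_content <- function(pb, hd, params, include_dissolved = TRUE) {
  bound <- hd * params$c0 * hill_saturation(pb, params$p50, params$n_hill)
  if (include_dissolved) bound + params$alpha_b * pb else bound
}

## Invert oxygen content -> PO2 by safeguarded Newton. `content` is per unit
## blood volume; monotone increasing in PO2, so the root is unique.
invert_oxygen_content <- function(content, hd, params, include_dissolved = TRUE,
                                  start = 40) {
  if (content <= 0) return(0)
  cmax <- oxygen_content(1e4, hd, params, include_dissolved)
  if (content >= cmax) return(1e4)
  p <- max(start, 1e-3)
  for (i in 1:60) {
    s <- hill_saturation(p, params$p50, params$n_hill)
    g <- hd * params$c0 * s + (if (include_dissolved) params$alpha_b * p else 0) -
      content
    ds <- params$n_hill * s * (1 - s) / p
    dg <- hd * params$c0 * ds + (if (include_dissolved) params$alpha_b else 0)
    step <- g / dg
    p_new <- p - step
    if (!is.finite(p_new) || p_new <= 0) p_new <- p / 2
    if (abs(p_new - p) < 1e-12 * (1 + p)) { p <- p_new; break }
    p <- p_new
  }
  p
}
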