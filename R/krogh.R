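#' Radial oxygen profile in a Krogh tissue cylinder
#'
#' Solves the radial two-point boundary-value problem
#' `D_diff*alpha * (1/r) d/dr(r dPO2/dr) = M(PO2)` on `[r_v, r_t]` with
#' `PO2(r_v) = P_b` at the capillary wall and zero flux at the outer tissue
#' radius, where `M` follows Michaelis-Menten kinetics. Discretized by
#' second-order finite differences on `n_nodes` radial collocation nodes; the
#' consumption term is handled semi-implicitly (`M ~ M0 * P / (P0 + P_prev)`),
#' which preserves positivity, so the anoxic limit is reached smoothly and the
#' profile never goes negative.
#'
#' @param pb capillary blood PO2 (wall value), mmHg.
#' @param r_v_cm capillary radius, cm.
#' @param r_t_cm tissue cylinder radius, cm (`>= r_v_cm`).
#' @param params an [oxygen_params()] (uses `m0`, `p0`, `d_diff_alpha`).
#' @param n_nodes number of radial nodes.
#' @return list with `r` (cm), `po2` (mmHg), and `consumption_per_length`
#'   (`cm^3 O2/cm/s`, the integral of `M(PO2) 2 pi r dr` over the annulus).
#' @export
krogh_radial_profile <- function(pb, r_v_cm, r_t_cm, params = oxygen_params(),
                                 n_nodes = 50) {
  if (pb < 0) stop_invalid("pb must be non-negative")
  if (r_v_cm <= 0 || r_t_cm < r_v_cm) stop_invalid("need r_t >= r_v > 0")
  m0 <- demand_to_cgs(params$m0)
  k_diff <- params$d_diff_alpha
  if (r_t_cm == r_v_cm || pb == 0 || m0 == 0) {
    r <- seq(r_v_cm, r_t_cm, length.out = n_nodes)
    po2 <- rep(pb, n_nodes)
    cons <- sum_annulus(michaelis_menten(po2, m0, params$p0), r)
    return(list(r = r, po2 = po2, consumption_per_length = cons))
  }
  r <- seq(r_v_cm, r_t_cm, length.out = n_nodes)
  h <- r[2] - r[1]
  p <- rep(pb, n_nodes)
  for (iter in 1:300) {
    ## tridiagonal system K * L p = m0 * p / (p0 + p_prev), Dirichlet at r_v,
    ## ghost-node Neumann at r_t
    lo <- numeric(n_nodes); di <- numeric(n_nodes); up <- numeric(n_nodes)
    rhs <- numeric(n_nodes)
    di[1] <- 1; rhs[1] <- pb
    sink <- m0 / (params$p0 + p)          # linearized uptake coefficient / K
    for (i in 2:(n_nodes - 1)) {
      rm <- (r[i] + r[i - 1]) / 2; rp <- (r[i] + r[i + 1]) / 2
      lo[i] <- k_diff * rm / (h^2 * r[i])
      up[i] <- k_diff * rp / (h^2 * r[i])
      di[i] <- -(lo[i] + up[i]) - sink[i]
    }
    ## zero flux at r_t: mirror ghost node
    rm <- (r[n_nodes] + r[n_nodes - 1]) / 2
    lo[n_nodes] <- 2 * k_diff * rm / (h^2 * r[n_nodes])
    di[n_nodes] <- -lo[n_nodes] - sink[n_nodes]
    p_new <- solve_tridiag(lo, di, up, rhs)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < 1e-10 * max(pb, 1)) break
  }
  p <- pmax(p, 0)
  cons <- sum_annulus(michaelis_menten(p, m0, params$p0), r)
  list(r = r, po2 = p, consumption_per_length = cons)
}

## integral of f(r) * 2 pi r dr by the trapezoidal rule
sum_annulus <- function(f, r) {
  g <- f * 2 * pi * r
  sum((g[-1] + g[-length(g)]) / 2 * diff(r))
}

## Thomas algorithm for a tridiagonal system.
solve_tridiag <- function(lo, di, up, rhs) {
  n <- length(di)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- up[1] / di[1]; dp[1] <- rhs[1] / di[1]
  for (i in 2:n) {
    m <- di[i] - lo[i] * cp[i - 1]
    cp[i] <- if (i < n) up[i] / m else 0
    dp[i] <- (rhs[i] - lo[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

## Smooth cache of the Krogh consumption-per-length as a function of blood
## PO2 for fixed geometry and demand: the BVP is solved on a PO2 knot grid
## and interpolated by a monotone spline. Exactly zero at PO2 = 0.
krogh_consumption_fn <- function(r_v_cm, r_t_cm, params, n_knots = 40,
                                 pb_max = 150) {
  knots <- c(0, params$p0 * ((1:12) / 8), seq(params$p0 * 2, pb_max,
                                              length.out = n_knots - 13))
  knots <- sort(unique(knots))
  q <- vapply(knots, function(pb)
    krogh_radial_profile(pb, r_v_cm, r_t_cm, params)$consumption_per_length,
    numeric(1))
  stats::splinefun(knots, q, method = "hyman")
}

#' Axial oxygen marching along a compartment chain
#'
#' Integrates the convective oxygen balance `d f / ds = -q(s)` along the
#' capillary compartment of one pathway, with the diffusive efflux per length
#' `q` supplied by the Krogh cylinder model at the local blood PO2, using a
#' classical fourth-order Runge-Kutta scheme on `n_steps` axial samples. The
#' saturation is inverted through the Hill curve at every stage. If the blood
#' PO2 reaches zero the remainder of the capillary is clamped at zero and the
#' clamp position recorded. Oxygen exchange in the venular compartments is
#' neglected (tissue width zero), so their PO2 is constant and equal to the
#' capillary outflow value.
#'
#' @param chain the three compartment rows (C, SV, LV) of one pathway, as
#'   built by [build_pathway_chains()].
#' @param pb_in capillary inflow blood PO2, mmHg.
#' @param d_cm tissue width around the capillary, cm.
#' @param params an [oxygen_params()] (`include_dissolved` selects whether the
#'   dissolved term `alpha_b P_b` is carried in the marched flux).
#' @param n_steps axial integration steps in the capillary (>= 100 samples).
#' @param q_fun optional consumption-per-length function of PO2 (defaults to a
#'   spline cache of [krogh_radial_profile()]).
#' @return list with per-compartment profiles (`s`, `pb`), `pb_out` of each
#'   compartment, `clamped_from_cm` (NA when never clamped), and the capillary
#'   consumption integral `consumption` (cm^3 O2/s per capillary).
#' @export
march_chain <- function(chain, pb_in, d_cm, params = oxygen_params(),
                        n_steps = 100, q_fun = NULL) {
  if (pb_in < 0) stop_invalid("pb_in must be non-negative")
  cc <- chain[chain$kind == "C", ]
  if (nrow(cc) != 1) stop_invalid("chain must contain one capillary compartment")
  r_v <- um_to_cm(cc$D_um) / 2
  if (is.null(q_fun)) {
    q_fun0 <- krogh_consumption_fn(r_v, r_v + d_cm, params,
                                   pb_max = max(150, pb_in * 1.2))
    q_fun <- function(p) ifelse(p <= 0, 0, q_fun0(pmin(p, 1e6)))
  }
  q_flow <- cc$Q; hd <- cc$H_D
  incl <- params$include_dissolved
  content <- function(p) oxygen_content(p, hd, params, incl)
  inv <- function(cv) {
    if (cv <= 0) 0 else invert_oxygen_content(cv, hd, params, incl)
  }
  h <- cc$L_cm / n_steps
  s <- seq(0, cc$L_cm, length.out = n_steps + 1)
  pb <- numeric(n_steps + 1)
  pb[1] <- pb_in
  cval <- content(pb_in)
  clamp_at <- NA_real_
  rate <- function(cv) -q_fun(inv(cv)) / q_flow   # d(content)/ds
  for (i in seq_len(n_steps)) {
    if (cval <= 0) { pb[i + 1] <- 0; next }
    k1 <- rate(cval)
    k2 <- rate(max(cval + h / 2 * k1, 0))
    k3 <- rate(max(cval + h / 2 * k2, 0))
    k4 <- rate(max(cval + h * k3, 0))
    c_new <- cval + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (c_new <= 0) {
      ## linear estimate of the anoxia onset within the step
      frac <- min(max(cval / max(cval - c_new, 1e-300), 0), 1)
      if (is.na(clamp_at)) clamp_at <- s[i] + frac * h
      c_new <- 0
    }
    cval <- c_new
    pb[i + 1] <- inv(cval)
    if (pb[i + 1] == 0 && is.na(clamp_at)) clamp_at <- s[i + 1]
  }
  pb_out <- pb[n_steps + 1]
  consumption <- q_flow * (content(pb_in) - content(pb_out))
  sv <- chain[chain$kind == "SV", ]; lv <- chain[chain$kind == "LV", ]
  list(capillary = list(s = s, pb = pb),
       sv = list(s = c(0, sv$L_cm), pb = rep(pb_out, 2)),
       lv = list(s = c(0, lv$L_cm), pb = rep(pb_out, 2)),
       pb_in = pb_in, pb_out = pb_out, clamped_from_cm = clamp_at,
       consumption = consumption)
}

#' Capillary inflow PO2 from the outflowing terminal arterioles
#'
#' The inflow oxygen content of a capillary compartment is the flow-weighted
#' mean content of the terminal arterioles feeding it,
#' `sum(Q_k (H_k C0 S(P_k) + alpha_b P_k)) / sum(Q_k)`; the inflow PO2 is
#' recovered by numerically inverting the content-PO2 relation at the
#' flow-weighted hematocrit.
#'
#' @param q flows of the contributing terminal arterioles, cm^3/s.
#' @param hd their discharge hematocrits.
#' @param pb their outflow blood PO2, mmHg.
#' @param params an [oxygen_params()].
#' @return inflow PO2, mmHg.
#' @export
capillary_inflow_po2 <- function(q, hd, pb, params = oxygen_params()) {
  if (sum(q) <= 0) stop_invalid("total inflow is zero: inflow PO2 undefined")
  content <- sum(q * oxygen_content(pb, hd, params)) / sum(q)
  hd_mix <- sum(q * hd) / sum(q)
  invert_oxygen_content(content, hd_mix, params, start = max(pb))
}
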