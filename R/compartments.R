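#' Control-state parameters for the compartmental microcirculation
#'
#' Scalar constants defining the healthy reference state of the capillary (C),
#' small-venule (SV) and large-venule (LV) compartments: arterial inflow
#' pressure `p_a`, intraocular pressure `iop` (the effective outflow pressure),
#' capillary diameter and wall shear stress, the capillary density `n_cap`
#' (per cm^2 of retina), the arteriolar network vessel-plus-tissue volume
#' `a_vol`, the anchor diameters at which venular wall shear rates are
#' interpolated, and the wall-shear-rate-versus-diameter table.
#'
#' The default shear-rate table is a synthetic stand-in constructed for this
#' package: its capillary, small-venule and large-venule knots equal the
#' control-state ratios tau/mu (15/9.05 cP, 15.6/2.28 cP, 14.7/2.39 cP at 6,
#' 69 and 140 um), its 20 um knot is a peak arteriolar shear rate typical of
#' microvascular measurements, and it is flat above 140 um where measured
#' shear rates are nearly constant. Override it with measured values via
#' `shear_rate_table`.
#'
#' @param p_a arterial inflow pressure, mmHg.
#' @param iop intraocular pressure, mmHg.
#' @param d_c_um capillary diameter, um.
#' @param tau_c capillary wall shear stress, dyn/cm^2.
#' @param n_cap capillary density, 1/cm^2.
#' @param a_vol arteriolar network vessel+tissue volume, cm^3.
#' @param d_sv_anchor,d_lv_anchor diameters (um) at which the SV and LV wall
#'   shear rates are read from the table.
#' @param shear_rate_table data.frame `diameter_um`, `omega` (1/s), diameters
#'   strictly increasing.
#' @param hd_capillary discharge hematocrit used for capillary and venular
#'   viscosities, or `NULL` to use each pathway's terminal-arteriole
#'   hematocrit.
#' @return list of class `control_state_params`.
#' @export
control_state_params <- function(p_a = 40, iop = 15, d_c_um = 6, tau_c = 15,
                                 n_cap = 50000, a_vol = 0.0025,
                                 d_sv_anchor = 69, d_lv_anchor = 140,
                                 shear_rate_table = default_shear_rate_table(),
                                 hd_capillary = 0.40) {
  if (p_a <= iop) stop_invalid("p_a must exceed iop")
  stopifnot(d_c_um > 0, tau_c > 0, n_cap > 0, a_vol > 0)
  structure(list(p_a = p_a, iop = iop, d_c_um = d_c_um, tau_c = tau_c,
                 n_cap = n_cap, a_vol = a_vol, d_sv_anchor = d_sv_anchor,
                 d_lv_anchor = d_lv_anchor,
                 shear_rate_table = shear_rate_table,
                 hd_capillary = hd_capillary),
            class = "control_state_params")
}

#' @rdname control_state_params
#' @export
default_shear_rate_table <- function() {
  data.frame(diameter_um = c(6, 20, 69, 140, 300),
             omega = c(15 / 0.0905, 2200, 15.6 / 0.0228, 14.7 / 0.0239,
                       14.7 / 0.0239))
}

#' Flow in a single capillary from its wall shear stress
#'
#' `Q_C = pi * tau_C * D_C^3 / (32 * mu_C)`, the Poiseuille relation expressed
#' through the wall shear stress instead of the pressure gradient.
#'
#' @param tau_c wall shear stress, dyn/cm^2.
#' @param d_c_um capillary diameter, um.
#' @param mu_c_cP capillary apparent viscosity, cP.
#' @return flow, cm^3/s.
#' @export
capillary_flow <- function(tau_c = 15, d_c_um = 6, mu_c_cP = 9.05) {
  if (tau_c < 0 || d_c_um <= 0 || mu_c_cP <= 0)
    stop_invalid("capillary parameters must be positive")
  pi * tau_c * um_to_cm(d_c_um)^3 / (32 * cP_to_poise(mu_c_cP))
}

#' Interpolate a wall shear rate from a diameter table
#'
#' Linear interpolation in diameter. Above the tabulated range the maximum
#' possible interpolated value (the largest tabulated shear rate) is returned,
#' reflecting that measured wall shear rates are nearly constant at large
#' diameters; below the range is an error.
#'
#' @param d_um vessel diameter, um.
#' @param table data.frame `diameter_um`, `omega` with >= 2 rows, diameters
#'   strictly increasing.
#' @return wall shear rate, 1/s.
#' @export
interpolate_shear_rate <- function(d_um, table = default_shear_rate_table()) {
  if (nrow(table) < 2 || is.unsorted(table$diameter_um, strictly = TRUE))
    stop_invalid("shear-rate table needs >= 2 rows with increasing diameters")
  if (any(d_um < table$diameter_um[1]))
    stop_invalid("diameter %g um below the shear-rate table range",
                 min(d_um))
  out <- stats::approx(table$diameter_um, table$omega, xout = d_um,
                       rule = 1)$y
  out[d_um > max(table$diameter_um)] <- max(table$omega)
  out
}

#' Venular diameters from arteriolar diameters and wall shear rates
#'
#' Symmetry and flow conservation give `D_SV = D_SA * (w_SA / w_SV)^(1/3)` and
#' `D_LV = D_LA * (w_LA / w_LV)^(1/3)`.
#'
#' @param d_sa_um,d_la_um small/large arteriole diameters, um.
#' @param w_sa,w_la,w_sv,w_lv wall shear rates, 1/s.
#' @return list `D_SV_um`, `D_LV_um`.
#' @export
venular_diameters <- function(d_sa_um, d_la_um, w_sa, w_la, w_sv, w_lv) {
  if (any(c(d_sa_um, d_la_um, w_sa, w_la, w_sv, w_lv) <= 0))
    stop_invalid("diameters and shear rates must be positive")
  list(D_SV_um = d_sa_um * (w_sa / w_sv)^(1 / 3),
       D_LV_um = d_la_um * (w_la / w_lv)^(1 / 3))
}

#' Build capillary/venule compartment chains for every terminal arteriole
#'
#' For each pathway of the classified network, constructs the series chain of
#' capillary (C), small-venule (SV) and large-venule (LV) compartments in the
#' control state. The symmetry assumptions set `n_SV = 1`,
#' `n_LV = Q_SA / Q_LA`, `n_C = Q_SA / Q_C`, `L_SV = L_SA`, `L_LV = L_LA`;
#' venular diameters follow [venular_diameters()] with shear rates interpolated
#' from the control table; venular pressure drops follow Poiseuille's law; the
#' capillary pressure drop is the residual of the total perfusion pressure
#' `p_a - iop` after the arteriolar and venular drops, and the capillary
#' length follows from Poiseuille's law given that residual.
#'
#' @param flow a `flow_solution` whose network has been classified by
#'   [classify_segments()] before solving (pathways present).
#' @param params a [control_state_params()].
#' @return object of class `compartment_chains`: data.frame `chains` with one
#'   row per pathway and compartment (kind, n, D_um, L_cm, mu_cP, tau,
#'   dP_mmHg, Q), plus pathway metadata and solved tissue width slot `d_cm`
#'   (NA until [solve_tissue_width()]).
#' @export
build_pathway_chains <- function(flow, params = control_state_params()) {
  net <- flow$net
  if (is.null(net$pathways))
    stop_invalid("network has no pathways: run classify_segments() before solving flow")
  pw <- net$pathways
  sg <- flow$segments
  seg_row <- stats::setNames(seq_len(nrow(sg)), sg$id)
  tab <- params$shear_rate_table
  w_sv_anchor <- interpolate_shear_rate(params$d_sv_anchor, tab)
  w_lv_anchor <- interpolate_shear_rate(params$d_lv_anchor, tab)
  rows <- vector("list", nrow(pw))
  for (i in seq_len(nrow(pw))) {
    t_seg <- seg_row[[pw$terminal_segment[i]]]
    r_seg <- seg_row[[pw$root_segment[i]]]
    q_sa <- sg$Q[t_seg]; q_la <- sg$Q[r_seg]
    d_sa <- pw$D_SA_um[i]; d_la <- pw$D_LA_um[i]
    dp_sa <- sg$dP_mmHg[t_seg]
    dp_path <- params$p_a - flow$node_pressures[[sg$to[t_seg]]]
    dp_la <- dp_path - dp_sa
    l_sa <- sg$length_cm[t_seg]
    l_la <- pw$path_length_cm[i] - l_sa
    hd <- if (is.null(params$hd_capillary)) sg$H_D[t_seg] else params$hd_capillary

    w_sa <- interpolate_shear_rate(d_sa, tab)
    w_la <- interpolate_shear_rate(d_la, tab)
    dv <- venular_diameters(d_sa, d_la, w_sa, w_la, w_sv_anchor, w_lv_anchor)
    mu_c <- viscosity_in_vivo(params$d_c_um, hd)
    mu_sv <- viscosity_in_vivo(dv$D_SV_um, hd)
    mu_lv <- viscosity_in_vivo(dv$D_LV_um, hd)
    q_c <- capillary_flow(params$tau_c, params$d_c_um, mu_c)
    n_c <- q_sa / q_c
    n_lv <- q_sa / q_la
    q_lv <- q_la                       # per-segment flow in the LV compartment
    l_sv <- l_sa; l_lv <- if (l_la > 0) l_la else l_sa
    dp_sv <- cgs_to_mmHg(128 * cP_to_poise(mu_sv) * q_sa * l_sv /
                           (pi * um_to_cm(dv$D_SV_um)^4))
    dp_lv <- cgs_to_mmHg(128 * cP_to_poise(mu_lv) * q_lv * l_lv /
                           (pi * um_to_cm(dv$D_LV_um)^4))
    dp_c <- (params$p_a - params$iop) - dp_path - dp_sv - dp_lv
    if (dp_c <= 0)
      stop_invalid(paste("infeasible control state for pathway %s:",
                         "residual capillary pressure drop %.3f mmHg"),
                   pw$terminal_node[i], dp_c)
    l_c <- mmHg_to_cgs(dp_c) * pi * um_to_cm(params$d_c_um)^4 /
      (128 * cP_to_poise(mu_c) * q_c)
    rows[[i]] <- data.frame(
      pathway = pw$terminal_node[i],
      kind = c("C", "SV", "LV"),
      n = c(n_c, 1, n_lv),
      D_um = c(params$d_c_um, dv$D_SV_um, dv$D_LV_um),
      L_cm = c(l_c, l_sv, l_lv),
      mu_cP = c(mu_c, mu_sv, mu_lv),
      tau = c(params$tau_c, w_sv_anchor * cP_to_poise(mu_sv),
              w_lv_anchor * cP_to_poise(mu_lv)),
      dP_mmHg = c(dp_c, dp_sv, dp_lv),
      Q = c(q_c, q_sa, q_lv),
      H_D = hd,
      stringsAsFactors = FALSE)
  }
  meta <- data.frame(pathway = pw$terminal_node,
                     terminal_segment = pw$terminal_segment,
                     Q_SA = sg$Q[seg_row[pw$terminal_segment]],
                     Q_LA = sg$Q[seg_row[pw$root_segment]],
                     H_D_terminal = sg$H_D[seg_row[pw$terminal_segment]],
                     D_SA_um = pw$D_SA_um, D_LA_um = pw$D_LA_um,
                     stringsAsFactors = FALSE)
  structure(list(chains = do.call(rbind, rows), meta = meta, params = params,
                 d_cm = NA_real_),
            class = "compartment_chains")
}

#' @export
print.compartment_chains <- function(x, ...) {
  cat(sprintf("<compartment_chains> %d pathways, tissue width d = %s\n",
              nrow(x$meta),
              if (is.na(x$d_cm)) "unsolved"
              else sprintf("%.1f um", cm_to_um(x$d_cm))))
  agg <- stats::aggregate(x$chains[c("n", "D_um", "L_cm", "dP_mmHg")],
                          by = list(kind = x$chains$kind), FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Solve for the capillary tissue-cylinder width from the capillary density
#'
#' Finds the tissue width `d` such that the prescribed capillary density `N`
#' equals the total capillary length divided by the total tissue volume: the
#' arteriolar vessel+tissue volume `a_vol` plus the Krogh cylinders of all
#' capillaries (radius `r_C + d`) and the volumes of the venular compartments.
#' The right-hand side decreases strictly in `d`, so the root is unique;
#' it is bracketed on `[0, 1]` cm.
#'
#' @param chains a `compartment_chains`.
#' @param n_cap capillary density, 1/cm^2 (default from the chain params).
#' @param a_vol arteriolar volume, cm^3 (default from the chain params).
#' @return the chains object with `d_cm` set.
#' @export
solve_tissue_width <- function(chains, n_cap = chains$params$n_cap,
                               a_vol = chains$params$a_vol) {
  ch <- chains$chains
  cc <- ch[ch$kind == "C", ]; sv <- ch[ch$kind == "SV", ]
  lv <- ch[ch$kind == "LV", ]
  if (nrow(cc) == 0) stop_invalid("no capillary compartments")
  cap_len <- sum(cc$n * cc$L_cm)
  r_c <- um_to_cm(cc$D_um) / 2
  ven_vol <- sum(sv$n * sv$L_cm * pi * um_to_cm(sv$D_um / 2)^2) +
    sum(lv$n * lv$L_cm * pi * um_to_cm(lv$D_um / 2)^2)
  density <- function(d) {
    cap_len / (a_vol + sum(cc$n * cc$L_cm * pi * (r_c + d)^2) + ven_vol)
  }
  if (density(0) < n_cap)
    stop_invalid("capillary density %g unattainable even at d = 0 (max %g)",
                 n_cap, density(0))
  root <- stats::uniroot(function(d) density(d) - n_cap, c(0, 1),
                         tol = 1e-14)
  chains$d_cm <- root$root
  chains
}

#' Export compartment chains as CSV
#' @param chains a `compartment_chains`.
#' @param file output path.
#' @export
write_compartments_csv <- function(chains, file) {
  utils::write.csv(chains$chains, file, row.names = FALSE)
  invisible(file)
}
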