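#' Simulation configuration
#'
#' Collects every scalar parameter of the hybrid model with its control-state
#' default: boundary pressures (inlet 40 mmHg, terminal arterioles 24 mmHg,
#' IOP 15 mmHg, hence a fixed 16 mmHg arteriolar drop), inlet discharge
#' hematocrit 0.40 with 1 cP plasma, the oxygen constants (demand `m0`,
#' `p0` = 10 mmHg, `p50` = 26 mmHg, Hill exponent 2.7, inflow PO2 84.4 mmHg,
#' `D_diff alpha` = 6e-10), the compartment control state (capillary 6 um at
#' 15 dyn/cm^2, capillary density 50,000/cm^2, `a_vol` = 0.0025 cm^3, venular
#' shear anchors 69/140 um), the conduction constant `l0` = 1 cm, and the
#' numerical resolutions (vessel element length, tissue grid, tolerances).
#'
#' @param ... overrides for any default field (unknown names are an error).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    p_a = 40, iop = 15, p_terminal = 24,
    hd_in = 0.40, plasma_cP = 1,
    m0 = 1, p0 = 10, p50 = 26, n_hill = 2.7,
    d_diff_alpha = 6e-10, c0 = 0.5, alpha_b = 3.1e-5, inflow_po2 = 84.4,
    include_dissolved = TRUE,
    l0 = 1, junction_rule = "additive",
    d_c_um = 6, tau_c = 15, n_cap = 50000, a_vol = 0.0025,
    d_sv_anchor = 69, d_lv_anchor = 140, hd_capillary = 0.40,
    shear_rate_table = default_shear_rate_table(),
    max_element_cm = 0.0025, max_vessel_elements = 4000,
    tissue_spacing_cm = 0.004, tissue_margin_cm = 0.05,
    tissue_thickness_cm = 0.02, tissue_nz = 2, tissue_max_dist_cm = 0.06,
    max_tissue_points = 3000,
    n_images = 1,
    flow_tol = 1e-6, flow_max_iter = 100,
    greens_tol = 1e-3, greens_max_iter = 200, greens_relax = 0.5,
    cap_steps = 100)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_invalid("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) {
      cat(sprintf("  %s: <%d-row table>\n", nm, nrow(x[[nm]])))
    } else cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Save or load a configuration as JSON
#' @param cfg a [sim_config()].
#' @param file path.
#' @export
write_config <- function(cfg, file) {
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  obj$shear_rate_table <- as.data.frame(obj$shear_rate_table)
  do.call(sim_config, obj)
}

config_oxygen_params <- function(cfg) {
  oxygen_params(m0 = cfg$m0, p0 = cfg$p0, p50 = cfg$p50, n_hill = cfg$n_hill,
                d_diff_alpha = cfg$d_diff_alpha, c0 = cfg$c0,
                alpha_b = cfg$alpha_b, inflow_po2 = cfg$inflow_po2,
                include_dissolved = cfg$include_dissolved)
}

config_control_params <- function(cfg) {
  control_state_params(p_a = cfg$p_a, iop = cfg$iop, d_c_um = cfg$d_c_um,
                       tau_c = cfg$tau_c, n_cap = cfg$n_cap, a_vol = cfg$a_vol,
                       d_sv_anchor = cfg$d_sv_anchor,
                       d_lv_anchor = cfg$d_lv_anchor,
                       shear_rate_table = cfg$shear_rate_table,
                       hd_capillary = cfg$hd_capillary)
}

#' Run the full hybrid pipeline once
#'
#' Executes the model stages in order: segment classification, network flow
#' solve, Green's function oxygen transport on the arterioles, construction of
#' the compartment chains and the tissue-width solve, capillary hand-off and
#' Krogh-cylinder axial marching, and metabolic signal propagation. When
#' `out_dir` is given, writes `flow.csv`, `tissue_po2.csv`, `compartments.csv`,
#' `capillary_po2.csv`, `smeta.csv`, and `summary.json` there.
#'
#' @param net a [vascular_network()].
#' @param cfg a [sim_config()].
#' @param out_dir optional output directory (created if missing).
#' @param quiet suppress per-stage progress messages.
#' @return list of class `run_result` with `flow`, `greens`, `chains`,
#'   `profiles`, `signals`, `summary`, and `config`.
#' @export
run_pipeline <- function(net, cfg = sim_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  net <- stage("classify", classify_segments(net))
  say("flow: solving %d segments", nrow(net$segments))
  flow <- stage("flow", solve_network_flow(
    net, cfg$p_a, cfg$p_terminal, cfg$hd_in, cfg$plasma_cP,
    tol = cfg$flow_tol, max_iter = cfg$flow_max_iter))
  ox <- config_oxygen_params(cfg)
  tissue <- stage("tissue_grid", tissue_grid(
    net, cfg$tissue_spacing_cm, cfg$tissue_margin_cm,
    cfg$tissue_thickness_cm, cfg$tissue_nz, cfg$tissue_max_dist_cm))
  if (nrow(tissue) > cfg$max_tissue_points)
    stop_invalid(paste("tissue grid has %d points (> max_tissue_points = %d);",
                       "increase tissue_spacing_cm"),
                 nrow(tissue), cfg$max_tissue_points)
  say("oxygen: Green's function solve (%d tissue points)", nrow(tissue))
  greens <- stage("greens", solve_greens(
    flow, tissue, ox, cfg$max_element_cm, cfg$greens_tol, cfg$greens_max_iter,
    cfg$greens_relax, cfg$n_images))
  say("compartments: building chains")
  chains <- stage("compartments", build_pathway_chains(
    flow, config_control_params(cfg)))
  chains <- stage("tissue_width", solve_tissue_width(chains))
  say("capillaries: Krogh marching (%d pathways, d = %.1f um)",
      nrow(chains$meta), cm_to_um(chains$d_cm))
  profiles <- stage("krogh", march_all_chains(flow, greens, chains, ox,
                                              cfg$cap_steps))
  say("signal: conducting upstream")
  signals <- stage("signal", propagate_signal(
    flow, greens, chains, profiles, ox, cfg$l0, cfg$junction_rule))
  res <- structure(list(flow = flow, greens = greens, chains = chains,
                        profiles = profiles, signals = signals,
                        summary = summarize_run(greens, chains, profiles,
                                                signals, cfg$m0),
                        config = cfg),
                   class = "run_result")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

## Hand off terminal-arteriole oxygen to every chain and march the capillary.
## The Krogh consumption spline is shared across pathways (same geometry).
march_all_chains <- function(flow, greens, chains, ox, n_steps = 100) {
  r_v <- um_to_cm(chains$params$d_c_um) / 2
  q_fun0 <- krogh_consumption_fn(r_v, r_v + chains$d_cm, ox,
                                 pb_max = max(150, ox$inflow_po2 * 1.2))
  q_fun <- function(p) ifelse(p <= 0, 0, q_fun0(pmin(p, 1e6)))
  seg <- greens$segments
  seg_row <- stats::setNames(seq_len(nrow(seg)), seg$id)
  profiles <- list()
  for (i in seq_len(nrow(chains$meta))) {
    pid <- chains$meta$pathway[i]
    t_row <- seg_row[[chains$meta$terminal_segment[i]]]
    pb_in <- capillary_inflow_po2(seg$Q[t_row], seg$H_D[t_row],
                                  seg$pb_out[t_row], ox)
    ch <- chains$chains[chains$chains$pathway == pid, ]
    profiles[[pid]] <- march_chain(ch, pb_in, chains$d_cm, ox,
                                   n_steps = n_steps, q_fun = q_fun)
  }
  profiles
}

summarize_run <- function(greens, chains, profiles, signals, m0) {
  up <- vapply(profiles, function(p) p$pb_in, numeric(1))
  dn <- vapply(profiles, function(p) p$pb_out, numeric(1))
  cap <- signals[signals$class == "C", ]
  art <- signals[signals$class %in% c("LA", "SA"), ]
  list(m0 = m0,
       cap_po2_up_mean = mean(up), cap_po2_up_sd = stats::sd(up),
       cap_po2_down_mean = mean(dn), cap_po2_down_sd = stats::sd(dn),
       smeta_cap_up_mean = mean(cap$S_up), smeta_cap_up_sd = stats::sd(cap$S_up),
       smeta_arteriole_mean = mean(art$S_meta),
       smeta_arteriole_sd = stats::sd(art$S_meta),
       smeta_terminal_mean = mean(art$S_meta[art$class == "SA"]),
       smeta_terminal_sd = stats::sd(art$S_meta[art$class == "SA"]),
       tissue_po2_mean = mean(greens$tissue$po2),
       tissue_po2_sd = stats::sd(greens$tissue$po2),
       n_clamped = sum(vapply(profiles,
                              function(p) !is.na(p$clamped_from_cm),
                              logical(1))))
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_flow_csv(res$flow, file.path(out_dir, "flow.csv"))
  write_tissue_csv(res$greens, file.path(out_dir, "tissue_po2.csv"))
  write_compartments_csv(res$chains, file.path(out_dir, "compartments.csv"))
  cap <- data.frame(pathway = names(res$profiles),
                    pb_upstream = vapply(res$profiles, `[[`, numeric(1),
                                         "pb_in"),
                    pb_downstream = vapply(res$profiles, `[[`, numeric(1),
                                           "pb_out"),
                    clamp_position_cm = vapply(res$profiles, `[[`, numeric(1),
                                               "clamped_from_cm"))
  utils::write.csv(cap, file.path(out_dir, "capillary_po2.csv"),
                   row.names = FALSE)
  write_smeta_csv(res$signals, file.path(out_dir, "smeta.csv"))
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<run_result> M0 = %g cm^3 O2/100cm^3/min\n", s$m0))
  cat(sprintf("  capillary PO2 up %.1f +/- %.1f, down %.1f +/- %.1f mmHg\n",
              s$cap_po2_up_mean, s$cap_po2_up_sd, s$cap_po2_down_mean,
              s$cap_po2_down_sd))
  cat(sprintf("  S_meta (capillary upstream) %.3f +/- %.3f; arterioles %.3f +/- %.3f\n",
              s$smeta_cap_up_mean, s$smeta_cap_up_sd, s$smeta_arteriole_mean,
              s$smeta_arteriole_sd))
  cat(sprintf("  tissue PO2 %.1f +/- %.1f mmHg; %d anoxic capillary pathway(s)\n",
              s$tissue_po2_mean, s$tissue_po2_sd, s$n_clamped))
  invisible(x)
}

#' Sweep oxygen demand and summarize each run
#'
#' Re-runs the oxygen, compartment, and signal stages for each oxygen demand
#' in `m0_values`, reusing the flow solution and all geometric couplings
#' (flow and geometry are demand-independent).
#'
#' @param net a [vascular_network()].
#' @param cfg a [sim_config()] (its `m0` field is overridden per run).
#' @param m0_values oxygen demands, cm^3 O2/100 cm^3/min.
#' @param out_dir optional directory; writes `sweep_summary.csv` and one
#'   subdirectory of full outputs per demand.
#' @param quiet suppress progress messages.
#' @return list with `summary` (one row per demand) and `runs` (the
#'   individual `run_result`s, named by demand).
#' @export
demand_sweep <- function(net, cfg = sim_config(), m0_values = c(1, 2, 4),
                         out_dir = NULL, quiet = FALSE) {
  if (any(m0_values <= 0)) stop_invalid("m0 values must be positive")
  net <- classify_segments(net)
  flow <- solve_network_flow(net, cfg$p_a, cfg$p_terminal, cfg$hd_in,
                             cfg$plasma_cP, tol = cfg$flow_tol,
                             max_iter = cfg$flow_max_iter)
  tissue <- tissue_grid(net, cfg$tissue_spacing_cm, cfg$tissue_margin_cm,
                        cfg$tissue_thickness_cm, cfg$tissue_nz,
                        cfg$tissue_max_dist_cm)
  if (nrow(tissue) > cfg$max_tissue_points)
    stop_invalid("tissue grid has %d points; increase tissue_spacing_cm",
                 nrow(tissue))
  ox0 <- config_oxygen_params(cfg)
  sys <- greens_system(flow, tissue, ox0, cfg$max_element_cm, cfg$n_images,
                       cfg$max_vessel_elements)
  chains <- build_pathway_chains(flow, config_control_params(cfg))
  chains <- solve_tissue_width(chains)
  runs <- list()
  for (m0 in m0_values) {
    if (!quiet) message(sprintf("demand sweep: M0 = %g", m0))
    cfg_i <- cfg; cfg_i$m0 <- m0
    ox <- config_oxygen_params(cfg_i)
    greens <- solve_greens(flow, tissue, ox, cfg$max_element_cm,
                           cfg$greens_tol, cfg$greens_max_iter,
                           cfg$greens_relax, cfg$n_images, system = sys)
    profiles <- march_all_chains(flow, greens, chains, ox, cfg$cap_steps)
    signals <- propagate_signal(flow, greens, chains, profiles, ox, cfg$l0,
                                cfg$junction_rule)
    res <- structure(list(flow = flow, greens = greens, chains = chains,
                          profiles = profiles, signals = signals,
                          summary = summarize_run(greens, chains, profiles,
                                                  signals, m0),
                          config = cfg_i),
                     class = "run_result")
    runs[[as.character(m0)]] <- res
    if (!is.null(out_dir))
      write_run(res, file.path(out_dir, sprintf("m0_%g", m0)))
  }
  summary <- do.call(rbind, lapply(runs, function(r)
    as.data.frame(r$summary)))
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "sweep_summary.csv"),
                     row.names = FALSE)
  list(summary = summary, runs = runs)
}
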