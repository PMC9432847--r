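test_that("capillary flow from wall shear matches the control state", {
  expect_equal(capillary_flow(15, 6, 9.05), 3.51e-9, tolerance = 0.005 / 3.51)
  ## cross-check against Poiseuille with the Table-consistent drop and length
  expect_equal(capillary_flow(15, 6, 9.05), poiseuille_flow(6, 6, 0.080, 9.05),
               tolerance = 2e-3)
  expect_equal(capillary_flow(0, 6, 9.05), 0)
  expect_equal(capillary_flow(15, 12, 9.05), 8 * capillary_flow(15, 6, 9.05))
  expect_error(capillary_flow(15, -6, 9.05), "positive")
})

test_that("shear-rate interpolation is linear, capped above, error below", {
  tab <- data.frame(diameter_um = c(10, 20, 40), omega = c(100, 300, 250))
  expect_equal(interpolate_shear_rate(20, tab), 300)
  expect_equal(interpolate_shear_rate(15, tab), 200)   # midpoint mean
  expect_equal(interpolate_shear_rate(30, tab), 275)
  ## above range: the maximum possible interpolated value
  expect_equal(interpolate_shear_rate(100, tab), 300)
  expect_error(interpolate_shear_rate(5, tab), "below")
  expect_error(interpolate_shear_rate(20, tab[1, , drop = FALSE]), "rows")
  ## shipped default table hits the control-state anchors
  def <- default_shear_rate_table()
  expect_equal(interpolate_shear_rate(6, def), 15 / 0.0905)
  expect_equal(interpolate_shear_rate(69, def), 15.6 / 0.0228)
  expect_equal(interpolate_shear_rate(140, def), 14.7 / 0.0239)
})

test_that("venular diameters follow the cube-root shear symmetry relation", {
  v <- venular_diameters(36, 140, 500, 600, 500, 600)
  expect_equal(v$D_SV_um, 36)
  expect_equal(v$D_LV_um, 140)
  expect_equal(venular_diameters(36, 140, 8 * 500, 600, 500, 600)$D_SV_um, 72)
  expect_error(venular_diameters(-1, 140, 1, 1, 1, 1), "positive")
})

test_that("pathway chains satisfy the symmetry and pressure bookkeeping", {
  net <- classify_segments(make_paper_scale_network(seed = 3,
                                                    bifurcation_levels = 3))
  fl <- solve_network_flow(net)
  ch <- build_pathway_chains(fl)
  cc <- ch$chains
  for (pid in ch$meta$pathway) {
    rows <- cc[cc$pathway == pid, ]
    meta <- ch$meta[ch$meta$pathway == pid, ]
    ## n_SV = 1, n_LV = Q_SA / Q_LA, n_C = Q_SA / Q_C
    expect_equal(rows$n[rows$kind == "SV"], 1)
    expect_equal(rows$n[rows$kind == "LV"], meta$Q_SA / meta$Q_LA)
    expect_equal(rows$n[rows$kind == "C"],
                 meta$Q_SA / rows$Q[rows$kind == "C"])
    ## flow conservation along the chain: n * Q identical in each compartment
    expect_equal(unique(round(rows$n * rows$Q / meta$Q_SA, 12)), 1)
    ## total pressure drop = P_a - IOP exactly (arteriolar 16 + compartments)
    expect_equal(sum(rows$dP_mmHg) + 16, 40 - 15, tolerance = 1e-10)
  }
  ## capillary length follows Poiseuille at the residual drop
  crow <- cc[cc$kind == "C", ][1, ]
  expect_equal(poiseuille_flow(crow$dP_mmHg, crow$D_um, crow$L_cm, crow$mu_cP),
               crow$Q, tolerance = 1e-10)
})

test_that("tissue width solves the capillary-density balance", {
  net <- classify_segments(make_paper_scale_network(seed = 3,
                                                    bifurcation_levels = 3))
  fl <- solve_network_flow(net)
  ch <- solve_tissue_width(build_pathway_chains(fl))
  expect_false(is.na(ch$d_cm))
  ## residual: density evaluated at the returned d equals N to 1e-9 relative
  cc <- ch$chains[ch$chains$kind == "C", ]
  sv <- ch$chains[ch$chains$kind == "SV", ]
  lv <- ch$chains[ch$chains$kind == "LV", ]
  r_c <- cc$D_um / 2 * 1e-4
  dens <- sum(cc$n * cc$L_cm) /
    (0.0025 + sum(cc$n * cc$L_cm * pi * (r_c + ch$d_cm)^2) +
       sum(sv$n * sv$L_cm * pi * (sv$D_um / 2 * 1e-4)^2) +
       sum(lv$n * lv$L_cm * pi * (lv$D_um / 2 * 1e-4)^2))
  expect_equal(dens, 50000, tolerance = 1e-9)
  ## a denser capillary bed implies a thinner tissue sleeve
  ch_hi <- solve_tissue_width(ch, n_cap = 80000)
  expect_lt(ch_hi$d_cm, ch$d_cm)
  ## grid-scan oracle on a single-pathway toy
  toy <- classify_segments(make_toy_network("single"))
  ft <- solve_network_flow(toy)
  cht <- solve_tissue_width(build_pathway_chains(ft))
  grid <- seq(0, 0.01, by = 1e-7)
  cct <- cht$chains[cht$chains$kind == "C", ]
  svt <- cht$chains[cht$chains$kind == "SV", ]
  lvt <- cht$chains[cht$chains$kind == "LV", ]
  dens_g <- sum(cct$n * cct$L_cm) /
    (0.0025 + cct$n * cct$L_cm * pi * (cct$D_um / 2 * 1e-4 + grid)^2 +
       svt$n * svt$L_cm * pi * (svt$D_um / 2 * 1e-4)^2 +
       lvt$n * lvt$L_cm * pi * (lvt$D_um / 2 * 1e-4)^2)
  d_scan <- grid[which.min(abs(dens_g - 50000))]
  expect_equal(cht$d_cm, d_scan, tolerance = 1e-6 / max(d_scan, 1e-6))
})

test_that("compartment chains round-trip through CSV export", {
  net <- classify_segments(make_toy_network("y_split"))
  ch <- solve_tissue_width(build_pathway_chains(solve_network_flow(net)))
  td <- withr::local_tempdir()
  f <- file.path(td, "compartments.csv")
  write_compartments_csv(ch, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$n, ch$chains$n)
  expect_equal(back$L_cm, ch$chains$L_cm)
  expect_equal(back$dP_mmHg, ch$chains$dP_mmHg)
})
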