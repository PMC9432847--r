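test_that("Poiseuille flow reproduces the control-state capillary and scales as D^4", {
  ## capillary control state: 6 mmHg over 0.080 cm at 6 um, 9.05 cP
  expect_equal(poiseuille_flow(6, 6, 0.080, 9.05), 3.51e-9,
               tolerance = 0.005 / 3.51)
  expect_equal(poiseuille_flow(0, 6, 0.080, 9.05), 0)
  expect_equal(poiseuille_flow(6, 12, 0.080, 9.05),
               16 * poiseuille_flow(6, 6, 0.080, 9.05))
  expect_lt(poiseuille_flow(-6, 6, 0.08, 9.05), 0)
  expect_error(poiseuille_flow(6, 0, 0.08, 9.05), "positive")
})

test_that("in-vivo viscosity law reproduces the control-state values", {
  ## frozen from direct evaluation of the published law at H_D = 0.40
  expect_equal(viscosity_in_vivo(6, 0.40), 9.0517, tolerance = 1e-4)
  expect_equal(viscosity_in_vivo(29.5, 0.40), 2.2759, tolerance = 1e-4)
  expect_equal(viscosity_in_vivo(137.3, 0.40), 2.3926, tolerance = 1e-4)
  ## scales with plasma viscosity; H_D -> 0 leaves the wall-layer factor only
  expect_equal(viscosity_in_vivo(50, 0.3, 1.2),
               1.2 * viscosity_in_vivo(50, 0.3))
  ## at H_D = 0 only the wall-layer diameter factor remains
  d <- 40
  expect_equal(viscosity_in_vivo(d, 0), (d / (d - 1.1))^2)
  expect_error(viscosity_in_vivo(6, 1), "hematocrit")
})

test_that("phase separation conserves red-cell flux and matches the published law", {
  ## symmetric bifurcation splits hematocrit evenly
  expect_equal(phase_separation(0.4, 2e-6, 1e-6, 1e-6, 50, 36, 36),
               c(0.4, 0.4))
  ## one daughter takes all flow and all red cells
  h <- phase_separation(0.4, 2e-6, 2e-6, 0, 50, 36, 36)
  expect_equal(h[1] * 2e-6, 0.4 * 2e-6)
  ## asymmetric case against an independent direct evaluation of the
  ## logit-linear law
  hd <- 0.45; qp <- 3e-6; q1 <- 1e-6; q2 <- 2e-6
  dp <- 40; d1 <- 24; d2 <- 34
  x0 <- 0.964 * (1 - hd) / dp
  a <- -13.29 * ((d1 / d2)^2 - 1) / ((d1 / d2)^2 + 1) * (1 - hd) / dp
  b <- 1 + 6.98 * (1 - hd) / dp
  fqb <- q1 / qp
  logit <- a + b * log((fqb - x0) / (1 - fqb - x0))
  fqe <- plogis(logit)
  expect_equal(phase_separation(hd, qp, q1, q2, dp, d1, d2),
               c(fqe * hd * qp / q1, (1 - fqe) * hd * qp / q2),
               tolerance = 1e-12)
  ## red-cell flux conservation over random bifurcations
  set.seed(42)
  for (i in 1:50) {
    hd <- runif(1, 0.1, 0.6); qp <- 10^runif(1, -8, -5)
    fr <- runif(1, 0.02, 0.98); q1 <- fr * qp; q2 <- qp - q1
    dpar <- runif(1, 20, 140)
    dd <- sort(runif(2, 8, dpar), decreasing = TRUE)
    h <- phase_separation(hd, qp, q1, q2, dpar, dd[1], dd[2])
    expect_true(all(h >= 0 & h <= 1))
    expect_equal(q1 * h[1] + q2 * h[2], qp * hd, tolerance = 1e-10)
  }
  expect_error(phase_separation(0.4, 0, 0, 0, 50, 36, 36), "zero parent")
})

test_that("wall shear stress matches the capillary control state and Poiseuille", {
  ws <- wall_shear(3.51e-9, 6, 9.05)
  expect_equal(ws$tau, 15, tolerance = 0.01)
  expect_equal(ws$omega, ws$tau / 0.0905)
  expect_equal(wall_shear(0, 6, 9.05)$tau, 0)
  ## algebraic identity: poiseuille then shear recovers dP * D / (4 L)
  q <- poiseuille_flow(8, 30, 0.12, 2.3)
  expect_equal(wall_shear(q, 30, 2.3)$tau,
               8 * 1333.22 * 30e-4 / (4 * 0.12), tolerance = 1e-12)
})

test_that("network flow solver reduces to Poiseuille and respects symmetry", {
  single <- classify_segments(make_toy_network("single"))
  fl <- solve_network_flow(single)
  expect_true(fl$converged)
  mu <- fl$segments$mu_cP
  expect_equal(fl$segments$Q, poiseuille_flow(16, 36, 0.05, mu))
  expect_equal(fl$segments$dP_mmHg, 16)

  y <- classify_segments(make_toy_network("y_split"))
  fy <- solve_network_flow(y)
  qs <- fy$segments$Q[match(c("s1", "s2", "s3"), fy$segments$id)]
  expect_equal(qs[2], qs[3], tolerance = 1e-12)
  expect_equal(qs[1], qs[2] + qs[3], tolerance = 1e-12)
  ## pressures decrease along the flow direction
  expect_true(all(fy$segments$dP_mmHg > 0))
})

test_that("flow solver with uniform-hematocrit viscosity matches a dense oracle", {
  net <- classify_segments(make_toy_network("two_level"))
  ## force fixed viscosities by solving at zero hematocrit (no phase
  ## separation feedback, viscosity depends on diameter only)
  fl <- solve_network_flow(net, hd_in = 0)
  mu <- viscosity_in_vivo(net$segments$diameter_um, 0)
  oracle <- dense_flow_oracle(net, mu)
  expect_equal(unname(fl$segments$Q[match(net$segments$id, fl$segments$id)]),
               unname(oracle$Q), tolerance = 1e-12)
  expect_equal(unname(fl$node_pressures[names(oracle$node_pressures_mmHg)]),
               unname(oracle$node_pressures_mmHg), tolerance = 1e-12)

  big <- classify_segments(generate_synthetic_tree(bifurcation_levels = 3,
                                                   jitter = 0.25, seed = 3))
  fb <- solve_network_flow(big, hd_in = 0)
  ob <- dense_flow_oracle(big, viscosity_in_vivo(big$segments$diameter_um, 0))
  expect_equal(unname(fb$segments$Q[match(big$segments$id, fb$segments$id)]),
               unname(ob$Q), tolerance = 1e-12)
})

test_that("mass and red-cell flux are conserved on a heterogeneous tree", {
  net <- classify_segments(make_paper_scale_network(seed = 7,
                                                    bifurcation_levels = 4))
  fl <- solve_network_flow(net)
  expect_true(fl$converged)
  sg <- fl$segments
  ## junction mass balance
  for (nd in unique(sg$from)) {
    parent <- which(sg$to == nd)
    if (length(parent) == 0) next
    kids <- which(sg$from == nd)
    expect_lt(abs(sum(sg$Q[kids]) - sg$Q[parent]) / sg$Q[parent], 1e-10)
  }
  ## network-wide red-cell flux: inlet = sum over terminals
  inlet_seg <- sg$from == "n0"
  term_seg <- sg$class == "SA"
  rbc_in <- sum(sg$Q[inlet_seg] * sg$H_D[inlet_seg])
  rbc_out <- sum(sg$Q[term_seg] * sg$H_D[term_seg])
  expect_equal(rbc_out, rbc_in, tolerance = 1e-8)
  ## total inlet flow is monotone in the driving pressure
  q1 <- sum(solve_network_flow(net, 40, 24)$segments$Q[inlet_seg])
  q2 <- sum(solve_network_flow(net, 40, 20)$segments$Q[inlet_seg])
  q3 <- sum(solve_network_flow(net, 44, 20)$segments$Q[inlet_seg])
  expect_true(q1 < q2 && q2 < q3)
})
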