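test_that("local signal is inverse in PO2 with the documented limits", {
  expect_equal(local_signal(10, 10), 0.5)
  expect_equal(local_signal(0), 1)
  expect_equal(local_signal(90, 10), 0.1)
  expect_true(all(diff(local_signal(seq(0, 100, 1))) < 0))
  expect_error(local_signal(-5), "non-negative")
})

test_that("conduction matches the exponential closed forms", {
  ## no local generation, no downstream signal
  expect_equal(conduct_along_vessel(0, 0, 0.5)$S_meta, 0)
  ## uniform local signal, L = L0: S_meta = exp(-1)
  c1 <- conduct_along_vessel(1, 0, 1, l0 = 1)
  expect_equal(c1$S_meta, exp(-1), tolerance = 1e-9)
  expect_equal(c1$S_up, 1 - exp(-1), tolerance = 1e-9)
  ## closed form for general L: S_meta = L0 (1 - (L0/L)(1 - exp(-L/L0)))
  for (len in c(0.05, 0.3, 2)) {
    cc <- conduct_along_vessel(1, 0, len, l0 = 1)
    expect_equal(cc$S_meta, 1 - (1 / len) * (1 - exp(-len)), tolerance = 1e-9)
  }
  ## pure decay of a downstream signal; short vessels pass it through
  c2 <- conduct_along_vessel(0, 0.7, 0.3, l0 = 1)
  expect_equal(c2$S_meta, 0.7 * (1 / 0.3) * (1 - exp(-0.3)), tolerance = 1e-9)
  expect_equal(c2$S_up, 0.7 * exp(-0.3), tolerance = 1e-9)
  c3 <- conduct_along_vessel(0, 0.7, 1e-4, l0 = 1)
  expect_equal(c3$S_meta, 0.7, tolerance = 1e-4)
  expect_error(conduct_along_vessel(1, -0.1, 1), "non-negative")
})

test_that("conduction quadrature agrees with dense-trapezoid brute force to 1e-6", {
  set.seed(31)
  for (rep in 1:3) {
    len <- runif(1, 0.2, 1.2); l0 <- 1
    a <- runif(3, -0.2, 0.3)
    s_fun <- function(x) 0.4 + a[1] * sin(3 * x) + a[2] * cos(7 * x) +
      a[3] * x
    s_out <- runif(1, 0, 0.5)
    xs <- seq(0, len, length.out = 2001)
    res <- conduct_along_vessel(s_fun(xs), s_out, len, l0, x = xs)
    ## brute force on 1e5 points: S(x) = e^(-x/L0) [S_out + int g e^(y/L0) dy]
    xf <- seq(0, len, length.out = 100001)
    g <- s_fun(xf) * exp(xf / l0)
    h <- xf[2] - xf[1]
    cg <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * h))
    s_b <- exp(-xf / l0) * (s_out + cg)
    smeta_b <- sum((s_b[-1] + s_b[-length(s_b)]) / 2 * h) / len
    expect_equal(res$S_up, s_b[length(s_b)], tolerance = 1e-6)
    expect_equal(res$S_meta, smeta_b, tolerance = 1e-6)
  }
})

test_that("network propagation starts at the venules and respects symmetry", {
  net <- classify_segments(make_toy_network("y_split"))
  fl <- solve_network_flow(net)
  tg <- tissue_grid(net, spacing_cm = 0.02, margin_cm = 0.04,
                    thickness_cm = 0.02, nz = 2)
  ox <- oxygen_params(m0 = 2)
  gr <- solve_greens(fl, tg, ox, max_element_cm = 0.005)
  ch <- solve_tissue_width(build_pathway_chains(fl))
  prof <- retmicro:::march_all_chains(fl, gr, ch, ox)
  sig <- propagate_signal(fl, gr, ch, prof, ox)
  ## every vessel and compartment received a signal
  expect_equal(nrow(sig), 3 + 2 * 3)
  expect_true(all(is.finite(sig$S_meta)) && all(sig$S_meta >= 0))
  ## mirror-image daughters carry identical signals
  s2 <- sig[sig$id == "s2", ]; s3 <- sig[sig$id == "s3", ]
  expect_equal(s2$S_meta, s3$S_meta, tolerance = 1e-10)
  expect_equal(s2$S_up, s3$S_up, tolerance = 1e-10)
  ## additive junction rule: parent S_out is the sum of daughter S_up
  s1 <- sig[sig$id == "s1", ]
  expect_equal(s1$S_out, s2$S_up + s3$S_up, tolerance = 1e-12)
  ## flow-weighted alternative: equal daughters give the mean instead
  sig_fw <- propagate_signal(fl, gr, ch, prof, ox,
                             junction_rule = "flow_weighted")
  s1fw <- sig_fw[sig_fw$id == "s1", ]
  expect_equal(s1fw$S_out, s2$S_up, tolerance = 1e-10)
  ## downstream boundary: the large venule starts from zero signal
  lv <- sig[sig$class == "LV", ]
  expect_true(all(lv$S_out == 0))
})

test_that("well-oxygenated networks generate almost no signal", {
  net <- classify_segments(make_toy_network("y_split"))
  fl <- solve_network_flow(net)
  tg <- tissue_grid(net, spacing_cm = 0.02, margin_cm = 0.04,
                    thickness_cm = 0.02, nz = 2)
  ox <- oxygen_params(m0 = 0)
  gr <- solve_greens(fl, tg, ox, max_element_cm = 0.005)
  ch <- solve_tissue_width(build_pathway_chains(fl))
  prof <- retmicro:::march_all_chains(fl, gr, ch, ox)
  sig <- propagate_signal(fl, gr, ch, prof, ox)
  ## S_loc = P0/(P0 + 84.4) ~ 0.106 everywhere; with short vessels the
  ## conducted signal stays of that order, far below the anoxic limit 1
  expect_true(all(sig$S_meta < 0.4))
  ## and the signal vanishes when PO2 is pushed very high via P0 -> 0
  ox0 <- oxygen_params(m0 = 0, p0 = 1e-9)
  gr0 <- solve_greens(fl, tg, ox0, max_element_cm = 0.005)
  prof0 <- retmicro:::march_all_chains(fl, gr0, ch, ox0)
  sig0 <- propagate_signal(fl, gr0, ch, prof0, ox0)
  expect_true(all(sig0$S_meta < 1e-6))
})
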