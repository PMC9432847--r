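## Independent oracles used across the suite. These are deliberately written
## against the continuous equations, not against the package's solvers.

## Dense linear-algebra oracle for network flow at prescribed per-segment
## viscosities: assembles the full nodal conservation system (Dirichlet rows
## for inlet/terminals) and solves it with base::solve.
dense_flow_oracle <- function(net, mu_cP, p_in = 40, p_out = 24) {
  nd <- net$nodes; sg <- net$segments
  nid <- stats::setNames(seq_len(nrow(nd)), nd$id)
  g <- pi * (sg$diameter_um * 1e-4)^4 / (128 * mu_cP * 1e-2 * sg$length_cm)
  a_mat <- matrix(0, nrow(nd), nrow(nd))
  b <- numeric(nrow(nd))
  for (s in seq_len(nrow(sg))) {
    i <- nid[[sg$from[s]]]; j <- nid[[sg$to[s]]]
    a_mat[i, i] <- a_mat[i, i] + g[s]; a_mat[j, j] <- a_mat[j, j] + g[s]
    a_mat[i, j] <- a_mat[i, j] - g[s]; a_mat[j, i] <- a_mat[j, i] - g[s]
  }
  for (i in seq_len(nrow(nd))) {
    if (nd$kind[i] != "junction") {
      a_mat[i, ] <- 0; a_mat[i, i] <- 1
      b[i] <- (if (nd$kind[i] == "inlet") p_in else p_out) * 1333.22
    }
  }
  press <- solve(a_mat, b)
  q <- g * (press[nid[sg$from]] - press[nid[sg$to]])
  list(node_pressures_mmHg = stats::setNames(press / 1333.22, nd$id), Q = q)
}

## Axisymmetric finite-difference oracle for steady oxygen diffusion around a
## single straight vessel on the z axis:
##   K [ (1/r) d/dr (r dP/dr) + d2P/dz2 ] = M(P) * (r <= r_sink)
## Dirichlet P = Pb(z) at the vessel wall, no-flux at r_far and both z ends,
## coupled to axial marching of the blood PO2 through the wall flux.
fd_single_vessel_oracle <- function(r_v, r_sink, r_far, length_cm, q_flow, hd,
                                    params, nr = 48, nz = 36, outer_iter = 40,
                                    tol = 1e-4) {
  k_diff <- params$d_diff_alpha
  m0c <- params$m0 / 6000
  r <- seq(r_v, r_far, length.out = nr)
  z <- seq(0, length_cm, length.out = nz)
  hr <- r[2] - r[1]; hz <- z[2] - z[1]
  idx <- function(i, j) (j - 1) * nr + i
  n <- nr * nz
  in_sink <- r <= r_sink + 1e-15
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(a, b, v) { ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v) }
  for (j in seq_len(nz)) for (i in seq_len(nr)) {
    k <- idx(i, j)
    if (i == 1) { push(k, k, 1); next }
    rm <- r[i] - hr / 2; rp <- r[i] + hr / 2
    cw <- k_diff * rm / (hr^2 * r[i]); ce <- k_diff * rp / (hr^2 * r[i])
    cz <- k_diff / hz^2
    if (i < nr) {
      push(k, idx(i + 1, j), ce); push(k, idx(i - 1, j), cw)
      push(k, k, -(ce + cw))
    } else { push(k, idx(i - 1, j), cw + ce); push(k, k, -(ce + cw)) }
    if (j > 1) push(k, idx(i, j - 1), cz) else push(k, idx(i, j + 1), cz)
    if (j < nz) push(k, idx(i, j + 1), cz) else push(k, idx(i, j - 1), cz)
    push(k, k, -2 * cz)
  }
  base_m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  content <- function(p) hd * params$c0 * hill_saturation(p, params$p50, params$n_hill) +
    params$alpha_b * p
  invert <- function(cv, lo = 0, hi = 500) {
    stats::uniroot(function(p) content(p) - cv, c(lo, hi), tol = 1e-12)$root
  }
  pb <- rep(params$inflow_po2, nz)
  p <- rep(params$inflow_po2, n)
  delta <- Inf
  for (outer in seq_len(outer_iter)) {
    for (inner in 1:60) {
      dcoef <- ifelse(rep(in_sink, nz), m0c / (params$p0 + pmax(p, 0)), 0)
      dcoef[idx(1, seq_len(nz))] <- 0
      mat <- base_m - Matrix::Diagonal(n, dcoef)
      rhs <- numeric(n)
      rhs[idx(1, seq_len(nz))] <- pb
      p_new <- as.numeric(Matrix::solve(mat, rhs))
      if (max(abs(p_new - p)) < 1e-8) { p <- p_new; break }
      p <- p_new
    }
    pm <- matrix(p, nr, nz)
    dpdr <- (-3 * pm[1, ] + 4 * pm[2, ] - pm[3, ]) / (2 * hr)
    qz <- -k_diff * 2 * pi * r_v * dpdr
    cv <- content(pb[1])
    pb_new <- numeric(nz); pb_new[1] <- pb[1]
    for (j in 2:nz) {
      cv <- cv - (qz[j - 1] + qz[j]) / 2 * hz / q_flow
      pb_new[j] <- invert(cv)
    }
    delta <- max(abs(pb_new - pb))
    pb <- (pb + pb_new) / 2
    if (delta < tol) break
  }
  list(r = r, z = z, p = matrix(p, nr, nz), pb = pb, q = qz, delta = delta)
}

## Bilinear interpolation of an FD oracle field at (r, z) query points.
fd_interp <- function(oracle, rq, zq) {
  pi_ <- findInterval(rq, oracle$r, all.inside = TRUE)
  pj <- findInterval(zq, oracle$z, all.inside = TRUE)
  tr <- (rq - oracle$r[pi_]) / diff(oracle$r)[1]
  tz <- (zq - oracle$z[pj]) / diff(oracle$z)[1]
  oracle$p[cbind(pi_, pj)] * (1 - tr) * (1 - tz) +
    oracle$p[cbind(pi_ + 1, pj)] * tr * (1 - tz) +
    oracle$p[cbind(pi_, pj + 1)] * (1 - tr) * tz +
    oracle$p[cbind(pi_ + 1, pj + 1)] * tr * tz
}

## Single-vessel oracle scenario shared by the Green's-function checks:
## a 36 um vessel, 0.08 cm long, with a 120 um Michaelis-Menten sink annulus.
single_vessel_scenario <- function(m0 = 1) {
  nd <- data.frame(id = c("n0", "n1"), x = 0, y = 0, z = c(0, 0.08),
                   kind = c("inlet", "terminal"), stringsAsFactors = FALSE)
  sg <- data.frame(id = "s1", from = "n0", to = "n1", diameter_um = 36,
                   length_cm = 0.08, stringsAsFactors = FALSE)
  net <- classify_segments(vascular_network(nd, sg))
  flow <- solve_network_flow(net)
  r_v <- 18e-4; r_sink <- 0.012
  nr_s <- 5; nz_s <- 10; nth <- 8
  redges <- seq(r_v, r_sink, length.out = nr_s + 1)
  zedges <- seq(0, 0.08, length.out = nz_s + 1)
  rc <- (redges[-1] + redges[-(nr_s + 1)]) / 2
  zc <- (zedges[-1] + zedges[-(nz_s + 1)]) / 2
  grid <- expand.grid(ir = seq_len(nr_s), jz = seq_len(nz_s),
                      th = (seq_len(nth) - 0.5) / nth * 2 * pi)
  vol_ring <- pi * (redges[-1]^2 - redges[-(nr_s + 1)]^2) * (0.08 / nz_s)
  tissue <- data.frame(x = rc[grid$ir] * cos(grid$th),
                       y = rc[grid$ir] * sin(grid$th),
                       z = zc[grid$jz],
                       volume = vol_ring[grid$ir] / nth)
  list(net = net, flow = flow, tissue = tissue, grid = grid, rc = rc, zc = zc,
       r_v = r_v, r_sink = r_sink, r_far = 0.048,
       params = oxygen_params(m0 = m0))
}
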