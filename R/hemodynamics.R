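#' Poiseuille flow through a cylindrical vessel
#'
#' `Q = pi * dP * D^4 / (128 * mu * L)`, evaluated in CGS units internally.
#'
#' @param delta_p_mmHg pressure drop along the vessel, mmHg.
#' @param diameter_um vessel diameter, um.
#' @param length_cm vessel length, cm.
#' @param viscosity_cP apparent blood viscosity, cP.
#' @return volumetric flow rate, cm^3/s (sign follows the sign of the drop).
#' @export
poiseuille_flow <- function(delta_p_mmHg, diameter_um, length_cm, viscosity_cP) {
  if (any(diameter_um <= 0) || any(length_cm <= 0) || any(viscosity_cP <= 0))
    stop_invalid("diameter, length and viscosity must be positive")
  dp <- mmHg_to_cgs(delta_p_mmHg)
  d <- um_to_cm(diameter_um)
  mu <- cP_to_poise(viscosity_cP)
  pi * dp * d^4 / (128 * mu * length_cm)
}

#' In-vivo apparent blood viscosity (Pries diameter-hematocrit law)
#'
#' Empirical in-vivo viscosity law capturing the Fahraeus-Lindqvist effect:
#' relative apparent viscosity as a function of vessel diameter and discharge
#' hematocrit, multiplied by the plasma viscosity. The relative viscosity is
#' minimal near capillary diameters ~ in the 5-10 um range the endothelial
#' surface layer raises it steeply again, which is why a 6 um capillary at
#' `H_D` = 0.40 carries an apparent viscosity of ~9 cP.
#'
#' @param diameter_um vessel diameter, um.
#' @param hematocrit discharge hematocrit, fraction in `[0, 1)`.
#' @param plasma_cP plasma viscosity, cP (default 1).
#' @return apparent viscosity, cP.
#' @export
viscosity_in_vivo <- function(diameter_um, hematocrit, plasma_cP = 1) {
  if (any(diameter_um <= 0)) stop_invalid("diameter must be positive")
  if (any(hematocrit < 0) || any(hematocrit >= 1))
    stop_invalid("hematocrit must be in [0, 1)")
  d <- diameter_um
  mu45 <- 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  wall <- (d / (d - 1.1))^2
  rel <- (1 + (mu45 - 1) * ((1 - hematocrit)^cc - 1) /
            ((1 - 0.45)^cc - 1) * wall) * wall
  rel * plasma_cP
}

#' Red-cell phase separation at a bifurcation
#'
#' Partitions the parent red-cell flux between two daughter branches with the
#' empirical in-vivo bifurcation law (logit-linear in the fractional blood
#' flow, with diameter-ratio bias and plasma skimming threshold), then recovers
#' the daughter discharge hematocrits from flux conservation
#' `Q_p H_p = Q_1 H_1 + Q_2 H_2`. Hematocrits exceeding 1 are clamped with the
#' excess red-cell flux diverted to the other daughter.
#'
#' @param hd_parent parent discharge hematocrit.
#' @param q_parent,q_d1,q_d2 blood flows, cm^3/s (`q_parent = q_d1 + q_d2`).
#' @param d_parent_um,d1_um,d2_um diameters, um.
#' @return numeric vector `c(hd_d1, hd_d2)`.
#' @export
phase_separation <- function(hd_parent, q_parent, q_d1, q_d2,
                             d_parent_um, d1_um, d2_um) {
  if (q_parent <= 0) stop_invalid("phase separation undefined for zero parent flow")
  if (abs(q_d1 + q_d2 - q_parent) > 1e-8 * q_parent)
    stop_invalid("daughter flows must sum to the parent flow")
  if (q_d1 <= 0) return(c(0, hd_parent * q_parent / q_d2))
  if (q_d2 <= 0) return(c(hd_parent * q_parent / q_d1, 0))
  fqb <- q_d1 / q_parent
  x0 <- 0.964 * (1 - hd_parent) / d_parent_um
  a <- -13.29 * ((d1_um / d2_um)^2 - 1) / ((d1_um / d2_um)^2 + 1) *
    (1 - hd_parent) / d_parent_um
  b <- 1 + 6.98 * (1 - hd_parent) / d_parent_um
  fqe <- if (fqb <= x0) 0 else if (fqb >= 1 - x0) 1 else {
    z <- a + b * log((fqb - x0) / (1 - fqb - x0))
    1 / (1 + exp(-z))
  }
  rbc <- hd_parent * q_parent
  h1 <- fqe * rbc / q_d1
  h2 <- (1 - fqe) * rbc / q_d2
  if (h1 > 1) { h1 <- 1; h2 <- (rbc - q_d1) / q_d2 }
  if (h2 > 1) { h2 <- 1; h1 <- (rbc - q_d2) / q_d1 }
  c(max(h1, 0), max(h2, 0))
}

#' Wall shear stress and shear rate
#'
#' `tau = 32 mu Q / (pi D^3)` (dyn/cm^2) and `omega = tau / mu` (1/s).
#'
#' @param q flow, cm^3/s.
#' @param diameter_um diameter, um.
#' @param viscosity_cP apparent viscosity, cP.
#' @return list with `tau` (dyn/cm^2) and `omega` (1/s).
#' @export
wall_shear <- function(q, diameter_um, viscosity_cP) {
  if (any(diameter_um <= 0)) stop_invalid("diameter must be positive")
  d <- um_to_cm(diameter_um)
  mu <- cP_to_poise(viscosity_cP)
  tau <- 32 * mu * q / (pi * d^3)
  list(tau = tau, omega = tau / mu)
}

#' Solve pressure-driven flow, hematocrit and viscosity on an arteriolar tree
#'
#' Iterates between (i) a linear nodal-pressure solve with Dirichlet conditions
#' at the inlet and at every terminal node, (ii) a single downstream
#' phase-separation pass propagating discharge hematocrit from the inlet, and
#' (iii) an under-relaxed update of the diameter- and hematocrit-dependent
#' apparent viscosity, until the maximum relative flow change falls below
#' `tol`. At junctions with more than two daughters (the inlet fan-out) the
#' daughters inherit the parent hematocrit, which conserves red-cell flux.
#'
#' @param net a valid [vascular_network()].
#' @param p_in inlet pressure, mmHg (default taken from the network).
#' @param p_out terminal pressure, mmHg (default taken from the network).
#' @param hd_in inlet discharge hematocrit (default 0.40).
#' @param plasma_cP plasma viscosity, cP.
#' @param tol relative flow-change convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @param relax under-relaxation factor on viscosity updates.
#' @return a `flow_solution`: list with `node_pressures` (named, mmHg),
#'   `segments` (id, from, to, diameter_um, length_cm, Q, dP_mmHg, H_D, mu_cP,
#'   tau, omega), `converged`, `iterations`, and the oriented network `net`.
#' @export
solve_network_flow <- function(net, p_in = net$inlet_pressure,
                               p_out = net$terminal_pressure, hd_in = 0.40,
                               plasma_cP = 1, tol = 1e-6, max_iter = 100,
                               relax = 0.5) {
  if (tol <= 0) stop_invalid("tol must be positive")
  viol <- validate_network(net)
  if (length(viol)) stop_invalid("invalid network: %s", viol[1])
  net <- orient_segments(net)
  sg <- net$segments
  nd <- net$nodes
  ns <- nrow(sg)
  idx <- node_index(net)
  fixed <- nd$kind != "junction"
  p_fixed <- ifelse(nd$kind == "inlet", p_in, p_out)
  from_i <- idx[sg$from]; to_i <- idx[sg$to]

  mu <- viscosity_in_vivo(sg$diameter_um, hd_in, plasma_cP)
  hd <- rep(hd_in, ns)
  q_old <- rep(NA_real_, ns)
  children <- split(seq_len(ns), sg$from)   # segment indices by tail node
  parent_seg <- stats::setNames(seq_len(ns), sg$to)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    d_cm <- um_to_cm(sg$diameter_um)
    g <- pi * d_cm^4 / (128 * cP_to_poise(mu) * sg$length_cm)  # cm^3/s per dyn/cm^2
    press <- rep(NA_real_, nrow(nd))
    press[fixed] <- mmHg_to_cgs(p_fixed[fixed])
    free <- which(!fixed)
    if (length(free)) {
      pos <- integer(nrow(nd)); pos[free] <- seq_along(free)
      ii <- integer(0); jj <- integer(0); xx <- numeric(0)
      rhs <- numeric(length(free))
      for (s in seq_len(ns)) {
        a <- from_i[s]; b <- to_i[s]
        if (!fixed[a]) { ii <- c(ii, pos[a]); jj <- c(jj, pos[a]); xx <- c(xx, g[s]) }
        if (!fixed[b]) { ii <- c(ii, pos[b]); jj <- c(jj, pos[b]); xx <- c(xx, g[s]) }
        if (!fixed[a] && !fixed[b]) {
          ii <- c(ii, pos[a], pos[b]); jj <- c(jj, pos[b], pos[a])
          xx <- c(xx, -g[s], -g[s])
        } else if (!fixed[a]) {
          rhs[pos[a]] <- rhs[pos[a]] + g[s] * press[b]
        } else if (!fixed[b]) {
          rhs[pos[b]] <- rhs[pos[b]] + g[s] * press[a]
        }
      }
      lap <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                  dims = c(length(free), length(free)))
      press[free] <- as.numeric(Matrix::solve(lap, rhs))
    }
    q <- g * (press[from_i] - press[to_i])

    ## hematocrit: single downstream pass in topological (storage) order
    for (s in seq_len(ns)) {
      tail_nd <- sg$from[s]
      if (tail_nd == inlet_id(net)) { hd[s] <- hd_in; next }
      p_seg <- parent_seg[[tail_nd]]
      sibs <- children[[tail_nd]]
      if (length(sibs) == 1) {
        hd[s] <- hd[p_seg]
      } else if (length(sibs) == 2) {
        if (s == sibs[1]) {
          hh <- phase_separation(hd[p_seg], q[p_seg], q[sibs[1]], q[sibs[2]],
                                 sg$diameter_um[p_seg],
                                 sg$diameter_um[sibs[1]], sg$diameter_um[sibs[2]])
          hd[sibs[1]] <- hh[1]; hd[sibs[2]] <- hh[2]
        }
      } else {
        hd[s] <- hd[p_seg]
      }
    }
    mu_new <- viscosity_in_vivo(sg$diameter_um, pmin(hd, 0.99), plasma_cP)
    mu <- relax * mu_new + (1 - relax) * mu

    if (!anyNA(q_old)) {
      rel <- max(abs(q - q_old) / pmax(abs(q_old), 1e-30))
      if (rel < tol) { converged <- TRUE; q_old <- q; break }
    }
    q_old <- q
  }
  q <- q_old

  ## orient any counter-flowing segment downstream once
  neg <- which(q < 0)
  if (length(neg)) {
    tmp <- sg$from[neg]; sg$from[neg] <- sg$to[neg]; sg$to[neg] <- tmp
    q[neg] <- -q[neg]
    net$segments <- sg
    from_i <- idx[sg$from]; to_i <- idx[sg$to]
  }

  shear <- wall_shear(q, sg$diameter_um, mu)
  out_sg <- data.frame(id = sg$id, from = sg$from, to = sg$to,
                       diameter_um = sg$diameter_um, length_cm = sg$length_cm,
                       class = sg$class,
                       Q = q, dP_mmHg = cgs_to_mmHg(press[from_i] - press[to_i]),
                       H_D = hd, mu_cP = mu, tau = shear$tau,
                       omega = shear$omega, stringsAsFactors = FALSE)
  structure(list(node_pressures = stats::setNames(cgs_to_mmHg(press), nd$id),
                 segments = out_sg, converged = converged, iterations = iter,
                 net = net),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d segments, %s after %d iterations\n",
              nrow(x$segments),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  inlet flow %.3e cm^3/s; hematocrit %.3f-%.3f\n",
              total_inlet_flow(x), min(x$segments$H_D), max(x$segments$H_D)))
  invisible(x)
}

## Total flow leaving the inlet node.
total_inlet_flow <- function(flow) {
  sum(flow$segments$Q[flow$segments$from == inlet_id(flow$net)])
}

#' Export a flow solution as CSV
#' @param flow a `flow_solution`.
#' @param file output path.
#' @export
write_flow_csv <- function(flow, file) {
  utils::write.csv(flow$segments, file, row.names = FALSE)
  invisible(file)
}
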