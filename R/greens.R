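#' Regular tissue sampling grid for the Green's function solver
#'
#' Lays out tissue sample points on a regular grid covering the bounding box of
#' the network (plus a margin) over a thin slab centred on the vessel plane.
#' Each point represents an equal tissue volume `spacing^2 * thickness / nz`.
#' The slab z-faces are recorded so the solver can apply no-flux mirror images
#' across them.
#'
#' @param net a [vascular_network()].
#' @param spacing_cm in-plane grid spacing, cm (default 40 um).
#' @param margin_cm margin added around the vessel bounding box, cm.
#' @param thickness_cm slab thickness, cm.
#' @param nz number of z layers.
#' @param max_vessel_dist_cm when given, keep only points within this in-plane
#'   distance of some vessel segment, restricting the modeled tissue to the
#'   perivascular layer the arterioles serve rather than the full bounding
#'   rectangle.
#' @param min_vessel_dist_cm drop points closer than this to a vessel axis
#'   (default half the grid spacing): the grid cannot resolve the steep
#'   near-wall gradient, and sample points effectively inside or hugging a
#'   vessel read spuriously high from the singular part of the kernel.
#' @return data.frame `x, y, z, volume` with attribute `slab_z = c(lo, hi)`.
#' @export
tissue_grid <- function(net, spacing_cm = 0.004, margin_cm = 0.05,
                        thickness_cm = 0.02, nz = 2,
                        max_vessel_dist_cm = NULL,
                        min_vessel_dist_cm = spacing_cm / 2) {
  if (spacing_cm <= 0 || thickness_cm <= 0 || nz < 1)
    stop_invalid("grid parameters must be positive")
  xr <- range(net$nodes$x) + c(-1, 1) * margin_cm
  yr <- range(net$nodes$y) + c(-1, 1) * margin_cm
  z0 <- mean(range(net$nodes$z))
  xs <- seq(xr[1], xr[2], by = spacing_cm)
  ys <- seq(yr[1], yr[2], by = spacing_cm)
  zs <- z0 + ((seq_len(nz)) - (nz + 1) / 2) / nz * thickness_cm
  pts <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  pts$volume <- spacing_cm^2 * thickness_cm / nz
  if (!is.null(max_vessel_dist_cm) ||
      (!is.null(min_vessel_dist_cm) && min_vessel_dist_cm > 0)) {
    dmin <- rep(Inf, nrow(pts))
    idx <- node_index(net)
    nd <- net$nodes
    for (s in seq_len(nrow(net$segments))) {
      a <- idx[net$segments$from[s]]; b <- idx[net$segments$to[s]]
      ax <- nd$x[a]; ay <- nd$y[a]
      vx <- nd$x[b] - ax; vy <- nd$y[b] - ay
      len2 <- vx^2 + vy^2
      t_par <- if (len2 > 0)
        pmin(pmax(((pts$x - ax) * vx + (pts$y - ay) * vy) / len2, 0), 1)
      else 0
      dmin <- pmin(dmin, sqrt((pts$x - (ax + t_par * vx))^2 +
                                (pts$y - (ay + t_par * vy))^2))
    }
    keep <- rep(TRUE, nrow(pts))
    if (!is.null(max_vessel_dist_cm)) keep <- keep & dmin <= max_vessel_dist_cm
    if (!is.null(min_vessel_dist_cm)) keep <- keep & dmin >= min_vessel_dist_cm
    pts <- pts[keep, , drop = FALSE]
    rownames(pts) <- NULL
  }
  attr(pts, "slab_z") <- z0 + c(-0.5, 0.5) * thickness_cm
  pts
}

## Subdivide every segment into axial elements no longer than max_element_cm.
## Geometry is taken from the straight chord between the segment's nodes;
## the hydraulic length (length_cm) sets the per-element axial metric.
discretize_vessels <- function(flow, max_element_cm = 0.0025) {
  sg <- flow$segments
  idx <- node_index(flow$net)
  nd <- flow$net$nodes
  out <- vector("list", nrow(sg))
  for (s in seq_len(nrow(sg))) {
    n_el <- max(1L, ceiling(sg$length_cm[s] / max_element_cm))
    fr <- (seq_len(n_el) - 0.5) / n_el
    a <- idx[sg$from[s]]; b <- idx[sg$to[s]]
    out[[s]] <- data.frame(
      seg = s, seg_id = sg$id[s],
      x = nd$x[a] + fr * (nd$x[b] - nd$x[a]),
      y = nd$y[a] + fr * (nd$y[b] - nd$y[a]),
      z = nd$z[a] + fr * (nd$z[b] - nd$z[a]),
      length_cm = sg$length_cm[s] / n_el,
      radius_cm = um_to_cm(sg$diameter_um[s]) / 2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Direct free-space kernel 1/(4 pi K r) between two point sets, with a
## distance floor for near/coincident pairs (floor_cm may be scalar or a
## matrix conformable with the result).
kernel_direct <- function(p1, p2, k_diff, floor_cm) {
  d <- sqrt(outer(p1$x, p2$x, "-")^2 + outer(p1$y, p2$y, "-")^2 +
              outer(p1$z, p2$z, "-")^2)
  1 / (4 * pi * k_diff * pmax(d, floor_cm))
}

## Mirror-image kernel contribution across the slab z-faces (one reflection
## per face), approximating no-flux slab boundaries. Never singular for
## points strictly inside the slab.
kernel_images <- function(p1, p2, k_diff, slab_z, n_images = 1) {
  if (is.null(slab_z) || n_images < 1) return(0)
  d2 <- outer(p1$x, p2$x, "-")^2 + outer(p1$y, p2$y, "-")^2
  gmat <- 0
  for (zf in slab_z)
    gmat <- gmat + 1 / sqrt(d2 + outer(p1$z, 2 * zf - p2$z, "-")^2)
  gmat / (4 * pi * k_diff)
}

## Potential of a uniform finite line source of length l, averaged along a
## collinear target element of the same length whose centre is a distance d
## away, evaluated at radial offset r (the vessel wall). d = 0 gives the
## element self term. Vectorized over d.
line_line_coeff <- function(d, l, r, k_diff) {
  f1 <- function(x) asinh(x / r)
  f2 <- function(x) sqrt(r^2 + x^2)
  i_int <- (l - d) * (f1(d) - f1(d - l)) + f2(d) - f2(d - l) +
    (l + d) * (f1(d + l) - f1(d)) - f2(d + l) + f2(d)
  i_int / (4 * pi * k_diff * l^2)
}

## Precompute the geometric coupling of a Green's function solve so demand
## sweeps can reuse it (the kernels depend on geometry only).
greens_system <- function(flow, tissue, params, max_element_cm = 0.0025,
                          n_images = 1, max_vessel_elements = 4000) {
  el <- discretize_vessels(flow, max_element_cm)
  nv <- nrow(el); nt <- nrow(tissue)
  if (nv > max_vessel_elements)
    stop_invalid(paste("vessel discretization yields %d elements (> %d);",
                       "increase max_element_cm or raise max_vessel_elements"),
                 nv, max_vessel_elements)
  k_diff <- params$d_diff_alpha
  slab_z <- attr(tissue, "slab_z")
  ## vessel-vessel: point kernel floored at the larger radius of the pair,
  ## replaced within each segment (collinear elements, where the point kernel
  ## misrepresents the near coupling and makes the first-kind system ring) by
  ## the exact uniform-line-source coefficient averaged along the target
  ## element at the vessel-wall radius; the same expression at distance 0 is
  ## the self term
  floor_v <- outer(el$radius_cm, el$radius_cm, pmax)
  gvv <- kernel_direct(el, el, k_diff, floor_v)
  for (s in unique(el$seg)) {
    ix <- which(el$seg == s)
    l <- el$length_cm[ix[1]]
    rw <- el$radius_cm[ix[1]]
    dmat <- abs(outer(seq_along(ix), seq_along(ix), "-")) * l
    gvv[ix, ix] <- line_line_coeff(dmat, l, rw, k_diff)
  }
  gvv <- gvv + kernel_images(el, el, k_diff, slab_z, n_images)
  ## vessel-tissue: each tissue point stands for a finite cell, so inside the
  ## cell's equivalent sphere the potential follows the smooth uniform-sphere
  ## profile (3R^2 - d^2)/(2R^3) instead of the singular point kernel -- a
  ## point kernel there imprints the tissue grid granularity onto the vessel
  ## wall condition and makes the source solve ring
  ## (zero-volume points act as pure field probes: floor keeps self terms finite)
  r_eq <- pmax((3 * tissue$volume / (4 * pi))^(1 / 3), 1e-6)
  dvs <- sqrt(outer(el$x, tissue$x, "-")^2 + outer(el$y, tissue$y, "-")^2 +
                outer(el$z, tissue$z, "-")^2)
  r_cell <- matrix(r_eq, nv, nt, byrow = TRUE)
  gvs <- 1 / (4 * pi * k_diff * dvs)
  inside <- dvs < r_cell
  gvs[inside] <- (3 * r_cell[inside]^2 - dvs[inside]^2) /
    (2 * r_cell[inside]^3) / (4 * pi * k_diff)
  gvs <- gvs + kernel_images(el, tissue, k_diff, slab_z, n_images)
  ## tissue-tissue: same cell-averaged near field, volume-averaged self term
  dtt <- sqrt(outer(tissue$x, tissue$x, "-")^2 +
                outer(tissue$y, tissue$y, "-")^2 +
                outer(tissue$z, tissue$z, "-")^2)
  r_cell_t <- matrix(r_eq, nt, nt, byrow = TRUE)
  gtt <- 1 / (4 * pi * k_diff * pmax(dtt, 1e-300))
  inside <- dtt < r_cell_t
  gtt[inside] <- (3 * r_cell_t[inside]^2 - dtt[inside]^2) /
    (2 * r_cell_t[inside]^3) / (4 * pi * k_diff)
  diag(gtt) <- 1.2 / (4 * pi * k_diff * r_eq)
  gtt <- gtt + kernel_images(tissue, tissue, k_diff, slab_z, n_images)
  ## bordered system enforcing global balance; the far-field constant column
  ## is scaled to the kernel magnitude to keep the factorization well posed
  beta <- mean(diag(gvv))
  big <- rbind(cbind(gvv, beta), c(rep(beta, nv), 0))
  list(el = el, tissue = tissue, gvs = gvs, gtt = gtt,
       qr_big = qr(big), beta = beta, nv = nv, nt = nt)
}

## Vectorized inversion of blood oxygen content -> PO2 (safeguarded Newton).
invert_content_vec <- function(content, hd, params, include_dissolved = TRUE) {
  p <- rep(50, length(content))
  lo <- rep(0, length(content)); hi <- rep(500, length(content))
  ab <- if (include_dissolved) params$alpha_b else 0
  for (i in 1:80) {
    s <- hill_saturation(p, params$p50, params$n_hill)
    g <- hd * params$c0 * s + ab * p - content
    hi[g > 0] <- pmin(hi[g > 0], p[g > 0])
    lo[g < 0] <- pmax(lo[g < 0], p[g < 0])
    dg <- hd * params$c0 * params$n_hill * s * (1 - s) / pmax(p, 1e-12) + ab
    p_new <- p - g / dg
    bad <- !is.finite(p_new) | p_new <= lo | p_new >= hi
    p_new[bad] <- (lo[bad] + hi[bad]) / 2
    if (max(abs(p_new - p)) < 1e-11 * (1 + max(p))) { p <- p_new; break }
    p <- p_new
  }
  p[content <= 0] <- 0
  p
}

#' Solve coupled intravascular-tissue oxygen transport (Green's function method)
#'
#' Vessel segments are subdivided into finite source elements and tissue sample
#' points act as Michaelis-Menten oxygen sinks. The oxygen field is the
#' superposition of free-space kernels `G = 1/(4 pi D_diff alpha |x - x'|)`
#' over all sources and sinks plus a constant, with optional mirror images
#' across the tissue slab faces. Each fixed-point iteration (i) evaluates sink
#' strengths at the current tissue PO2, (ii) solves the linear system that
#' makes the superposed field match the blood PO2 at every element surface
#' while enforcing global balance (total vessel efflux = total consumption),
#' (iii) re-marches blood PO2 along the flow directions with the new efflux
#' (`df/ds = -q`, content inverted through the Hill curve), and (iv) updates
#' the tissue field, clamped at zero. Iteration stops when the largest PO2
#' change falls below `tol` mmHg.
#'
#' @param flow a converged `flow_solution`.
#' @param tissue tissue sample points from [tissue_grid()] (or any data.frame
#'   with `x, y, z, volume` and optionally a `slab_z` attribute).
#' @param params an [oxygen_params()].
#' @param max_element_cm maximum vessel element length, cm.
#' @param tol fixed-point tolerance on PO2, mmHg.
#' @param max_iter maximum fixed-point iterations.
#' @param relax under-relaxation factor for source and tissue updates.
#' @param n_images mirror-image reflections per slab face (0 disables).
#' @param system optional precomputed geometric system (internal reuse across
#'   demand sweeps).
#' @return a `greens_solution`: tissue field (`po2`, `sink`), per-element blood
#'   PO2 profile, per-segment inflow/outflow PO2, node PO2, far-field constant,
#'   convergence and oxygen-balance diagnostics.
#' @export
solve_greens <- function(flow, tissue, params = oxygen_params(),
                         max_element_cm = 0.0025, tol = 1e-3, max_iter = 200,
                         relax = 0.5, n_images = 1, system = NULL) {
  if (!isTRUE(flow$converged))
    warning("flow solution is not converged")
  if (is.null(system))
    system <- greens_system(flow, tissue, params, max_element_cm, n_images)
  el <- system$el; nv <- system$nv; nt <- system$nt
  sg <- flow$segments
  el_of_seg <- split(seq_len(nv), el$seg)
  m0_cgs <- demand_to_cgs(params$m0)
  inlet <- inlet_id(flow$net)

  march <- function(qe) {
    pb_node <- stats::setNames(rep(NA_real_, nrow(flow$net$nodes)),
                               flow$net$nodes$id)
    pb_node[inlet] <- params$inflow_po2
    c_mid <- numeric(nv)
    for (s in seq_len(nrow(sg))) {
      p_in <- pb_node[[sg$from[s]]]
      c_in <- oxygen_content(p_in, sg$H_D[s], params)
      els <- el_of_seg[[s]]
      dq <- qe[els] / max(sg$Q[s], 1e-30)
      c_exit <- c_in - cumsum(dq)
      c_mid[els] <- c_exit + dq / 2
      pb_node[[sg$to[s]]] <-
        if (c_exit[length(c_exit)] <= 0) 0
        else invert_oxygen_content(c_exit[length(c_exit)], sg$H_D[s], params,
                                   start = p_in)
    }
    pb <- invert_content_vec(pmax(c_mid, 0), sg$H_D[el$seg], params)
    pb[c_mid <= 0] <- 0
    list(pb = pb, pb_node = pb_node)
  }

  p_t <- rep(params$inflow_po2, nt)
  qe <- numeric(nv)
  m <- march(qe)
  pb <- m$pb
  converged <- FALSE; resid <- Inf; iter <- 0L; p_inf <- params$inflow_po2
  d_prev <- NULL; cooldown <- 0L
  for (iter in seq_len(max_iter)) {
    ## Michaelis-Menten sinks linearized about the current tissue field:
    ## s_k = dcoef_k * P_k with dcoef = M0 V / (P0 + P_prev)
    dcoef <- m0_cgs * system$tissue$volume / (params$p0 + p_t)
    sink <- dcoef * p_t
    rhs <- c(pb + as.numeric(system$gvs %*% sink), system$beta * sum(sink))
    sol <- qr.coef(system$qr_big, rhs)
    qe_new <- sol[1:nv]; p_inf <- sol[nv + 1] * system$beta
    qe <- relax * qe_new + (1 - relax) * qe
    m <- march(qe)
    ## semi-implicit tissue update: (I + Gtt D) P = P_inf + Gtv q keeps the
    ## sink-field self-coupling from oscillating in supply-limited regions
    lhs <- system$gtt * rep(dcoef, each = nt)
    diag(lhs) <- diag(lhs) + 1
    p_t_imp <- pmax(0, solve(lhs, p_inf + as.numeric(crossprod(system$gvs, qe))))
    resid <- max(max(abs(p_t_imp - p_t)), max(abs(m$pb - pb)))
    p_t_new <- relax * p_t_imp + (1 - relax) * p_t
    d <- p_t_new - p_t
    p_t <- p_t_new
    pb <- m$pb
    if (resid < tol) { converged <- TRUE; break }
    ## Aitken extrapolation of the dominant slow mode of the damped map
    cooldown <- cooldown - 1L
    if (!is.null(d_prev) && cooldown <= 0L) {
      nd <- sqrt(sum(d^2)); ndp <- sqrt(sum(d_prev^2))
      if (nd > 0 && ndp > 0) {
        rho <- sum(d * d_prev) / ndp^2   # projected contraction ratio
        if (rho > 0.2 && rho < 0.995) {
          p_t <- pmax(0, p_t + d * rho / (1 - rho))
          cooldown <- 3L; d <- NULL
        }
      }
    }
    d_prev <- d
  }
  if (!converged)
    warning(sprintf("Green's function solve not converged: residual %.3g mmHg",
                    resid))

  sink <- m0_cgs * p_t / (params$p0 + p_t) * system$tissue$volume
  tissue_out <- cbind(system$tissue, po2 = p_t, sink = sink)
  seg_in <- m$pb_node[sg$from]; seg_out <- m$pb_node[sg$to]
  mean_pb <- vapply(seq_len(nrow(sg)),
                    function(s) mean(pb[el_of_seg[[s]]]), numeric(1))
  inlet_flux <- sum(vapply(which(sg$from == inlet), function(s)
    convective_flux(sg$Q[s], sg$H_D[s], params$inflow_po2, params), numeric(1)))
  term_seg <- which(sg$class == "SA" |
                      sg$to %in% flow$net$nodes$id[flow$net$nodes$kind == "terminal"])
  term_flux <- sum(vapply(term_seg, function(s)
    convective_flux(sg$Q[s], sg$H_D[s], seg_out[s], params), numeric(1)))
  structure(list(
    tissue = tissue_out,
    elements = cbind(el, pb = pb, q_total = qe,
                     q_per_length = qe / el$length_cm),
    segments = data.frame(id = sg$id, class = sg$class, pb_in = seg_in,
                          pb_out = seg_out, mean_pb = mean_pb, Q = sg$Q,
                          H_D = sg$H_D, stringsAsFactors = FALSE),
    node_po2 = m$pb_node, p_inf = p_inf, converged = converged,
    iterations = iter, residual = resid,
    balance = list(inlet_flux = inlet_flux, terminal_flux = term_flux,
                   vessel_efflux = sum(qe), tissue_consumption = sum(sink))),
    class = "greens_solution")
}

#' @export
print.greens_solution <- function(x, ...) {
  cat(sprintf("<greens_solution> %d elements, %d tissue points, %s (%d iter, residual %.2g mmHg)\n",
              nrow(x$elements), nrow(x$tissue),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  b <- x$balance
  cat(sprintf("  tissue PO2 %.1f-%.1f mmHg; consumption %.3g cm^3 O2/s (efflux %.3g)\n",
              min(x$tissue$po2), max(x$tissue$po2), b$tissue_consumption,
              b$vessel_efflux))
  invisible(x)
}

#' Export tissue PO2 as CSV or legacy VTK point data
#'
#' @param greens a `greens_solution`.
#' @param file output path.
#' @export
write_tissue_csv <- function(greens, file) {
  utils::write.csv(greens$tissue[c("x", "y", "z", "po2")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_tissue_csv
#' @export
write_tissue_vtk <- function(greens, file) {
  tp <- greens$tissue
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tissue PO2", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(tp))), con)
  writeLines(sprintf("%g %g %g", tp$x, tp$y, tp$z), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(tp)), "SCALARS po2 float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", tp$po2), con)
  invisible(file)
}
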