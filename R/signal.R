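#' Local metabolic wall signal
#'
#' `S_loc = P0 / (P0 + PO2)`: inversely related to the local blood oxygen
#' tension, approaching 1 as PO2 approaches zero.
#'
#' @param po2 blood PO2, mmHg (>= 0).
#' @param p0 half-point constant, mmHg.
#' @export
local_signal <- function(po2, p0 = 10) {
  if (any(po2 < 0)) stop_invalid("po2 must be non-negative")
  p0 / (p0 + po2)
}

#' Conduct a metabolic signal upstream along one vessel
#'
#' The pointwise conducted signal, with `x` measured upstream from the vessel's
#' outflow node, is
#' `S(x) = S_out exp(-x/L0) + integral_0^x S_loc(y) exp(-(x-y)/L0) dy`:
#' the downstream signal decays exponentially with length constant `L0` while
#' the locally generated signal accumulates and decays over the remaining
#' distance. Equivalently `dS/dx = S_loc(x) - S/L0`, which is integrated
#' exactly per interval for a piecewise-linear `S_loc` (exponential
#' integrator), so the quadrature is exact for the sampled profile. The
#' vessel-average signal follows analytically as
#' `S_meta = (L0/L) (integral S_loc dx - S_up + S_out)`.
#'
#' @param s_loc local signal: a scalar (uniform along the vessel) or a vector
#'   sampled at `x`.
#' @param s_out conducted signal entering at the outflow end (>= 0).
#' @param length_cm vessel length, cm.
#' @param l0 exponential decay constant, cm (default 1).
#' @param x sample positions (cm, increasing from 0 = outflow end to
#'   `length_cm`); defaults to a uniform 200-interval grid.
#' @return list with `S_meta` (vessel average), `S_up` (value at the upstream
#'   end), and the pointwise profile `x`, `S`.
#' @export
conduct_along_vessel <- function(s_loc, s_out, length_cm, l0 = 1, x = NULL) {
  if (length_cm <= 0 || l0 <= 0) stop_invalid("length and l0 must be positive")
  if (s_out < 0 || any(s_loc < 0)) stop_invalid("signals must be non-negative")
  if (is.null(x)) {
    n <- if (length(s_loc) > 1) length(s_loc) else 201
    x <- seq(0, length_cm, length.out = n)
  }
  if (length(s_loc) == 1) s_loc <- rep(s_loc, length(x))
  if (length(s_loc) != length(x))
    stop_invalid("s_loc and x must have equal length")
  n <- length(x)
  s <- numeric(n)
  s[1] <- s_out
  for (i in seq_len(n - 1)) {
    h <- x[i + 1] - x[i]
    e <- exp(-h / l0)
    a <- s_loc[i]
    b <- (s_loc[i + 1] - s_loc[i]) / h
    s[i + 1] <- s[i] * e + a * l0 * (1 - e) + b * (l0 * h - l0^2 * (1 - e))
  }
  int_sloc <- sum((s_loc[-1] + s_loc[-n]) / 2 * diff(x))
  s_up <- s[n]
  s_meta <- (l0 / length_cm) * (int_sloc - s_up + s_out)
  list(S_meta = s_meta, S_up = s_up, x = x, S = s)
}

#' Propagate conducted metabolic signals through chains and arterioles
#'
#' Starting from zero signal at the downstream end of every large-venule
#' compartment, conducts the signal upstream through LV, SV and capillary
#' compartments of each pathway (local signals from the compartment blood PO2
#' profiles), hands the capillary upstream value to its terminal arteriole,
#' and then traverses the arteriolar tree in reverse-topological order. At a
#' bifurcation the parent's outflow signal combines the daughters' upstream
#' values either additively (`junction_rule = "additive"`, the default,
#' consistent with conducted-response superposition) or as a flow-weighted
#' mean (`"flow_weighted"`). Arteriolar local signals use the blood PO2 of the
#' Green's function solution sampled at element midpoints.
#'
#' @param flow a `flow_solution` on a classified network.
#' @param greens the matching `greens_solution`.
#' @param chains a `compartment_chains` (with tissue width solved).
#' @param profiles list of [march_chain()] results named by pathway.
#' @param params an [oxygen_params()] (supplies `p0`).
#' @param l0 conduction decay constant, cm.
#' @param junction_rule combination rule at converging junctions.
#' @return data.frame with one row per vessel/compartment: `id`, `class`,
#'   `pathway`, `S_meta`, `S_up`, `S_out`, `mean_po2`, `Q`.
#' @export
propagate_signal <- function(flow, greens, chains, profiles,
                             params = oxygen_params(), l0 = 1,
                             junction_rule = c("additive", "flow_weighted")) {
  junction_rule <- match.arg(junction_rule)
  sg <- flow$segments
  el <- greens$elements
  p0 <- params$p0
  rows <- list()
  s_up_chain <- numeric(0)

  for (pid in chains$meta$pathway) {
    ch <- chains$chains[chains$chains$pathway == pid, ]
    pr <- profiles[[pid]]
    s_out <- 0
    for (kind in c("LV", "SV", "C")) {
      cpt <- ch[ch$kind == kind, ]
      prof <- switch(kind, LV = pr$lv, SV = pr$sv, C = pr$capillary)
      ## x runs upstream from the compartment outflow: reverse the axial profile
      pb_up <- rev(prof$pb)
      xx <- max(prof$s) - rev(prof$s)
      cond <- conduct_along_vessel(local_signal(pb_up, p0), s_out,
                                   cpt$L_cm, l0, x = xx)
      rows[[length(rows) + 1]] <- data.frame(
        id = paste(pid, kind, sep = ":"), class = kind, pathway = pid,
        S_meta = cond$S_meta, S_up = cond$S_up, S_out = s_out,
        mean_po2 = mean(prof$pb), Q = cpt$Q, stringsAsFactors = FALSE)
      s_out <- cond$S_up
    }
    s_up_chain[[pid]] <- s_out   # capillary upstream value
  }

  ## arterioles in reverse-topological order (segments stored topologically)
  term_of <- stats::setNames(chains$meta$pathway,
                             chains$meta$terminal_segment)
  s_up_seg <- stats::setNames(rep(NA_real_, nrow(sg)), sg$id)
  res_seg <- vector("list", nrow(sg))
  children <- split(seq_len(nrow(sg)), sg$from)
  for (s in rev(seq_len(nrow(sg)))) {
    kids <- children[[sg$to[s]]]
    if (is.null(kids) || length(kids) == 0) {
      pid <- unname(term_of[sg$id[s]])
      if (is.na(pid))
        stop_invalid("terminal segment %s has no compartment chain", sg$id[s])
      s_out <- s_up_chain[[pid]]
    } else {
      vals <- s_up_seg[sg$id[kids]]
      if (anyNA(vals))
        stop_invalid("segment %s visited before its daughters", sg$id[s])
      s_out <- if (junction_rule == "additive") sum(vals)
      else sum(vals * sg$Q[kids]) / sum(sg$Q[kids])
    }
    els <- which(el$seg == s)
    pb_el <- el$pb[els]
    ## element midpoints from the downstream end, upstream-ordered
    n_el <- length(els)
    x_mid <- (seq_len(n_el) - 0.5) / n_el * sg$length_cm[s]
    x <- c(0, rev(x_mid), sg$length_cm[s])
    sl <- local_signal(c(pb_el[n_el], rev(pb_el), pb_el[1]), p0)
    cond <- conduct_along_vessel(sl, s_out, sg$length_cm[s], l0, x = x)
    s_up_seg[[sg$id[s]]] <- cond$S_up
    res_seg[[s]] <- data.frame(
      id = sg$id[s], class = sg$class[s],
      pathway = if (length(kids) == 0) pid else NA_character_,
      S_meta = cond$S_meta, S_up = cond$S_up, S_out = s_out,
      mean_po2 = mean(pb_el), Q = sg$Q[s], stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, res_seg), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Export metabolic signals as CSV
#' @param signals data.frame from [propagate_signal()].
#' @param file output path.
#' @export
write_smeta_csv <- function(signals, file) {
  utils::write.csv(signals, file, row.names = FALSE)
  invisible(file)
}
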