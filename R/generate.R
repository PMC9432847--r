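## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards so fixture generation never perturbs analyses.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a seeded synthetic arteriolar tree
#'
#' Builds a planar bifurcating tree emulating the gross architecture of the
#' retinal arteriolar network: `n_main_branches` first-level branches leave the
#' inlet (the CRA endpoint) at prescribed angles, each bifurcating
#' `bifurcation_levels - 1` times. Daughter diameters obey the Murray relation
#' `D_p^k = D_1^k + D_2^k` exactly, with the flow split fraction per
#' bifurcation drawn uniformly within `0.5 +/- jitter/2` to create
#' heterogeneity; segment lengths are `length_to_diameter * D` with log-normal
#' jitter. When `terminal_diameter_um` is given, every deepest-level segment is
#' assigned that uniform diameter, mirroring the uniform terminal arterioles of
#' the retinal network.
#'
#' @param n_main_branches number of first-level branches (>= 1).
#' @param bifurcation_levels tree depth; 1 means the main branches are terminal.
#' @param murray_exponent exponent `k` of the Murray relation (default 3).
#' @param root_diameter_um diameter of each main branch, um.
#' @param terminal_diameter_um uniform terminal diameter, um, or `NULL` to keep
#'   the Murray-derived value.
#' @param length_to_diameter segment length as a multiple of its diameter.
#' @param jitter heterogeneity amplitude in `[0, 0.9]`: spread of the
#'   bifurcation split fraction and `sdlog` of the length jitter. 0 gives a
#'   perfectly symmetric deterministic tree.
#' @param branch_angles angles (degrees) of the main branches; defaults to an
#'   even spread.
#' @param branch_spread half-angle (degrees) between daughters at bifurcations.
#' @param seed integer RNG seed; the same seed always reproduces the same tree.
#' @param inlet_pressure,terminal_pressure boundary pressures, mmHg.
#' @return a valid [vascular_network()].
#' @export
generate_synthetic_tree <- function(n_main_branches = 4, bifurcation_levels = 6,
                                    murray_exponent = 3, root_diameter_um = 140,
                                    terminal_diameter_um = 20,
                                    length_to_diameter = 15, jitter = 0.2,
                                    branch_angles = NULL, branch_spread = 28,
                                    seed, inlet_pressure = 40,
                                    terminal_pressure = 24) {
  if (missing(seed)) stop_invalid("a seed is required for reproducibility")
  if (n_main_branches < 1 || bifurcation_levels < 1)
    stop_invalid("n_main_branches and bifurcation_levels must be >= 1")
  if (murray_exponent <= 0 || root_diameter_um <= 0 || length_to_diameter <= 0)
    stop_invalid("murray_exponent, root_diameter_um, length_to_diameter must be positive")
  if (jitter < 0 || jitter > 0.9)
    stop_invalid("jitter must be in [0, 0.9]")
  if (!is.null(terminal_diameter_um) && terminal_diameter_um <= 0)
    stop_invalid("terminal_diameter_um must be positive")
  if (is.null(branch_angles))
    branch_angles <- seq(0, 360, length.out = n_main_branches + 1)[-1] + 22.5
  if (length(branch_angles) != n_main_branches)
    stop_invalid("branch_angles must have one angle per main branch")

  with_seed(seed, {
    nodes <- list(data.frame(id = "n0", x = 0, y = 0, z = 0, kind = "inlet",
                             stringsAsFactors = FALSE))
    segs <- list()
    cnt_n <- 0L; cnt_s <- 0L
    k <- murray_exponent
    new_node <- function(x, y, kind) {
      cnt_n <<- cnt_n + 1L
      id <- paste0("n", cnt_n)
      nodes[[length(nodes) + 1L]] <<- data.frame(id = id, x = x, y = y, z = 0,
                                                 kind = kind,
                                                 stringsAsFactors = FALSE)
      id
    }
    new_seg <- function(from, to, d, l) {
      cnt_s <<- cnt_s + 1L
      segs[[length(segs) + 1L]] <<- data.frame(id = paste0("s", cnt_s),
                                               from = from, to = to,
                                               diameter_um = d, length_cm = l,
                                               class = NA_character_,
                                               stringsAsFactors = FALSE)
    }
    seg_len <- function(d) {
      l <- length_to_diameter * d * UM_TO_CM
      if (jitter > 0) l <- l * stats::rlnorm(1, 0, jitter) else l
    }
    grow <- function(from_id, x, y, angle, d, level) {
      terminal_level <- level == bifurcation_levels
      if (terminal_level && !is.null(terminal_diameter_um))
        d <- terminal_diameter_um
      l <- seg_len(d)
      xt <- x + l * cospi(angle / 180); yt <- y + l * sinpi(angle / 180)
      to_id <- new_node(xt, yt, if (terminal_level) "terminal" else "junction")
      new_seg(from_id, to_id, d, l)
      if (!terminal_level) {
        beta <- if (jitter > 0)
          stats::runif(1, 0.5 - jitter / 2, 0.5 + jitter / 2) else 0.5
        d1 <- d * beta^(1 / k)
        d2 <- d * (1 - beta)^(1 / k)
        wob <- if (jitter > 0) stats::runif(2, -8, 8) else c(0, 0)
        grow(to_id, xt, yt, angle + branch_spread + wob[1], d1, level + 1)
        grow(to_id, xt, yt, angle - branch_spread + wob[2], d2, level + 1)
      }
    }
    for (b in seq_len(n_main_branches))
      grow("n0", 0, 0, branch_angles[b], root_diameter_um, 1L)
    vascular_network(do.call(rbind, nodes), do.call(rbind, segs),
                     inlet_pressure, terminal_pressure)
  })
}

#' Hand-specified toy networks used throughout the test suite
#'
#' @param kind one of `"single"` (inlet-terminal segment), `"y_split"`
#'   (symmetric bifurcation), `"two_level"` (asymmetric bifurcation), or
#'   `"four_branch"` (four terminal main branches).
#' @return a valid [vascular_network()].
#' @export
make_toy_network <- function(kind = c("single", "y_split", "two_level",
                                      "four_branch")) {
  kind <- match.arg(kind)
  nd <- function(...) data.frame(..., stringsAsFactors = FALSE)
  switch(kind,
    single = vascular_network(
      nd(id = c("n0", "n1"), x = c(0, 0.05), y = 0, z = 0,
         kind = c("inlet", "terminal")),
      nd(id = "s1", from = "n0", to = "n1", diameter_um = 36, length_cm = 0.05)),
    y_split = vascular_network(
      nd(id = c("n0", "n1", "n2", "n3"),
         x = c(0, 0.1, 0.15, 0.15), y = c(0, 0, 0.04, -0.04), z = 0,
         kind = c("inlet", "junction", "terminal", "terminal")),
      nd(id = c("s1", "s2", "s3"), from = c("n0", "n1", "n1"),
         to = c("n1", "n2", "n3"), diameter_um = c(50, 36, 36),
         length_cm = c(0.1, 0.06, 0.06))),
    two_level = vascular_network(
      nd(id = c("n0", "n1", "n2", "n3"),
         x = c(0, 0.1, 0.18, 0.16), y = c(0, 0, 0.03, -0.05), z = 0,
         kind = c("inlet", "junction", "terminal", "terminal")),
      nd(id = c("s1", "s2", "s3"), from = c("n0", "n1", "n1"),
         to = c("n1", "n2", "n3"), diameter_um = c(50, 40, 25),
         length_cm = c(0.1, 0.08, 0.06))),
    four_branch = vascular_network(
      nd(id = c("n0", "n1", "n2", "n3", "n4"),
         x = c(0, 0.05, 0, -0.05, 0), y = c(0, 0, 0.05, 0, -0.05), z = 0,
         kind = c("inlet", rep("terminal", 4))),
      nd(id = paste0("s", 1:4), from = "n0", to = paste0("n", 1:4),
         diameter_um = 36, length_cm = 0.05)))
}

#' Seeded network emulating the human-scale retinal arteriolar tree
#'
#' Four main branches at superior/inferior temporal/nasal positions, main
#' branch diameters near the large-arteriole scale (140 um), uniform 20 um
#' terminal arterioles, and heterogeneous Murray-law bifurcations. Solved with
#' the default boundary conditions it carries the standard 16 mmHg end-to-end
#' arteriolar pressure drop (40 to 24 mmHg).
#'
#' @param seed integer RNG seed.
#' @param bifurcation_levels tree depth (default 6, i.e. 128 terminals).
#' @return a valid [vascular_network()].
#' @export
make_paper_scale_network <- function(seed, bifurcation_levels = 6) {
  generate_synthetic_tree(n_main_branches = 4,
                          bifurcation_levels = bifurcation_levels,
                          murray_exponent = 3, root_diameter_um = 140,
                          terminal_diameter_um = 20, length_to_diameter = 15,
                          jitter = 0.2, branch_angles = c(45, 135, 225, 315),
                          seed = seed)
}
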