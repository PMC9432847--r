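#' Construct a vascular network
#'
#' A `vascular_network` is a directed tree of nodes and vessel segments with
#' pressure boundary conditions. Nodes carry 3-D positions (cm); segments carry
#' a diameter (um) and length (cm). The unique `inlet` node models the
#' downstream end of the central retinal artery; `terminal` nodes are the
#' distal ends of the terminal arterioles, where capillary compartments attach.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (cm), and `kind`
#'   (one of `"inlet"`, `"junction"`, `"terminal"`).
#' @param segments data.frame with columns `id`, `from`, `to` (node ids),
#'   `diameter_um`, `length_cm`, and optionally `class` (`"LA"`/`"SA"`).
#' @param inlet_pressure inlet blood pressure, mmHg.
#' @param terminal_pressure pressure imposed at every terminal node, mmHg.
#' @return an object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, segments, inlet_pressure = 40,
                             terminal_pressure = 24) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "z", "kind")
  need_s <- c("id", "from", "to", "diameter_um", "length_cm")
  if (!all(need_n %in% names(nodes)))
    stop_invalid("nodes must have columns: %s", paste(need_n, collapse = ", "))
  if (!all(need_s %in% names(segments)))
    stop_invalid("segments must have columns: %s", paste(need_s, collapse = ", "))
  nodes$id <- as.character(nodes$id)
  segments$id <- as.character(segments$id)
  segments$from <- as.character(segments$from)
  segments$to <- as.character(segments$to)
  if (is.null(segments$class)) segments$class <- NA_character_
  net <- structure(list(nodes = nodes, segments = segments,
                        inlet_pressure = inlet_pressure,
                        terminal_pressure = terminal_pressure),
                   class = "vascular_network")
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("<vascular_network> %d nodes, %d segments\n",
              nrow(x$nodes), nrow(x$segments)))
  cat(sprintf("  inlet %s at %g mmHg; %d terminals at %g mmHg\n",
              x$nodes$id[x$nodes$kind == "inlet"][1], x$inlet_pressure,
              sum(x$nodes$kind == "terminal"), x$terminal_pressure))
  dr <- range(x$segments$diameter_um)
  cat(sprintf("  diameters %.1f-%.1f um, total length %.3f cm\n",
              dr[1], dr[2], sum(x$segments$length_cm)))
  invisible(x)
}

node_index <- function(net) {
  stats::setNames(seq_len(nrow(net$nodes)), net$nodes$id)
}

inlet_id <- function(net) net$nodes$id[net$nodes$kind == "inlet"][1]

#' Validate the structural invariants of a network
#'
#' Checks that the network is a connected, acyclic tree rooted at a unique
#' inlet, that terminal nodes have no outgoing segments, that geometry is
#' positive and finite, and that all segment endpoints reference known nodes.
#'
#' @param net a [vascular_network()].
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_network <- function(net) {
  v <- character()
  nd <- net$nodes; sg <- net$segments
  if (anyDuplicated(nd$id))
    v <- c(v, "nodes: duplicated ids")
  n_in <- sum(nd$kind == "inlet")
  if (n_in != 1)
    v <- c(v, sprintf("nodes: inlet must be unique (found %d)", n_in))
  bad_pos <- !is.finite(nd$x) | !is.finite(nd$y) | !is.finite(nd$z)
  for (id in nd$id[bad_pos])
    v <- c(v, sprintf("node %s: position not finite", id))
  unknown <- setdiff(c(sg$from, sg$to), nd$id)
  for (id in unknown)
    v <- c(v, sprintf("segments reference unknown node %s", id))
  for (i in seq_len(nrow(sg))) {
    if (!is.finite(sg$diameter_um[i]) || sg$diameter_um[i] <= 0)
      v <- c(v, sprintf("segment %s: diameter > 0 violated", sg$id[i]))
    if (!is.finite(sg$length_cm[i]) || sg$length_cm[i] <= 0)
      v <- c(v, sprintf("segment %s: length > 0 violated", sg$id[i]))
  }
  if (length(unknown) == 0 && n_in == 1 && nrow(sg) > 0) {
    if (nrow(sg) != nrow(nd) - 1)
      v <- c(v, sprintf("acyclic tree violated: %d segments != %d nodes - 1",
                        nrow(sg), nrow(nd)))
    reach <- reachable_nodes(net)
    miss <- setdiff(nd$id, reach)
    for (id in miss)
      v <- c(v, sprintf("node %s not reachable from inlet", id))
    out_deg <- table(factor(sg$from, levels = nd$id))
    for (id in nd$id[nd$kind == "terminal"])
      if (out_deg[[id]] > 0)
        v <- c(v, sprintf("terminal node %s has out-degree %d", id, out_deg[[id]]))
  }
  v
}

## Undirected reachability from the inlet (segment orientation not yet trusted).
reachable_nodes <- function(net) {
  adj <- split(c(net$segments$to, net$segments$from),
               c(net$segments$from, net$segments$to))
  seen <- inlet_id(net)
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

## Segments reordered/reoriented so every segment points away from the inlet
## and appears after its parent (topological order). Assumes a valid tree.
orient_segments <- function(net) {
  sg <- net$segments
  adj <- split(rep(seq_len(nrow(sg)), 2L),
               c(sg$from, sg$to))  # segment indices touching each node
  ord <- integer(0)
  seen_nodes <- inlet_id(net)
  frontier <- seen_nodes
  used <- rep(FALSE, nrow(sg))
  while (length(frontier)) {
    nxt_nodes <- character(0)
    for (nd in frontier) {
      for (si in adj[[nd]]) {
        if (used[si]) next
        used[si] <- TRUE
        if (sg$to[si] == nd) {  # flip toward downstream
          tmp <- sg$from[si]; sg$from[si] <- sg$to[si]; sg$to[si] <- tmp
        }
        ord <- c(ord, si)
        nxt_nodes <- c(nxt_nodes, sg$to[si])
      }
    }
    frontier <- setdiff(nxt_nodes, seen_nodes)
    seen_nodes <- c(seen_nodes, frontier)
  }
  net$segments <- sg[ord, , drop = FALSE]
  rownames(net$segments) <- NULL
  net
}

#' Scale a network between species
#'
#' Multiplies every segment diameter by `diameter_factor` and every length and
#' node coordinate by `length_factor`, leaving the topology unchanged. The
#' mouse-to-human translation of the retinal arteriolar tree uses a diameter
#' factor of 3.6 (from oximetry biomarkers) and a length factor of 5.9 (from
#' the CRA-to-fovea distance).
#'
#' @param net a [vascular_network()].
#' @param diameter_factor,length_factor positive scale factors.
#' @return the scaled network.
#' @export
scale_network <- function(net, diameter_factor = 3.6, length_factor = 5.9) {
  if (!is.finite(diameter_factor) || diameter_factor <= 0 ||
      !is.finite(length_factor) || length_factor <= 0)
    stop_invalid("scale factors must be positive")
  net$segments$diameter_um <- net$segments$diameter_um * diameter_factor
  net$segments$length_cm <- net$segments$length_cm * length_factor
  net$nodes$x <- net$nodes$x * length_factor
  net$nodes$y <- net$nodes$y * length_factor
  net$nodes$z <- net$nodes$z * length_factor
  net
}

#' Classify arterioles into large (LA) and small (SA) and enumerate pathways
#'
#' Terminal arterioles (segments that end at a terminal node) are classified as
#' small arterioles (SA); every segment upstream of a terminal arteriole is a
#' large arteriole (LA). One pathway is recorded per terminal, carrying the
#' diameter of its most-upstream vessel (`D_LA_um`, the main branch feeding the
#' pathway) and of its terminal segment (`D_SA_um`).
#'
#' @param net a valid [vascular_network()].
#' @return `net` with `segments$class` filled and a `pathways` data.frame
#'   attached (`terminal_node`, `terminal_segment`, `root_segment`, `D_LA_um`,
#'   `D_SA_um`, `path_length_cm`).
#' @export
classify_segments <- function(net) {
  net <- orient_segments(net)
  sg <- net$segments
  term_nodes <- net$nodes$id[net$nodes$kind == "terminal"]
  if (length(term_nodes) == 0)
    stop_invalid("network has no terminal nodes")
  sg$class <- ifelse(sg$to %in% term_nodes, "SA", "LA")
  parent_of <- stats::setNames(seq_len(nrow(sg)), sg$to)  # segment index by head node
  root <- inlet_id(net)
  pw <- lapply(term_nodes, function(tn) {
    path <- integer(0)
    nd <- tn
    while (nd != root) {
      si <- parent_of[[nd]]
      path <- c(si, path)
      nd <- sg$from[si]
    }
    data.frame(terminal_node = tn,
               terminal_segment = sg$id[path[length(path)]],
               root_segment = sg$id[path[1]],
               D_LA_um = sg$diameter_um[path[1]],
               D_SA_um = sg$diameter_um[path[length(path)]],
               path_length_cm = sum(sg$length_cm[path]),
               stringsAsFactors = FALSE)
  })
  net$segments <- sg
  net$pathways <- do.call(rbind, pw)
  net
}

## Ordered segment-id path (inlet -> terminal) for one terminal node.
pathway_segments <- function(net, terminal_node) {
  sg <- net$segments
  parent_of <- stats::setNames(seq_len(nrow(sg)), sg$to)
  root <- inlet_id(net)
  path <- character(0)
  nd <- terminal_node
  while (nd != root) {
    si <- parent_of[[nd]]
    path <- c(sg$id[si], path)
    nd <- sg$from[si]
  }
  path
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Read and write networks as CSV or JSON
#'
#' The CSV form is a pair of files, `nodes.csv` (`id,x,y,z,kind`) and
#' `segments.csv` (`id,from,to,diameter_um,length_cm,class`); the JSON form is
#' a single file holding the same tables plus the boundary pressures. Numeric
#' fields are written with 17 significant digits so a write/read cycle
#' reproduces the network bit-exactly.
#'
#' @param net a [vascular_network()].
#' @param nodes_file,segments_file CSV paths.
#' @param file JSON path.
#' @param inlet_pressure,terminal_pressure boundary pressures (mmHg) attached
#'   on CSV read (the CSV pair carries geometry only).
#' @return `read_*` return a [vascular_network()]; `write_*` return the path(s)
#'   invisibly.
#' @export
write_network_csv <- function(net, nodes_file, segments_file) {
  nd <- net$nodes
  nd$x <- fmt_num(nd$x); nd$y <- fmt_num(nd$y); nd$z <- fmt_num(nd$z)
  utils::write.csv(nd, nodes_file, row.names = FALSE, quote = FALSE)
  sg <- net$segments
  sg$diameter_um <- fmt_num(sg$diameter_um)
  sg$length_cm <- fmt_num(sg$length_cm)
  utils::write.csv(sg[c("id", "from", "to", "diameter_um", "length_cm", "class")],
                   segments_file, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_file, segments_file))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(nodes_file, segments_file, inlet_pressure = 40,
                             terminal_pressure = 24) {
  nd <- utils::read.csv(nodes_file, stringsAsFactors = FALSE)
  sg <- utils::read.csv(segments_file, stringsAsFactors = FALSE)
  if (!is.null(sg$class)) sg$class[sg$class == ""] <- NA_character_
  vascular_network(nd, sg, inlet_pressure, terminal_pressure)
}

#' @rdname write_network_csv
#' @export
write_network_json <- function(net, file) {
  obj <- list(nodes = net$nodes, segments = net$segments,
              inlet_pressure = net$inlet_pressure,
              terminal_pressure = net$terminal_pressure)
  jsonlite::write_json(obj, file, dataframe = "columns", digits = I(17),
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(file)
}

#' @rdname write_network_csv
#' @export
read_network_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  vascular_network(as.data.frame(obj$nodes), as.data.frame(obj$segments),
                   as.numeric(obj$inlet_pressure),
                   as.numeric(obj$terminal_pressure))
}
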