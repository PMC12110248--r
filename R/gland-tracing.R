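#' Gland tracing through a layered peak graph
#'
#' Every profile is a layer of a graph; every peak a node. Nodes of
#' consecutive layers are fully connected by edges weighted with the Euclidean
#' pixel distance between the two peaks, nodes within a layer are not
#' connected at all, and two virtual nodes - a supersource above the top layer
#' and a supersink below the bottom one, attached with zero-weight edges -
#' give Dijkstra's algorithm uniform start and end points. A shortest
#' source-to-sink path chains one peak per layer into a gland whose length is
#' the sum of its edge weights; extracted nodes are removed and the search
#' repeats. Dropping the top layer between phases finds glands shortened from
#' the lid's distal edge.
#'
#' @name gland-tracing
NULL

#' Build the layered peak graph
#'
#' @param peak_layers list of peak data.frames (see [detect_peaks()]), ordered
#'   top layer first.
#' @return an [igraph::igraph] with vertices `SRC`, `SNK` and one vertex per
#'   peak (attributes `layer`, `x`, `y`, `width`), directed top to bottom;
#'   edge attribute `weight` carries the Euclidean distance (0 for virtual
#'   edges). An empty intermediate layer leaves the graph disconnected, so no
#'   gland path can cross it.
#' @export
build_layered_graph <- function(peak_layers) {
  nodes <- peak_nodes(peak_layers)
  if (length(unique(nodes$layer)) < 2)
    stop("no-gland result: fewer than 2 non-empty layers", call. = FALSE)
  graph_from_nodes(nodes, seq_along(peak_layers))
}

# Flatten peak data.frames into one node table with stable ids.
peak_nodes <- function(peak_layers) {
  rows <- lapply(seq_along(peak_layers), function(l) {
    pk <- peak_layers[[l]]
    if (is.null(pk) || nrow(pk) == 0) return(NULL)
    data.frame(layer = l, x = pk$x, y = pk$y, width = pk$width)
  })
  nodes <- do.call(rbind, rows)
  if (is.null(nodes)) nodes <- data.frame(layer = integer(0), x = numeric(0),
                                          y = numeric(0), width = numeric(0))
  if (nrow(nodes)) {
    nodes <- nodes[order(nodes$layer, nodes$x), , drop = FALSE]
    nodes$id <- sprintf("p%04d", seq_len(nrow(nodes)))
  } else nodes$id <- character(0)
  rownames(nodes) <- NULL
  nodes
}

# igraph over the given layer span: full bipartite edges between consecutive
# layers of the span, SRC to the first span layer, last span layer to SNK.
# A span layer without nodes simply contributes no edges (disconnection).
graph_from_nodes <- function(nodes, span) {
  span <- sort(span)
  ed <- list()
  for (k in seq_len(length(span) - 1)) {
    a <- nodes[nodes$layer == span[k], , drop = FALSE]
    b <- nodes[nodes$layer == span[k + 1], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    ed[[length(ed) + 1]] <- data.frame(
      from = a$id[grid$i], to = b$id[grid$j],
      weight = sqrt((a$x[grid$i] - b$x[grid$j])^2 +
                    (a$y[grid$i] - b$y[grid$j])^2))
  }
  top <- nodes[nodes$layer == span[1], , drop = FALSE]
  bot <- nodes[nodes$layer == span[length(span)], , drop = FALSE]
  if (nrow(top)) ed[[length(ed) + 1]] <-
    data.frame(from = "SRC", to = top$id, weight = 0)
  if (nrow(bot)) ed[[length(ed) + 1]] <-
    data.frame(from = bot$id, to = "SNK", weight = 0)
  keep <- nodes[nodes$layer %in% span, , drop = FALSE]
  verts <- rbind(data.frame(name = c("SRC", "SNK"), layer = NA, x = NA,
                            y = NA, width = NA),
                 data.frame(name = keep$id, layer = keep$layer, x = keep$x,
                            y = keep$y, width = keep$width))
  edges <- if (length(ed)) do.call(rbind, ed)
           else data.frame(from = character(0), to = character(0),
                           weight = numeric(0))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Shortest supersource-to-supersink path
#'
#' Dijkstra's algorithm over the layered graph; among equal-weight shortest
#' paths the lexicographically smallest node-id sequence is returned for
#' determinism. The reported length excludes the zero-weight virtual edges
#' (numerically moot) and equals the gland length.
#'
#' @param graph layered [igraph::igraph] from [build_layered_graph()].
#' @return `NULL` when no path exists, else a list with `ids` (peak vertex
#'   names, top to bottom) and `length` (px).
#' @export
shortest_gland_path <- function(graph) {
  if (!all(c("SRC", "SNK") %in% igraph::V(graph)$name)) return(NULL)
  d <- suppressWarnings(igraph::distances(graph, v = "SRC", to = "SNK",
                                          mode = "out",
                                          weights = igraph::E(graph)$weight))
  if (!is.finite(d[1, 1])) return(NULL)
  ap <- suppressWarnings(
    igraph::all_shortest_paths(graph, from = "SRC", to = "SNK", mode = "out",
                               weights = igraph::E(graph)$weight))
  seqs <- lapply(ap$vpaths, function(p) igraph::V(graph)$name[as.integer(p)])
  keys <- vapply(seqs, function(s) paste(s, collapse = "|"), character(1))
  ids <- seqs[[order(keys)[1]]]
  list(ids = ids[!ids %in% c("SRC", "SNK")], length = d[1, 1])
}

#' Trace glands by iterated shortest-path extraction
#'
#' Phase 1 runs on all layers: the shortest source-sink path is accepted as a
#' gland while its length does not exceed `full_max_len`; its nodes are
#' removed and the search repeats, ending when the minimal path first exceeds
#' the threshold or no path remains. The top layer is then dropped, the
#' supersource reattached to the new top layer, and the extraction repeated
#' while at least three layers remain (shortened glands are missing their
#' distal, upper portion). With two layers left, every remaining
#' adjacent-layer edge strictly shorter than `pair_max_len` becomes a
#' two-node gland, taken greedily shortest first with node removal. Each
#' gland is labeled by the number of layers it spans (see
#' [classify_gland()]).
#'
#' @param peak_layers list of per-layer peak data.frames, top first.
#' @param full_max_len px; path-length threshold for the multi-layer phases.
#' @param pair_max_len px; edge-length threshold for two-node glands.
#' @param accept_leq accept paths with length equal to `full_max_len`
#'   (default); `FALSE` switches to the strictly-below reading of the
#'   stopping rule.
#' @return list of `mg_gland` objects sorted by leftmost x, each with
#'   `nodes` (data.frame `layer`, `x`, `y`, `width`), `path_length`,
#'   `n_layers`, `label` and `widths`.
#' @export
trace_glands <- function(peak_layers, full_max_len = 100, pair_max_len = 60,
                         accept_leq = TRUE) {
  total_layers <- length(peak_layers)
  nodes <- peak_nodes(peak_layers)
  glands <- list()
  ok_len <- function(len) if (accept_leq) len <= full_max_len else len < full_max_len
  # multi-layer phases: span top..total_layers while the span has >= 3 layers
  if (total_layers >= 3) {
    for (top in seq_len(total_layers - 2)) {
      span <- top:total_layers
      repeat {
        sp <- shortest_gland_path(graph_from_nodes(nodes, span))
        if (is.null(sp) || !ok_len(sp$length)) break
        member <- nodes[match(sp$ids, nodes$id), , drop = FALSE]
        g <- new_gland(member, sp$length, total_layers)
        g$phase <- length(span)
        g$order <- length(glands) + 1L
        glands[[length(glands) + 1L]] <- g
        nodes <- nodes[!nodes$id %in% sp$ids, , drop = FALSE]
      }
    }
  }
  # two-layer phase on the bottom pair of layers
  if (total_layers >= 2) {
    a <- nodes[nodes$layer == total_layers - 1, , drop = FALSE]
    b <- nodes[nodes$layer == total_layers, , drop = FALSE]
    if (nrow(a) && nrow(b)) {
      grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
      grid$w <- sqrt((a$x[grid$i] - b$x[grid$j])^2 +
                     (a$y[grid$i] - b$y[grid$j])^2)
      grid <- grid[grid$w < pair_max_len, , drop = FALSE]
      grid <- grid[order(grid$w, a$id[grid$i], b$id[grid$j]), , drop = FALSE]
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      for (r in seq_len(nrow(grid))) {
        i <- grid$i[r]; j <- grid$j[r]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        g <- new_gland(rbind(a[i, ], b[j, ]), grid$w[r], total_layers)
        g$phase <- 2L
        g$order <- length(glands) + 1L
        glands[[length(glands) + 1L]] <- g
      }
    }
  }
  if (length(glands)) {
    ord <- order(vapply(glands, function(g) min(g$nodes$x), numeric(1)),
                 vapply(glands, function(g) g$nodes$layer[1], numeric(1)))
    glands <- glands[ord]
  }
  glands
}

new_gland <- function(member, path_length, total_layers) {
  member <- member[order(member$layer), , drop = FALSE]
  rownames(member) <- NULL
  structure(list(
    nodes = member[, c("layer", "x", "y", "width")],
    path_length = path_length,
    n_layers = nrow(member),
    label = classify_gland(nrow(member), total_layers),
    widths = member$width), class = "mg_gland")
}

#' Classify a gland by the number of layers it spans
#'
#' With four profile lines a gland touching all four is long (L), three is
#' medium (M), two is short (S): gland length is discretized by the profile
#' layers involved.
#'
#' @param n_layers layers the gland spans.
#' @param total_layers number of profile layers in the analysis (4).
#' @return `"L"`, `"M"` or `"S"`.
#' @export
classify_gland <- function(n_layers, total_layers = 4) {
  if (n_layers < 2 || n_layers > total_layers)
    stop("n_layers must be between 2 and ", total_layers, call. = FALSE)
  if (n_layers == total_layers) "L"
  else if (n_layers == total_layers - 1) "M"
  else "S"
}

#' @export
print.mg_gland <- function(x, ...) {
  cat(sprintf("<gland %s: %d layers, length %.1f px, x ~ %d>\n",
              x$label, x$n_layers, x$path_length, round(mean(x$nodes$x))))
  invisible(x)
}
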