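#' Weighted undirected graph with shortest-path distance measure
#'
#' Container for an undirected graph with non-negative edge weights, the
#' basic object on which delta-teams are computed. The induced distance
#' between two vertices is the length (sum of edge weights) of the shortest
#' path connecting them, `Inf` when no path exists and 0 for a vertex and
#' itself. Parallel edges collapse to the minimum weight; self-loops are
#' dropped with a warning.
#'
#' @param edges a data frame (or NULL) with columns `u`, `v`, `weight`;
#'   vertex identifiers are coerced to character.
#' @param vertices optional character vector of additional (possibly
#'   isolated) vertex identifiers.
#' @return an object of class `weighted_graph` with elements `vertices`
#'   (sorted character vector) and `edges` (canonical data frame with
#'   `u < v` per row).
#' @export
weighted_graph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (!all(c("u", "v", "weight") %in% names(edges)))
    stop("`edges` must have columns u, v, weight", call. = FALSE)
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight) || any(edges$weight < 0))
    stop("edge weights must be non-negative and non-missing", call. = FALSE)
  loops <- edges$u == edges$v
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation + parallel-edge collapse to minimum weight
  flip <- edges$u > edges$v
  tmp <- edges$u[flip]; edges$u[flip] <- edges$v[flip]; edges$v[flip] <- tmp
  if (nrow(edges)) {
    key <- paste(edges$u, edges$v, sep = "\r")
    w <- tapply(edges$weight, key, min)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(u = vapply(parts, `[`, "", 1L),
                        v = vapply(parts, `[`, "", 2L),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  }
  verts <- sort(unique(c(as.character(vertices), edges$u, edges$v)))
  if (!length(verts))
    stop("graph has no vertices", call. = FALSE)
  structure(list(vertices = verts, edges = edges, .cache = new.env()),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$vertices), name = g$vertices)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(ig, rbind(g$edges$u, g$edges$v),
                            weight = g$edges$weight)
  }
  ig
}

#' All-pairs shortest-path distances of a weighted graph
#'
#' Computed once per graph and cached. Distances are sums of edge weights;
#' unreachable pairs are `Inf`.
#'
#' @param g a [weighted_graph()].
#' @return a symmetric numeric matrix with vertex names as dimnames.
#' @export
graph_distances <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (is.null(g$.cache$dist)) {
    ig <- as_igraph(g)
    w <- if (nrow(g$edges)) igraph::E(ig)$weight else NULL
    D <- igraph::distances(ig, weights = w)
    D <- D[g$vertices, g$vertices, drop = FALSE]
    g$.cache$dist <- D
  }
  g$.cache$dist
}

#' Shortest-path distance between two vertices
#'
#' @param graph a [weighted_graph()].
#' @param u,v vertex identifiers.
#' @return the minimum sum of edge weights over all u-v paths; 0 when
#'   `u == v`; `Inf` when no path exists.
#' @export
shortest_path_distance <- function(graph, u, v) {
  u <- as.character(u); v <- as.character(v)
  unknown <- setdiff(c(u, v), graph$vertices)
  if (length(unknown))
    stop("unknown vertex id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  graph_distances(graph)[u, v]
}

#' Threshold graph of a weighted graph
#'
#' Builds the unit-weight graph on `candidate_vertices` in which two
#' vertices share an edge iff their shortest-path distance in `graph` is
#' `<= delta`. This is the transformation behind the alternative
#' "shortest-path graph" mode: delta-teams of the originals equal 1-teams
#' of their threshold graphs.
#'
#' @param graph a [weighted_graph()].
#' @param candidate_vertices subset of the graph's vertices.
#' @param delta non-negative distance threshold.
#' @return a [weighted_graph()] on `candidate_vertices` with unit weights.
#' @export
build_threshold_graph <- function(graph, candidate_vertices, delta) {
  candidate_vertices <- sort(as.character(candidate_vertices))
  unknown <- setdiff(candidate_vertices, graph$vertices)
  if (length(unknown))
    stop("unknown vertex id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  D <- graph_distances(graph)[candidate_vertices, candidate_vertices,
                              drop = FALSE]
  idx <- which(D <= delta & upper.tri(D), arr.ind = TRUE)
  edges <- data.frame(u = candidate_vertices[idx[, 1L]],
                      v = candidate_vertices[idx[, 2L]],
                      weight = rep(1, nrow(idx)), stringsAsFactors = FALSE)
  weighted_graph(edges, vertices = candidate_vertices)
}

#' Read / write the tab-separated edge-list format
#'
#' The on-disk format is tab-separated `vertex_u  vertex_v  weight` with
#' optional `#`-prefixed comment/header lines. Isolated vertices may be
#' listed as lines with a single field.
#'
#' @param path file path.
#' @return for the reader, a [weighted_graph()].
#' @export
read_graph_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  iso <- vapply(parts[nf == 1L], `[`, "", 1L)
  ep <- parts[nf >= 3L]
  bad <- which(nf == 2L | nf > 3L)
  if (length(bad))
    stop("malformed edge line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  edges <- data.frame(u = vapply(ep, `[`, "", 1L),
                      v = vapply(ep, `[`, "", 2L),
                      weight = as.numeric(vapply(ep, `[`, "", 3L)),
                      stringsAsFactors = FALSE)
  weighted_graph(edges, vertices = iso)
}

#' @param graph a [weighted_graph()].
#' @param name graph name written into the `#` header.
#' @param header extra `#` comment lines (character vector).
#' @rdname read_graph_tsv
#' @export
write_graph_tsv <- function(graph, path, name = "graph", header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- if (length(header)) paste0("# ", header) else character()
  writeLines(c(sprintf("# graph: %s", name), hdr), con)
  if (nrow(graph$edges)) {
    writeLines(sprintf("%s\t%s\t%.10g", graph$edges$u, graph$edges$v,
                       graph$edges$weight), con)
  }
  iso <- setdiff(graph$vertices, c(graph$edges$u, graph$edges$v))
  if (length(iso)) writeLines(iso, con)
  invisible(path)
}
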