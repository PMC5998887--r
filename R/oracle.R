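# Independent brute-force references for the team algorithms.
#
# The no-family oracle is alternating per-graph component refinement:
# starting from the whole shared vertex set, each part is repeatedly
# replaced by the connected components of its per-graph threshold graph
# (full-graph shortest-path distance <= delta) until stable. The fixpoint
# is exactly the set of delta-teams. This deliberately is NOT
# single-linkage on the pointwise-max distance matrix, which contradicts
# the chain-based definition when per-graph chains differ (see the
# counterexample regression test).

# connected components of the threshold relation D[S,S] <= delta
.threshold_components <- function(D, S, delta) {
  n <- length(S)
  if (n <= 1L) return(list(S))
  A <- D[S, S, drop = FALSE] <= delta
  diag(A) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  unname(split(S, comp))
}

#' Is a vertex set a delta-set of a graph?
#'
#' True iff every pair of members is linked by a chain of members whose
#' consecutive shortest-path distances (in the full graph) are all
#' `<= delta`; equivalently, iff the threshold graph on the set is
#' connected. Sets of size <= 1 are vacuously delta-sets.
#'
#' @param graph a [weighted_graph()].
#' @param S vertex subset.
#' @param delta non-negative threshold.
#' @return logical scalar.
#' @export
check_delta_set <- function(graph, S, delta) {
  S <- as.character(S)
  if (length(S) <= 1L) return(TRUE)
  D <- graph_distances(graph)
  length(.threshold_components(D, S, delta)) == 1L
}

#' Brute-force delta-teams by alternating partition refinement
#'
#' Reference implementation for small instances: refine the partition
#' `{V_intersect}` by per-graph threshold components until stable.
#'
#' @param graphs list of >= 2 [weighted_graph()]s.
#' @param delta non-negative threshold.
#' @return a `team_partition`, canonically ordered as in
#'   [find_delta_teams()].
#' @export
oracle_teams <- function(graphs, delta) {
  shared <- sort(Reduce(intersect, lapply(graphs, `[[`, "vertices")))
  if (!length(shared))
    stop("the graphs share no vertices", call. = FALSE)
  Ds <- lapply(graphs, graph_distances)
  parts <- list(shared)
  repeat {
    changed <- FALSE
    for (D in Ds) {
      new_parts <- list()
      for (p in parts) {
        cs <- .threshold_components(D, p, delta)
        if (length(cs) > 1L) changed <- TRUE
        new_parts <- c(new_parts, cs)
      }
      parts <- new_parts
    }
    if (!changed) break
  }
  parts <- lapply(parts, sort)
  parts <- parts[order(vapply(parts, `[`, "", 1L))]
  structure(list(teams = parts, delta = delta), class = "team_partition")
}

# all non-empty subsets of ids as bitmasks paired with vertex vectors
.all_subsets <- function(ids) {
  n <- length(ids)
  masks <- seq_len(2^n - 1L)
  sets <- lapply(masks, function(m) ids[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0])
  list(masks = masks, sets = sets)
}

#' Brute-force delta-teams with families by exhaustive enumeration
#'
#' Enumerates every tuple of per-graph subsets with equal family spectra
#' in which each subset is a delta-set of its own graph, then keeps the
#' component-wise maximal tuples. Exponential; refuses instances with more
#' than `max_vertices` vertices in any graph.
#'
#' @param graphs list of [family_graph()]s.
#' @param delta non-negative threshold.
#' @param max_vertices guard against exponential blowup (default 6).
#' @return a `family_teams` object, canonically ordered as in
#'   [find_delta_teams_families()].
#' @export
oracle_family_teams <- function(graphs, delta, max_vertices = 6L) {
  ns <- vapply(graphs, function(fg) length(fg$graph$vertices), 0L)
  if (any(ns > max_vertices))
    stop("instance too large for exhaustive family oracle", call. = FALSE)
  k <- length(graphs)
  fams <- lapply(graphs, `[[`, "family_of")
  Ds <- lapply(graphs, function(fg) graph_distances(fg$graph))
  # per graph: delta-set subsets grouped by spectrum key
  per_graph <- lapply(seq_len(k), function(x) {
    ids <- sort(graphs[[x]]$graph$vertices)
    ss <- .all_subsets(ids)
    ok <- vapply(ss$sets, function(s)
      length(.threshold_components(Ds[[x]], s, delta)) == 1L ||
        length(s) == 1L, TRUE)
    spec <- vapply(ss$sets, function(s)
      paste(sort(unique(unname(fams[[x]][s]))), collapse = ","), "")
    data.frame(mask = ss$masks[ok], spec = spec[ok],
               idx = which(ok), stringsAsFactors = FALSE)
  })
  ids_per_graph <- lapply(graphs, function(fg) sort(fg$graph$vertices))
  specs <- Reduce(intersect, lapply(per_graph, function(d) unique(d$spec)))
  if (!length(specs)) {
    return(structure(list(teams = list(), delta = delta, n_graphs = k),
                     class = "family_teams"))
  }
  # all valid tuples as a mask matrix (rows = tuples, cols = graphs)
  tuples <- do.call(rbind, lapply(specs, function(sp) {
    choices <- lapply(per_graph, function(d) d$mask[d$spec == sp])
    as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  }))
  m <- nrow(tuples)
  keep <- logical(m)
  for (i in seq_len(m)) {
    sup <- rep(TRUE, m)
    for (x in seq_len(k))
      sup <- sup & bitwAnd(tuples[, x], tuples[i, x]) == tuples[i, x]
    keep[i] <- sum(sup) == 1L  # only the tuple itself contains it
  }
  maximal <- tuples[keep, , drop = FALSE]
  teams <- lapply(seq_len(nrow(maximal)), function(i) {
    sets <- lapply(seq_len(k), function(x) {
      ids <- ids_per_graph[[x]]
      sort(ids[bitwAnd(maximal[i, x], 2^(seq_along(ids) - 1L)) > 0])
    })
    list(vertex_sets = sets,
         spectrum = sort(unique(unname(fams[[1L]][sets[[1L]]]))))
  })
  ord <- order(vapply(teams, function(t) paste(t$spectrum, collapse = ","), ""),
               vapply(teams, function(t) .team_key(t$vertex_sets), ""))
  structure(list(teams = teams[ord], delta = delta, n_graphs = k),
            class = "family_teams")
}
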