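# Core delta-team machinery: bounded expansion, SMALLMAX, DECOMPOSE.
#
# All internal workers operate on precomputed per-graph shortest-path
# distance matrices restricted to the relevant vertex universe; distances
# are taken in the *full* graph, so paths may route through vertices that
# are not members of any working set.

# next expandable vertex: smallest-id s in members \ visited with
# min_{t in visited} D[s, t] <= delta, or NULL
.expand_next <- function(D, members, visited, delta) {
  cand <- setdiff(members, visited)
  if (!length(cand)) return(NULL)
  sub <- D[cand, visited, drop = FALSE]
  reach <- apply(sub, 1L, min) <= delta
  hits <- cand[reach]
  if (!length(hits)) NULL else sort(hits)[1L]
}

#' Bounded expansion step of the team traversal
#'
#' Returns one not-yet-visited member vertex lying within shortest-path
#' distance `delta` of the visited set, or `NULL` when none exists.
#' Distances are measured in the full graph, so connecting paths may pass
#' through non-member vertices; only endpoints must be members.
#'
#' @param graph a [weighted_graph()].
#' @param members candidate vertex set.
#' @param visited non-empty subset of `members` already reached.
#' @param delta non-negative distance threshold.
#' @return a vertex id or `NULL`.
#' @export
bounded_expand <- function(graph, members, visited, delta) {
  members <- as.character(members); visited <- as.character(visited)
  if (!length(visited))
    stop("`visited` must be non-empty", call. = FALSE)
  if (length(setdiff(visited, members)))
    stop("`visited` must be a subset of `members`", call. = FALSE)
  unknown <- setdiff(members, graph$vertices)
  if (length(unknown))
    stop("unknown vertex id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  .expand_next(graph_distances(graph), members, visited, delta)
}

# SMALLMAX on k >= 2 distance matrices. member_sets is a list of character
# vectors, one per graph. Performs one expansion step per still-active
# graph per round (round-robin, input order). The first graph whose
# traversal exhausts on a *proper* subset of its member set wins and that
# subset (a maximal delta-set) is returned. Only when every member set is
# a delta-set in its own graph is the full set returned, flagged with the
# index of the last graph by convention.
.smallmax_core <- function(Ds, member_sets, delta) {
  k <- length(Ds)
  if (any(!lengths(member_sets)))
    stop("empty member set", call. = FALSE)
  visited <- lapply(member_sets, function(s) sort(s)[1L])
  active <- lengths(member_sets) > 1L
  while (any(active)) {
    for (x in seq_len(k)) {
      if (!active[x]) next
      s <- .expand_next(Ds[[x]], member_sets[[x]], visited[[x]], delta)
      if (is.null(s)) {
        if (length(visited[[x]]) < length(member_sets[[x]]))
          return(list(graph = x, subset = sort(visited[[x]]), proper = TRUE))
        active[x] <- FALSE
      } else {
        visited[[x]] <- c(visited[[x]], s)
        if (length(visited[[x]]) == length(member_sets[[x]]))
          active[x] <- FALSE
      }
    }
  }
  list(graph = k, subset = sort(member_sets[[k]]), proper = FALSE)
}

#' Find a maximal delta-set within per-graph member sets (SMALLMAX)
#'
#' Searches all graphs simultaneously, one expansion step per graph per
#' round, and terminates as early as possible: the first graph whose
#' traversal exhausts on a proper subset of its members yields that subset
#' (a maximal delta-set of that member set). Only when every member set is
#' itself a delta-set in its own graph is the full set returned, with the
#' index of the last graph by convention.
#'
#' @param graphs list of >= 2 [weighted_graph()]s.
#' @param member_sets list of one vertex set per graph (identical sets in
#'   the shared-vertex setting).
#' @param delta non-negative distance threshold.
#' @return list with `graph` (index), `subset` (sorted vertex set) and
#'   `proper` (TRUE iff the subset is proper).
#' @export
smallmax <- function(graphs, member_sets, delta) {
  member_sets <- lapply(member_sets, as.character)
  Ds <- lapply(graphs, graph_distances)
  .smallmax_core(Ds, member_sets, delta)
}

# DECOMPOSE: appends the delta-teams contained in S to acc (an environment
# with a list `teams`), splitting S into S' and S \ S' whenever SMALLMAX
# finds a proper maximal delta-set S'.
.decompose_core <- function(Ds, S, delta, acc) {
  repeat {
    res <- .smallmax_core(Ds, rep(list(S), length(Ds)), delta)
    if (!res$proper) {
      acc$teams[[length(acc$teams) + 1L]] <- sort(S)
      return(invisible(NULL))
    }
    .decompose_core(Ds, res$subset, delta, acc)
    S <- setdiff(S, res$subset)
  }
}

#' Find all delta-teams of two or more graphs over their shared vertices
#'
#' A delta-team is a maximal vertex set that is a delta-set (single-linkage
#' connected at threshold `delta` under the shortest-path distance) in
#' every input graph simultaneously. Teams partition the shared vertex set;
#' vertices unique to some graphs are excluded from teams but still carry
#' paths. Divide-and-conquer: SMALLMAX either certifies the working set or
#' splits it, and the recursion enumerates all teams.
#'
#' @param graphs list of >= 2 [weighted_graph()]s.
#' @param delta non-negative distance threshold.
#' @param mode `"direct"` runs the decomposition on the input graphs;
#'   `"threshold"` first converts each graph to its unit-weight threshold
#'   graph (distance `<= delta` becomes an edge) and computes 1-teams.
#' @return a `team_partition`: list with `teams` (list of sorted vertex
#'   sets, canonically ordered by smallest member) and `delta`.
#' @export
find_delta_teams <- function(graphs, delta, mode = c("direct", "threshold")) {
  mode <- match.arg(mode)
  if (length(graphs) < 2L)
    stop("need at least two graphs", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("`delta` must be a single non-negative number", call. = FALSE)
  shared <- Reduce(intersect, lapply(graphs, `[[`, "vertices"))
  if (!length(shared))
    stop("the graphs share no vertices", call. = FALSE)
  shared <- sort(shared)
  if (mode == "threshold") {
    tg <- lapply(graphs, build_threshold_graph,
                 candidate_vertices = shared, delta = delta)
    part <- find_delta_teams(tg, delta = 1, mode = "direct")
    part$delta <- delta
    return(part)
  }
  Ds <- lapply(graphs, function(g)
    graph_distances(g)[shared, shared, drop = FALSE])
  acc <- new.env(parent = emptyenv())
  acc$teams <- list()
  .decompose_core(Ds, shared, delta, acc)
  teams <- acc$teams[order(vapply(acc$teams, `[`, "", 1L))]
  structure(list(teams = teams, delta = delta), class = "team_partition")
}

#' @rdname find_delta_teams
#' @export
find_teams_via_threshold <- function(graphs, delta) {
  find_delta_teams(graphs, delta, mode = "threshold")
}

#' @export
print.team_partition <- function(x, ...) {
  cat(sprintf("<team_partition> delta = %g, %d team(s)\n",
              x$delta, length(x$teams)))
  for (i in seq_along(x$teams))
    cat(sprintf("  %d: {%s}\n", i, paste(x$teams[[i]], collapse = ", ")))
  invisible(x)
}

#' Write a team partition to the tab-separated report format
#'
#' Columns: `team_id  delta  size  members` (comma-joined, sorted).
#'
#' @param partition a `team_partition`.
#' @param path output file.
#' @export
write_team_partition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# team_id\tdelta\tsize\tmembers", con)
  for (i in seq_along(partition$teams)) {
    tm <- partition$teams[[i]]
    writeLines(sprintf("%d\t%g\t%d\t%s", i, partition$delta, length(tm),
                       paste(tm, collapse = ",")), con)
  }
  invisible(path)
}
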