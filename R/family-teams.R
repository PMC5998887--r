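# delta-teams with families: vertices carry gene-family labels, and
# correspondence across graphs is by family rather than by identity.
# The recursion follows a two-branch split: when a
# proper maximal delta-set B is found in one graph, recurse on B with the
# other graphs restricted to B's family spectrum, and on the remainder
# with the complementary restriction. Branches may overlap, so outputs
# are deduplicated by their tuple of sorted vertex sets.

#' Weighted graph with gene-family labels
#'
#' @param graph a [weighted_graph()].
#' @param family_of named character vector mapping every vertex of `graph`
#'   to its family identifier (total mapping).
#' @return an object of class `family_graph`.
#' @export
family_graph <- function(graph, family_of) {
  stopifnot(inherits(graph, "weighted_graph"))
  family_of <- stats::setNames(as.character(family_of), names(family_of))
  missing <- setdiff(graph$vertices, names(family_of))
  if (length(missing))
    stop("vertices without family label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(graph = graph,
                 family_of = family_of[graph$vertices]),
            class = "family_graph")
}

#' @export
print.family_graph <- function(x, ...) {
  cat(sprintf("<family_graph> %d vertices, %d families, %d edges\n",
              length(x$graph$vertices), length(unique(x$family_of)),
              nrow(x$graph$edges)))
  invisible(x)
}

#' Family spectrum of a vertex set
#'
#' @param graph a [family_graph()].
#' @param vertices vertex subset.
#' @return sorted character vector of the distinct family labels.
#' @export
family_spectrum <- function(graph, vertices) {
  vertices <- as.character(vertices)
  unknown <- setdiff(vertices, graph$graph$vertices)
  if (length(unknown))
    stop("unknown vertex id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sort(unique(unname(graph$family_of[vertices])))
}

#' Family index: members of each family per graph
#'
#' @param graph a [family_graph()].
#' @return named list family -> sorted vertex ids.
#' @export
family_index <- function(graph) {
  split(names(graph$family_of), unname(graph$family_of))
}

#' Restrict a member set to vertices whose family lies in a spectrum
#'
#' @param graph a [family_graph()].
#' @param member_set vertex subset.
#' @param spectrum family identifiers to keep.
#' @return the filtered, sorted vertex set.
#' @export
restrict_by_families <- function(graph, member_set, spectrum) {
  member_set <- as.character(member_set)
  sort(member_set[unname(graph$family_of[member_set]) %in% spectrum])
}

# restrict every member set to the common family spectrum until stable;
# returns NULL when any set empties out (no team can live here)
.normalize_spectra <- function(fams, member_sets) {
  repeat {
    spectra <- Map(function(f, s) unique(unname(f[s])), fams, member_sets)
    common <- Reduce(intersect, spectra)
    if (!length(common)) return(NULL)
    new_sets <- Map(function(f, s) s[unname(f[s]) %in% common],
                    fams, member_sets)
    if (any(!lengths(new_sets))) return(NULL)
    if (identical(lengths(new_sets), lengths(member_sets)))
      return(new_sets)
    member_sets <- new_sets
  }
}

.team_key <- function(vertex_sets) {
  paste(vapply(vertex_sets, function(s) paste(sort(s), collapse = ","), ""),
        collapse = "|")
}

.decompose_families_core <- function(Ds, fams, member_sets, delta, acc) {
  member_sets <- .normalize_spectra(fams, member_sets)
  if (is.null(member_sets)) return(invisible(NULL))
  res <- .smallmax_core(Ds, member_sets, delta)
  if (!res$proper) {
    sets <- lapply(member_sets, sort)
    key <- .team_key(sets)
    if (is.null(acc$seen[[key]])) {
      acc$seen[[key]] <- TRUE
      acc$teams[[length(acc$teams) + 1L]] <- sets
    }
    return(invisible(NULL))
  }
  x <- res$graph
  B <- res$subset
  rest <- setdiff(member_sets[[x]], B)
  spec_b <- unique(unname(fams[[x]][B]))
  spec_r <- unique(unname(fams[[x]][rest]))
  branch_b <- Map(function(f, s) s[unname(f[s]) %in% spec_b],
                  fams, member_sets)
  branch_b[[x]] <- B
  branch_r <- Map(function(f, s) s[unname(f[s]) %in% spec_r],
                  fams, member_sets)
  branch_r[[x]] <- rest
  .decompose_families_core(Ds, fams, branch_b, delta, acc)
  .decompose_families_core(Ds, fams, branch_r, delta, acc)
  invisible(NULL)
}

#' Two-branch family decomposition on explicit member sets
#'
#' Low-level entry point appending every family delta-team contained
#' component-wise in `member_sets` to a fresh accumulator. Member sets
#' must have equal family spectra on entry.
#'
#' @param graphs list of [family_graph()]s.
#' @param member_sets list of one vertex set per graph.
#' @param delta non-negative threshold.
#' @return list of teams; each team is a list of per-graph vertex sets.
#' @export
decompose_families <- function(graphs, member_sets, delta) {
  member_sets <- lapply(member_sets, as.character)
  fams <- lapply(graphs, `[[`, "family_of")
  spectra <- Map(function(f, s) sort(unique(unname(f[s]))),
                 fams, member_sets)
  if (!all(vapply(spectra[-1L], identical, TRUE, spectra[[1L]])))
    stop("member sets must have equal family spectra", call. = FALSE)
  Ds <- lapply(graphs, function(fg) graph_distances(fg$graph))
  acc <- new.env(parent = emptyenv())
  acc$teams <- list(); acc$seen <- list()
  .decompose_families_core(Ds, fams, member_sets, delta, acc)
  acc$teams
}

#' Find all delta-teams with families across two or more labelled graphs
#'
#' A family delta-team is a maximal tuple of per-graph vertex sets with
#' identical family spectra, each set being a delta-set in its own graph.
#' Vertices whose family is absent from any input graph are removed up
#' front (they still serve as path intermediates); unlike the shared-vertex
#' case, teams may overlap in family labels, so the result is a list, not
#' a partition.
#'
#' @param graphs list of >= 2 [family_graph()]s.
#' @param delta non-negative threshold.
#' @param min_size drop teams whose largest per-graph vertex set is
#'   smaller than this (1 keeps singleton teams).
#' @return object of class `family_teams`: list of teams, each a list with
#'   `vertex_sets` (per graph, sorted) and `spectrum`; canonically ordered.
#' @export
find_delta_teams_families <- function(graphs, delta, min_size = 1L) {
  if (length(graphs) < 2L)
    stop("need at least two graphs", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("`delta` must be a single non-negative number", call. = FALSE)
  fams <- lapply(graphs, `[[`, "family_of")
  universes <- lapply(fams, function(f) unique(unname(f)))
  common <- Reduce(intersect, universes)
  if (!length(common))
    stop("the graphs share no gene families", call. = FALSE)
  member_sets <- lapply(fams, function(f) sort(names(f)[unname(f) %in% common]))
  dropped <- sum(lengths(fams) - lengths(member_sets))
  if (dropped > 0)
    message(sprintf("dropped %d vertex(es) of families absent from some graph",
                    dropped))
  Ds <- lapply(graphs, function(fg) graph_distances(fg$graph))
  acc <- new.env(parent = emptyenv())
  acc$teams <- list(); acc$seen <- list()
  .decompose_families_core(Ds, fams, member_sets, delta, acc)
  teams <- lapply(acc$teams, function(sets) {
    list(vertex_sets = sets,
         spectrum = sort(unique(unname(fams[[1L]][sets[[1L]]]))))
  })
  sizes <- vapply(teams, function(t) max(lengths(t$vertex_sets)), 0L)
  teams <- teams[sizes >= min_size]
  ord <- order(vapply(teams, function(t) paste(t$spectrum, collapse = ","), ""),
               vapply(teams, function(t) .team_key(t$vertex_sets), ""))
  structure(list(teams = teams[ord], delta = delta,
                 n_graphs = length(graphs)),
            class = "family_teams")
}

#' @export
print.family_teams <- function(x, ...) {
  cat(sprintf("<family_teams> delta = %g, %d team(s) across %d graphs\n",
              x$delta, length(x$teams), x$n_graphs))
  for (i in seq_along(x$teams)) {
    t <- x$teams[[i]]
    cat(sprintf("  %d: families {%s} | %s\n", i,
                paste(t$spectrum, collapse = ","),
                paste(vapply(t$vertex_sets,
                             function(s) paste(s, collapse = ","), ""),
                      collapse = " / ")))
  }
  invisible(x)
}

#' Write / read the family-team report format
#'
#' Tab-separated columns: `team_id  delta  families  <one column per
#' graph>`, vertex sets comma-joined and sorted.
#'
#' @param teams a `family_teams` object.
#' @param path file path.
#' @param graph_names column names for the per-graph vertex sets.
#' @export
write_family_teams <- function(teams, path,
                               graph_names = paste0("graph", seq_len(teams$n_graphs))) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# team_id", "delta", "families", graph_names),
                   collapse = "\t"), con)
  for (i in seq_along(teams$teams)) {
    t <- teams$teams[[i]]
    writeLines(paste(c(i, sprintf("%g", teams$delta),
                       paste(t$spectrum, collapse = ","),
                       vapply(t$vertex_sets,
                              function(s) paste(s, collapse = ","), "")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_family_teams
#' @export
read_family_teams <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)][1L]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cols <- strsplit(sub("^#\\s*", "", hdr), "\t", fixed = TRUE)[[1L]]
  n_graphs <- length(cols) - 3L
  teams <- lapply(strsplit(lines, "\t", fixed = TRUE), function(p) {
    list(vertex_sets = lapply(p[seq(4L, 3L + n_graphs)],
                              function(s) sort(strsplit(s, ",", fixed = TRUE)[[1L]])),
         spectrum = sort(strsplit(p[3L], ",", fixed = TRUE)[[1L]]))
  })
  delta <- if (length(lines)) {
    as.numeric(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][2L])
  } else NA_real_
  structure(list(teams = teams, delta = delta, n_graphs = n_graphs),
            class = "family_teams")
}
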