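# shared test helpers: canonical keys for comparing team outputs, and a
# tiny path-graph builder

team_key <- function(partition) {
  vapply(partition$teams, paste, "", collapse = ",")
}

family_team_keys <- function(ft) {
  sort(vapply(ft$teams, function(t)
    paste(vapply(t$vertex_sets, paste, "", collapse = ","), collapse = "|"),
    ""))
}

path_graph <- function(ids, weights) {
  weighted_graph(data.frame(u = ids[-length(ids)], v = ids[-1L],
                            weight = weights))
}

# family sets of all teams with at least `min` vertices in graph 1
spectra_of <- function(ft, min = 2L) {
  keep <- vapply(ft$teams, function(t)
    max(lengths(t$vertex_sets)) >= min, TRUE)
  lapply(ft$teams[keep], function(t) t$spectrum)
}
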