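# Small worked-example instances with fully known team structure, used
# throughout the documentation and tests. Both are synthetic
# constructions (built for this package, verified against the
# brute-force oracle) exhibiting the canonical behaviour of the model:
# a 1-team nested inside a 2-team nested inside a 3-team, plus a
# non-maximal 3-cluster that must not be reported.

#' Seven-vertex worked example without families
#'
#' Two weighted graphs on vertices a..g whose delta-teams of size >= 2
#' are: the 1-team \{d, f\}; the 2-team \{c, d, f\}; and the 3-team
#' \{a, c, d, f, g\}. The set \{c, d, f, g\} is a 3-cluster of both
#' graphs but non-maximal, so it is never reported.
#'
#' @return list of two [weighted_graph()]s named `G` and `H`.
#' @export
example_team_graphs <- function() {
  G <- weighted_graph(data.frame(
    u = c("d", "c", "a", "f", "a", "e"),
    v = c("f", "d", "c", "g", "b", "g"),
    weight = c(1, 2, 3, 3, 4, 4)))
  H <- weighted_graph(data.frame(
    u = c("d", "c", "c", "a", "b", "e"),
    v = c("f", "f", "g", "g", "c", "f"),
    weight = c(1, 2, 3, 3, 4, 4)))
  list(G = G, H = H)
}

#' Seven-vertex worked example with families
#'
#' Two family-labelled graphs (disjoint vertex ids, family universe
#' a, c, d, e, f, g with family c duplicated) whose delta-teams of size
#' >= 2, identified by family spectrum, are: the 1-team \{d, f\}; the
#' 2-teams \{c, d, f\} and \{c, e\} (family c belongs to both); and the
#' 3-team \{a, c, d, f, g\}. The spectrum \{c, d, f, g\} corresponds to
#' a non-maximal 3-cluster.
#'
#' @return list of two [family_graph()]s named `G` and `H`.
#' @export
example_family_graphs <- function() {
  gG <- weighted_graph(data.frame(
    u = c("gd", "gc1", "ga", "gf", "gc2"),
    v = c("gf", "gd", "gc1", "gg", "ge"),
    weight = c(1, 2, 3, 3, 2)))
  famG <- c(ga = "a", gc1 = "c", gc2 = "c", gd = "d", ge = "e",
            gf = "f", gg = "g")
  gH <- weighted_graph(data.frame(
    u = c("hd", "hc1", "hc1", "ha", "hc2"),
    v = c("hf", "hf", "hg", "hg", "he"),
    weight = c(1, 2, 3, 3, 2)))
  famH <- c(ha = "a", hc1 = "c", hc2 = "c", hd = "d", he = "e",
            hf = "f", hg = "g")
  list(G = family_graph(gG, famG), H = family_graph(gH, famH))
}
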