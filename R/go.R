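# GO-based functional dissimilarity (GFD) and the gene-cluster penalty.
#
# GFD between two annotated genes is the minimum, over all pairs of their
# terms (u, v), of p(u, v) / (depth(u) + depth(v)), where p counts the
# nodes separating u and v on the shortest undirected path in the term
# DAG (adjacent terms separate by 0) and depth is the shortest root path
# in edges. The cluster penalty of a gene set is, summed over members,
# the nearest-GFD co-member minus the nearest-GFD gene genome-wide; it is
# always >= 0 because the genome-wide minimum ranges over a superset.
# Clusters are ranked by empirical p-values against pools of uniformly
# drawn size-matched gene sets.

#' Gene Ontology term DAG (one namespace)
#'
#' @param terms character vector of term ids.
#' @param parents named list term -> character vector of `is_a` parents
#'   (empty for the root).
#' @return object of class `go_dag` with `terms`, `parents`, `root` and
#'   `depth` (shortest root path, in edges).
#' @export
go_dag <- function(terms, parents) {
  parents <- parents[terms]
  roots <- terms[lengths(parents) == 0L]
  if (length(roots) != 1L)
    stop(sprintf("namespace must have exactly one root (found %d)",
                 length(roots)), call. = FALSE)
  el <- do.call(rbind, lapply(terms, function(t) {
    ps <- parents[[t]]
    if (!length(ps)) return(NULL)
    cbind(ps, t)
  }))
  ig <- igraph::make_empty_graph(n = 0, directed = TRUE)
  ig <- igraph::add_vertices(ig, length(terms), name = terms)
  if (!is.null(el)) ig <- igraph::add_edges(ig, t(el))
  if (!igraph::is_dag(ig))
    stop("term hierarchy is cyclic", call. = FALSE)
  depth <- suppressWarnings(
    igraph::distances(ig, v = roots, mode = "out")[1L, terms])
  if (any(!is.finite(depth)))
    stop("term(s) unreachable from the root: ",
         paste(terms[!is.finite(depth)], collapse = ", "), call. = FALSE)
  structure(list(terms = terms, parents = parents, root = roots,
                 depth = stats::setNames(as.integer(depth), terms),
                 .igraph = ig, .cache = new.env()),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, root %s, max depth %d\n",
              length(x$terms), x$root, max(x$depth)))
  invisible(x)
}

#' Pairwise term separation matrix
#'
#' Number of separating (intermediate) nodes on the shortest path between
#' every term pair in the undirected view of the DAG: 0 for identical or
#' adjacent terms, path-length-minus-one otherwise.
#'
#' @param dag a [go_dag()].
#' @return integer matrix with term dimnames (cached on the dag).
#' @export
term_separation_matrix <- function(dag) {
  if (is.null(dag$.cache$sep)) {
    D <- igraph::distances(igraph::as_undirected(dag$.igraph))
    D <- D[dag$terms, dag$terms]
    dag$.cache$sep <- pmax(D - 1, 0)
  }
  dag$.cache$sep
}

#' Separation between two terms
#'
#' @param dag a [go_dag()].
#' @param u,v term ids.
#' @return non-negative integer (0 when equal or adjacent), `Inf` for
#'   disconnected terms (cannot occur within one rooted namespace).
#' @export
term_path_separation <- function(dag, u, v) {
  unknown <- setdiff(c(u, v), dag$terms)
  if (length(unknown))
    stop("unknown term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (identical(u, v)) return(0)
  term_separation_matrix(dag)[u, v]
}

#' Parse an OBO v1.2 subset and GAF-like annotations
#'
#' Reads `[Term]` stanzas (id, name, namespace, `is_a`, `is_obsolete`)
#' restricted to one namespace, dropping obsolete terms, and a
#' tab-separated `gene_id go_term` annotation table. Annotations to
#' unknown terms are dropped with a warning; genes with no surviving
#' term are excluded.
#'
#' @param obo_path path to the OBO file.
#' @param gaf_path path to the two-column annotation TSV.
#' @param namespace namespace to keep (case/space-insensitive match
#'   against the stanza `namespace:`; default "biological_process").
#' @return list with `dag` (a [go_dag()]) and `annotations` (named list
#'   gene -> character vector of terms).
#' @export
load_go <- function(obo_path, gaf_path,
                    namespace = "biological_process") {
  norm_ns <- function(x) gsub("[ _]", "", tolower(x))
  lines <- readLines(obo_path)
  starts <- grep("^\\[Term\\]$", lines)
  bounds <- c(starts, length(lines) + 1L)
  terms <- character(); parents <- list()
  for (s in seq_along(starts)) {
    stanza <- lines[seq(bounds[s], bounds[s + 1L] - 1L)]
    field <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), stanza, value = TRUE))
      sub("\\s*!.*$", "", v)
    }
    if (any(grepl("^is_obsolete:\\s*true", stanza))) next
    ns <- field("namespace")
    if (length(ns) && norm_ns(ns[1L]) != norm_ns(namespace)) next
    id <- field("id")[1L]
    isa <- field("is_a")
    terms <- c(terms, id)
    parents[[id]] <- isa
  }
  if (!length(terms))
    stop("no terms in namespace ", namespace, call. = FALSE)
  # is_a links out of the namespace are dropped
  parents <- lapply(parents, function(p) intersect(p, terms))
  dag <- go_dag(terms, parents)
  gaf <- utils::read.table(gaf_path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "go_term"))
  known <- gaf$go_term %in% dag$terms
  if (any(!known))
    warning(sprintf("dropping %d annotation(s) to unknown terms",
                    sum(!known)), call. = FALSE)
  gaf <- gaf[known, , drop = FALSE]
  ann <- lapply(split(gaf$go_term, gaf$gene_id), unique)
  list(dag = dag, annotations = ann)
}

# GFD ratio matrix over a set of terms: sep / (depth_u + depth_v), with
# the degenerate root-root pair (0/0) defined as 0
.gfd_ratio_matrix <- function(dag, terms) {
  sep <- term_separation_matrix(dag)[terms, terms, drop = FALSE]
  dsum <- outer(dag$depth[terms], dag$depth[terms], `+`)
  R <- sep / dsum
  R[sep == 0 & dsum == 0] <- 0
  R
}

#' GO-based functional dissimilarity between two genes
#'
#' Minimum over all term pairs of `separation / (depth_u + depth_v)`;
#' 0 whenever the genes share a term. Symmetric.
#'
#' @param dag a [go_dag()].
#' @param annotations named list gene -> terms.
#' @param g1,g2 distinct annotated gene ids.
#' @return non-negative real.
#' @export
gene_gfd <- function(dag, annotations, g1, g2) {
  t1 <- annotations[[g1]]; t2 <- annotations[[g2]]
  if (is.null(t1) || is.null(t2))
    stop("both genes must be annotated", call. = FALSE)
  R <- .gfd_ratio_matrix(dag, union(t1, t2))
  min(R[t1, t2])
}

#' Precomputed GFD scorer for a genome
#'
#' Computes the gene-by-gene GFD matrix and each gene's genome-wide
#' nearest-GFD value once; [cluster_penalty()], [sample_null()] and
#' [score_clusters()] reuse it.
#'
#' @param dag a [go_dag()].
#' @param annotations named list gene -> terms; genes with no terms are
#'   excluded.
#' @return object of class `go_scorer`.
#' @export
go_scorer <- function(dag, annotations) {
  annotations <- annotations[lengths(annotations) > 0L]
  genes <- sort(names(annotations))
  annotations <- annotations[genes]
  terms <- sort(unique(unlist(annotations)))
  unknown <- setdiff(terms, dag$terms)
  if (length(unknown))
    stop("annotations reference unknown terms: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(vapply(annotations, function(t) all(t == dag$root), TRUE)))
    warning("gene(s) annotated only to the root term are trivially similar",
            call. = FALSE)
  R <- .gfd_ratio_matrix(dag, terms)
  n <- length(genes)
  G <- matrix(0, n, n, dimnames = list(genes, genes))
  idx <- lapply(annotations, function(t) match(t, terms))
  for (i in seq_len(n - 1L)) {
    Ri <- R[idx[[i]], , drop = FALSE]
    for (j in seq(i + 1L, n)) {
      G[i, j] <- G[j, i] <- min(Ri[, idx[[j]]])
    }
  }
  Ginf <- G; diag(Ginf) <- Inf
  nearest <- apply(Ginf, 1L, min)
  structure(list(genes = genes, gfd = G, nearest = nearest),
            class = "go_scorer")
}

#' @export
print.go_scorer <- function(x, ...) {
  cat(sprintf("<go_scorer> %d annotated genes\n", length(x$genes)))
  invisible(x)
}

.penalty_idx <- function(scorer, idx) {
  sub <- scorer$gfd[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  sum(apply(sub, 1L, min) - scorer$nearest[idx])
}

#' Gene cluster penalty
#'
#' Sum over cluster genes of (nearest-GFD co-member) minus (nearest-GFD
#' gene genome-wide, excluding the gene itself); always >= 0, and 0 when
#' every member's closest functional neighbour lies inside the cluster.
#'
#' @param scorer a [go_scorer()].
#' @param cluster_genes >= 2 annotated gene ids.
#' @return non-negative real; `NA` (with a message) when fewer than two
#'   cluster genes are annotated — such clusters are unscorable.
#' @export
cluster_penalty <- function(scorer, cluster_genes) {
  idx <- match(cluster_genes, scorer$genes)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2L) {
    message("cluster has fewer than two annotated genes; not scored")
    return(NA_real_)
  }
  .penalty_idx(scorer, idx)
}

#' Null pool of penalties for a given cluster size
#'
#' Draws `n_pool` uniform size-`size` subsets (without replacement within
#' a draw) of the annotated genome and returns their penalties. Seeded
#' and reproducible.
#'
#' @param scorer a [go_scorer()].
#' @param size cluster size (>= 2).
#' @param n_pool number of draws.
#' @param seed integer seed.
#' @return numeric vector of length `n_pool`.
#' @export
sample_null <- function(scorer, size, n_pool, seed) {
  n <- length(scorer$genes)
  if (size < 2L) stop("`size` must be >= 2", call. = FALSE)
  if (size > n) stop("`size` exceeds the annotated genome", call. = FALSE)
  set.seed(seed)
  vapply(seq_len(n_pool), function(i)
    .penalty_idx(scorer, sample.int(n, size)), 0)
}

#' Empirical p-value of a penalty against a null pool
#'
#' `(# pool values <= phi + 1) / (N + 1)`: lower penalty (more functional
#' coherence) gives lower p; the smallest attainable value is 1/(N+1).
#'
#' @param phi observed penalty.
#' @param pool numeric vector from [sample_null()].
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(phi, pool) {
  if (!length(pool)) stop("empty pool", call. = FALSE)
  (sum(pool <= phi) + 1) / (length(pool) + 1)
}

#' Score and rank gene cluster candidates
#'
#' Computes the penalty of each cluster, an empirical p-value against a
#' per-size null pool (pools cached across clusters of equal size), and
#' ranks ascending by p, tie-broken by ascending penalty, descending
#' size, then cluster id. Clusters with fewer than two annotated genes
#' are reported unscorable (NA penalty and p).
#'
#' @param scorer a [go_scorer()].
#' @param clusters named list cluster id -> gene ids.
#' @param n_pool pool size N per cluster size (default 1e5 desk-scale;
#'   1e7 reproduces publication-scale pools).
#' @param seed integer seed (per-size pool seeds derive from it).
#' @return data frame `cluster_id size phi p_value significant`
#'   (significant at p < 0.05), ranked; class `penalty_report`.
#' @export
score_clusters <- function(scorer, clusters, n_pool = 1e5, seed = 1L) {
  sizes <- vapply(clusters, function(g)
    sum(g %in% scorer$genes), 0L)
  pools <- list()
  res <- data.frame(cluster_id = names(clusters),
                    size = sizes,
                    phi = NA_real_, p_value = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (i in seq_along(clusters)) {
    if (sizes[i] < 2L) next
    phi <- suppressMessages(cluster_penalty(scorer, clusters[[i]]))
    key <- as.character(sizes[i])
    if (is.null(pools[[key]]))
      pools[[key]] <- sample_null(scorer, sizes[i], n_pool,
                                  seed = seed + sizes[i])
    res$phi[i] <- phi
    res$p_value[i] <- empirical_pvalue(phi, pools[[key]])
  }
  res$significant <- res$p_value < 0.05
  rank_clusters(res)
}

#' Order a penalty report by significance
#'
#' @param results data frame with columns `cluster_id`, `size`, `phi`,
#'   `p_value` (+ optionally `significant`).
#' @return the ranked data frame (unscorable clusters last).
#' @export
rank_clusters <- function(results) {
  if (!nrow(results)) return(results)
  if (is.null(results$significant))
    results$significant <- results$p_value < 0.05
  ord <- order(is.na(results$p_value), results$p_value, results$phi,
               -results$size, results$cluster_id)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("penalty_report", "data.frame")
  out
}
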