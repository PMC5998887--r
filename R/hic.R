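# Hi-C ingestion and transformation into weighted gene graphs.
#
# Contact counts are closeness scores; the dissimilarity between genes in
# segments i, j of a (normalized) map M is max(M) + 1 - M_ij, so the
# densest contact gives the smallest distance (1) and an empty cell the
# largest finite one (max + 1). Maps are first rescaled so every map's
# maximum equals c, the average per-map maximum across all maps of all
# genomes, making distances from different experiments comparable.
# Same-segment gene pairs (and empty adjacent-diagonal cells) are scored
# by an estimator built from C, the mean non-empty adjacent-segment count.

#' Hi-C contact map container
#'
#' @param counts numeric matrix of non-negative contact counts.
#' @param chrom_a,chrom_b chromosome names (equal for intrachromosomal,
#'   `chrom_b` defaults to `chrom_a`).
#' @param resolution_bp segment (bin) size in base pairs.
#' @return object of class `hic_map`. Intrachromosomal maps are
#'   symmetrized with the pairwise maximum, warning when entries disagree.
#' @export
hic_map <- function(counts, chrom_a, chrom_b = chrom_a, resolution_bp) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("contact counts must be non-negative and non-missing",
         call. = FALSE)
  intra <- identical(chrom_a, chrom_b)
  if (intra) {
    if (nrow(counts) != ncol(counts))
      stop("intrachromosomal map must be square", call. = FALSE)
    tc <- t(counts)
    if (any(counts != tc)) {
      warning(sprintf("symmetrizing %d asymmetric cell(s) with the maximum",
                      sum(counts != tc) %/% 2L), call. = FALSE)
      counts <- pmax(counts, tc)
    }
  }
  structure(list(chrom_a = chrom_a, chrom_b = chrom_b,
                 resolution_bp = as.integer(resolution_bp),
                 counts = unname(counts), intra = intra),
            class = "hic_map")
}

#' @export
print.hic_map <- function(x, ...) {
  cat(sprintf("<hic_map> %s x %s, %d x %d bins @ %d bp, max %g\n",
              x$chrom_a, x$chrom_b, nrow(x$counts), ncol(x$counts),
              x$resolution_bp, max(x$counts)))
  invisible(x)
}

#' Read a Hi-C map from a dense-matrix or sparse-triple text file
#'
#' Dense files hold whitespace-separated matrix rows; sparse files hold
#' tab- or whitespace-separated `bin_i bin_j count` triples with 0-based
#' bin indices (intrachromosomal triples populate both (i,j) and (j,i)).
#'
#' @param path file path.
#' @param format `"dense"` or `"sparse"`.
#' @param resolution_bp bin size in base pairs.
#' @param chrom_a,chrom_b chromosome names.
#' @param n_bins_a,n_bins_b matrix dimensions for sparse input (inferred
#'   from the largest bin index when omitted).
#' @return a [hic_map()].
#' @export
read_hic_map <- function(path, format = c("dense", "sparse"),
                         resolution_bp, chrom_a, chrom_b = chrom_a,
                         n_bins_a = NULL, n_bins_b = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  if (format == "dense") {
    nf <- lengths(rows)
    if (length(unique(nf)) != 1L)
      stop(sprintf("ragged dense matrix at line %d of %s",
                   lineno[which(nf != nf[1L])[1L]], path), call. = FALSE)
    vals <- suppressWarnings(as.numeric(unlist(rows)))
    if (anyNA(vals))
      stop("non-numeric contact count in ", path, call. = FALSE)
    M <- matrix(vals, nrow = length(rows), byrow = TRUE)
  } else {
    bad <- which(lengths(rows) != 3L)
    if (length(bad))
      stop(sprintf("sparse triple with %d field(s) at line %d of %s",
                   lengths(rows)[bad[1L]], lineno[bad[1L]], path),
           call. = FALSE)
    trip <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                   ncol = 3L, byrow = TRUE)
    if (anyNA(trip))
      stop("non-numeric sparse triple in ", path, call. = FALSE)
    na <- if (is.null(n_bins_a)) max(trip[, 1L]) + 1L else n_bins_a
    nb <- if (is.null(n_bins_b)) {
      if (identical(chrom_a, chrom_b)) na else max(trip[, 2L]) + 1L
    } else n_bins_b
    if (identical(chrom_a, chrom_b)) na <- nb <- max(na, nb)
    if (any(trip[, 1L] >= na | trip[, 2L] >= nb | trip[, 1:2] < 0))
      stop("bin index out of range in ", path, call. = FALSE)
    M <- matrix(0, na, nb)
    M[trip[, 1:2, drop = FALSE] + 1L] <- trip[, 3L]
    if (identical(chrom_a, chrom_b))
      M[trip[, 2:1, drop = FALSE] + 1L] <- trip[, 3L]
  }
  if (any(M < 0)) stop("negative contact count in ", path, call. = FALSE)
  hic_map(M, chrom_a = chrom_a, chrom_b = chrom_b,
          resolution_bp = resolution_bp)
}

#' Global normalization scale c: average per-map maximum
#'
#' @param maps list of [hic_map()] across ALL genomes of the run.
#' @return the arithmetic mean of the per-map maxima.
#' @export
compute_scale <- function(maps) {
  if (!length(maps)) stop("no maps supplied", call. = FALSE)
  mx <- vapply(maps, function(m) max(m$counts), 0)
  if (all(mx == 0))
    stop("all maps are empty; nothing to normalize", call. = FALSE)
  mean(mx)
}

#' Rescale a map so its maximum count equals c
#'
#' Every entry is multiplied by `c / max(M)`. Zero-maximum maps are
#' returned unchanged with a warning (their genes keep only
#' sequential-estimator edges).
#'
#' @param map a [hic_map()].
#' @param c_scale the shared scale from [compute_scale()].
#' @return the rescaled [hic_map()].
#' @export
normalize_map <- function(map, c_scale) {
  mx <- max(map$counts)
  if (mx == 0) {
    warning(sprintf("map %s-%s has no counts; skipping normalization",
                    map$chrom_a, map$chrom_b), call. = FALSE)
    return(map)
  }
  map$counts <- map$counts * (c_scale / mx)
  map
}

#' Mean contact count between adjacent segments (the constant C)
#'
#' Mean of the non-empty superdiagonal cells M[i, i+1] of an
#' intrachromosomal map. When every adjacent cell is empty, the map
#' maximum is used as a fallback with a warning.
#'
#' @param map an intrachromosomal [hic_map()].
#' @return numeric scalar.
#' @export
adjacency_mean <- function(map) {
  if (!map$intra)
    stop("adjacency mean is defined for intrachromosomal maps",
         call. = FALSE)
  n <- nrow(map$counts)
  adj <- map$counts[cbind(seq_len(n - 1L), seq(2L, n))]
  adj <- adj[adj > 0]
  if (!length(adj)) {
    warning("all adjacent-segment cells empty; using map maximum as C",
            call. = FALSE)
    return(max(map$counts))
  }
  mean(adj)
}

#' Read a BED-like gene annotation table
#'
#' Tab-separated `chrom start end gene_id family_id`, 0-based half-open
#' coordinates, `#` comments allowed.
#'
#' @param path file path.
#' @return data frame with those five columns plus `midpoint`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "gene_id", "family_id"))
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (any(ann$start >= ann$end))
    stop("annotation has start >= end", call. = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene ids in annotation", call. = FALSE)
  ann$midpoint <- floor((ann$start + ann$end) / 2)
  ann
}

#' Map genes to Hi-C segments by their midpoint
#'
#' @param annotation annotation data frame (see [read_annotation()]).
#' @param resolution_bp bin size.
#' @return integer vector of 0-based segment indices,
#'   `floor(midpoint / resolution_bp)`.
#' @export
assign_genes <- function(annotation, resolution_bp) {
  mid <- floor((annotation$start + annotation$end) / 2)
  as.integer(mid %/% resolution_bp)
}

#' Contact-to-distance transform of a (normalized) map cell
#'
#' `max(M) + 1 - M[i,j]`: the largest count maps to distance 1, an empty
#' cell to the largest finite distance `max + 1`. Indices are 0-based
#' segment indices. The gene-identity case (distance 0) is handled by the
#' caller.
#'
#' @param map a [hic_map()].
#' @param i,j 0-based segment indices (row, column).
#' @return non-negative distance.
#' @export
contact_to_distance <- function(map, i, j) {
  max(map$counts) + 1 - map$counts[i + 1L, j + 1L]
}

#' Intra-segment / adjacent-gap distance estimator
#'
#' Scores the one-dimensional gap `b` (base pairs between gene midpoints)
#' as a distance. The default `"interpolate"` model scales the mean
#' adjacent-segment distance by the base-pair fraction,
#' `d = (b / r) * (map_max + 1 - C)`, so `b = r` reproduces the distance
#' of an average adjacent segment pair and `d -> 0` as `b -> 0`. The
#' literal `"count_per_bp"` reading, `d = b * C / r`, is kept as an
#' alternative.
#'
#' @param b non-negative base-pair gap between midpoints.
#' @param adjacency_mean the constant C of the map (see
#'   [adjacency_mean()]).
#' @param resolution_bp the map resolution r.
#' @param map_max maximum count of the (normalized) map.
#' @param model `"interpolate"` (default) or `"count_per_bp"`.
#' @return non-negative distance.
#' @export
intra_segment_distance <- function(b, adjacency_mean, resolution_bp,
                                   map_max,
                                   model = c("interpolate", "count_per_bp")) {
  model <- match.arg(model)
  if (any(b < 0)) stop("`b` must be non-negative", call. = FALSE)
  switch(model,
         interpolate = (b / resolution_bp) * (map_max + 1 - adjacency_mean),
         count_per_bp = b * adjacency_mean / resolution_bp)
}

# per-chromosome gene bookkeeping: 0-based segment, midpoint order
.gene_segments <- function(annotation, maps) {
  res_of <- list()
  nbin_of <- list()
  for (m in maps) {
    for (ch in unique(c(m$chrom_a, m$chrom_b))) {
      res_of[[ch]] <- m$resolution_bp
      nb <- if (identical(ch, m$chrom_a)) nrow(m$counts) else ncol(m$counts)
      nbin_of[[ch]] <- max(nbin_of[[ch]] %||% 0L, nb)
    }
  }
  ann <- annotation
  ann$segment <- NA_integer_
  ann$mapped <- FALSE
  for (ch in unique(ann$chrom)) {
    sel <- ann$chrom == ch
    if (is.null(res_of[[ch]])) next
    seg <- floor(ann$midpoint[sel] / res_of[[ch]])
    ok <- seg < nbin_of[[ch]]
    if (any(!ok))
      warning(sprintf("%d gene(s) on %s beyond the map extent",
                      sum(!ok), ch), call. = FALSE)
    ann$segment[sel] <- as.integer(seg)
    ann$mapped[sel] <- ok
  }
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chain same-segment genes in midpoint order with estimator edges
.intra_segment_edges <- function(ann_ch, C, r, map_max, model) {
  out <- list()
  for (sg in unique(ann_ch$segment[ann_ch$mapped])) {
    here <- ann_ch[ann_ch$mapped & ann_ch$segment == sg, , drop = FALSE]
    if (nrow(here) < 2L) next
    here <- here[order(here$midpoint, here$gene_id), , drop = FALSE]
    b <- diff(here$midpoint)
    out[[length(out) + 1L]] <- data.frame(
      u = here$gene_id[-nrow(here)], v = here$gene_id[-1L],
      weight = intra_segment_distance(b, C, r, map_max, model),
      stringsAsFactors = FALSE)
  }
  out
}

.map_pair_edges <- function(map, ann, C_of, model, sequential = FALSE) {
  out <- list()
  mx <- max(map$counts)
  r <- map$resolution_bp
  ann_a <- ann[ann$chrom == map$chrom_a & ann$mapped, , drop = FALSE]
  ann_b <- ann[ann$chrom == map$chrom_b & ann$mapped, , drop = FALSE]
  if (!nrow(ann_a) || !nrow(ann_b)) return(out)
  by_a <- split(seq_len(nrow(ann_a)), ann_a$segment)
  by_b <- split(seq_len(nrow(ann_b)), ann_b$segment)
  segs_a <- as.integer(names(by_a))
  segs_b <- as.integer(names(by_b))
  C <- if (map$intra) C_of[[map$chrom_a]] else NA_real_
  for (ia in seq_along(segs_a)) {
    for (ib in seq_along(segs_b)) {
      i <- segs_a[ia]; j <- segs_b[ib]
      if (map$intra && i >= j) next       # upper triangle only, i != j
      if (sequential && (!map$intra || j != i + 1L)) next
      ga <- ann_a[by_a[[ia]], , drop = FALSE]
      gb <- ann_b[by_b[[ib]], , drop = FALSE]
      cnt <- map$counts[i + 1L, j + 1L]
      pairs <- expand.grid(a = seq_len(nrow(ga)), b = seq_len(nrow(gb)))
      if (map$intra && j == i + 1L && cnt == 0) {
        # empty adjacent-diagonal cell: fill with the 1D estimator, using
        # the actual midpoint gap of each gene pair
        w <- intra_segment_distance(
          abs(gb$midpoint[pairs$b] - ga$midpoint[pairs$a]), C, r, mx, model)
      } else {
        w <- rep(mx + 1 - cnt, nrow(pairs))
      }
      out[[length(out) + 1L]] <- data.frame(
        u = ga$gene_id[pairs$a], v = gb$gene_id[pairs$b], weight = w,
        stringsAsFactors = FALSE)
    }
  }
  out
}

.build_gene_graph <- function(annotation, maps, model, delta_prune,
                              sequential) {
  annotation <- validate_annotation(annotation)
  ann <- .gene_segments(annotation, maps)
  C_of <- list()
  for (m in maps) if (m$intra) C_of[[m$chrom_a]] <- adjacency_mean(m)
  edges <- list()
  for (m in maps) {
    if (sequential && !m$intra) next
    edges <- c(edges, .map_pair_edges(m, ann, C_of, model, sequential))
  }
  for (ch in unique(ann$chrom)) {
    m_ch <- Filter(function(m) m$intra && identical(m$chrom_a, ch), maps)
    if (!length(m_ch)) next
    mx <- max(m_ch[[1L]]$counts)
    edges <- c(edges, .intra_segment_edges(ann[ann$chrom == ch, , drop = FALSE],
                                           C_of[[ch]], m_ch[[1L]]$resolution_bp,
                                           mx, model))
  }
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  if (!is.null(edges) && !is.null(delta_prune))
    edges <- edges[edges$weight <= delta_prune, , drop = FALSE]
  g <- weighted_graph(edges, vertices = ann$gene_id)
  family_graph(g, stats::setNames(ann$family_id, ann$gene_id))
}

#' Build the spatial (3D) gene graph of a genome
#'
#' Vertices are genes labelled by family. For every map cell (i, j),
#' i != j, with at least one gene in each segment, all gene pairs across
#' the two segments get an edge weighted by the contact-to-distance
#' transform (empty cells give the maximal finite distance, except empty
#' adjacent-diagonal cells which are filled by the 1D estimator);
#' interchromosomal maps contribute cross-chromosome edges; genes sharing
#' a segment are chained in midpoint order with estimator edges.
#'
#' @param annotation annotation data frame `chrom start end gene_id
#'   family_id` for one genome.
#' @param maps list of that genome's (normalized) [hic_map()]s.
#' @param model estimator model, see [intra_segment_distance()].
#' @param delta_prune optional: drop edges heavier than this (team-
#'   invariant when equal to the analysis delta).
#' @return a [family_graph()].
#' @export
build_spatial_graph <- function(annotation, maps, model = "interpolate",
                                delta_prune = NULL) {
  .build_gene_graph(annotation, maps, model, delta_prune, sequential = FALSE)
}

#' Build the sequential (1D) gene graph of a genome
#'
#' Same vertices as the spatial graph, but edges only between genes of
#' the same segment (chained) and of adjacent segments i, i+1 of
#' intrachromosomal maps — identical one-dimensional distances without
#' three-dimensional shortcuts.
#'
#' @inheritParams build_spatial_graph
#' @return a [family_graph()].
#' @export
build_sequential_graph <- function(annotation, maps, model = "interpolate",
                                   delta_prune = NULL) {
  .build_gene_graph(annotation, maps, model, delta_prune, sequential = TRUE)
}

#' Normalize all maps of all genomes and build their gene graphs
#'
#' Computes the shared scale c across every map of every genome, rescales,
#' and builds one graph per genome.
#'
#' @param genomes list as returned by [gen_synthetic_hic()]: each element
#'   has `annotation` and `maps`.
#' @param flavor `"spatial"` or `"sequential"`.
#' @param model estimator model.
#' @param delta_prune optional pruning threshold.
#' @return list of [family_graph()], one per genome.
#' @export
build_genome_graphs <- function(genomes, flavor = c("spatial", "sequential"),
                                model = "interpolate", delta_prune = NULL) {
  flavor <- match.arg(flavor)
  all_maps <- unlist(lapply(genomes, `[[`, "maps"), recursive = FALSE)
  res <- unique(vapply(all_maps, `[[`, 0L, "resolution_bp"))
  if (length(res) > 1L)
    message("maps of different resolutions in one run; ",
            "scales assimilated through the shared c")
  c_scale <- compute_scale(all_maps)
  build <- if (flavor == "spatial") build_spatial_graph else build_sequential_graph
  lapply(genomes, function(gen) {
    maps <- lapply(gen$maps, function(m)
      if (max(m$counts) > 0) normalize_map(m, c_scale) else m)
    build(gen$annotation, maps, model = model, delta_prune = delta_prune)
  })
}

#' Spatial gain: genes recruited only through 3D shortcuts
#'
#' For each 3D team (of reference-genome size >= 2), counts its
#' reference-genome genes contained in no 1D team of size >= 2, and
#' returns the mean over those 3D teams.
#'
#' @param teams_3d,teams_1d `family_teams` computed at the same delta on
#'   the spatial and sequential graphs.
#' @param reference index of the reference genome (default 1).
#' @return numeric scalar (NA when there is no 3D team of size >= 2).
#' @export
spatial_gain <- function(teams_3d, teams_1d, reference = 1L) {
  if (!identical(teams_3d$delta, teams_1d$delta))
    stop("team lists were computed at different delta", call. = FALSE)
  sets_3d <- lapply(teams_3d$teams, function(t) t$vertex_sets[[reference]])
  sets_3d <- sets_3d[lengths(sets_3d) >= 2L]
  if (!length(sets_3d)) return(NA_real_)
  sets_1d <- lapply(teams_1d$teams, function(t) t$vertex_sets[[reference]])
  covered <- unique(unlist(sets_1d[lengths(sets_1d) >= 2L]))
  mean(vapply(sets_3d, function(s) length(setdiff(s, covered)), 0L))
}
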