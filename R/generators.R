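# Seeded synthetic-data generators. Each generator is a pure function of
# its arguments including `seed`: the same call yields byte-identical
# output. They emulate only the statistical structure the method consumes
# (distance-decaying Hi-C counts with empty cells, planted spatial
# clusters, random rooted term DAGs with planted functional modules), not
# Hi-C biophysics.

#' Random team-discovery instance
#'
#' Generates `k` random weighted graphs over a shared vertex subset plus
#' per-graph private vertices (which can carry paths between shared
#' vertices), with integer weights drawn uniformly from a range. With
#' `families = TRUE` the graphs instead get disjoint vertex ids labelled
#' by a common family universe: one member per family per graph, plus
#' extra duplicate members at rate `dup_rate`.
#'
#' @param seed integer seed.
#' @param k number of graphs.
#' @param n_shared shared vertices (no-family) or families (family mode).
#' @param n_extra private vertices per graph (no-family mode).
#' @param density edge probability per vertex pair.
#' @param wrange integer weight range, e.g. `c(1, 5)`.
#' @param families generate a family-labelled instance?
#' @param dup_rate expected duplicate family members per family per graph.
#' @return list of [weighted_graph()]s, or of [family_graph()]s when
#'   `families = TRUE`.
#' @export
gen_team_instance <- function(seed, k = 2L, n_shared = 8L, n_extra = 2L,
                              density = 0.3, wrange = c(1L, 5L),
                              families = FALSE, dup_rate = 0.3) {
  set.seed(seed)
  rand_edges <- function(ids) {
    if (length(ids) < 2L) {
      return(data.frame(u = character(), v = character(), weight = numeric(),
                        stringsAsFactors = FALSE))
    }
    pr <- t(utils::combn(ids, 2L))
    on <- stats::runif(nrow(pr)) < density
    data.frame(u = pr[on, 1L], v = pr[on, 2L],
               weight = sample(seq(wrange[1L], wrange[2L]), sum(on),
                               replace = TRUE),
               stringsAsFactors = FALSE)
  }
  if (!families) {
    shared <- sprintf("v%02d", seq_len(n_shared))
    lapply(seq_len(k), function(x) {
      ids <- c(shared, if (n_extra > 0) sprintf("g%dx%02d", x, seq_len(n_extra)))
      weighted_graph(rand_edges(ids), vertices = ids)
    })
  } else {
    fam <- sprintf("F%02d", seq_len(n_shared))
    lapply(seq_len(k), function(x) {
      n_dup <- stats::rbinom(1L, n_shared, min(dup_rate, 1))
      labels <- c(fam, if (n_dup > 0) sample(fam, n_dup, replace = TRUE))
      ids <- sprintf("g%dv%02d", x, seq_along(labels))
      fg <- stats::setNames(labels, ids)
      family_graph(weighted_graph(rand_edges(ids), vertices = ids), fg)
    })
  }
}

#' Synthetic Hi-C maps and gene annotations with planted spatial clusters
#'
#' For each genome, intrachromosomal contact counts follow a power-law
#' distance decay `round(A * |i-j|^-alpha)` with multiplicative noise and
#' a configurable rate of empty (zero) cells; planted clusters are gene
#' sets whose segments receive mutual counts at `boost` (near the map
#' maximum), optionally spanning two chromosomes via an interchromosomal
#' map. Genes are placed one per occupied segment with orthologous family
#' labels shared across genomes.
#'
#' @param seed integer seed.
#' @param n_genomes number of genomes.
#' @param n_chrom chromosomes per genome.
#' @param n_seg segments (bins) per chromosome.
#' @param resolution_bp bin size in base pairs.
#' @param occupancy probability a segment holds a gene.
#' @param A background count scale at adjacent segments.
#' @param alpha distance-decay exponent.
#' @param noise_sd multiplicative log-normal noise sd.
#' @param zero_rate fraction of off-diagonal cells blanked to 0.
#' @param boost contact count of planted cluster segment pairs.
#' @param planted_size number of genes in the planted cluster (0 = none).
#' @param interchromosomal plant the cluster across chromosomes 1 and 2
#'   and emit the corresponding interchromosomal map?
#' @return list with one element per genome: `annotation` (data frame
#'   `chrom start end gene_id family_id`), `maps` (list of [hic_map()]),
#'   and `planted_families` (character vector, possibly empty).
#' @export
gen_synthetic_hic <- function(seed, n_genomes = 2L, n_chrom = 2L,
                              n_seg = 20L, resolution_bp = 40000L,
                              occupancy = 0.8, A = 20, alpha = 1,
                              noise_sd = 0.1, zero_rate = 0.1,
                              boost = 100, planted_size = 4L,
                              interchromosomal = FALSE) {
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  # shared gene layout: same occupied segments / families in every genome
  occ <- lapply(chroms, function(ch) which(stats::runif(n_seg) < occupancy))
  names(occ) <- chroms
  fam_ids <- sprintf("FAM%03d",
                     seq_len(sum(lengths(occ))))
  # planted cluster: families drawn from segments far apart (and on two
  # chromosomes when interchromosomal)
  planted <- character()
  planted_pos <- NULL
  if (planted_size > 0L) {
    pool <- do.call(rbind, lapply(seq_along(chroms), function(ci)
      data.frame(chrom = chroms[ci], seg = occ[[ci]],
                 stringsAsFactors = FALSE)))
    pool$fam <- fam_ids[seq_len(nrow(pool))]
    if (interchromosomal && n_chrom >= 2L) {
      h1 <- pool[pool$chrom == chroms[1L], ][seq_len(ceiling(planted_size / 2)), ]
      h2 <- pool[pool$chrom == chroms[2L], ][seq_len(floor(planted_size / 2)), ]
      planted_pos <- rbind(h1, h2)
    } else {
      cand <- pool[pool$chrom == chroms[1L], ]
      # spread the planted genes out along the chromosome
      pick <- round(seq(1L, nrow(cand), length.out = planted_size))
      planted_pos <- cand[unique(pick), ]
    }
    planted <- planted_pos$fam
  }
  make_intra <- function(ch) {
    M <- outer(seq_len(n_seg), seq_len(n_seg), function(i, j) {
      d <- abs(i - j)
      ifelse(d == 0, 2 * A, A * pmax(d, 1)^(-alpha))
    })
    M <- round(M * exp(matrix(stats::rnorm(n_seg^2, 0, noise_sd), n_seg)))
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    zero <- matrix(stats::runif(n_seg^2) < zero_rate, n_seg)
    zero[lower.tri(zero)] <- t(zero)[lower.tri(zero)]
    diag(zero) <- FALSE
    M[zero] <- 0
    if (length(planted)) {
      here <- planted_pos[planted_pos$chrom == ch, ]
      if (nrow(here) >= 2L) {
        for (a in seq_len(nrow(here) - 1L)) for (b in seq((a + 1L), nrow(here))) {
          M[here$seg[a], here$seg[b]] <- boost
          M[here$seg[b], here$seg[a]] <- boost
        }
      }
    }
    hic_map(M, chrom_a = ch, resolution_bp = resolution_bp)
  }
  lapply(seq_len(n_genomes), function(gi) {
    maps <- lapply(chroms, make_intra)
    if (interchromosomal && n_chrom >= 2L) {
      M <- matrix(0, n_seg, n_seg)
      p1 <- planted_pos[planted_pos$chrom == chroms[1L], ]
      p2 <- planted_pos[planted_pos$chrom == chroms[2L], ]
      for (a in seq_len(nrow(p1))) for (b in seq_len(nrow(p2)))
        M[p1$seg[a], p2$seg[b]] <- boost
      maps <- c(maps, list(hic_map(M, chrom_a = chroms[1L],
                                   chrom_b = chroms[2L],
                                   resolution_bp = resolution_bp)))
    }
    ann <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      segs <- occ[[ci]]
      if (!length(segs)) return(NULL)
      start <- (segs - 1L) * resolution_bp + round(resolution_bp / 4)
      data.frame(chrom = chroms[ci], start = start,
                 end = start + round(resolution_bp / 4),
                 gene_id = sprintf("g%d_%s_s%02d", gi, chroms[ci], segs),
                 family_id = NA_character_, stringsAsFactors = FALSE)
    }))
    ann$family_id <- fam_ids[seq_len(nrow(ann))]
    list(annotation = ann, maps = maps, planted_families = planted)
  })
}

#' Synthetic GO hierarchy and gene annotations with planted modules
#'
#' Builds a random rooted DAG in one namespace (every non-root term gets
#' one tree parent among earlier terms plus extra `is_a` links at rate
#' `extra_parent_p`) and annotates background genes to random non-root
#' terms. Planted functional modules are gene sets annotated to a common
#' anchor term (module radius 0) or to terms within `module_radius`
#' separating nodes of the anchor.
#'
#' @param seed integer seed.
#' @param n_terms number of DAG terms (including the root).
#' @param n_genes number of background genes.
#' @param extra_parent_p probability of a second parent per term.
#' @param terms_per_gene range of annotation counts per background gene.
#' @param n_modules number of planted modules.
#' @param module_size genes per module.
#' @param module_radius maximal separation from the anchor term.
#' @return list with `dag` (a `go_dag`), `annotations` (named list
#'   gene -> terms) and `modules` (list of gene-id vectors).
#' @export
gen_synthetic_go <- function(seed, n_terms = 150L, n_genes = 120L,
                             extra_parent_p = 0.2,
                             terms_per_gene = c(1L, 3L),
                             n_modules = 0L, module_size = 4L,
                             module_radius = 0L) {
  set.seed(seed)
  terms <- sprintf("T%04d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- terms
  parents[[1L]] <- character()
  for (i in seq(2L, n_terms)) {
    p <- terms[sample.int(i - 1L, 1L)]
    extra <- if (i > 2L && stats::runif(1) < extra_parent_p)
      terms[sample.int(i - 1L, 1L)] else character()
    parents[[i]] <- unique(c(p, extra))
  }
  dag <- go_dag(terms, parents)
  deep <- terms[dag$depth >= 2L]
  if (!length(deep)) deep <- terms[-1L]
  ann <- lapply(seq_len(n_genes), function(i) {
    n <- sample(seq(terms_per_gene[1L], terms_per_gene[2L]), 1L)
    sample(terms[-1L], n)
  })
  names(ann) <- sprintf("gene%04d", seq_len(n_genes))
  modules <- list()
  if (n_modules > 0L) {
    sep <- term_separation_matrix(dag)
    anchors <- sample(deep, n_modules, replace = n_modules > length(deep))
    for (m in seq_len(n_modules)) {
      near <- terms[sep[anchors[m], ] <= module_radius]
      gid <- sprintf("mod%02d_g%02d", m, seq_len(module_size))
      for (g in gid) ann[[g]] <- unique(sample(near, 1L))
      modules[[m]] <- gid
    }
  }
  list(dag = dag, annotations = ann, modules = modules)
}
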