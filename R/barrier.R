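# Monmonier maximum-difference barrier detection: a barrier is traced across
# the Voronoi dual of a Delaunay triangulation of the sampling sites, always
# crossing the Delaunay edge with the largest genetic distance. Ties break
# deterministically on the lowest population-id pair.

#' Delaunay triangulation of the population coordinates
#'
#' Coordinates are projected to a plane by an equirectangular projection
#' about the centroid before triangulating (adequate at a country-wide
#' extent). Collinear or duplicated points are jittered by 1e-6 degrees,
#' with a message.
#'
#' @param popmap a [population_map()] with >= 3 populations.
#' @param jitter jitter magnitude (degrees) for degenerate configurations.
#' @return A list of class `delaunay_graph`: `edges` (data frame `i`, `j`
#'   of population indices, `id1`, `id2`), `triangles` (matrix of point
#'   index triples), `xy` (projected coordinates), `popmap`.
#' @export
delaunay_graph <- function(popmap, jitter = 1e-6) {
  if (nrow(popmap) < 3) stop("need at least 3 populations")
  lat0 <- mean(popmap$lat)
  lon0 <- mean(popmap$lon)
  x <- (popmap$lon - lon0) * cos(lat0 * pi / 180)
  y <- popmap$lat - lat0
  degenerate <- function(x, y) {
    sd(x) == 0 || sd(y) == 0 || anyDuplicated(cbind(x, y)) > 0 ||
      abs(cor(x, y)) > 1 - 1e-12
  }
  if (degenerate(x, y)) {
    message("degenerate coordinates: jittering by ", jitter, " degrees")
    set.seed(sum(utf8ToInt(paste(popmap$id, collapse = ""))) %% 10000L)
    x <- x + runif(length(x), -jitter, jitter)
    y <- y + runif(length(y), -jitter, jitter)
  }
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  triangles <- t(vapply(tl, function(tr) sort(tr$ptNum), integer(3)))
  e <- unique(rbind(triangles[, c(1, 2), drop = FALSE],
                    triangles[, c(1, 3), drop = FALSE],
                    triangles[, c(2, 3), drop = FALSE]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  structure(list(edges = data.frame(i = e[, 1], j = e[, 2],
                                    id1 = popmap$id[e[, 1]],
                                    id2 = popmap$id[e[, 2]],
                                    stringsAsFactors = FALSE),
                 triangles = triangles, xy = cbind(x = x, y = y),
                 popmap = popmap),
            class = "delaunay_graph")
}

# triangles adjacent to each edge (edge key "i-j", i < j)
edge_key <- function(i, j) paste0(pmin(i, j), "-", pmax(i, j))

edge_triangles <- function(tri) {
  out <- list()
  for (t in seq_len(nrow(tri$triangles))) {
    v <- tri$triangles[t, ]
    for (k in list(c(1, 2), c(1, 3), c(2, 3))) {
      key <- edge_key(v[k[1]], v[k[2]])
      out[[key]] <- c(out[[key]], t)
    }
  }
  out
}

#' Trace Monmonier barriers
#'
#' Starting from the Delaunay edge with the maximal genetic distance, the
#' barrier extends across adjacent Voronoi edges, at each step crossing the
#' neighbouring Delaunay edge with the larger distance; it stops at the
#' convex-hull boundary or when every continuation would re-cross an edge
#' or re-enter a used triangle. With `n_barriers > 1`, subsequent barriers
#' are traced on the remaining edges (edge-disjoint paths).
#'
#' @param tri a [delaunay_graph()].
#' @param dist_matrix symmetric genetic distance matrix over the populations
#'   (same order as the population map).
#' @param n_barriers number of barriers to trace.
#' @return A list of class `barrier_result`: `barriers`, a list of data
#'   frames of crossed edges (`i`, `j`, `id1`, `id2`, `distance`) in path
#'   order.
#' @export
trace_barrier <- function(tri, dist_matrix, n_barriers = 1) {
  stopifnot(inherits(tri, "delaunay_graph"))
  dist_matrix <- as.matrix(dist_matrix)
  ed <- tri$edges
  dvals <- dist_matrix[cbind(ed$i, ed$j)]
  if (any(!is.finite(dvals))) stop("non-finite distance on a Delaunay edge")
  et <- edge_triangles(tri)
  keys <- edge_key(ed$i, ed$j)
  dist_of <- setNames(dvals, keys)
  # deterministic order: distance desc, then lowest pair
  rank_order <- order(-dvals, ed$i, ed$j)
  used_edges <- character(0)
  barriers <- list()
  other_edges_of <- function(t, key) {
    v <- tri$triangles[t, ]
    ks <- c(edge_key(v[1], v[2]), edge_key(v[1], v[3]), edge_key(v[2], v[3]))
    setdiff(ks, key)
  }
  for (b in seq_len(n_barriers)) {
    avail <- setdiff(keys[rank_order], used_edges)
    if (!length(avail)) break
    seed_key <- avail[1]
    path <- seed_key
    used_tri <- integer(0)
    # grow in both directions from the seed edge
    for (t0 in et[[seed_key]]) {
      cur_key <- seed_key
      cur_tri <- t0
      repeat {
        if (cur_tri %in% used_tri) break
        used_tri <- c(used_tri, cur_tri)
        cand <- other_edges_of(cur_tri, cur_key)
        cand <- setdiff(cand, c(path, used_edges))
        if (!length(cand)) break
        cd <- dist_of[cand]
        pick <- cand[order(-cd, cand)][1]
        path <- c(path, pick)
        # next triangle: the other triangle adjacent to the picked edge
        nt <- setdiff(et[[pick]], cur_tri)
        cur_key <- pick
        if (!length(nt)) break  # reached the convex hull
        cur_tri <- nt[1]
      }
    }
    idx <- match(path, keys)
    barriers[[b]] <- data.frame(i = ed$i[idx], j = ed$j[idx],
                                id1 = ed$id1[idx], id2 = ed$id2[idx],
                                distance = dvals[idx],
                                stringsAsFactors = FALSE)
    used_edges <- c(used_edges, path)
  }
  structure(list(barriers = barriers), class = "barrier_result")
}

#' Bootstrap support for the point-estimate barrier
#'
#' Re-traces the first barrier on each of a set of replicate distance
#' matrices and reports, for every edge crossed by the point-estimate
#' barrier, the percentage of replicates whose barrier crosses it.
#'
#' @param popmap a [population_map()].
#' @param matrices list of >= 2 replicate distance matrices (e.g. simulated
#'   F-ST matrices).
#' @param observed optional observed distance matrix for the point-estimate
#'   barrier; defaults to the element-wise mean of `matrices`.
#' @return A list of class `barrier_support`: `edges` (data frame of the
#'   point-estimate barrier with a `support` column in percent) and
#'   `n_matrices`.
#' @export
barrier_support <- function(popmap, matrices, observed = NULL) {
  if (length(matrices) < 2) stop("need at least 2 replicate matrices")
  tri <- delaunay_graph(popmap)
  observed <- observed %||% Reduce(`+`, matrices) / length(matrices)
  point <- trace_barrier(tri, observed)$barriers[[1]]
  pt_keys <- edge_key(point$i, point$j)
  hits <- setNames(numeric(length(pt_keys)), pt_keys)
  for (m in matrices) {
    bk <- trace_barrier(tri, m)$barriers[[1]]
    bkeys <- edge_key(bk$i, bk$j)
    hits[pt_keys %in% bkeys] <- hits[pt_keys %in% bkeys] + 1
  }
  point$support <- 100 * hits / length(matrices)
  structure(list(edges = point, n_matrices = length(matrices)),
            class = "barrier_support")
}

#' Simulated Phi-ST matrices for the barrier bootstrap
#'
#' Generates replicate distance matrices by re-simulating each population's
#' sequences under its fitted sudden-expansion model (populations evolve
#' from a shared ancestral sequence) and recomputing the pairwise Phi-ST
#' matrix. The generator is deliberately simple and pluggable: any list of
#' matrices can be fed to [barrier_support()].
#'
#' @param aln observed [sequence_alignment()] with population labels.
#' @param n_boot number of replicate matrices.
#' @param seed RNG seed.
#' @param model distance model for [phist_matrix()].
#' @return List of symmetric matrices.
#' @export
bootstrap_phist_matrices <- function(aln, n_boot = 100, seed = NULL,
                                     model = "diff") {
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(aln$pop_labels)
  fits <- lapply(pops, function(p) {
    sub <- subset_alignment(aln, aln$pop_labels == p)
    if (n_sequences(sub) >= 3) fit_sudden_expansion(observed_mismatch(sub))
    else list(tau = 1, theta0 = 0.5, theta1 = 10)
  })
  names(fits) <- pops
  sizes <- table(aln$pop_labels)[pops]
  bases <- c("A", "C", "G", "T")
  lapply(seq_len(n_boot), function(r) {
    root <- paste(sample(bases, aln$L, replace = TRUE), collapse = "")
    parts <- lapply(pops, function(p) {
      f <- fits[[p]]
      simulate_mtdna(sizes[[p]], expansion = c(f$tau, f$theta0, f$theta1),
                     L = aln$L, root_seq = root, pop = p,
                     id_prefix = paste0(p, "_"))
    })
    comb <- sequence_alignment(
      unlist(lapply(parts, `[[`, "sample_ids")),
      unlist(lapply(parts, `[[`, "sequences")),
      unlist(lapply(parts, `[[`, "pop_labels")))
    phist_matrix(comb, model = model)$phist
  })
}
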