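# Graph representation of connectivity maps and weighted graph metrics.
#
# Nodes are granule-cell-layer columns; edge weights are the Pearson
# correlations between the columns' amplitude depth-profiles, clipped at
# zero (negative correlation reads as absence of similarity). Metrics
# follow the weighted conventions of the Brain Connectivity Toolbox:
# modularity Q^w, within-module degree z-score, participation coefficient
# and weighted degree assortativity, each normalisable as a percent
# deviation from degree-preserving rewired null graphs.

#' Build the column-correlation graph of a map
#'
#' Pairwise Pearson correlations between the amplitude profiles of all
#' column pairs form the adjacency matrix of a weighted undirected graph.
#' Negative correlations and self-links are set to zero; columns with zero
#' variance (constant profiles) get zero weight to every partner.
#'
#' @param map a [connectivity_map()] with at least 3 rows and 2 columns.
#' @return object of class `map_graph`: list with `adjacency` (symmetric,
#'   zero diagonal, weights in \[0, 1\]), `positions_um`, `positions_norm`,
#'   `n`.
#' @export
build_correlation_graph <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  a <- map$amplitudes
  if (ncol(a) < 2L) stop("map must have >= 2 columns")
  if (nrow(a) < 3L) stop("column correlation needs >= 3 rows")
  sds <- apply(a, 2, stats::sd)
  C <- suppressWarnings(stats::cor(a))
  C[!is.finite(C)] <- 0          # constant columns
  C[C < 0] <- 0
  diag(C) <- 0
  C[sds == 0, ] <- 0
  C[, sds == 0] <- 0
  structure(
    list(adjacency = C, positions_um = map$positions,
         positions_norm = align_to_zebrin(map$positions, map$geometry),
         n = ncol(a)),
    class = "map_graph"
  )
}

#' Construct a map graph directly from an adjacency matrix
#'
#' Mostly for testing and for null-model graphs; validates the map-graph
#' invariants.
#'
#' @param adjacency symmetric non-negative matrix with zero diagonal.
#' @param positions_um,positions_norm optional node positions.
#' @return object of class `map_graph`.
#' @export
map_graph <- function(adjacency, positions_um = NULL, positions_norm = NULL) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency), tol = 1e-12)) stop("adjacency must be symmetric")
  if (any(adjacency < 0)) stop("weights must be non-negative")
  diag(adjacency) <- 0
  structure(
    list(adjacency = adjacency, positions_um = positions_um,
         positions_norm = positions_norm, n = ncol(adjacency)),
    class = "map_graph"
  )
}

.as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# canonical form: modules renumbered 1..k in order of first appearance
.canonical_membership <- function(m) {
  match(m, unique(m))
}

#' Detect graph modules with seeded Louvain restarts
#'
#' Runs the Louvain community-detection algorithm `n_restarts` times with
#' distinct seeds, scores every candidate partition with the weighted
#' modularity [graph_modularity()], and returns the best. Ties are broken
#' by the lower module count, then by the lexicographically smallest
#' canonical membership, so the result is deterministic given `seed`.
#'
#' @param graph a [map_graph()].
#' @param seed integer seed.
#' @param n_restarts number of seeded Louvain runs (default 20).
#' @return object of class `module_partition`: list with `membership`
#'   (integer vector, canonical labels), `n_modules`, `modularity`.
#' @export
detect_modules <- function(graph, seed = 1, n_restarts = 20) {
  stopifnot(inherits(graph, "map_graph"))
  n <- graph$n
  if (sum(graph$adjacency) == 0) {
    return(structure(list(membership = rep(1L, n), n_modules = 1L,
                          modularity = NA_real_),
                     class = "module_partition"))
  }
  g <- .as_igraph(graph)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    m <- .canonical_membership(igraph::membership(cl))
    q <- graph_modularity(graph, m)
    cand <- list(membership = m, n_modules = max(m), modularity = q)
    if (is.null(best) ||
        q > best$modularity + 1e-12 ||
        (abs(q - best$modularity) <= 1e-12 &&
         (cand$n_modules < best$n_modules ||
          (cand$n_modules == best$n_modules &&
           paste(m, collapse = ",") <
           paste(best$membership, collapse = ","))))) {
      best <- cand
    }
  }
  structure(best, class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("Module partition: %d modules, Q = %.4f\n", x$n_modules,
              x$modularity))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' Q^w = (1/l^w) * sum_ij \[w_ij - k_i k_j / l^w\] delta(m_i, m_j), where
#' the sum runs over all ordered node pairs (including i = j) and
#' l^w = sum_ij w_ij is the total (double-counted) weight.
#'
#' @param graph a [map_graph()].
#' @param membership integer module label per node (or a
#'   `module_partition`).
#' @return Q^w.
#' @export
graph_modularity <- function(graph, membership) {
  stopifnot(inherits(graph, "map_graph"))
  if (inherits(membership, "module_partition")) membership <- membership$membership
  W <- graph$adjacency
  if (length(membership) != ncol(W)) stop("membership length mismatch")
  l <- sum(W)
  if (l == 0) stop("graph has zero total weight")
  k <- rowSums(W)
  same <- outer(membership, membership, "==")
  sum((W - outer(k, k) / l)[same]) / l
}

#' Weighted degrees of a map graph
#'
#' @param graph a [map_graph()].
#' @return numeric vector of node strengths (sums of incident weights).
#' @export
weighted_degree <- function(graph) {
  rowSums(graph$adjacency)
}

#' Within-module degree z-score
#'
#' Standardises each node's within-module weighted degree against the
#' degree distribution of its own module (population SD). Nodes in
#' singleton modules, or in modules whose within-degrees are identical
#' (SD zero), get z = 0.
#'
#' @param graph a [map_graph()].
#' @param membership module labels (or a `module_partition`).
#' @return numeric vector of per-node z-scores.
#' @export
module_degree_zscore <- function(graph, membership) {
  stopifnot(inherits(graph, "map_graph"))
  if (inherits(membership, "module_partition")) membership <- membership$membership
  W <- graph$adjacency
  z <- numeric(ncol(W))
  for (m in unique(membership)) {
    idx <- which(membership == m)
    kin <- rowSums(W[idx, idx, drop = FALSE])
    mu <- mean(kin)
    sg <- sqrt(mean((kin - mu)^2))   # population SD, BCT convention
    z[idx] <- if (length(idx) < 2L || sg == 0) 0 else (kin - mu) / sg
  }
  z
}

#' Participation coefficient
#'
#' y_i = 1 - sum_m (k_i(m) / k_i)^2: zero when all of a node's weight
#' stays inside its own module, approaching 1 - 1/|M| when spread evenly
#' over all modules. Isolated nodes get 0.
#'
#' @param graph a [map_graph()].
#' @param membership module labels (or a `module_partition`).
#' @return numeric vector of per-node participation coefficients.
#' @export
participation <- function(graph, membership) {
  stopifnot(inherits(graph, "map_graph"))
  if (inherits(membership, "module_partition")) membership <- membership$membership
  W <- graph$adjacency
  k <- rowSums(W)
  y <- numeric(ncol(W))
  mods <- unique(membership)
  km <- vapply(mods, function(m) {
    rowSums(W[, membership == m, drop = FALSE])
  }, numeric(ncol(W)))
  pos <- k > 0
  y[pos] <- 1 - rowSums((km[pos, , drop = FALSE] / k[pos])^2)
  y
}

#' Weighted degree assortativity
#'
#' Weighted Pearson correlation between the degrees of connected node
#' pairs, evaluated over all links of the graph (or of the subgraph
#' induced by `nodes`). Degenerate graphs whose link-weighted degree
#' variance is zero (for example regular graphs) return `NA`, an explicit
#' undefined marker.
#'
#' @param graph a [map_graph()].
#' @param nodes optional node index subset; the metric is computed on the
#'   induced subgraph.
#' @return r^w, or `NA` when undefined.
#' @export
assortativity_weighted <- function(graph, nodes = NULL) {
  stopifnot(inherits(graph, "map_graph"))
  W <- graph$adjacency
  if (!is.null(nodes)) W <- W[nodes, nodes, drop = FALSE]
  k <- rowSums(W)
  link <- which(W > 0, arr.ind = TRUE)   # ordered pairs, both directions
  if (nrow(link) < 2L) return(NA_real_)
  w <- W[link]
  ki <- k[link[, 1]]; kj <- k[link[, 2]]
  l <- sum(w)
  m1 <- sum(w * (ki + kj) / 2) / l
  num <- sum(w * ki * kj) / l - m1^2
  den <- sum(w * (ki^2 + kj^2) / 2) / l - m1^2
  if (abs(den) < 1e-12) return(NA_real_)
  num / den
}

#' Degree-preserving null ensemble by edge rewiring
#'
#' Generates rewired copies of a graph that preserve its (binary) degree
#' sequence: pairs of edges (a-b, c-d) are repeatedly swapped to
#' (a-d, c-b) when the move creates neither a self-loop nor a duplicate
#' edge; weights travel with the rewired edges. This is the standard
#' Maslov-Sneppen null model for weighted undirected graphs.
#'
#' @param graph a [map_graph()].
#' @param n_nulls ensemble size (default 10, the minimum used for
#'   normalisation).
#' @param n_swaps_per_edge rewiring effort: swap attempts per edge.
#' @param seed integer seed.
#' @return list of `map_graph` objects. If the graph has fewer than two
#'   edges the originals are returned with attribute `rewired = FALSE`.
#' @export
null_ensemble <- function(graph, n_nulls = 10, n_swaps_per_edge = 10,
                          seed = 1) {
  stopifnot(inherits(graph, "map_graph"), n_nulls >= 1)
  W <- graph$adjacency
  n <- ncol(W)
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  n_edges <- nrow(ut)
  if (n_edges < 2L) {
    warning("too few edges to rewire; returning copies of the original")
    out <- replicate(n_nulls, graph, simplify = FALSE)
    for (i in seq_along(out)) attr(out[[i]], "rewired") <- FALSE
    return(out)
  }
  set.seed(seed)
  lapply(seq_len(n_nulls), function(b) {
    ei <- ut[, 1]; ej <- ut[, 2]; ew <- W[ut]
    adj <- W > 0
    attempts <- n_swaps_per_edge * n_edges
    for (t in seq_len(attempts)) {
      e <- sample.int(n_edges, 2L)
      a <- ei[e[1]]; bb <- ej[e[1]]; cc <- ei[e[2]]; d <- ej[e[2]]
      if (stats::runif(1) < 0.5) { tmp <- cc; cc <- d; d <- tmp }
      # propose (a-d) and (c-b)
      if (a == d || cc == bb) next
      if (adj[a, d] || adj[cc, bb]) next
      adj[a, bb] <- adj[bb, a] <- FALSE
      adj[cc, d] <- adj[d, cc] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[cc, bb] <- adj[bb, cc] <- TRUE
      ei[e[1]] <- min(a, d); ej[e[1]] <- max(a, d)
      ei[e[2]] <- min(cc, bb); ej[e[2]] <- max(cc, bb)
    }
    Wn <- matrix(0, n, n)
    Wn[cbind(ei, ej)] <- ew
    Wn[cbind(ej, ei)] <- ew
    gnull <- map_graph(Wn, graph$positions_um, graph$positions_norm)
    attr(gnull, "rewired") <- TRUE
    gnull
  })
}

#' Percent deviation from the null-model expectation
#'
#' Delta percent = (actual - median(nulls)) / median(nulls) * 100. When
#' the null median is numerically zero the ratio is undefined and `NA` is
#' returned.
#'
#' @param actual metric value on the actual graph.
#' @param nulls metric values over the null ensemble.
#' @param eps magnitude below which the null median counts as zero.
#' @return Delta percent, or `NA`.
#' @export
relative_metric <- function(actual, nulls, eps = 1e-12) {
  nulls <- nulls[is.finite(nulls)]
  if (length(nulls) == 0L) stop("no finite null values")
  m <- stats::median(nulls)
  if (!is.finite(actual)) return(NA_real_)
  if (abs(m) < eps) return(NA_real_)
  (actual - m) / m * 100
}

#' All node and graph metrics for one partitioned graph
#'
#' @param graph a [map_graph()].
#' @param partition a `module_partition` from [detect_modules()].
#' @return list with per-node `z` (module degree z-score), `y`
#'   (participation), `k` (weighted degree), and graph-level `modularity`
#'   and `assortativity`.
#' @export
graph_metrics <- function(graph, partition) {
  m <- if (inherits(partition, "module_partition")) partition$membership else partition
  list(
    z = module_degree_zscore(graph, m),
    y = participation(graph, m),
    k = weighted_degree(graph),
    modularity = graph_modularity(graph, m),
    assortativity = assortativity_weighted(graph)
  )
}

#' Assemble a graph feature vector
#'
#' Reduces node-wise metrics to one of the published schemes:
#' * `g_global` (4): modularity, median module-degree z-score, median
#'   participation, assortativity.
#' * `g_bilateral` (7): modularity, then (median z, median y,
#'   assortativity) evaluated separately over ipsilateral and
#'   contralateral nodes (assortativity on the induced side subgraphs).
#' * `g_zonewise`: per-zone medians of the three node metrics, flattened
#'   zone by zone (requires `zones`).
#' * `g_weights_zonewise` (one entry per zone, 8 under the eight-zone
#'   template): mean significant synaptic weight per structural
#'   microzone, normalised to the map's maximum zone value (requires
#'   `map`, `zmap`, `zones`).
#'
#' Empty zones or sides yield `NA` entries.
#'
#' @param graph a [map_graph()].
#' @param partition a `module_partition`.
#' @param scheme one of `"g_global"`, `"g_bilateral"`, `"g_zonewise"`,
#'   `"g_weights_zonewise"`.
#' @param zones a [structural_zones()] labeling of the graph's columns.
#' @param map,zmap the underlying map and z-score map (weights scheme).
#' @param relative if `TRUE`, graph-level and node-summarised metrics are
#'   reported as percent deviations from `nulls` (a [null_ensemble()]);
#'   applies to `g_global` and `g_bilateral`.
#' @param nulls optional list of null graphs for `relative = TRUE`.
#' @param seed seed used to partition null graphs.
#' @return named numeric vector with attribute `scheme`.
#' @export
assemble_features <- function(graph, partition,
                              scheme = c("g_global", "g_bilateral",
                                         "g_zonewise", "g_weights_zonewise"),
                              zones = NULL, map = NULL, zmap = NULL,
                              relative = FALSE, nulls = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  met <- graph_metrics(graph, partition)
  med <- function(v) if (length(v) == 0L) NA_real_ else stats::median(v, na.rm = TRUE)

  vec <- switch(scheme,
    g_global = c(
      modularity = met$modularity,
      z = med(met$z),
      y = med(met$y),
      assortativity = met$assortativity
    ),
    g_bilateral = {
      side <- sign(graph$positions_um)
      ip <- which(side > 0); co <- which(side < 0)
      c(modularity = met$modularity,
        z_ipsi = med(met$z[ip]), y_ipsi = med(met$y[ip]),
        assortativity_ipsi = assortativity_weighted(graph, ip),
        z_contra = med(met$z[co]), y_contra = med(met$y[co]),
        assortativity_contra = assortativity_weighted(graph, co))
    },
    g_zonewise = {
      if (is.null(zones)) stop("`zones` required for g_zonewise")
      zl <- unique(as.character(zones))
      out <- unlist(lapply(zl, function(zn) {
        idx <- which(as.character(zones) == zn)
        stats::setNames(c(med(met$z[idx]), med(met$y[idx]),
                          med(met$k[idx])),
                        paste0(c("z_", "y_", "k_"), zn))
      }))
      c(modularity = met$modularity, out)
    },
    g_weights_zonewise = {
      if (is.null(zones) || is.null(map) || is.null(zmap)) {
        stop("`zones`, `map` and `zmap` required for g_weights_zonewise")
      }
      zl <- unique(as.character(zones))
      sig <- zmap$z >= zmap$threshold
      w <- vapply(zl, function(zn) {
        idx <- which(as.character(zones) == zn)
        s <- sig[, idx, drop = FALSE]
        if (!any(s)) NA_real_ else mean(map$amplitudes[, idx, drop = FALSE][s])
      }, numeric(1))
      mx <- max(w, na.rm = TRUE)
      if (is.finite(mx) && mx > 0) w <- w / mx
      stats::setNames(w, paste0("w_", zl))
    }
  )

  if (relative && scheme %in% c("g_global", "g_bilateral")) {
    if (is.null(nulls)) stop("`nulls` required when relative = TRUE")
    null_vecs <- vapply(seq_along(nulls), function(i) {
      gp <- detect_modules(nulls[[i]], seed = seed + i)
      assemble_features(nulls[[i]], gp, scheme = scheme)
    }, numeric(length(vec)))
    null_vecs <- matrix(null_vecs, nrow = length(vec))
    vec <- vapply(seq_along(vec), function(j) {
      nv <- null_vecs[j, ]
      if (all(!is.finite(nv))) NA_real_ else relative_metric(vec[j], nv)
    }, numeric(1))
    names(vec) <- names(null_vecs) <- NULL
    names(vec) <- switch(scheme,
      g_global = c("modularity", "z", "y", "assortativity"),
      g_bilateral = c("modularity", "z_ipsi", "y_ipsi",
                      "assortativity_ipsi", "z_contra", "y_contra",
                      "assortativity_contra"))
  }
  structure(vec, scheme = scheme)
}
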