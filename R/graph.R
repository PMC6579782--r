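# Weighted graph-theoretic network properties of PLV matrices: Onnela
# clustering coefficient, characteristic path length and Latora-Marchiori
# efficiencies with edge lengths 1/w, plus small-worldness against
# degree-preserving rewired null graphs. Shortest paths and rewiring are
# delegated to igraph; the weighted property definitions are local.

#' Convert a PLV matrix to a weighted graph
#'
#' Keeps the fully weighted matrix (no thresholding or binarization) and
#' zeroes the self-connection diagonal.
#'
#' @param x a [PLVMatrix-class] or a symmetric numeric matrix.
#' @param channels optional node subset (e.g. scalp channels only).
#' @return a [WeightedGraph-class].
#' @export
asWeightedGraph <- function(x, channels = NULL) {
  w <- if (is(x, "PLVMatrix")) x@plv else as.matrix(x)
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- paste0("n", seq_len(nrow(w)))
  }
  if (!is.null(channels)) w <- w[channels, channels, drop = FALSE]
  w <- (w + t(w)) / 2
  diag(w) <- 0
  new("WeightedGraph", weights = w, nodeNames = rownames(w))
}

.asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g@weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# all-pairs shortest-path distances with edge length 1/w
.spDistances <- function(g) {
  ig <- .asIgraph(g)
  n <- nrow(g@weights)
  if (igraph::ecount(ig) == 0) {
    D <- matrix(Inf, n, n)
    diag(D) <- 0
    return(D)
  }
  igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                    algorithm = "dijkstra")
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node geometric-mean triangle intensity
#' sum_jh (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1)) with weights
#' normalized by the network maximum (w' = w / max w), averaged over nodes;
#' nodes with degree < 2 contribute 0.
#'
#' @param g a [WeightedGraph-class] with >= 3 nodes.
#' @return C in [0, 1].
#' @export
clusteringCoefficient <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  n <- nrow(g@weights)
  if (n < 3) stop("clustering coefficient needs >= 3 nodes")
  mx <- max(g@weights)
  if (mx == 0) return(0)
  W <- (g@weights / mx)^(1 / 3)
  k <- rowSums(g@weights > 0)
  tri <- diag(W %*% W %*% W)        # 2 x triangle intensity sum per node
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs, with edge
#' length 1/w (stronger coupling = shorter distance).
#'
#' @param g a connected [WeightedGraph-class].
#' @return L (>= 1 for a complete unit-weight graph).
#' @export
characteristicPathLength <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  D <- .spDistances(g)
  up <- D[upper.tri(D)]
  if (any(!is.finite(up)))
    stop("graph is disconnected: characteristic path length undefined; ",
         "use globalEfficiency(), which handles unreachable pairs")
  mean(up)
}

#' Global efficiency
#'
#' Mean over unordered pairs of 1/d_ij with d the 1/w shortest-path
#' distance; unreachable pairs contribute 0, so disconnection is handled.
#'
#' @param g a [WeightedGraph-class] with >= 2 nodes.
#' @return Ge in [0, 1] for weights in [0, 1].
#' @export
globalEfficiency <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  if (nrow(g@weights) < 2) stop("global efficiency needs >= 2 nodes")
  D <- .spDistances(g)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (w > 0); nodes with fewer than 2 neighbors contribute 0.
#'
#' @param g a [WeightedGraph-class] with >= 2 nodes.
#' @return Le in [0, 1] for weights in [0, 1].
#' @export
localEfficiency <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  n <- nrow(g@weights)
  if (n < 2) stop("local efficiency needs >= 2 nodes")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(g@weights[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- new("WeightedGraph",
               weights = g@weights[nb, nb, drop = FALSE],
               nodeNames = g@nodeNames[nb])
    globalEfficiency(sub)
  }, numeric(1))
  mean(vals)
}

#' Node strength
#'
#' Sum of edge weights per node; exported as a convenience summary of
#' node-level connectedness ("hubness" has no agreed threshold and none is
#' asserted).
#'
#' @param g a [WeightedGraph-class].
#' @return named numeric vector.
#' @export
nodeStrength <- function(g) {
  stopifnot(is(g, "WeightedGraph"))
  stats::setNames(rowSums(g@weights), g@nodeNames)
}

#' Small-worldness
#'
#' sigma = (C / C_rand) / (L / L_rand) where the null values average over
#' \code{nRand} degree-sequence-preserving edge rewirings with the original
#' weights shuffled onto the rewired edges. sigma > 1 indicates
#' small-world organization.
#'
#' @param g a connected [WeightedGraph-class].
#' @param nRand number of rewired null graphs (>= 1).
#' @param seed RNG seed (deterministic result for a fixed seed).
#' @param maxAttempts bounded retries per null graph when a rewiring comes
#'   out disconnected.
#' @return sigma (> 0).
#' @export
smallWorldness <- function(g, nRand = 20, seed = 1, maxAttempts = 50) {
  stopifnot(is(g, "WeightedGraph"), nRand >= 1)
  C <- clusteringCoefficient(g)
  L <- characteristicPathLength(g)      # errors if disconnected
  ig <- .asIgraph(g)
  w <- igraph::E(ig)$weight
  withSeed(seed, {
    Cr <- numeric(nRand); Lr <- numeric(nRand)
    for (r in seq_len(nRand)) {
      ok <- FALSE
      for (a in seq_len(maxAttempts)) {
        rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = 20 * length(w)))
        igraph::E(rg)$weight <- sample(w)
        A <- igraph::as_adjacency_matrix(rg, attr = "weight", sparse = FALSE)
        gr <- new("WeightedGraph", weights = (A + t(A)) / 2,
                  nodeNames = g@nodeNames)
        D <- .spDistances(gr)
        if (all(is.finite(D[upper.tri(D)]))) {
          Cr[r] <- clusteringCoefficient(gr)
          Lr[r] <- mean(D[upper.tri(D)])
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("degree-preserving rewiring failed to produce a connected ",
                    "null graph after ", maxAttempts, " attempts")
    }
    (C / mean(Cr)) / (L / mean(Lr))
  })
}

#' All network properties of one graph
#'
#' @param g a [WeightedGraph-class].
#' @param sigma also compute small-worldness (slower; needs a connected
#'   graph).
#' @param nRand,seed passed to [smallWorldness()].
#' @return one-row data.frame with C, L, Ge, Le (and sigma when requested);
#'   L is NA for a disconnected graph.
#' @export
graphMetrics <- function(g, sigma = FALSE, nRand = 20, seed = 1) {
  stopifnot(is(g, "WeightedGraph"))
  L <- tryCatch(characteristicPathLength(g), error = function(e) NA_real_)
  out <- data.frame(C = clusteringCoefficient(g), L = L,
                    Ge = globalEfficiency(g), Le = localEfficiency(g))
  if (sigma)
    out$sigma <- if (is.na(L)) NA_real_ else smallWorldness(g, nRand, seed)
  out
}
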