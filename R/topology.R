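# Binary graph topology: proportional thresholding of the PEC matrix and the
# five metrics (clustering coefficient, characteristic path length,
# small-worldness, global and local efficiency), referenced against
# degree-preserving, connectedness-preserving random networks.
#
# Conventions (documented, since sparse 10%-density graphs make them bite):
# nodes of degree < 2 contribute 0 to the clustering coefficient and local
# efficiency; the characteristic path length averages reachable ordered
# pairs only and the unreachable fraction is reported alongside; global
# efficiency treats unreachable pairs as efficiency 0.

#' Proportional threshold to a binary graph
#'
#' Retains the `K = ceiling(density * N(N-1)/2)` largest upper-triangle
#' weights as undirected edges. Ties at the cutoff are broken by fixed
#' row-major (i, j) index order, so the result is deterministic.
#'
#' @param W Symmetric weight matrix (e.g. a ROI PEC matrix or `pec_matrix`
#'   object); the diagonal is ignored; `NA` weights rank last.
#' @param density Fraction of possible edges to keep, default 0.10.
#' @return Symmetric binary adjacency matrix with zero diagonal.
#' @export
threshold_proportional <- function(W, density = 0.10) {
  if (inherits(W, "pec_matrix")) W <- W$matrix
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!(density > 0 && density <= 1)) stop("density must lie in (0, 1]")
  n <- nrow(W)
  w <- upper_tri_vec(W)
  K <- ceiling(density * length(w))
  w[is.na(w)] <- -Inf
  # order by weight descending, ties by row-major index (stable sort)
  ord <- order(-w, seq_along(w))
  if (length(unique(w)) == 1L)
    warning("all weights equal: keeping the first ", K, " edges by index order")
  keep <- ord[seq_len(K)]
  idx <- upper_tri_index(n)
  A <- matrix(0L, n, n)
  A[idx[keep, , drop = FALSE]] <- 1L
  A + t(A)
}

# adjacency -> igraph, undirected
.as_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Clustering coefficient
#'
#' Mean over nodes of the local triangle density
#' `sum_{i,j in N(k)} a_ij / (d_k (d_k - 1))`; nodes with degree < 2
#' contribute 0.
#'
#' @param A Binary adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(A) {
  stopifnot(is.matrix(A))
  d <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)          # 2 x triangles through each node
  cc <- ifelse(d >= 2, tri2 / (d * (d - 1)), 0)
  mean(cc)
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over ordered reachable pairs `i != j`;
#' unreachable pairs are excluded from the mean and their fraction reported.
#'
#' @param A Binary adjacency matrix.
#' @return List with `L` (NA if the graph has no edges) and
#'   `unreachable_fraction`.
#' @export
characteristic_path_length <- function(A) {
  n <- nrow(A)
  if (sum(A) == 0L)
    return(list(L = NA_real_, unreachable_fraction = 1))
  D <- igraph::distances(.as_graph(A))
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  list(L = mean(off[reach]), unreachable_fraction = mean(!reach))
}

#' Global efficiency
#'
#' Mean over ordered pairs `i != j` of the inverse shortest-path length,
#' with `1/Inf = 0` for unreachable pairs.
#'
#' @param A Binary adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  if (sum(A) == 0L) return(0)
  D <- igraph::distances(.as_graph(A))
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (the node itself excluded); nodes with degree < 2
#' contribute 0.
#'
#' @param A Binary adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) next
    vals[i] <- global_efficiency(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

#' Degree-preserving, connectedness-preserving random ensemble
#'
#' Each member is produced by Maslov-Sneppen double-edge swaps
#' (`10 * |E|` attempted swaps; swaps creating self-loops or multi-edges are
#' rejected), repeated until the rewired graph is connected (bounded
#' restarts). Degree sequences are exactly preserved.
#'
#' @param A Connected binary adjacency matrix.
#' @param n Ensemble size, default 100.
#' @param seed Seed.
#' @param max_restarts Connectivity restarts per member (default 100).
#' @return List of adjacency matrices (class `random_ensemble`, attributes
#'   `seed` and `swap_count`).
#' @export
randomize_degree_preserving <- function(A, n = 100L, seed = 1L,
                                        max_restarts = 100L) {
  g <- .as_graph(A)
  if (!igraph::is_connected(g)) stop("source graph must be connected")
  m <- igraph::ecount(g)
  if (m < 2L) {
    warning("graph too small to randomize: returning copies")
    return(structure(rep(list(A), n), class = "random_ensemble",
                     seed = seed, swap_count = 0L))
  }
  oldseed <- .snapshot_rng()
  on.exit(.restore_rng(oldseed))
  set.seed(seed)
  niter <- 10L * m
  out <- vector("list", n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (r in seq_len(max_restarts)) {
      rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                     niter = niter))
      if (igraph::is_connected(rg)) { ok <- TRUE; break }
    }
    if (!ok) {
      warning("could not reach a connected rewiring; returning the original")
      rg <- g
    }
    out[[k]] <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
  }
  structure(out, class = "random_ensemble", seed = seed, swap_count = niter)
}

#' Small-worldness
#'
#' `sigma = (CC / CC_rand) / (L / L_rand)` where `CC_rand` and `L_rand` are
#' the ensemble means over matched random networks.
#'
#' @param A Binary adjacency matrix.
#' @param ensemble A `random_ensemble` (list of adjacency matrices).
#' @return List with `sigma`, `CC`, `L`, `CC_rand`, `L_rand` (`sigma` is
#'   `NA` when `CC_rand` or `L_rand` vanish).
#' @export
small_worldness <- function(A, ensemble) {
  cc <- clustering_coefficient(A)
  L <- characteristic_path_length(A)$L
  cc_r <- mean(vapply(ensemble, clustering_coefficient, numeric(1)))
  L_r <- mean(vapply(ensemble, function(g) characteristic_path_length(g)$L,
                     numeric(1)))
  sigma <- if (isTRUE(cc_r > 0) && isTRUE(L_r > 0)) (cc / cc_r) / (L / L_r)
           else NA_real_
  list(sigma = sigma, CC = cc, L = L, CC_rand = cc_r, L_rand = L_r)
}

#' All five topology metrics for one weighted connectivity matrix
#'
#' Thresholds the weights to the top `density` fraction, computes CC, L,
#' Eglobal, Elocal and sigma against a degree-preserving random ensemble.
#' When the thresholded graph is disconnected, the random ensemble (which
#' requires connectedness) is built on the largest connected component and
#' `sigma` refers to that component; `unreachable_fraction` flags the
#' situation.
#'
#' @param W Weight matrix or `pec_matrix` object.
#' @param density Proportional threshold, default 0.10.
#' @param n_random Random ensemble size, default 100.
#' @param seed Seed for the ensemble.
#' @return A one-row data.frame: CC, L, sigma, Eglobal, Elocal, CC_rand,
#'   L_rand, unreachable_fraction, n_random.
#' @export
graph_metrics <- function(W, density = 0.10, n_random = 100L, seed = 1L) {
  A <- threshold_proportional(W, density)
  cc <- clustering_coefficient(A)
  pl <- characteristic_path_length(A)
  eg <- global_efficiency(A)
  el <- local_efficiency(A)
  g <- .as_graph(A)
  if (!igraph::is_connected(g)) {
    comp <- igraph::components(g)
    big <- which(comp$membership == which.max(comp$csize))
    A_sw <- A[big, big, drop = FALSE]
  } else {
    A_sw <- A
  }
  ens <- randomize_degree_preserving(A_sw, n = n_random, seed = seed)
  sw <- small_worldness(A_sw, ens)
  data.frame(CC = cc, L = pl$L, sigma = sw$sigma, Eglobal = eg, Elocal = el,
             CC_rand = sw$CC_rand, L_rand = sw$L_rand,
             unreachable_fraction = pl$unreachable_fraction,
             n_random = n_random)
}
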