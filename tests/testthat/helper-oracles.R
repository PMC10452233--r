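# Independent brute-force oracles used to cross-check the package's graph
# machinery. Deliberately implemented with plain loops and no igraph.

# all-pairs shortest-path hop counts by explicit breadth-first search
oracle_bfs_dist <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (dist[w] > d) {
            dist[w] <- d
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

oracle_cc <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (k in seq_len(n)) {
    nb <- which(A[k, ] > 0)
    if (length(nb) < 2) next
    tri <- 0
    for (i in nb) for (j in nb) if (i != j && A[i, j] > 0) tri <- tri + 1
    vals[k] <- tri / (length(nb) * (length(nb) - 1))
  }
  mean(vals)
}

oracle_L <- function(A) {
  D <- oracle_bfs_dist(A)
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  list(L = if (any(reach)) mean(off[reach]) else NA_real_,
       unreachable_fraction = mean(!reach))
}

oracle_eglobal <- function(A) {
  if (nrow(A) < 2 || sum(A) == 0) return(0)
  D <- oracle_bfs_dist(A)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_elocal <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_eglobal(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_connected <- function(A) {
  all(is.finite(oracle_bfs_dist(A)))
}

# random connected Erdos-Renyi adjacency matrix (resampled until connected)
random_connected_graph <- function(n, p) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    if (sum(A) > 0 && oracle_connected(A)) return(A)
  }
}

# small worked graphs used across tests
graph_triangle <- function() {
  A <- matrix(1L, 3, 3); diag(A) <- 0L; A
}
graph_star <- function(leaves = 3) {
  A <- matrix(0L, leaves + 1, leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1L
  A
}
graph_path3 <- function() {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  A
}
# 4-cycle A-B-C-D plus chord A-C
graph_chorded_square <- function() {
  A <- matrix(0L, 4, 4)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3))
  for (k in seq_len(nrow(edges)))
    A[edges[k, 1], edges[k, 2]] <- A[edges[k, 2], edges[k, 1]] <- 1L
  A
}

# two-ROI config with one planted coupling, used by connectivity tests
coupled_pair_config <- function(rho, band = c(13, 30), fs = 256,
                                private_noise = 0) {
  sim_config(n_rois = 2, dipoles_per_roi = 1, n_sensors = 4,
             coupling_spec = data.frame(roi_i = 1, roi_j = 2, rho = rho),
             band = band, fs = fs, private_noise = private_noise, seed = 1)
}
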