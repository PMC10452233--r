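# Graph topology: proportional threshold, the five metrics against
# brute-force oracles, degree-preserving randomization, small-worldness.

test_that("proportional threshold keeps the top-K edges deterministically", {
  set.seed(1)
  n <- 68
  W <- matrix(rnorm(n * n), n, n)
  W <- (W + t(W)) / 2
  A <- threshold_proportional(W, 0.10)
  expect_equal(sum(A) / 2, 228)                 # ceil(0.10 * 2278)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))

  W4 <- matrix(0, 4, 4)
  W4[1, 3] <- W4[3, 1] <- 9
  W4[2, 4] <- W4[4, 2] <- 1
  A4 <- threshold_proportional(W4, 0.10)        # ceil(0.6) = 1 edge
  expect_equal(sum(A4) / 2, 1)
  expect_equal(A4[1, 3], 1L)

  expect_equal(sum(threshold_proportional(W, 1)) / 2, 2278)
  expect_warning(threshold_proportional(matrix(1, 4, 4), 0.5), "equal")
  expect_error(threshold_proportional(W, 0), "density")
})

test_that("worked graph examples give their exact metric values", {
  expect_equal(clustering_coefficient(graph_triangle()), 1)
  expect_equal(clustering_coefficient(graph_star()), 0)
  expect_equal(clustering_coefficient(graph_chorded_square()), 5 / 6)

  expect_equal(characteristic_path_length(graph_triangle())$L, 1)
  p3 <- characteristic_path_length(graph_path3())
  expect_equal(p3$L, 4 / 3)
  expect_equal(p3$unreachable_fraction, 0)

  two_k2 <- matrix(0L, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1L
  pk <- characteristic_path_length(two_k2)
  expect_equal(pk$L, 1)
  expect_equal(pk$unreachable_fraction, 2 / 3)

  expect_equal(global_efficiency(graph_triangle()), 1)
  expect_equal(global_efficiency(graph_path3()), 5 / 6)
  expect_equal(global_efficiency(matrix(0L, 3, 3)), 0)

  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_equal(local_efficiency(K4), 1)
  expect_equal(local_efficiency(graph_star()), 0)
  expect_equal(local_efficiency(graph_chorded_square()),
               oracle_elocal(graph_chorded_square()), tolerance = 1e-14)
})

test_that("metrics match the brute-force oracle on random small graphs", {
  set.seed(2)
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    A <- random_connected_graph(n, runif(1, 0.3, 0.9))
    expect_equal(clustering_coefficient(A), oracle_cc(A), tolerance = 1e-12)
    expect_equal(characteristic_path_length(A)$L, oracle_L(A)$L,
                 tolerance = 1e-12)
    expect_equal(global_efficiency(A), oracle_eglobal(A), tolerance = 1e-12)
    expect_equal(local_efficiency(A), oracle_elocal(A), tolerance = 1e-12)
  }
})

test_that("efficiency dominates inverse path length and grows with edges", {
  set.seed(3)
  for (rep in 1:30) {
    A <- random_connected_graph(sample(5:9, 1), runif(1, 0.3, 0.7))
    eg <- global_efficiency(A)
    expect_gte(eg + 1e-12, 1 / characteristic_path_length(A)$L)
    # add one absent edge: Eglobal never decreases
    absent <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(A2) + 1e-12, eg)
  }
})

test_that("rewired ensembles preserve degrees and connectedness and mix well", {
  set.seed(4)
  W <- matrix(rnorm(68 * 68), 68, 68)
  W <- (W + t(W)) / 2
  A <- threshold_proportional(W, 0.10)
  # work on the largest component if thresholding disconnected the graph
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  A <- A[big, big]
  ens <- randomize_degree_preserving(A, n = 10, seed = 9)
  jacc <- numeric(length(ens))
  e0 <- which(A == 1 & upper.tri(A))
  for (k in seq_along(ens)) {
    B <- ens[[k]]
    expect_identical(sort(rowSums(B)), sort(rowSums(A)))
    expect_true(oracle_connected(B))
    ek <- which(B == 1 & upper.tri(B))
    jacc[k] <- length(intersect(e0, ek)) / length(union(e0, ek))
  }
  expect_lt(mean(jacc), 0.7)
})

test_that("small-worldness is exactly 1 against an ensemble of copies", {
  set.seed(5)
  A <- random_connected_graph(12, 0.4)
  sw <- small_worldness(A, list(A, A))
  expect_equal(sw$sigma, 1)
})

test_that("random graphs sit at sigma ~ 1 and ring lattices above 1.5", {
  set.seed(6)
  sig_er <- sapply(1:3, function(k) {
    A <- random_connected_graph(50, 0.3)
    ens <- randomize_degree_preserving(A, n = 30, seed = k)
    small_worldness(A, ens)$sigma
  })
  expect_lt(max(abs(sig_er - 1)), 0.1)

  g <- igraph::sample_smallworld(1, 68, 3, 0.1)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  if (!oracle_connected(A)) skip("rewired lattice disconnected for this draw")
  ens <- randomize_degree_preserving(A, n = 30, seed = 7)
  expect_gt(small_worldness(A, ens)$sigma, 1.5)
})

test_that("graph_metrics assembles all five metrics for a weighted matrix", {
  set.seed(8)
  W <- matrix(rnorm(30 * 30), 30, 30)
  W <- (W + t(W)) / 2
  gm <- graph_metrics(W, density = 0.2, n_random = 20, seed = 1)
  expect_true(all(c("CC", "L", "sigma", "Eglobal", "Elocal",
                    "unreachable_fraction") %in% names(gm)))
  expect_true(gm$CC >= 0 && gm$CC <= 1)
  expect_true(gm$Eglobal >= 0 && gm$Eglobal <= 1)
  expect_true(gm$Elocal >= 0 && gm$Elocal <= 1)
  expect_gte(gm$L, 1)
  expect_gt(gm$sigma, 0)
})
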