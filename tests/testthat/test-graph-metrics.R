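triangle_net <- function(w = 0.5) {
  W <- matrix(c(0, w, w, w, 0, w, w, w, 0), 3, 3)
  make_network(W)
}

star_net <- function() {
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- 1
  make_network(W)
}

test_that("strength follows the 1/N-normalized definition on toy graphs", {
  tri <- triangle_net(0.5)
  expect_equal(node_strength(tri), rep(1 / 3, 3), ignore_attr = TRUE)
  expect_equal(network_strength(tri), 1 / 3)
  star <- star_net()
  expect_equal(node_strength(star), c(0.75, 0.25, 0.25, 0.25), ignore_attr = TRUE)
  expect_equal(network_strength(star), 0.375)
  expect_equal(node_strength(star, normalization = "classic"),
    c(3, 1, 1, 1),
    ignore_attr = TRUE
  )
  empty <- make_network(matrix(0, 3, 3))
  expect_equal(network_strength(empty), 0)
})

test_that("degree counts direct neighbours", {
  expect_equal(network_degree(triangle_net()), 2)
  expect_equal(network_degree(star_net()), 1.5)
  expect_equal(network_degree(make_network(matrix(0, 3, 3))), 0)
})

test_that("path lengths use 1/w edge lengths and the L = 0 unreachable rule", {
  two <- make_network(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(path_length_matrix(two), matrix(c(0, 2, 2, 0), 2, 2), ignore_attr = TRUE)
  expect_equal(average_path_length(two), 2)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[1, 3] <- W[3, 1] <- 0.5
  L <- path_length_matrix(make_network(W))
  expect_equal(L[1, 3], 2) # direct 1/0.5 ties the 1+1 route via node 2
  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- 1
  Ld <- path_length_matrix(make_network(disc))
  expect_equal(Ld[1, 3], 0)
  expect_equal(Ld[3, 4], 0)
  expect_equal(average_path_length(make_network(matrix(0, 3, 3))), 0)
})

test_that("clustering matches the enumerated 4-node example", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 1
  W[2, 3] <- W[3, 2] <- 0.5
  W[1, 4] <- W[4, 1] <- 1
  net <- make_network(W)
  ci <- clustering_coefficient(net)
  expect_equal(ci[1], 2 * 0.5^(1 / 3) / 6, ignore_attr = TRUE)
  expect_equal(ci[1], 0.26457, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(ci[2], 0.7937, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(ci[3], 0.7937, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(ci[4], 0, ignore_attr = TRUE)
  expect_equal(network_clustering(net), 0.4630, tolerance = 1e-4)
  expect_equal(clustering_coefficient(triangle_net()), rep(1, 3), ignore_attr = TRUE)
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(clustering_coefficient(make_network(path)), rep(0, 3), ignore_attr = TRUE)
})

test_that("Dijkstra distances and clustering agree with brute-force oracles", {
  set.seed(77)
  for (trial in 1:200) {
    n <- sample(4:12, 1)
    W <- random_weight_matrix(n, p_edge = runif(1, 0.2, 0.7))
    net <- make_network(W)
    expect_equal(path_length_matrix(net, "absolute"), fw_path_oracle(W),
      tolerance = 1e-12, ignore_attr = TRUE
    )
    expect_equal(clustering_coefficient(net, "absolute"), brute_clustering_oracle(W),
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
})

test_that("metrics scale correctly under uniform weight scaling", {
  set.seed(3)
  W <- random_weight_matrix(8, 0.5)
  net1 <- make_network(W)
  net2 <- make_network(2.5 * W)
  expect_equal(clustering_coefficient(net2), clustering_coefficient(net1))
  expect_equal(node_strength(net2), 2.5 * node_strength(net1))
  expect_equal(average_path_length(net2), average_path_length(net1) / 2.5)
  expect_equal(node_degree(net2), node_degree(net1))
})

test_that("the binary special case reduces to unweighted definitions", {
  set.seed(12)
  W <- (random_weight_matrix(9, 0.4) > 0) * 1
  net <- make_network(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
  expect_equal(clustering_coefficient(net),
    ifelse(is.nan(igraph::transitivity(g, type = "local")), 0,
      igraph::transitivity(g, type = "local")
    ),
    ignore_attr = TRUE
  )
  Lu <- igraph::distances(g)
  Lu[!is.finite(Lu)] <- 0
  expect_equal(path_length_matrix(net), Lu, ignore_attr = TRUE)
})

test_that("edge policies select positive, absolute or signed weights", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- -0.4
  net <- make_network(W)
  expect_equal(sum(adjacency_matrix(net, "positive") != 0) / 2, 1)
  expect_equal(sum(adjacency_matrix(net, "absolute") != 0) / 2, 2)
  expect_equal(adjacency_matrix(net, "signed")[1, 3], -0.4)
  expect_equal(adjacency_matrix(net, "absolute")[1, 3], 0.4)
})

test_that("regional connectivity averages positive edges touching a role", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.6
  W[1, 3] <- W[3, 1] <- -0.5
  W[3, 4] <- W[4, 3] <- 0.2
  net <- make_network(W, roles = c("frontal", "frontal", "other", "other"))
  expect_equal(regional_connectivity(net, "frontal"), 0.6)
  expect_equal(regional_connectivity(net, "other"), 0.2)
  expect_equal(regional_connectivity(net, "pcc"), 0)
})
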