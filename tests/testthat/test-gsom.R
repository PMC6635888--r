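test_that("map initialization builds a seeded 2x2 lattice", {
  set.seed(1)
  m <- init_map(5, center = rep(0.5, 5))
  expect_equal(map_size(m), 4)
  pos <- map_positions(m)
  expect_setequal(paste(pos[, 1], pos[, 2]),
                  c("0 0", "0 1", "1 0", "1 1"))
  set.seed(1)
  m2 <- init_map(5, center = rep(0.5, 5))
  expect_identical(map_state(m), map_state(m2))
  expect_error(init_map(0), ">= 1")
})

test_that("winner search matches an exhaustive scan and breaks ties low", {
  set.seed(2)
  w <- matrix(runif(12 * 6), 12, 6)
  m <- map_from_state(list(positions = cbind(0:11, 0L), weights = w))
  expect_equal(find_bmu(m, w[7, ]), 7)  # zero distance
  for (i in 1:100) {
    x <- runif(6)
    expect_equal(find_bmu(m, x), brute_bmu(w, x))
  }
  # exact tie between nodes 2 and 5 -> lower id
  w2 <- w
  w2[5, ] <- w2[2, ]
  m2 <- map_from_state(list(positions = cbind(0:11, 0L), weights = w2))
  expect_equal(find_bmu(m2, w2[2, ]), 2)
  expect_error(find_bmu(m, runif(4)), "dimensionality")
})

test_that("adaptation moves the winner toward the input as specified", {
  set.seed(3)
  m <- init_map(4)
  x <- runif(4)
  before <- map_weights(clone_map(m))
  adapt(m, x, find_bmu(m, x), list(lr = 0, radius = 1))
  expect_equal(map_weights(m), before)  # lr = 0 leaves weights unchanged
  b <- find_bmu(m, x)
  adapt(m, x, b, list(lr = 1, radius = 0))
  expect_equal(map_weights(m)[b, ], x)  # lr = 1, radius 0 copies exactly
  # repeated presentation converges monotonically
  set.seed(4)
  m2 <- init_map(4)
  x2 <- runif(4)
  d_prev <- Inf
  for (i in 1:20) {
    b2 <- find_bmu(m2, x2)
    adapt(m2, x2, b2, list(lr = 0.3, radius = 0))
    d <- sqrt(sum((map_weights(m2)[b2, ] - x2)^2))
    expect_lte(d, d_prev + 1e-12)
    d_prev <- d
  }
  expect_lt(d_prev, 1e-2)
})

test_that("growth only extends the boundary and node count never decreases", {
  set.seed(5)
  m <- init_map(3)
  expect_equal(maybe_grow(m, 10)$new_nodes, integer(0))  # below threshold
  gsom_err <- function(m, e) phonmap:::gsom_set_errors_(m$ptr, e)
  gsom_err(m, c(100, 0, 0, 0))
  res <- maybe_grow(m, 10)
  expect_gt(length(res$new_nodes), 0)
  pos <- map_positions(m)
  # new nodes occupy free 4-neighbours of (0,0): (-1,0) and (0,-1)
  new_pos <- pos[res$new_nodes, , drop = FALSE]
  expect_true(all(paste(new_pos[, 1], new_pos[, 2]) %in%
                    c("-1 0", "0 -1")))
  expect_equal(anyDuplicated(paste(pos[, 1], pos[, 2])), 0)
  expect_equal(map_errors(m)[1], 0)  # grown node's error was reset
})

test_that("training a map keeps positions unique and the lattice 4-connected", {
  set.seed(6)
  X <- matrix(runif(60 * 8), 60, 8)
  m <- init_map(8, colMeans(X))
  sizes <- map_size(m)
  for (epoch in 1:15) {
    for (i in sample(nrow(X))) {
      b <- find_bmu(m, X[i, ])
      adapt(m, X[i, ], b, list(lr = 0.2, radius = 1.5))
      maybe_grow(m, 3)
    }
    sizes <- c(sizes, map_size(m))
  }
  expect_true(all(diff(sizes) >= 0))  # monotone growth
  pos <- map_positions(m)
  expect_equal(anyDuplicated(paste(pos[, 1], pos[, 2])), 0)
  lab <- data.frame(x = pos[, 1], y = pos[, 2], label = "n")
  expect_equal(flood_fill_regions(lab), 1)  # one connected component
})

test_that("with growth off and radius zero the map behaves like online k-means", {
  set.seed(7)
  X <- rbind(matrix(rnorm(50 * 2, mean = 0, sd = 0.1), ncol = 2),
             matrix(rnorm(50 * 2, mean = 3, sd = 0.1), ncol = 2))
  m <- init_map(2, colMeans(X), noise_sd = 0.5)
  qe <- function() {
    ids <- assign_items(m, X)$item_node
    w <- map_weights(m)
    mean(sqrt(rowSums((X - w[ids, ])^2)))
  }
  q0 <- qe()
  for (epoch in 1:10)
    for (i in sample(nrow(X)))
      adapt(m, X[i, ], find_bmu(m, X[i, ]), list(lr = 0.1, radius = 0))
  expect_lt(qe(), q0)
  # two tight clusters -> two centroids land near the cluster means
  w <- map_weights(m)
  ids <- assign_items(m, X)$item_node
  expect_lt(qe(), 0.2)
  expect_equal(length(unique(ids[1:50])), 1)
  expect_equal(length(unique(ids[51:100])), 1)
})

test_that("lattice neighbours end nearer in input space than random node pairs", {
  set.seed(8)
  grid <- as.matrix(expand.grid(x = seq(0, 1, length.out = 6),
                                y = seq(0, 1, length.out = 6)))
  X <- cbind(grid, matrix(0, nrow(grid), 6))  # 2D manifold in 8 dims
  m <- init_map(8, colMeans(X))
  for (epoch in 1:40) {
    r <- max(0.5, 2.5 - epoch * 0.05)
    for (i in sample(nrow(X))) {
      adapt(m, X[i, ], find_bmu(m, X[i, ]), list(lr = 0.15, radius = r))
      maybe_grow(m, 2)
    }
  }
  pos <- map_positions(m)
  w <- map_weights(m)
  dl <- as.matrix(dist(pos))
  dw <- as.matrix(dist(w))
  ut <- upper.tri(dl)
  expect_lt(mean(dw[ut & dl == 1]), mean(dw[ut & dl > 3]))
})

test_that("item assignment equals itemwise winner search", {
  set.seed(9)
  w <- matrix(runif(10 * 4), 10, 4)
  m <- map_from_state(list(positions = cbind(0:9, 0L), weights = w))
  X <- matrix(runif(25 * 4), 25, 4)
  asg <- assign_items(m, X)
  expect_equal(asg$item_node,
               vapply(seq_len(25), function(i) find_bmu(m, X[i, ]), 0L))
  # inverse index is consistent
  for (k in names(asg$node_items))
    expect_true(all(asg$item_node[asg$node_items[[k]]] == as.integer(k)))
  expect_error(assign_items(m, X[0, , drop = FALSE]), "nonempty")
  # items equal to distinct node weights land on their own nodes
  asg2 <- assign_items(m, w)
  expect_equal(asg2$item_node, 1:10)
})
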