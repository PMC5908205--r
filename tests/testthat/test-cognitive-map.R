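test_that("hebbian_update follows the competitive rule with renormalisation", {
  W <- matrix(c(1, 0), 1, 2)
  expect_identical(hebbian_update(W, c(0, 1), 1, rate = 0), W)

  W1 <- hebbian_update(W, pre = c(0, 1), post = 1, rate = 0.5, k = 1)
  expect_equal(as.vector(W1), c(1, 0.5) / sqrt(1.25), tolerance = 1e-12)

  # only the k most active rows learn; every touched row keeps unit norm
  set.seed(3)
  W <- matrix(runif(50), 10, 5)
  W <- W / sqrt(rowSums(W^2))
  post <- runif(10)
  W2 <- hebbian_update(W, pre = runif(5), post = post, rate = 0.3, k = 4)
  expect_equal(unname(sqrt(rowSums(W2^2))), rep(1, 10), tolerance = 1e-12)
  untouched <- order(-post, seq_along(post))[5:10]
  expect_identical(W2[untouched, ], W[untouched, ])

  expect_error(hebbian_update(W, pre = runif(3), post = post, rate = 0.1),
               "dimension")
})

test_that("pc_activity rectifies, sparsifies and normalises", {
  W <- rbind(c(1, 0), c(0, 1), c(-1, 0.2), c(0.5, 0.5))
  a <- pc_activity(W, c(2, 1))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(max(a), 1)
  a2 <- pc_activity(W, c(2, 1), k_active = 2)
  expect_equal(sum(a2 > 0), 2)
  expect_equal(which(a2 > 0), c(1, 4))
})

test_that("learn_place_cells keeps the initial weights at rate zero", {
  mz <- tiny_maze()
  ps <- perception_state(mz)
  set.seed(17)
  walk <- random_walk(mz, 60)
  set.seed(99)
  pc <- learn_place_cells(walk, mz, ps, n_pc = 40, rate = 0)
  set.seed(99)
  W0 <- matrix(runif(40 * ps$ec_length), 40, ps$ec_length)
  W0 <- W0 / sqrt(rowSums(W0^2))
  expect_equal(pc$W, W0, tolerance = 1e-12)
  expect_equal(nrow(pc$W), 40)
})

test_that("learned place fields are compact for strongly active cells", {
  mz <- tiny_maze()
  ps <- perception_state(mz, grid_gain = 0.3)
  set.seed(12)
  walk <- random_walk(mz, 1000, persist = 8)
  pc <- learn_place_cells(walk, mz, ps, n_pc = 1000, rate = 1, k = 10,
                          k_active = 50)
  expect_equal(pc$n_pc, 1000)

  xs <- seq(-85, 85, by = 10)
  gp <- as.matrix(expand.grid(xs, xs))
  gp <- gp[sqrt(rowSums(gp^2)) <= 88, ]
  geom <- watermaze:::pack_geometry(mz, ps)
  act <- watermaze:::cpp_population_activity(
    pc$W, watermaze:::cpp_ec_inputs(gp, geom), 50L)
  peaks <- apply(act, 2, max)
  strong <- which(peaks > 0.5)
  cell_area <- 10 * 10
  diam <- vapply(strong, function(i) {
    area <- sum(act[, i] >= peaks[i] / 2) * cell_area
    2 * sqrt(area / pi)
  }, numeric(1))
  # half-max field diameter below 40% of the arena diameter (200 cm)
  expect_gte(mean(diam < 80), 0.5)
})

test_that("graph edges follow the consecutive-distinct-winner rule", {
  mz <- tiny_maze()
  ps <- perception_state(mz, grid_gain = 0.3)
  set.seed(23)
  walk <- random_walk(mz, 600, persist = 8)
  pc <- learn_place_cells(walk, mz, ps, n_pc = 400, rate = 1, k = 10,
                          k_active = 30)
  g <- learn_graph(pc, walk, n_gc = 100, rate = 0.02, k = 3, k_active = 10,
                   vigilance = 0.65)
  expect_equal(g$n_nodes, 100)
  expect_true(isSymmetric(g$adjacency))
  expect_false(any(diag(g$adjacency)))

  # replay the walk and rebuild the edge set independently
  geom <- watermaze:::pack_geometry(mz, ps)
  pcm <- watermaze:::cpp_population_activity(
    pc$W, watermaze:::cpp_ec_inputs(walk, geom), 30L)
  gcm <- watermaze:::cpp_population_activity(g$W_pc_gc, pcm, 10L)
  winners <- max.col(gcm, ties.method = "first")
  winners <- winners[rowSums(gcm) > 0]
  ref <- matrix(FALSE, 100, 100)
  for (t in seq_len(length(winners) - 1)) {
    a <- winners[t]; b <- winners[t + 1]
    if (a != b) { ref[a, b] <- TRUE; ref[b, a] <- TRUE }
  }
  expect_identical(g$adjacency, ref)
})

test_that("a constant-position walk yields a degenerate edge-free graph", {
  mz <- tiny_maze()
  ps <- perception_state(mz)
  walk <- matrix(rep(c(10, 10), each = 30), ncol = 2)
  set.seed(2)
  pc <- learn_place_cells(walk, mz, ps, n_pc = 100, rate = 0.5, k = 5,
                          k_active = 10)
  g <- learn_graph(pc, walk, n_gc = 20, rate = 0, k = 3, vigilance = 0.5)
  expect_equal(sum(g$adjacency), 0)
})

test_that("current_node picks the most driven graph cell", {
  g <- structure(list(W_pc_gc = rbind(c(1, 0, 0), c(0, 1, 0)), n_nodes = 2),
                 class = "wm_graph")
  expect_equal(current_node(g, c(0.1, 0.9, 0)), 2)
  g2 <- structure(list(W_pc_gc = rbind(c(1, 0), c(1, 0), c(0, 1)),
                       n_nodes = 3), class = "wm_graph")
  expect_equal(current_node(g2, c(1, 0)), 1)   # tie -> lowest id
  expect_error(current_node(g, c(0, 0, 0)), "unlocalized")
})

test_that("map learning is reproducible and reward-free", {
  mz <- tiny_maze()
  ps <- perception_state(mz, grid_gain = 0.3)
  build <- function() {
    set.seed(31)
    walk <- random_walk(mz, 300, persist = 8)
    pc <- learn_place_cells(walk, mz, ps, n_pc = 200, rate = 1, k = 5,
                            k_active = 20)
    learn_graph(pc, walk, n_gc = 40, rate = 0, k = 3, vigilance = 0.6)
  }
  g1 <- build(); g2 <- build()
  expect_identical(g1$W_pc_gc, g2$W_pc_gc)
  expect_identical(g1$adjacency, g2$adjacency)
  expect_identical(g1$centroids, g2$centroids)

  # no map-learning operation takes a reward argument
  expect_false("reward" %in% c(names(formals(learn_place_cells)),
                               names(formals(learn_graph)),
                               names(formals(hebbian_update))))
})
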