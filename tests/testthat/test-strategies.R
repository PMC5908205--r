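make_mf <- function(W, eta = 0.1, gamma = 0.9) {
  set.seed(1)
  m <- mf_module("D_c", "cue", cue_id = "c", n_input = ncol(W), n_ac = nrow(W),
                 eta = eta, gamma = gamma, w_init = 0)
  m$W <- W
  m
}

test_that("ac_activations is the weighted sum over the input", {
  m <- make_mf(matrix(0, 4, 3))
  expect_equal(ac_activations(m, c(1, 2, 3)), rep(0, 4))

  m2 <- make_mf(rbind(c(1, 2), c(0, 1)))
  expect_equal(ac_activations(m2, c(0.5, 1)), c(2.5, 1))
  r <- c(0.2, 0.7)
  expect_equal(ac_activations(m2, 2 * r), 2 * ac_activations(m2, r))
  expect_error(ac_activations(m2, c(1, 2, 3)), "dimension")
})

test_that("mf_propose is greedy with lowest-index ties and silence check", {
  m <- make_mf(matrix(0, 36, 2))
  p <- mf_propose(m, c(0.5, 0.5))  # all activations equal -> phi_0
  expect_equal(p$orientation, 0)
  expect_true(p$valid)

  m9 <- make_mf(matrix(0, 36, 1)); m9$W[10, 1] <- 1   # argmax i = 9 (0-based)
  expect_equal(mf_propose(m9, 1)$orientation, pi / 2)

  m3 <- make_mf(matrix(c(0.1, 0.9, 0.3), 3, 1))
  expect_equal(mf_propose(m3, 1)$orientation, 2 * pi / 3)

  # silent input population (invisible cue) -> invalid proposal
  expect_false(mf_propose(m3, 0)$valid)
})

test_that("mf_update applies TD learning on the nearest action cell", {
  m <- make_mf(matrix(0.5, 4, 2), eta = 0.1, gamma = 0.9)
  # delta = 0: reward 0, max a(next) chosen so target equals a_istar
  m_eq <- make_mf(rbind(c(1, 0), c(0.9, 0), c(0, 0), c(0, 0)), gamma = 0.9)
  # a_t[1] = 1 (executed 0 -> cell 1); target = 0.9 * max(a_next)
  upd <- mf_update(m_eq, c(1, 0), 0, reward = 0, input_next = c(10 / 9, 0))
  expect_equal(upd$W, m_eq$W, tolerance = 1e-12)

  # terminal reward 1 with zero value: dW = eta * 1 * input
  m0 <- make_mf(matrix(0, 4, 2), eta = 0.1)
  u <- mf_update(m0, c(1, 0), executed_orientation = 0, reward = 1,
                 input_next = c(0, 1), terminal = TRUE)
  expect_equal(u$W[1, ], c(0.1, 0))
  expect_equal(u$W[-1, ], m0$W[-1, ])

  # orientation exactly between cells 4 and 5 (0-based 3 and 4) -> row 4
  m36 <- make_mf(matrix(0, 36, 1), eta = 1)
  phi <- (2 * pi * 3 / 36 + 2 * pi * 4 / 36) / 2
  u2 <- mf_update(m36, 1, phi, reward = 1, input_next = 1, terminal = TRUE)
  expect_equal(which(u2$W != 0), 4)

  expect_error(mf_update(m0, c(1, 0), 0, reward = 0.5, input_next = c(0, 1)),
               "reward")
})

path_graph <- function(alpha = 0.9) {
  g <- random_wm_graph(3, alpha)
  g$adjacency[] <- FALSE
  g$adjacency[1, 2] <- g$adjacency[2, 1] <- TRUE
  g$adjacency[2, 3] <- g$adjacency[3, 2] <- TRUE
  g$centroids <- rbind(c(0, 0), c(10, 0), c(20, 0))
  g
}

test_that("goal value diffusion equals alpha^distance", {
  g <- planning_set_goal(path_graph(), 3, c(22, 0))
  expect_equal(g$G, c(0.81, 0.9, 1), tolerance = 1e-12)

  # re-setting the goal fully replaces the field
  g2 <- planning_set_goal(g, 1, c(-2, 0))
  expect_equal(g2$G, c(1, 0.9, 0.81), tolerance = 1e-12)

  # nodes disconnected from the goal stay at zero
  g3 <- path_graph()
  g3$adjacency[2, 3] <- g3$adjacency[3, 2] <- FALSE
  g3 <- planning_set_goal(g3, 3, c(22, 0))
  expect_equal(g3$G, c(0, 0, 1))

  # alpha -> 1: all reachable nodes approach 1
  g4 <- path_graph(alpha = 1 - 1e-9)
  g4 <- planning_set_goal(g4, 3, c(22, 0))
  expect_equal(g4$G, c(1, 1, 1), tolerance = 1e-6)

  expect_error(planning_propagate(path_graph()), "goal")
  expect_error(planning_set_goal(path_graph(), 99, c(0, 0)), "unknown node")
})

test_that("planning proposals head for the best-valued neighbour", {
  g <- path_graph()
  expect_false(planning_propose(g, 1)$valid)      # no goal yet

  g <- planning_set_goal(g, 3, c(22, 0))
  expect_equal(planning_propose(g, 1)$orientation, 0)  # towards node 2
  expect_equal(planning_propose(g, 3)$orientation, 0)  # towards goal position

  lone <- g
  lone$adjacency[1, ] <- lone$adjacency[, 1] <- FALSE
  expect_false(planning_propose(lone, 1)$valid)
})

test_that("diffusion and first steps match a breadth-first-search oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    g <- random_wm_graph(n, alpha = 0.9)
    goal <- sample(n, 1)
    g <- planning_set_goal(g, goal, g$centroids[goal, ])
    d <- bfs_distances(g$adjacency, goal)
    expect_equal(g$G, ifelse(is.finite(d), 0.9^d, 0), tolerance = 1e-9)
    for (node in sample(n, 3)) {
      if (node == goal) next
      nb <- which(g$adjacency[node, ])
      if (length(nb) == 0) next
      p <- planning_propose(g, node)
      best <- nb[which.max(g$G[nb])]
      # the chosen neighbour lies on a shortest path to the goal
      if (is.finite(d[node]) && d[node] > 0) {
        expect_equal(d[best], d[node] - 1)
      }
      v <- g$centroids[best, ] - g$centroids[node, ]
      expect_equal(p$orientation, atan2(v[2], v[1]) %% (2 * pi))
    }
  }
})

test_that("exploration persists for three executed steps and draws uniformly", {
  st <- exploration_state(orientation = 1.0, steps_remaining = 2L)
  out <- exploration_propose(st)
  expect_equal(out$proposal$orientation, 1.0)
  expect_equal(out$state$steps_remaining, 1L)
  out2 <- exploration_propose(out$state)
  expect_equal(out2$proposal$orientation, 1.0)
  expect_equal(out2$state$steps_remaining, 0L)

  set.seed(8)
  fresh <- exploration_propose(exploration_state())
  expect_equal(fresh$state$steps_remaining, 2L)  # 3 uses in total

  # uniformity of fresh draws on [0, 2*pi) at the 1% level
  set.seed(42)
  draws <- vapply(1:10000,
                  function(i) exploration_propose(exploration_state())$proposal$orientation,
                  numeric(1))
  h <- table(cut(draws, breaks = seq(0, 2 * pi, length.out = 21)))
  expect_gt(chisq.test(h)$p.value, 0.01)
})
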