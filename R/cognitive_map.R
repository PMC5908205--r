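# Cognitive map: Hebbian learning of a pool of place cells from entorhinal
# input, sparsification into graph cells, and construction of the topological
# planning graph from a random walk. Everything here is reward-independent:
# the map is learned latently, before any platform is encountered.

#' Competitive Hebbian weight update
#'
#' For the `k` most active postsynaptic cells, `dW[i, j] = rate * post[i] *
#' pre[j]`, after which each updated row is renormalised to unit L2 norm.
#' Other rows are untouched. Ties in postsynaptic activity are broken by
#' lowest cell index.
#'
#' @param W weight matrix, `n_post x n_pre`, rows of unit norm.
#' @param pre presynaptic activity vector (length `n_pre`).
#' @param post postsynaptic activity vector (length `n_post`).
#' @param rate learning rate (>= 0).
#' @param k number of winners that learn.
#' @return the updated weight matrix.
#' @export
hebbian_update <- function(W, pre, post, rate, k = 10) {
  if (ncol(W) != length(pre) || nrow(W) != length(post)) {
    stop("dimension mismatch between W, pre and post")
  }
  stopifnot(rate >= 0)
  if (rate == 0) return(W)
  winners <- order(-post, seq_along(post))[seq_len(min(k, length(post)))]
  for (i in winners) {
    row <- W[i, ] + rate * post[i] * pre
    nrm <- sqrt(sum(row^2))
    if (nrm > 0) W[i, ] <- row / nrm
  }
  W
}

#' Place-cell activity
#'
#' Weighted sum of the entorhinal input, rectified, sparsified by
#' k-winner-take-all (only the `k_active` most active cells stay on,
#' emulating the sparse dentate code needed for the downstream graph
#' competition), then divisively normalised by the population maximum so
#' that activities lie in `[0, 1]`.
#'
#' @param W `n_pc x |EC|` weight matrix.
#' @param ec entorhinal input vector.
#' @param k_active number of cells allowed to stay active (0 = all).
#' @return activity vector in `[0, 1]`.
#' @export
pc_activity <- function(W, ec, k_active = 0) {
  a <- pmax(as.vector(W %*% ec), 0)
  if (k_active > 0 && k_active < length(a)) {
    keep <- order(-a, seq_along(a))[seq_len(k_active)]
    sparse <- numeric(length(a))
    sparse[keep] <- a[keep]
    a <- sparse
  }
  m <- max(a)
  if (m > 0) a / m else a
}

#' Generate a random exploratory walk
#'
#' Persistent random walk used to pre-train the map: a fresh uniform heading
#' is drawn every `persist` steps and the agent moves `step` cm per timestep,
#' sliding along the wall. Uses the current R random number generator state.
#'
#' @param maze a [maze()].
#' @param n_steps number of timesteps.
#' @param step step length, cm.
#' @param persist number of steps a drawn heading is kept.
#' @return an `(n_steps + 1) x 2` matrix of positions (row 1 = start).
#' @export
random_walk <- function(maze, n_steps = 1000, step = 6, persist = 3) {
  rmax <- maze$arena_radius - maze$agent_radius
  r0 <- rmax * sqrt(runif(1))
  th0 <- runif(1, 0, 2 * pi)
  p <- pose(r0 * cos(th0), r0 * sin(th0))
  out <- matrix(0, n_steps + 1, 2)
  out[1, ] <- p[1:2]
  heading <- 0
  for (t in seq_len(n_steps)) {
    if ((t - 1) %% persist == 0) heading <- runif(1, 0, 2 * pi)
    p <- move_agent(p, heading, step, maze)
    out[t + 1, ] <- p[1:2]
  }
  out
}

#' Learn a population of place cells from a walk
#'
#' Weights from the entorhinal input to `n_pc` place cells are randomly
#' initialised (rows unit-norm), then updated by [hebbian_update()] at every
#' walk step with the entorhinal input as presynaptic and the place-cell
#' activity as postsynaptic signal. Field centres are estimated as
#' activity-weighted mean positions over the walk.
#'
#' @param walk matrix of positions from [random_walk()].
#' @param maze the [maze()] the walk was generated in.
#' @param pstate a [perception_state()] for that maze.
#' @param n_pc number of place cells.
#' @param rate Hebbian learning rate.
#' @param k number of winners per update.
#' @param k_active population sparseness (cells active per timestep).
#' @return an object of class `wm_place_cells` with elements `W`
#'   (`n_pc x |EC|`), `field_centers` (`n_pc x 2`) and `pstate`.
#' @export
learn_place_cells <- function(walk, maze, pstate = perception_state(maze),
                              n_pc = 1000, rate = 0.1, k = 10,
                              k_active = 50) {
  stopifnot(nrow(walk) >= 1)
  geom <- pack_geometry(maze, pstate)
  ec <- cpp_ec_inputs(walk, geom)
  W0 <- matrix(runif(n_pc * pstate$ec_length), n_pc, pstate$ec_length)
  W0 <- W0 / sqrt(rowSums(W0^2))
  W <- cpp_learn_population(W0, ec, rate, as.integer(k), as.integer(k_active))
  act <- cpp_population_activity(W, ec, as.integer(k_active))   # n_steps x n_pc
  wsum <- colSums(act)
  fx <- as.vector(crossprod(act, walk[, 1])) / ifelse(wsum > 0, wsum, 1)
  fy <- as.vector(crossprod(act, walk[, 2])) / ifelse(wsum > 0, wsum, 1)
  structure(list(W = W, field_centers = cbind(fx, fy), pstate = pstate,
                 maze = maze, n_pc = n_pc, k_active = k_active),
            class = "wm_place_cells")
}

#' Build the topological planning graph
#'
#' Graph-cell weights over the place-cell population are learned by a
#' competitive Hebbian rule with novelty-gated recruitment along the walk:
#' a fresh cell commits to the current place-cell pattern whenever no
#' committed cell matches it above the vigilance threshold, and the
#' best-matching committed cells are otherwise refined Hebbian-style. The walk is then replayed with the
#' trained weights: the winning (most active) graph cell is recorded at every
#' step and an edge is added between every pair of consecutive distinct
#' winners, so two nodes are linked exactly when the agent moved between the
#' locations they represent without a third winner in between. Node centroids
#' are activity-weighted mean positions over the steps the node won.
#'
#' @param pc_pop a trained [learn_place_cells()] population.
#' @param walk the walk matrix the population was trained on.
#' @param n_gc number of graph cells.
#' @param rate Hebbian learning rate.
#' @param k number of winners per update.
#' @param k_active graph-cell population sparseness (nodes active per step).
#' @param vigilance cosine-similarity threshold below which a fresh graph
#'   cell is recruited for the current place-cell pattern; sets the spatial
#'   grain of the graph.
#' @param alpha goal-devaluation factor in `(0, 1)` used by planning.
#' @return an object of class `wm_graph` with fields `W_pc_gc`, `adjacency`
#'   (symmetric logical matrix), `centroids`, `goal_node`, `goal_position`,
#'   `G` (goal values), `alpha`.
#' @export
learn_graph <- function(pc_pop, walk, n_gc = 100, rate = 0.1, k = 10,
                        k_active = 10, vigilance = 0.3, alpha = 0.9) {
  stopifnot(inherits(pc_pop, "wm_place_cells"), alpha > 0, alpha < 1)
  geom <- pack_geometry(pc_pop$maze, pc_pop$pstate)
  ec <- cpp_ec_inputs(walk, geom)
  pc <- cpp_population_activity(pc_pop$W, ec, as.integer(pc_pop$k_active))
  Wg <- cpp_learn_population_recruit(as.integer(n_gc), pc, rate,
                                     as.integer(k), vigilance)
  gc <- cpp_population_activity(Wg, pc, as.integer(k_active))  # n_steps x n_gc
  winners <- max.col(gc, ties.method = "first")
  zero <- rowSums(gc) == 0
  adjacency <- matrix(FALSE, n_gc, n_gc)
  wseq <- winners[!zero]
  if (length(wseq) >= 2) {
    a <- wseq[-length(wseq)]
    b <- wseq[-1]
    keep <- a != b
    for (e in which(keep)) {
      adjacency[a[e], b[e]] <- TRUE
      adjacency[b[e], a[e]] <- TRUE
    }
  }
  gw <- gc * 0
  gw[cbind(seq_along(winners), winners)] <- gc[cbind(seq_along(winners), winners)]
  wsum <- colSums(gw)
  cx <- as.vector(crossprod(gw, walk[, 1])) / ifelse(wsum > 0, wsum, 1)
  cy <- as.vector(crossprod(gw, walk[, 2])) / ifelse(wsum > 0, wsum, 1)
  visited <- wsum > 0
  structure(list(W_pc_gc = Wg, adjacency = adjacency,
                 centroids = cbind(cx, cy), visited = visited,
                 n_nodes = n_gc, k_active = k_active,
                 goal_node = NA_integer_,
                 goal_position = NULL, G = numeric(n_gc), alpha = alpha),
            class = "wm_graph")
}

#' Current graph node of the agent
#'
#' The graph cell with maximal activation `W_pc_gc %*% pc_activity`; ties are
#' broken by lowest node id.
#'
#' @param graph a [learn_graph()] object.
#' @param pc_activity place-cell activity vector.
#' @return integer node id.
#' @export
current_node <- function(graph, pc_activity) {
  if (all(pc_activity == 0)) stop("unlocalized agent: all-zero place-cell activity")
  a <- as.vector(graph$W_pc_gc %*% pc_activity)
  which.max(a)
}
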