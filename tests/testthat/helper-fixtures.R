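# Shared fixtures and independent oracles.

# small maze with one proximal and two distal cues
tiny_maze <- function() {
  maze(100, 7.5,
       cues = list(cue_spec("p1", "proximal", c(30, 30)),
                   cue_spec("d1", "distal", c(120, 0)),
                   cue_spec("d2", "distal", c(0, 120))),
       platform = platform_spec(c(30, 30), 5))
}

# random connected graph as a wm_graph-shaped object (no learning involved)
random_wm_graph <- function(n, alpha = 0.9) {
  adjacency <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)[-1]) {          # random spanning tree
    j <- sample(i - 1, 1)
    adjacency[i, j] <- adjacency[j, i] <- TRUE
  }
  extra <- max(0, round(n / 2))
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    adjacency[ij[1], ij[2]] <- adjacency[ij[2], ij[1]] <- TRUE
  }
  diag(adjacency) <- FALSE
  structure(
    list(W_pc_gc = NULL, adjacency = adjacency,
         centroids = cbind(runif(n, -90, 90), runif(n, -90, 90)),
         visited = rep(TRUE, n), n_nodes = n, k_active = 10,
         goal_node = NA_integer_, goal_position = NULL,
         G = numeric(n), alpha = alpha),
    class = "wm_graph")
}

# independent BFS distances via igraph
bfs_distances <- function(adjacency, from) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  as.vector(igraph::distances(g, v = from))
}

# exact Mann-Whitney oracle by full enumeration of group assignments
mw_oracle <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(n, na), 2, u_of)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exact signed-rank oracle by recursive enumeration over ranks
wsr_oracle <- function(a, b) {
  d <- (a - b)[a != b]
  r <- rank(abs(d))
  wp_obs <- sum(r[d > 0])
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)   # distribution of W+ by recursion
  p_le <- mean(sums <= wp_obs + 1e-9)
  p_ge <- mean(sums >= wp_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# cached experiment runs shared across test files (acceptance re-uses them)
.sim_cache <- new.env(parent = emptyenv())
sim_cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}
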