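# Perception: convert agent pose and maze contents into population activities.
# Two codes form the entorhinal input: lattice-periodic grid cells carrying
# idiothetic position (path integration is assumed perfect, so grid activity
# is a deterministic function of true position) and, per landmark, a ring of
# bearing-tuned cue cells with exponential distance decay.

#' Cue-cell block for one landmark
#'
#' `n_cells` cells with preferred allocentric bearings `2*pi*m/n_cells`;
#' cell m responds with `exp(-d(theta_m, bearing)^2 / (2 sigma^2)) *
#' exp(-distance / lambda)` where `d` is the wrapped angular difference.
#' Distal cues get a large distance constant so that they act mostly as
#' directional references.
#'
#' @param cue_id label of the cue this block encodes.
#' @param n_cells number of cells in the ring.
#' @param sigma angular tuning width, radians.
#' @param lambda distance constant, cm.
#' @return an object of class `wm_cue_block`.
#' @export
cue_cell_block <- function(cue_id, n_cells = 12, sigma = pi / 8, lambda = 50) {
  stopifnot(n_cells >= 1, sigma > 0, lambda > 0)
  structure(
    list(cue_id = as.character(cue_id), n_cells = n_cells,
         preferred = 2 * pi * (seq_len(n_cells) - 1) / n_cells,
         sigma = sigma, lambda = lambda),
    class = "wm_cue_block"
  )
}

#' Cue-cell activity for one cue
#'
#' @param pose a [pose()].
#' @param cue a [cue_spec()]; if invisible the whole block is silent.
#' @param block the matching [cue_cell_block()].
#' @return numeric activity vector in `[0, 1]`, length `block$n_cells`.
#' @export
cue_cell_activity <- function(pose, cue, block) {
  if (block$cue_id != cue$id) stop("block does not belong to cue '", cue$id, "'")
  if (!cue$visible) return(numeric(block$n_cells))
  bd <- bearing_distance(pose, cue)
  dth <- angle_diff(block$preferred, bd[["bearing"]])
  exp(-dth^2 / (2 * block$sigma^2)) * exp(-bd[["distance"]] / block$lambda)
}

#' Grid-cell block
#'
#' Standard three-plane-wave interference pattern: each cell sums three
#' cosines whose wave vectors are 60 degrees apart, at the cell's lattice
#' scale, orientation and spatial phase; the sum is rectified and scaled into
#' `[0, 1]` (activity 1 at the lattice peaks).
#'
#' @param scales lattice scales in cm, one module per scale.
#' @param orientations lattice orientation per scale, radians.
#' @param phases_per_scale number of spatial phases per scale (laid out on a
#'   square grid over the unit cell).
#' @return an object of class `wm_grid_block` with `n_cells =
#'   length(scales) * phases_per_scale`.
#' @export
grid_cell_block <- function(scales = c(40, 60, 85),
                            orientations = c(0, 0.35, 0.7),
                            phases_per_scale = 9) {
  if (any(scales <= 0)) stop("grid scale must be > 0")
  stopifnot(length(orientations) == length(scales))
  m <- as.integer(round(sqrt(phases_per_scale)))
  stopifnot(m * m == phases_per_scale)
  sc <- numeric(0); ori <- numeric(0); px <- numeric(0); py <- numeric(0)
  for (s in seq_along(scales)) {
    for (i in 0:(m - 1)) for (j in 0:(m - 1)) {
      sc <- c(sc, scales[s]); ori <- c(ori, orientations[s])
      px <- c(px, scales[s] * i / m)
      py <- c(py, scales[s] * j / m)
    }
  }
  structure(list(n_cells = length(sc), scale = sc, orientation = ori,
                 phase = cbind(px, py)), class = "wm_grid_block")
}

#' Grid-cell activity at a position
#'
#' @param position length-2 numeric, cm.
#' @param block a [grid_cell_block()].
#' @return numeric activity vector in `[0, 1]`.
#' @export
grid_cell_activity <- function(position, block) {
  if (any(block$scale <= 0)) stop("grid scale must be > 0")
  n <- block$n_cells
  out <- numeric(n)
  for (i in seq_len(n)) {
    dx <- position[1] - block$phase[i, 1]
    dy <- position[2] - block$phase[i, 2]
    k <- 4 * pi / (sqrt(3) * block$scale[i])
    s <- 0
    for (j in 0:2) {
      th <- block$orientation[i] + j * pi / 3
      s <- s + cos(k * (cos(th) * dx + sin(th) * dy))
    }
    out[i] <- max(0, s) / 3
  }
  out
}

#' Build the perception state for a maze
#'
#' Fixes the entorhinal layout for a run: one grid block plus one cue-cell
#' block per cue in the maze's cue-id order. The resulting input vector length
#' is constant across the run.
#'
#' @param maze a [maze()].
#' @param n_cc cells per cue block.
#' @param sigma cue-cell angular tuning width, radians.
#' @param lambda_proximal,lambda_distal cue-cell distance constants, cm.
#' @param grid a [grid_cell_block()].
#' @param grid_gain gain applied to the grid segment of the entorhinal
#'   vector, balancing idiothetic against visual input energy (the cue
#'   segment disambiguates residual lattice aliases of the grid code).
#' @return an object of class `wm_perception`.
#' @export
perception_state <- function(maze, n_cc = 12, sigma = pi / 8,
                             lambda_proximal = 50, lambda_distal = 150,
                             grid = grid_cell_block(), grid_gain = 1) {
  blocks <- lapply(maze$cues, function(cc) {
    cue_cell_block(cc$id, n_cells = n_cc, sigma = sigma,
                   lambda = if (cc$kind == "distal") lambda_distal else lambda_proximal)
  })
  structure(
    list(maze_cue_ids = names(maze$cues), grid = grid, cue_blocks = blocks,
         grid_gain = grid_gain, n_grid = grid$n_cells,
         n_cc_total = n_cc * length(blocks),
         ec_length = grid$n_cells + n_cc * length(blocks)),
    class = "wm_perception"
  )
}

#' Entorhinal input vector
#'
#' Deterministic concatenation `[grid activities; cue blocks in fixed cue-id
#' order]`.
#'
#' @param pose a [pose()].
#' @param maze a [maze()] (must carry the same cues the perception state was
#'   built for).
#' @param pstate a [perception_state()].
#' @return numeric vector of length `pstate$ec_length`, entries in `[0, 1]`.
#' @export
ec_input <- function(pose, maze, pstate) {
  if (!identical(names(maze$cues), pstate$maze_cue_ids)) {
    stop("maze cues do not match the perception state")
  }
  g <- pstate$grid_gain * grid_cell_activity(c(pose[["x"]], pose[["y"]]), pstate$grid)
  ccs <- unlist(lapply(pstate$maze_cue_ids, function(id) {
    cue_cell_activity(pose, maze$cues[[id]], pstate$cue_blocks[[id]])
  }))
  c(g, ccs)
}

#' All cue-cell activities (visual segment of the input)
#'
#' @inheritParams ec_input
#' @return numeric vector of length `pstate$n_cc_total`.
#' @export
cue_cell_activities <- function(pose, maze, pstate) {
  unlist(lapply(pstate$maze_cue_ids, function(id) {
    cue_cell_activity(pose, maze$cues[[id]], pstate$cue_blocks[[id]])
  }))
}
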