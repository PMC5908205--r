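# Model assembly: instantiate a group (which strategies an agent carries),
# pre-train its cognitive map, and run trials through the simulation engine.

#' Default simulation parameters
#'
#' All constants of the model in one place; every entry can be overridden via
#' the `params` argument of [build_model()] / [run_experiment()] or a config
#' file. Units: cm, radians, timesteps.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of parameters.
#' @export
wm_params <- function(...) {
  defaults <- list(
    arena_radius = 100, agent_radius = 7.5, platform_radius = 5,
    step_len = 6, max_steps = 350L,
    # perception
    n_cc = 12L, sigma = pi / 8, lambda_proximal = 50, lambda_distal = 500,
    grid_scales = c(40, 60, 85), grid_orientations = c(0, 0.35, 0.7),
    phases_per_scale = 9L, grid_gain = 0.3,
    # cognitive map
    n_pc = 1000L, n_gc = 100L, hebb_rate = 1, gc_rate = 0.02,
    k_pc = 10L, k_gc = 3L, n_pc_active = 50L, n_gc_active = 10L,
    vigilance = 0.8, walk_steps = 1000L, walk_persist = 8L, alpha = 0.9,
    # model-free strategies
    n_ac = 36L, gamma = 0.9, eta_direction = 0.1, eta_locale = 0.3,
    w_init = 0.01,
    # gating network
    eta_gating = 0.05, gamma_gating = 0.9, z_init = 0.01,
    # trial mechanics
    guided = TRUE, learn_guided = TRUE,
    start_radius = 88, start_angles = c(1, 3, 5, 7) * pi / 4
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  modifyList(defaults, over)
}

# Pack maze + perception geometry for the engine. Cue order is the maze's
# fixed cue-id order; all cue blocks share n_cc and sigma.
pack_geometry <- function(maze, pstate) {
  ids <- pstate$maze_cue_ids
  blocks <- pstate$cue_blocks
  n_cc <- if (length(blocks)) blocks[[1]]$n_cells else 0L
  sigma <- if (length(blocks)) blocks[[1]]$sigma else pi / 8
  list(
    arena_radius = maze$arena_radius, agent_radius = maze$agent_radius,
    grid_gain = pstate$grid_gain,
    grid_scale = pstate$grid$scale, grid_orient = pstate$grid$orientation,
    grid_px = pstate$grid$phase[, 1], grid_py = pstate$grid$phase[, 2],
    n_cues = length(ids), n_cc = as.integer(n_cc),
    cue_x = vapply(ids, function(i) maze$cues[[i]]$position[1], numeric(1)),
    cue_y = vapply(ids, function(i) maze$cues[[i]]$position[2], numeric(1)),
    cue_lambda = vapply(ids, function(i) blocks[[i]]$lambda, numeric(1)),
    cue_visible = vapply(ids, function(i) as.integer(maze$cues[[i]]$visible), integer(1)),
    sigma = sigma,
    prefs = if (n_cc > 0) blocks[[1]]$preferred else numeric(0),
    plat_x = maze$platform$center[1], plat_y = maze$platform$center[2],
    plat_r = maze$platform$radius, plat_present = maze$platform$present
  )
}

#' Instantiate a model group
#'
#' Builds the agent for one simulated individual: the requested strategy
#' composition, a freshly pre-trained cognitive map when a place-based
#' strategy is present (1000-step random walk), randomly initialised
#' model-free and gating weights.
#'
#' Compositions: `D` = one Direction module per cue (plus Exploration);
#' `P` = Planning; `L` = Locale; `DP`, `DL` = Direction modules on the
#' proximal cues (on all cues when the maze has none) plus the place-based
#' strategy; `chance` = Exploration only. A hippocampal lesion corresponds to
#' removing P/L, a striatal lesion to removing D/L. Every group includes
#' Exploration.
#'
#' @param maze the experiment's [maze()] with all cues registered.
#' @param group composition label.
#' @param params parameter list from [wm_params()].
#' @return an object of class `wm_model`.
#' @export
build_model <- function(maze, group = c("DP", "D", "P", "DL", "L", "chance"),
                        params = wm_params()) {
  group <- match.arg(group)
  pstate <- perception_state(
    maze, n_cc = params$n_cc, sigma = params$sigma,
    lambda_proximal = params$lambda_proximal,
    lambda_distal = params$lambda_distal,
    grid = grid_cell_block(params$grid_scales, params$grid_orientations,
                           params$phases_per_scale),
    grid_gain = params$grid_gain)

  needs_map <- group %in% c("P", "DP", "L", "DL")
  map <- NULL
  if (needs_map) {
    walk <- random_walk(maze, params$walk_steps, step = params$step_len,
                        persist = params$walk_persist)
    pc_pop <- learn_place_cells(walk, maze, pstate, n_pc = params$n_pc,
                                rate = params$hebb_rate, k = params$k_pc,
                                k_active = params$n_pc_active)
    graph <- learn_graph(pc_pop, walk, n_gc = params$n_gc,
                         rate = params$gc_rate, k = params$k_gc,
                         k_active = params$n_gc_active,
                         vigilance = params$vigilance, alpha = params$alpha)
    map <- list(pc_pop = pc_pop, graph = graph)
  }

  cue_ids <- names(maze$cues)
  kinds <- vapply(maze$cues, function(cc) cc$kind, character(1))
  direction_cues <- switch(group,
    D = cue_ids,
    DP = , DL = if (any(kinds == "proximal")) cue_ids[kinds == "proximal"] else cue_ids,
    character(0))

  modules <- list()
  levels <- character(0)
  for (cid in direction_cues) {
    modules[[length(modules) + 1]] <- mf_module(
      paste0("D_", cid), "cue", cue_id = cid, n_input = params$n_cc,
      n_ac = params$n_ac, eta = params$eta_direction, gamma = params$gamma,
      w_init = params$w_init)
    levels <- c(levels, "direction")
  }
  if (group %in% c("P", "DP")) {
    modules[[length(modules) + 1]] <- list(id = "planning")
    levels <- c(levels, "top")
  }
  if (group %in% c("L", "DL")) {
    modules[[length(modules) + 1]] <- mf_module(
      "locale", "pc", n_input = params$n_pc, n_ac = params$n_ac,
      eta = params$eta_locale, gamma = params$gamma, w_init = params$w_init)
    levels <- c(levels, "top")
  }
  modules[[length(modules) + 1]] <- list(id = "exploration")
  levels <- c(levels, "exploration")

  ids <- vapply(modules, function(m) m$id, character(1))
  n_gate_in <- pstate$n_cc_total + if (needs_map) params$n_gc else 0L
  gating <- gating_network(ids, levels, n_gate_in, eta = params$eta_gating,
                           gamma = params$gamma_gating, z_init = params$z_init)

  structure(
    list(maze = maze, pstate = pstate, params = params, group = group,
         map = map, modules = modules, module_ids = ids, levels = levels,
         gating = gating, exploration = exploration_state()),
    class = "wm_model"
  )
}

# Per-node planning waypoint table: for each graph node, the point the
# Planning module steers towards while that node is active -- the centroid of
# the neighbour with maximal goal value, or the memorised goal position at
# the goal node itself. The engine computes the proposed orientation from the
# agent's current position towards this waypoint, which avoids orbiting
# artefacts that a fixed per-node direction would produce.
plan_table <- function(graph) {
  n <- graph$n_nodes
  tx <- numeric(n); ty <- numeric(n)
  valid <- logical(n)
  if (is.na(graph$goal_node)) {
    return(list(tx = tx, ty = ty, valid = valid, goal_set = FALSE))
  }
  for (i in seq_len(n)) {
    if (i == graph$goal_node) {
      tx[i] <- graph$goal_position[1]; ty[i] <- graph$goal_position[2]
      valid[i] <- TRUE
    } else {
      nb <- which(graph$adjacency[i, ])
      if (length(nb) == 0) next
      best <- nb[which.max(graph$G[nb])]
      tx[i] <- graph$centroids[best, 1]; ty[i] <- graph$centroids[best, 2]
      valid[i] <- TRUE
    }
  }
  list(tx = tx, ty = ty, valid = valid, goal_set = TRUE)
}

# Apply a protocol row to the maze template: platform position / presence and
# per-trial cue visibility and positions (attached cues follow the platform).
trial_maze <- function(maze, trial) {
  maze$platform$center <- c(trial$platform_x, trial$platform_y)
  maze$platform$present <- trial$platform_present
  vis <- trial$cue_vis[[1]]
  if (!is.null(vis)) for (id in names(vis)) maze$cues[[id]]$visible <- vis[[id]]
  maze <- resolve_cue_positions(maze, c(trial$platform_x, trial$platform_y))
  pos <- trial$cue_pos[[1]]
  if (!is.null(pos)) for (id in names(pos)) maze$cues[[id]]$position <- pos[[id]]
  maze
}

#' Run one trial
#'
#' Executes the per-timestep loop: perceive, let every module propose, select
#' by the gating network, move 6 cm, check reward, update all model-free
#' modules and the gating network with the executed orientation. On reaching
#' the platform the trial ends and the planning goal is (re)memorised at the
#' current graph node. If the platform is not found within `max_steps` the
#' agent is guided straight to it (learning updates still applied en route,
#' terminal update on arrival) and the trial is flagged guided. Probe trials
#' without a platform run the full `max_steps` unrewarded.
#'
#' The model-free and gating weight matrices are updated in place by the
#' engine for speed: after the call, matrices reachable from the input
#' `model` object alias the updated state (take explicit copies with
#' `W + 0` if the pre-trial weights are needed).
#'
#' @param model a [build_model()] agent.
#' @param trial one row of a protocol tibble (see [build_protocol()]).
#' @param record_steps record the per-timestep trajectory?
#' @return list with elements `model` (updated agent) and `record` (latency,
#'   rewarded, guided, per-module selection counts, optional steps matrix).
#' @export
run_trial <- function(model, trial, record_steps = FALSE) {
  mz <- trial_maze(model$maze, trial)
  geom <- pack_geometry(mz, model$pstate)
  pt <- if (!is.null(model$map)) plan_table(model$map$graph) else
    list(tx = numeric(0), ty = numeric(0), valid = logical(0), goal_set = FALSE)

  mf_list <- list()
  mf_index <- integer(length(model$modules))
  cue_ids <- names(mz$cues)
  for (k in seq_along(model$modules)) {
    m <- model$modules[[k]]
    if (inherits(m, "wm_mf_module")) {
      input <- if (m$input_source == "pc") -1L else
        as.integer(match(m$cue_id, cue_ids) - 1L)
      mf_list[[length(mf_list) + 1]] <-
        list(W = m$W, input = input, eta = m$eta, gamma = m$gamma)
      mf_index[k] <- length(mf_list) - 1L
    } else {
      mf_index[k] <- -1L
    }
  }
  lv <- match(model$levels, c("direction", "top", "exploration")) - 1L

  opts <- list(
    levels = as.integer(lv), mf_index = as.integer(mf_index),
    goal_set = pt$goal_set,
    eta_g = model$gating$eta, gamma_g = model$gating$gamma,
    step_len = model$params$step_len, max_steps = model$params$max_steps,
    record_steps = isTRUE(record_steps),
    learn_guided = model$params$learn_guided, guided = model$params$guided,
    start_x = trial$start_x, start_y = trial$start_y,
    expl_orientation = 0, expl_steps_remaining = 0L,
    pc_active = as.integer(model$params$n_pc_active),
    gc_active = as.integer(model$params$n_gc_active))

  map_arg <- if (!is.null(model$map))
    list(W_ec_pc = model$map$pc_pop$W, W_pc_gc = model$map$graph$W_pc_gc) else NULL

  rec <- cpp_run_trial(geom, map_arg, mf_list, pt$tx, pt$ty, pt$valid, opts,
                       model$gating$z)

  if (rec$rewarded && !is.null(model$map) && !is.na(rec$final_node)) {
    model$map$graph <- planning_set_goal(model$map$graph, rec$final_node,
                                         c(trial$platform_x, trial$platform_y))
  }
  if (isTRUE(record_steps) && rec$n_rec > 0) {
    rec$steps <- rec$steps[seq_len(rec$n_rec), , drop = FALSE]
    colnames(rec$steps) <- c("x", "y", "module", "orientation", "guided")
    rec$proposals <- rec$proposals[seq_len(rec$n_rec), , drop = FALSE]
    colnames(rec$proposals) <- model$module_ids
  } else {
    rec$steps <- NULL
    rec$proposals <- NULL
  }
  list(model = model, record = rec)
}
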