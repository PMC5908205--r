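# The behavioural experts. Each module emits an orientation proposal -- the
# model's common currency -- at every timestep:
#   * Direction / Locale: model-free TD Q-learning from an input population
#     (one cue's cue-cell block, or the place cells) to 36 action cells whose
#     preferred orientations tile [0, 2*pi).
#   * Planning: model-based activation-diffusion of goal value over the
#     learned topological graph; proposes the first step of a shortest path.
#   * Exploration: uniform random orientation, persisted for three
#     consecutive executed steps.

#' Create a model-free module (Direction or Locale)
#'
#' @param id module label.
#' @param input_source `"cue"` (Direction: one cue's cue-cell block) or
#'   `"pc"` (Locale: the place-cell population).
#' @param cue_id cue label for Direction modules.
#' @param n_input input dimensionality.
#' @param n_ac number of action cells; cell i prefers orientation
#'   `2*pi*i/n_ac`.
#' @param eta TD learning rate.
#' @param gamma TD discount.
#' @param w_init upper bound of the uniform random weight initialisation.
#' @return an object of class `wm_mf_module`.
#' @export
mf_module <- function(id, input_source = c("cue", "pc"), cue_id = NULL,
                      n_input, n_ac = 36, eta = 0.1, gamma = 0.9,
                      w_init = 0.01) {
  input_source <- match.arg(input_source)
  if (input_source == "cue" && is.null(cue_id)) stop("Direction module needs a cue_id")
  W <- matrix(runif(n_ac * n_input, 0, w_init), n_ac, n_input)
  structure(
    list(id = as.character(id), input_source = input_source, cue_id = cue_id,
         W = W, n_ac = n_ac, phis = 2 * pi * (seq_len(n_ac) - 1) / n_ac,
         eta = eta, gamma = gamma),
    class = "wm_mf_module"
  )
}

#' Action-cell activations
#'
#' `a_i = sum_j W[i, j] * r[j]`: the expected value of moving in orientation
#' `phi_i` given the current input.
#'
#' @param module a [mf_module()].
#' @param input activity vector.
#' @return numeric activation vector of length `n_ac`.
#' @export
ac_activations <- function(module, input) {
  if (length(input) != ncol(module$W)) stop("dimension mismatch: input length")
  as.vector(module$W %*% input)
}

#' Orientation proposal
#'
#' A proposal is the common currency exchanged between strategies: a module
#' id, an orientation in `[0, 2*pi)` and a validity flag. Invalid proposals
#' carry no orientation semantics and are excluded from selection.
#'
#' @param module_id label.
#' @param orientation radians.
#' @param valid logical.
#' @return a `wm_proposal` list.
#' @export
proposal <- function(module_id, orientation = 0, valid = TRUE) {
  structure(list(module_id = as.character(module_id),
                 orientation = wrap_angle(orientation), valid = isTRUE(valid)),
            class = "wm_proposal")
}

#' Greedy model-free proposal
#'
#' The orientation of the action cell with maximal activation; ties broken by
#' lowest index. Exploration is a separate module, so no softmax is applied.
#' A module whose input population is silent (e.g. a Direction module whose
#' cue is invisible) carries no information and emits an invalid proposal,
#' which excludes it from selection and from the generalized gating update.
#'
#' @inheritParams ac_activations
#' @return a [proposal()].
#' @export
mf_propose <- function(module, input) {
  a <- ac_activations(module, input)
  proposal(module$id, module$phis[which.max(a)], valid = any(input > 0))
}

# index of the action cell angularly nearest to an orientation; ties -> lowest
nearest_action_cell <- function(phis, orientation) {
  which.min(angle_diff(phis, orientation))
}

#' TD Q-learning update of a model-free module
#'
#' The executed orientation (whatever module produced it) is mapped to the
#' angularly nearest action cell `i*`; the reward-prediction error is
#' `delta = R + gamma * max_i a_i(input_next) - a_i*(input_t)` (no bootstrap
#' on terminal steps) and only row `i*` changes:
#' `dW[i*, j] = eta * delta * input_t[j]`.
#'
#' @param module a [mf_module()].
#' @param input_t input at the current step.
#' @param executed_orientation orientation actually executed, radians.
#' @param reward 0 or 1.
#' @param input_next input after the move.
#' @param terminal logical; TRUE when the goal was reached.
#' @return the updated module.
#' @export
mf_update <- function(module, input_t, executed_orientation, reward,
                      input_next, terminal = FALSE) {
  stopifnot(reward %in% c(0, 1))
  istar <- nearest_action_cell(module$phis, executed_orientation)
  a_t <- ac_activations(module, input_t)
  target <- reward + if (terminal) 0 else module$gamma * max(ac_activations(module, input_next))
  delta <- target - a_t[istar]
  module$W[istar, ] <- module$W[istar, ] + module$eta * delta * input_t
  module
}

#' Set the planning goal and propagate goal values
#'
#' Memorises the goal node and position (overwriting any previous goal) and
#' runs [planning_propagate()]. A single rewarded trial is enough to make the
#' whole graph point to the new goal.
#'
#' @param graph a [learn_graph()] object.
#' @param node goal node id.
#' @param position goal position (cm), used for the final approach.
#' @return the updated graph.
#' @export
planning_set_goal <- function(graph, node, position) {
  if (!(node %in% seq_len(graph$n_nodes))) stop("unknown node: ", node)
  graph$goal_node <- as.integer(node)
  graph$goal_position <- as.numeric(position)
  planning_propagate(graph)
}

#' Activation-diffusion of goal value over the graph
#'
#' Starting from `G[goal] = 1`, iterates `G_i <- alpha * max_{j in N(i)} G_j`
#' to a fixpoint. The result equals `alpha^d(i)` where `d` is the unweighted
#' shortest-path distance to the goal; unreachable nodes keep value 0.
#'
#' @param graph a graph with a goal set.
#' @return the graph with updated goal values `G`.
#' @export
planning_propagate <- function(graph) {
  if (is.na(graph$goal_node)) stop("no goal set")
  n <- graph$n_nodes
  G <- numeric(n)
  G[graph$goal_node] <- 1
  repeat {
    spread <- graph$alpha * apply(graph$adjacency * rep(G, each = n), 1, max)
    Gnew <- pmax(G, spread)
    Gnew[graph$goal_node] <- 1
    if (max(abs(Gnew - G)) < 1e-15) break
    G <- Gnew
  }
  graph$G <- G
  graph
}

#' Planning proposal at a node
#'
#' With no goal set the proposal is invalid. At the goal node the proposed
#' orientation points from the node centroid to the memorised goal position;
#' elsewhere it points from the node centroid towards the centroid of the
#' neighbour with maximal goal value (ties broken by lowest node id). A node
#' with no neighbours (and not the goal) yields an invalid proposal.
#'
#' @param graph a [learn_graph()] object.
#' @param node current node id.
#' @return a [proposal()] with module id `"planning"`.
#' @export
planning_propose <- function(graph, node) {
  if (is.na(graph$goal_node)) return(proposal("planning", valid = FALSE))
  c0 <- graph$centroids[node, ]
  if (node == graph$goal_node) {
    v <- graph$goal_position - c0
    return(proposal("planning", atan2(v[2], v[1])))
  }
  nb <- which(graph$adjacency[node, ])
  if (length(nb) == 0) return(proposal("planning", valid = FALSE))
  best <- nb[which.max(graph$G[nb])]
  v <- graph$centroids[best, ] - c0
  proposal("planning", atan2(v[2], v[1]))
}

#' Exploration state
#' @param orientation persisted orientation or `NA`.
#' @param steps_remaining persistence steps left (0, 1 or 2).
#' @return a `wm_exploration` list.
#' @export
exploration_state <- function(orientation = NA_real_, steps_remaining = 0L) {
  structure(list(orientation = orientation,
                 steps_remaining = as.integer(steps_remaining)),
            class = "wm_exploration")
}

#' Exploration proposal
#'
#' If persistence is active the persisted orientation is proposed and one
#' persistence step is consumed; otherwise a fresh orientation is drawn
#' uniformly on `[0, 2*pi)` and will be persisted for three executed steps in
#' total if Exploration is selected. Persistence is consumed only when
#' Exploration is the executed module; callers discard the updated state when
#' another module wins a fresh draw.
#'
#' @param state an [exploration_state()].
#' @return list with elements `proposal` (a [proposal()]) and `state`.
#' @export
exploration_propose <- function(state) {
  if (state$steps_remaining > 0) {
    state$steps_remaining <- state$steps_remaining - 1L
    list(proposal = proposal("exploration", state$orientation), state = state)
  } else {
    phi <- runif(1, 0, 2 * pi)
    state$orientation <- phi
    state$steps_remaining <- 2L
    list(proposal = proposal("exploration", phi), state = state)
  }
}
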