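# The gating network arbitrates between strategies. Each registered module
# has one gating unit whose value g^k is a weighted sum of the gating input
# (all cue-cell activities plus the planning-graph node activities). Selection
# is hierarchical winner-take-all: first among Direction modules, then between
# that winner, the place-based module and Exploration. Learning is TD-based
# Q-learning generalised across modules: every module with a valid proposal is
# reinforced in proportion to the cosine of the angle between its proposal and
# the executed movement, so a module that proposed the executed orientation
# gets the full update and one that proposed the opposite gets the negated
# update.

#' Create a gating network
#'
#' @param module_ids labels of the registered behavioural modules, in
#'   registration order.
#' @param levels module level per id: `"direction"`, `"top"` (Planning or
#'   Locale) or `"exploration"`.
#' @param n_input gating input length (number of cue cells + number of graph
#'   nodes).
#' @param eta TD learning rate of the gating level.
#' @param gamma TD discount of the gating level.
#' @param z_init upper bound of the uniform random weight initialisation.
#' @return an object of class `wm_gating` with weight matrix `z`
#'   (`n_input x n_modules`).
#' @export
gating_network <- function(module_ids, levels, n_input, eta = 0.05,
                           gamma = 0.9, z_init = 0.01) {
  stopifnot(length(module_ids) == length(levels),
            all(levels %in% c("direction", "top", "exploration")))
  z <- matrix(runif(n_input * length(module_ids), 0, z_init),
              n_input, length(module_ids),
              dimnames = list(NULL, module_ids))
  structure(list(z = z, module_ids = module_ids, levels = levels,
                 eta = eta, gamma = gamma),
            class = "wm_gating")
}

#' Gating values
#'
#' `g^k = sum_j z[j, k] * r[j]` for every registered module k.
#'
#' @param net a [gating_network()].
#' @param r gating input vector.
#' @return named numeric vector of gating values.
#' @export
gating_values <- function(net, r) {
  if (length(r) != nrow(net$z)) stop("dimension mismatch: gating input length")
  setNames(as.vector(crossprod(net$z, r)), net$module_ids)
}

#' Hierarchical winner-take-all module selection
#'
#' If Exploration persistence is active, Exploration wins outright and no
#' comparison takes place. Otherwise a first winner-take-all is run on the
#' gating values of the valid Direction modules, then a second among that
#' winner, the place-based module (if its proposal is valid) and Exploration.
#' Exact ties are broken by the fixed order top (Planning/Locale) > Direction
#' > Exploration, then by lowest module index.
#'
#' @param proposals list of [proposal()] objects, one per registered module,
#'   in registration order.
#' @param g gating values as returned by [gating_values()].
#' @param levels module levels (as in [gating_network()]).
#' @param persistence_active logical; TRUE while Exploration is persisting.
#' @return list with `winner` (module index), `module_id`, and
#'   `orientation` (the executed orientation).
#' @export
select_module <- function(proposals, g, levels, persistence_active = FALSE) {
  valid <- vapply(proposals, function(p) p$valid, logical(1))
  if (!any(valid)) stop("no valid proposal to select from")
  expl <- which(levels == "exploration")
  if (persistence_active && length(expl)) {
    k <- expl[1]
    return(list(winner = k, module_id = proposals[[k]]$module_id,
                orientation = proposals[[k]]$orientation))
  }
  dir_idx <- which(levels == "direction" & valid)
  stage1 <- if (length(dir_idx)) dir_idx[which.max(g[dir_idx])] else integer(0)
  top_idx <- which(levels == "top" & valid)
  cand <- c(top_idx, stage1, expl[valid[expl]])
  # candidates listed in tie-priority order: top > direction > exploration,
  # each already at lowest index first; which.max keeps the first maximum.
  k <- cand[which.max(g[cand])]
  list(winner = k, module_id = proposals[[k]]$module_id,
       orientation = proposals[[k]]$orientation)
}

#' Generalised TD update of the gating network
#'
#' `delta = reward + gamma * max_k g^k(r_next) - g^selected(r_t)` (no
#' bootstrap on terminal steps). Every module k with a valid proposal is
#' updated over the whole input column:
#' `dz[j, k] = eta * cos(phi_k - executed_orientation) * delta * r_t[j]`;
#' modules with invalid proposals are unchanged.
#'
#' @param net a [gating_network()].
#' @param r_t gating input at the current step.
#' @param r_next gating input after the move.
#' @param proposals list of proposals (registration order).
#' @param executed_orientation orientation actually executed.
#' @param selected index of the selected module.
#' @param reward 0 or 1.
#' @param terminal logical.
#' @return the updated network.
#' @export
gating_update <- function(net, r_t, r_next, proposals, executed_orientation,
                          selected, reward, terminal = FALSE) {
  stopifnot(reward %in% c(0, 1))
  g_t <- gating_values(net, r_t)
  target <- reward + if (terminal) 0 else net$gamma * max(gating_values(net, r_next))
  delta <- target - g_t[[selected]]
  for (k in seq_along(proposals)) {
    p <- proposals[[k]]
    if (!p$valid) next
    kappa <- cos(p$orientation - executed_orientation)
    net$z[, k] <- net$z[, k] + net$eta * kappa * delta * r_t
  }
  net
}
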