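# One full timestep of the engine against the same step composed from the
# exported R operations (perception -> proposals -> selection -> movement ->
# TD updates). Any drift between the fast path and the documented operations
# fails here.

small_params <- wm_params(n_pc = 200L, n_gc = 40L, walk_steps = 300L,
                          max_steps = 1L, guided = FALSE)

trial_row <- function(px, py, present = TRUE, sx, sy) {
  tibble::tibble(session = 1L, trial = 1L, trial_global = 1L, tag = "escape",
                 stage = 1L, platform_x = px, platform_y = py,
                 platform_present = present, angle = NA_real_,
                 cue_angle = NA_real_, record_steps = TRUE,
                 start_x = sx, start_y = sy,
                 cue_vis = list(NULL), cue_pos = list(NULL))
}

test_that("one engine timestep equals the composed R operations", {
  mz <- tiny_maze()
  set.seed(101)
  model <- build_model(mz, "DP", small_params)
  # plant a goal so the Planning module takes part
  gstart <- pose(20, 20)
  ecg <- ec_input(gstart, mz, model$pstate)
  pcg <- pc_activity(model$map$pc_pop$W, ecg, small_params$n_pc_active)
  node_g <- current_node(model$map$graph, pcg)
  model$map$graph <- planning_set_goal(model$map$graph, node_g, c(20, 20))

  # deep copies: the engine updates the weight matrices in place
  z0 <- model$gating$z + 0
  W0 <- lapply(model$modules, function(m) if (is.matrix(m$W)) m$W + 0 else NULL)

  tr <- trial_row(-40, -40, TRUE, 55, -10)
  set.seed(202)
  res <- run_trial(model, tr, record_steps = TRUE)
  rec <- res$record

  # ---- independent R composition of the same step ----
  set.seed(202)
  p0 <- pose(55, -10)
  mz_t <- watermaze:::trial_maze(mz, tr[1, ])
  ec_t <- ec_input(p0, mz_t, model$pstate)
  cc_t <- cue_cell_activities(p0, mz_t, model$pstate)
  pc_t <- pc_activity(model$map$pc_pop$W, ec_t, small_params$n_pc_active)
  gc_t <- pc_activity(model$map$graph$W_pc_gc, pc_t, small_params$n_gc_active)
  node_t <- current_node(model$map$graph, pc_t)
  r_t <- c(cc_t, gc_t)

  n_cc <- small_params$n_cc
  cue_block <- function(cid) {
    k <- match(cid, names(mz_t$cues))
    cc_t[((k - 1) * n_cc + 1):(k * n_cc)]
  }
  props <- list()
  for (k in seq_along(model$modules)) {
    m <- model$modules[[k]]
    if (inherits(m, "wm_mf_module")) {
      props[[k]] <- mf_propose(m, cue_block(m$cue_id))
    } else if (m$id == "planning") {
      pt <- watermaze:::plan_table(model$map$graph)
      props[[k]] <- if (pt$valid[node_t]) {
        proposal("planning", atan2(pt$ty[node_t] - p0[["y"]],
                                   pt$tx[node_t] - p0[["x"]]))
      } else proposal("planning", valid = FALSE)
    } else {
      out <- exploration_propose(exploration_state())
      props[[k]] <- out$proposal
    }
  }
  g_t <- gating_values(structure(list(z = z0, module_ids = model$module_ids,
                                      levels = model$levels,
                                      eta = model$gating$eta,
                                      gamma = model$gating$gamma),
                                 class = "wm_gating"), r_t)
  selR <- select_module(props, g_t, model$levels)
  p1 <- move_agent(p0, selR$orientation, small_params$step_len, mz_t)

  # engine recorded the same selection and position
  expect_equal(unname(rec$steps[1, "x"]), unname(p1[["x"]]), tolerance = 1e-10)
  expect_equal(unname(rec$steps[1, "y"]), unname(p1[["y"]]), tolerance = 1e-10)
  expect_equal(unname(rec$steps[1, "module"]), selR$winner)

  # ---- TD updates ----
  ec_n <- ec_input(p1, mz_t, model$pstate)
  cc_n <- cue_cell_activities(p1, mz_t, model$pstate)
  pc_n <- pc_activity(model$map$pc_pop$W, ec_n, small_params$n_pc_active)
  gc_n <- pc_activity(model$map$graph$W_pc_gc, pc_n, small_params$n_gc_active)
  r_n <- c(cc_n, gc_n)
  reward <- as.numeric(on_platform(p1, mz_t$platform))
  terminal <- reward == 1
  expect_false(terminal)

  for (k in seq_along(model$modules)) {
    m <- model$modules[[k]]
    if (!inherits(m, "wm_mf_module")) next
    m$W <- W0[[k]]
    mu <- mf_update(m, cue_block(m$cue_id), selR$orientation, reward,
                    if (m$input_source == "pc") pc_n else {
                      kk <- match(m$cue_id, names(mz_t$cues))
                      cc_n[((kk - 1) * n_cc + 1):(kk * n_cc)]
                    })
    expect_equal(res$model$modules[[k]]$W, mu$W, tolerance = 1e-12)
  }

  netR <- structure(list(z = z0, module_ids = model$module_ids,
                         levels = model$levels, eta = model$gating$eta,
                         gamma = model$gating$gamma), class = "wm_gating")
  netU <- gating_update(netR, r_t, r_n, props, selR$orientation, selR$winner,
                        reward, terminal)
  expect_equal(res$model$gating$z, unname(netU$z), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("trial mechanics honour the cap, guidance and zero-latency start", {
  mz <- tiny_maze()
  set.seed(7)
  pars <- wm_params(n_pc = 200L, n_gc = 40L, walk_steps = 300L,
                    max_steps = 30L)
  model <- build_model(mz, "chance", pars)

  # start on the platform -> latency 0, rewarded before any movement
  r0 <- run_trial(model, trial_row(10, 10, TRUE, 10, 10))
  expect_equal(r0$record$latency, 0)
  expect_true(r0$record$rewarded)

  # unreachable in 30 steps -> capped latency, guided to the platform
  r1 <- run_trial(model, trial_row(-60, 0, TRUE, 60, 0))
  expect_lte(r1$record$latency, 30)
  if (!r1$record$guided) succeed() else {
    expect_equal(r1$record$latency, 30)
    expect_true(r1$record$rewarded)
  }

  # platform-absent probe runs the full budget unrewarded
  r2 <- run_trial(model, trial_row(0, 0, FALSE, 60, 0), record_steps = TRUE)
  expect_equal(r2$record$latency, 30)
  expect_false(r2$record$rewarded)
  expect_equal(nrow(r2$record$steps), 30)
})

test_that("a deterministic goal-pointing module yields ceiling(d / step) latency", {
  # single Direction module whose cue sits on the platform: force its
  # weights so that every bearing maps to the action cell pointing at it
  mz <- maze(100, 7.5,
             cues = list(cue_spec("c", "proximal", platform_offset = c(0, 0))),
             platform = platform_spec(c(30, 0), 5))
  pars <- wm_params(n_ac = 36L, max_steps = 60L)
  set.seed(3)
  model <- build_model(mz, "D", pars)
  # hand-craft: cue-cell m prefers bearing 2*pi*m/12; make action cell
  # nearest that bearing respond maximally to it
  W <- matrix(0, 36, 12)
  for (m in 1:12) {
    phi <- 2 * pi * (m - 1) / 12
    i <- which.min(angle_diff(2 * pi * (0:35) / 36, phi))
    W[i, m] <- 10
  }
  model$modules[[1]]$W <- W
  model$gating$z[] <- 0
  model$gating$z[1:12, 1] <- 1   # Direction always wins selection
  tr <- trial_row(30, 0, TRUE, 0, 0)
  res <- run_trial(model, tr)
  expect_equal(res$record$latency, ceiling(30 / 6))
  expect_true(res$record$rewarded)
})
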