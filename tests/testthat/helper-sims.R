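# Cached simulation runs shared by the behavioural test blocks. Each entry is
# computed once per test session; seeds are fixed so results are stable.

simI <- function(group) sim_cached(paste0("I_", group),
  run_experiment("I", group, n_repeats = 20, master_seed = 1))

simII <- function(group) sim_cached(paste0("II_", group),
  run_experiment("II", group, n_repeats = 20, master_seed = 1))

simIV <- function(group) sim_cached(paste0("IV_", group),
  run_experiment("IV", group, n_repeats = 20, master_seed = 1))

simV <- function(group) sim_cached(paste0("V_", group),
  run_experiment("V", group, n_repeats = 50, master_seed = 1))

simVI <- function(group, cond) sim_cached(paste0("VI_", group, "_", cond),
  run_experiment("VI", group, condition = cond, n_repeats = 50,
                 master_seed = 1))

simIII <- function(group) sim_cached(paste0("III_", group),
  run_experiment("III", group, n_repeats = 50, master_seed = 1))

# per-repeat mean latency for a subset of trials
rep_latency <- function(ex, subset_expr) {
  tr <- dplyr::filter(ex$trials, {{ subset_expr }})
  out <- dplyr::summarise(dplyr::group_by(tr, .data$rep),
                          latency = mean(.data$latency), .groups = "drop")
  out$latency[order(out$rep)]
}

# paired per-repeat within-session contrast: first vs fourth trial of each
# session (restricted to platform-present trials and sessions >= from)
within_session_pair <- function(ex, from = 1) {
  tr <- dplyr::filter(ex$trials, .data$platform_present,
                      .data$session >= from, .data$trial %in% c(1, 4))
  agg <- dplyr::summarise(
    dplyr::group_by(tr, .data$rep, .data$trial),
    latency = mean(.data$latency), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "trial",
                             values_from = "latency", names_prefix = "t")
  wide[order(wide$rep), ]
}

# goal-quadrant occupancy per repeat on the blocking test trial
vi_occupancy <- function(ex) {
  tq <- test_quadrant_occupancy(ex)
  tq$occupancy$fraction[order(tq$occupancy$rep)]
}
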