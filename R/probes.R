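# Probe-trial analyses built on occupancy_rate(): octant occupancy for the
# generalization-gradient experiment, goal-quadrant occupancy for the
# blocking experiment, and selection rates split at the first entry into the
# reference region ("Before"/"After" phases).

steps_for <- function(x, r, tg) {
  x$steps[x$steps$rep == r & x$steps$trial_global == tg, ]
}

#' Octant occupancy on gradient probe trials
#'
#' For every recorded gradient trial, the fraction of timesteps spent in the
#' octant (45-degree sector) centred on the displaced proximal cue, overall
#' and split into the phases before and after the first entry into that
#' octant.
#'
#' @param x a [run_experiment()] result of the generalization-gradient
#'   protocol with probe steps recorded.
#' @return tibble with `rep`, `trial_global`, `angle` (rotation in degrees),
#'   `phase`, `fraction`, `n_steps`, `entered`.
#' @export
gradient_occupancy <- function(x) {
  gr <- dplyr::filter(x$trials, .data$tag == "gradient")
  purrr::pmap_dfr(gr[, c("rep", "trial_global", "angle", "cue_angle")],
    function(rep, trial_global, angle, cue_angle) {
      st <- steps_for(x, rep, trial_global)
      if (nrow(st) == 0) return(NULL)
      octant <- sector_region(cue_angle * pi / 180, pi / 4)
      purrr::map_dfr(c("full", "before", "after"), function(ph) {
        dplyr::mutate(occupancy_rate(st, octant, ph),
                      rep = rep, trial_global = trial_global,
                      angle = angle, phase = ph, .before = 1)
      })
    })
}

#' Octant-F occupancy on extinction probe trials
#'
#' Fraction of timesteps spent in the octant centred on the distal frame cue
#' during extinction trials (proximal cue and platform absent).
#'
#' @param x a [run_experiment()] result of the generalization-gradient
#'   protocol.
#' @return tibble with `rep`, `trial_global`, `fraction`.
#' @export
extinction_occupancy <- function(x) {
  ex <- dplyr::filter(x$trials, .data$tag == "extinction")
  purrr::pmap_dfr(ex[, c("rep", "trial_global", "cue_angle")],
    function(rep, trial_global, cue_angle) {
      st <- steps_for(x, rep, trial_global)
      if (nrow(st) == 0) return(NULL)
      octant <- sector_region(cue_angle * pi / 180, pi / 4)
      dplyr::mutate(occupancy_rate(st, octant, "full"),
                    rep = rep, trial_global = trial_global, .before = 1)
    })
}

#' Goal-quadrant occupancy on the blocking test trial
#'
#' Fraction of test-trial timesteps spent in the quadrant (90-degree sector)
#' containing the previous platform location, plus per-module selection
#' rates before and after the first entry into that quadrant.
#'
#' @param x a [run_experiment()] result of the blocking protocol.
#' @return list with `occupancy` (tibble: `rep`, `fraction`, `entered`) and
#'   `phase_selection` (tibble: `rep`, `phase`, `module`, `steps`, `rate`).
#' @export
test_quadrant_occupancy <- function(x) {
  te <- dplyr::filter(x$trials, .data$tag == "test")
  occ <- list(); sel <- list()
  for (i in seq_len(nrow(te))) {
    r <- te$rep[i]; tg <- te$trial_global[i]
    st <- steps_for(x, r, tg)
    if (nrow(st) == 0) next
    ang <- atan2(te$platform_y[i], te$platform_x[i])
    quad <- sector_region(ang, pi / 2)
    occ[[length(occ) + 1]] <- dplyr::mutate(
      occupancy_rate(st, quad, "full"), rep = r, .before = 1)
    sel[[length(sel) + 1]] <- dplyr::mutate(
      phase_selection_rates(st, quad, x$module_ids), rep = r, .before = 1)
  }
  list(occupancy = dplyr::bind_rows(occ),
       phase_selection = dplyr::bind_rows(sel))
}

#' Per-module selection rates before/after first entry into a region
#'
#' @param steps one trial's steps tibble (columns `x`, `y`, `module`).
#' @param region the reference region.
#' @param module_ids all registered module ids (so absent modules report 0).
#' @return tibble with `phase`, `module`, `steps`, `rate`.
#' @export
phase_selection_rates <- function(steps, region, module_ids) {
  if ("guided" %in% names(steps)) steps <- steps[!steps$guided, ]
  first_in <- which(in_region(cbind(steps$x, steps$y), region))[1]
  n <- nrow(steps)
  split_at <- if (is.na(first_in)) n + 1 else first_in
  purrr::map_dfr(list(before = seq_len(split_at - 1),
                      after = if (split_at <= n) seq(split_at, n) else integer(0)),
    function(idx) {
      cnt <- table(factor(steps$module[idx], levels = module_ids))
      tibble::tibble(module = module_ids, steps = as.integer(cnt),
                     rate = if (length(idx)) as.numeric(cnt) / length(idx)
                            else NA_real_)
    }, .id = "phase")
}
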