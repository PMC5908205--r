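# The six experimental protocols. Each builder returns the maze template
# (all cues registered, so the perceptual input layout is constant across the
# experiment) and a trial table: one row per trial with the platform
# schedule, per-trial cue visibility/position overrides, start position and
# analysis tag. Start positions are pseudo-randomised from the protocol's
# start set under the caller's RNG state, so each simulated agent gets its
# own (seeded) ordering.

expand_trials <- function(n) {
  tibble::tibble(
    session = integer(n), trial = integer(n), trial_global = seq_len(n),
    tag = character(n), stage = 1L,
    platform_x = NA_real_, platform_y = NA_real_, platform_present = TRUE,
    angle = NA_real_, cue_angle = NA_real_, record_steps = FALSE,
    start_x = NA_real_, start_y = NA_real_,
    cue_vis = vector("list", n), cue_pos = vector("list", n)
  )
}

polar <- function(r, theta_deg) {
  th <- theta_deg * pi / 180
  c(r * cos(th), r * sin(th))
}

# draw one start per trial, balanced within blocks of 4
draw_starts <- function(n, params) {
  angles <- params$start_angles
  out <- numeric(0)
  while (length(out) < n) out <- c(out, sample(angles))
  out <- out[seq_len(n)]
  cbind(params$start_radius * cos(out), params$start_radius * sin(out))
}

# platform location sequence over a ring of candidate positions, no
# immediate repeats
draw_positions <- function(n, radius = 50) {
  angs <- seq(0, 315, by = 45)
  idx <- integer(n)
  idx[1] <- sample(8, 1)
  if (n > 1) for (i in 2:n) idx[i] <- sample(setdiff(1:8, idx[i - 1]), 1)
  t(vapply(idx, function(i) polar(radius, angs[i]), numeric(2)))
}

four_distal_cues <- function() {
  list(cue_spec("d1", "distal", polar(120, 30)),
       cue_spec("d2", "distal", polar(120, 110)),
       cue_spec("d3", "distal", polar(120, 200)),
       cue_spec("d4", "distal", polar(120, 300)))
}

#' Build an experimental protocol
#'
#' Experiments:
#' \describe{
#'   \item{I}{Reference memory: hidden stable platform, 4 distal cues,
#'     20 trials (analysed in sessions of 4).}
#'   \item{II}{Delayed matching to place: hidden platform moved every session
#'     of four trials, 9 sessions.}
#'   \item{III}{Cue/place competition: cued stable platform plus distal cues;
#'     10 trials, the proximal cue hidden on trials 3, 6 and 9; on trial 10
#'     (competition) platform and cue move to the diametrically opposite
#'     position.}
#'   \item{IV}{Gradual competition: platform moved every session of four
#'     trials, a proximal cue held at a constant offset from it; 11 sessions.}
#'   \item{V}{Generalization gradient: Stage 1 = 4 sessions x 8 trials with
#'     proximal cue B at the platform and distal cue F behind it; Stage 2 =
#'     10 sessions x 9 trials, the 9th trial of even sessions a gradient
#'     probe (no platform, B rotated 0/45/90/135 degrees about the centre)
#'     and of odd sessions an extinction probe (F only).}
#'   \item{VI}{Blocking (conditions `Session-Same`, `Trial-Same`,
#'     `Session-Diff`, `Trial-Diff`): Stage 1 = 12 sessions x 4 trials with
#'     cued platform (cue A), moved per session (Session) or per trial
#'     (Trial); Stage 2 = 3 sessions x 4 trials, fixed platform cued by A
#'     (Same) or B (Diff); Stage 3 = one test trial with platform and
#'     proximal cue removed.}
#' }
#'
#' @param id experiment id: `"I"` to `"VI"`.
#' @param condition condition label (Experiment VI only).
#' @param params parameter list from [wm_params()].
#' @return list with elements `maze` (template) and `trials` (tibble).
#' @export
build_protocol <- function(id = c("I", "II", "III", "IV", "V", "VI"),
                           condition = NULL, params = wm_params()) {
  id <- match.arg(id)
  base_maze <- function(cues) {
    maze(params$arena_radius, params$agent_radius, cues,
         platform_spec(c(0, 0), params$platform_radius, present = FALSE))
  }

  if (id == "I") {
    mz <- base_maze(four_distal_cues())
    tr <- expand_trials(20)
    tr$session <- rep(1:5, each = 4)
    tr$trial <- rep(1:4, 5)
    tr$tag <- "escape"
    pp <- polar(50, 45)
    tr$platform_x <- pp[1]; tr$platform_y <- pp[2]
  } else if (id == "II") {
    mz <- base_maze(four_distal_cues())
    tr <- expand_trials(36)
    tr$session <- rep(1:9, each = 4)
    tr$trial <- rep(1:4, 9)
    tr$tag <- "escape"
    pos <- draw_positions(9)
    tr$platform_x <- pos[tr$session, 1]
    tr$platform_y <- pos[tr$session, 2]
  } else if (id == "III") {
    cues <- c(four_distal_cues(),
              list(cue_spec("c", "proximal", platform_offset = c(0, 0))))
    mz <- base_maze(cues)
    tr <- expand_trials(10)
    tr$session <- 1L
    tr$trial <- 1:10
    pp <- polar(50, 135)
    tr$platform_x <- pp[1]; tr$platform_y <- pp[2]
    tr$tag <- "cued"
    hidden <- c(3, 6, 9)
    tr$tag[hidden] <- "hidden-cue"
    for (i in hidden) tr$cue_vis[[i]] <- list(c = FALSE)
    opp <- polar(50, 135 - 180)
    tr$tag[10] <- "competition"
    tr$platform_x[10] <- opp[1]; tr$platform_y[10] <- opp[2]
    tr$record_steps[10] <- TRUE
  } else if (id == "IV") {
    cues <- c(four_distal_cues(),
              list(cue_spec("c", "proximal", platform_offset = c(0, 10))))
    mz <- base_maze(cues)
    tr <- expand_trials(44)
    tr$session <- rep(1:11, each = 4)
    tr$trial <- rep(1:4, 11)
    tr$tag <- "escape"
    pos <- draw_positions(11, radius = 45)
    tr$platform_x <- pos[tr$session, 1]
    tr$platform_y <- pos[tr$session, 2]
  } else if (id == "V") {
    cues <- list(
      cue_spec("B", "proximal", platform_offset = c(0, 0)),
      cue_spec("F", "distal", polar(120, 90)),
      cue_spec("d2", "distal", polar(120, 210)),
      cue_spec("d3", "distal", polar(120, 330)))
    mz <- base_maze(cues)
    n <- 4 * 8 + 10 * 9
    tr <- expand_trials(n)
    pp <- polar(60, 90)
    tr$platform_x <- pp[1]; tr$platform_y <- pp[2]
    tr$tag <- "escape"
    tr$session <- c(rep(1:4, each = 8), rep(5:14, each = 9))
    tr$trial <- c(rep(1:8, 4), rep(1:9, 10))
    tr$stage <- ifelse(tr$session <= 4, 1L, 2L)
    # probe trials: 9th trial of each Stage-2 session
    probes <- which(tr$stage == 2L & tr$trial == 9L)
    grad <- probes[seq(2, 10, by = 2)]             # sessions 6, 8, 10, 12, 14
    ext <- probes[seq(1, 9, by = 2)]               # sessions 5, 7, 9, 11, 13
    rot_sign <- sample(c(-1, 1), 1)                # constant per agent
    angles <- sample(c(0, 45, 90, 135, 0))         # one per gradient trial
    for (j in seq_along(grad)) {
      i <- grad[j]
      tr$tag[i] <- "gradient"
      tr$platform_present[i] <- FALSE
      tr$angle[i] <- angles[j]
      tr$cue_angle[i] <- 90 + rot_sign * angles[j]
      tr$record_steps[i] <- TRUE
      tr$cue_pos[[i]] <- list(B = polar(60, 90 + rot_sign * angles[j]))
    }
    for (i in ext) {
      tr$tag[i] <- "extinction"
      tr$platform_present[i] <- FALSE
      tr$cue_angle[i] <- 90       # octant F reference
      tr$cue_vis[[i]] <- list(B = FALSE)
      tr$record_steps[i] <- TRUE
    }
  } else {  # VI
    if (is.null(condition)) stop("Experiment VI needs a condition")
    cond <- match.arg(condition,
                      c("Session-Same", "Trial-Same", "Session-Diff", "Trial-Diff"))
    per_trial <- grepl("^Trial", cond)
    diff_cue <- grepl("Diff$", cond)
    cues <- c(four_distal_cues(),
              list(cue_spec("A", "proximal", platform_offset = c(0, 0)),
                   cue_spec("B", "proximal", platform_offset = c(0, 0),
                            visible = FALSE)))
    mz <- base_maze(cues)
    n <- 12 * 4 + 3 * 4 + 1
    tr <- expand_trials(n)
    tr$session <- c(rep(1:12, each = 4), rep(13:15, each = 4), 16L)
    tr$trial <- c(rep(1:4, 15), 1L)
    tr$tag <- "escape"
    tr$stage <- ifelse(tr$session <= 12, 1L, ifelse(tr$session <= 15, 2L, 3L))
    s1 <- tr$stage == 1L
    if (per_trial) {
      pos <- draw_positions(48)
      tr$platform_x[s1] <- pos[, 1]; tr$platform_y[s1] <- pos[, 2]
    } else {
      pos <- draw_positions(12)
      tr$platform_x[s1] <- pos[tr$session[s1], 1]
      tr$platform_y[s1] <- pos[tr$session[s1], 2]
    }
    goal <- polar(50, 45)
    s23 <- tr$stage >= 2L
    tr$platform_x[s23] <- goal[1]; tr$platform_y[s23] <- goal[2]
    # stage 1: cue A marks the platform
    for (i in which(s1)) tr$cue_vis[[i]] <- list(A = TRUE, B = FALSE)
    # stage 2: same cue (A) or a different proximal cue (B)
    for (i in which(tr$stage == 2L)) {
      tr$cue_vis[[i]] <- if (diff_cue) list(A = FALSE, B = TRUE)
                         else list(A = TRUE, B = FALSE)
    }
    # stage 3: platform and proximal cue removed
    i3 <- which(tr$stage == 3L)
    tr$platform_present[i3] <- FALSE
    tr$tag[i3] <- "test"
    tr$record_steps[i3] <- TRUE
    tr$cue_vis[[i3]] <- list(A = FALSE, B = FALSE)
  }

  st <- draw_starts(nrow(tr), params)
  tr$start_x <- st[, 1]; tr$start_y <- st[, 2]
  list(maze = mz, trials = tr)
}
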