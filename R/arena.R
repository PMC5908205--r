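# Circular arena geometry, cue/platform bookkeeping, agent kinematics and
# region queries. All positions in cm (arena-centred), all angles in radians,
# allocentric with a zero direction fixed per environment at construction.

#' Wrap an angle into [0, 2*pi)
#' @param theta angle(s) in radians.
#' @return angle(s) in `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) theta %% (2 * pi)

#' Smallest absolute angular difference between two angles
#' @param a,b angles in radians.
#' @return wrapped absolute difference in `[0, pi]`.
#' @export
angle_diff <- function(a, b) {
  d <- wrap_angle(a - b)
  pmin(d, 2 * pi - d)
}

#' Agent pose
#'
#' @param x,y position in cm, arena-centred.
#' @param heading allocentric heading in radians; wrapped into `[0, 2*pi)`.
#' @return a named numeric vector with elements `x`, `y`, `heading`.
#' @export
pose <- function(x, y, heading = 0) {
  c(x = as.numeric(x), y = as.numeric(y), heading = wrap_angle(as.numeric(heading)))
}

#' Cue specification
#'
#' A landmark of the environment. Proximal cues lie inside the arena (short
#' distance constant in the cue-cell code); distal cues sit at or beyond the
#' wall and act mainly as directional references. A cue with a
#' `platform_offset` tracks the platform: its position is recomputed whenever
#' the platform moves.
#'
#' @param id unique cue label.
#' @param kind `"proximal"` or `"distal"`.
#' @param position length-2 numeric, cm.
#' @param visible logical; invisible cues produce all-zero cue-cell activity.
#' @param platform_offset optional length-2 numeric; when given, the cue is
#'   placed at `platform_center + platform_offset` for each trial.
#' @return an object of class `wm_cue`.
#' @export
cue_spec <- function(id, kind = c("proximal", "distal"), position = c(0, 0),
                     visible = TRUE, platform_offset = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 2, is.logical(visible))
  if (!is.null(platform_offset)) stopifnot(length(platform_offset) == 2)
  structure(
    list(id = as.character(id), kind = kind, position = as.numeric(position),
         visible = visible, platform_offset = platform_offset),
    class = "wm_cue"
  )
}

#' Platform specification
#'
#' @param center length-2 numeric, cm.
#' @param radius platform radius in cm.
#' @param present logical; an absent platform never rewards.
#' @param cued logical bookkeeping flag (platform marked by a proximal cue).
#' @return an object of class `wm_platform`.
#' @export
platform_spec <- function(center = c(0, 0), radius = 5, present = TRUE, cued = FALSE) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 present = isTRUE(present), cued = isTRUE(cued)),
            class = "wm_platform")
}

#' Circular water-maze environment
#'
#' @param arena_radius arena radius in cm.
#' @param agent_radius radius of the simulated agent body in cm (the agent is a
#'   15 cm diameter disk by default); the agent centre is constrained to stay
#'   within `arena_radius - agent_radius` of the origin.
#' @param cues list of [cue_spec()] objects with unique ids.
#' @param platform a [platform_spec()] or `NULL` (no platform).
#' @param zero_direction allocentric reference direction of this environment,
#'   fixed at construction.
#' @return an object of class `wm_maze`.
#' @export
maze <- function(arena_radius = 100, agent_radius = 7.5, cues = list(),
                 platform = NULL, zero_direction = 0) {
  stopifnot(arena_radius > agent_radius, agent_radius >= 0)
  ids <- vapply(cues, function(cc) cc$id, character(1))
  if (anyDuplicated(ids)) stop("cue ids must be unique")
  if (is.null(platform)) platform <- platform_spec(present = FALSE)
  for (cc in cues) {
    if (cc$kind == "proximal" && is.null(cc$platform_offset) &&
        sqrt(sum(cc$position^2)) > arena_radius + 1e-9) {
      stop("proximal cue '", cc$id, "' lies outside the arena")
    }
  }
  if (platform$present &&
      sqrt(sum(platform$center^2)) + platform$radius > arena_radius + 1e-9) {
    stop("platform disk must lie fully inside the arena")
  }
  structure(
    list(arena_radius = arena_radius, agent_radius = agent_radius,
         cues = setNames(cues, ids), platform = platform,
         zero_direction = wrap_angle(zero_direction)),
    class = "wm_maze"
  )
}

#' Displace the agent one step, sliding along the wall
#'
#' Moves the agent centre `step` cm along `heading_cmd`. If the displaced
#' centre would violate the wall constraint it is radially clamped to distance
#' `arena_radius - agent_radius` from the origin while keeping the displaced
#' angular coordinate (slide-along-wall); the heading is set to `heading_cmd`.
#'
#' @param pose a [pose()].
#' @param heading_cmd commanded allocentric heading, radians.
#' @param step step length in cm (>= 0); the simulated agent moves 6 cm per
#'   timestep in the experiments.
#' @param maze a [maze()].
#' @return the new pose.
#' @export
move_agent <- function(pose, heading_cmd, step, maze) {
  stopifnot(step >= 0)
  nx <- pose[["x"]] + step * cos(heading_cmd)
  ny <- pose[["y"]] + step * sin(heading_cmd)
  rmax <- maze$arena_radius - maze$agent_radius
  r <- sqrt(nx^2 + ny^2)
  if (r > rmax) {
    nx <- nx * rmax / r
    ny <- ny * rmax / r
  }
  pose(nx, ny, heading_cmd)
}

#' Is the agent on the platform?
#'
#' Reward is delivered when the agent centre lies within the platform disk of a
#' present platform.
#'
#' @param pose a [pose()].
#' @param platform a [platform_spec()].
#' @return logical.
#' @export
on_platform <- function(pose, platform) {
  if (!platform$present) return(FALSE)
  dx <- pose[["x"]] - platform$center[1]
  dy <- pose[["y"]] - platform$center[2]
  sqrt(dx^2 + dy^2) <= platform$radius
}

#' Sector (pie-slice) region of the arena
#'
#' Membership is computed on the position angle only; an octant has width
#' `pi/4`, a quadrant `pi/2`.
#'
#' @param center_angle sector bisector angle, radians.
#' @param width angular width in `(0, 2*pi]`.
#' @return an object of class `wm_region`.
#' @export
sector_region <- function(center_angle, width) {
  if (!(width > 0 && width <= 2 * pi)) stop("invalid region: width must be in (0, 2*pi]")
  structure(list(shape = "sector", center_angle = wrap_angle(center_angle),
                 width = width), class = "wm_region")
}

#' Disk region
#' @param center length-2 numeric, cm.
#' @param radius disk radius in cm (> 0).
#' @return an object of class `wm_region`.
#' @export
disk_region <- function(center, radius) {
  if (!(radius > 0)) stop("invalid region: radius must be > 0")
  structure(list(shape = "disk", center = as.numeric(center), radius = radius),
            class = "wm_region")
}

#' Region membership
#'
#' @param position length-2 numeric or an n x 2 matrix of positions.
#' @param region a `wm_region` from [sector_region()] or [disk_region()].
#' @return logical vector.
#' @export
in_region <- function(position, region) {
  if (!inherits(region, "wm_region")) stop("region must be a wm_region")
  p <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  if (region$shape == "sector") {
    ang <- atan2(p[, 2], p[, 1])
    angle_diff(ang, region$center_angle) <= region$width / 2 + 1e-12
  } else {
    sqrt((p[, 1] - region$center[1])^2 + (p[, 2] - region$center[2])^2) <=
      region$radius
  }
}

#' Allocentric bearing and distance from the agent to a cue
#'
#' @param pose a [pose()].
#' @param cue a [cue_spec()].
#' @return numeric vector `c(bearing, distance)`; bearing in `[0, 2*pi)`. A cue
#'   coincident with the agent centre has bearing 0 and distance 0.
#' @export
bearing_distance <- function(pose, cue) {
  dx <- cue$position[1] - pose[["x"]]
  dy <- cue$position[2] - pose[["y"]]
  d <- sqrt(dx^2 + dy^2)
  b <- if (d == 0) 0 else wrap_angle(atan2(dy, dx))
  c(bearing = b, distance = d)
}

# Resolve per-trial cue positions: cues with a platform_offset follow the
# platform centre supplied for the trial.
resolve_cue_positions <- function(maze, platform_center = NULL) {
  for (id in names(maze$cues)) {
    cc <- maze$cues[[id]]
    if (!is.null(cc$platform_offset) && !is.null(platform_center)) {
      maze$cues[[id]]$position <- platform_center + cc$platform_offset
    }
  }
  maze
}
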