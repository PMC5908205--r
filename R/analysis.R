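# Behavioural read-outs: escape latencies, region occupancy with
# before/after-first-entry phases, strategy selection rates, responder
# classification, and the nonparametric tests (exact under ties).

#' Escape latencies in tidy form
#'
#' @param x a [run_experiment()] result.
#' @param by grouping: `"trial"` (one row per repeat x trial),
#'   `"session"` (mean over each session's trials) or `"session_trial"`
#'   (repeat x session x within-session trial, for first-vs-fourth-trial
#'   analyses).
#' @param tags trial tags to include; defaults to all platform-present
#'   trials.
#' @return a tibble with columns `rep`, the grouping columns, and `latency`
#'   (timesteps to the platform, capped at the trial limit).
#' @export
escape_latencies <- function(x, by = c("trial", "session", "session_trial"),
                             tags = NULL) {
  by <- match.arg(by)
  tr <- dplyr::filter(x$trials, .data$platform_present)
  if (!is.null(tags)) tr <- dplyr::filter(tr, .data$tag %in% tags)
  switch(by,
    trial = dplyr::select(tr, "rep", "trial_global", "session", "trial",
                          "stage", "tag", "latency"),
    session = dplyr::summarise(dplyr::group_by(tr, .data$rep, .data$session),
                               latency = mean(.data$latency), .groups = "drop"),
    session_trial = dplyr::select(tr, "rep", "session", "trial", "stage",
                                  "tag", "latency"))
}

#' Occupancy of a region during one recorded trial
#'
#' The fraction of the trial's (non-guided) timesteps spent inside `region`,
#' optionally restricted to the phase before or after the first entry into a
#' reference region. If the reference region is never entered, the
#' before-phase spans the full trial and the after-phase is empty (fraction
#' 0, flagged by `entered = FALSE`). Phases partition the trial.
#'
#' @param steps tibble of one trial's steps (columns `x`, `y`, optionally
#'   `guided`).
#' @param region a [sector_region()] or [disk_region()].
#' @param phase `"full"`, `"before"` or `"after"` (relative to first entry
#'   into `ref_region`).
#' @param ref_region reference region for the phase split; defaults to
#'   `region`.
#' @return a one-row tibble with `fraction`, `n_steps` (steps in the phase
#'   window) and `entered` (was the reference region entered?).
#' @export
occupancy_rate <- function(steps, region, phase = c("full", "before", "after"),
                           ref_region = region) {
  phase <- match.arg(phase)
  if ("guided" %in% names(steps)) steps <- steps[!steps$guided, ]
  pos <- cbind(steps$x, steps$y)
  inside <- in_region(pos, region)
  first_in <- which(in_region(pos, ref_region))[1]
  entered <- !is.na(first_in)
  idx <- switch(phase,
    full = seq_len(nrow(pos)),
    before = seq_len(if (entered) first_in - 1 else nrow(pos)),
    after = if (entered) seq(first_in, nrow(pos)) else integer(0))
  tibble::tibble(
    fraction = if (length(idx)) mean(inside[idx]) else 0,
    n_steps = length(idx), entered = entered)
}

#' Strategy selection rates
#'
#' Fraction of executed (non-guided) timesteps on which each module won the
#' winner-take-all selection, per repeat and grouping cell. Within each cell
#' the rates over the registered modules sum to 1.
#'
#' @param x a [run_experiment()] result.
#' @param by character vector of grouping columns of the selection table
#'   (any of `"session"`, `"trial"`, `"tag"`, `"stage"`, `"angle"`,
#'   `"trial_global"`); empty for whole-run rates.
#' @return tibble with `rep`, the grouping columns, `module`, `steps`
#'   (selected timesteps) and `rate`.
#' @export
selection_rates <- function(x, by = character()) {
  sel <- dplyr::group_by(x$selection,
                         dplyr::across(dplyr::all_of(c("rep", by, "module"))))
  sel <- dplyr::summarise(sel, steps = sum(.data$count), .groups = "drop_last")
  sel <- dplyr::mutate(sel, rate = if (sum(.data$steps) > 0)
    .data$steps / sum(.data$steps) else NA_real_)
  dplyr::ungroup(sel)
}

#' Classify repeats as cue- or place-responders
#'
#' On the competition trial the platform and its attached cue stand at the
#' position diametrically opposite the trained one. A repeat whose trajectory
#' enters the old-platform zone (disk of `radius_mult` x platform radius
#' around the previous platform centre) before first reaching the new
#' platform is a place-responder; otherwise it is a cue-responder.
#'
#' @param x a [run_experiment()] result for the competition protocol, with
#'   the competition trial's steps recorded.
#' @param radius_mult zone radius as a multiple of the platform radius.
#' @return tibble with `rep` and `responder` (`"place"` or `"cue"`).
#' @export
classify_responders <- function(x, radius_mult = 2) {
  comp <- dplyr::filter(x$trials, .data$tag == "competition")
  if (nrow(comp) == 0) stop("no competition trial in this experiment")
  prev <- dplyr::filter(x$trials, .data$tag != "competition",
                        .data$platform_present)
  purrr::map_dfr(unique(comp$rep), function(r) {
    ct <- comp[comp$rep == r, ]
    old_center <- c(prev$platform_x[prev$rep == r][1],
                    prev$platform_y[prev$rep == r][1])
    zone <- disk_region(old_center, radius_mult * x$params$platform_radius)
    st <- x$steps[x$steps$rep == r & x$steps$trial_global == ct$trial_global, ]
    hit <- if (nrow(st)) any(in_region(cbind(st$x, st$y), zone)) else FALSE
    tibble::tibble(rep = r,
                   responder = if (hit) "place" else "cue")
  })
}

# exact distribution of the sum of a size-na subset of (2x) midranks, by
# dynamic programming over the generating polynomial; counts are exact in
# doubles up to 2^53
rank_subset_distribution <- function(ranks2, na) {
  n <- length(ranks2)
  maxs <- sum(ranks2)
  # dp[j+1, s+1] = number of j-subsets with sum s
  dp <- matrix(0, na + 1, maxs + 1)
  dp[1, 1] <- 1
  for (i in seq_len(n)) {
    jmax <- min(i, na)
    for (j in jmax:1) {
      shifted <- c(rep(0, ranks2[i]), dp[j, seq_len(maxs + 1 - ranks2[i])])
      dp[j + 1, ] <- dp[j + 1, ] + shifted
    }
  }
  dp[na + 1, ]
}

#' Mann-Whitney U test (exact under ties for small samples)
#'
#' Rank-sum test with mid-ranks for ties. For `length(a) * length(b) <= 400`
#' the two-sided p-value is exact, computed from the full permutation
#' distribution of the rank sum; larger samples use the normal approximation
#' with tie correction and continuity correction. The two-sided p-value is
#' twice the smaller tail (capped at 1).
#'
#' @param a,b numeric samples.
#' @return list with `U` (statistic of sample `a`), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  Ra <- sum(r[seq_len(na)])
  U <- Ra - na * (na + 1) / 2
  if (na * nb <= 400) {
    ranks2 <- as.integer(round(2 * r))
    dist <- rank_subset_distribution(ranks2, na)
    total <- choose(n, na)
    s_obs <- as.integer(round(2 * Ra))
    sums <- seq_along(dist) - 1
    p_le <- sum(dist[sums <= s_obs]) / total
    p_ge <- sum(dist[sums >= s_obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    zraw <- U - mu
    z <- (zraw - sign(zraw) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Wilcoxon signed-rank test (exact for n <= 12)
#'
#' Paired test with zero differences dropped and mid-ranks on tied absolute
#' differences. For 12 or fewer nonzero differences the two-sided p-value is
#' exact (enumeration of all sign assignments); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b paired numeric samples of equal length.
#' @return list with `W` (the smaller of the positive/negative rank sums),
#'   `p` (two-sided) and `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero: test undefined")
  n <- length(d)
  r <- rank(abs(d))
  Wp <- sum(r[d > 0])
  Wm <- sum(r[d < 0])
  W <- min(Wp, Wm)
  if (n <= 12) {
    # distribution of W+ over all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wplus <- as.vector(signs %*% r)
    p_le <- mean(wplus <= Wp + 1e-9)
    p_ge <- mean(wplus >= Wp - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    zraw <- Wp - mu
    z <- (zraw - sign(zraw) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = W, p = p, method = method)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `""` otherwise.
#'
#' @param p p-value(s).
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}
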