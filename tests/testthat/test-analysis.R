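fake_experiment <- function(trials, selection = NULL, steps = NULL,
                            module_ids = c("D_c", "planning", "exploration")) {
  structure(list(trials = trials, selection = selection, steps = steps,
                 module_ids = module_ids,
                 params = wm_params(), n_repeats = max(trials$rep)),
            class = "wm_experiment")
}

test_that("escape_latencies aggregates by the requested grouping", {
  tr <- tibble::tibble(
    rep = c(1, 1, 2, 2), session = c(1, 1, 1, 1), trial = c(1, 2, 1, 2),
    trial_global = c(1, 2, 1, 2), tag = "escape", stage = 1L,
    platform_present = TRUE, latency = c(42, 10, 42, 20))
  x <- fake_experiment(tr)
  by_tr <- escape_latencies(x, "trial")
  expect_equal(by_tr$latency[by_tr$rep == 1 & by_tr$trial_global == 1], 42)
  by_se <- escape_latencies(x, "session")
  expect_equal(sort(by_se$latency), c(26, 31))
  # mean over repeats of trial 2: (10 + 20) / 2
  expect_equal(mean(by_tr$latency[by_tr$trial_global == 2]), 15)
})

test_that("occupancy_rate counts phase-restricted region time", {
  reg <- disk_region(c(0, 0), 10)
  never <- tibble::tibble(x = rep(50, 20), y = rep(50, 20))
  expect_equal(occupancy_rate(never, reg)$fraction, 0)

  half <- tibble::tibble(x = c(rep(0, 175), rep(50, 175)), y = 0)
  expect_equal(occupancy_rate(half, reg)$fraction, 0.5)

  inside <- tibble::tibble(x = rep(1, 30), y = 0)
  expect_equal(occupancy_rate(inside, reg)$fraction, 1)

  # phases partition the trial at the first entry into the reference region
  traj <- tibble::tibble(x = c(50, 40, 5, 5, 50, 5), y = 0)
  bef <- occupancy_rate(traj, reg, "before")
  aft <- occupancy_rate(traj, reg, "after")
  expect_equal(bef$n_steps + aft$n_steps, nrow(traj))
  expect_equal(bef$fraction, 0)
  expect_equal(aft$fraction, 3 / 4)

  # reference region never entered: before = full trial, empty after phase
  out <- occupancy_rate(never, reg, "after")
  expect_false(out$entered)
  expect_equal(out$fraction, 0)
  expect_equal(occupancy_rate(never, reg, "before")$n_steps, 20)
})

test_that("selection rates normalise per cell and sum to one", {
  sel <- tibble::tibble(
    rep = 1, session = 1, trial = 1:4, trial_global = 1:4, tag = "escape",
    stage = 1L, angle = NA_real_)
  sel <- tidyr::crossing(sel, module = c("D_c", "planning", "exploration"))
  sel$count <- 0L
  sel$count[sel$module == "D_c" & sel$trial %in% 1:2] <- 1L
  sel$count[sel$module == "planning" & sel$trial == 3] <- 1L
  sel$count[sel$module == "exploration" & sel$trial == 4] <- 1L
  x <- fake_experiment(tibble::tibble(rep = 1), selection = sel)
  r <- selection_rates(x)
  expect_equal(r$rate[r$module == "D_c"], 0.5)
  expect_equal(r$rate[r$module == "planning"], 0.25)
  expect_equal(r$rate[r$module == "exploration"], 0.25)
  expect_equal(sum(r$rate), 1)

  # an all-exploration (chance) run has rate 1 everywhere
  sel2 <- tibble::tibble(rep = 1, session = 1, trial = 1:3, trial_global = 1:3,
                         tag = "escape", stage = 1L, angle = NA_real_,
                         module = "exploration", count = c(5L, 9L, 2L))
  x2 <- fake_experiment(tibble::tibble(rep = 1), selection = sel2,
                        module_ids = "exploration")
  r2 <- selection_rates(x2, by = "session")
  expect_equal(r2$rate, 1)
})

test_that("responder classification follows the old-zone-first rule", {
  trials <- tibble::tibble(
    rep = rep(1:2, each = 2), session = 1L, trial = c(1, 2, 1, 2),
    trial_global = c(1, 2, 1, 2), tag = rep(c("cued", "competition"), 2),
    stage = 1L, platform_present = TRUE,
    platform_x = c(-35, 35, -35, 35), platform_y = c(35, -35, 35, -35),
    latency = 10, guided = FALSE, rewarded = TRUE,
    angle = NA_real_, cue_angle = NA_real_,
    start_x = 0, start_y = 0)
  # rep 1 goes straight to the new platform; rep 2 visits the old zone first
  steps <- dplyr::bind_rows(
    tibble::tibble(rep = 1, trial_global = 2, t = 1:3,
                   x = c(10, 20, 35), y = c(-10, -20, -35),
                   module = "D_c", guided = FALSE),
    tibble::tibble(rep = 2, trial_global = 2, t = 1:4,
                   x = c(-20, -35, 0, 35), y = c(20, 35, 0, -35),
                   module = "planning", guided = FALSE))
  x <- fake_experiment(trials, steps = steps)
  r <- classify_responders(x)
  expect_equal(r$responder[r$rep == 1], "cue")
  expect_equal(r$responder[r$rep == 2], "place")
})

test_that("Mann-Whitney exact p-values match the printed conventions", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  a <- c(3, 1, 4, 1, 5); b <- c(2, 7, 1)
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Mann-Whitney agrees with full enumeration for all n <= 5", {
  set.seed(61)
  for (na in 1:5) for (nb in 1:5) {
    for (k in 1:3) {
      a <- sample(1:4, na, replace = TRUE)   # ties happen often
      b <- sample(1:4, nb, replace = TRUE)
      expect_equal(mann_whitney_u(a, b)$p, mw_oracle(a, b),
                   tolerance = 1e-12,
                   label = paste("na", na, "nb", nb, "k", k))
    }
  }
})

test_that("Wilcoxon signed-rank handles zeros, ties and sign symmetry", {
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(r$W, 0)
  expect_equal(r$p, 2 / 2^5)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")

  set.seed(62)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(a, b)$p, wilcoxon_signed_rank(b, a)$p)
})

test_that("Wilcoxon agrees with enumeration and stats::wilcox.test", {
  set.seed(63)
  for (n in 2:5) for (k in 1:3) {
    a <- sample(1:5, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    if (all(a == b)) a[1] <- a[1] + 1
    expect_equal(wilcoxon_signed_rank(a, b)$p, wsr_oracle(a, b),
                 tolerance = 1e-12, label = paste("n", n, "k", k))
  }
  # tie-free case against the independent base-R exact test
  a <- c(1.3, 2.7, 0.2, 4.4, 3.1, 5.9)
  b <- c(2.2, 1.1, 0.9, 3.3, 4.8, 5.0)
  expect_equal(wilcoxon_signed_rank(a, b)$p,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("significance stars follow the reporting convention", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", ""))
})
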