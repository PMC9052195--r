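test_that("the four-block cost matrix has the documented structure", {
  f1 <- data.frame(x = c(0, 10), y = c(0, 0))
  f2 <- data.frame(x = c(0.5, 10.5, 40), y = c(0, 0, 0))
  pr <- build_linking_problem(f1, f2, max_link_distance = 2)
  expect_equal(dim(pr$C), c(5, 5))
  L <- pr$C[1:2, 1:3]
  expect_equal(L[1, 1], 0.5)
  expect_equal(L[2, 2], 0.5)
  expect_true(all(is.infinite(L[cbind(c(1, 1, 2, 2), c(2, 3, 1, 3))])))
  # E and S diagonals carry b, off-diagonals are forbidden
  expect_equal(diag(pr$C[1:2, 4:5]), rep(pr$b, 2))
  expect_equal(diag(pr$C[3:5, 1:3]), rep(pr$b, 3))
  expect_true(is.infinite(pr$C[1, 5]))
  # T block mirrors L's sparsity with the auxiliary cost
  expect_equal(pr$C[3, 4], pr$c)
  expect_true(is.infinite(pr$C[5, 4]))
})

test_that("a 2-vs-3 frame pair links both probes and flags one appearance", {
  f1 <- data.frame(x = c(0, 10), y = c(0, 0))
  f2 <- data.frame(x = c(0.5, 10.5, 40), y = c(0, 0, 0))
  pr <- build_linking_problem(f1, f2, max_link_distance = 2)
  ev <- acidtrace:::assignment_events(pr, solve_lap(pr))
  expect_equal(ev$links, cbind(from = c(1, 2), to = c(1, 2)))
  expect_equal(ev$births, 3)
  expect_length(ev$deaths, 0)
})

test_that("an empty first frame forces all detections through the birth block", {
  f1 <- data.frame(x = numeric(0), y = numeric(0))
  f2 <- data.frame(x = c(1, 2, 3), y = c(0, 0, 0))
  pr <- build_linking_problem(f1, f2, max_link_distance = 2)
  ev <- acidtrace:::assignment_events(pr, solve_lap(pr))
  expect_equal(ev$births, 1:3)
  expect_equal(nrow(ev$links), 0)
})

test_that("identical frames produce the zero-cost identity linking", {
  f <- data.frame(x = c(3, 8, 20), y = c(1, 5, 9))
  pr <- build_linking_problem(f, f, max_link_distance = 2)
  sol <- solve_lap(pr)
  ev <- acidtrace:::assignment_events(pr, sol)
  expect_equal(ev$links[, "from"], ev$links[, "to"])
  expect_equal(sum(pr$C[1:3, 1:3][ev$links]), 0)
})

test_that("LAP solutions equal the brute-force permutation optimum", {
  set.seed(10)
  for (i in 1:100) {
    n <- if (i <= 50) 4 else 5
    C <- matrix(runif(n * n), n, n)
    sol <- solve_lap(C)
    expect_equal(sol$total_cost, brute_lap_cost(C), tolerance = 1e-10)
    # doubly-stochastic 0/1 constraints
    expect_true(all(rowSums(sol$assignment) == 1))
    expect_true(all(colSums(sol$assignment) == 1))
  }
})

test_that("infeasible assignment problems raise identifying errors", {
  C <- matrix(c(1, Inf, Inf, Inf, 2, Inf, Inf, Inf, Inf), 3, 3, byrow = TRUE)
  expect_error(solve_lap(C), "row 3")
  expect_error(solve_lap(matrix(1, 2, 3)), "square|==")
  expect_equal(solve_lap(matrix(5, 1, 1))$cols, 1L)
})

test_that("a stationary probe over three frames yields one gap-free track", {
  frames <- rep(list(data.frame(x = 50, y = 50)), 3)
  tracks <- track_frames(frames, max_link_distance = 5)
  expect_equal(unique(tracks$track_id), 1)
  expect_equal(tracks$frame, 1:3)
})

test_that("a disappearing probe ends its track with a death", {
  frames <- list(data.frame(x = 50, y = 50), data.frame(x = 51, y = 50),
                 data.frame(x = numeric(0), y = numeric(0)))
  ev <- link_all_frames(frames, max_link_distance = 5)
  expect_equal(ev[[2]]$deaths, 1)
  tracks <- concatenate_segments(ev, frames)
  expect_equal(max(tracks$frame), 2)
})

test_that("a birth mid-movie starts a second track", {
  frames <- list(data.frame(x = 10, y = 10),
                 data.frame(x = c(11, 80), y = c(10, 80)),
                 data.frame(x = c(12, 81), y = c(10, 80)))
  tracks <- concatenate_segments(link_all_frames(frames, 5), frames)
  expect_equal(length(unique(tracks$track_id)), 2)
  second <- tracks[tracks$track_id == 2, ]
  expect_equal(min(second$frame), 2)
})

test_that("empty inputs produce empty track lists", {
  frames <- rep(list(data.frame(x = numeric(0), y = numeric(0))), 3)
  tracks <- concatenate_segments(link_all_frames(frames, 5), frames)
  expect_equal(nrow(tracks), 0)
})

test_that("gap closing merges a single candidate pair across a gap", {
  # probe visible frames 1-5 and 7-10, missing in frame 6
  frames <- lapply(1:10, function(t) {
    if (t == 6) data.frame(x = numeric(0), y = numeric(0))
    else data.frame(x = 10 + t, y = 20)
  })
  segs <- concatenate_segments(link_all_frames(frames, 5), frames)
  expect_equal(length(unique(segs$track_id)), 2)
  closed <- close_gaps(segs, max_gap = 3, n_frames = 10)
  expect_equal(length(unique(closed$track_id)), 1)
  expect_true(closed$gap_flag[closed$frame == 7])
  expect_false(any(closed$gap_flag[closed$frame != 7]))
})

test_that("gap closing picks the near continuation under the Brownian cost", {
  # track A ends at frame 5 at x=20; two candidate continuations start at
  # frame 7: near (x=22) and far (x=40)
  frames <- lapply(1:12, function(t) {
    xs <- c()
    if (t <= 5) xs <- c(xs, 20)
    if (t >= 7) xs <- c(xs, 22, 40)
    data.frame(x = xs, y = rep(0, length(xs)))
  })
  segs <- concatenate_segments(link_all_frames(frames, 3), frames)
  closed <- close_gaps(segs, max_gap = 3, n_frames = 12)
  merged <- closed[closed$frame %in% c(5, 7), ]
  a <- closed$track_id[closed$frame == 5 & closed$x == 20]
  expect_equal(closed$track_id[closed$frame == 7 & closed$x == 22], a)
  expect_false(closed$track_id[closed$frame == 7 & closed$x == 40] == a)
  # hand-enumerated 2-candidate costs: (22-20)^2/2 = 2 < (40-20)^2/2 = 200
})

test_that("gaps larger than max_gap are never bridged", {
  frames <- lapply(1:10, function(t) {
    if (t %in% 4:8) data.frame(x = numeric(0), y = numeric(0))
    else data.frame(x = 10, y = 10)
  })
  segs <- concatenate_segments(link_all_frames(frames, 5), frames)
  closed <- close_gaps(segs, max_gap = 3, n_frames = 10)
  expect_equal(length(unique(closed$track_id)), 2)
})

test_that("every detection lands in exactly one track (conservation)", {
  cfg <- vicsek_config(n_particles = 20, n_frames = 30, init = "ordered",
                       min_separation = 8, burn_in = 10, seed = 17)
  traj <- simulate_vicsek(cfg)
  frames <- lapply(1:30, function(t) {
    data.frame(x = traj$positions[, t, 1], y = traj$positions[, t, 2])
  })
  tracks <- track_frames(frames, periodic_box = 512)
  expect_equal(nrow(tracks), 20 * 30)
  key <- paste(tracks$frame, tracks$x, tracks$y)
  expect_equal(anyDuplicated(key), 0)
})

test_that("tracking is invariant under global translation and detection order", {
  cfg <- vicsek_config(n_particles = 12, n_frames = 20, box_size = 400,
                       init = "ordered", min_separation = 8, burn_in = 5,
                       seed = 23)
  traj <- simulate_vicsek(cfg)
  frames <- lapply(1:20, function(t) {
    data.frame(x = traj$positions[, t, 1], y = traj$positions[, t, 2])
  })
  base <- track_frames(frames, max_link_distance = 5)
  shifted <- lapply(frames, function(f) data.frame(x = f$x + 3, y = f$y - 7))
  tr_shift <- track_frames(shifted, max_link_distance = 5)
  expect_equal(tr_shift$track_id, base$track_id)
  expect_equal(tr_shift$x, base$x + 3)
  # permute detections within frames: same partition of detections
  set.seed(4)
  perm <- lapply(frames, function(f) f[sample(nrow(f)), , drop = FALSE])
  tr_perm <- track_frames(perm, max_link_distance = 5)
  canon <- function(tr) {
    unname(lapply(split(paste(tr$frame, tr$x, tr$y), tr$track_id), sort))
  }
  expect_setequal(canon(tr_perm), canon(base))
})

test_that("perfect reconstructions score zero error and swaps are counted", {
  cfg <- vicsek_config(n_particles = 10, n_frames = 15, init = "ordered",
                       min_separation = 10, burn_in = 5, seed = 29)
  traj <- simulate_vicsek(cfg)
  perfect <- trajectories_to_df(traj)
  perfect$ph <- NA_real_
  perfect$gap_flag <- FALSE
  sc <- evaluate_tracking(perfect, traj)
  expect_equal(sc$wrong_links, 0)
  expect_equal(sc$missed_links, 0)
  expect_equal(sc$error_fraction, 0)
  # swap two identities from frame 8 on: 2 wrong + 2 missed links
  swapped <- perfect
  a <- swapped$track_id == 1 & swapped$frame >= 8
  b <- swapped$track_id == 2 & swapped$frame >= 8
  swapped$track_id[a] <- 2L
  swapped$track_id[b] <- 1L
  sc2 <- evaluate_tracking(swapped, traj)
  expect_equal(sc2$wrong_links, 2)
  expect_equal(sc2$missed_links, 2)
  expect_equal(sc2$wrong_track_count, 2)
})

test_that("low-density ordered scenes are reconstructed without error", {
  rep1 <- run_validation_study(n_grid = 20, n_reps = 3, seed = 5)
  expect_equal(attr(rep1, "summary")$mean_error_fraction, 0)
  # determinism of the full study
  rep2 <- run_validation_study(n_grid = 20, n_reps = 3, seed = 5)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))
})
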