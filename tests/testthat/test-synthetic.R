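test_that("pure-inertia motion is a straight line at constant speed", {
  cfg <- vicsek_config(n_particles = 1, n_frames = 12, alpha = 1, beta = 0,
                       gamma = 0, n_neighbors = 0, speed = 2,
                       box_size = 1e4, seed = 3)
  tr <- simulate_vicsek(cfg)
  v <- tr$velocities[1, , ]
  expect_lt(max(abs(sweep(v, 2, v[1, ]))), 1e-10)
  steps <- sqrt(diff(tr$positions[1, , 1])^2 + diff(tr$positions[1, , 2])^2)
  expect_equal(steps, rep(2, 11), tolerance = 1e-7)
})

test_that("speed is conserved at every step with noise and imitation on", {
  cfg <- vicsek_config(n_particles = 20, n_frames = 30, speed = 1.5,
                       gamma = 0.5, seed = 5)
  tr <- simulate_vicsek(cfg)
  # steps measured away from the periodic wrap
  for (i in 1:20) {
    dx <- diff(tr$positions[i, , 1]); dy <- diff(tr$positions[i, , 2])
    ok <- abs(dx) < 100 & abs(dy) < 100
    expect_equal(sqrt(dx[ok]^2 + dy[ok]^2),
                 rep(1.5, sum(ok)), tolerance = 1e-7)
  }
})

test_that("simulation is bit-identical under a repeated seed and differs across seeds", {
  cfg <- vicsek_config(n_particles = 10, n_frames = 20, seed = 11)
  expect_identical(simulate_vicsek(cfg)$positions,
                   simulate_vicsek(cfg)$positions)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(simulate_vicsek(cfg)$positions,
                         simulate_vicsek(cfg2)$positions))
})

test_that("strong imitation drives global polar order", {
  cfg <- vicsek_config(n_particles = 50, n_frames = 200, alpha = 0.1,
                       beta = 5, gamma = 0, n_neighbors = 6, speed = 1,
                       seed = 7)
  tr <- simulate_vicsek(cfg)
  expect_gt(tail(polar_order(tr), 1), 0.95)
})

test_that("simulator agrees with an independent reference implementation", {
  cfg <- vicsek_config(n_particles = 15, n_frames = 40, alpha = 1,
                       beta = 2, gamma = 0, n_neighbors = 4, speed = 1,
                       box_size = 300, seed = 21)
  tr <- simulate_vicsek(cfg)
  ref <- reference_vicsek(15, 40, 300, alpha = 1, beta = 2, k = 4,
                          speed = 1, seed = 21)
  expect_equal(tr$positions, ref, tolerance = 1e-10)
})

test_that("trajectories are complete: every particle has a position in every frame", {
  tr <- simulate_vicsek(vicsek_config(n_particles = 8, n_frames = 25,
                                      seed = 2))
  expect_true(all(is.finite(tr$positions)))
  expect_identical(dim(tr$positions), c(8L, 25L, 2L))
})

test_that("ordered init with exclusion distance respects the minimum separation", {
  cfg <- vicsek_config(n_particles = 40, n_frames = 2, init = "ordered",
                       min_separation = 10, seed = 9)
  tr <- simulate_vicsek(cfg)
  p <- tr$positions[, 1, ]
  d <- as.matrix(dist(p))
  dW <- pmin(d, 512 - d)   # lower bound on the torus distance per axis pair
  diag(d) <- Inf
  expect_gt(min(d), 0)     # no coincident particles
  expect_gt(tail(polar_order(tr), 1), 0.9)
})

test_that("invalid simulation configs are rejected with a message", {
  expect_error(vicsek_config(n_particles = 0), "n_particles")
  expect_error(vicsek_config(alpha = -1), "non-negative")
  expect_error(vicsek_config(alpha = NaN), "finite")
})

test_that("noiseless renders carry the exact channel ratio at lit pixels", {
  rc <- render_config(noise_sigma = 0, background_level = 0,
                      channel_ratio_truth = 2)
  fr <- render_single_probe(rc)
  lit <- fr$red > 1e-6
  expect_gt(sum(lit), 100)
  expect_lt(max(abs(fr$green[lit] / fr$red[lit] - 2)), 1e-10)
})

test_that("an empty trajectory set renders to background plus noise", {
  rc <- render_config(noise_sigma = 1, background_level = 20)
  st <- render_frames(data.frame(track_id = integer(0), frame = integer(0),
                                 x = numeric(0), y = numeric(0)),
                      rc, seed = 4)
  fr <- st[[1]]
  expect_equal(mean(fr$red), 20, tolerance = 0.2)
  expect_equal(sd(as.vector(fr$green)), 1, tolerance = 0.1)
})

test_that("rendering is deterministic under a fixed seed", {
  rc <- render_config(noise_sigma = 3)
  a <- render_single_probe(rc, seed = 77)
  b <- render_single_probe(rc, seed = 77)
  expect_identical(a, b)
})

test_that("out-of-bounds particles are flagged as truncated", {
  rc <- render_config()
  st <- render_frames(data.frame(track_id = 1, frame = 1, x = 2, y = 64),
                      rc, seed = 1)
  expect_length(attr(st, "truncated"), 1)
})

test_that("outer archetype with zero noise is constant at ph_high", {
  tr <- generate_ph_track(archetype_track_config("outer", noise_sigma = 0,
                                                 n_frames = 50))
  expect_equal(tr$ph, rep(7.2, 50))
})

test_that("instantaneous caging drop gives a two-valued step track", {
  cfg <- archetype_track_config("caging", noise_sigma = 0,
                                drop_duration = 0, drop_time = 25,
                                n_frames = 50)
  tr <- generate_ph_track(cfg)
  expect_identical(sort(unique(tr$ph)), c(5.4, 7.2))
  expect_equal(tr$ph[1:24], rep(7.2, 24))
})

test_that("caging reads are bimodal where outer reads are monomodal", {
  # modes = connected runs of (3-bin smoothed) 20-bin histogram counts
  # above half maximum
  count_peaks <- function(x) {
    h <- hist(x, breaks = 20, plot = FALSE)$counts
    h <- h + c(0, h[-length(h)]) + c(h[-1], 0)
    high <- h > 0.5 * max(h)
    sum(diff(c(FALSE, high)) == 1)
  }
  ce <- generate_ph_track(archetype_track_config("caging", ph_high = 7.2,
                                                 ph_low = 5.4,
                                                 noise_sigma = 0.05,
                                                 n_frames = 200, seed = 8))
  oe <- generate_ph_track(archetype_track_config("outer", noise_sigma = 0.05,
                                                 n_frames = 200, seed = 8))
  expect_gte(count_peaks(ce$ph), 2)
  expect_equal(count_peaks(oe$ph), 1)
})

test_that("archetype reads stay within the noise envelope of the plateaus", {
  for (arche in c("outer", "caging", "inner")) {
    cfg <- archetype_track_config(arche, noise_sigma = 0.05, n_frames = 150,
                                  seed = 31)
    tr <- generate_ph_track(cfg)
    expect_gte(quantile(tr$ph, 0.05), 5.4 - 4 * 0.05)
    expect_lte(quantile(tr$ph, 0.95), 7.2 + 4 * 0.05)
  }
})

test_that("calibration fixture generator produces one fixture per level", {
  truth <- function(p) 0.6 + 1.6 / (1 + exp(-(p - 6.5) / 0.6))
  rc <- render_config(noise_sigma = 0, background_level = 0,
                      image_shape = c(96L, 96L))
  fx <- generate_calibration_fixture(seq(5, 8, by = 0.5), truth, rc)
  expect_length(fx, 7)
  expect_equal(vapply(fx, `[[`, numeric(1), "nominal_ph"), seq(5, 8, 0.5))
  # non-monotone truth curves are refused
  expect_error(generate_calibration_fixture(c(5, 6, 7), function(p) (p - 6)^2,
                                            rc),
               "monotone")
})
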