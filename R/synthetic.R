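# Synthetic-data generators: Vicsek trajectories, rendered two-channel image
# stacks, archetype pH tracks and calibration fixtures.  Every downstream
# stage of the pipeline can be exercised on these without external data.

#' Configuration for a Vicsek self-propelled particle simulation
#'
#' The simulated particles move at constant speed; at every step each
#' heading is updated as a normalized mixture of its own previous heading
#' (inertia, weight `alpha`), the mean heading of its topological
#' neighbours (imitation, weight `beta`) and a fresh 2-D standard-normal
#' noise vector (weight `gamma`).  Topological neighbours are the
#' `n_neighbors` nearest particles by Euclidean distance, self excluded.
#'
#' @param n_particles number of particles (>= 1).
#' @param n_frames number of frames (>= 2).
#' @param box_size side of the square box, in pixels.
#' @param alpha,beta,gamma non-negative weights of the inertia, imitation
#'   and noise terms of the heading update.
#' @param n_neighbors number of topological neighbours (0 disables the
#'   imitation term).
#' @param speed displacement per frame, in pixels.
#' @param boundary `"periodic"` (wrap-around) or `"reflecting"` (particles
#'   bounce off the walls).
#' @param init `"random"` starts from uniform random headings (the model
#'   then orders through a disordered transient); `"ordered"` starts in
#'   the polar ordered phase, with headings drawn around one common
#'   random direction with angular spread `heading_jitter`.
#' @param heading_jitter angular standard deviation (radians) of the
#'   initial headings when `init = "ordered"`.
#' @param min_separation minimum initial pairwise distance, pixels
#'   (dart-throwing placement; 0 disables).  Micron-sized probes cannot
#'   overlap, so validation scenes use a non-zero exclusion distance.
#' @param burn_in number of update steps evolved before the first
#'   recorded frame.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   trajectory bit for bit.
#' @return an object of class `vicsek_config`.
#' @export
vicsek_config <- function(n_particles = 50, n_frames = 100, box_size = 512,
                          alpha = 1, beta = 0.5, gamma = 0.2,
                          n_neighbors = 6, speed = 1,
                          boundary = c("periodic", "reflecting"),
                          init = c("random", "ordered"),
                          heading_jitter = 0.1, min_separation = 0,
                          burn_in = 0, seed = 1L) {
  boundary <- match.arg(boundary)
  init <- match.arg(init)
  for (nm in c("n_particles", "n_frames", "box_size", "alpha", "beta",
               "gamma", "n_neighbors", "speed", "seed")) {
    stop_if_not_scalar(get(nm), nm)
  }
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (alpha < 0 || beta < 0 || gamma < 0) {
    stop("alpha, beta and gamma must be non-negative")
  }
  if (n_neighbors < 0) stop("n_neighbors must be >= 0")
  if (box_size <= 0 || speed < 0) stop("box_size must be > 0 and speed >= 0")
  if (min_separation < 0 || burn_in < 0 || heading_jitter < 0) {
    stop("min_separation, burn_in and heading_jitter must be >= 0")
  }
  structure(list(n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames),
                 box_size = box_size, alpha = alpha, beta = beta,
                 gamma = gamma, n_neighbors = as.integer(n_neighbors),
                 speed = speed, boundary = boundary, init = init,
                 heading_jitter = heading_jitter,
                 min_separation = min_separation,
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed)),
            class = "vicsek_config")
}

# normalize rows of a 2-column matrix to unit length; zero rows stay zero
unitize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm > 0
  m[ok, ] <- m[ok, , drop = FALSE] / nrm[ok]
  m
}

# one heading + position update; consumes RNG only for gamma > 0
vicsek_step <- function(p, v, config) {
  n <- nrow(p)
  L <- config$box_size
  drive <- config$alpha * v
  if (config$beta > 0 && config$n_neighbors > 0 && n > 1) {
    k <- min(config$n_neighbors, n - 1)
    dx <- outer(p[, 1], p[, 1], `-`)
    dy <- outer(p[, 2], p[, 2], `-`)
    if (config$boundary == "periodic") {
      dx <- pmin(abs(dx), L - abs(dx))
      dy <- pmin(abs(dy), L - abs(dy))
    }
    d2 <- dx^2 + dy^2
    diag(d2) <- Inf
    imit <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      nb <- order(d2[i, ])[seq_len(k)]
      imit[i, ] <- colMeans(v[nb, , drop = FALSE])
    }
    drive <- drive + config$beta * unitize(imit)
  }
  if (config$gamma > 0) {
    drive <- drive + config$gamma * cbind(rnorm(n), rnorm(n))
  }
  vnew <- unitize(drive)
  zero <- rowSums(vnew^2) == 0
  vnew[zero, ] <- v[zero, , drop = FALSE]
  p <- p + config$speed * vnew
  if (config$boundary == "periodic") {
    p <- p %% L
  } else {
    for (d in 1:2) {
      lo <- p[, d] < 0
      p[lo, d] <- -p[lo, d]
      vnew[lo, d] <- -vnew[lo, d]
      hi <- p[, d] > L
      p[hi, d] <- 2 * L - p[hi, d]
      vnew[hi, d] <- -vnew[hi, d]
    }
    # box much larger than one step, so a single reflection suffices
    p <- pmin(pmax(p, 0), L)
  }
  list(p = p, v = vnew)
}

#' Simulate Vicsek trajectories
#'
#' Headings evolve as
#' `v_i(t+1) = theta(alpha * theta(v_i) + beta * theta(<theta(v_j)>_N(i)) +
#' gamma * eta_i)` where `theta(v) = v/|v|` and `eta_i` is a 2-D
#' standard-normal draw; positions advance by `speed * v_i(t+1)`.
#' If the mixed vector vanishes, the previous heading is kept.
#'
#' @param config a [vicsek_config()].
#' @return a `trajectory_set`: list with `positions` and `velocities`
#'   (arrays of dimension `n_particles x n_frames x 2`, velocities are unit
#'   headings), `particle_ids`, and the `config`.
#' @export
simulate_vicsek <- function(config) {
  stopifnot(inherits(config, "vicsek_config"))
  n <- config$n_particles
  nf <- config$n_frames
  L <- config$box_size
  pos <- array(NA_real_, dim = c(n, nf, 2))
  vel <- array(NA_real_, dim = c(n, nf, 2))

  with_seed(config$seed, {
    if (config$min_separation > 0) {
      p <- matrix(NA_real_, n, 2)
      placed <- 0L
      tries <- 0L
      while (placed < n) {
        cand <- c(runif(1, 0, L), runif(1, 0, L))
        ok <- TRUE
        if (placed > 0) {
          d <- abs(sweep(p[seq_len(placed), , drop = FALSE], 2, cand))
          if (config$boundary == "periodic") d <- pmin(d, L - d)
          ok <- all(sqrt(rowSums(d^2)) >= config$min_separation)
        }
        if (ok) { placed <- placed + 1L; p[placed, ] <- cand }
        tries <- tries + 1L
        if (tries > 1000L * n) {
          stop("could not place particles with the requested min_separation")
        }
      }
    } else {
      p <- cbind(runif(n, 0, L), runif(n, 0, L))
    }
    ang <- if (config$init == "ordered") {
      runif(1, 0, 2 * pi) + rnorm(n, 0, config$heading_jitter)
    } else {
      runif(n, 0, 2 * pi)
    }
    v <- cbind(cos(ang), sin(ang))
    for (t in seq_len(config$burn_in)) {
      st <- vicsek_step(p, v, config)
      p <- st$p; v <- st$v
    }
    pos[, 1, ] <- p
    vel[, 1, ] <- v
    for (t in seq_len(nf - 1)) {
      st <- vicsek_step(p, v, config)
      p <- st$p; v <- st$v
      pos[, t + 1, ] <- p
      vel[, t + 1, ] <- v
    }
  })

  structure(list(positions = pos, velocities = vel,
                 particle_ids = seq_len(n), config = config),
            class = "trajectory_set")
}

#' Polar order parameter of a trajectory set
#'
#' Modulus of the mean unit heading over particles, per frame; 1 means
#' global alignment.
#' @param traj a `trajectory_set`.
#' @return numeric vector, one value per frame.
#' @export
polar_order <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  apply(traj$velocities, 2, function(v) sqrt(sum(colMeans(v)^2)))
}

#' Convert a trajectory set to a tidy data frame
#' @param traj a `trajectory_set`.
#' @return data frame with columns `track_id`, `frame`, `x`, `y`.
#' @export
trajectories_to_df <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- dim(traj$positions)[1]
  nf <- dim(traj$positions)[2]
  data.frame(track_id = rep(traj$particle_ids, nf),
             frame = rep(seq_len(nf), each = n),
             x = as.vector(traj$positions[, , 1]),
             y = as.vector(traj$positions[, , 2]))
}

#' Rendering configuration for synthetic two-channel probe images
#'
#' Probes are drawn as uniform disks convolved with a Gaussian point-spread
#' function.  The red channel carries amplitude `peak_intensity`, the green
#' channel `peak_intensity * channel_ratio_truth`, so at background-free
#' pixels the green/red ratio equals the configured truth exactly.
#'
#' @param psf_sigma Gaussian blur scale, pixels.
#' @param particle_radius disk radius, pixels.
#' @param channel_ratio_truth true green/red amplitude ratio (> 0); may be
#'   a vector, recycled over particles.
#' @param background_level constant background intensity added to both
#'   channels.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param image_shape integer vector `c(rows, cols)`.
#' @param bit_depth intensities are clipped to `[0, 2^bit_depth - 1]`.
#' @param peak_intensity red-channel disk amplitude before blurring.
#' @return an object of class `render_config`.
#' @export
render_config <- function(psf_sigma = 4, particle_radius = 8,
                          channel_ratio_truth = 1.5, background_level = 10,
                          noise_sigma = 4, image_shape = c(128L, 128L),
                          bit_depth = 16, peak_intensity = 120) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  if (any(channel_ratio_truth <= 0)) stop("channel_ratio_truth must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (psf_sigma <= 0 || particle_radius <= 0) {
    stop("psf_sigma and particle_radius must be > 0")
  }
  structure(list(psf_sigma = psf_sigma, particle_radius = particle_radius,
                 channel_ratio_truth = channel_ratio_truth,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 image_shape = as.integer(image_shape),
                 bit_depth = bit_depth, peak_intensity = peak_intensity),
            class = "render_config")
}

# anti-aliased disk coverage at integer pixel centres
disk_coverage <- function(shape, center, radius) {
  rows <- seq_len(shape[1])
  cols <- seq_len(shape[2])
  d <- sqrt(outer((rows - center[1])^2, (cols - center[2])^2, `+`))
  pmin(1, pmax(0, radius - d + 0.5))
}

#' Render a trajectory set as a two-channel image stack
#'
#' @param traj a `trajectory_set`, or a data frame with columns
#'   `track_id`, `frame`, `x`, `y` (positions interpreted as (row, col),
#'   1-based, pixels).
#' @param rc a [render_config()].
#' @param seed RNG seed for the additive noise (`NULL` for noiseless
#'   reproducibility only when `noise_sigma = 0`).
#' @return an `image_stack`: a list of frames, each a list with matrices
#'   `green` and `red`; attribute `truth` holds the ground-truth positions
#'   and per-particle ratios, attribute `truncated` flags particles that
#'   were clipped at a frame border.
#' @export
render_frames <- function(traj, rc = render_config(), seed = NULL) {
  df <- if (inherits(traj, "trajectory_set")) trajectories_to_df(traj) else traj
  stopifnot(is.data.frame(df),
            all(c("track_id", "frame", "x", "y") %in% names(df)))
  ids <- sort(unique(df$track_id))
  ratios <- rep_len(rc$channel_ratio_truth, max(length(ids), 1L))
  frames_idx <- if (nrow(df)) seq_len(max(df$frame)) else 1L
  shape <- rc$image_shape
  cap <- 2^rc$bit_depth - 1
  truncated <- character(0)

  stack <- with_seed(seed, lapply(frames_idx, function(t) {
    red_raw <- matrix(0, shape[1], shape[2])
    green_raw <- matrix(0, shape[1], shape[2])
    sub <- df[df$frame == t, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      ctr <- c(sub$x[r], sub$y[r])
      if (any(ctr < 1 + rc$particle_radius) ||
          ctr[1] > shape[1] - rc$particle_radius ||
          ctr[2] > shape[2] - rc$particle_radius) {
        truncated <<- c(truncated, sprintf("frame %d id %s", t, sub$track_id[r]))
      }
      cov <- disk_coverage(shape, ctr, rc$particle_radius)
      ratio <- ratios[match(sub$track_id[r], ids)]
      red_raw <- red_raw + rc$peak_intensity * cov
      green_raw <- green_raw + rc$peak_intensity * ratio * cov
    }
    red <- rc$background_level + gaussian_blur(red_raw, rc$psf_sigma)
    green <- rc$background_level + gaussian_blur(green_raw, rc$psf_sigma)
    if (rc$noise_sigma > 0) {
      red <- red + matrix(rnorm(length(red), 0, rc$noise_sigma),
                          nrow(red), ncol(red))
      green <- green + matrix(rnorm(length(green), 0, rc$noise_sigma),
                              nrow(green), ncol(green))
    }
    list(green = pmin(pmax(green, 0), cap), red = pmin(pmax(red, 0), cap))
  }))

  structure(stack, class = "image_stack",
            truth = list(positions = df,
                         ratios = data.frame(track_id = ids,
                                             ratio = ratios[seq_along(ids)]),
                         render_config = rc),
            truncated = truncated)
}

#' Configuration for an archetype pH track
#'
#' Three archetypes mirror the three event classes: `outer` fluctuates
#' around `ph_high` (probe never enters a cell), `inner` around `ph_low`,
#' and `caging` drops from `ph_high` to `ph_low` through a logistic
#' transition centred at `drop_time` whose 10-90% width is about
#' `1.1 * drop_duration` frames (logistic scale = `drop_duration / 4`).
#'
#' @param archetype `"outer"`, `"caging"` or `"inner"`.
#' @param ph_high,ph_low plateau pH values (`ph_high > ph_low`).
#' @param drop_time centre frame of the caging transition.
#' @param drop_duration width parameter of the transition, frames; 0 gives
#'   an instantaneous step.
#' @param noise_sigma read noise, pH units.
#' @param n_frames number of reads.
#' @param frame_interval seconds between reads (acquisition cadence).
#' @param seed RNG seed.
#' @return an object of class `archetype_track_config`.
#' @export
archetype_track_config <- function(archetype = c("outer", "caging", "inner"),
                                   ph_high = 7.2, ph_low = 5.4,
                                   drop_time = NULL, drop_duration = 20,
                                   noise_sigma = 0.05, n_frames = 100,
                                   frame_interval = 30, seed = 1L) {
  archetype <- match.arg(archetype)
  if (!(ph_high > ph_low)) stop("ph_high must exceed ph_low")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (archetype == "caging") {
    drop_time <- drop_time %||% (n_frames / 2)
    if (drop_time <= 0 || drop_time >= n_frames) {
      stop("drop_time must satisfy 0 < drop_time < n_frames")
    }
    if (drop_duration < 0) stop("drop_duration must be >= 0")
  }
  structure(list(archetype = archetype, ph_high = ph_high, ph_low = ph_low,
                 drop_time = drop_time, drop_duration = drop_duration,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "archetype_track_config")
}

#' Generate an archetype pH track
#'
#' @param cfg an [archetype_track_config()].
#' @return a `ph_track`: list with `ph` (numeric vector), `frame`,
#'   `frame_interval` (seconds), `archetype` and the `config`.
#' @export
generate_ph_track <- function(cfg) {
  stopifnot(inherits(cfg, "archetype_track_config"))
  t <- seq_len(cfg$n_frames)
  base <- switch(cfg$archetype,
    outer = rep(cfg$ph_high, cfg$n_frames),
    inner = rep(cfg$ph_low, cfg$n_frames),
    caging = {
      s <- cfg$drop_duration / 4
      if (s <= 0) {
        ifelse(t < cfg$drop_time, cfg$ph_high, cfg$ph_low)
      } else {
        cfg$ph_low + (cfg$ph_high - cfg$ph_low) /
          (1 + exp((t - cfg$drop_time) / s))
      }
    })
  ph <- with_seed(cfg$seed,
                  base + rnorm(cfg$n_frames, 0, cfg$noise_sigma))
  structure(list(ph = ph, frame = t, frame_interval = cfg$frame_interval,
                 archetype = cfg$archetype, config = cfg),
            class = "ph_track")
}

#' Caging drop width that yields a target acidification time
#'
#' Inverts the logistic parameterization of the caging archetype: a
#' transition with `drop_duration = d` frames completes 10% to 90% of its
#' drop in `log(81)/4 * d` frames.
#'
#' @param tau_min target 10-90% acidification time, minutes.
#' @param frame_interval seconds per frame.
#' @return `drop_duration` in frames.
#' @export
caging_duration_for_tau <- function(tau_min, frame_interval = 30) {
  tau_frames <- tau_min * 60 / frame_interval
  tau_frames / (log(81) / 4)
}

#' Generate rendered calibration fixtures
#'
#' One single-probe image per pH level, with the probe's true channel
#' ratio set by a user-supplied monotone truth curve, paired with the
#' nominal pH — emulating gels at known pH imaged for calibration.
#'
#' @param ph_levels strictly increasing pH levels.
#' @param truth_curve monotone function pH -> true green/red ratio.
#' @param rc a [render_config()].
#' @param seed RNG seed for render noise.
#' @return list of elements `list(stack, nominal_ph, true_ratio)`.
#' @export
generate_calibration_fixture <- function(ph_levels, truth_curve,
                                         rc = render_config(), seed = 1L) {
  stopifnot(is.numeric(ph_levels), length(ph_levels) >= 1)
  if (is.unsorted(ph_levels, strictly = TRUE)) {
    stop("ph_levels must be strictly increasing")
  }
  ratios <- vapply(ph_levels, truth_curve, numeric(1))
  d <- diff(ratios)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("truth_curve must be strictly monotone over ph_levels")
  }
  ctr <- (rc$image_shape + 1) / 2
  lapply(seq_along(ph_levels), function(i) {
    rci <- rc
    rci$channel_ratio_truth <- ratios[i]
    df <- data.frame(track_id = 1L, frame = 1L, x = ctr[1], y = ctr[2])
    list(stack = render_frames(df, rci, seed = derive_seed(seed, i)),
         nominal_ph = ph_levels[i], true_ratio = ratios[i])
  })
}

#' Write pH tracks to CSV
#'
#' Columns `track_id, frame, x, y, pH`; positions are `NA` for tracks that
#' carry no spatial information.
#' @param tracks a list of `ph_track` objects or a tracks data frame.
#' @param path output file.
#' @export
write_tracks_csv <- function(tracks, path) {
  df <- if (is.data.frame(tracks)) tracks else {
    do.call(rbind, lapply(seq_along(tracks), function(i) {
      tr <- tracks[[i]]
      data.frame(track_id = i, frame = tr$frame, x = NA_real_, y = NA_real_,
                 pH = tr$ph)
    }))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
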