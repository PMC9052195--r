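# Trajectory reconstruction by linear assignment: frame-to-frame linking
# with a four-block cost matrix (link L, death E, birth S, auxiliary T),
# segment concatenation, and Brownian-weighted gap closing.

# Forbidden entries are Inf in the stored cost matrix; solve_lap() swaps in
# a finite sentinel so a dense square solver applies, then verifies that no
# sentinel entry was selected.

# all pairwise distances between two point sets; minimum-image convention
# when the scene lives on a periodic box (synthetic validation scenes)
cross_dist <- function(ax, ay, bx, by, periodic_box = NULL) {
  dx <- outer(ax, bx, `-`)
  dy <- outer(ay, by, `-`)
  if (!is.null(periodic_box)) {
    dx <- pmin(abs(dx), periodic_box - abs(dx))
    dy <- pmin(abs(dy), periodic_box - abs(dy))
  }
  sqrt(dx^2 + dy^2)
}

make_four_block <- function(L, b, c_aux) {
  n <- nrow(L); m <- ncol(L)
  E <- matrix(Inf, n, n); diag(E) <- b
  S <- matrix(Inf, m, m); diag(S) <- b
  Tm <- matrix(Inf, m, n)
  Tm[t(is.finite(L))] <- c_aux   # reversed-L sparsity pattern
  rbind(cbind(L, E), cbind(S, Tm))
}

#' Build the frame-to-frame linking problem
#'
#' Constructs the `(n+m) x (n+m)` four-block cost matrix for linking the
#' `n` detections of frame `t` to the `m` detections of frame `t+1`.
#' Block `L` holds Euclidean distances (Inf beyond `max_link_distance`),
#' diagonal blocks `E` and `S` hold the death/birth cost `b`, and `T` is
#' the transposed sparsity pattern of `L` filled with the auxiliary cost
#' `c`, which guarantees a feasible solution.
#'
#' By default `b` is 1.05 times the largest finite link cost (death/birth
#' as a last resort) and `c` is the smallest finite link cost, following
#' the usual LAP-tracking convention.
#'
#' @param f_t,f_t1 data frames with columns `x`, `y` (consecutive frames).
#' @param max_link_distance maximum allowed displacement, pixels.
#' @param b,c optional overrides for the death/birth and auxiliary costs.
#' @param periodic_box side of a periodic box (minimum-image distances),
#'   or `NULL` for plain Euclidean geometry.
#' @return an object of class `linking_problem`: list with `C`, `n`, `m`,
#'   `b`, `c`, `max_link_distance`.
#' @export
build_linking_problem <- function(f_t, f_t1, max_link_distance,
                                  b = NULL, c = NULL, periodic_box = NULL) {
  stopifnot(is.data.frame(f_t), is.data.frame(f_t1))
  n <- nrow(f_t); m <- nrow(f_t1)
  L <- matrix(numeric(0), n, m)
  if (n > 0 && m > 0) {
    L <- cross_dist(f_t$x, f_t$y, f_t1$x, f_t1$y, periodic_box)
    L[L > max_link_distance] <- Inf
  }
  fin <- L[is.finite(L)]
  b <- b %||% if (length(fin)) 1.05 * max(fin) else 1
  c <- c %||% if (length(fin)) min(fin) else 1
  structure(list(C = make_four_block(L, b, c), n = n, m = m, b = b, c = c,
                 max_link_distance = max_link_distance),
            class = "linking_problem")
}

#' Solve a linear assignment problem
#'
#' Minimum-cost one-to-one assignment of rows to columns of a square cost
#' matrix.  Infinite entries are forbidden; a solution that would need one
#' is reported as infeasible.  Ties are resolved deterministically (rows
#' augmented in index order).
#'
#' @param x a square numeric cost matrix (may contain `Inf`), or a
#'   `linking_problem` / `gap_problem` whose `C` matrix is solved.
#' @return an object of class `lap_assignment`: list with `cols`
#'   (assigned column per row), `assignment` (binary matrix), and
#'   `total_cost`.
#' @export
solve_lap <- function(x) {
  C <- if (inherits(x, c("linking_problem", "gap_problem"))) x$C else x
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  n <- nrow(C)
  if (n == 0) {
    return(structure(list(cols = integer(0),
                          assignment = matrix(0L, 0, 0), total_cost = 0),
                     class = "lap_assignment"))
  }
  bad_row <- which(!apply(C, 1, function(r) any(is.finite(r))))
  if (length(bad_row)) {
    stop(sprintf("infeasible assignment: row %s has no finite cost",
                 paste(bad_row, collapse = ", ")))
  }
  bad_col <- which(!apply(C, 2, function(r) any(is.finite(r))))
  if (length(bad_col)) {
    stop(sprintf("infeasible assignment: column %s has no finite cost",
                 paste(bad_col, collapse = ", ")))
  }
  fin <- C[is.finite(C)]
  sentinel <- 10 * max(abs(fin), 1) * n + 1
  Cs <- C
  Cs[!is.finite(Cs)] <- sentinel
  cols <- lap_solve_cpp(Cs)
  picked <- C[cbind(seq_len(n), cols)]
  if (any(!is.finite(picked))) {
    stop("infeasible assignment: optimal solution requires a forbidden entry")
  }
  A <- matrix(0L, n, n)
  A[cbind(seq_len(n), cols)] <- 1L
  structure(list(cols = cols, assignment = A, total_cost = sum(picked)),
            class = "lap_assignment")
}

# interpret a solved linking problem as link / death / birth events
assignment_events <- function(problem, sol) {
  n <- problem$n; m <- problem$m
  links <- births <- deaths <- NULL
  if (n > 0) {
    to <- sol$cols[seq_len(n)]
    linked <- to <= m
    links <- cbind(from = which(linked), to = to[linked])
    deaths <- which(!linked)
  } else {
    links <- cbind(from = integer(0), to = integer(0))
    deaths <- integer(0)
  }
  if (m > 0) {
    scols <- sol$cols[n + seq_len(m)]
    births <- which(scols == seq_len(m))   # S-diagonal selected
  } else births <- integer(0)
  list(links = links, deaths = deaths, births = births)
}

#' Default maximum link distance from the data
#'
#' The 99th percentile of nearest-neighbour displacements over the first
#' (up to) 10 frame pairs, inflated by a safety factor of 3 so that true
#' links at the typical per-frame displacement are never cut off by
#' quantile interpolation sitting exactly at that displacement.
#'
#' @param frames list of per-frame detection data frames (`x`, `y`).
#' @param inflate safety factor.
#' @param periodic_box optional periodic box side.
#' @return a distance in pixels.
#' @export
estimate_max_link_distance <- function(frames, inflate = 3,
                                       periodic_box = NULL) {
  dd <- c()
  for (t in seq_len(min(10, length(frames) - 1))) {
    a <- frames[[t]]; bb <- frames[[t + 1]]
    if (!nrow(a) || !nrow(bb)) next
    D <- cross_dist(a$x, a$y, bb$x, bb$y, periodic_box)
    dd <- c(dd, apply(D, 1, min))
  }
  if (!length(dd)) return(Inf)
  inflate * as.numeric(quantile(dd, 0.99, names = FALSE))
}

#' Link detections across all adjacent frame pairs
#'
#' @param frames list of data frames with columns `x`, `y` and optionally
#'   `ph` (one per frame, in time order).
#' @param max_link_distance maximum displacement; `NULL` to estimate it
#'   with [estimate_max_link_distance()].
#' @param periodic_box optional periodic box side.
#' @return list of per-pair event lists (`links`, `deaths`, `births`),
#'   with attribute `max_link_distance`.
#' @export
link_all_frames <- function(frames, max_link_distance = NULL,
                            periodic_box = NULL) {
  stopifnot(is.list(frames), length(frames) >= 2)
  max_link_distance <- max_link_distance %||%
    estimate_max_link_distance(frames, periodic_box = periodic_box)
  ev <- lapply(seq_len(length(frames) - 1), function(t) {
    pr <- build_linking_problem(frames[[t]], frames[[t + 1]],
                                max_link_distance,
                                periodic_box = periodic_box)
    if (pr$n == 0 && pr$m == 0) {
      return(list(links = cbind(from = integer(0), to = integer(0)),
                  deaths = integer(0), births = integer(0)))
    }
    assignment_events(pr, solve_lap(pr))
  })
  attr(ev, "max_link_distance") <- max_link_distance
  ev
}

#' Concatenate frame-to-frame links into gap-free tracks
#'
#' Follows each link from frame to frame; a birth starts a new track and
#' a death ends one.  Every detection lands in exactly one track.
#'
#' @param link_events result of [link_all_frames()].
#' @param frames the same list of per-frame detection data frames.
#' @return data frame with columns `track_id`, `frame`, `x`, `y`, `ph`
#'   (NA if absent), `gap_flag` (all FALSE at this stage).
#' @export
concatenate_segments <- function(link_events, frames) {
  n_frames <- length(frames)
  next_id <- 0L
  new_id <- function() { next_id <<- next_id + 1L; next_id }
  rows <- list()
  add_row <- function(id, t, i) {
    f <- frames[[t]]
    rows[[length(rows) + 1L]] <<- data.frame(
      track_id = id, frame = t, x = f$x[i], y = f$y[i],
      ph = if ("ph" %in% names(f)) f$ph[i] else NA_real_,
      gap_flag = FALSE)
  }
  # active[i] = track id owning detection i of the current frame
  active <- integer(0)
  if (n_frames >= 1 && nrow(frames[[1]])) {
    active <- vapply(seq_len(nrow(frames[[1]])), function(i) {
      id <- new_id(); add_row(id, 1L, i); id
    }, integer(1))
  }
  for (t in seq_along(link_events)) {
    ev <- link_events[[t]]
    m <- nrow(frames[[t + 1]])
    nxt <- integer(m)
    if (nrow(ev$links)) {
      for (r in seq_len(nrow(ev$links))) {
        id <- active[ev$links[r, "from"]]
        j <- ev$links[r, "to"]
        add_row(id, t + 1L, j)
        nxt[j] <- id
      }
    }
    for (j in ev$births) {
      id <- new_id(); add_row(id, t + 1L, j); nxt[j] <- id
    }
    if (m > 0 && any(nxt == 0L)) {
      stop("internal consistency error: unassigned detection after linking")
    }
    active <- nxt
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(track_id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), ph = numeric(0), gap_flag = logical(0))
  }
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Close gaps between track fragments
#'
#' A second LAP over track fragments: every track ending before the last
#' frame may continue as a track starting after the first frame, with
#' cost `|dr|^2 / dt` for temporal gaps `1 <= dt <= max_gap` (squared
#' displacement over elapsed time, the Brownian reference weighting) and
#' `Inf` otherwise.  Birth/death and auxiliary blocks are built as in
#' frame-to-frame linking.  Merged tracks keep only observed frames; the
#' first frame after a gap is marked `gap_flag = TRUE`.
#'
#' @param tracks track data frame from [concatenate_segments()].
#' @param max_gap largest temporal gap to bridge, frames.
#' @param max_jump optional cap on the spatial jump, pixels.
#' @param n_frames total number of frames (defaults to the largest frame
#'   index present).
#' @param periodic_box optional periodic box side.
#' @return track data frame with merged tracks and renumbered ids.
#' @export
close_gaps <- function(tracks, max_gap = 3, max_jump = Inf,
                       n_frames = NULL, periodic_box = NULL) {
  if (!nrow(tracks)) return(tracks)
  n_frames <- n_frames %||% max(tracks$frame)
  ids <- sort(unique(tracks$track_id))
  info <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    data.frame(id = id,
               start = min(tr$frame), end = max(tr$frame),
               x0 = tr$x[which.min(tr$frame)], y0 = tr$y[which.min(tr$frame)],
               x1 = tr$x[which.max(tr$frame)], y1 = tr$y[which.max(tr$frame)])
  }))
  enders <- info[info$end < n_frames, , drop = FALSE]
  starters <- info[info$start > 1, , drop = FALSE]
  if (!nrow(enders) || !nrow(starters)) return(tracks)

  L <- matrix(Inf, nrow(enders), nrow(starters))
  for (i in seq_len(nrow(enders))) for (j in seq_len(nrow(starters))) {
    dt <- starters$start[j] - enders$end[i]
    if (dt >= 1 && dt <= max_gap && enders$id[i] != starters$id[j]) {
      dr <- cross_dist(enders$x1[i], enders$y1[i],
                       starters$x0[j], starters$y0[j], periodic_box)[1, 1]
      if (dr <= max_jump) L[i, j] <- dr^2 / dt
    }
  }
  fin <- L[is.finite(L)]
  if (!length(fin)) return(tracks)
  b <- 1.05 * max(fin); c_aux <- min(fin)
  pr <- structure(list(C = make_four_block(L, b, c_aux),
                       n = nrow(enders), m = nrow(starters),
                       b = b, c = c_aux),
                  class = "gap_problem")
  sol <- solve_lap(pr)
  ev <- assignment_events(list(n = pr$n, m = pr$m), sol)

  # merge chains via successor pointers
  succ <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  if (nrow(ev$links)) {
    for (r in seq_len(nrow(ev$links))) {
      succ[as.character(enders$id[ev$links[r, "from"]])] <-
        starters$id[ev$links[r, "to"]]
    }
  }
  merged_into <- stats::setNames(ids, ids)
  has_pred <- ids %in% succ[!is.na(succ)]
  out <- tracks
  for (root in ids[!has_pred]) {
    cur <- root
    while (!is.na(succ[as.character(cur)])) {
      nxt <- succ[as.character(cur)]
      sel <- out$track_id == nxt
      out$track_id[sel] <- root
      first <- which(sel & out$frame == min(out$frame[sel]))
      out$gap_flag[first] <- TRUE
      cur <- nxt
    }
  }
  # renumber by first appearance
  out <- out[order(out$track_id, out$frame), ]
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}

#' Track detections end to end
#'
#' Convenience wrapper: frame-to-frame linking, segment concatenation and
#' gap closing.
#'
#' @inheritParams link_all_frames
#' @inheritParams close_gaps
#' @return track data frame (see [concatenate_segments()]), with a
#'   `manifest` attribute recording parameters and event counts.
#' @export
track_frames <- function(frames, max_link_distance = NULL, max_gap = 3,
                         max_jump = Inf, periodic_box = NULL) {
  ev <- link_all_frames(frames, max_link_distance, periodic_box)
  segs <- concatenate_segments(ev, frames)
  out <- close_gaps(segs, max_gap = max_gap, max_jump = max_jump,
                    n_frames = length(frames), periodic_box = periodic_box)
  attr(out, "manifest") <- list(
    max_link_distance = attr(ev, "max_link_distance"),
    max_gap = max_gap, max_jump = max_jump,
    n_links = sum(vapply(ev, function(e) nrow(e$links), integer(1))),
    n_births = sum(vapply(ev, function(e) length(e$births), integer(1))),
    n_deaths = sum(vapply(ev, function(e) length(e$deaths), integer(1))),
    n_tracks_before_gap_closing = length(unique(segs$track_id)),
    n_tracks = length(unique(out$track_id)))
  out
}

#' Score inferred tracks against ground truth
#'
#' Maps every detection to its ground-truth particle by position and
#' counts two kinds of error on consecutive observations within inferred
#' tracks: links joining two different true particles (wrong links) and
#' true consecutive-frame links that no inferred track reproduces (missed
#' links).  The error fraction is their sum over the number of true
#' links.
#'
#' @param tracks inferred track data frame.
#' @param truth a `trajectory_set`.
#' @param tol matching tolerance in pixels when mapping detections to
#'   true particles.
#' @return list with `wrong_links`, `missed_links`, `total_true_links`,
#'   `error_fraction`, `wrong_track_count`.
#' @export
evaluate_tracking <- function(tracks, truth, tol = 0.5) {
  stopifnot(inherits(truth, "trajectory_set"))
  n <- dim(truth$positions)[1]
  nf <- dim(truth$positions)[2]
  if (nrow(tracks) && max(tracks$frame) > nf) {
    stop("inferred tracks extend beyond the ground-truth frame range")
  }
  # map each observation to a true particle id
  tid <- integer(nrow(tracks))
  for (r in seq_len(nrow(tracks))) {
    t <- tracks$frame[r]
    d2 <- (truth$positions[, t, 1] - tracks$x[r])^2 +
          (truth$positions[, t, 2] - tracks$y[r])^2
    j <- which.min(d2)
    if (d2[j] > tol^2) {
      stop("a detection could not be matched to any ground-truth particle")
    }
    tid[r] <- j
  }
  ord <- order(tracks$track_id, tracks$frame)
  tt <- tracks$track_id[ord]; ff <- tracks$frame[ord]; pid <- tid[ord]
  same <- which(tt[-1] == tt[-length(tt)])
  wrong <- sum(pid[same + 1L] != pid[same])
  wrong_tracks <- length(unique(tt[same[pid[same + 1L] != pid[same]]]))
  # inferred consecutive-frame links, keyed particle@t -> particle@t+1
  link_key <- paste(pid[same], ff[same], pid[same + 1L], ff[same + 1L])
  true_keys <- paste(rep(seq_len(n), nf - 1),
                     rep(seq_len(nf - 1), each = n),
                     rep(seq_len(n), nf - 1),
                     rep(2:nf, each = n))
  total_true <- n * (nf - 1)
  missed <- sum(!(true_keys %in% link_key))
  list(wrong_links = wrong, missed_links = missed,
       total_true_links = total_true,
       error_fraction = (wrong + missed) / total_true,
       wrong_track_count = wrong_tracks)
}

#' Write / read a tracks CSV
#' @param tracks track data frame.
#' @param path file path.
#' @export
write_tracking_csv <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_tracking_csv <- function(path) read.csv(path)
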