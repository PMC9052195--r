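# Event classification (quantile embedding -> PCA -> k-means++) and
# acidification-time estimation by isotonic regression.

QUANTILE_PROBS <- seq(0.05, 0.95, length.out = 10)

#' Quantile embedding of a pH track
#'
#' Discards temporal order and summarizes the distribution of reads by 10
#' empirical quantiles uniformly spaced on [5%, 95%].  Monomodal reads
#' (outer/inner events) give tight embeddings at high/low pH; the bimodal
#' reads of a caging event spread the quantiles between the two modes.
#'
#' @param track a `ph_track` or numeric vector of pH reads.
#' @param min_len minimum number of reads required (shorter tracks carry
#'   too little support for 10 quantiles).
#' @return numeric vector of 10 nondecreasing quantiles.
#' @export
quantile_embed <- function(track, min_len = 20) {
  x <- if (inherits(track, "ph_track")) track$ph else track
  stopifnot(is.numeric(x))
  if (length(x) < min_len) {
    stop(sprintf("track has %d reads; minimum is %d", length(x), min_len))
  }
  quantile(x, probs = QUANTILE_PROBS, names = FALSE)
}

#' Embed a collection of tracks
#'
#' @param tracks list of `ph_track` objects / numeric vectors, or a track
#'   data frame with columns `track_id` and `ph`.
#' @param min_len minimum track length; shorter tracks are excluded and
#'   listed in the `excluded` attribute with the reason.
#' @return matrix (tracks x 10 quantiles) with rownames = track ids.
#' @export
embed_tracks <- function(tracks, min_len = 20) {
  if (is.data.frame(tracks)) {
    ids <- unique(tracks$track_id)
    tracks <- stats::setNames(
      lapply(ids, function(id) tracks$ph[tracks$track_id == id]), ids)
  }
  if (is.null(names(tracks))) names(tracks) <- seq_along(tracks)
  lens <- vapply(tracks, function(tr) {
    length(if (inherits(tr, "ph_track")) tr$ph else tr)
  }, integer(1))
  ok <- lens >= min_len
  E <- t(vapply(tracks[ok], quantile_embed, numeric(10), min_len = min_len))
  attr(E, "excluded") <- data.frame(
    track_id = names(tracks)[!ok],
    reason = sprintf("only %d reads (< %d)", lens[!ok], min_len))
  E
}

#' Project quantile embeddings onto the first two principal components
#'
#' Column-centred (not variance-scaled: all 10 coordinates share pH
#' units) SVD projection.  Signs are fixed so that PC1 increases with the
#' track's mean pH and PC2 with its dispersion, matching the usual
#' reading of the two components.
#'
#' @param embeddings matrix from [embed_tracks()] (>= 3 rows).
#' @return list with `coords` (n x 2), `explained_fraction`, `loadings`
#'   (10 x 2) and `degenerate` (TRUE when all embeddings coincide, in
#'   which case coords are zero and the fraction is NA).
#' @export
pca_project <- function(embeddings) {
  stopifnot(is.matrix(embeddings), ncol(embeddings) == 10)
  if (nrow(embeddings) < 3) stop("need at least 3 embedded tracks")
  if (all(apply(embeddings, 2, function(col) diff(range(col)) == 0))) {
    return(list(coords = matrix(0, nrow(embeddings), 2,
                                dimnames = list(rownames(embeddings), NULL)),
                explained_fraction = NA_real_,
                loadings = matrix(NA_real_, 10, 2), degenerate = TRUE))
  }
  pc <- prcomp(embeddings, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  if (k < 2) {  # rank-1 input
    coords <- cbind(coords, 0)
    load <- cbind(load, 0)
  }
  # sign conventions: PC1 ~ mean pH (all-positive loadings), PC2 ~ spread
  if (sum(load[, 1]) < 0) { load[, 1] <- -load[, 1]; coords[, 1] <- -coords[, 1] }
  if (load[10, 2] - load[1, 2] < 0) {
    load[, 2] <- -load[, 2]; coords[, 2] <- -coords[, 2]
  }
  expl <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  list(coords = coords, explained_fraction = expl, loadings = load,
       degenerate = FALSE)
}

# k-means++ seeding: first centre uniform, then far points with
# probability proportional to squared distance to the nearest centre
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- colSums((t(X) - X[centers[1], ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j] <- sample.int(n, 1)
      } else {
        centers[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, colSums((t(X) - X[centers[j], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

#' Cluster event coordinates with k-means++
#'
#' k-means with k-means++ far-point seeding; the best of `n_restarts`
#' seedings by total within-cluster sum of squares is kept.
#' Deterministic under a fixed seed.
#'
#' @param coords numeric matrix (points x dims), e.g. PCA coordinates.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param n_restarts number of independent seedings.
#' @return list with `cluster` (assignments), `centers`, `tot_withinss`.
#' @export
cluster_events <- function(coords, k = 3, seed = 1L, n_restarts = 10) {
  coords <- as.matrix(coords)
  if (k > nrow(coords)) stop("k exceeds the number of points")
  if (k < 1) stop("k must be >= 1")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      ctr <- kmeanspp_centers(coords, k)
      # Lloyd iterations from the ++ seeds; duplicate seeds can arise in
      # degenerate data, so fall back to jittered centres when needed
      fit <- tryCatch(
        kmeans(coords, centers = ctr, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed on all restarts")
    list(cluster = best$cluster, centers = best$centers,
         tot_withinss = best$tot.withinss)
  })
}

#' Label clusters as outer / caging / inner events
#'
#' With k = 3 clusters of quantile embeddings: the cluster with the
#' largest mean inter-quantile spread (Q95 - Q5) is the caging class CE
#' (bimodal reads spread the quantiles); of the remaining two, the higher
#' mean pH is the outer class OE and the lower the inner class IE.  If no
#' cluster stands out in spread (ratio of largest to second-largest below
#' `spread_ratio`), the labelling is ambiguous and an error asks for
#' manual review.
#'
#' @param assignments integer cluster assignments (k = 3).
#' @param embeddings the quantile-embedding matrix the clustering was
#'   derived from.
#' @param spread_ratio minimum ratio of largest to second-largest mean
#'   cluster spread required to declare a CE cluster.
#' @return data frame (`event records`) with columns `track_id`, `label`
#'   (OE/CE/IE), `cluster`.
#' @export
label_clusters <- function(assignments, embeddings, spread_ratio = 2) {
  stopifnot(length(assignments) == nrow(embeddings))
  ks <- sort(unique(assignments))
  if (length(ks) != 3) stop("labelling requires exactly 3 clusters")
  spread <- vapply(ks, function(kk) {
    mean(embeddings[assignments == kk, 10] - embeddings[assignments == kk, 1])
  }, numeric(1))
  mean_ph <- vapply(ks, function(kk) {
    mean(embeddings[assignments == kk, ])
  }, numeric(1))
  o <- order(spread, decreasing = TRUE)
  if (spread[o[2]] > 0 && spread[o[1]] / spread[o[2]] < spread_ratio) {
    stop("ambiguous clustering: no cluster has a dominant quantile spread; ",
         "manual review required")
  }
  lab <- character(3)
  lab[o[1]] <- "CE"
  rest <- o[2:3]
  lab[rest[which.max(mean_ph[rest])]] <- "OE"
  lab[rest[which.min(mean_ph[rest])]] <- "IE"
  data.frame(track_id = rownames(embeddings) %||%
               as.character(seq_len(nrow(embeddings))),
             label = lab[match(assignments, ks)],
             cluster = assignments,
             stringsAsFactors = FALSE)
}

#' Classify pH tracks into outer / caging / inner events
#'
#' Full classifier: quantile embedding, 2-component PCA and k-means++
#' with k = 3, then spread/mean-based labelling.
#'
#' @inheritParams embed_tracks
#' @param k number of clusters (3 for the three archetypes).
#' @param seed,n_restarts passed to [cluster_events()].
#' @param spread_ratio passed to [label_clusters()].
#' @return data frame of event records: `track_id`, `label`, `cluster`,
#'   `pc1`, `pc2`, plus attributes `explained_fraction`, `loadings` and
#'   `excluded`.
#' @export
classify_events <- function(tracks, min_len = 20, k = 3, seed = 1L,
                            n_restarts = 10, spread_ratio = 2) {
  E <- embed_tracks(tracks, min_len = min_len)
  pca <- pca_project(E)
  if (pca$degenerate) stop("degenerate embeddings: all tracks identical")
  cl <- cluster_events(pca$coords, k = k, seed = seed,
                       n_restarts = n_restarts)
  rec <- label_clusters(cl$cluster, E, spread_ratio = spread_ratio)
  rec$pc1 <- pca$coords[, 1]
  rec$pc2 <- pca$coords[, 2]
  attr(rec, "explained_fraction") <- pca$explained_fraction
  attr(rec, "loadings") <- pca$loadings
  attr(rec, "excluded") <- attr(E, "excluded")
  rec
}

#' Nonincreasing isotonic fit (pool adjacent violators)
#'
#' Least-squares projection of the reads onto the cone of nonincreasing
#' sequences.  Already-nonincreasing input is returned unchanged; the fit
#' is idempotent.
#'
#' @param track a `ph_track` or numeric vector (>= 4 reads).
#' @param decreasing fit a nonincreasing (default) or nondecreasing
#'   sequence.
#' @return an `isotonic_fit`: list with `fitted`, `raw`,
#'   `frame_interval` (seconds; taken from the track or defaulting to 30).
#' @export
fit_isotonic <- function(track, decreasing = TRUE) {
  x <- if (inherits(track, "ph_track")) track$ph else track
  fi <- if (inherits(track, "ph_track")) track$frame_interval else 30
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (length(x) < 4) stop("isotonic fit needs at least 4 reads")
  structure(list(fitted = pava_fit(x, decreasing = decreasing), raw = x,
                 frame_interval = fi, decreasing = decreasing),
            class = "isotonic_fit")
}

# weighted pool-adjacent-violators; nonincreasing fits run on the negated
# sequence
pava_fit <- function(y, decreasing = FALSE) {
  if (decreasing) return(-pava_fit(-y, decreasing = FALSE))
  n <- length(y)
  # blocks as (value, weight) stacks
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- 1; len[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      w <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / w
      wt[m - 1L] <- w
      len[m - 1L] <- len[m - 1L] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], len[seq_len(m)])
}

#' Acidification time from an isotonic fit
#'
#' For a drop-completion fraction `1 - lambda`, `t(lambda)` is the
#' earliest frame at which the fit has fallen to
#' `pH_end + lambda * (pH_start - pH_end)`.  The plateau levels
#' `pH_start`/`pH_end` are medians of the first and last `seg_frac` of
#' the raw reads: the extreme values of the isotonic fit itself are
#' prefix/suffix extrema of pooled means and sit systematically outside
#' the plateaus, which would inflate the estimated drop and widen the
#' window, while terminal-segment medians are unbiased and equally
#' robust to single-frame outliers.  The acidification time is the
#' conventional rise-time-style window
#' `delta_tau = t(lambda_lo) - t(lambda_hi)` (default: time from 10% to
#' 90% of the completed drop), reported in minutes.
#'
#' @param fit an [fit_isotonic()] result.
#' @param lambda_hi,lambda_lo remaining-drop fractions bounding the
#'   window (defaults 0.9 and 0.1).
#' @param frame_interval seconds per frame (defaults to the fit's).
#' @param min_drop smallest total drop (pH units) considered a real
#'   acidification; below it no estimate is produced.
#' @param seg_frac fraction of the track length (at least 3 reads) used
#'   for each plateau-level median.
#' @return list with `delta_tau_min`, `t_hi_frame`, `t_lo_frame`,
#'   `lambda_window`, `total_drop`, `ok` (FALSE with a `reason` when the
#'   track shows no drop — likely a misclassified track).
#' @export
acidification_time <- function(fit, lambda_hi = 0.9, lambda_lo = 0.1,
                               frame_interval = NULL, min_drop = 1e-8,
                               seg_frac = 0.1) {
  stopifnot(inherits(fit, "isotonic_fit"))
  stopifnot(lambda_hi > lambda_lo, lambda_hi < 1, lambda_lo > 0)
  frame_interval <- frame_interval %||% fit$frame_interval
  f <- fit$fitted
  n <- length(f)
  m <- max(3L, ceiling(seg_frac * n))
  start <- median(fit$raw[seq_len(m)])
  end <- median(fit$raw[seq(n - m + 1L, n)])
  drop <- start - end
  if (drop < min_drop) {
    return(list(delta_tau_min = NA_real_, t_hi_frame = NA_real_,
                t_lo_frame = NA_real_, lambda_window = c(lambda_hi, lambda_lo),
                total_drop = drop, ok = FALSE,
                reason = "no pH drop in isotonic fit"))
  }
  t_of <- function(lam) {
    idx <- which(f <= end + lam * drop)[1]
    if (is.na(idx)) n else idx
  }
  t_hi <- t_of(lambda_hi); t_lo <- t_of(lambda_lo)
  list(delta_tau_min = (t_lo - t_hi) * frame_interval / 60,
       t_hi_frame = t_hi, t_lo_frame = t_lo,
       lambda_window = c(lambda_hi, lambda_lo), total_drop = drop, ok = TRUE)
}

#' Cohort summary of acidification times
#'
#' @param estimates data frame with columns `delta_tau_min` and
#'   optionally `cohort`.
#' @return data frame with per-cohort `n`, `mean`, `sd`, `median`, `q25`,
#'   `q75` (box-plot-ready).
#' @export
summarize_acidification <- function(estimates) {
  if (!nrow(estimates)) {
    return(data.frame(cohort = character(0), n = integer(0),
                      mean = numeric(0), sd = numeric(0), median = numeric(0),
                      q25 = numeric(0), q75 = numeric(0)))
  }
  if (!"cohort" %in% names(estimates)) estimates$cohort <- "all"
  out <- do.call(rbind, lapply(split(estimates, estimates$cohort), function(g) {
    x <- g$delta_tau_min[is.finite(g$delta_tau_min)]
    data.frame(cohort = g$cohort[1], n = length(x),
               mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
               median = median(x),
               q25 = quantile(x, 0.25, names = FALSE),
               q75 = quantile(x, 0.75, names = FALSE))
  }))
  rownames(out) <- NULL
  out
}
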