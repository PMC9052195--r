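# Independent oracles used to pin down expected values: deliberately
# naive implementations that share no code with the package internals.

# all permutations of a vector (recursive)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# brute-force LAP minimum by exhaustive permutation enumeration
brute_lap_cost <- function(C) {
  n <- nrow(C)
  min(vapply(all_perms(seq_len(n)),
             function(p) sum(C[cbind(seq_len(n), p)]), numeric(1)))
}

# direct nested-loop 2-D convolution with reflect padding, unit-sum kernel
conv2_oracle <- function(img, kern1d) {
  k <- (length(kern1d) - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    acc <- 0
    for (dr in -k:k) for (dc in -k:k) {
      acc <- acc + kern1d[dr + k + 1] * kern1d[dc + k + 1] *
        img[reflect(r + dr, nr), reflect(cc + dc, nc)]
    }
    out[r, cc] <- acc
  }
  out
}

# isotonic (nonincreasing) least squares by enumerating every partition of
# the index range into consecutive blocks with nonincreasing block means
pava_oracle <- function(y) {
  n <- length(y)
  best <- NULL; best_sse <- Inf
  # compositions of n encoded as subsets of cut points
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    means <- numeric(length(bounds) - 1)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- mean(y[idx])
      fit[idx] <- means[b]
    }
    if (all(diff(means) <= 1e-12)) {
      sse <- sum((y - fit)^2)
      if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
    }
  }
  best
}

# compact reference implementation of the self-propelled update rule for
# gamma = 0 (no noise consumed after initialization), periodic box with
# minimum-image neighbour distances
reference_vicsek <- function(n, nf, L, alpha, beta, k, speed, seed) {
  set.seed(seed)
  p <- cbind(runif(n, 0, L), runif(n, 0, L))
  ang <- runif(n, 0, 2 * pi)
  v <- cbind(cos(ang), sin(ang))
  theta <- function(w) if (sum(w^2) > 0) w / sqrt(sum(w^2)) else w
  pos <- array(NA_real_, c(n, nf, 2))
  pos[, 1, ] <- p
  for (t in 2:nf) {
    vn <- v
    for (i in 1:n) {
      drive <- alpha * theta(v[i, ])
      if (beta > 0 && k > 0 && n > 1) {
        ax <- abs(p[, 1] - p[i, 1]); ay <- abs(p[, 2] - p[i, 2])
        d2 <- pmin(ax, L - ax)^2 + pmin(ay, L - ay)^2
        d2[i] <- Inf
        nb <- order(d2)[seq_len(min(k, n - 1))]
        hh <- t(apply(v[nb, , drop = FALSE], 1, theta))
        drive <- drive + beta * theta(colMeans(hh))
      }
      vi <- theta(drive)
      vn[i, ] <- if (sum(vi^2) > 0) vi else v[i, ]
    }
    v <- vn
    p <- (p + speed * v) %% L
    pos[, t, ] <- p
  }
  pos
}
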