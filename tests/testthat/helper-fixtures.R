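# Shared in-code fixtures.

# a labelled set of archetype pH tracks (outer / inner / caging)
make_archetype_set <- function(seed, n_oe = 40, n_ie = 40, n_ce = 20,
                               noise_sigma = 0.05, n_frames = 100) {
  tracks <- list(); labels <- character(0)
  k <- 0
  add <- function(arche, lab, count) {
    for (i in seq_len(count)) {
      k <<- k + 1
      tracks[[k]] <<- generate_ph_track(archetype_track_config(
        arche, noise_sigma = noise_sigma, n_frames = n_frames,
        seed = seed * 100000L + k))
      labels[k] <<- lab
    }
  }
  add("outer", "OE", n_oe)
  add("inner", "IE", n_ie)
  add("caging", "CE", n_ce)
  list(tracks = tracks, labels = labels)
}

# one rendered single-probe frame plus its detection
render_single_probe <- function(rc = render_config(), center = c(64.5, 64.5),
                                seed = NULL) {
  df <- data.frame(track_id = 1L, frame = 1L, x = center[1], y = center[2])
  render_frames(df, rc, seed = seed)[[1]]
}
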