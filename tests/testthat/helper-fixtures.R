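# Shared in-code fixtures: everything is generated at test time.

# minimal epochs object from a channel x time x trial array builder
make_epochs <- function(fun, n_ch = 4, srate = 250, t_lim = c(-0.5, 1),
                        n_trials = 8, channels = NULL,
                        alignment = "stimulus") {
  tt <- seq(t_lim[1], t_lim[2], by = 1 / srate)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_ch))
  dat <- array(0, dim = c(n_ch, length(tt), n_trials))
  for (c in seq_len(n_ch)) {
    for (tr in seq_len(n_trials)) dat[c, , tr] <- fun(tt, c, tr)
  }
  maat_epochs(dat, srate, tt, alignment, channels)
}

# hand-built pupil object with controllable content
make_pupil <- function(diameter, srate = 200, t0 = -1,
                       blinks = data.frame(trial = integer(),
                                           start = numeric(),
                                           end = numeric()),
                       gaze_y = NULL, load = NULL) {
  d <- if (is.matrix(diameter)) diameter else matrix(diameter, nrow = 1)
  tt <- t0 + (seq_len(ncol(d)) - 1) / srate
  if (is.null(gaze_y)) {
    # bounded-derivative gaze so the z-screen flags nothing by itself
    gaze_y <- matrix(rep(sin(2 * pi * 0.5 * tt), nrow(d)),
                     nrow = nrow(d), byrow = TRUE)
  }
  structure(list(diameter = d, gaze_y = gaze_y, time = tt, srate = srate,
                 blinks = blinks,
                 load = load %||% rep(1, nrow(d)),
                 alignment = "stimulus"),
            class = "maat_pupil")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-class pattern set with controllable separation
make_patterns <- function(n_per_class, n_feat, sep, seed) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * n_feat, +sep / 2), n_per_class),
             matrix(rnorm(n_per_class * n_feat, -sep / 2), n_per_class))
  list(X = X, y = rep(c(1L, 0L), each = n_per_class))
}
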