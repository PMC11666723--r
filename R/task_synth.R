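MAAT_FEATURES <- c("color", "direction", "size", "saturation")

#' Stimulus configuration for the multi-attribute attention task
#'
#' Per-feature evidence ratios give the fraction of display elements
#' carrying the dominant option of each binary feature. Defaults are the
#' task's calibrated values: color 60/40, direction 80/20, size 65/35,
#' saturation 60/40, with motion coherence 0.2 for the moving elements.
#'
#' @param evidence named numeric vector of dominant-option fractions in
#'   (0.5, 1], one per feature.
#' @param coherence motion coherence in `[0, 1]`: the fraction of
#'   direction-feature elements moving coherently (the rest move in random
#'   directions).
#' @param n_elements display elements per frame.
#' @param frame_rate display frame rate (Hz).
#' @return a `maat_stimulus_config` list.
#' @export
stimulus_config <- function(evidence = c(color = 0.60, direction = 0.80,
                                         size = 0.65, saturation = 0.60),
                            coherence = 0.2, n_elements = 120,
                            frame_rate = 60) {
  stopifnot(all(names(evidence) == MAAT_FEATURES),
            all(evidence >= 0.5), all(evidence <= 1), # 0.5 = symmetric null
            coherence >= 0, coherence <= 1, n_elements >= 1)
  structure(list(evidence = evidence, coherence = coherence,
                 n_elements = n_elements, frame_rate = frame_rate),
            class = c("maat_stimulus_config", "list"))
}

#' Planted-effect configuration for the synthetic generators
#'
#' Houses every planted condition effect consumed by the modality
#' simulators: per-group diffusion-model intercepts and load slopes,
#' EEG effect sizes (theta gain, alpha suppression, aperiodic-slope
#' shift, broadband/entropy shift, centro-parietal ramp slope), pupil
#' dilation-rate gain, BOLD feature SNR and the rank-1 brain-behavior
#' latent pattern, plus noise levels. Load slopes are per unit of
#' target load above one, so load 1 uses the intercept alone.
#'
#' Defaults encode the qualitative pattern the young group shows under
#' rising uncertainty — drift rate down, theta power up, posterior alpha
#' down, sample entropy up, aperiodic slope shallower (exponent down),
#' pupil dilation rate up — with the old group showing the same signs but
#' dampened magnitudes; see the methods vignette for the rationale behind
#' each magnitude.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return a `maat_effect_config` list.
#' @export
effect_config <- function(...) {
  cfg <- list(
    ddm = list(
      young = list(v0 = 2.2, v_slope = -0.35, a0 = 1.8, a_slope = 0.05,
                   t00 = 0.30, t0_slope = 0.02),
      old   = list(v0 = 1.6, v_slope = -0.12, a0 = 2.0, a_slope = 0.05,
                   t00 = 0.35, t0_slope = 0.02),
      p_outlier = 0.05
    ),
    eeg = list(
      theta_amp = 1.0,
      theta_slope = list(young = 0.25, old = 0.08),
      alpha_amp = 1.5,
      alpha_slope = list(young = -0.20, old = -0.06),
      chi0 = 1.8,                       # aperiodic exponent at load 1
      chi_slope = list(young = -0.15, old = -0.04),
      broadband_sd = 0.5,               # entropy carrier (white component)
      entropy_slope = list(young = 0.25, old = 0.08),
      cpp_k = list(young = 8.0, old = 5.0),   # ramp slope at load 1 (units/s)
      cpp_slope = list(young = -0.20, old = -0.07),
      ssvep_amp = 0.8,
      mubeta_amp = 1.2,
      noise_sd = 1.0
    ),
    pupil = list(
      dilation_rate = 0.8,              # units/s at load 1
      dilation_slope = list(young = 0.30, old = 0.10),
      constriction = 1.5,
      blink_rate = 0.10,                # blinks per second
      noise_sd = 0.05
    ),
    bold = list(
      feature_snr_cued = 1.2,
      cued_load_slope = -0.15,          # probed/cued fidelity drops with load
      feature_snr_uncued = 0.15,
      uncued_load_slope = 0.25,         # unprobed fidelity rises with load
      latent_loading = c(1, 2, 3, 4),   # per-load loading of the rank-1 plant
      noise_sd = 1.0
    ),
    seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown effect keys: ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
  }
  stopifnot(cfg$eeg$noise_sd > 0, cfg$pupil$noise_sd > 0,
            cfg$bold$noise_sd > 0)
  structure(cfg, class = c("maat_effect_config", "list"))
}

group_ddm_params <- function(effects, group, load) {
  g <- effects$ddm[[group]]
  if (is.null(g)) stop("no diffusion parameters configured for group '",
                       group, "'")
  ddm_params(v = g$v0 + g$v_slope * (load - 1),
             a = g$a0 + g$a_slope * (load - 1),
             t0 = g$t00 + g$t0_slope * (load - 1),
             p_outlier = effects$ddm$p_outlier, load = load)
}

## ---------------------------------------------------------------------
## Session design

no_adjacent_sequence <- function(counts, prev, rng_n = 1000) {
  # permute a multiset of set sizes such that no two adjacent entries are
  # equal and the first differs from `prev` (last block of previous run)
  pool <- rep(seq_along(counts), counts)
  for (i in seq_len(rng_n)) {
    s <- sample(pool)
    if (!any(diff(s) == 0) && (is.na(prev) || s[1] != prev)) return(s)
  }
  stop("could not sequence cue-set sizes without adjacent repeats")
}

#' Generate a balanced session design
#'
#' Builds the full trial list of one session: `n_runs` runs of
#' `blocks_per_run` blocks of `trials_per_block` trials. The cue set (the
#' features a probe may query) is constant within a block; with 8 blocks
#' per run each set size 1-4 appears exactly twice per run; adjacent
#' blocks never share a set size (also across run boundaries); every
#' cued feature is probed at least once per block, with remaining probe
#' slots filled round-robin over the cue set and shuffled; and the 16
#' dominant-option combinations of the four binary features are exactly
#' balanced over the session whenever the trial total divides by 16.
#' Trial phase timings are fixed: cue 1 s, fixation 2 s, stimulus 3 s,
#' probe 2 s, inter-trial interval 1.5 s.
#'
#' @param config a [stimulus_config()].
#' @param n_runs,blocks_per_run,trials_per_block session geometry
#'   (defaults 4 x 8 x 8 = 256 trials).
#' @param seed integer seed; the design is a pure function of its
#'   arguments.
#' @param set_sizes optional integer vector (length `blocks_per_run`) of
#'   cue-set sizes per run, overriding the balanced default.
#' @return a `maat_design` data.frame, one row per trial, with columns
#'   `run`, `block`, `trial`, `block_global`, `load`, `cue_set`
#'   (`+`-separated feature names), `probe_feature`, `dom_<feature>`
#'   (option `"A"`/`"B"` per feature) and the phase timings.
#' @export
generate_session_design <- function(config = stimulus_config(),
                                    n_runs = 4, blocks_per_run = 8,
                                    trials_per_block = 8, seed,
                                    set_sizes = NULL) {
  stopifnot(n_runs >= 1, blocks_per_run >= 1, trials_per_block >= 1)
  if (missing(seed)) stop("seed must be given")
  if (is.null(set_sizes)) {
    if (blocks_per_run %% 4 == 0) {
      counts <- rep(blocks_per_run / 4, 4)
    } else {
      counts <- tabulate(rep(1:4, length.out = blocks_per_run), nbins = 4)
    }
    max_size <- max(which(counts > 0))
  } else {
    stopifnot(length(set_sizes) == blocks_per_run,
              all(set_sizes %in% 1:4))
    max_size <- max(set_sizes)
  }
  if (trials_per_block < max_size) {
    stop("constraint violation [probe coverage]: trials_per_block (",
         trials_per_block, ") < largest cue-set size (", max_size,
         "); each cued feature must be probed at least once per block")
  }
  set.seed(split_seed(seed, "design"))
  rows <- vector("list", n_runs * blocks_per_run)
  prev <- NA_integer_
  bg <- 0L
  for (r in seq_len(n_runs)) {
    sizes <- if (is.null(set_sizes)) no_adjacent_sequence(counts, prev)
             else set_sizes
    if (!is.null(set_sizes) && !is.na(prev) && sizes[1] == prev) {
      stop("constraint violation [set-size sequencing]: supplied set_sizes",
           " repeat across a run boundary")
    }
    if (!is.null(set_sizes) && any(diff(sizes) == 0)) {
      stop("constraint violation [set-size sequencing]: supplied set_sizes",
           " contain adjacent repeats")
    }
    prev <- sizes[length(sizes)]
    for (b in seq_len(blocks_per_run)) {
      bg <- bg + 1L
      sz <- sizes[b]
      cue <- sort(sample(MAAT_FEATURES, sz))
      # each cued feature probed >= once; remainder round-robin, shuffled
      probes <- c(cue, rep(cue, length.out = trials_per_block - sz))
      probes <- sample(probes)
      rows[[bg]] <- data.frame(
        run = r, block = b, trial = seq_len(trials_per_block),
        block_global = bg, load = sz,
        cue_set = paste(cue, collapse = "+"),
        probe_feature = probes, stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, rows)
  n_total <- nrow(design)
  # exact dominant-option balance over the 16 combinations
  combos <- expand.grid(rep(list(c("A", "B")), 4), stringsAsFactors = FALSE)
  names(combos) <- paste0("dom_", MAAT_FEATURES)
  idx <- rep(seq_len(16), length.out = n_total)
  if (n_total %% 16 == 0) idx <- rep(seq_len(16), each = n_total / 16)
  design <- cbind(design, combos[sample(idx), , drop = FALSE])
  rownames(design) <- NULL
  design$t_cue <- 1; design$t_fix <- 2; design$t_stim <- 3
  design$t_probe <- 2; design$t_iti <- 1.5
  attr(design, "n_runs") <- n_runs
  attr(design, "blocks_per_run") <- blocks_per_run
  attr(design, "trials_per_block") <- trials_per_block
  attr(design, "seed") <- seed
  class(design) <- c("maat_design", "data.frame")
  design
}

#' Validate the invariants of a session design
#'
#' Checks trial totals, within-block cue-set constancy, no adjacent
#' blocks sharing a set size, probe coverage of every cued feature per
#' block, and (for sessions whose trial count divides by 16) exact
#' balance of dominant-option combinations.
#'
#' @param design a `maat_design`.
#' @return `TRUE` invisibly, or an error naming the violated invariant.
#' @export
validate_design <- function(design) {
  nr <- attr(design, "n_runs"); bp <- attr(design, "blocks_per_run")
  tp <- attr(design, "trials_per_block")
  if (nrow(design) != nr * bp * tp) stop("invariant [trial total] violated")
  by_block <- split(design, design$block_global)
  for (blk in by_block) {
    if (length(unique(blk$cue_set)) != 1)
      stop("invariant [cue set constant within block] violated")
    cue <- strsplit(blk$cue_set[1], "+", fixed = TRUE)[[1]]
    if (!all(blk$probe_feature %in% cue))
      stop("invariant [probe within cue set] violated")
    if (!all(cue %in% blk$probe_feature))
      stop("invariant [each cued feature probed >= once] violated")
  }
  sizes <- vapply(by_block, function(b) b$load[1], numeric(1))
  sizes <- sizes[order(as.integer(names(by_block)))]
  if (any(diff(sizes) == 0))
    stop("invariant [no adjacent blocks share set size] violated")
  if (nrow(design) %% 16 == 0) {
    key <- do.call(paste0, design[paste0("dom_", MAAT_FEATURES)])
    if (length(unique(table(key))) != 1 || length(unique(key)) != 16)
      stop("invariant [dominant-option balance] violated")
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------
## Stimulus evidence

#' Generate per-frame element evidence for one trial
#'
#' Renders the stimulus abstractly, as element attribute tables rather
#' than pixels: for every feature, each display element on each frame is
#' independently assigned the dominant option with the configured
#' evidence probability. For the direction feature, a `coherent` flag
#' additionally marks the fraction of elements (the configured motion
#' coherence) moving in their assigned direction; the rest move randomly.
#'
#' @param trial one row of a `maat_design` (or `NULL` for a generic trial).
#' @param config a [stimulus_config()].
#' @param n_frames number of frames (defaults to 3 s at the configured
#'   frame rate).
#' @param seed integer seed.
#' @return list with one `n_frames x n_elements` 0/1 matrix per feature
#'   (1 = dominant option) and a `coherent` matrix for direction.
#' @export
generate_stimulus_evidence <- function(trial = NULL,
                                       config = stimulus_config(),
                                       n_frames = NULL, seed) {
  if (missing(seed)) stop("seed must be given")
  if (is.null(n_frames)) n_frames <- round(3 * config$frame_rate)
  set.seed(split_seed(seed, "evidence"))
  ne <- config$n_elements
  out <- lapply(MAAT_FEATURES, function(f) {
    matrix(rbinom(n_frames * ne, 1, config$evidence[[f]]),
           nrow = n_frames)
  })
  names(out) <- MAAT_FEATURES
  out$coherent <- matrix(rbinom(n_frames * ne, 1, config$coherence),
                         nrow = n_frames)
  out
}

## ---------------------------------------------------------------------
## Behavior

#' Simulate choices and response times for a session
#'
#' Resolves group- and load-dependent diffusion parameters from the
#' effect configuration and delegates trial generation to
#' [simulate_ddm_trials()]. Premature responses (< 250 ms) carry
#' `excluded = TRUE`.
#'
#' @param design a `maat_design`.
#' @param effects an [effect_config()].
#' @param group `"young"` or `"old"`.
#' @param subject subject identifier.
#' @param seed integer seed.
#' @return data.frame of behavioral trials: `subject`, `group`, `load`,
#'   `probe_feature`, `rt` (s), `correct` (0/1), `excluded`, aligned with
#'   the design rows.
#' @export
simulate_behavior <- function(design, effects = effect_config(), group,
                              subject = "s01", seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(inherits(design, "maat_design"))
  rt <- numeric(nrow(design)); correct <- integer(nrow(design))
  for (ld in sort(unique(design$load))) {
    idx <- which(design$load == ld)
    p <- group_ddm_params(effects, group, ld)
    tr <- simulate_ddm_trials(p, n = length(idx),
                              seed = split_seed(seed, paste0("beh", ld)))
    rt[idx] <- tr$rt; correct[idx] <- tr$correct
  }
  data.frame(subject = subject, group = group, load = design$load,
             probe_feature = design$probe_feature, rt = rt,
             correct = correct, excluded = rt < 0.25,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------
## EEG

default_montage <- function() {
  list(channels = c("Fz", "Cz", "CPz", "Pz", "POz", "Oz", "C3", "C4"),
       neighbors = list(
         Fz = c("Cz"), Cz = c("Fz", "CPz", "C3", "C4"),
         CPz = c("Cz", "Pz"), Pz = c("CPz", "POz"),
         POz = c("Pz", "Oz"), Oz = c("POz"),
         C3 = c("Cz"), C4 = c("Cz")),
       posterior = c("Pz", "POz", "Oz"),
       frontal = c("Fz", "Cz"),
       centroparietal = c("CPz", "Pz", "POz"),
       motor_left = "C3", motor_right = "C4")
}

colored_noise <- function(n, srate, exponent) {
  # Gaussian noise with PSD ~ f^(-exponent), unit variance
  nf <- n %/% 2
  f <- seq_len(nf) * srate / n
  amp <- f^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, if (n %% 2 == 0) Re(spec[nf]) else NULL,
            Conj(rev(spec[seq_len(nf - (n %% 2 == 0))])))
  x <- Re(fft(full[seq_len(n)], inverse = TRUE))
  as.numeric(scale(x))
}

#' Simulate epoched EEG-like signals with planted load effects
#'
#' Generates stimulus-locked and response-locked epochs containing
#' (i) an aperiodic 1/f background whose log-log slope shifts with load,
#' (ii) theta and alpha bursts whose amplitudes scale with load during
#' the stimulus period (theta on frontal, alpha on posterior channels),
#' (iii) a load-scaled high-frequency (> 85 Hz) broadband component
#' driving sample-entropy effects while leaving the 2-80 Hz aperiodic
#' fit range governed by the planted exponent,
#' (iv) a 30 Hz entrained component during the stimulus period,
#' and (v) a response-locked linear ramp on centro-parietal channels
#' whose slope scales with load, plus lateralized mu-beta attenuation
#' contralateral to the response hand.
#'
#' @param design a `maat_design`.
#' @param effects an [effect_config()].
#' @param group `"young"` or `"old"`.
#' @param channels,neighbors montage; defaults to a small 8-channel net.
#' @param srate sampling rate, >= 250 Hz.
#' @param seed integer seed.
#' @param rt optional per-trial response times (s, probe-locked) used to
#'   place response-locked components; defaults to 1 s.
#' @return list with elements `stim` and `resp` ([maat_epochs]) and
#'   `response_side` (per-trial `"left"`/`"right"`).
#' @export
simulate_eeg <- function(design, effects = effect_config(), group,
                         channels = NULL, neighbors = NULL, srate = 250,
                         seed, rt = NULL) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(srate >= 250)
  mont <- default_montage()
  if (is.null(channels)) {
    channels <- mont$channels; neighbors <- mont$neighbors
  } else {
    if (is.null(neighbors)) stop("neighbor structure required for custom montage")
    if (!all(names(neighbors) %in% channels))
      stop("channel/neighbor mismatch")
    if (length(channels) < 4) stop("need >= 4 channels")
  }
  set.seed(split_seed(seed, "eeg"))
  n_tr <- nrow(design)
  t_stim <- seq(-1.5, 4, by = 1 / srate)
  t_resp <- seq(-0.8, 0.2, by = 1 / srate)
  nc <- length(channels); ns <- length(t_stim); nr <- length(t_resp)
  stim <- array(0, dim = c(nc, ns, n_tr))
  resp <- array(0, dim = c(nc, nr, n_tr))
  side <- sample(c("left", "right"), n_tr, replace = TRUE)
  e <- effects$eeg
  post <- which(channels %in% mont$posterior)
  front <- which(channels %in% mont$frontal)
  cpar <- which(channels %in% mont$centroparietal)
  if (!length(post)) post <- seq_len(nc)
  if (!length(front)) front <- seq_len(nc)
  if (!length(cpar)) cpar <- seq_len(nc)
  stim_win <- t_stim >= 0 & t_stim <= 3
  ramp_on <- t_resp >= -0.5
  for (i in seq_len(n_tr)) {
    ld <- design$load[i]
    chi <- e$chi0 + e$chi_slope[[group]] * (ld - 1)
    bb_sd <- e$broadband_sd * (1 + e$entropy_slope[[group]] * (ld - 1))
    th_a <- e$theta_amp * (1 + e$theta_slope[[group]] * (ld - 1))
    al_a <- e$alpha_amp * (1 + e$alpha_slope[[group]] * (ld - 1))
    for (c in seq_len(nc)) {
      # entropy carrier band-limited above the 2-80 Hz aperiodic range
      bb <- fft_filter(rnorm(ns), srate, low = 85, order = 8)
      x <- e$noise_sd * colored_noise(ns, srate, chi) +
        bb_sd * bb / sd(bb)
      if (c %in% front) {
        x[stim_win] <- x[stim_win] +
          th_a * sin(2 * pi * 5 * t_stim[stim_win] + runif(1, 0, 2 * pi))
      }
      if (c %in% post) {
        x[stim_win] <- x[stim_win] +
          al_a * sin(2 * pi * 10 * t_stim[stim_win] + runif(1, 0, 2 * pi))
        x[stim_win] <- x[stim_win] +
          e$ssvep_amp * sin(2 * pi * 30 * t_stim[stim_win])
      }
      stim[c, , i] <- x
    }
    # response-locked epochs: fresh background + CPP ramp + mu-beta
    k <- e$cpp_k[[group]] * (1 + e$cpp_slope[[group]] * (ld - 1))
    contra <- if (side[i] == "left") mont$motor_right else mont$motor_left
    ipsi <- if (side[i] == "left") mont$motor_left else mont$motor_right
    ci <- which(channels == contra); ii <- which(channels == ipsi)
    for (c in seq_len(nc)) {
      x <- e$noise_sd * colored_noise(nr, srate, e$chi0) / 2
      if (c %in% cpar) x[ramp_on] <- x[ramp_on] + k * (t_resp[ramp_on] + 0.5)
      amp <- e$mubeta_amp
      if (length(ci) && c == ci) {
        # contralateral desynchronization ramping down toward response
        amp <- e$mubeta_amp * pmax(0.2, 1 + 0.8 * t_resp / 0.8)
      }
      if (c %in% c(ci, ii)) {
        x <- x + amp * sin(2 * pi * 20 * t_resp + runif(1, 0, 2 * pi))
      }
      resp[c, , i] <- x
    }
  }
  info <- data.frame(load = design$load, response_side = side)
  list(stim = maat_epochs(stim, srate, t_stim, "stimulus", channels,
                          neighbors, info),
       resp = maat_epochs(resp, srate, t_resp, "response", channels,
                          neighbors, info),
       response_side = side)
}

## ---------------------------------------------------------------------
## Pupil

#' Simulate pupil-diameter traces with blinks
#'
#' Each trial's trace (stimulus-locked, -3.5 s to +4 s, i.e. 1 s past
#' stimulus offset) contains a stimulus-locked constriction lobe, a
#' dilation component whose rate of change scales with load, slow
#' drift plus measurement noise, and Poisson-placed blink dropouts
#' recorded in an annotation table.
#'
#' @param design a `maat_design`.
#' @param effects an [effect_config()].
#' @param group `"young"` or `"old"`.
#' @param srate sampling rate, >= 100 Hz (default 1000 Hz).
#' @param seed integer seed.
#' @return a `maat_pupil` list: `diameter` (trial x time matrix), `time`,
#'   `srate`, `blinks` (data.frame trial/start/end in s), `gaze_y`
#'   (vertical gaze channel, trial x time), `load` per trial.
#' @export
simulate_pupil <- function(design, effects = effect_config(), group,
                           srate = 1000, seed) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(srate >= 100)
  set.seed(split_seed(seed, "pupil"))
  p <- effects$pupil
  tt <- seq(-3.5, 4, by = 1 / srate)
  n <- length(tt); n_tr <- nrow(design)
  d <- matrix(0, n_tr, n); gz <- matrix(0, n_tr, n)
  blinks <- list()
  dil_win <- tt >= 0.5 & tt <= 3
  for (i in seq_len(n_tr)) {
    ld <- design$load[i]
    g <- p$dilation_rate * (1 + p$dilation_slope[[group]] * (ld - 1))
    x <- 5 + cumsum(rnorm(n, 0, p$noise_sd / sqrt(srate)))  # slow drift
    x <- x - p$constriction * exp(-((tt - 0.4)^2) / (2 * 0.15^2))
    ramp <- numeric(n)
    ramp[dil_win] <- g * (tt[dil_win] - 0.5)
    ramp[tt > 3] <- g * 2.5 * exp(-(tt[tt > 3] - 3) / 0.8)
    x <- x + ramp + rnorm(n, 0, p$noise_sd)
    gz[i, ] <- cumsum(rnorm(n, 0, 1 / sqrt(srate)))
    if (p$blink_rate > 0) {
      nb <- rbinom(1, 1e3, min(1, p$blink_rate * diff(range(tt)) / 1e3))
      if (nb > 0) {
        st <- sort(runif(nb, min(tt), max(tt) - 0.3))
        en <- st + runif(nb, 0.1, 0.3)
        for (b in seq_len(nb)) {
          seg <- tt >= st[b] & tt <= en[b]
          x[seg] <- 0
          gz[i, seg] <- gz[i, seg] + 50  # eyelid sweep artifact
        }
        blinks[[length(blinks) + 1L]] <-
          data.frame(trial = i, start = st, end = en)
      }
    }
    d[i, ] <- x
  }
  blinks <- if (length(blinks)) do.call(rbind, blinks) else
    data.frame(trial = integer(), start = numeric(), end = numeric())
  structure(list(diameter = d, gaze_y = gz, time = tt, srate = srate,
                 blinks = blinks, load = design$load,
                 alignment = "stimulus"),
            class = "maat_pupil")
}

## ---------------------------------------------------------------------
## BOLD

#' Simulate trial-wise voxel patterns and condition beta maps
#'
#' Two planted structures: (a) for decoding, disjoint voxel subsets carry
#' each feature's dominant-option information during the stimulus
#' volumes, with signal-to-noise that depends on cue status and load;
#' (b) for brain-behavior linking, a rank-1 latent pattern enters the
#' condition beta matrix scaled by a per-load loading and a per-subject
#' expression weight.
#'
#' @param design a `maat_design`.
#' @param effects an [effect_config()].
#' @param n_voxels number of voxels, >= 50.
#' @param seed integer seed.
#' @param subject_score scalar expression weight of the latent pattern
#'   for this subject (0 = average).
#' @param n_time volumes per trial (TR-spaced samples).
#' @return list: `patterns` (trial x voxel x time), `betas` (voxel x 4
#'   load conditions), `latent_pattern` (voxel vector), `feature_voxels`
#'   (named list of voxel indices), `time_volumes`, `design` echo.
#' @export
simulate_bold <- function(design, effects = effect_config(), n_voxels = 200,
                          seed, subject_score = 0, n_time = 12) {
  if (missing(seed)) stop("seed must be given")
  stopifnot(n_voxels >= 50)
  set.seed(split_seed(seed, "bold"))
  b <- effects$bold
  n_tr <- nrow(design)
  pat <- array(rnorm(n_tr * n_voxels * n_time, 0, b$noise_sd),
               dim = c(n_tr, n_voxels, n_time))
  per <- max(10L, floor(n_voxels / 8))
  fvox <- lapply(seq_along(MAAT_FEATURES), function(k) {
    ((k - 1) * per + 1):(k * per)
  })
  names(fvox) <- MAAT_FEATURES
  fpat <- lapply(MAAT_FEATURES, function(f) rnorm(per))
  names(fpat) <- MAAT_FEATURES
  stim_vols <- 4:9
  for (i in seq_len(n_tr)) {
    ld <- design$load[i]
    cue <- strsplit(design$cue_set[i], "+", fixed = TRUE)[[1]]
    for (f in MAAT_FEATURES) {
      cued <- f %in% cue
      snr <- if (cued) {
        b$feature_snr_cued * (1 + b$cued_load_slope * (ld - 1))
      } else {
        b$feature_snr_uncued * (1 + b$uncued_load_slope * (ld - 1))
      }
      snr <- max(snr, 0)
      cls <- if (design[[paste0("dom_", f)]][i] == "A") 1 else -1
      pat[i, fvox[[f]], stim_vols] <-
        pat[i, fvox[[f]], stim_vols] + cls * snr * fpat[[f]]
    }
  }
  latent <- rnorm(n_voxels)
  betas <- sapply(1:4, function(ld) {
    latent * b$latent_loading[ld] * (1 + subject_score) +
      rnorm(n_voxels, 0, b$noise_sd)
  })
  colnames(betas) <- paste0("load", 1:4)
  list(patterns = pat, betas = betas, latent_pattern = latent,
       feature_voxels = fvox, feature_patterns = fpat,
       time_volumes = stim_vols, load = design$load)
}
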