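#' ODR trial timings
#'
#' Phase boundaries (ms) of a single 6 s oculomotor delayed-response trial:
#' fixation, brief cue, 2.5 s delay, and a response phase beginning at 4 s,
#' at which the corollary discharge drives MD/SC at 35 Hz for 500 ms. The cue
#' and fixation durations are model choices (the cue is only "briefly
#' flashed" in the task description); all boundaries are configurable.
#'
#' @param fixation_end,cue_end,delay_end,trial_end Phase boundaries in ms.
#' @param cd_onset,cd_duration Corollary-discharge window (ms).
#' @return Named list of timings, validated to be ordered and within the
#'   trial.
#' @export
odr_timings <- function(fixation_end = 1000, cue_end = 1500, delay_end = 4000,
                        trial_end = 6000, cd_onset = 4000, cd_duration = 500) {
  t <- list(fixation_end = fixation_end, cue_end = cue_end,
            delay_end = delay_end, trial_end = trial_end,
            cd_onset = cd_onset, cd_duration = cd_duration)
  if (!(0 < fixation_end && fixation_end <= cue_end && cue_end <= delay_end &&
        delay_end <= trial_end)) {
    stop("phase boundaries must be ordered within the trial")
  }
  if (cd_onset < 0 || cd_onset + cd_duration > trial_end) {
    stop("corollary-discharge window exceeds the trial")
  }
  t
}

timings_from_config <- function(config) {
  tm <- config$timings
  do.call(odr_timings, tm[c("fixation_end", "cue_end", "delay_end",
                            "trial_end", "cd_onset", "cd_duration")])
}

#' Per-trial drive schedule
#'
#' Builds the per-millisecond Poisson drive rates for every generator group
#' over one trial: all four PC direction groups at the 5 Hz baseline, raised
#' to 35 Hz for the cued direction during the cue phase; the MD/SC drive at
#' its background rate except for the 35 Hz corollary discharge (500 ms from
#' response onset); the constant basal-ganglia pacemaker; and the constant
#' thalamic background drive.
#'
#' @param target Cued direction, integer in `0:3`.
#' @param timings An [odr_timings()] list.
#' @param rates Named list of drive rates in Hz (`pc_baseline`, `pc_cue`,
#'   `mdsc_baseline`, `mdsc_cd`, `pace`, `thal_drive`).
#' @return Object of class `"trial_schedule"`: a `rates` matrix (generator
#'   groups x trial ms) plus the target and timings.
#' @export
make_schedule <- function(target,
                          timings = odr_timings(),
                          rates = list(pc_baseline = 5, pc_cue = 35,
                                       mdsc_baseline = 2, mdsc_cd = 35,
                                       pace = 8, thal_drive = 10)) {
  stopifnot(length(target) == 1, target %in% 0:3)
  T <- timings$trial_end
  groups <- c(paste0("PC", 0:3), "MDSCgen", "PACEgen", "THALgen")
  m <- matrix(0, nrow = length(groups), ncol = T, dimnames = list(groups, NULL))
  m[paste0("PC", 0:3), ] <- rates$pc_baseline
  cue <- seq.int(timings$fixation_end + 1L, timings$cue_end)
  if (timings$cue_end > timings$fixation_end) {
    m[paste0("PC", target), cue] <- rates$pc_cue
  }
  m["MDSCgen", ] <- rates$mdsc_baseline
  if (timings$cd_duration > 0) {
    cd <- seq.int(timings$cd_onset + 1L, timings$cd_onset + timings$cd_duration)
    m["MDSCgen", cd] <- rates$mdsc_cd
  }
  m["PACEgen", ] <- rates$pace
  m["THALgen", ] <- rates$thal_drive
  structure(list(rates = m, target = as.integer(target), timings = timings),
            class = "trial_schedule")
}

#' Sample inhomogeneous Poisson spike trains
#'
#' Independent per-neuron Bernoulli thinning of a rate trace:
#' `P(spike in bin) = rate * dt`. Refuses bins coarse enough that this
#' probability would exceed 1.
#'
#' @param rate_hz Numeric rate trace (Hz), one value per time bin.
#' @param n_neurons Number of independent generator neurons.
#' @param dt Bin width in ms (default 1).
#' @param seed Integer seed.
#' @return data.frame with columns `neuron` and `time` (bin index, 1-based).
#' @export
sample_poisson_trains <- function(rate_hz, n_neurons, dt = 1, seed = 1) {
  stopifnot(all(rate_hz >= 0), n_neurons >= 1, dt > 0)
  p <- rate_hz * dt / 1000
  if (any(p > 1)) stop("rate * dt exceeds 1 per bin; use a finer dt")
  set.seed(seed)
  nb <- length(p)
  hit <- which(stats::runif(n_neurons * nb) < rep(p, each = n_neurons))
  data.frame(neuron = (hit - 1L) %% n_neurons + 1L,
             time = (hit - 1L) %/% n_neurons + 1L)
}

#' Plan a session of ODR trials
#'
#' Assigns targets to trials balanced across the four directions as evenly as
#' `n_trials` allows, shuffled under the seed with the constraint that the
#' target always changes between consecutive trials (the task varies the
#' target position in each trial; see the methods vignette for why this
#' matters for perseveration scoring).
#'
#' @param n_trials Number of trials (default 50).
#' @param seed Integer seed.
#' @return Object of class `"session_plan"`: list with `targets` (integer
#'   vector in `0:3`), `n_trials`, `seed`.
#' @export
make_session <- function(n_trials = 50, seed = 1) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  counts <- tabulate(rep(1:4, length.out = n_trials), 4)
  draw <- function() {
    left <- counts
    seqv <- integer(n_trials)
    prev <- 0L  # no previous target
    for (i in seq_len(n_trials)) {
      avail <- which(left > 0 & (seq_len(4) != prev | i == 1L))
      if (length(avail) == 0) return(NULL)  # dead end; restart
      # weight by remaining count so the most-owed direction cannot strand
      pick <- avail[sample.int(length(avail), 1, prob = left[avail])]
      seqv[i] <- pick
      left[pick] <- left[pick] - 1L
      prev <- pick
    }
    seqv
  }
  targets <- NULL
  while (is.null(targets)) targets <- draw()
  targets <- targets - 1L
  structure(list(targets = as.integer(targets), n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat("<session_plan>", x$n_trials, "trials, seed", x$seed, "\n")
  print(table(target = x$targets))
  invisible(x)
}
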