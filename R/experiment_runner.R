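#' @useDynLib pfcdopa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# assemble per-neuron parameter arrays for the engine
neuron_arrays <- function(net, mod) {
  pops <- net$pops
  npop <- pops[pops$role != "generator", ]
  n <- sum(npop$count)
  a <- numeric(n); b <- numeric(n); cc <- numeric(n); d <- numeric(n)
  gain <- rep(1.0, n)
  for (k in seq_len(nrow(npop))) {
    idx <- npop$start[k]:npop$end[k]
    p <- izhikevich_preset(npop$preset[k])
    a[idx] <- p$a; b[idx] <- p$b; cc[idx] <- p$c; d[idx] <- p$d
    # high-D1 gain applies to layer-2/3 excitatory PFC neurons only
    if (grepl("^L3e", npop$name[k])) gain[idx] <- mod$gains[["L23_exc"]]
  }
  list(a = a, b = b, c = cc, d = d, gain = gain, n = n)
}

# per-synapse effective weights: config weight / scale * modulation factor
effective_weights <- function(net, mod) {
  proj <- net$projections
  wcfg <- net$config$weights
  w_block <- vapply(seq_len(nrow(proj)), function(k) {
    base <- wcfg[[proj$wname[k]]]
    if (is.null(base)) stop("no weight named '", proj$wname[k], "' in config")
    (base / net$scale) * modulation_factor(mod, proj$modkey[k])
  }, numeric(1))
  w_block[net$syn$block]
}

# run the compiled engine over a prepared rate matrix
run_engine <- function(net, mod, rate_matrix, seed, init_state = NULL,
                       record_spikes = FALSE) {
  stopifnot(inherits(net, "odr_network"), !is.null(net$syn))
  arr <- neuron_arrays(net, mod)
  n <- arr$n
  if (is.null(init_state)) {
    init_state <- list(v = rep(-70, n), u = rep(-14, n),
                       g_ampa = numeric(n), g_nmda = numeric(n),
                       g_gabaa = numeric(n), g_gabab = numeric(n))
  }
  gpop <- net$pops[net$pops$role == "generator", ]
  gen_group <- rep(match(gpop$name, rownames(rate_matrix)) - 1L, gpop$count)
  if (any(is.na(gen_group))) stop("rate matrix is missing a generator group")
  pop_of_unit <- integer(net$n_units)
  for (k in seq_len(nrow(net$pops))) {
    pop_of_unit[net$pops$start[k]:net$pops$end[k]] <- k - 1L
  }
  use140 <- !isFALSE(net$config$use_140_constant)
  res <- engine_run(
    n_neurons = n,
    a = arr$a, b = arr$b, c = arr$c, d = arr$d,
    gain = arr$gain, I_ext = numeric(n),
    v0 = init_state$v, u0 = init_state$u,
    g0_ampa = init_state$g_ampa, g0_nmda = init_state$g_nmda,
    g0_gabaa = init_state$g_gabaa, g0_gabab = init_state$g_gabab,
    row_ptr = net$row_ptr, col_idx = net$syn$post - 1L,
    w = effective_weights(net, mod), chan = net$syn$chan,
    gen_group = gen_group, rates = rate_matrix, T = ncol(rate_matrix),
    pop_of_unit = pop_of_unit, n_pops = nrow(net$pops),
    seed = as.numeric(seed), record_spikes = record_spikes,
    use_140_constant = use140)
  rownames(res$pop_counts) <- net$pops$name
  res
}

#' Run one ODR session under a dopamine condition
#'
#' Executes `plan$n_trials` consecutive 6 s trials as one continuous
#' simulation — membrane and conductance state is never reset between trials,
#' so activity can carry across trial boundaries (the substrate for
#' perseveration). Each trial presents the cue for its planned target, drives
#' the corollary discharge at response onset, and reads out the saccade from
#' the motor layer.
#'
#' @param config Configuration list ([default_config()]).
#' @param cond A [dopamine_condition()].
#' @param plan A [make_session()] plan.
#' @param seed Integer seed controlling wiring, Poisson drives and the
#'   decision RNG; identical `(config, seed)` gives byte-identical output.
#' @param scale Network scale (default from config).
#' @param record_spikes Keep the per-neuron spike table (large; off by
#'   default — per-population 1 ms count traces are always kept unless
#'   `keep_counts = FALSE`).
#' @param keep_counts Keep the population count matrix (on by default; turned
#'   off in grid runs to bound memory).
#' @param net Optionally, a prebuilt [build_network()] to reuse.
#' @return Object of class `"odr_session"`: `behavior` (a
#'   [score_session()] result), `records`, `pop_counts` (population x ms
#'   spike counts), optional `spikes`, `condition`, `plan`, `seed`, `scale`,
#'   `timings`, `pops`, `config_hash`, `final_state`.
#' @export
run_session <- function(config = default_config(),
                        cond = dopamine_condition(),
                        plan = make_session(50, seed = seed),
                        seed = 1, scale = config$scale,
                        record_spikes = FALSE, keep_counts = TRUE,
                        net = NULL) {
  mod <- resolve_modulation(cond)
  if (is.null(net)) {
    net <- build_network(config, scale = scale, seed = seed)
  }
  timings <- timings_from_config(config)
  rates <- config$rates
  sched <- lapply(plan$targets, make_schedule, timings = timings, rates = rates)
  rate_matrix <- do.call(cbind, lapply(sched, function(s) s$rates))
  rownames(rate_matrix) <- rownames(sched[[1]]$rates)
  res <- run_engine(net, mod, rate_matrix, seed = seed,
                    record_spikes = record_spikes)
  trial_len <- timings$trial_end
  rule <- decision_rule(window_ms = config$timings$decision_window,
                        threshold_hz = config$timings$decision_threshold)
  mot_rows <- match(paste0("MOT", 0:3), net$pops$name)
  n_mot <- sum(net$pops$count[mot_rows])
  # decisions consume R's RNG sequentially; seed it after wiring for
  # reproducibility of the random-saccade fallback
  set.seed(seed + 1L)
  recs <- vector("list", plan$n_trials)
  for (tr in seq_len(plan$n_trials)) {
    # the 500 ms leading up to the response: the saccade is read out from
    # motor activity accumulated before the corollary discharge clears it
    w0 <- (tr - 1L) * trial_len + timings$cd_onset - rule$window_ms + 1L
    win <- w0:(w0 + rule$window_ms - 1L)
    counts <- rowSums(res$pop_counts[mot_rows, win, drop = FALSE])
    overall <- sum(counts) / (n_mot * rule$window_ms / 1000)
    dec <- decide(counts, overall, rule)
    recs[[tr]] <- data.frame(trial = tr, target = plan$targets[tr],
                             choice = dec$choice, basis = dec$basis,
                             overall_rate = overall,
                             stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  behavior <- score_session(records)
  out <- list(behavior = behavior, records = behavior$records,
              condition = cond, plan = plan, seed = seed, scale = net$scale,
              timings = timings, pops = net$pops,
              config_hash = config_hash(config))
  if (keep_counts) out$pop_counts <- res$pop_counts
  if (record_spikes) {
    pop_of_unit <- rep(net$pops$name, net$pops$count)
    out$spikes <- data.frame(unit = res$spike_unit,
                             population = pop_of_unit[res$spike_unit],
                             time = res$spike_time)
  }
  out$final_state <- res[c("v", "u", "g_ampa", "g_nmda", "g_gabaa", "g_gabab")]
  class(out) <- "odr_session"
  out
}

#' @export
print.odr_session <- function(x, ...) {
  cat("<odr_session>", format(x$condition), "| scale", x$scale,
      "| seed", x$seed, "\n")
  print(x$behavior)
  invisible(x)
}

#' Moving-average firing-rate trace of a population
#'
#' `rate(t)` = spike count of the population in a centred window divided by
#' `(window length x population size)`, in Hz.
#'
#' @param session An [run_session()] result with `pop_counts`, or a
#'   population-by-ms count matrix plus `pops`.
#' @param population Population name (e.g. `"L3e0"`).
#' @param window Window length in ms (default 100).
#' @return data.frame with `time` (ms) and `rate` (Hz).
#' @export
smooth_rate <- function(session, population, window = 100) {
  stopifnot(window > 0)
  counts <- session$pop_counts
  if (is.null(counts)) stop("session carries no population counts")
  if (!population %in% rownames(counts)) {
    stop("unknown population: ", population)
  }
  n <- session$pops[population, "count"]
  if (is.na(n) || n == 0) stop("empty population: ", population)
  x <- counts[population, ]
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm[is.na(sm)] <- 0
  data.frame(time = seq_along(x), rate = as.numeric(sm) * 1000 / n)
}

#' Run the 3x3 D1 x D2 behavioural grid
#'
#' Runs every dopamine condition for `repeats` sessions of `n_trials` trials.
#' Within a repeat, all nine conditions share the same session plan (target
#' sequence) and seed, so cells differ only in their modulation factors.
#'
#' @param config Configuration list.
#' @param repeats Sessions per cell (default 5).
#' @param base_seed First seed; repeat `r` uses `base_seed + r - 1`.
#' @param n_trials Trials per session (default 50).
#' @param scale Network scale.
#' @param conditions List of conditions (default all nine).
#' @param verbose Print progress.
#' @return Object of class `"grid_result"`: `cells` (one row per condition x
#'   repeat with the three percentages) and `summary` (per-condition means).
#' @export
run_grid <- function(config = default_config(), repeats = 5, base_seed = 1,
                     n_trials = 50, scale = config$scale,
                     conditions = all_conditions(), verbose = FALSE) {
  stopifnot(repeats >= 1)
  rows <- list()
  for (r in seq_len(repeats)) {
    seed <- base_seed + r - 1L
    plan <- make_session(n_trials, seed = seed)
    net <- build_network(config, scale = scale, seed = seed)
    for (cond in conditions) {
      s <- run_session(config, cond, plan, seed = seed, scale = scale,
                       keep_counts = FALSE, net = net)
      if (verbose) {
        message(sprintf("repeat %d %s: %.0f%% correct, %.0f%% persev, %.0f%% random",
                        r, format(cond), s$behavior$percent_correct,
                        s$behavior$percent_perseverative,
                        s$behavior$percent_random))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        d1 = cond$d1, d2 = cond$d2, repeat_ = r, seed = seed,
        percent_correct = s$behavior$percent_correct,
        percent_perseverative = s$behavior$percent_perseverative,
        percent_random = s$behavior$percent_random,
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  summ <- stats::aggregate(
    cells[c("percent_correct", "percent_perseverative", "percent_random")],
    by = cells[c("d1", "d2")], FUN = mean)
  structure(list(cells = cells, summary = summ, repeats = repeats,
                 n_trials = n_trials, scale = scale, base_seed = base_seed),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", x$repeats, "repeat(s) x", x$n_trials,
      "trials, scale", x$scale, "\n")
  s <- x$summary
  lv <- c("low", "optimal", "high")
  for (what in c("percent_correct", "percent_perseverative", "percent_random")) {
    cat(" ", what, "(rows: D2, cols: D1)\n")
    m <- matrix(NA_real_, 3, 3, dimnames = list(lv, lv))
    for (i in seq_len(nrow(s))) m[s$d2[i], s$d1[i]] <- s[[what]][i]
    print(round(m, 1))
  }
  invisible(x)
}

# mean rate (Hz) of a population over a time window of a count matrix
window_rate <- function(counts, pops, population, t0, t1) {
  n <- pops[population, "count"]
  sum(counts[population, (t0 + 1L):t1]) / (n * (t1 - t0) / 1000)
}

# one diagnostic trial; returns the population count matrix
probe_trial <- function(config, cond, target = 0, seed = 1,
                        scale = config$scale, cue = TRUE, net = NULL) {
  if (!cue) config$timings$cue_end <- config$timings$fixation_end
  s <- run_session(config, cond, plan = structure(
    list(targets = as.integer(target), n_trials = 1L, seed = seed),
    class = "session_plan"), seed = seed, scale = scale, net = net)
  s
}

#' Calibrate the column weights for bistability
#'
#' Staged tuning mirroring how the network is brought to its operating
#' point:
#'
#' 1. a single layer-2/3 column (lateral connections silenced) is made
#'    bistable — spontaneous rate below 5 Hz without a cue, persistent rate
#'    above 15 Hz through the 2.5 s delay after a cue — by bisecting the
#'    recurrent excitatory weight;
#' 2. with the four columns coupled, the lateral excitatory/inhibitory
#'    balance is adjusted so only the cued column persists;
#' 3. the corollary-discharge weight is adjusted so layer 5 is near-silent
#'    during the delay but fires during the response window;
#' 4. the update-loop (inhibitory pool) weight is raised until the cued
#'    column's activity is cleared to within twice its pre-cue baseline
#'    within 1 s of the response.
#'
#' Every probe is a single 6 s trial at the requested scale under the
#' optimal/optimal condition. If a stage exhausts its search range the best
#' candidate is kept and the failure is reported.
#'
#' @param config Starting configuration.
#' @param seed Integer seed for probe trials.
#' @param scale Network scale for probes (default 0.1).
#' @param max_iter Bisection iterations per stage.
#' @param verbose Print stage progress.
#' @return List with `config` (tuned weights substituted), `weights`, and
#'   `report` (data.frame: stage, pass, detail).
#' @export
calibrate_bistability <- function(config = default_config(), seed = 1,
                                  scale = 0.1, max_iter = 8, verbose = FALSE) {
  report <- list()
  note <- function(stage, pass, detail) {
    report[[length(report) + 1L]] <<- data.frame(stage = stage, pass = pass,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
    if (verbose) message(stage, ": ", detail, if (pass) " [ok]" else " [FAIL]")
  }
  tm <- timings_from_config(config)
  opt <- dopamine_condition("optimal", "optimal")

  # stage-1 probes run the column in true isolation: lateral coupling,
  # thalamic leak and the inhibitory pool are silenced, leaving only the
  # parietal baseline drive and the column's own recurrence
  stage1_stats <- function(cfg) {
    cfg$weights$l3_lat_ee <- 0
    cfg$weights$l3_lat_ei <- 0
    cfg$weights$thal_l3 <- 0
    cfg$weights$inhpool_l3 <- 0
    spont <- probe_trial(cfg, opt, seed = seed, scale = scale, cue = FALSE)
    pers <- probe_trial(cfg, opt, seed = seed, scale = scale, cue = TRUE)
    delay <- c(tm$cue_end, tm$delay_end)
    list(
      spont = window_rate(spont$pop_counts, spont$pops, "L3e0",
                          delay[1], delay[2]),
      late = window_rate(pers$pop_counts, pers$pops, "L3e0",
                         tm$delay_end - 500, tm$delay_end))
  }

  # stage 1: bisect recurrent excitation for single-column bistability
  # (spontaneous < 5 Hz without a cue, > 15 Hz through the delay after one).
  # The isolated operating point seeds the coupled retuning of stage 2; once
  # the columns are coupled, the whole set is retuned, so the final
  # recurrent weight is the coupled one.
  lo <- 0; hi <- config$weights$l3_ee * 2
  best <- NA_real_; ok1 <- FALSE; st <- list(spont = NA, late = NA)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cfg <- config; cfg$weights$l3_ee <- mid
    st <- stage1_stats(cfg)
    if (st$spont >= 5) {            # too excitable even at rest
      hi <- mid
    } else if (st$late <= 15) {     # persistence dies before delay end
      lo <- mid
    } else {
      best <- mid; ok1 <- TRUE
      break
    }
  }
  note("1: single-column bistability", ok1,
       sprintf("isolated l3_ee = %.4g; spontaneous %.1f Hz, late-delay %.1f Hz%s",
               if (ok1) best else (lo + hi) / 2, st$spont, st$late,
               if (ok1) "" else
                 " (no isolated band at this scale; best candidate kept, coupled retuning proceeds)"))
  if (ok1 && config$weights$l3_ee < best) config$weights$l3_ee <- best

  # stage 2: retune the coupled columns so only the cued one persists
  ok2 <- FALSE; cued <- NA; others <- NA
  for (it in seq_len(max_iter)) {
    pers <- probe_trial(config, opt, seed = seed, scale = scale)
    cued <- window_rate(pers$pop_counts, pers$pops, "L3e0",
                        tm$delay_end - 1000, tm$delay_end)
    others <- vapply(1:3, function(d)
      window_rate(pers$pop_counts, pers$pops, paste0("L3e", d),
                  tm$delay_end - 1000, tm$delay_end), numeric(1))
    if (cued > 15 && cued > 2 * max(others)) { ok2 <- TRUE; break }
    if (cued <= 15) {
      # coupled network needs stronger recurrence than the isolated column
      config$weights$l3_ee <- config$weights$l3_ee * 1.08
    } else {
      config$weights$l3_lat_ei <- config$weights$l3_lat_ei * 1.3
    }
  }
  note("2: coupled-column selectivity", ok2,
       sprintf("l3_ee = %.4g, l3_lat_ei = %.4g; cued %.1f Hz, max other %.1f Hz",
               config$weights$l3_ee, config$weights$l3_lat_ei,
               cued, max(others)))

  # stage 3: layer-5 response window (silent in delay, active at response)
  ok3 <- FALSE
  for (it in seq_len(max_iter)) {
    pers <- probe_trial(config, opt, seed = seed, scale = scale)
    l5_delay <- mean(vapply(0:3, function(d)
      window_rate(pers$pop_counts, pers$pops, paste0("L5e", d),
                  tm$cue_end, tm$delay_end), numeric(1)))
    l5_resp <- mean(vapply(0:3, function(d)
      window_rate(pers$pop_counts, pers$pops, paste0("L5e", d),
                  tm$cd_onset, tm$cd_onset + tm$cd_duration), numeric(1)))
    if (l5_delay < 5 && l5_resp > 15) { ok3 <- TRUE; break }
    if (l5_resp <= 15) config$weights$mdsc_l5 <- config$weights$mdsc_l5 * 1.4
    if (l5_delay >= 5) config$weights$mdscgen_mdsc <- config$weights$mdscgen_mdsc * 0.8
  }
  note("3: layer-5 response window", ok3,
       sprintf("mdsc_l5 = %.4g; delay %.1f Hz, response %.1f Hz",
               config$weights$mdsc_l5, l5_delay, l5_resp))

  # stage 4: update loop clears working memory within 1 s of the response
  ok4 <- FALSE
  for (it in seq_len(max_iter)) {
    pers <- probe_trial(config, opt, seed = seed, scale = scale)
    base <- window_rate(pers$pop_counts, pers$pops, "L3e0", 0, tm$fixation_end)
    post <- window_rate(pers$pop_counts, pers$pops, "L3e0",
                        tm$cd_onset + 1000, tm$trial_end)
    if (post <= 2 * max(base, 0.5)) { ok4 <- TRUE; break }
    config$weights$inhpool_l3 <- config$weights$inhpool_l3 * 1.4
  }
  note("4: working-memory clearing", ok4,
       sprintf("inhpool_l3 = %.4g; baseline %.1f Hz, post-response %.1f Hz",
               config$weights$inhpool_l3, base, post))

  list(config = config, weights = config$weights,
       report = do.call(rbind, report))
}
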