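test_that("smoothed rate traces follow their definition", {
  # single spike, one neuron, 100 ms window -> rectangular 10 Hz bump
  fake <- list(
    pop_counts = matrix(0L, 1, 1000, dimnames = list("X", NULL)),
    pops = data.frame(count = 1L, row.names = "X"))
  fake$pop_counts["X", 500] <- 1L
  r <- smooth_rate(fake, "X", window = 100)
  expect_equal(max(r$rate), 10)
  expect_equal(sum(r$rate > 0), 100L)
  # zero spikes -> identically zero
  fake$pop_counts["X", 500] <- 0L
  expect_true(all(smooth_rate(fake, "X")$rate == 0))
  expect_error(smooth_rate(fake, "Y"), "unknown population")
})

test_that("smoothed rate of a homogeneous Poisson population matches its rate", {
  set.seed(4)
  n <- 200; T <- 2000; hz <- 10
  counts <- matrix(as.integer(stats::rbinom(T, n, hz / 1000)), 1, T,
                   dimnames = list("P", NULL))
  fake <- list(pop_counts = counts,
               pops = data.frame(count = n, row.names = "P"))
  r <- smooth_rate(fake, "P", window = 100)
  got <- mean(r$rate[100:(T - 100)])
  se <- sqrt(hz * 1000 / (n * T)) # Poisson counting error on the mean
  expect_lt(abs(got - hz), 3 * se)
})

test_that("sessions are exactly reproducible under (config, seed)", {
  cfg <- tiny_config()
  plan <- make_session(2, seed = 3)
  a <- run_session(cfg, dopamine_condition(), plan, seed = 3)
  b <- run_session(cfg, dopamine_condition(), plan, seed = 3)
  expect_identical(a$records, b$records)
  expect_identical(a$pop_counts, b$pop_counts)
  expect_identical(a$config_hash, b$config_hash)
})

test_that("spike tables stay inside the session and populations label spikes", {
  cfg <- tiny_config()
  s <- run_session(cfg, dopamine_condition(), one_trial_plan(0), seed = 2,
                   record_spikes = TRUE)
  expect_true(all(s$spikes$time >= 1 & s$spikes$time <= 6000))
  expect_true(all(s$spikes$population %in% s$pops$name))
  expect_equal(sum(s$pop_counts), nrow(s$spikes))
})

test_that("a cue ignites selective persistence that outlives the stimulus", {
  cfg <- tiny_config()
  cued <- c(); others <- c()
  for (sd in 1:3) {
    s <- run_session(cfg, dopamine_condition("optimal", "optimal"),
                     one_trial_plan(1, seed = sd), seed = sd)
    tm <- s$timings
    cued <- c(cued, pop_rate(s, "L3e1", 3000, tm$delay_end))
    others <- c(others, vapply(c(0, 2, 3), function(d)
      pop_rate(s, paste0("L3e", d), 3000, tm$delay_end), numeric(1)))
  }
  expect_gt(mean(cued), 10)
  expect_gt(mean(cued), 2 * max(mean(others), 0.5))
})

test_that("a zeroed recurrent weight fails bistability calibration stage 1", {
  cfg <- tiny_config()
  cfg$weights$l3_ee <- 0
  out <- calibrate_bistability(cfg, seed = 1, scale = 0.1, max_iter = 2)
  st1 <- out$report[out$report$stage == "1: single-column bistability", ]
  expect_false(st1$pass)
})

test_that("the tuned network is bistable in the cue on/off sense", {
  # spontaneous (no-cue) delay activity is low; a cue drives the same column
  # to a persistent rate more than three times higher
  cfg <- tiny_config()
  opt <- dopamine_condition("optimal", "optimal")
  cfg_nocue <- cfg
  cfg_nocue$timings$cue_end <- cfg_nocue$timings$fixation_end
  spont <- c(); pers <- c()
  for (sd in 1:3) {
    sp <- run_session(cfg_nocue, opt, one_trial_plan(0, sd), seed = sd)
    pc <- run_session(cfg, opt, one_trial_plan(0, sd), seed = sd)
    tm <- pc$timings
    spont <- c(spont, pop_rate(sp, "L3e0", 3000, tm$delay_end))
    pers <- c(pers, pop_rate(pc, "L3e0", 3000, tm$delay_end))
  }
  expect_lt(mean(spont), 5)
  expect_gt(mean(pers), 15)
  expect_gt(mean(pers) / max(mean(spont), 0.5), 3)
})

test_that("coupled-column calibration stages pass on the tuned defaults", {
  out <- calibrate_bistability(tiny_config(), seed = 1, scale = 0.1,
                               max_iter = 4)
  rep <- out$report
  expect_equal(nrow(rep), 4L)
  expect_true(rep$pass[rep$stage == "2: coupled-column selectivity"])
  expect_true(rep$pass[rep$stage == "4: working-memory clearing"])
})

test_that("grid runs cover all nine cells with valid percentages", {
  cfg <- tiny_config()
  g <- run_grid(cfg, repeats = 1, base_seed = 1, n_trials = 2)
  expect_equal(nrow(g$summary), 9L)
  for (col in c("percent_correct", "percent_perseverative", "percent_random")) {
    expect_true(all(g$cells[[col]] >= 0 & g$cells[[col]] <= 100))
  }
})
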