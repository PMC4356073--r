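# Small-scale fixtures shared across test files. Everything is generated in
# code; nothing is read from disk except the shipped default configuration.

tiny_config <- function() {
  cfg <- default_config()
  cfg$scale <- 0.1
  cfg
}

one_trial_plan <- function(target = 0L, seed = 1L) {
  structure(list(targets = as.integer(target), n_trials = 1L,
                 seed = as.integer(seed)),
            class = "session_plan")
}

# mean rate (Hz) of a population over (t0, t1] ms from a session
pop_rate <- function(session, population, t0, t1) {
  n <- session$pops[population, "count"]
  sum(session$pop_counts[population, (t0 + 1L):t1]) / (n * (t1 - t0) / 1000)
}

# random small network expressed directly in engine arrays, for
# reference-vs-engine equivalence checks (no generator units)
random_micro_net <- function(n = 10, n_syn = 40, seed = 99) {
  set.seed(seed)
  pre <- sample.int(n, n_syn, replace = TRUE)
  post <- sample.int(n, n_syn, replace = TRUE)
  keep <- pre != post
  pre <- pre[keep]; post <- post[keep]
  ord <- order(pre)
  list(
    n = n,
    pre = pre[ord], post = post[ord],
    w = runif(sum(keep), 0.05, 0.3),
    chan = sample(0:1, sum(keep), replace = TRUE),
    I_ext = runif(n, 2, 7),
    a = rep(c(0.01, 0.1), length.out = n),
    b = rep(0.2, n), c = rep(-65, n),
    d = rep(c(8, 2), length.out = n),
    v0 = runif(n, -75, -60), u0 = runif(n, -16, -12))
}

run_micro_engine <- function(net, T, gain = rep(1, net$n)) {
  pfcdopa:::engine_run(
    n_neurons = net$n, a = net$a, b = net$b, c = net$c, d = net$d,
    gain = gain, I_ext = net$I_ext, v0 = net$v0, u0 = net$u0,
    g0_ampa = numeric(net$n), g0_nmda = numeric(net$n),
    g0_gabaa = numeric(net$n), g0_gabab = numeric(net$n),
    row_ptr = c(0L, cumsum(tabulate(net$pre, net$n))),
    col_idx = net$post - 1L, w = net$w, chan = as.integer(net$chan),
    gen_group = integer(0), rates = matrix(0, 0, T), T = as.integer(T),
    pop_of_unit = rep(0L, net$n), n_pops = 1L, seed = 1,
    record_spikes = TRUE, use_140_constant = TRUE)
}
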