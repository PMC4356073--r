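#' Reference network simulator (pure R)
#'
#' Slow, transparent re-implementation of the engine loop used to validate
#' the compiled engine: exact-exponential conductance decay, synaptic current
#' per [synaptic_current()], neuron update per [step_neurons()], 1 ms
#' transmission delay (arrivals from spikes at `t` take effect at `t + 1`).
#' Supports only deterministic runs (constant external current, no Poisson
#' generator units), which is all that is needed for bit-level comparison.
#'
#' @param params List with per-neuron vectors `a`, `b`, `c`, `d`.
#' @param gain Per-neuron current gain.
#' @param I_ext Per-neuron constant external current.
#' @param v0,u0 Initial state vectors.
#' @param pre,post 1-based synapse endpoint vectors.
#' @param w Per-synapse weights.
#' @param chan Per-synapse channel class (0 = AMPA+NMDA, 1 = GABAA+GABAB).
#' @param T Number of 1 ms steps.
#' @param use_140_constant See [step_neurons()].
#' @return List with `pop_counts` substitute `spikes` (data.frame `unit`,
#'   `time`), final `v`, `u` and the four conductance vectors.
#' @export
simulate_reference <- function(params, gain, I_ext, v0, u0,
                               pre, post, w, chan, T,
                               use_140_constant = TRUE) {
  n <- length(v0)
  v <- v0; u <- u0
  g <- conductance_state(n)
  incA <- numeric(n); incN <- numeric(n); incGA <- numeric(n); incGB <- numeric(n)
  dec <- exp(-1 / synapse_tau())
  sp_unit <- integer(0); sp_time <- integer(0)
  for (t in seq_len(T)) {
    g$g_ampa <- g$g_ampa * dec[["ampa"]] + incA
    g$g_nmda <- g$g_nmda * dec[["nmda"]] + incN
    g$g_gabaa <- g$g_gabaa * dec[["gaba_a"]] + incGA
    g$g_gabab <- g$g_gabab * dec[["gaba_b"]] + incGB
    incA[] <- 0; incN[] <- 0; incGA[] <- 0; incGB[] <- 0
    I <- I_ext + synaptic_current(v, g)
    st <- step_neurons(list(v = v, u = u), params, I, gain = gain, dt = 1,
                       use_140_constant = use_140_constant)
    v <- st$state$v; u <- st$state$u
    fired <- which(st$spiked)
    if (length(fired) > 0) {
      sp_unit <- c(sp_unit, fired)
      sp_time <- c(sp_time, rep(t, length(fired)))
      hit <- pre %in% fired
      if (any(hit)) {
        exc <- hit & chan == 0L
        inh <- hit & chan == 1L
        if (any(exc)) {
          addA <- tapply(w[exc], post[exc], sum)
          ids <- as.integer(names(addA))
          incA[ids] <- incA[ids] + as.numeric(addA)
          incN[ids] <- incN[ids] + as.numeric(addA)
        }
        if (any(inh)) {
          addG <- tapply(w[inh], post[inh], sum)
          ids <- as.integer(names(addG))
          incGA[ids] <- incGA[ids] + as.numeric(addG)
          incGB[ids] <- incGB[ids] + as.numeric(addG)
        }
      }
    }
  }
  list(spikes = data.frame(unit = sp_unit, time = sp_time),
       v = v, u = u, g = g)
}
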