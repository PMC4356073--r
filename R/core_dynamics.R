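#' Izhikevich parameter presets
#'
#' Two-variable quadratic spiking neuron parameters `(a, b, c, d)`:
#' `a` sets the recovery time scale, `b` the recovery sensitivity to the
#' membrane potential, `c` the post-spike reset potential (mV) and `d` the
#' post-spike recovery increment. Excitatory cortical neurons use the
#' regular-spiking (RS) preset `(0.01, 0.2, -65, 8)`; inhibitory interneurons
#' use the fast-spiking (FS) preset `(0.1, 0.2, -65, 2)`.
#'
#' @param preset `"RS"` (regular spiking) or `"FS"` (fast spiking).
#' @return A list with numeric scalars `a`, `b`, `c`, `d` and class
#'   `"izhikevich_params"`.
#' @examples
#' izhikevich_preset("RS")
#' @export
izhikevich_preset <- function(preset = c("RS", "FS")) {
  preset <- match.arg(preset)
  p <- switch(preset,
    RS = list(a = 0.01, b = 0.2, c = -65.0, d = 8.0),
    FS = list(a = 0.1,  b = 0.2, c = -65.0, d = 2.0))
  p$preset <- preset
  class(p) <- "izhikevich_params"
  p
}

#' Synaptic channel time constants (ms)
#'
#' Exponential decay constants for the four conductance channels, in the order
#' AMPA, NMDA, GABA_A, GABA_B.
#' @return Named numeric vector of length 4 (ms).
#' @export
synapse_tau <- function() {
  c(ampa = 5, nmda = 100, gaba_a = 6, gaba_b = 150)
}

#' Per-neuron conductance state
#'
#' @param n Number of neurons.
#' @return A list of four numeric vectors (`g_ampa`, `g_nmda`, `g_gabaa`,
#'   `g_gabab`), all zero, with class `"conductance_state"`.
#' @export
conductance_state <- function(n = 1) {
  z <- numeric(n)
  structure(list(g_ampa = z, g_nmda = z, g_gabaa = z, g_gabab = z),
            class = "conductance_state")
}

check_conductances <- function(g) {
  stopifnot(inherits(g, "conductance_state"))
  for (nm in names(g)) {
    if (any(!is.finite(g[[nm]])) || any(g[[nm]] < 0)) {
      stop("invalid conductance state: '", nm, "' must be finite and >= 0")
    }
  }
  invisible(g)
}

#' NMDA voltage gate
#'
#' Sigmoidal magnesium-block gate `((v + 80)/60)^2 / (1 + ((v + 80)/60)^2)`;
#' zero at -80 mV and approaching 1 with depolarisation.
#'
#' @param v Membrane potential (mV), vectorised.
#' @return Gate value in `[0, 1)`.
#' @export
nmda_gate <- function(v) {
  x2 <- ((v + 80) / 60)^2
  x2 / (1 + x2)
}

#' Net synaptic current
#'
#' Total injected current from the four conductance channels at membrane
#' potential `v`:
#' `I = -(g_ampa (v - 0) + g_nmda gate(v) (v - 0) + g_gabaa (v + 70) + g_gabab (v + 90))`.
#' The leading sign is chosen so that excitatory conductances depolarise below
#' their 0 mV reversal and GABAergic conductances hyperpolarise above their
#' -70 / -90 mV reversals.
#'
#' @param v Membrane potential (mV), length n.
#' @param g A [conductance_state] with vectors of length n.
#' @return Numeric current vector (model units).
#' @examples
#' g <- conductance_state(1)
#' g$g_nmda <- 2
#' synaptic_current(-20, g)  # gate = 1/2, depolarising current +20
#' @export
synaptic_current <- function(v, g) {
  if (any(!is.finite(v))) stop("invalid state: non-finite membrane potential")
  check_conductances(g)
  -(g$g_ampa * v + g$g_nmda * nmda_gate(v) * v +
      g$g_gabaa * (v + 70) + g$g_gabab * (v + 90))
}

#' Exponential conductance decay
#'
#' Advances each channel by its first-order decay `g <- g * exp(-dt / tau)`
#' with `tau = (5, 100, 6, 150)` ms for (AMPA, NMDA, GABA_A, GABA_B). The
#' exact exponential factor is used (not a forward-Euler approximation), both
#' here and in the compiled engine.
#'
#' @param g A [conductance_state].
#' @param dt Time step (ms), > 0.
#' @return The decayed `conductance_state`.
#' @export
decay_conductances <- function(g, dt) {
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  check_conductances(g)
  tau <- synapse_tau()
  g$g_ampa  <- g$g_ampa  * exp(-dt / tau[["ampa"]])
  g$g_nmda  <- g$g_nmda  * exp(-dt / tau[["nmda"]])
  g$g_gabaa <- g$g_gabaa * exp(-dt / tau[["gaba_a"]])
  g$g_gabab <- g$g_gabab * exp(-dt / tau[["gaba_b"]])
  g
}

#' Deliver presynaptic spikes to conductances
#'
#' Each arrival increments the named channel by `weight * mu`, where `mu` is
#' the dopaminergic modulation factor attached to the connection. An
#' excitatory presynaptic spike is represented by two arrivals (AMPA and
#' NMDA); an inhibitory spike by GABA_A and GABA_B arrivals.
#'
#' @param g A [conductance_state].
#' @param arrivals A data.frame with columns `weight` (>= 0), `channel` (one
#'   of `"ampa"`, `"nmda"`, `"gaba_a"`, `"gaba_b"`), `mu` (> 0) and optionally
#'   `neuron` (index into `g`, default 1).
#' @return The updated `conductance_state`.
#' @export
deliver_spikes <- function(g, arrivals) {
  check_conductances(g)
  if (is.null(arrivals) || nrow(arrivals) == 0) return(g)
  stopifnot(all(c("weight", "channel", "mu") %in% names(arrivals)))
  if (any(arrivals$weight < 0)) stop("synaptic weights must be >= 0")
  if (any(arrivals$mu <= 0)) stop("modulation factors must be > 0")
  idx <- if ("neuron" %in% names(arrivals)) arrivals$neuron else rep(1L, nrow(arrivals))
  slot <- c(ampa = "g_ampa", nmda = "g_nmda",
            gaba_a = "g_gabaa", gaba_b = "g_gabab")[as.character(arrivals$channel)]
  if (any(is.na(slot))) {
    stop("unknown conductance channel: ",
         paste(unique(arrivals$channel[is.na(slot)]), collapse = ", "))
  }
  for (k in seq_len(nrow(arrivals))) {
    g[[slot[k]]][idx[k]] <- g[[slot[k]]][idx[k]] + arrivals$weight[k] * arrivals$mu[k]
  }
  g
}

#' Advance a homogeneous Izhikevich population one time step
#'
#' Reference (pure-R) integrator for the membrane equations
#' `v' = 0.04 v^2 + 5 v + 140 - u + I * mu` and `u' = a (b v - u)` with the
#' hard reset `v >= 30 mV -> v = c, u = u + d`. The algorithm matches the
#' compiled engine exactly: neurons at or above threshold at step entry spike
#' and reset without integrating; otherwise `v` is advanced with two 0.5 ms
#' substeps (clipped at 30 mV) and `u` with one full-`dt` step. The input
#' current is held fixed across the substeps.
#'
#' @param state List with numeric vectors `v` and `u`.
#' @param params An [izhikevich_preset] (or list with `a`, `b`, `c`, `d`),
#'   recycled over the population.
#' @param I Input current vector (before the neuromodulatory gain).
#' @param gain Multiplicative current gain `mu_DA,grp` (default 1).
#' @param dt Time step in ms; must be <= 1 for stability.
#' @param use_140_constant Include the `+140` constant of the canonical
#'   quadratic nullcline (default `TRUE`; without it the model has no resting
#'   state near -65 mV).
#' @return List with `state` (updated `v`, `u`) and logical `spiked` mask.
#' @examples
#' p <- izhikevich_preset("RS")
#' step_neurons(list(v = -70, u = -14), p, I = 0)  # resting fixed point
#' @export
step_neurons <- function(state, params, I, gain = 1, dt = 1,
                         use_140_constant = TRUE) {
  stopifnot(dt > 0, dt <= 1)
  v <- state$v; u <- state$u
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    stop("invalid state: non-finite membrane state")
  }
  n <- length(v)
  I <- rep_len(I, n) * rep_len(gain, n)
  k140 <- if (use_140_constant) 140 else 0
  spiked <- v >= 30
  v[spiked] <- rep_len(params$c, n)[spiked]
  u[spiked] <- u[spiked] + rep_len(params$d, n)[spiked]
  live <- !spiked
  if (any(live)) {
    vv <- v[live]; uu <- u[live]; Il <- I[live]
    clipped <- rep(FALSE, length(vv))
    for (s in 1:2) {
      adv <- !clipped
      vv[adv] <- vv[adv] +
        (dt / 2) * (0.04 * vv[adv]^2 + 5 * vv[adv] + k140 - uu[adv] + Il[adv])
      hit <- vv >= 30
      vv[hit] <- 30
      clipped <- clipped | hit
      # floor at the GABA_B reversal; below -90 mV driving forces flip sign
      vv[vv < -90 & !clipped] <- -90
    }
    uu <- uu + rep_len(params$a, n)[live] * (rep_len(params$b, n)[live] * vv - uu)
    v[live] <- vv; u[live] <- uu
    if (any(!is.finite(vv))) {
      stop("integration diverged at dt = ", dt, " ms")
    }
  }
  list(state = list(v = v, u = u), spiked = spiked)
}
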