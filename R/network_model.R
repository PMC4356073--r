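#' Default network configuration
#'
#' Reads the configuration shipped with the package
#' (`inst/extdata/odr_network.yaml`): population counts, connection
#' probabilities, calibrated synaptic weights, modulation keys, drive rates
#' and trial timings. All weights were produced by the staged calibration
#' procedure (see [calibrate_bistability()]); the fixed quantities of the
#' model (population counts, the 0.1 default connection probability, task
#' drive rates and phase durations) are part of the circuit definition and
#' are not calibration targets.
#'
#' @param path Optional path to an alternative YAML file.
#' @return Nested configuration list.
#' @export
default_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "odr_network.yaml", package = "pfcdopa")
  }
  cfg <- yaml::read_yaml(path)
  cfg
}

#' Hash a configuration
#'
#' FNV-1a hash over the serialised configuration; changes iff any
#' configuration value changes.
#' @param config Configuration list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  fnv1a_hex(serialize(config, NULL, version = 2))
}

# population table at a given scale. Counts at scale 1 are the reference
# area sizes of the circuit (L2/3: 2585 exc + 729 inh and L5: 606 exc + 133
# inh per column; 1000 for each subcortical / input / motor area); sizes the
# reference leaves open (inhibitory pool, thalamic gate, MOT interneurons,
# BG split) come from the config.
population_table <- function(config, scale = 1.0) {
  stopifnot(scale > 0, scale <= 1)
  pc <- config$populations
  rows <- list()
  add <- function(name, role, preset, count, column = NA_integer_,
                  direction = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, role = role, preset = preset, count1 = count,
      column = column, direction = direction, stringsAsFactors = FALSE)
  }
  for (d in 0:3) {
    add(paste0("L3e", d), "excitatory", "RS", pc$L3_exc, d, d)
    add(paste0("L3i", d), "inhibitory", "FS", pc$L3_inh, d, d)
    add(paste0("L5e", d), "excitatory", "RS", pc$L5_exc, d, d)
    add(paste0("L5i", d), "inhibitory", "FS", pc$L5_inh, d, d)
  }
  add("MDSC", "excitatory", "RS", pc$MDSC)
  add("VTA", "excitatory", "RS", pc$VTA)
  add("BGrelay", "inhibitory", "FS", pc$BG_relay)
  add("BGtonic", "inhibitory", "FS", pc$BG_tonic)
  add("INHpool", "inhibitory", "FS", pc$INH_pool)
  add("THAL", "excitatory", "RS", pc$THAL)
  for (d in 0:3) add(paste0("MOT", d), "excitatory", "RS", pc$MOT, NA, d)
  add("MOTi", "inhibitory", "FS", pc$MOT_inh)
  for (d in 0:3) add(paste0("PC", d), "generator", "none", pc$PC, NA, d)
  add("MDSCgen", "generator", "none", pc$MDSC_gen)
  add("PACEgen", "generator", "none", pc$PACE_gen)
  add("THALgen", "generator", "none", pc$THAL_gen)
  pops <- do.call(rbind, rows)
  pops$count <- round(scale * pops$count1)
  if (any(pops$count < 10)) {
    bad <- pops$name[pops$count < 10]
    stop("scale ", scale, " produces fewer than 10 neurons in group(s): ",
         paste(bad, collapse = ", "))
  }
  # neurons first, generators after; global unit id ranges
  pops <- pops[order(pops$role == "generator"), ]
  pops$end <- cumsum(pops$count)
  pops$start <- pops$end - pops$count + 1L
  rownames(pops) <- pops$name
  pops
}

# declarative projection list: src, dst, probability, weight name, modulation
# key. Within-column L3 <-> L5 connections are absent by construction.
projection_table <- function(config) {
  pr <- config$probabilities
  p0 <- pr$default
  rows <- list()
  add <- function(src, dst, p, wname, modkey = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0(src, "->", dst), src = src, dst = dst, p = p,
      wname = wname, modkey = modkey, stringsAsFactors = FALSE)
  }
  for (d in 0:3) {
    l3e <- paste0("L3e", d); l3i <- paste0("L3i", d)
    l5e <- paste0("L5e", d); l5i <- paste0("L5i", d)
    add(paste0("PC", d), l3e, p0, "pc_l3")
    # within-column recurrent blocks (never scaled by the D1-low factor)
    add(l3e, l3e, pr$ee, "l3_ee")
    add(l3e, l3i, pr$ei, "l3_ei")
    add(l3i, l3e, pr$ie, "l3_ie")
    add(l3i, l3i, pr$ii, "l3_ii")
    add(l5e, l5e, pr$ee, "l5_ee")
    add(l5e, l5i, pr$ei, "l5_ei")
    add(l5i, l5e, pr$ie, "l5_ie")
    add(l5i, l5i, pr$ii, "l5_ii")
    # lateral (between-column, non-preferred) pathways
    for (d2 in setdiff(0:3, d)) {
      add(l3e, paste0("L3e", d2), p0, "l3_lat_ee", "lateral_L3_nonpreferred")
      add(l3e, paste0("L3i", d2), p0, "l3_lat_ei")
    }
    add(l3e, paste0("MOT", d), p0, "l3_mot")
    add(paste0("MOT", d), "MOTi", p0, "mot_moti")
    add("MOTi", paste0("MOT", d), p0, "moti_mot")
    add("MDSC", l5e, p0, "mdsc_l5", "sc_to_L5")
    add(l5e, "INHpool", p0, "l5_inhpool")
    add("INHpool", l3e, p0, "inhpool_l3")
    add(l5e, "BGrelay", p0, "l5_bgrelay")
    add("THAL", l3e, p0, "thal_l3")
  }
  add("MDSCgen", "MDSC", p0, "mdscgen_mdsc")
  add("BGrelay", "BGtonic", p0, "bgrelay_bgtonic")
  add("PACEgen", "BGtonic", p0, "pace_bgtonic")
  add("BGtonic", "THAL", p0, "bgtonic_thal")
  add("THALgen", "THAL", p0, "thalgen_thal")
  proj <- do.call(rbind, rows)
  if (!is.null(config$extra_projections)) {
    for (x in config$extra_projections) {
      proj <- rbind(proj, data.frame(
        name = paste0(x$src, "->", x$dst), src = x$src, dst = x$dst,
        p = x$p, wname = x$wname, modkey = if (is.null(x$modkey)) "" else x$modkey,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(config$drop_projections)) {
    proj <- proj[!(proj$name %in% config$drop_projections), ]
  }
  rownames(proj) <- NULL
  proj
}

#' Build the four-column working-memory network
#'
#' Realises the full architecture from the declarative configuration: four
#' two-layer cortical columns (layer 2/3 and layer 5, each with excitatory RS
#' and inhibitory FS neurons), topographic parietal (PC) input per column,
#' motor output (MOT) groups with a shared interneuron pool for
#' winner-take-all competition, MD/SC corollary-discharge relay to layer 5 of
#' all columns, an inhibitory pool that clears layer-2/3 activity, and a
#' basal-ganglia/thalamic gate (tonically active inhibitory group suppressed
#' by an L5-driven striatal relay) providing non-specific excitation back to
#' all columns. There are no connections between layer 3 and layer 5 within a
#' column; unless specified otherwise, inter-group connection probability is
#' 0.1.
#'
#' Wiring is Bernoulli per candidate pair (no self-synapses) and is exactly
#' reproducible from `seed`. When scaling down, per-synapse weights are
#' multiplied by `1/scale` so the mean total synaptic drive per neuron — and
#' with it the bistable operating point — is approximately preserved.
#'
#' @param config Configuration list, see [default_config()].
#' @param scale Fraction of the full population sizes to instantiate
#'   (`0 < scale <= 1`); counts are rounded and any group that would fall
#'   below 10 neurons is refused.
#' @param seed Integer RNG seed for the wiring.
#' @param wire If `FALSE`, only populations are instantiated (no synapses);
#'   used to inspect counts at scales where full wiring would be very large.
#' @return An object of class `"odr_network"` with elements `pops`
#'   (population table with unit-id ranges), `projections` (realised block
#'   table with synapse counts), `syn` (pre/post/block/chan arrays sorted for
#'   the engine), `row_ptr`, `gen_groups`, `scale`, `seed`, `config`.
#' @export
build_network <- function(config = default_config(), scale = config$scale,
                          seed = config$seed, wire = TRUE) {
  stopifnot(scale > 0, scale <= 1)
  pops <- population_table(config, scale)
  proj <- projection_table(config)
  unknown <- setdiff(unique(c(proj$src, proj$dst)), pops$name)
  if (length(unknown) > 0) {
    stop("unknown population name in projection config: ",
         paste(unknown, collapse = ", "))
  }
  n_units <- sum(pops$count)
  n_neurons <- sum(pops$count[pops$role != "generator"])
  net <- list(pops = pops, projections = proj, scale = scale, seed = seed,
              config = config, n_units = n_units, n_neurons = n_neurons)
  net$gen_groups <- pops$name[pops$role == "generator"]
  class(net) <- "odr_network"
  if (!wire) return(net)

  set.seed(seed)
  pre_l <- vector("list", nrow(proj)); post_l <- pre_l
  n_syn <- integer(nrow(proj))
  for (k in seq_len(nrow(proj))) {
    s <- pops[proj$src[k], ]; t <- pops[proj$dst[k], ]
    m <- s$count; n <- t$count
    if (proj$p[k] <= 0) next
    hit <- which(stats::runif(m * n) < proj$p[k])
    if (length(hit) == 0) next
    pre <- s$start + (hit - 1L) %% m
    post <- t$start + (hit - 1L) %/% m
    if (identical(s$name, t$name)) {
      keep <- pre != post
      pre <- pre[keep]; post <- post[keep]
    }
    pre_l[[k]] <- pre; post_l[[k]] <- post
    n_syn[k] <- length(pre)
  }
  proj$n_syn <- n_syn
  pre <- unlist(pre_l, use.names = FALSE)
  post <- unlist(post_l, use.names = FALSE)
  block <- rep(seq_len(nrow(proj)), n_syn)
  ord <- order(pre)
  src_role <- pops[proj$src, "role"]
  chan_of_block <- ifelse(src_role == "inhibitory", 1L, 0L)
  net$projections <- proj
  net$syn <- list(pre = pre[ord], post = post[ord], block = block[ord],
                  chan = chan_of_block[block[ord]])
  net$row_ptr <- c(0L, cumsum(tabulate(net$syn$pre, n_units)))
  net
}

#' @export
print.odr_network <- function(x, ...) {
  cat("<odr_network> scale", x$scale, "seed", x$seed, "\n")
  cat(" ", x$n_neurons, "neurons +", x$n_units - x$n_neurons,
      "Poisson generator units in", nrow(x$pops), "groups\n")
  if (!is.null(x$syn)) cat(" ", length(x$syn$pre), "synapses in",
                           sum(x$projections$n_syn > 0), "blocks\n")
  invisible(x)
}

#' Validate the realised architecture
#'
#' Machine-readable check that every pathway of the circuit diagram exists,
#' that no forbidden pathway exists (layer 3 <-> layer 5 within a column),
#' and that excitatory sources target only AMPA/NMDA channels while
#' inhibitory sources target only GABA channels.
#'
#' @param net A wired [build_network()] result.
#' @return data.frame with columns `rule`, `pass`, `detail`.
#' @export
validate_architecture <- function(net) {
  stopifnot(inherits(net, "odr_network"))
  if (is.null(net$syn)) stop("network was built with wire = FALSE")
  proj <- net$projections
  out <- list()
  note <- function(rule, pass, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(rule = rule, pass = pass,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  required <- c(
    sprintf("PC%d->L3e%d", 0:3, 0:3),
    sprintf("L3e%d->L3e%d", 0:3, 0:3),
    sprintf("L3e%d->MOT%d", 0:3, 0:3),
    sprintf("MDSC->L5e%d", 0:3),
    sprintf("L5e%d->INHpool", 0:3),
    sprintf("INHpool->L3e%d", 0:3),
    sprintf("L5e%d->BGrelay", 0:3),
    sprintf("THAL->L3e%d", 0:3),
    sprintf("MOT%d->MOTi", 0:3),
    sprintf("MOTi->MOT%d", 0:3),
    "MDSCgen->MDSC", "BGrelay->BGtonic", "PACEgen->BGtonic",
    "BGtonic->THAL", "THALgen->THAL",
    as.vector(outer(0:3, 0:3, function(a, b)
      ifelse(a == b, NA, sprintf("L3e%d->L3e%d", a, b)))))
  required <- required[!is.na(required)]
  for (r in required) {
    ok <- r %in% proj$name && proj$n_syn[match(r, proj$name)] > 0
    note(paste0("edge present: ", r), ok,
         if (ok) "" else "missing or empty projection")
  }
  # forbidden within-column L3 <-> L5 pathways
  forbidden <- FALSE; bad <- character()
  for (d in 0:3) {
    l3 <- paste0(c("L3e", "L3i"), d); l5 <- paste0(c("L5e", "L5i"), d)
    hits <- proj$name[(proj$src %in% l3 & proj$dst %in% l5) |
                        (proj$src %in% l5 & proj$dst %in% l3)]
    hits <- hits[proj$n_syn[match(hits, proj$name)] > 0]
    if (length(hits) > 0) { forbidden <- TRUE; bad <- c(bad, hits) }
  }
  note("no within-column L3<->L5 pathway", !forbidden,
       paste(bad, collapse = ", "))
  # channel consistency
  src_role <- net$pops[proj$src, "role"]
  want <- ifelse(src_role == "inhibitory", 1L, 0L)
  blk_chan <- tapply(net$syn$chan, net$syn$block, function(x) unique(x)[1])
  mismatch <- names(blk_chan)[blk_chan != want[as.integer(names(blk_chan))]]
  note("excitatory sources -> AMPA/NMDA, inhibitory -> GABA",
       length(mismatch) == 0, paste(mismatch, collapse = ", "))
  # no self-synapses
  note("no self-synapses", !any(net$syn$pre == net$syn$post))
  do.call(rbind, out)
}
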