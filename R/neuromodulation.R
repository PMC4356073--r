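#' Dopamine receptor stimulation condition
#'
#' A condition is the pair of D1 and D2 receptor stimulation levels, each one
#' of `"low"`, `"optimal"`, `"high"` — the nine cells of the behavioural grid.
#'
#' @param d1,d2 Stimulation level strings.
#' @return List with `d1` and `d2`, class `"dopamine_condition"`.
#' @examples
#' dopamine_condition("low", "high")
#' @export
dopamine_condition <- function(d1 = c("optimal", "low", "high"),
                               d2 = c("optimal", "low", "high")) {
  levels <- c("low", "optimal", "high")
  if (!(is.character(d1) && length(d1) %in% c(1L, 3L) && d1[1] %in% levels)) {
    stop("invalid D1 level: must be one of low/optimal/high")
  }
  if (!(is.character(d2) && length(d2) %in% c(1L, 3L) && d2[1] %in% levels)) {
    stop("invalid D2 level: must be one of low/optimal/high")
  }
  structure(list(d1 = d1[1], d2 = d2[1]), class = "dopamine_condition")
}

#' @export
format.dopamine_condition <- function(x, ...) {
  sprintf("D1 %s / D2 %s", x$d1, x$d2)
}

#' @export
print.dopamine_condition <- function(x, ...) {
  cat("<dopamine_condition>", format(x), "\n")
  invisible(x)
}

#' All nine D1 x D2 conditions
#'
#' @return List of nine [dopamine_condition] objects, D2 varying slowest, in
#'   low/optimal/high order.
#' @export
all_conditions <- function() {
  lv <- c("low", "optimal", "high")
  out <- list()
  for (d2 in lv) for (d1 in lv) out[[length(out) + 1L]] <- dopamine_condition(d1, d2)
  out
}

#' Resolve a dopamine condition to modulation factors
#'
#' Maps the condition to every multiplicative factor the engine consumes:
#'
#' * `lateral_L3_nonpreferred` — the factor on AMPA and NMDA conductance
#'   increments of between-column (non-preferred -> preferred) layer-2/3
#'   excitatory connections: 1.4 when D1 is low (lateral excitation is
#'   released), 1.0 otherwise.
#' * `sc_to_L5` — the factor on AMPA and NMDA increments of the MD/SC -> layer-5
#'   corollary-discharge projection: 0.6 / 1.0 / 1.8 for low / optimal / high D2.
#' * current gain `L23_exc` — the multiplicative gain on the total input
#'   current of layer-2/3 excitatory neurons: 0.8 when D1 is high (all inputs
#'   weakened), 1.0 otherwise.
#'
#' Every factor not named here is exactly 1; GABA conductances are never
#' modulated.
#'
#' @param cond A [dopamine_condition].
#' @return List with named numeric vectors `factors` (connection keys) and
#'   `gains` (group keys), class `"modulation_table"`.
#' @examples
#' resolve_modulation(dopamine_condition("low", "high"))
#' @export
resolve_modulation <- function(cond) {
  if (!inherits(cond, "dopamine_condition")) {
    cond <- do.call(dopamine_condition, as.list(cond))
  }
  factors <- c(
    lateral_L3_nonpreferred = if (cond$d1 == "low") 1.4 else 1.0,
    sc_to_L5 = switch(cond$d2, low = 0.6, optimal = 1.0, high = 1.8))
  gains <- c(L23_exc = if (cond$d1 == "high") 0.8 else 1.0)
  structure(list(condition = cond, factors = factors, gains = gains),
            class = "modulation_table")
}

#' @export
print.modulation_table <- function(x, ...) {
  cat("<modulation_table>", format(x$condition), "\n")
  cat("  conductance factors:\n")
  for (nm in names(x$factors)) cat(sprintf("    %-24s %.2f\n", nm, x$factors[[nm]]))
  cat("  current gains:\n")
  for (nm in names(x$gains)) cat(sprintf("    %-24s %.2f\n", nm, x$gains[[nm]]))
  invisible(x)
}

# factor for a projection's modulation key ("" or NA means unmodulated)
modulation_factor <- function(table, key) {
  if (is.null(key) || is.na(key) || !nzchar(key)) return(1.0)
  if (key %in% names(table$factors)) return(unname(table$factors[[key]]))
  1.0
}
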