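# Small internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed from a master seed
#'
#' Child seeds are keyed by a stage label so that adding a pipeline stage
#' never perturbs the random draws of earlier stages. The result is always a
#' valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 69069 + h * 1000003) %% 2147483647L)
}

# stop() with a consistent prefix for user-facing domain errors
abort_domain <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

# unique per-trial grouping key; subblock may be NA (first design)
trial_key <- function(events) {
  sub <- events$subblock
  sub[is.na(sub)] <- 0L
  factor(paste(events$participant, events$block, sub, events$trial_index,
               sep = "\r"))
}
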