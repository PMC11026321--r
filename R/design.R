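#' Trial specifications for the first (number-line 1-9) design
#'
#' Per participant: 8 blocks, each containing every combination of target
#' number (1, 2, 3, 4, 6, 7, 8, 9), vertical start position (-0.4, 0, +0.4),
#' and horizontal start side (left, right) exactly once, in an independently
#' randomised order per block.
#'
#' @param n_participants number of participants.
#' @param seed integer seed controlling the trial-order shuffles.
#' @return A data frame of trial specs, one row per trial, with columns
#'   `participant`, `experiment`, `block`, `subblock`, `trial_index`,
#'   `target_number`, `start_vertical`, `start_side`, `condition`,
#'   `eccentricity_condition`.
#' @export
generate_exp1_design <- function(n_participants, seed = 1L) {
  stopifnot(n_participants >= 1)
  cell <- expand.grid(
    target_number = c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L),
    start_vertical = c(-0.4, 0, 0.4),
    start_side = c("left", "right"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_participants), function(p) {
      blocks <- lapply(1:8, function(b) {
        sh <- cell[sample.int(nrow(cell)), , drop = FALSE]
        data.frame(
          participant = p, experiment = "exp1", block = b,
          subblock = NA_integer_, trial_index = seq_len(nrow(sh)),
          sh, condition = "none", eccentricity_condition = "none",
          row.names = NULL, stringsAsFactors = FALSE
        )
      })
      do.call(rbind, blocks)
    })
    do.call(rbind, out)
  })
}

# target sets per inducer-eccentricity block type; 13 and 17 are the test
# targets common to all block types
exp2_block_targets <- function() {
  list(
    low = c(13L, 14L, 16L, 17L),
    medium = c(12L, 13L, 17L, 18L),
    high = c(10L, 13L, 17L, 20L)
  )
}

#' Trial specifications for the second (inducer-eccentricity) design
#'
#' Per participant: the three inducer-eccentricity block types (low, medium,
#' high) in random order; each block has 3 subblocks of 32 trials in which
#' every combination of the block's four target numbers and the start side
#' appears exactly four times, shuffled. Targets 13 and 17 are test trials
#' in every block type; the remaining targets are inducers.
#'
#' @inheritParams generate_exp1_design
#' @return A data frame of trial specs (same columns as
#'   [generate_exp1_design()]).
#' @export
generate_exp2_design <- function(n_participants, seed = 1L) {
  stopifnot(n_participants >= 1)
  tgt <- exp2_block_targets()
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_participants), function(p) {
      order_types <- sample(names(tgt))
      blocks <- lapply(seq_along(order_types), function(b) {
        type <- order_types[b]
        cell <- expand.grid(
          target_number = tgt[[type]],
          start_side = c("left", "right"),
          rep = 1:4,
          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
        )
        subs <- lapply(1:3, function(s) {
          sh <- cell[sample.int(nrow(cell)), c("target_number", "start_side")]
          data.frame(
            participant = p, experiment = "exp2", block = b, subblock = s,
            trial_index = seq_len(nrow(sh)), sh,
            start_vertical = 0,
            condition = ifelse(sh$target_number %in% c(13L, 17L),
                               "test", "inducer"),
            eccentricity_condition = type,
            row.names = NULL, stringsAsFactors = FALSE
          )
        })
        do.call(rbind, subs)
      })
      do.call(rbind, blocks)
    })
    res <- do.call(rbind, out)
    res[, c("participant", "experiment", "block", "subblock", "trial_index",
            "target_number", "start_vertical", "start_side", "condition",
            "eccentricity_condition")]
  })
}
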