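# The virtual clock: each cycling cell carries a phase, an elapsed time
# within the phase and a sampled phase duration. When elapsed time reaches
# the duration the clock parks at the boundary checkpoint (or, after M2,
# at the division point) until the checkpoint releases it.

# next phase in the cycle (G1 -> S -> G2 -> M1 -> M2); M2 exit is division
.next_phase <- function(phase) phase + 1L

#' Advance virtual clocks by one step
#'
#' Elapsed time within the current phase grows by `dt_h` for every cell
#' that is cycling (not G0, not reproductively dead, not arrested) and
#' clips at the phase duration, where the clock parks at the next
#' checkpoint or at the division point.
#'
#' @param elapsed,duration Numeric vectors (hours).
#' @param active Logical vector: cell is cycling this step.
#' @param dt_h Step length in hours.
#' @return Updated `elapsed` vector.
#' @export
advance_clock <- function(elapsed, duration, active, dt_h) {
  elapsed[active] <- pmin(elapsed[active] + dt_h, duration[active])
  elapsed
}

#' Checkpoint decision
#'
#' A clock parked at a checkpoint halts (cell-cycle arrest) while the DSB
#' count is at or above the checkpoint's threshold and is released as soon
#' as repair brings the count below it; the decision is re-evaluated every
#' step.
#'
#' @param Z DSB counts.
#' @param threshold Per-cell checkpoint thresholds.
#' @return Logical vector: `TRUE` = arrest, `FALSE` = progress.
#' @export
checkpoint_decision <- function(Z, threshold) Z >= threshold

#' Death-state classification from the DSB count
#'
#' Proliferating cells whose DSB count exceeds the interphase-death
#' threshold transit to pre-interphase death (`pID`); those exceeding only
#' the reproductive-death threshold transit to pre-reproductive death
#' (`pRD`). Both transitions are irreversible and are evaluated at every
#' step.
#'
#' @param Z DSB counts.
#' @param prd_threshold,pid_threshold Per-cell thresholds.
#' @return Integer vector: 0 no transition, 1 to `pRD`, 2 to `pID`.
#' @export
classify_death <- function(Z, prd_threshold, pid_threshold) {
  out <- integer(length(Z))
  out[Z > prd_threshold] <- 1L
  out[Z > pid_threshold] <- 2L
  out
}

#' Draw the residual division count of a pre-reproductive-death cell
#'
#' @param n Number of draws.
#' @return Integer vector, uniform on `{1, 2, 3}`.
#' @export
sample_divisions_remaining <- function(n) {
  sample.int(3L, n, replace = TRUE)
}

# checkpoint index for a phase whose duration has elapsed:
# G1 -> G1/S (1), S -> S/G2 (2), G2 -> G2/M1 (3), M1 -> M1/M2 (4),
# M2 -> division point (5)
.checkpoint_of_phase <- function(phase) phase

# per-cell arrest threshold for the checkpoint at the end of `phase`
.arrest_threshold_at <- function(world, idx, phase) {
  thr <- numeric(length(idx))
  thr[phase == PHASES[["G1"]]] <- world$thr_g1s[idx[phase == PHASES[["G1"]]]]
  thr[phase == PHASES[["S"]]]  <- world$thr_sg2[idx[phase == PHASES[["S"]]]]
  thr[phase == PHASES[["G2"]]] <- world$thr_g2m1[idx[phase == PHASES[["G2"]]]]
  thr[phase == PHASES[["M1"]]] <- world$thr_m1m2[idx[phase == PHASES[["M1"]]]]
  thr[phase == PHASES[["M2"]]] <- Inf   # division point has no DSB gate
  thr
}
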