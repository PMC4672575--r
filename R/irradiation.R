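#' Define an irradiation plan
#'
#' Radiation is delivered as discrete track traversals: each track deposits
#' a fixed elementary dose `d1track_gy` and tracks arrive in every masked
#' site as a Poisson process with rate `tracks_per_min`. The product
#' `d1track_gy * tracks_per_min` is the nominal dose rate (Gy/min); the
#' exposure lasts exactly `target_dose / dose_rate` minutes, after which
#' the per-step dose is identically zero.
#'
#' @param dose_gy Target (expected) dose in Gy.
#' @param d1track_gy Dose deposited by one track traversal (Gy).
#' @param tracks_per_min Mean track arrivals per site per minute.
#' @param mask Logical matrix of irradiated sites.
#' @param start_time_s Exposure start time (s).
#' @return An object of class `irradiation_plan`.
#' @examples
#' pl <- irradiation_plan(5, mask = matrix(TRUE, 1, 1))
#' exposure_window(pl)  # 5 Gy at 1 Gy/min: 300 s
#' @export
irradiation_plan <- function(dose_gy, d1track_gy = 1e-3,
                             tracks_per_min = 1000,
                             mask, start_time_s = 0) {
  stopifnot(dose_gy >= 0, d1track_gy >= 0, tracks_per_min >= 0,
            is.matrix(mask), is.logical(mask))
  rate <- d1track_gy * tracks_per_min   # Gy/min
  if (dose_gy > 0 && rate == 0)
    stop("nonzero dose with zero dose rate")
  structure(list(dose_gy = dose_gy, d1track_gy = d1track_gy,
                 tracks_per_min = tracks_per_min,
                 dose_rate_gy_min = rate, mask = mask,
                 start_time_s = start_time_s),
            class = "irradiation_plan")
}

#' Exposure window of an irradiation plan
#'
#' @param plan An [irradiation_plan()].
#' @return Numeric `c(start, end)` in seconds; an empty (zero-length)
#'   window for zero dose.
#' @export
exposure_window <- function(plan) {
  if (plan$dose_gy == 0)
    return(c(plan$start_time_s, plan$start_time_s))
  dur_s <- plan$dose_gy / plan$dose_rate_gy_min * 60
  c(plan$start_time_s, plan$start_time_s + dur_s)
}

#' Sample the dose delivered during one time step
#'
#' For every masked site the number of track traversals in `[t, t + dt)`
#' is drawn from a Poisson distribution with mean
#' `tracks_per_min * overlap / 60`, where `overlap` is the intersection of
#' the step with the exposure window, and converted to dose by the
#' per-track dose. Sites outside the mask, and all sites outside the
#' window, receive exactly zero.
#'
#' @param plan An [irradiation_plan()].
#' @param t Current time (s).
#' @param dt Step length (s), `> 0`.
#' @return A numeric matrix of per-site step doses (Gy), or `NULL` when
#'   the step does not intersect the exposure window (identically zero).
#' @export
sample_step_dose <- function(plan, t, dt) {
  if (dt <= 0) stop("dt must be > 0")
  win <- exposure_window(plan)
  overlap <- min(win[2L], t + dt) - max(win[1L], t)
  if (overlap <= 0) return(NULL)
  idx <- which(plan$mask)
  dose <- matrix(0, nrow(plan$mask), ncol(plan$mask))
  if (length(idx)) {
    lam <- plan$tracks_per_min * overlap / 60
    dose[idx] <- plan$d1track_gy * stats::rpois(length(idx), lam)
  }
  dose
}
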