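#' Poisson means for DSB induction in one step
#'
#' Four independent DSB sources act on every cell each step: direct
#' radiation (`lambda_zr * step_dose`), the medium-mediated signal
#' (`lambda_zm * M * dt`), the gap-junctional signal
#' (`lambda_zg * G * dt`) and endogenous background. Background follows
#' the per-step reading of the model (`lambda_zb` per step) by default;
#' `background_mode = "per_second"` rescales it by `dt`.
#'
#' All arguments are vectorised over cells.
#'
#' @param step_dose Dose received this step (Gy).
#' @param M,G Signal concentrations at the cell (units).
#' @param lambda_zr,lambda_zm,lambda_zg,lambda_zb Per-cell induction
#'   coefficients.
#' @param dt Time step (s).
#' @param background_mode `"per_step"` (default) or `"per_second"`.
#' @return List of numeric vectors `radiation`, `mdp`, `gjp`,
#'   `background`.
#' @export
induction_means <- function(step_dose, M, G, lambda_zr, lambda_zm,
                            lambda_zg, lambda_zb, dt,
                            background_mode = c("per_step", "per_second")) {
  background_mode <- match.arg(background_mode)
  stopifnot(all(step_dose >= 0), all(M >= 0), all(G >= 0), dt > 0)
  list(radiation = lambda_zr * step_dose,
       mdp = lambda_zm * M * dt,
       gjp = lambda_zg * G * dt,
       background = if (background_mode == "per_step") lambda_zb + 0 * M
                    else lambda_zb * dt + 0 * M)
}

#' Draw DSB induction counts
#'
#' @param means List of Poisson means as returned by [induction_means()].
#' @return List of integer vectors of the same shape.
#' @export
sample_induction <- function(means) {
  lapply(means, function(m) stats::rpois(length(m), m))
}

#' Number of DSBs repaired in one step
#'
#' Every DSB present at the previous step is repaired independently with
#' the cell's repair probability, i.e. the repaired count is binomial in
#' `Z_prev`. `method = "per_dsb"` realises this literally as one uniform
#' draw per DSB (the flowchart formulation); `"binomial"` draws the
#' equivalent binomial count directly. Both give the same distribution.
#'
#' @param Z_prev Integer vector of DSB counts before this step.
#' @param repair_lambda Per-DSB repair probability in `[0, 1]` (vector
#'   recycled over cells).
#' @param method `"binomial"` (default) or `"per_dsb"`.
#' @return Integer vector of repaired counts, elementwise `<= Z_prev`.
#' @export
repair_step <- function(Z_prev, repair_lambda,
                        method = c("binomial", "per_dsb")) {
  method <- match.arg(method)
  if (any(repair_lambda < 0) || any(repair_lambda > 1))
    stop("repair probability outside [0, 1]")
  if (method == "binomial")
    return(stats::rbinom(length(Z_prev), Z_prev, repair_lambda))
  lam <- rep_len(repair_lambda, length(Z_prev))
  vapply(seq_along(Z_prev), function(i) {
    z <- Z_prev[i]
    if (z == 0L) 0L else sum(stats::runif(z) < lam[i])
  }, integer(1L))
}

#' Update the DSB ledger for one step
#'
#' `Z(t + dt) = Z(t) + induced - repaired`. Repair is a thinning of the
#' previous step's DSBs, so the count can never go negative; a negative
#' result indicates inconsistent inputs and is an error.
#'
#' @param Z Integer vector of current DSB counts.
#' @param induced List of induction counts (as from [sample_induction()])
#'   or a single numeric vector of totals.
#' @param repaired Integer vector of repaired counts.
#' @return Updated integer vector.
#' @export
update_dsbs <- function(Z, induced, repaired) {
  tot <- if (is.list(induced)) Reduce(`+`, induced) else induced
  out <- Z + tot - repaired
  if (any(out < 0)) stop("DSB count went negative: repair exceeded ledger")
  out
}
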