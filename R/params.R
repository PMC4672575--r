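#' Cell-cycle phase labels
#'
#' Integer phase codes used throughout the simulator. `G0` is the quiescent
#' phase (indefinite duration); the cycling phases are `G1`, `S`, `G2`, `M1`
#' and `M2`, with checkpoints at the G1/S, S/G2, G2/M1 and M1/M2 boundaries
#' and the division point at the end of M2.
#'
#' @format Named integer vector mapping phase label to internal code.
#' @export
PHASES <- c(G0 = 0L, G1 = 1L, S = 2L, G2 = 3L, M1 = 4L, M2 = 5L)

#' Life-state labels
#'
#' `PR` proliferating, `pRD` pre-reproductive death (1-3 divisions left),
#' `RD` reproductive death (alive, clock permanently stopped), `pID`
#' pre-interphase death (removed within one division).
#'
#' @format Named integer vector mapping state label to internal code.
#' @export
LIFE_STATES <- c(PR = 1L, pRD = 2L, RD = 3L, pID = 4L)

#' Specification of a truncated-normal parameter distribution
#'
#' Individual-cell parameters are drawn from the part of a normal
#' distribution exceeding a lower bound (by default 0, i.e. the positive
#' part), realised by rejection sampling.
#'
#' @param av Mean of the underlying normal.
#' @param sd Standard deviation of the underlying normal (`>= 0`).
#' @param min Lower truncation bound; draws must strictly exceed it.
#' @param units Free-text unit annotation.
#' @return An object of class `param_spec`.
#' @examples
#' sp <- param_spec(40, 22)
#' mean(sample_truncated_normal(1e4, sp)) # close to the truncated mean
#' @export
param_spec <- function(av, sd, min = 0, units = "") {
  stopifnot(is.numeric(av), is.numeric(sd), is.numeric(min), sd >= 0)
  if (sd == 0 && av <= min)
    stop("degenerate spec (sd = 0) requires av > min")
  structure(list(av = av, sd = sd, min = min, units = units),
            class = "param_spec")
}

#' @export
print.param_spec <- function(x, ...) {
  cat(sprintf("truncated normal: av %g, sd %g, > %g %s\n",
              x$av, x$sd, x$min, x$units))
  invisible(x)
}

#' Sample from a truncated normal by rejection
#'
#' Draws `n` values from `N(av, sd)` conditioned on exceeding `min`:
#' values at or below the bound are simply regenerated until all draws
#' pass. With `sd = 0` the degenerate value `av` is returned.
#'
#' @param n Number of draws.
#' @param spec A [param_spec()], or a list with `av`, `sd`, `min` fields.
#' @return Numeric vector of length `n`, all values `> spec$min`.
#' @export
sample_truncated_normal <- function(n, spec) {
  if (n == 0L) return(numeric(0))
  av <- spec$av; s <- spec$sd; lo <- if (is.null(spec$min)) 0 else spec$min
  if (s == 0) {
    if (av <= lo) stop("degenerate spec never exceeds its minimum")
    return(rep.int(av, n))
  }
  out <- stats::rnorm(n, av, s)
  bad <- which(out <= lo)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), av, s)
    bad <- bad[out[bad] <= lo]
  }
  out
}

#' Load the default parameter catalogue
#'
#' Reads the packaged catalogue of model parameters: time step, grid
#' spacing, irradiation constants, signal diffusion/production/decay
#' constants for the medium-mediated (MDP) and gap-junctional (GJP)
#' pathways, and the phase-dependent truncated-normal distributions for
#' DSB induction, repair, death thresholds, checkpoint thresholds and
#' phase periods. Any field may be overridden by assigning into the
#' returned list before passing it to [sim_config()].
#'
#' @param path Optional path to an alternative YAML catalogue.
#' @return A nested list (class `param_catalogue`).
#' @export
default_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "bystandr", mustWork = TRUE)
  cat <- yaml::read_yaml(path)
  class(cat) <- "param_catalogue"
  cat
}

# Fields of the per-cell parameter set that are phase-grouped.
.CELL_FIELDS <- c("zr_lambda", "zm_lambda", "zg_lambda", "zb_lambda",
                  "repair_lambda", "prd_threshold", "pid_threshold")

# Group key of a phase-grouped field for a given phase code.
.field_group <- function(catalogue, field, phase_code) {
  ph <- names(PHASES)[match(phase_code, PHASES)]
  catalogue$cell[[field]]$groups[[ph]]
}

.field_spec <- function(catalogue, field, phase_code) {
  grp <- .field_group(catalogue, field, phase_code)
  if (is.null(grp)) stop("no catalogue entry for ", field)
  sp <- catalogue$cell[[field]]$values[[grp]]
  if (is.null(sp)) stop("no catalogue group '", grp, "' for ", field)
  sp
}

#' Sample a full per-cell parameter set
#'
#' Draws one value per parameter field for `n` cells in the stated
#' cell-cycle phase. Phase-grouped fields (DSB induction coefficients,
#' repair probability, death thresholds) are drawn from the distribution
#' of the group containing `phase`; the four checkpoint arrest thresholds
#' are drawn from their per-checkpoint distributions. All draws are
#' independent between cells and between fields.
#'
#' @param phase Phase label (`"G0"`..`"M2"`) or code.
#' @param catalogue A [default_catalogue()]-style list.
#' @param n Number of cells.
#' @return A list of numeric vectors of length `n`: the seven
#'   phase-grouped fields plus `thr_g1s`, `thr_sg2`, `thr_g2m1`,
#'   `thr_m1m2`.
#' @export
sample_cell_params <- function(phase, catalogue = default_catalogue(),
                               n = 1L) {
  code <- if (is.character(phase)) PHASES[[phase]] else as.integer(phase)
  out <- lapply(.CELL_FIELDS, function(f)
    sample_truncated_normal(n, .field_spec(catalogue, f, code)))
  names(out) <- .CELL_FIELDS
  thr <- catalogue$checkpoint$arrest_threshold$values
  out$thr_g1s  <- sample_truncated_normal(n, thr$g1s)
  out$thr_sg2  <- sample_truncated_normal(n, thr$sg2)
  out$thr_g2m1 <- sample_truncated_normal(n, thr$g2m1)
  out$thr_m1m2 <- sample_truncated_normal(n, thr$m1m2)
  out
}

#' Sample cell-cycle phase durations
#'
#' @param phase Phase label or code (`G0` has no duration and yields `Inf`).
#' @param catalogue Parameter catalogue.
#' @param n Number of draws.
#' @return Numeric vector of durations in hours.
#' @export
sample_phase_period <- function(phase, catalogue = default_catalogue(),
                                n = 1L) {
  code <- if (is.character(phase)) PHASES[[phase]] else as.integer(phase)
  if (code == PHASES[["G0"]]) return(rep.int(Inf, n))
  ph <- names(PHASES)[match(code, PHASES)]
  sample_truncated_normal(n, catalogue$period$values[[ph]])
}

#' Derive a reproducible sub-seed
#'
#' Folds a master seed together with labels (trial index, purpose string)
#' into a seed in `[1, 2^31 - 2]`, so that separate concerns of a run can
#' be seeded reproducibly and changing any label changes the stream.
#'
#' @param master Master seed (integer-valued).
#' @param ... Further integer or character labels.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647                      # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (lab in list(...)) {
    ks <- if (is.character(lab)) utf8ToInt(lab) else as.numeric(lab)
    for (k in ks) h <- (h * 31 + k + 17) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
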