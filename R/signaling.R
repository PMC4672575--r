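#' Pathway parameters for a virtual signal
#'
#' The medium-mediated pathway (MDP) signal diffuses through cell and
#' medium sites alike; the gap-junctional pathway (GJP) signal is confined
#' to contiguous cell sites. Both are produced in irradiated cells in
#' proportion to the step dose and decay exponentially.
#'
#' @param w Diffusion constant (m^2/s).
#' @param alpha Production constant (signal units per Gy).
#' @param beta First-order decay constant (1/s).
#' @param medium_permeable `TRUE` for the MDP, `FALSE` for the GJP.
#' @param name Pathway tag.
#' @return Object of class `pathway_params`.
#' @export
pathway_params <- function(w, alpha, beta, medium_permeable,
                           name = if (medium_permeable) "MDP" else "GJP") {
  stopifnot(w >= 0, alpha >= 0, beta >= 0, is.logical(medium_permeable))
  structure(list(w = w, alpha = alpha, beta = beta,
                 medium_permeable = medium_permeable, name = name),
            class = "pathway_params")
}

#' Explicit-scheme stability check
#'
#' The synchronous 8-neighbour update is a convex combination of old field
#' values iff `3 * dt * w / d^2 <= 1` (the twelve weight units of the
#' stencil times `dt / (4 d^2)`). Violating it lets the field oscillate
#' and go negative.
#'
#' @param w Diffusion constant (m^2/s).
#' @param dt Time step (s).
#' @param d Grid spacing (m).
#' @return List with `stable` (logical) and `margin` (`3 dt w / d^2`;
#'   stable iff `<= 1`).
#' @examples
#' stability_check(1e-10, 0.1, 1e-5)  # margin 0.3
#' @export
stability_check <- function(w, dt, d) {
  margin <- 3 * dt * w / d^2
  list(stable = margin <= 1, margin = margin)
}

# Neighbour-permitted indicator for a pathway: which site kinds a signal
# may diffuse *into* (and hence exchange with).
.permit_matrix <- function(lattice, params) {
  if (params$medium_permeable) (lattice$kind != KIND_WALL) * 1
  else (lattice$kind == KIND_CELL) * 1
}

#' Diffusion-direction constants
#'
#' The effective diffusion coefficient from each site towards each of its
#' eight neighbours: the pathway's `w` when the *neighbour* is of a
#' permitted kind (MDP: cell or medium; GJP: cell only), and 0 otherwise
#' (walls always 0). This is the case table controlling inhomogeneous
#' diffusion through the gap-junction network.
#'
#' @param lattice A `ca_lattice`.
#' @param params A [pathway_params()].
#' @return Named list of eight numeric matrices (`up`, `down`, `left`,
#'   `right`, `up_left`, `up_right`, `down_left`, `down_right`), each
#'   giving the weight from every site towards that neighbour.
#' @export
direction_weights <- function(lattice, params) {
  P <- .permit_matrix(lattice, params)
  out <- lapply(.DIRS, function(dd)
    params$w * .shift_mat(P, -dd[1L], -dd[2L]))
  names(out) <- .DIR_NAMES
  out
}

# Precompute the per-lattice part of the diffusion stencil: the permitted
# indicator, the weighted neighbour-permit sum, and the defined-site mask.
.diffusion_kernel <- function(lattice, params) {
  P <- .permit_matrix(lattice, params)
  list(P = P,
       wsum = .stencil_sum(P),
       defined = if (params$medium_permeable) lattice$kind != KIND_WALL
                 else lattice$kind == KIND_CELL)
}

#' Advance a signal field by one time step
#'
#' Synchronous update of the whole field: production `alpha * R` in sites
#' receiving step dose `R`, first-order decay, and 8-neighbour diffusion
#' with orthogonal neighbours weighted twice and diagonal once, scaled by
#' `dt / (4 d^2)` and gated by the pathway's direction constants. Sites
#' where the field is undefined (walls; medium sites for the GJP) are held
#' at zero.
#'
#' @param field Numeric matrix, the signal concentration at time `t`.
#' @param lattice A `ca_lattice`.
#' @param params A [pathway_params()].
#' @param dt Time step (s).
#' @param step_dose Per-site dose delivered this step (matrix, Gy), or
#'   `NULL` for none.
#' @param decay_mode `"per_second"` (decay fraction `beta * dt` per step;
#'   the default, consistent with `beta` in 1/s) or `"literal"` (fraction
#'   `beta` per step regardless of `dt`).
#' @param kernel Precomputed internals (for repeated stepping); computed
#'   from the lattice when `NULL`.
#' @return The field at `t + dt`.
#' @export
diffusion_step <- function(field, lattice, params, dt, step_dose = NULL,
                           decay_mode = c("per_second", "literal"),
                           kernel = NULL) {
  decay_mode <- match.arg(decay_mode)
  if (is.null(kernel)) kernel <- .diffusion_kernel(lattice, params)
  sc <- stability_check(params$w, dt, lattice$d)
  if (!sc$stable)
    stop(sprintf("unstable diffusion step: 3*dt*w/d^2 = %.3g > 1", sc$margin))
  decay <- if (decay_mode == "per_second") params$beta * dt else params$beta
  .diffuse_cpp(field, kernel$wsum, kernel$P, decay = decay,
               coef = params$w * dt / (4 * lattice$d^2),
               alpha = params$alpha,
               dose = if (is.null(step_dose)) numeric(0)
                      else as.numeric(step_dose))
}

#' Extract a row profile of a signal field
#'
#' Concentrations along one lattice row (constant row index `j`, all
#' columns `i = 1..n_cols`), the format used to display how far each
#' signal has spread from the irradiated area.
#'
#' @param field Numeric matrix.
#' @param row 1-based row index.
#' @return Numeric vector of length `ncol(field)`.
#' @export
signal_profile <- function(field, row) {
  if (row < 1 || row > nrow(field)) stop("row index out of bounds")
  as.numeric(field[row, ])
}

#' Write signal row profiles as CSV
#'
#' @param M,G Signal field matrices (either may be `NULL`).
#' @param row Row index.
#' @param file Output path.
#' @return Invisibly, the data frame written (`position`, `M`, `G`).
#' @export
write_profile <- function(M, G, row, file) {
  n <- ncol(if (!is.null(M)) M else G)
  df <- data.frame(position = seq_len(n))
  if (!is.null(M)) df$M <- signal_profile(M, row)
  if (!is.null(G)) df$G <- signal_profile(G, row)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
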