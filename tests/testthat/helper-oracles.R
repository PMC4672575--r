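# Independent oracles used across the test suite. These deliberately do
# not share code paths with the package internals they check.

# Closed-form mean of a normal(av, sd) truncated below at `lo`.
tnorm_mean <- function(av, sd, lo = 0) {
  a <- (lo - av) / sd
  av + sd * dnorm(a) / (1 - pnorm(a))
}

# Literal per-site reference implementation of the synchronous signal
# update: loops over every site, applies the neighbour case table
# (weight w if the neighbour is of a permitted kind, else 0), orthogonal
# neighbours twice, diagonal once, production alpha * dose and decay
# beta * dt, holding the field at zero where it is not defined.
scalar_diffusion_ref <- function(field, lattice, params, dt,
                                 step_dose = NULL,
                                 decay_mode = "per_second") {
  nr <- lattice$n_rows; nc <- lattice$n_cols
  kind <- lattice$kind
  permitted <- function(k) {
    if (params$medium_permeable) k != 0L else k == 2L
  }
  defined <- matrix(FALSE, nr, nc)
  for (i in 1:nr) for (j in 1:nc) defined[i, j] <- permitted(kind[i, j])
  decay <- if (decay_mode == "per_second") params$beta * dt else params$beta
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    if (!defined[i, j]) next
    acc <- 0
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                    c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))) {
      k <- i + dd[1]; l <- j + dd[2]
      if (k < 1 || k > nr || l < 1 || l > nc) next
      w <- if (permitted(kind[k, l])) params$w else 0
      mult <- if (dd[1] == 0 || dd[2] == 0) 2 else 1
      acc <- acc + mult * w * (field[k, l] - field[i, j])
    }
    val <- field[i, j] * (1 - decay) + dt / (4 * lattice$d^2) * acc
    if (!is.null(step_dose)) val <- val + params$alpha * step_dose[i, j]
    out[i, j] <- val
  }
  out
}

# A small lattice with a hand-placed mixture of cell, medium and wall
# sites, for kernel equivalence tests.
mixed_kind_lattice <- function(seed = 1, nr = 5, nc = 5, p_cell = 0.5) {
  set.seed(seed)
  lat <- build_lattice(nr, nc)
  interior <- which(lat$kind == 1L)
  cells <- sample(interior, round(p_cell * length(interior)))
  lat$kind[cells] <- 2L
  lat
}

# Catalogue with every stochastic width collapsed to zero, so each cell
# receives the group mean exactly.
degenerate_catalogue <- function() {
  cat <- default_catalogue()
  for (f in names(cat$cell))
    for (g in names(cat$cell[[f]]$values)) {
      cat$cell[[f]]$values[[g]]$sd <- 0
      if (cat$cell[[f]]$values[[g]]$av <= cat$cell[[f]]$values[[g]]$min)
        cat$cell[[f]]$values[[g]]$min <- -1
    }
  for (g in names(cat$checkpoint$arrest_threshold$values))
    cat$checkpoint$arrest_threshold$values[[g]]$sd <- 0
  for (g in names(cat$period$values))
    cat$period$values[[g]]$sd <- 0
  cat
}

# Zero a set of induction/repair coefficients in a catalogue (degenerate
# at exactly 0, with the truncation bound lowered to admit it).
zero_fields <- function(cat, fields) {
  for (f in fields)
    for (g in names(cat$cell[[f]]$values))
      cat$cell[[f]]$values[[g]] <- list(av = 0, sd = 0, min = -1)
  cat
}
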