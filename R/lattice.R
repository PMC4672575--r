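# Site kind codes; walls are immutable, cell<->medium transitions happen
# through division and interphase death only.
KIND_WALL <- 0L
KIND_MEDIUM <- 1L
KIND_CELL <- 2L

KIND_NAMES <- c("wall", "medium", "cell")  # index = code + 1

#' Build a rectangular lattice with a wall border
#'
#' Creates the simulation grid: `n_rows x n_cols` sites of which the
#' outermost ring is wall (the culture-container boundary, giving the
#' diffusion scheme zero-flux edges) and the interior starts as medium.
#' Rows are indexed 1-based from the top, columns from the left.
#'
#' @param n_rows,n_cols Grid dimensions including the wall ring (`>= 3`).
#' @param d Grid spacing in metres (one site is one cell diameter;
#'   default 10 micrometres).
#' @return An object of class `ca_lattice`: a list with `n_rows`,
#'   `n_cols`, `d`, integer matrix `kind` (0 wall / 1 medium / 2 cell),
#'   integer matrix `region` (0 none, 1 A, 2 B, 3 C) and logical matrix
#'   `mask` (irradiated sites).
#' @examples
#' lat <- build_lattice(5, 7)
#' table(lat$kind)
#' @export
build_lattice <- function(n_rows, n_cols, d = 1e-5) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 3 || n_cols < 3)
    stop("lattice needs n_rows >= 3 and n_cols >= 3 (no interior otherwise)")
  if (!is.numeric(d) || d <= 0) stop("grid spacing d must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  kind <- matrix(KIND_MEDIUM, n_rows, n_cols)
  kind[c(1L, n_rows), ] <- KIND_WALL
  kind[, c(1L, n_cols)] <- KIND_WALL
  structure(list(
    n_rows = n_rows, n_cols = n_cols, d = d, kind = kind,
    region = matrix(0L, n_rows, n_cols),
    mask = matrix(FALSE, n_rows, n_cols)
  ), class = "ca_lattice")
}

#' @export
print.ca_lattice <- function(x, ...) {
  tab <- table(factor(KIND_NAMES[x$kind + 1L], levels = KIND_NAMES))
  cat(sprintf("<ca_lattice> %d x %d sites, d = %g m\n",
              x$n_rows, x$n_cols, x$d))
  cat(sprintf("  wall %d, medium %d, cell %d; irradiation mask %d sites\n",
              tab[["wall"]], tab[["medium"]], tab[["cell"]], sum(x$mask)))
  invisible(x)
}

#' Neighbourhoods of a lattice site
#'
#' Returns the two neighbour classes of the 8-neighbourhood of an interior
#' site: the four orthogonal neighbours (up, down, left, right) and the
#' four diagonal ones. Wall or medium neighbours are listed like any
#' others; pathway permeability is the diffusion kernel's concern, not the
#' geometry's.
#'
#' @param lattice A [build_lattice()] object.
#' @param i,j Row and column (1-based) of an interior site.
#' @return A list with integer matrices `orthogonal` and `diagonal`
#'   (columns `i`, `j`; 4 rows each).
#' @export
neighbors <- function(lattice, i, j) {
  if (i <= 1L || j <= 1L || i >= lattice$n_rows || j >= lattice$n_cols)
    stop("neighbourhood is defined for interior sites only")
  orth <- cbind(i = c(i + 1L, i - 1L, i, i), j = c(j, j, j + 1L, j - 1L))
  diag <- cbind(i = c(i + 1L, i - 1L, i + 1L, i - 1L),
                j = c(j + 1L, j + 1L, j - 1L, j - 1L))
  list(orthogonal = orth, diagonal = diag)
}

# Column-major flat-index offsets of the 8 neighbours.
.neighbor_offsets <- function(n_rows) {
  c(-1L, 1L, -n_rows, n_rows,                      # orthogonal
    -n_rows - 1L, -n_rows + 1L, n_rows - 1L, n_rows + 1L)  # diagonal
}

# Shift a matrix by (dr, dc), zero-filling the vacated band.
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

# The eight shift directions: first four orthogonal, last four diagonal.
.DIRS <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
              c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
.DIR_NAMES <- c("up", "down", "left", "right",
                "up_left", "up_right", "down_left", "down_right")

# For every site, the weighted sum over its 8 neighbours: orthogonal
# neighbours count twice, diagonal once (the explicit 2D stencil).
# Compiled kernel: this runs twice per field per time step.
.stencil_sum <- function(m) .stencil_sum_cpp(m)

#' Count medium neighbours of every site
#'
#' @param lattice A `ca_lattice`.
#' @return Integer matrix: number of medium sites among the 8 neighbours.
#' @keywords internal
medium_neighbor_count <- function(lattice) {
  med <- (lattice$kind == KIND_MEDIUM) * 1L
  acc <- matrix(0L, lattice$n_rows, lattice$n_cols)
  for (d in .DIRS) acc <- acc + .shift_mat(med, d[1L], d[2L])
  acc
}

#' Write a lattice snapshot as plain-text CSV
#'
#' Writes the site-kind matrix (and, if a world is supplied, the per-site
#' cell phase and life state) as CSV matrices, one file per layer.
#'
#' @param lattice A `ca_lattice` or a simulation world.
#' @param file Base file path; layer suffixes are appended before `.csv`.
#' @return Invisibly, the paths written.
#' @export
write_snapshot <- function(lattice, file) {
  base <- sub("\\.csv$", "", file)
  paths <- character(0)
  lat <- if (inherits(lattice, "ca_lattice")) lattice else lattice$lat
  p <- paste0(base, "_kind.csv")
  utils::write.table(matrix(KIND_NAMES[lat$kind + 1L], lat$n_rows),
                     p, sep = ",", row.names = FALSE, col.names = FALSE)
  paths <- c(paths, p)
  if (!inherits(lattice, "ca_lattice")) {
    w <- lattice
    ph <- matrix(NA_character_, lat$n_rows, lat$n_cols)
    ph[] <- names(PHASES)[match(w$phase, PHASES)]
    st <- matrix(NA_character_, lat$n_rows, lat$n_cols)
    st[] <- names(LIFE_STATES)[w$state]
    for (layer in list(list("_phase.csv", ph), list("_state.csv", st))) {
      p <- paste0(base, layer[[1L]])
      utils::write.table(layer[[2L]], p, sep = ",",
                         row.names = FALSE, col.names = FALSE, na = "")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
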