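# Discrete reaction-diffusion dynamics for one cytokine species:
# dphi/dt = D * laplacian(phi) - K * phi, explicit forward Euler with dt = 1,
# 5-point stencil, no-flux (reflecting) boundaries. Concentrations are
# dimensionless model units (agents deposit +1 at their site).

# Shift a matrix by one row/column, replicating the edge (reflecting
# boundary). Summing the four shifted copies minus 4x the field gives a
# Laplacian whose total flux over the grid is exactly zero.
shift_up    <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]
shift_down  <- function(m) m[c(1L, 1:(nrow(m) - 1L)), , drop = FALSE]
shift_left  <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]
shift_right <- function(m) m[, c(1L, 1:(ncol(m) - 1L)), drop = FALSE]

#' One explicit diffusion-decay step of a cytokine field
#'
#' Applies a single forward-Euler update of the reaction-diffusion equation
#' dphi/dt = D lap(phi) - K phi on the lattice, with the standard 5-point
#' Laplacian, reflecting (no-flux) boundaries and dt = 1, then first-order
#' decay by the factor (1 - K). Under the stability bound D <= 1/4 the field
#' stays non-negative, and with K = 0 total mass is conserved exactly.
#'
#' @param field Numeric matrix of non-negative concentrations.
#' @param params A [cytokine_params()] object (or anything with `diffusion`
#'   and `degradation` fields).
#' @return The updated matrix, same shape.
#' @examples
#' f <- field_deposit(matrix(0, 3, 3), 2, 2, 1)
#' field_step(f, cytokine_params(0.25, 0))
#' @export
field_step <- function(field, params) {
  if (!is.matrix(field) || !is.numeric(field)) {
    stop("`field` must be a numeric matrix", call. = FALSE)
  }
  D <- params$diffusion
  K <- params$degradation
  if (nrow(field) == 1L && ncol(field) == 1L) {
    return(field * (1 - K))
  }
  lap <- shift_up(field) + shift_down(field) +
    shift_left(field) + shift_right(field) - 4 * field
  (field + D * lap) * (1 - K)
}

#' Deposit cytokine at a lattice site
#'
#' @param field Numeric concentration matrix.
#' @param row,col 1-based site indices.
#' @param amount Positive amount added at the site.
#' @return The updated matrix.
#' @export
field_deposit <- function(field, row, col, amount = 1) {
  if (row < 1L || row > nrow(field) || col < 1L || col > ncol(field)) {
    stop(sprintf("deposit site (%d, %d) outside the %d x %d grid",
                 row, col, nrow(field), ncol(field)), call. = FALSE)
  }
  field[row, col] <- field[row, col] + amount
  field
}

#' Total cytokine mass on the grid
#'
#' @param field Numeric concentration matrix.
#' @return Sum of all entries.
#' @export
field_mass <- function(field) sum(field)

# Moore-neighbourhood maximum of a matrix: at each site, the max over the
# 3x3 block (centre + 8 neighbours), edges handled by replication so that
# off-grid sites never contribute.
moore_max <- function(m) {
  horiz <- pmax(m, shift_left(m), shift_right(m))
  pmax(horiz, shift_up(horiz), shift_down(horiz))
}

# Zero-padded single shifts (off-grid contributes 0), used for block sums.
zshift_up    <- function(m) rbind(m[-1L, , drop = FALSE], 0)
zshift_down  <- function(m) rbind(0, m[-nrow(m), , drop = FALSE])
zshift_left  <- function(m) cbind(m[, -1L, drop = FALSE], 0)
zshift_right <- function(m) cbind(0, m[, -ncol(m), drop = FALSE])

# Moore-block sum (3x3 including centre); off-grid contributes 0.
moore_sum <- function(m) {
  horiz <- m + zshift_left(m) + zshift_right(m)
  horiz + zshift_up(horiz) + zshift_down(horiz)
}
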