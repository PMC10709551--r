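#' The D3Q19 discrete velocity set
#'
#' Returns the lattice stencil used throughout the solver: 19 discrete
#' velocities on the 3-D cubic lattice (the rest vector, the 6 face
#' neighbours, and the 12 edge neighbours), their quadrature weights, the
#' lattice speed of sound squared (1/3), and the index map to each
#' direction's opposite. The ordering is fixed and shared with the compiled
#' kernels.
#'
#' The weights satisfy the usual isotropy conditions
#' \eqn{\sum_i w_i = 1}, \eqn{\sum_i w_i c_{i\alpha} = 0} and
#' \eqn{\sum_i w_i c_{i\alpha} c_{i\beta} = c_s^2 \delta_{\alpha\beta}},
#' which are what make the second-order equilibrium recover the
#' Navier--Stokes stress.
#'
#' @return An object of class `velocity_set`: a list with elements
#'   `directions` (19 x 3 integer matrix), `weights` (length 19),
#'   `cs2` (scalar, 1/3) and `opposite` (length-19 integer index map).
#' @export
#' @examples
#' vs <- velocity_set()
#' sum(vs$weights)                     # 1
#' colSums(vs$weights * vs$directions) # 0 0 0
velocity_set <- function() {
  directions <- matrix(c(
     0,  0,  0,
     1,  0,  0,  -1,  0,  0,
     0,  1,  0,   0, -1,  0,
     0,  0,  1,   0,  0, -1,
     1,  1,  0,  -1, -1,  0,
     1, -1,  0,  -1,  1,  0,
     1,  0,  1,  -1,  0, -1,
     1,  0, -1,  -1,  0,  1,
     0,  1,  1,   0, -1, -1,
     0,  1, -1,   0, -1,  1
  ), ncol = 3, byrow = TRUE)
  storage.mode(directions) <- "integer"
  weights <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  opposite <- c(1L, 3L, 2L, 5L, 4L, 7L, 6L, 9L, 8L, 11L, 10L,
                13L, 12L, 15L, 14L, 17L, 16L, 19L, 18L)
  structure(
    list(directions = directions, weights = weights,
         cs2 = 1 / 3, opposite = opposite),
    class = "velocity_set"
  )
}

#' @export
print.velocity_set <- function(x, ...) {
  cat("<D3Q19 velocity set> 19 directions, c_s^2 = 1/3\n")
  invisible(x)
}
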