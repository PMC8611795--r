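#' Uniform 1-D spatial grid for the soil column
#'
#' Depth coordinate z runs from 0 at the soil surface downwards to the column
#' length. The default 70 mm column matches a syringe-barrel mesocosm deep
#' enough to hold a pellet at 15 mm and a probe 30 mm below it.
#'
#' @param length_mm Column depth L in mm.
#' @param n_nodes Number of grid nodes (including both end points).
#' @return An object of class `column_grid` with fields `length_mm`, `n_nodes`,
#'   `z_mm` (node depths) and `h_mm` (spacing).
#' @examples
#' column_grid(70, 401)
#' @export
column_grid <- function(length_mm = 70, n_nodes = 401) {
  stopifnot(is.numeric(length_mm), length(length_mm) == 1,
            is.numeric(n_nodes), length(n_nodes) == 1)
  if (!is.finite(length_mm) || length_mm <= 0)
    abort("`length_mm` must be positive.")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3)
    abort("`n_nodes` must be at least 3.")
  z <- seq(0, length_mm, length.out = n_nodes)
  structure(
    list(length_mm = length_mm, n_nodes = n_nodes, z_mm = z,
         h_mm = z[2] - z[1]),
    class = "column_grid"
  )
}

#' @export
print.column_grid <- function(x, ...) {
  cat(sprintf("<column_grid> L = %g mm, %d nodes, h = %.4g mm\n",
              x$length_mm, x$n_nodes, x$h_mm))
  invisible(x)
}
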