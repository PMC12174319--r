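# Heading space: candidate translation directions sampled retinotopically on
# a hexagonal lattice over the central square of the visual field.

#' Build the heading-candidate grid
#'
#' Candidates lie on a hexagonal lattice (nearest-neighbor distance
#' `spacing`) clipped to the square of side `extent` centered on the FOV
#' center. Rows are `spacing * sqrt(3)/2` apart with alternate rows offset by
#' half a spacing, so no point of the square is farther than
#' `spacing / sqrt(3)` from a candidate.
#'
#' @param extent side length of the covered square, dva (model default 86).
#' @param spacing nearest-neighbor candidate distance, dva (default 1).
#' @return a `heading_grid`: list with `positions` (m x 2 matrix, dva),
#'   `extent` and `spacing`.
#' @export
build_heading_grid <- function(extent = 86, spacing = 1) {
  stopifnot(extent > 0, spacing > 0)
  half <- extent / 2
  row_h <- spacing * sqrt(3) / 2
  ks <- seq(-floor(half / row_h), floor(half / row_h))
  pos <- lapply(ks, function(k) {
    off <- if (k %% 2 == 0) 0 else spacing / 2
    xmax <- floor((half - off) / spacing)
    xmin <- -floor((half + off) / spacing)
    x <- off + spacing * seq(xmin, xmax)
    cbind(x = x, y = rep(k * row_h, length(x)))
  })
  pos <- do.call(rbind, pos)
  structure(list(positions = pos, extent = extent, spacing = spacing),
            class = "heading_grid")
}

#' @export
print.heading_grid <- function(x, ...) {
  cat(sprintf("<heading_grid> %d candidates, %g x %g dva, spacing %g dva\n",
              nrow(x$positions), x$extent, x$extent, x$spacing))
  invisible(x)
}

#' Map a candidate image position to a unit 3D translation direction
#'
#' The heading space is retinotopic: an image position `(x, y)` stands for
#' the translation direction proportional to `(x/f, y/f, 1)`.
#'
#' @param p image position (dva), length-2 vector or `n x 2` matrix.
#' @param f focal constant.
#' @return unit translation(s): length-3 vector or `n x 3` matrix.
#' @export
candidate_translation <- function(p, f = flow_focal()) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  u <- cbind(p[, 1] / f, p[, 2] / f, 1)
  u <- u / sqrt(rowSums(u^2))
  if (nrow(u) == 1L) drop(u) else u
}
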