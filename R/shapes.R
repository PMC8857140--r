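# Biofilm footprint shapes for initializing 2D runs: named fixture
# generators, polygon rasterization and PNG mask input.

#' Biofilm footprint specification
#'
#' A footprint is either a named fixture generator (`disc`,
#' `wall_half_disc`, `three_biofilm_layout`), a polygon (vertex list in
#' mm), or a binary mask with an mm-per-pixel scale.
#'
#' @param kind `"disc"`, `"wall_half_disc"`, `"three_biofilm_layout"`,
#'   `"polygon"` or `"mask"`.
#' @param r radius (mm) for disc-type shapes.
#' @param center `c(x, y)` center (mm) for `disc`; for `wall_half_disc`,
#'   the x-position of the center on the bottom wall.
#' @param poly two-column matrix of vertices (mm) for `"polygon"`.
#' @param mask logical/0-1 matrix for `"mask"` (row = x, col = y).
#' @param mm_per_pixel scale of `mask`.
#' @return list of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("disc", "wall_half_disc",
                                "three_biofilm_layout", "polygon", "mask"),
                       r = 0.2, center = NULL, poly = NULL, mask = NULL,
                       mm_per_pixel = NULL) {
  kind <- match.arg(kind)
  if (kind == "polygon" && (is.null(poly) || ncol(poly) != 2))
    stop("'polygon' shape needs a two-column vertex matrix", call. = FALSE)
  if (kind == "mask" && (is.null(mask) || is.null(mm_per_pixel)))
    stop("'mask' shape needs 'mask' and 'mm_per_pixel'", call. = FALSE)
  structure(list(kind = kind, r = r, center = center, poly = poly,
                 mask = mask, mm_per_pixel = mm_per_pixel),
            class = "shape_spec")
}

#' Read a biofilm footprint from an 8-bit PNG mask
#'
#' Non-zero pixels mark the biofilm.  The image row order (top to bottom)
#' is flipped so that row 1 of the returned mask is the bottom wall.
#'
#' @param path PNG file.
#' @param mm_per_pixel physical pixel size.
#' @return a `shape_spec` of kind `"mask"`.
#' @export
shape_from_png <- function(path, mm_per_pixel) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- t(img[rev(seq_len(nrow(img))), , drop = FALSE]) > 0
  shape_spec("mask", mask = mask, mm_per_pixel = mm_per_pixel)
}

# Even-odd rule point-in-polygon, vectorized over points.
.in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a footprint onto a grid
#'
#' @param shape `shape_spec` (or the kind string of a fixture generator).
#' @param grid `grid2d`.
#' @param ... fixture parameters forwarded to [shape_spec()].
#' @return logical mask `[nx, ny]`, `TRUE` inside the biofilm.
#' @export
generate_fixture <- function(shape, grid, ...) {
  if (is.character(shape)) shape <- shape_spec(shape, ...)
  nx <- grid$nx; ny <- grid$ny
  X <- matrix(grid$x, nx, ny)
  Y <- matrix(grid$y, nx, ny, byrow = TRUE)
  mask <- switch(shape$kind,
    disc = {
      ctr <- if (is.null(shape$center)) c(grid$Lx / 2, grid$Ly / 2) else shape$center
      (X - ctr[1])^2 + (Y - ctr[2])^2 <= shape$r^2
    },
    wall_half_disc = {
      cx <- if (is.null(shape$center)) grid$Lx / 2 else shape$center[1]
      (X - cx)^2 + Y^2 <= shape$r^2
    },
    three_biofilm_layout = {
      # one large biofilm on the bottom wall, two smaller ones above it;
      # sizes are above the standalone oscillation-onset size at the slow
      # (10 mm/hour) inlet flow, so each biofilm oscillates unaided
      big <- (X - 0.45 * grid$Lx)^2 + Y^2 <= 0.55^2
      s1 <- (X - 0.30 * grid$Lx)^2 + (Y - 0.35 * grid$Ly)^2 <= 0.36^2
      s2 <- (X - 0.65 * grid$Lx)^2 + (Y - 0.42 * grid$Ly)^2 <= 0.33^2
      big | s1 | s2
    },
    polygon = matrix(.in_polygon(c(X), c(Y), shape$poly), nx, ny),
    mask = {
      sx <- (seq_len(nrow(shape$mask)) - 0.5) * shape$mm_per_pixel
      sy <- (seq_len(ncol(shape$mask)) - 0.5) * shape$mm_per_pixel
      ii <- pmin(pmax(round(X / shape$mm_per_pixel + 0.5), 1), nrow(shape$mask))
      jj <- pmin(pmax(round(Y / shape$mm_per_pixel + 0.5), 1), ncol(shape$mask))
      matrix(shape$mask[cbind(c(ii), c(jj))], nx, ny)
    })
  if (!any(mask)) stop("footprint rasterizes to an empty mask", call. = FALSE)
  mask
}
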