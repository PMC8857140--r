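# Cell-centered 2D grid over the flow cell, the signed-distance level-set
# field that tracks the biofilm-fluid interface, and small geometry tools.
# Convention throughout: fields are matrices indexed [i, j] with i the
# x-index (column 1 = inlet side) and j the y-index (row 1 = bottom wall);
# phi < 0 inside the biofilm.

#' Construct a 2D flow-cell grid
#'
#' @param Lx,Ly domain size (mm); the reference flow cell is 3 mm by 3 mm.
#' @param h cell size (mm); 0.01 resolves single-biofilm runs, 0.02-0.03 is
#'   the coarse desk-scale setting.
#' @return list of class `grid2d` with `nx`, `ny`, `h`, `x`, `y` (cell
#'   centers) and `Lx`, `Ly`.
#' @export
make_grid2d <- function(Lx = 3, Ly = 3, h = 0.03) {
  stopifnot(Lx > 0, Ly > 0, h > 0)
  nx <- max(4L, as.integer(round(Lx / h)))
  ny <- max(4L, as.integer(round(Ly / h)))
  structure(list(nx = nx, ny = ny, h = h, Lx = Lx, Ly = Ly,
                 x = (seq_len(nx) - 0.5) * h, y = (seq_len(ny) - 0.5) * h),
            class = "grid2d")
}

# Interface point cloud: zero crossings of phi along x- and y-edges located
# by linear interpolation, densified with the midpoints of the
# marching-squares contour segments so that point-to-cloud distances track
# the contour itself rather than its vertices.
.interface_points <- function(phi, grid) {
  h <- grid$h
  nx <- grid$nx; ny <- grid$ny
  crossing <- function(a, b, xs, ys, horiz) {
    cr <- which(a * b < 0, arr.ind = TRUE)
    if (!nrow(cr)) return(NULL)
    th <- a[cr] / (a[cr] - b[cr])
    if (horiz) cbind(xs[cr[, 1]] + th * h, ys[cr[, 2]])
    else cbind(xs[cr[, 1]], ys[cr[, 2]] + th * h)
  }
  pts_x <- crossing(phi[-nx, , drop = FALSE], phi[-1, , drop = FALSE],
                    grid$x, grid$y, TRUE)
  pts_y <- crossing(phi[, -ny, drop = FALSE], phi[, -1, drop = FALSE],
                    grid$x, grid$y, FALSE)
  pts <- rbind(pts_x, pts_y)
  on <- which(phi == 0, arr.ind = TRUE)
  if (nrow(on)) pts <- rbind(pts, cbind(grid$x[on[, 1]], grid$y[on[, 2]]))
  if (is.null(pts) || nrow(pts) < 2) return(pts)
  # densify: for every grid square containing >= 2 crossings, add their
  # pairwise midpoint (the marching-squares chord midpoint)
  ci <- pmin(pmax(ceiling(pts[, 1] / h), 1L), nx)
  cj <- pmin(pmax(ceiling(pts[, 2] / h), 1L), ny)
  key <- ci + (cj - 1) * nx
  ord <- order(key)
  k <- key[ord]
  same <- which(k[-1] == k[-length(k)])
  if (length(same)) {
    a <- pts[ord[same], , drop = FALSE]
    b <- pts[ord[same + 1], , drop = FALSE]
    pts <- rbind(pts, (a + b) / 2)
  }
  pts
}

# Exact (brute-force) signed distance to the current zero contour.  The
# domain is small enough that distance-to-point-cloud, chunked to bound
# memory, is both simple and robust; |grad phi| = 1 by construction.
.signed_distance <- function(phi, grid) {
  pts <- .interface_points(phi, grid)
  if (is.null(pts) || nrow(pts) == 0)
    return(matrix(sign(phi[1]) * (grid$Lx + grid$Ly), grid$nx, grid$ny))
  cx <- rep(grid$x, times = grid$ny)
  cy <- rep(grid$y, each = grid$nx)
  n <- length(cx)
  d <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(pts)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(cx[s:e], pts[, 1], "-")
    dy <- outer(cy[s:e], pts[, 2], "-")
    d[s:e] <- sqrt(pmin.int(apply(dx * dx + dy * dy, 1, min), Inf))
  }
  matrix(ifelse(c(phi) < 0, -d, d), grid$nx, grid$ny)
}

#' Signed-distance level-set field from a biofilm mask
#'
#' @param mask logical matrix `[nx, ny]`, `TRUE` inside the biofilm.
#' @param grid `grid2d`.
#' @return matrix `phi`, negative inside the biofilm, a signed distance to
#'   the interface.
#' @export
phi_from_mask <- function(mask, grid) {
  stopifnot(all(dim(mask) == c(grid$nx, grid$ny)))
  phi0 <- matrix(ifelse(mask, -grid$h / 2, grid$h / 2), grid$nx, grid$ny)
  .signed_distance(phi0, grid)
}

# Connected components of the biofilm region (4-neighbour adjacency),
# labelled 1..k in decreasing area order.
.label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nx, ny))
  id <- matrix(0L, nx, ny)
  id[idx] <- seq_along(idx)
  edges <- NULL
  m1 <- mask[-nx, , drop = FALSE] & mask[-1, , drop = FALSE]
  w <- which(m1, arr.ind = TRUE)
  if (nrow(w)) edges <- rbind(edges, cbind(id[cbind(w[, 1], w[, 2])],
                                           id[cbind(w[, 1] + 1L, w[, 2])]))
  m2 <- mask[, -ny, drop = FALSE] & mask[, -1, drop = FALSE]
  w <- which(m2, arr.ind = TRUE)
  if (nrow(w)) edges <- rbind(edges, cbind(id[cbind(w[, 1], w[, 2])],
                                           id[cbind(w[, 1], w[, 2] + 1L)]))
  g <- igraph::make_graph(edges = if (is.null(edges)) integer(0) else t(edges),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  rk <- setNames(rank(-as.numeric(sizes), ties.method = "first"), names(sizes))
  lab <- matrix(0L, nx, ny)
  lab[idx] <- as.integer(rk[as.character(comp)])
  lab
}

# Godunov upwind advance of phi under an outward normal speed F >= 0,
# followed by periodic reinitialization (handled by the caller).
.advance_phi <- function(phi, speed, dt, grid) {
  h <- grid$h
  nx <- grid$nx; ny <- grid$ny
  pW <- rbind(phi[1, ], phi[-nx, ])   # ghost: zero-gradient at domain edges
  pE <- rbind(phi[-1, ], phi[nx, ])
  pS <- cbind(phi[, 1], phi[, -ny])
  pN <- cbind(phi[, -1], phi[, ny])
  Dmx <- (phi - pW) / h; Dpx <- (pE - phi) / h
  Dmy <- (phi - pS) / h; Dpy <- (pN - phi) / h
  grad <- sqrt(pmax(Dmx, 0)^2 + pmin(Dpx, 0)^2 +
               pmax(Dmy, 0)^2 + pmin(Dpy, 0)^2)
  phi - dt * speed * grad
}
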