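#' Project sensor positions onto a 2D plane
#'
#' Azimuthal equidistant projection about the vertex: a sensor at polar
#' angle `theta` (from the +z axis) and azimuth `phi` maps to polar radius
#' `R * theta` (in millimetres, using the mean sensor radius `R`) at the
#' same azimuth.  The vertex maps to the origin and relative angular layout
#' is preserved; sensors mirrored about the midline get mirror-image
#' coordinates.
#'
#' @param positions_3d `n` x 3 matrix of positions on an approximately
#'   spherical cap centred on the origin (metres).
#' @return `n` x 2 matrix of coordinates in millimetres.
#' @export
project_sensors_2d <- function(positions_3d) {
  positions_3d <- as.matrix(positions_3d)
  stopifnot(ncol(positions_3d) == 3)
  r <- sqrt(rowSums(positions_3d^2))
  stopifnot(all(r > 0))
  theta <- acos(pmin(1, pmax(-1, positions_3d[, 3] / r)))
  phi <- atan2(positions_3d[, 2], positions_3d[, 1])
  rho <- mean(r) * theta * 1000
  cbind(x = rho * cos(phi), y = rho * sin(phi))
}

#' Square scalp grid with inside-head mask
#'
#' @param coordinates_2d projected sensor coordinates in millimetres.
#' @param grid_size number of pixels per side (default 64).
#' @param margin half-width of the grid as a multiple of the outermost
#'   sensor radius.
#' @return A list with `x`, `y` (pixel-centre coordinates in mm), `mask`
#'   (`grid_size` x `grid_size` logical disc reaching one pixel beyond the
#'   outermost sensor) and `pixel_mm`.
#' @export
make_scalp_grid <- function(coordinates_2d, grid_size = 64L, margin = 1.06) {
  rmax <- max(sqrt(rowSums(coordinates_2d^2)))
  half <- margin * rmax
  ax <- seq(-half, half, length.out = grid_size)
  pixel_mm <- ax[2] - ax[1]
  gx <- matrix(ax, grid_size, grid_size)
  gy <- matrix(ax, grid_size, grid_size, byrow = TRUE)
  mask <- sqrt(gx^2 + gy^2) <= rmax + pixel_mm
  list(x = ax, y = ax, mask = mask, pixel_mm = pixel_mm)
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(c(NA_real_, NA_real_, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Bowyer-Watson incremental Delaunay triangulation.  Adequate for the ~10^2
# well-separated points of a sensor layout; not tuned for degenerate or
# massive inputs.
delaunay_triangulation <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 3, ncol(points) == 2)
  cx <- mean(range(points[, 1]))
  cy <- mean(range(points[, 2]))
  big <- 100 * (max(sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)) + 1)
  P <- rbind(points,
             c(cx - sqrt(3) * big, cy - big),
             c(cx + sqrt(3) * big, cy - big),
             c(cx, cy + 2 * big))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), ncol = 3)
  cc <- matrix(circumcircle(P[n + 1, ], P[n + 2, ], P[n + 3, ]), ncol = 3)
  for (i in seq_len(n)) {
    p <- P[i, ]
    inside <- (p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] * (1 + 1e-12)
    inside[!is.finite(cc[, 3])] <- TRUE
    bad <- which(inside)
    edges <- rbind(tris[bad, c(1, 2), drop = FALSE],
                   tris[bad, c(2, 3), drop = FALSE],
                   tris[bad, c(3, 1), drop = FALSE])
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    new_tris <- cbind(boundary, i)
    new_cc <- t(apply(new_tris, 1, function(tr) {
      circumcircle(P[tr[1], ], P[tr[2], ], P[tr[3], ])
    }))
    tris <- rbind(tris, new_tris)
    cc <- rbind(cc, new_cc)
  }
  keep <- rowSums(tris > n) == 0
  unname(tris[keep, , drop = FALSE])
}

#' Precompute scatter-to-grid interpolation weights
#'
#' Piecewise-linear (barycentric, on a Delaunay triangulation) interpolation
#' inside the convex hull of the sensor coordinates; nearest-neighbour
#' extrapolation for grid pixels outside the hull but inside the mask;
#' pixels outside the mask stay `NaN`.  The returned weight matrix `W`
#' (`n_masked_pixels` x `n_nodes`) makes per-frequency interpolation a
#' single matrix product, and reproduces linear fields exactly inside the
#' hull.
#'
#' @param coordinates_2d `n_nodes` x 2 sensor coordinates (mm).
#' @param grid a grid from [make_scalp_grid()].
#' @return A list with `W`, `pixel_index` (linear indices of masked pixels),
#'   `inside_hull` (logical per masked pixel) and `grid`.
#' @export
build_grid_interpolator <- function(coordinates_2d, grid) {
  coordinates_2d <- as.matrix(coordinates_2d)
  n <- nrow(coordinates_2d)
  gs <- length(grid$x)
  tris <- delaunay_triangulation(coordinates_2d)
  pix <- which(grid$mask)
  px <- grid$x[((pix - 1L) %% gs) + 1L]
  py <- grid$y[((pix - 1L) %/% gs) + 1L]
  W <- matrix(0, length(pix), n)
  assigned <- logical(length(pix))
  for (t in seq_len(nrow(tris))) {
    a <- coordinates_2d[tris[t, 1], ]
    b <- coordinates_2d[tris[t, 2], ]
    c <- coordinates_2d[tris[t, 3], ]
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    if (abs(det) < 1e-12) next
    todo <- which(!assigned)
    if (length(todo) == 0) break
    l1 <- ((b[2] - c[2]) * (px[todo] - c[1]) +
             (c[1] - b[1]) * (py[todo] - c[2])) / det
    l2 <- ((c[2] - a[2]) * (px[todo] - c[1]) +
             (a[1] - c[1]) * (py[todo] - c[2])) / det
    l3 <- 1 - l1 - l2
    tol <- -1e-9
    hit <- todo[l1 >= tol & l2 >= tol & l3 >= tol]
    if (length(hit)) {
      sel <- match(hit, todo)
      W[cbind(hit, tris[t, 1])] <- l1[sel]
      W[cbind(hit, tris[t, 2])] <- l2[sel]
      W[cbind(hit, tris[t, 3])] <- l3[sel]
      assigned[hit] <- TRUE
    }
  }
  inside_hull <- assigned
  if (any(!assigned)) {
    out <- which(!assigned)
    d2 <- outer(px[out]^2 + py[out]^2, rep(1, n)) +
      outer(rep(1, length(out)), rowSums(coordinates_2d^2)) -
      2 * cbind(px[out], py[out]) %*% t(coordinates_2d)
    W[cbind(out, apply(d2, 1, which.min))] <- 1
  }
  list(W = W, pixel_index = pix, inside_hull = inside_hull, grid = grid)
}

#' Interpolate node values onto the scalp grid
#'
#' @param node_values numeric vector, one value per node.
#' @param coordinates_2d sensor coordinates (mm); ignored when
#'   `interpolator` is given.
#' @param grid_size pixels per side when the grid is built on the fly.
#' @param interpolator optional precomputed [build_grid_interpolator()]
#'   output.
#' @return `grid_size` x `grid_size` matrix, `NaN` outside the mask.
#' @export
interpolate_to_grid <- function(node_values, coordinates_2d = NULL,
                                grid_size = 64L, interpolator = NULL) {
  if (is.null(interpolator)) {
    grid <- make_scalp_grid(coordinates_2d, grid_size)
    interpolator <- build_grid_interpolator(coordinates_2d, grid)
  }
  gs <- length(interpolator$grid$x)
  img <- matrix(NaN, gs, gs)
  img[interpolator$pixel_index] <- as.vector(interpolator$W %*% node_values)
  img
}

#' Gaussian smoothing of a scalp-by-frequency image
#'
#' Separable Gaussian smoothing, mask- and NaN-normalized so constants are
#' preserved inside the mask.  Spatial FWHM is interpreted in millimetres
#' via the grid's pixel size and the spectral FWHM in Hz via the frequency
#' bin width; `fwhm = 0` on an axis disables smoothing along it.
#'
#' @param image_3d `gs` x `gs` x `n_freq` array.
#' @param mask `gs` x `gs` logical inside-head mask.
#' @param fwhm length-3 vector `(mm, mm, Hz)`; default `c(8, 8, 8)`.
#' @param pixel_mm spatial pixel size in millimetres.
#' @param freq_step_hz frequency bin width in Hz.
#' @return Smoothed array of the same dimensions, `NaN` outside the mask.
#' @export
smooth_image <- function(image_3d, mask, fwhm = c(8, 8, 8), pixel_mm,
                         freq_step_hz) {
  stopifnot(length(dim(image_3d)) == 3, length(fwhm) == 3,
            all(fwhm >= 0), pixel_mm > 0, freq_step_hz > 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / c(pixel_mm, pixel_mm, freq_step_hz)
  out <- cpp_smooth3d(as.numeric(image_3d), dim(image_3d),
                      as.logical(mask), sigma)
  array(out, dim = dim(image_3d))
}

#' Build a subject's smoothed scalp-by-frequency image
#'
#' Projects node positions to 2D, interpolates the local-efficiency value of
#' every node onto the scalp grid per frequency bin, stacks the planes into
#' a 3D scalp-by-frequency volume and applies Gaussian smoothing.
#'
#' @param efficiency_map an `efficiency_map` whose `node_locations` (or the
#'   `positions_3d` argument) give 3D node positions.
#' @param positions_3d optional 3D node positions overriding the map's.
#' @param grid_size pixels per side (default 64).
#' @param fwhm smoothing FWHM `(mm, mm, Hz)`.
#' @param interpolator optional precomputed interpolator (reuse across
#'   subjects sharing a layout).
#' @return An object of class `scalp_frequency_image`: `grid` (`gs` x `gs` x
#'   `n_freq`), `mask`, `freq_axis`, `projection_meta`.
#' @export
scalp_frequency_image <- function(efficiency_map, positions_3d = NULL,
                                  grid_size = 64L, fwhm = c(8, 8, 8),
                                  interpolator = NULL) {
  stopifnot(inherits(efficiency_map, "efficiency_map"))
  if (is.null(interpolator)) {
    pos <- if (is.null(positions_3d)) efficiency_map$node_locations else positions_3d
    if (is.null(pos)) stop("node positions are required to build the image")
    coords <- project_sensors_2d(pos)
    grid <- make_scalp_grid(coords, grid_size)
    interpolator <- build_grid_interpolator(coords, grid)
  }
  grid <- interpolator$grid
  gs <- length(grid$x)
  freqs <- efficiency_map$frequencies
  nf <- length(freqs)
  planes <- interpolator$W %*% efficiency_map$values   # masked pixels x nf
  vol <- array(NaN, dim = c(gs, gs, nf))
  idx <- interpolator$pixel_index
  for (f in seq_len(nf)) vol[idx + (f - 1L) * gs * gs] <- planes[, f]
  freq_step <- if (nf > 1) freqs[2] - freqs[1] else 1
  vol <- smooth_image(vol, grid$mask, fwhm, grid$pixel_mm, freq_step)
  structure(list(grid = vol, mask = grid$mask, freq_axis = freqs,
                 projection_meta = list(pixel_mm = grid$pixel_mm,
                                        grid_x = grid$x, grid_y = grid$y,
                                        fwhm = fwhm)),
            class = "scalp_frequency_image")
}

#' @export
print.scalp_frequency_image <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<scalp_frequency_image> %d x %d x %d (%.0f%% of pixels inside mask)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}
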