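# ---------------------------------------------------------------------------
# Probability-simplex ("spectrum") geometry: barycentric projection of
# participant-level class-probability vectors onto the equilateral triangle,
# and highest-density contours of their distribution per group.
# ---------------------------------------------------------------------------

#' Vertices of the probability triangle
#'
#' Fixed vertex assignment: BD at the lower-left (0, 0), HC at the
#' lower-right (1, 0), BPD at the apex (1/2, sqrt(3)/2).
#'
#' @return 3 x 2 matrix of vertex coordinates, rows named BD, HC, BPD.
#' @export
simplex_vertices <- function() {
  matrix(c(0, 0,
           1, 0,
           0.5, sqrt(3) / 2),
         nrow = 3L, byrow = TRUE,
         dimnames = list(MOODSIG_CLASSES, c("x", "y")))
}

#' Project probability vectors onto the equilateral triangle
#'
#' Barycentric interpolation of the vertices: `xy = sum_i p_i * vertex_i`.
#' Components must be non-negative and sum to one within `tol` (the vector is
#' renormalised); a negative component beyond tolerance is an error.
#'
#' @param prob a probability 3-vector, or a matrix with one vector per row.
#' @param tol tolerance for the non-negativity / normalisation checks.
#' @return An `(x, y)` vector, or an N x 2 matrix for matrix input.
#' @examples
#' simplex_project(c(0.1, 0.5, 0.4))  # (0.7, 0.2 * sqrt(3))
#' @export
simplex_project <- function(prob, tol = 1e-6) {
  V <- simplex_vertices()
  one_row <- is.null(dim(prob))
  P <- rbind(prob)
  if (ncol(P) != 3L) stop("probability vectors must have 3 components")
  if (any(P < -tol)) stop("negative probability component")
  P[P < 0] <- 0
  s <- rowSums(P)
  if (any(abs(s - 1) > 1e-3))
    stop("probability vectors must sum to 1")
  P <- P / s
  xy <- P %*% V
  if (one_row) drop(xy) else xy
}

#' Recover barycentric weights from triangle coordinates
#'
#' Inverse of [simplex_project()].
#'
#' @param xy an `(x, y)` pair or an N x 2 matrix.
#' @return The probability 3-vector(s).
#' @export
simplex_barycentric <- function(xy) {
  V <- simplex_vertices()
  A <- rbind(t(V), rep(1, 3))
  XY <- rbind(xy)
  out <- t(apply(XY, 1L, function(p) solve(A, c(p, 1))))
  colnames(out) <- MOODSIG_CLASSES
  if (is.null(dim(xy))) drop(out) else out
}

#' Highest-density contours of projected probability vectors
#'
#' Gaussian kernel density estimate of the projected points on the triangle
#' plane (Scott's-rule bandwidth), with contour levels chosen so the enclosed
#' probability mass is (by default) 25, 50 and 75%: densities on the
#' evaluation grid are sorted and the threshold is the density at which the
#' accumulated mass reaches each level (highest-density regions).
#'
#' @param xy N x 2 matrix of projected points (N >= 5).
#' @param levels target enclosed masses.
#' @param n evaluation grid resolution per axis.
#' @return An object of class `simplex_density`: list with `contours` (per
#'   level, a list of polyline data.frames), `thresholds`, `enclosed_mass`
#'   (the mass actually enclosed at each threshold), `kde`, `degenerate`.
#'   When all points coincide a degenerate-density warning is issued and the
#'   common point is returned instead of contours.
#' @export
density_contours <- function(xy, levels = c(0.25, 0.50, 0.75), n = 151L) {
  xy <- rbind(xy)
  if (nrow(xy) < 5L) stop("need at least 5 points for density contours")
  sdx <- stats::sd(xy[, 1L])
  sdy <- stats::sd(xy[, 2L])
  if (sdx < 1e-12 && sdy < 1e-12) {
    warning("all points identical: degenerate density, returning the point")
    return(structure(list(contours = NULL, thresholds = NULL,
                          enclosed_mass = NULL, kde = NULL,
                          degenerate = TRUE, point = xy[1L, ]),
                     class = "simplex_density"))
  }
  m <- nrow(xy)
  h <- 4 * pmax(c(sdx, sdy), 1e-3) * m^(-1 / 6)  # kde2d uses h/4 as the sd
  pad <- 0.15
  kde <- MASS::kde2d(xy[, 1L], xy[, 2L], h = h, n = n,
                     lims = c(-pad, 1 + pad, -pad, sqrt(3) / 2 + pad))
  cell <- diff(kde$x[1:2]) * diff(kde$y[1:2])
  z <- as.vector(kde$z)
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(z[ord]) * cell
  total <- sum(z) * cell
  thresholds <- vapply(levels, function(L) {
    z[ord][which(cum >= L * total)[1L]]
  }, numeric(1))
  enclosed <- vapply(thresholds, function(th)
    sum(z[z >= th]) * cell / total, numeric(1))
  contours <- lapply(thresholds, function(th) {
    lapply(grDevices::contourLines(kde$x, kde$y, kde$z, levels = th),
           function(cl) data.frame(x = cl$x, y = cl$y))
  })
  names(contours) <- paste0(100 * levels, "%")
  structure(list(contours = contours, thresholds = thresholds,
                 enclosed_mass = enclosed, levels = levels, kde = kde,
                 degenerate = FALSE),
            class = "simplex_density")
}

#' Draw the probability-simplex spectrum
#'
#' @param probs N x 3 matrix of participant probability vectors.
#' @param labels true group per row (used for colouring and per-group
#'   contours).
#' @param groups which groups to draw contours for.
#' @param contour_levels enclosed-mass levels for the contours.
#' @param main plot title.
#' @return Invisibly, the list of per-group `simplex_density` objects.
#' @export
plot_spectrum <- function(probs, labels, groups = MOODSIG_CLASSES,
                          contour_levels = c(0.25, 0.50, 0.75),
                          main = "Diagnostic spectrum") {
  V <- simplex_vertices()
  xy <- simplex_project(probs)
  cols <- c(BD = "#1b9e77", HC = "#7570b3", BPD = "#d95f02")
  graphics::plot(NA, xlim = c(-0.1, 1.1), ylim = c(-0.1, sqrt(3) / 2 + 0.1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(V[c(1, 2, 3), 1L], V[c(1, 2, 3), 2L], border = "grey40")
  off <- rbind(c(-0.04, -0.04), c(0.04, -0.04), c(0, 0.05))
  graphics::text(V[, 1L] + off[, 1L], V[, 2L] + off[, 2L],
                 rownames(V), font = 2)
  labels <- as.character(labels)
  graphics::points(xy, pch = 19, cex = 0.6, col = cols[labels])
  # red contour shades, lightest for the widest (75%) region
  reds <- grDevices::colorRampPalette(c("#67000d", "#fb6a4a"))(
    length(contour_levels))
  dens <- list()
  for (g in intersect(groups, unique(labels))) {
    pts <- xy[labels == g, , drop = FALSE]
    if (nrow(pts) < 5L) next
    dc <- density_contours(pts, levels = contour_levels)
    dens[[g]] <- dc
    if (!dc$degenerate) {
      for (li in seq_along(dc$contours)) {
        for (cl in dc$contours[[li]])
          graphics::lines(cl$x, cl$y, col = reds[li], lwd = 1.4)
      }
    }
  }
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(dens)
}
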