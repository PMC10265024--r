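#' Build a shared evaluation grid for acoustic spaces
#'
#' All spaces that will be compared must be evaluated on one common grid.
#' The grid spans the joint point range padded by three global Silverman
#' bandwidths on each side.
#'
#' @param points Tibble or matrix with `dim1`/`dim2` columns (typically the
#'   full joint embedding).
#' @param resolution Cells per axis.
#' @return Object of class `space_grid`: `x`, `y` (cell-centre coordinates),
#'   `cell_area`, `resolution`.
#' @export
space_grid <- function(points, resolution = 200L) {
  p <- as_xy(points)
  bw <- silverman_bw(p)
  rx <- range(p[, 1]) + c(-3, 3) * bw[1]
  ry <- range(p[, 2]) + c(-3, 3) * bw[2]
  x <- seq(rx[1], rx[2], length.out = resolution)
  y <- seq(ry[1], ry[2], length.out = resolution)
  structure(list(x = x, y = y,
                 cell_area = diff(x[1:2]) * diff(y[1:2]),
                 resolution = as.integer(resolution)),
            class = "space_grid")
}

as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    return(unname(points))
  }
  stopifnot(all(c("dim1", "dim2") %in% names(points)))
  cbind(points$dim1, points$dim2)
}

# Bivariate normal-reference (Silverman) bandwidth per axis, robust to heavy
# tails through the IQR variant, floored to stay positive on degenerate
# subsets.
silverman_bw <- function(p) {
  n <- nrow(p)
  vapply(1:2, function(j) {
    s <- min(sd(p[, j]), stats::IQR(p[, j]) / 1.349)
    if (!is.finite(s) || s <= 0) s <- max(sd(p[, j]), 1e-9)
    max(s * n^(-1 / 6), 1e-9)
  }, numeric(1))
}

#' Kernel-density acoustic space with highest-density-region area
#'
#' Estimates a Gaussian-kernel density for one subset of calls (one
#' individual in one recording block, or the pooled calls of three
#' flockmates) on a grid, normalizes it to unit mass, and marks the
#' highest-density region (HDR): the smallest-area set of cells whose
#' cumulated mass reaches `hdr_level`. The HDR area, in squared embedding
#' units, operationalizes the diversity of the call repertoire.
#'
#' @param points Subset coordinates (`dim1`/`dim2` tibble or 2-column
#'   matrix); at least 5 points.
#' @param grid A [space_grid()]; built from the points themselves when
#'   omitted (only valid if the space will not be compared to others).
#' @param hdr_level Probability mass of the HDR.
#' @param bandwidth Optional length-2 kernel sd override; defaults to the
#'   subset's own Silverman bandwidths.
#' @param key Optional label (individual/block) carried in the object.
#' @return Object of class `acoustic_space`: `grid`, `density` (matrix,
#'   rows = x), `hdr_mask` (logical matrix), `area`, `hdr_level`,
#'   `bandwidth`, `n`, `key`.
#' @export
kde_space <- function(points, grid = NULL, hdr_level = 0.95,
                      bandwidth = NULL, key = NULL) {
  p <- as_xy(points)
  if (nrow(p) < 5)
    stop("subset too small: kernel-density space needs at least 5 points, got ",
         nrow(p))
  bw <- bandwidth %||% silverman_bw(p)
  grid <- grid %||% space_grid(p)
  stopifnot(inherits(grid, "space_grid"))
  # MASS::kde2d's h is 4x the kernel sd
  z <- MASS::kde2d(p[, 1], p[, 2], h = 4 * bw,
                   n = c(length(grid$x), length(grid$y)),
                   lims = c(range(grid$x), range(grid$y)))$z
  total <- sum(z) * grid$cell_area
  if (total <= 0) stop("degenerate density: all mass outside the grid")
  z <- z / total
  mass <- z * grid$cell_area
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  n_in <- which(cum >= hdr_level)[1]
  if (is.na(n_in)) n_in <- length(ord)
  mask <- matrix(FALSE, nrow(z), ncol(z))
  mask[ord[seq_len(n_in)]] <- TRUE
  structure(list(grid = grid, density = z, hdr_mask = mask,
                 area = n_in * grid$cell_area, hdr_level = hdr_level,
                 bandwidth = bw, n = nrow(p), key = key),
            class = "acoustic_space")
}

#' @export
print.acoustic_space <- function(x, ...) {
  cat(sprintf(
    "<acoustic_space%s: n = %d, %d%% HDR area = %.3f units^2, grid %dx%d>\n",
    if (is.null(x$key)) "" else paste0(" ", paste(x$key, collapse = "/")),
    x$n, round(100 * x$hdr_level), x$area,
    length(x$grid$x), length(x$grid$y)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$grid$x, b$grid$x)) &&
    isTRUE(all.equal(a$grid$y, b$grid$y))
}

#' Directional density-weighted overlap between two acoustic spaces
#'
#' The share of space A's probability mass (restricted to A's own HDR) that
#' also lies inside B's HDR. Because the measure is A's density, overlap in
#' A's high-density cells counts for more than overlap in its sparse
#' margins; the self-overlap is exactly 1.
#'
#' @param a,b [kde_space()] objects on the same grid.
#' @return A proportion in \[0, 1\].
#' @export
directional_overlap <- function(a, b) {
  stopifnot(inherits(a, "acoustic_space"), inherits(b, "acoustic_space"))
  if (!same_grid(a, b))
    stop("acoustic spaces are on different grids; build them from one space_grid")
  mass_a <- a$density * a$grid$cell_area
  sum(mass_a[a$hdr_mask & b$hdr_mask]) / sum(mass_a[a$hdr_mask])
}

#' Pairwise mean overlap between two acoustic spaces
#'
#' The two directional overlaps are distinct quantities (the share of A
#' inside B and of B inside A); their arithmetic mean is the single
#' symmetric similarity used by the vocal plasticity and convergence
#' measures.
#'
#' @param a,b [kde_space()] objects on the same grid.
#' @return One-row tibble: `directional_ab`, `directional_ba`,
#'   `mean_overlap`.
#' @export
mean_overlap <- function(a, b) {
  ab <- directional_overlap(a, b)
  ba <- directional_overlap(b, a)
  tibble(directional_ab = ab, directional_ba = ba,
         mean_overlap = (ab + ba) / 2)
}
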