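#' Build the lattice geometry of the simulated cell
#'
#' The cell is a circle (default 30 um diameter) with a concentric circular
#' nucleus (default 10 um) on a square lattice of `patch_size` x `patch_size`
#' patches (default 0.5 um). Each patch is classified by the radial distance
#' of its centre: `nucleus` (<= nuclear radius), `cytosol` (in the annulus),
#' or `exterior`. Cytosol patches with at least one exterior 8-neighbour form
#' the `cytosol-border` ring that receives nutrient influx in the integrative
#' model.
#'
#' Coordinates are centre-origin in um; patch indices are 0-based with the
#' cell centre on a patch corner, so patch `(i, j)` has its centre at
#' `(-R + (i + 0.5) * patch_size, -R + (j + 0.5) * patch_size)` where `R` is
#' the cell radius.
#'
#' @param cell_diameter cell diameter in um (> 0)
#' @param nucleus_diameter nucleus diameter in um (>= 0, < cell diameter)
#' @param patch_size lattice spacing in um (> 0)
#' @return an object of class `grid_spec`: a list with the diameters, radii,
#'   lattice size `n`, patch-centre coordinate vectors, a label matrix
#'   (`"exterior"`, `"nucleus"`, `"cytosol"`), and logical masks `cytosol`
#'   and `border`.
#' @export
#' @examples
#' g <- build_grid(30, 10, 0.5)
#' sum(g$cytosol)         # number of cytosolic patches
#' region_of(g, c(0, 0))  # "nucleus"
build_grid <- function(cell_diameter = 30, nucleus_diameter = 10,
                       patch_size = 0.5) {
  if (!is.finite(cell_diameter) || cell_diameter <= 0)
    stop("invalid geometry: cell_diameter must be positive")
  if (!is.finite(patch_size) || patch_size <= 0)
    stop("invalid geometry: patch_size must be positive")
  if (!is.finite(nucleus_diameter) || nucleus_diameter < 0 ||
      nucleus_diameter >= cell_diameter)
    stop("invalid geometry: need 0 <= nucleus_diameter < cell_diameter")

  r_cell <- cell_diameter / 2
  r_nuc <- nucleus_diameter / 2
  n <- ceiling(cell_diameter / patch_size)
  # patch centres, 0-based indices, cell centre on a patch corner
  centers <- -r_cell + (seq_len(n) - 0.5) * patch_size
  cx <- matrix(centers, n, n)
  cy <- matrix(centers, n, n, byrow = TRUE)
  r <- sqrt(cx^2 + cy^2)

  label <- matrix("exterior", n, n)
  label[r <= r_cell] <- "cytosol"
  label[r <= r_nuc] <- "nucleus"
  cytosol <- label == "cytosol"

  # border ring: cytosol patches with >= 1 exterior 8-neighbour
  ext <- label == "exterior"
  pad <- matrix(TRUE, n + 2, n + 2)  # off-lattice counts as exterior
  pad[2:(n + 1), 2:(n + 1)] <- ext
  has_ext <- matrix(FALSE, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    has_ext <- has_ext | pad[(2 + di):(n + 1 + di), (2 + dj):(n + 1 + dj)]
  }
  border <- cytosol & has_ext

  # per-patch count of cytosolic 8-neighbours (used by nutrient diffusion)
  padc <- matrix(FALSE, n + 2, n + 2)
  padc[2:(n + 1), 2:(n + 1)] <- cytosol
  neigh_count <- matrix(0, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    neigh_count <- neigh_count +
      padc[(2 + di):(n + 1 + di), (2 + dj):(n + 1 + dj)]
  }

  structure(list(
    cell_diameter = cell_diameter, nucleus_diameter = nucleus_diameter,
    patch_size = patch_size, r_cell = r_cell, r_nuc = r_nuc, n = n,
    centers = centers, label = label, cytosol = cytosol, border = border,
    neigh_count = neigh_count, cyto_idx = which(cytosol)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> cell %g um, nucleus %g um, patch %g um (%d x %d lattice)\n",
    x$cell_diameter, x$nucleus_diameter, x$patch_size, x$n, x$n))
  cat(sprintf("  cytosol patches: %d (border ring: %d)\n",
              sum(x$cytosol), sum(x$border)))
  invisible(x)
}

#' Classify a point by cell region
#'
#' @param grid a `grid_spec`
#' @param pos numeric of length 2, `c(x, y)` in um, centre-origin
#' @return `"nucleus"`, `"cytosol"` or `"exterior"`
#' @export
region_of <- function(grid, pos) {
  r <- sqrt(pos[1]^2 + pos[2]^2)
  if (r <= grid$r_nuc) "nucleus"
  else if (r <= grid$r_cell) "cytosol"
  else "exterior"
}

#' Clamp a movement segment to the cytosolic annulus
#'
#' Vesicles neither enter the nucleus nor leave the cell. If the straight
#' segment `from -> to` crosses the nuclear envelope or the plasma membrane,
#' the returned position is the first crossing point on the violated
#' boundary; otherwise `to` is returned unchanged. Clamping is idempotent.
#'
#' @param grid a `grid_spec`
#' @param from,to numeric length-2 positions (um)
#' @return clamped position, numeric length 2
#' @export
clamp_move <- function(grid, from, to) {
  d <- to - from
  r_to2 <- sum(to^2)
  # outward crossing of the plasma membrane
  if (r_to2 > grid$r_cell^2)
    return(.segment_circle(from, d, grid$r_cell, outward = TRUE))
  # inward crossing of the nuclear envelope
  if (grid$r_nuc > 0 && r_to2 < grid$r_nuc^2)
    return(.segment_circle(from, d, grid$r_nuc, outward = FALSE))
  to
}

# boundary-crossing point of the segment from -> from + d: the relevant
# quadratic root (larger when leaving the cell, smaller when entering the
# nucleus), clipped to [0, 1] so that a boundary-hugging step stays put,
# then rescaled onto the circle against floating-point overshoot
.segment_circle <- function(from, d, radius, outward = TRUE) {
  a <- sum(d^2)
  if (a == 0) return(from)
  b <- 2 * sum(from * d)
  cc <- sum(from^2) - radius^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) disc <- 0
  t <- if (outward) (-b + sqrt(disc)) / (2 * a)
  else (-b - sqrt(disc)) / (2 * a)
  if (!is.finite(t)) t <- 0
  t <- min(max(t, 0), 1)
  p <- from + t * d
  r <- sqrt(sum(p^2))
  if (r > 0) p * (radius / r) else p
}

#' Sample uniform positions in the cytosolic annulus
#'
#' Area-uniform over the annulus between the nuclear and cell radii (inverse
#' transform in the radius, uniform angle). Consumes two uniform draws per
#' sample from the session RNG.
#'
#' @param grid a `grid_spec`
#' @param n number of positions
#' @return an `n x 2` matrix of positions (um)
#' @export
random_cytosol_position <- function(grid, n = 1) {
  u <- stats::runif(n)
  v <- stats::runif(n)
  r <- sqrt(u * (grid$r_cell^2 - grid$r_nuc^2) + grid$r_nuc^2)
  th <- 2 * pi * v
  cbind(x = r * cos(th), y = r * sin(th))
}

# 0-based patch index pair for positions (vectorised); positions outside the
# lattice are clipped onto it (can occur only by floating-point slop)
.patch_index <- function(grid, x, y) {
  i <- floor((x + grid$r_cell) / grid$patch_size)
  j <- floor((y + grid$r_cell) / grid$patch_size)
  i <- pmin(pmax(i, 0), grid$n - 1)
  j <- pmin(pmax(j, 0), grid$n - 1)
  cbind(i, j)
}

# linear (1-based, column-major, row = i+1) index into an n x n field matrix
.patch_linear <- function(grid, x, y) {
  ij <- .patch_index(grid, x, y)
  ij[, 1] + 1 + ij[, 2] * grid$n
}

# project a point radially into the cytosolic annulus (fusion midpoints can
# fall just inside the nuclear disk)
.project_annulus <- function(grid, x, y) {
  r <- sqrt(x^2 + y^2)
  if (r < grid$r_nuc) {
    if (r > 0) return(c(x, y) * (grid$r_nuc / r))
    return(c(grid$r_nuc, 0))
  }
  if (r > grid$r_cell) return(c(x, y) * (grid$r_cell / r))
  c(x, y)
}

# linear index of the cytosol patch receiving an agent's nutrient flux: the
# agent's own patch, or -- for positions on the nuclear/plasma boundary whose
# patch centre is classified off-cytosol -- the nearest cytosolic patch of
# its 3x3 neighbourhood (fixed scan order; global fallback never triggers
# for valid geometries)
.flux_patch_linear <- function(grid, x, y) {
  ij <- .patch_index(grid, x, y)
  i <- unname(ij[1, 1]); j <- unname(ij[1, 2])
  if (grid$cytosol[i + 1, j + 1]) return(i + 1 + j * grid$n)
  best <- -1L; bestd <- Inf
  for (di in -1:1) for (dj in -1:1) {
    ii <- i + di; jj <- j + dj
    if (ii < 0 || ii >= grid$n || jj < 0 || jj >= grid$n) next
    if (!grid$cytosol[ii + 1, jj + 1]) next
    d2 <- (x - grid$centers[ii + 1])^2 + (y - grid$centers[jj + 1])^2
    if (d2 < bestd) { bestd <- d2; best <- ii + 1L + jj * grid$n }
  }
  if (best > 0) return(best)
  idx <- grid$cyto_idx
  ii <- (idx - 1L) %% grid$n
  jj <- (idx - 1L) %/% grid$n
  d2 <- (x - grid$centers[ii + 1])^2 + (y - grid$centers[jj + 1])^2
  idx[which.min(d2)]
}

# vectorised flux patches for a pool (fast path: own patch is cytosolic)
.flux_patch_vec <- function(grid, x, y) {
  idx <- .patch_linear(grid, x, y)
  fix <- which(!grid$cytosol[idx])
  for (k in fix) idx[k] <- .flux_patch_linear(grid, x[k], y[k])
  idx
}
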