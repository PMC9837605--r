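#' Paired-samples t-map of two activation conditions
#'
#' Per voxel, a one-sample t statistic of the subject-wise differences
#' (aware minus unaware), df = n - 1. Zero-variance voxels are masked (t
#' undefined) and counted.
#'
#' @param aware_maps,unaware_maps 4D arrays (x, y, z, subject) on a common
#'   grid, equal subject counts.
#' @param voxel_mm Voxel size carried into downstream cluster volumes.
#' @return Object of class `eat_tmap`: list with 3D array `t`, `df`,
#'   `n_subjects`, `voxel_mm`, `n_masked`.
#' @export
paired_t_map <- function(aware_maps, unaware_maps, voxel_mm = 3) {
  da <- dim(aware_maps); du <- dim(unaware_maps)
  if (!identical(da, du)) stop("map dimensions differ between conditions")
  n <- da[4]
  if (n < 2L) stop("need at least 2 subjects")
  gs <- da[1:3]
  D <- matrix(aware_maps - unaware_maps, prod(gs), n)
  m <- rowMeans(D)
  s <- sqrt(rowSums((D - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[m == 0 & s == 0] <- 0          # identical conditions: no effect
  bad <- !is.finite(t)             # nonzero mean with zero variance
  t[bad] <- NA_real_
  out <- list(t = array(t, gs), df = n - 1L, n_subjects = n,
              voxel_mm = voxel_mm, n_masked = sum(bad))
  class(out) <- "eat_tmap"
  out
}

#' @export
print.eat_tmap <- function(x, ...) {
  cat(sprintf("paired t-map: %s grid, n = %d (df = %d), max |t| = %.2f\n",
              paste(dim(x$t), collapse = "x"), x$n_subjects, x$df,
              max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

# ---- connected components ---------------------------------------------------

# label connected components of a logical 3D mask; returns a list of integer
# vectors of linear voxel indices, one per component
label_components <- function(mask, connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  coord <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)

  pos <- seq_along(idx)
  parent <- pos
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }

  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    here <- pos[ok]
    hit <- match(nb_lin, idx)
    found <- !is.na(hit)
    for (q in which(found)) {
      a <- find(here[q]); b <- find(hit[q])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(pos, find, integer(1))
  split(idx, roots)
}

# half-space neighbor offsets are enough for union-find, but full sets keep
# the scan simple; 6 = faces, 18 = +edges, 26 = +corners
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity == 18L) g[rowSums(abs(g)) <= 2, , drop = FALSE]
  else g
}

max_cluster_size <- function(mask, connectivity = 6L) {
  comps <- label_components(mask, connectivity)
  if (!length(comps)) 0L else max(lengths(comps))
}

# one standardized smoothed null map
null_map <- function(grid, fwhm_mm, voxel_mm) {
  z <- array(stats::rnorm(prod(grid)), grid)
  if (fwhm_mm > 0) z <- smooth_volume(z, fwhm_mm, voxel_mm)
  (z - mean(z)) / stats::sd(z)
}

#' Monte Carlo null-cluster simulation and cluster-extent threshold selection
#'
#' Emulates the AFNI AlphaSim/3dClustSim procedure: on each iteration a
#' Gaussian white-noise volume is smoothed to the target FWHM, standardized
#' to unit variance, thresholded voxel-wise (two-tailed) at `voxel_p`, and
#' the maximum suprathreshold cluster size under the chosen connectivity is
#' recorded. The selected cluster-extent threshold is the smallest size whose
#' exceedance frequency over iterations is at most `alpha` (family-wise
#' control over the whole volume).
#'
#' @param grid Length-3 grid dimensions.
#' @param voxel_mm Voxel size (mm).
#' @param fwhm_mm Spatial smoothness of the null field (mm).
#' @param voxel_p Two-tailed voxel-wise p threshold.
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Integer seed.
#' @param alpha Corrected (family-wise) level.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @return Object of class `null_cluster_dist`: list with `max_sizes`,
#'   `threshold_voxels`, `threshold_uL`, `alpha`, and the simulation
#'   settings.
#' @export
simulate_null_clusters <- function(grid = c(24L, 24L, 18L), voxel_mm = 3,
                                   fwhm_mm = 6, voxel_p = 0.001,
                                   n_iter = 10000L, seed = 1L,
                                   alpha = 0.010, connectivity = 6L) {
  stopifnot(voxel_p > 0, voxel_p < 1, n_iter >= 100L)
  if (alpha < 1 / n_iter)
    stop("alpha below Monte Carlo resolution (1/n_iter); increase n_iter")
  zthr <- stats::qnorm(1 - voxel_p / 2)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  max_sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    z <- null_map(grid, fwhm_mm, voxel_mm)
    max_sizes[i] <- max_cluster_size(abs(z) >= zthr, connectivity)
  }
  threshold <- select_extent_threshold(max_sizes, alpha)
  out <- list(max_sizes = max_sizes, threshold_voxels = threshold,
              threshold_uL = threshold * voxel_mm^3,
              alpha = alpha, grid = grid, voxel_mm = voxel_mm,
              fwhm_mm = fwhm_mm, voxel_p = voxel_p, n_iter = n_iter,
              connectivity = connectivity)
  class(out) <- "null_cluster_dist"
  out
}

# smallest cluster size s with empirical P(max >= s) <= alpha
select_extent_threshold <- function(max_sizes, alpha) {
  for (s in seq_len(max(max_sizes) + 1L))
    if (mean(max_sizes >= s) <= alpha) return(s)
  1L
}

#' @export
print.null_cluster_dist <- function(x, ...) {
  cat(sprintf("null cluster distribution: %d iterations on %s grid (%g mm FWHM)\n",
              x$n_iter, paste(x$grid, collapse = "x"), x$fwhm_mm))
  cat(sprintf("  voxel p = %g (two-tailed); extent threshold %d voxels = %g uL at corrected alpha %g\n",
              x$voxel_p, x$threshold_voxels, x$threshold_uL, x$alpha))
  invisible(x)
}

#' Empirical family-wise rate of a selected extent threshold on fresh null maps
#'
#' Generates independent smoothed null maps and reports the fraction showing
#' any suprathreshold cluster at or above the given extent, i.e. the
#' realized family-wise false-positive rate of the selected threshold.
#'
#' @param dist A `null_cluster_dist` (supplies grid, smoothness, thresholds).
#' @param n_maps Number of fresh null maps.
#' @param seed Integer seed (independent of the selection seed).
#' @return List with `rate`, `n_maps`, `n_detected`.
#' @export
null_cluster_rate <- function(dist, n_maps = 1000L, seed = 2L) {
  zthr <- stats::qnorm(1 - dist$voxel_p / 2)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_maps)) {
    z <- null_map(dist$grid, dist$fwhm_mm, dist$voxel_mm)
    if (max_cluster_size(abs(z) >= zthr, dist$connectivity) >=
        dist$threshold_voxels) hits <- hits + 1L
  }
  list(rate = hits / n_maps, n_maps = n_maps, n_detected = hits)
}

#' Extract suprathreshold clusters from a t-map
#'
#' Connected components of voxels with `|t| >= t_threshold` under the chosen
#' connectivity; components smaller than `min_volume_uL` are discarded
#' (1 voxel of `v` mm isotropic = `v^3` uL). The center of mass is the
#' |t|-weighted mean of world coordinates (RAS+, `origin + index * voxel_mm`
#' with 0-based indices); hemisphere is taken from the sign of world x.
#'
#' @param tmap An `eat_tmap`.
#' @param t_threshold Voxel-wise |t| threshold.
#' @param min_volume_uL Minimum cluster volume in microliters.
#' @param connectivity 6, 18 or 26.
#' @param origin_mm World coordinate of voxel (0,0,0); defaults to centering
#'   the grid on 0.
#' @return A `cluster_table` data.frame: `cluster`, `n_voxels`, `volume_uL`,
#'   `hemisphere`, `x`, `y`, `z`, `peak_t`; voxel linear indices attached as
#'   attribute `voxel_indices` (list).
#' @export
extract_clusters <- function(tmap, t_threshold, min_volume_uL = 250,
                             connectivity = 6L, origin_mm = NULL) {
  stopifnot(t_threshold > 0, min_volume_uL >= 0)
  gs <- dim(tmap$t)
  vox_uL <- tmap$voxel_mm^3
  if (is.null(origin_mm)) origin_mm <- -(gs - 1) / 2 * tmap$voxel_mm
  tval <- tmap$t
  mask <- !is.na(tval) & abs(tval) >= t_threshold
  comps <- label_components(mask, connectivity)
  comps <- comps[order(-lengths(comps))]
  rows <- list(); vox <- list()
  for (cc in comps) {
    vol <- length(cc) * vox_uL
    if (vol < min_volume_uL) next
    w <- abs(tval[cc])
    xyz <- arrayInd(cc, gs) - 1L
    world <- sweep(xyz * tmap$voxel_mm, 2, origin_mm, "+")
    com <- colSums(world * w) / sum(w)
    rows[[length(rows) + 1L]] <- data.frame(
      n_voxels = length(cc), volume_uL = vol,
      hemisphere = if (com[1] < 0) "L" else "R",
      x = com[1], y = com[2], z = com[3],
      peak_t = tval[cc][which.max(w)])
    vox[[length(vox) + 1L]] <- cc
  }
  tab <- if (length(rows)) cbind(cluster = seq_along(rows), do.call(rbind, rows))
  else data.frame(cluster = integer(0), n_voxels = integer(0),
                  volume_uL = numeric(0), hemisphere = character(0),
                  x = numeric(0), y = numeric(0), z = numeric(0),
                  peak_t = numeric(0))
  attr(tab, "voxel_indices") <- vox
  attr(tab, "grid") <- gs
  class(tab) <- c("cluster_table", class(tab))
  tab
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("cluster table:", nrow(x), "suprathreshold clusters\n")
  if (nrow(x)) print.data.frame(format(as.data.frame(x), digits = 3))
  invisible(x)
}
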