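#' Per-subject mean activation within clusters
#'
#' Unweighted mean of each subject's percent-area activation over every
#' cluster's voxels, per condition (the 3DRoiStats step of the workflow).
#'
#' @param activation 4D array (x, y, z, subject) of per-subject activation
#'   maps for one condition, or a named list of such arrays (one per
#'   condition).
#' @param cluster_table A `cluster_table` from [extract_clusters()] carrying
#'   voxel indices on the same grid.
#' @return If `activation` is an array: subjects x clusters matrix. If a
#'   list: named list of such matrices.
#' @export
cluster_means <- function(activation, cluster_table) {
  vox <- attr(cluster_table, "voxel_indices")
  if (!length(vox)) stop("cluster table has no clusters (empty mask)")
  if (is.list(activation) && !is.array(activation))
    return(lapply(activation, cluster_means, cluster_table = cluster_table))
  d <- dim(activation)
  if (!identical(as.integer(d[1:3]), as.integer(attr(cluster_table, "grid"))))
    stop("activation maps and clusters are on different grids")
  M <- matrix(activation, prod(d[1:3]), d[4])
  out <- vapply(vox, function(ix) colMeans(M[ix, , drop = FALSE]),
                numeric(d[4]))
  if (is.null(dim(out))) out <- matrix(out, nrow = d[4])
  colnames(out) <- paste0("cluster", seq_along(vox))
  out
}

#' Brain-behavior Spearman correlations with Holm adjustment
#'
#' Spearman correlations between cluster activity estimates and behavioral
#' indices, with Holm adjustment applied within each declared family (by
#' default, one family per behavioral index across clusters/conditions).
#' Subjects with missing values are dropped pairwise and the retained count
#' reported.
#'
#' @param roi Named list or matrix of per-subject ROI estimates: a
#'   subjects x variables matrix (columns are cluster/condition estimates).
#' @param behavior Subjects x indices data.frame or matrix of behavioral
#'   measures.
#' @param pairs Optional data.frame with columns `roi`, `behavior` selecting
#'   pairs to test; defaults to all combinations.
#' @return Data.frame with `roi`, `behavior`, `rho`, `p`, `p_holm`, `n`;
#'   Holm families are the behavioral indices.
#' @export
behavior_correlations <- function(roi, behavior, pairs = NULL) {
  roi <- as.matrix(roi)
  behavior <- as.data.frame(behavior)
  if (nrow(roi) != nrow(behavior))
    stop("subject counts differ between ROI estimates and behavior")
  if (is.null(pairs))
    pairs <- expand.grid(roi = colnames(roi), behavior = names(behavior),
                         stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- roi[, pairs$roi[i]]
    y <- behavior[[pairs$behavior[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L)
      return(data.frame(roi = pairs$roi[i], behavior = pairs$behavior[i],
                        rho = NA_real_, p = NA_real_, n = sum(ok)))
    s <- spearman_rho(x[ok], y[ok])
    data.frame(roi = pairs$roi[i], behavior = pairs$behavior[i],
               rho = s$rho, p = s$p, n = s$n)
  })
  out <- do.call(rbind, res)
  out$p_holm <- NA_real_
  for (fam in unique(out$behavior)) {
    i <- which(out$behavior == fam & !is.na(out$p))
    if (length(i)) out$p_holm[i] <- holm_adjust(out$p[i])
  }
  out
}
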