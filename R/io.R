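#' Write / read BIDS-style events.tsv
#'
#' Columns: `onset` (s), `duration` (s), `trial_type`, `block`, `word`,
#' `ink`. Indices are 0-based; decimals use dots regardless of locale.
#'
#' @param seq An `eat_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(seq, path) {
  tr <- seq$trials
  df <- data.frame(onset = tr$onset_s,
                   duration = trial_dur_s(seq$config),
                   trial_type = tr$trial_type, block = tr$block,
                   word = tr$word, ink = tr$ink)
  write_tsv(df, path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read_tsv(path, c("onset", "duration", "trial_type", "block"))
  df
}

#' Write / read a subject response log
#'
#' @param resp An `eat_responses`.
#' @param path Output path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_responses_tsv <- function(resp, path) {
  write_tsv(as.data.frame(resp), path)
}

#' @rdname write_responses_tsv
#' @export
read_responses_tsv <- function(path) {
  df <- read_tsv(path, c("trial_index", "button", "rt_ms"))
  df
}

#' Write a per-trial outcome table
#'
#' One row per trial with the classified outcome and omission/anomalous
#' flags.
#'
#' @param outcomes An `eat_outcomes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes_tsv <- function(outcomes, path) {
  write_tsv(as.data.frame(outcomes), path)
}

#' Write / read a questionnaire trait matrix
#'
#' The header row must carry all 22 subscale labels from
#' [trait_subscales()]; the reader names any missing column explicitly.
#'
#' @param traits Subjects x 22 matrix.
#' @param path File path.
#' @return `path` invisibly (writer); matrix with a `missing` attribute
#'   (reader).
#' @export
write_traits_tsv <- function(traits, path) {
  df <- as.data.frame(traits, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_traits_tsv
#' @export
read_traits_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, sep = "\t")
  missing_cols <- setdiff(trait_subscales(), names(df))
  if (length(missing_cols))
    stop("traits file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(df[, trait_subscales()])
  attr(m, "missing") <- !stats::complete.cases(m)
  m
}

#' Write / read a 4D BOLD run as NIfTI-1
#'
#' Voxel size and repetition time are stored in the header (`pixdim`); the
#' reader checks both round-trip. Subjects of one cohort must share a grid;
#' mismatches raise an alignment error.
#'
#' @param bold An `eat_bold` (or a plain 3D/4D array plus `voxel_mm`,
#'   `tr_s`).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm,tr_s Geometry when `bold` is a plain array.
#' @return `path` invisibly (writer); an `eat_bold` (reader).
#' @export
write_bold_nifti <- function(bold, path, voxel_mm = NULL, tr_s = NULL) {
  if (inherits(bold, "eat_bold")) {
    arr <- bold$data; voxel_mm <- bold$voxel_mm; tr_s <- bold$tr_s
  } else arr <- bold
  img <- RNifti::asNifti(unclass(arr))
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3),
                           if (length(dim(arr)) == 4L) tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param expect_grid Optional grid dimensions to enforce on read.
#' @export
read_bold_nifti <- function(path, expect_grid = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (!is.null(expect_grid) &&
      !identical(as.integer(d[1:3]), as.integer(expect_grid)))
    stop("grid alignment error: volume is ", paste(d[1:3], collapse = "x"),
         ", expected ", paste(expect_grid, collapse = "x"))
  out <- list(data = unclass(as.array(img)),
              # pixdim is stored as float32; drop the excess binary digits
              voxel_mm = signif(pd[1], 7),
              tr_s = if (length(pd) >= 4L) signif(pd[4], 7) else NA_real_,
              n_volumes = if (length(d) == 4L) d[4] else 1L)
  class(out) <- "eat_bold"
  out
}

#' Write a cluster table TSV
#'
#' Columns mirror a standard cluster report: structure label (blank,
#' user-supplied), volume in microliters, hemisphere, and center-of-mass
#' world coordinates.
#'
#' @param tab A `cluster_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(tab, path) {
  df <- data.frame(structure = "", vol_uL = tab$volume_uL,
                   hemisphere = tab$hemisphere,
                   x = round(tab$x, 1), y = round(tab$y, 1),
                   z = round(tab$z, 1), peak_t = round(tab$peak_t, 2))
  write_tsv(df, path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, required_cols) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop("file ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

# ---- configuration ----------------------------------------------------------

#' Default pipeline configuration
#'
#' Nested configuration mirroring every module's parameter set, with one
#' global root seed feeding named per-module substreams.
#'
#' @return Named nested list of class `eat_config`.
#' @export
default_pipeline_config <- function() {
  cfg <- list(
    seed = 1L,
    n_subjects = 10L,
    task = list(n_blocks = 6L, trials_per_block = 175L, n_nogo_total = 150L,
                stim_ms = 900, isi_ms = 600, min_gap = 1L, max_gap = 12L,
                interblock_rest_s = 30),
    behavior = list(p_inhibit = 0.536, p_aware = 0.865, go_rt_mean_ms = 518,
                    go_rt_sd_ms = 81, aware_rt_shift_ms = -29,
                    unaware_rt_shift_ms = -10, p_omission = 0.02,
                    post_unaware_slow_ms = 19),
    neuro = list(grid_shape = c(24L, 24L, 18L), voxel_mm = 3, tr_s = 2.46,
                 noise_sd = 1, ar1_rho = 0.3, drift_amp = 2,
                 smooth_fwhm_mm = 6),
    traits = list(rho_within = 0.4, rho_between = 0.1, mcar_rate = 20 / 402),
    analysis = list(fir_window_s = 8 * 2.46, drift_order = 3L,
                    voxel_p = 0.001, alpha = 0.010, n_iter_cluster = 2000L,
                    connectivity = 6L, min_volume_uL = NULL,
                    n_boot = 500L))
  class(cfg) <- c("eat_config", class(cfg))
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values override the defaults of [default_pipeline_config()]; unknown keys
#' are rejected by name.
#'
#' @param path YAML file.
#' @return An `eat_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_pipeline_config())
  merged <- merge_config(cfg, user, prefix = "")
  class(merged) <- c("eat_config", class(merged))
  merged
}

merge_config <- function(base, user, prefix) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(prefix, nm, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Write the resolved configuration used by a run
#'
#' @param cfg An `eat_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
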