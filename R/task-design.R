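#' Error Awareness Task configuration
#'
#' Builds the design configuration of the Error Awareness Task (EAT): a serial
#' Go/No-Go paradigm in which color words are shown in an incongruent ink color
#' (Go trials, left button press) or a congruent ink color (No-Go trials,
#' response withheld). Defaults reproduce the published task: 6 blocks of 175
#' trials, 150 No-Go trials in total, 900 ms stimuli with a 600 ms
#' inter-stimulus interval, and between 1 and 12 Go trials separating
#' consecutive No-Go trials.
#'
#' @param n_blocks Number of task blocks.
#' @param trials_per_block Trials per block.
#' @param n_nogo_total Total number of No-Go trials across all blocks.
#' @param stim_ms Stimulus duration in milliseconds.
#' @param isi_ms Inter-stimulus interval in milliseconds.
#' @param min_gap Minimum number of Go trials between consecutive No-Go trials.
#' @param max_gap Maximum number of Go trials between consecutive No-Go trials.
#' @param interblock_rest_s Rest period between blocks, in seconds.
#' @param rng_seed Integer seed controlling the pseudorandom No-Go placement.
#' @return An object of class `eat_task_config` (a named list).
#' @export
eat_task_config <- function(n_blocks = 6L, trials_per_block = 175L,
                            n_nogo_total = 150L, stim_ms = 900, isi_ms = 600,
                            min_gap = 1L, max_gap = 12L,
                            interblock_rest_s = 30, rng_seed = 1L) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              n_nogo_total = as.integer(n_nogo_total),
              stim_ms = stim_ms, isi_ms = isi_ms,
              min_gap = as.integer(min_gap), max_gap = as.integer(max_gap),
              interblock_rest_s = interblock_rest_s,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "eat_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  n_trials <- cfg$n_blocks * cfg$trials_per_block
  if (cfg$n_nogo_total > n_trials)
    stop("infeasible config: n_nogo_total (", cfg$n_nogo_total,
         ") exceeds total trials (", n_trials, ")")
  if (cfg$min_gap < 1L)
    stop("infeasible config: min_gap must be >= 1, got ", cfg$min_gap)
  if (cfg$max_gap < cfg$min_gap)
    stop("infeasible config: max_gap (", cfg$max_gap,
         ") < min_gap (", cfg$min_gap, ")")
  n_go <- n_trials - cfg$n_nogo_total
  if (cfg$n_nogo_total > 1L && cfg$min_gap * (cfg$n_nogo_total - 1L) > n_go)
    stop("infeasible config: min_gap * (n_nogo - 1) = ",
         cfg$min_gap * (cfg$n_nogo_total - 1L),
         " exceeds the number of Go trials (", n_go, ")")
  invisible(cfg)
}

#' @export
print.eat_task_config <- function(x, ...) {
  cat("EAT task configuration\n")
  cat(sprintf("  %d blocks x %d trials; %d No-Go / %d Go\n",
              x$n_blocks, x$trials_per_block, x$n_nogo_total,
              x$n_blocks * x$trials_per_block - x$n_nogo_total))
  cat(sprintf("  stimulus %g ms + ISI %g ms; Go-run gaps in [%d, %d]\n",
              x$stim_ms, x$isi_ms, x$min_gap, x$max_gap))
  invisible(x)
}

# trial duration in seconds
trial_dur_s <- function(cfg) (cfg$stim_ms + cfg$isi_ms) / 1000

# absolute start time (s) of each block, rests interleaved
block_starts_s <- function(cfg) {
  block_len <- cfg$trials_per_block * trial_dur_s(cfg)
  (seq_len(cfg$n_blocks) - 1L) * (block_len + cfg$interblock_rest_s)
}

#' Total run duration and volume count implied by a task configuration
#'
#' @param cfg An [eat_task_config()].
#' @param tr_s Repetition time in seconds.
#' @return A list with `duration_s` and `n_volumes`.
#' @export
run_geometry <- function(cfg, tr_s = 2.46) {
  block_len <- cfg$trials_per_block * trial_dur_s(cfg)
  dur <- cfg$n_blocks * block_len +
    (cfg$n_blocks - 1L) * cfg$interblock_rest_s
  list(duration_s = dur, n_volumes = as.integer(ceiling(dur / tr_s)))
}

eat_palette <- c("red", "green", "blue", "yellow")

#' Generate an EAT trial sequence
#'
#' Places No-Go trials pseudorandomly among Go trials subject to the design
#' constraints: exact Go/No-Go counts, every run of Go trials between
#' consecutive No-Go trials within `[min_gap, max_gap]` (gaps are counted
#' across block boundaries over Go trials only), and no No-Go trial as the
#' first trial of a block (so a preceding Go reaction time always exists).
#' Inter-No-Go gaps are drawn uniformly from `[min_gap, max_gap]` and then
#' adjusted by random unit moves, within bounds, until the total Go count is
#' met.
#'
#' Trial onsets are deterministic: trial `k` within a block starts at
#' `block_start + k * (stim_ms + isi_ms) / 1000` seconds, with an
#' `interblock_rest_s` rest between blocks. Color-word and ink labels are
#' cosmetic; ink matches the word exactly on (congruent) No-Go trials.
#'
#' @param config An [eat_task_config()].
#' @return An object of class `eat_sequence`: list with `config` and a
#'   data.frame `trials` (columns `block`, `trial_index`, `trial_type`,
#'   `onset_s`, `word`, `ink`, `congruent`).
#' @export
generate_sequence <- function(config = eat_task_config()) {
  validate_task_config(config)
  cfg <- config
  n_trials <- cfg$n_blocks * cfg$trials_per_block
  n_nogo <- cfg$n_nogo_total
  n_go <- n_trials - n_nogo

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(cfg$rng_seed)

  nogo_pos <- if (n_nogo > 0L) sample_nogo_positions(cfg) else integer(0)

  trial_type <- rep("go", n_trials)
  trial_type[nogo_pos] <- "nogo"
  word <- sample(eat_palette, n_trials, replace = TRUE)
  ink <- vapply(seq_len(n_trials), function(i) {
    if (trial_type[i] == "nogo") word[i]
    else sample(setdiff(eat_palette, word[i]), 1L)
  }, character(1))

  block <- rep(seq_len(cfg$n_blocks), each = cfg$trials_per_block)
  within_idx <- rep(seq_len(cfg$trials_per_block) - 1L, cfg$n_blocks)
  onset <- block_starts_s(cfg)[block] + within_idx * trial_dur_s(cfg)

  trials <- data.frame(block = block,
                       trial_index = seq_len(n_trials) - 1L,
                       trial_type = trial_type,
                       onset_s = onset,
                       word = word, ink = ink,
                       congruent = trial_type == "nogo",
                       stringsAsFactors = FALSE)
  out <- list(config = cfg, trials = trials)
  class(out) <- "eat_sequence"
  out
}

# Draw global No-Go positions (1-based over the whole run).
# Gap vector g[1..n_nogo]: g[1] = Go trials before the first No-Go (>= 1 so a
# block never opens with a No-Go), g[i>1] = Go trials between No-Go i-1 and i,
# constrained to [min_gap, max_gap]; trailing Go trials are free.
sample_nogo_positions <- function(cfg) {
  n_trials <- cfg$n_blocks * cfg$trials_per_block
  n_nogo <- cfg$n_nogo_total
  n_go <- n_trials - n_nogo
  starts <- (seq_len(cfg$n_blocks) - 1L) * cfg$trials_per_block + 1L

  for (attempt in seq_len(2000L)) {
    inner <- if (n_nogo > 1L)
      sample(seq.int(cfg$min_gap, cfg$max_gap), n_nogo - 1L, replace = TRUE)
    else integer(0)
    lead <- sample.int(min(cfg$max_gap, max(1L, n_go - sum(inner))), 1L)
    gaps <- c(lead, inner)
    # random unit moves within bounds until the gaps fit the Go budget;
    # a trailing Go run is reserved so the run does not end on a No-Go
    lo <- c(1L, rep(cfg$min_gap, length(inner)))
    hi <- rep(cfg$max_gap, length(gaps))
    trail <- sample.int(cfg$max_gap + 1L, 1L) - 1L
    budget <- max(sum(lo), n_go - trail)
    for (step in seq_len(50000L)) {
      excess <- sum(gaps) - budget
      if (excess <= 0L) break
      j <- sample.int(length(gaps), 1L)
      if (gaps[j] > lo[j]) gaps[j] <- gaps[j] - 1L
    }
    if (sum(gaps) > budget) next
    pos <- cumsum(gaps + 1L)  # each No-Go sits after its gap of Go trials
    if (max(pos) > n_trials) next
    if (any(pos %in% starts)) {
      # a No-Go landed on a block start: nudge it back one slot if the
      # preceding gap allows, else retry
      bad <- which(pos %in% starts)
      ok <- TRUE
      for (b in bad) {
        if (gaps[b] - 1L >= lo[b] && (b == length(pos) ||
                                      pos[b] + 1L < pos[b + 1L])) {
          gaps[b] <- gaps[b] - 1L
          if (b < length(gaps)) gaps[b + 1L] <- gaps[b + 1L] + 1L
          pos <- cumsum(gaps + 1L)
        } else { ok <- FALSE; break }
      }
      if (!ok || any(pos %in% starts) ||
          any(gaps > hi) || any(gaps < lo)) next
    }
    return(pos)
  }
  stop("failed to place No-Go trials after 2000 attempts; ",
       "check gap bounds against the Go budget")
}

#' @export
print.eat_sequence <- function(x, ...) {
  tt <- table(x$trials$trial_type)
  cat("EAT trial sequence:", nrow(x$trials), "trials (",
      tt[["nogo"]], "No-Go,", tt[["go"]], "Go ) in",
      x$config$n_blocks, "blocks\n")
  cat(sprintf("  run length %.1f s\n", run_geometry(x$config)$duration_s))
  invisible(x)
}

#' Validate an EAT trial sequence against its design constraints
#'
#' Checks Go/No-Go counts, inter-No-Go gap bounds, onset arithmetic,
#' congruency coding, and the no-No-Go-at-block-start rule. Validation never
#' raises on content; it returns a report.
#'
#' @param seq An `eat_sequence`.
#' @return An object of class `eat_validation`: a data.frame with columns
#'   `constraint`, `location`, `observed` (zero rows when the sequence is
#'   valid), with the inter-No-Go gap lengths attached as attribute `gaps`.
#' @export
validate_sequence <- function(seq) {
  cfg <- seq$config
  tr <- seq$trials
  bad <- list()
  note <- function(constraint, location, observed)
    bad[[length(bad) + 1L]] <<- data.frame(constraint = constraint,
                                           location = location,
                                           observed = observed,
                                           stringsAsFactors = FALSE)

  n_nogo <- sum(tr$trial_type == "nogo")
  n_go <- sum(tr$trial_type == "go")
  if (n_nogo != cfg$n_nogo_total)
    note("nogo_count", NA_integer_, n_nogo)
  if (n_go != cfg$n_blocks * cfg$trials_per_block - cfg$n_nogo_total)
    note("go_count", NA_integer_, n_go)

  gaps <- integer(0)
  nogo_idx <- which(tr$trial_type == "nogo")
  if (length(nogo_idx) > 1L) {
    gaps <- diff(nogo_idx) - 1L
    viol <- which(gaps < cfg$min_gap | gaps > cfg$max_gap)
    for (v in viol) note("gap_bounds", nogo_idx[v + 1L] - 1L, gaps[v])
  }
  starts <- (seq_len(cfg$n_blocks) - 1L) * cfg$trials_per_block + 1L
  at_start <- intersect(nogo_idx, starts)
  for (i in at_start) note("nogo_at_block_start", i - 1L, 1)

  expected_onset <- block_starts_s(cfg)[tr$block] +
    (tr$trial_index %% cfg$trials_per_block) * trial_dur_s(cfg)
  off <- which(abs(tr$onset_s - expected_onset) > 1e-9)
  for (i in off) note("onset_arithmetic", i - 1L, tr$onset_s[i])

  incong <- which((tr$trial_type == "nogo") != tr$congruent |
                    (tr$trial_type == "nogo") != (tr$word == tr$ink))
  for (i in incong) note("congruency_coding", i - 1L, tr$congruent[i])

  rep <- if (length(bad)) do.call(rbind, bad)
  else data.frame(constraint = character(0), location = integer(0),
                  observed = numeric(0))
  attr(rep, "gaps") <- gaps
  class(rep) <- c("eat_validation", class(rep))
  rep
}

#' @export
print.eat_validation <- function(x, ...) {
  if (nrow(x) == 0L) cat("sequence valid: no constraint violations\n")
  else { cat("constraint violations:\n"); print.data.frame(x) }
  invisible(x)
}

# ---- seeding utilities ------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Derive a named sub-seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams, so partial re-runs of a module are reproducible. The derived
#' seed is a deterministic 31-bit hash of the root seed and the stream name.
#'
#' @param root_seed Integer root seed.
#' @param stream Character stream name (e.g. `"behavior"`, `"bold"`).
#' @param index Optional integer (e.g. a subject number).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(root_seed, stream, index = 0L) {
  h <- as.double(root_seed %% 2147483647L)
  for (ch in c(utf8ToInt(stream), as.integer(index) %% 2147483647L))
    h <- (h * 31 + as.double(ch)) %% 2147483647
  as.integer(h %% 2147483546 + 1)
}
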