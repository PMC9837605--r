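# shared fixtures and independent oracles, built in code

# hand-built sequence: one or more blocks, explicit trial types
toy_sequence <- function(types, trials_per_block = length(types),
                         stim_ms = 900, isi_ms = 600,
                         interblock_rest_s = 30) {
  n_blocks <- length(types) / trials_per_block
  stopifnot(n_blocks == round(n_blocks))
  cfg <- list(n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              n_nogo_total = sum(types == "nogo"),
              stim_ms = stim_ms, isi_ms = isi_ms,
              min_gap = 1L, max_gap = 12L,
              interblock_rest_s = interblock_rest_s, rng_seed = 1L)
  class(cfg) <- "eat_task_config"
  dur <- (stim_ms + isi_ms) / 1000
  block <- rep(seq_len(n_blocks), each = trials_per_block)
  within <- rep(seq_len(trials_per_block) - 1L, n_blocks)
  block_start <- (block - 1L) * (trials_per_block * dur + interblock_rest_s)
  word <- rep("red", length(types))
  ink <- ifelse(types == "nogo", "red", "blue")
  out <- list(config = cfg,
              trials = data.frame(block = block,
                                  trial_index = seq_along(types) - 1L,
                                  trial_type = types,
                                  onset_s = block_start + within * dur,
                                  word = word, ink = ink,
                                  congruent = types == "nogo",
                                  stringsAsFactors = FALSE))
  class(out) <- "eat_sequence"
  out
}

# hand-built response log
toy_responses <- function(buttons, rts = NULL, subject_id = "toy") {
  if (is.null(rts)) rts <- ifelse(buttons == "none", NA_real_, 500)
  rts[buttons == "none"] <- NA_real_
  out <- data.frame(trial_index = seq_along(buttons) - 1L,
                    button = buttons, rt_ms = rts, stringsAsFactors = FALSE)
  attr(out, "subject_id") <- subject_id
  class(out) <- c("eat_responses", class(out))
  out
}

# independent run-length scan: Go runs strictly between consecutive No-Go
gap_scan <- function(types) {
  nogo <- which(types == "nogo")
  if (length(nogo) < 2L) return(integer(0))
  diff(nogo) - 1L
}

# brute-force BFS flood fill over a logical 3D mask
flood_fill_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  offs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, ],
                 "18" = offs[rowSums(abs(offs)) <= 2, ],
                 "26" = offs)
  todo <- which(mask)
  seen <- logical(length(mask))
  comps <- list()
  for (start in todo) {
    if (seen[start]) next
    queue <- start; seen[start] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      co <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        nb <- co + as.integer(offs[o, ])
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask[lin] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# canonical form for comparing component partitions
canon_components <- function(comps) {
  comps <- unname(lapply(comps, function(x) sort(as.integer(x))))
  comps[order(vapply(comps, min, numeric(1)))]
}

region_linear_idx <- function(region, gs)
  1L + region$mask[, 1] + gs[1] * (region$mask[, 2] + gs[2] * region$mask[, 3])
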