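# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are written as explicit per-sample / per-element scans so
# they share no code path with the implementations they check.

# Brute-force burst detector: explicit loops for the quietest-baseline
# threshold, supra-threshold run building, gap merging and peak picking.
brute_force_bursts <- function(x, fs, t0_s, k = 3, merge_ms = 20,
                               baseline_ms = 100) {
  n <- length(x)
  w <- as.integer(round(baseline_ms / 1000 * fs))
  best_mean <- Inf; best_start <- 1L
  for (s in 1:(n - w + 1)) {
    m <- 0
    for (j in s:(s + w - 1)) m <- m + x[j]
    m <- m / w
    if (m < best_mean) { best_mean <- m; best_start <- s }
  }
  win <- x[best_start:(best_start + w - 1)]
  thr <- mean(win) + k * sd(win)

  runs <- list()
  in_run <- FALSE
  for (i in 1:n) {
    if (x[i] > thr) {
      if (!in_run) { start <- i; in_run <- TRUE }
      end <- i
    } else if (in_run) {
      runs[[length(runs) + 1]] <- c(start, end)
      in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1]] <- c(start, end)
  if (length(runs) == 0) {
    return(data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      peak_ms = numeric(), peak_amp = numeric()))
  }
  gap_samp <- merge_ms / 1000 * fs
  merged <- list(runs[[1]])
  if (length(runs) > 1) {
    for (i in 2:length(runs)) {
      last <- merged[[length(merged)]]
      gap <- runs[[i]][1] - last[2] - 1L
      if (gap < gap_samp) {
        merged[[length(merged)]] <- c(last[1], runs[[i]][2])
      } else {
        merged[[length(merged) + 1]] <- runs[[i]]
      }
    }
  }
  t_ms <- (t0_s + (seq_len(n) - 1) / fs) * 1000
  out <- lapply(merged, function(r) {
    pk <- r[1]; best <- x[r[1]]
    for (j in r[1]:r[2]) if (x[j] > best) { best <- x[j]; pk <- j }
    data.frame(onset_ms = t_ms[r[1]], offset_ms = t_ms[r[2]],
               peak_ms = t_ms[pk], peak_amp = x[pk])
  })
  do.call(rbind, out)
}

# Brute-force integration SSRT: augmented, selection-sorted by repeated
# minimum extraction, then 1-based rank indexing.
brute_force_ssrt <- function(go_rts, n_omissions, p_respond, mean_ssd) {
  slowest <- go_rts[1]
  for (v in go_rts) if (v > slowest) slowest <- v
  aug <- c(go_rts, rep(slowest, n_omissions))
  sorted <- numeric(0)
  while (length(aug) > 0) {
    i_min <- 1
    for (i in seq_along(aug)) if (aug[i] < aug[i_min]) i_min <- i
    sorted <- c(sorted, aug[i_min])
    aug <- aug[-i_min]
  }
  rank <- ceiling(p_respond * length(sorted))
  sorted[rank] - mean_ssd
}

# A deterministic rectangular envelope trace (no filtering needed) with a
# flat near-zero baseline; handy for burst-rule unit tests.
rect_envelope <- function(n = 2000, fs = 2000, t0_s = -0.1, bumps = list()) {
  x <- rep(0.001, n)
  t_ms <- (t0_s + (seq_len(n) - 1) / fs) * 1000
  for (b in bumps) {
    sel <- t_ms >= b$from_ms & t_ms <= b$to_ms
    x[sel] <- b$amp
    if (!is.null(b$peak_at_ms)) {
      x[which.min(abs(t_ms - b$peak_at_ms))] <- b$amp * 1.2
    }
  }
  emg_trace(x, fs = fs, t0_s = t0_s)
}

# Small fast generator preset for tests that only need behaviour.
test_params <- function(...) {
  race_params(go_omission_rate = 0, choice_error_rate = 0, ...)
}
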