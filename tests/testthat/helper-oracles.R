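# Independent oracles used to validate the implementation.

# full-matrix DP of the banded-DTW recurrence (unbanded)
dtw_oracle_cost <- function(ev, em, skip) {
  N <- length(ev); M <- length(em)
  D <- matrix(Inf, N, M)
  for (j in 1:M) for (i in 1:N) {
    cost <- abs(ev[i] - em[j])
    if (i == 1 && j == 1) { D[i, j] <- cost; next }
    d1 <- if (i > 1 && j > 1) cost + D[i - 1, j - 1] else Inf
    d2 <- if (i > 1) cost + D[i - 1, j] else Inf
    d3 <- if (j > 1) skip * cost + D[i, j - 1] else Inf
    D[i, j] <- min(d1, d2, d3)
  }
  D[N, M]
}

# exhaustive enumeration of all monotone warping paths (tiny instances):
# a path is a sequence of steps in {diag, stay, skip}; its cost is the sum
# of per-cell costs with the skip multiplier on skip steps.
dtw_enum_cost <- function(ev, em, skip) {
  N <- length(ev); M <- length(em)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (acc >= best) return()
    if (i == N && j == M) { best <<- min(best, acc); return() }
    if (i < N && j < M)
      recurse(i + 1, j + 1, acc + abs(ev[i + 1] - em[j + 1]))
    if (i < N) recurse(i + 1, j, acc + abs(ev[i + 1] - em[j]))
    if (j < M) recurse(i, j + 1, acc + skip * abs(ev[i] - em[j + 1]))
  }
  recurse(1, 1, abs(ev[1] - em[1]))
  best
}

# brute-force two-sample KS statistic (double loop over the pooled support)
ks_oracle <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  m <- 0
  for (v in pool) {
    f1 <- sum(x <= v) / length(x)
    f2 <- sum(y <= v) / length(y)
    m <- max(m, abs(f1 - f2))
  }
  m
}

# brute-force group-by reduction of a pore model over a kept window
reduce_oracle <- function(model, m, anchor) {
  k <- model$k
  kmers <- kmer_from_index(0:(4^k - 1L), k)
  key <- substr(kmers, anchor + 1L, anchor + m)
  means <- tapply(model$means, key, mean)
  sds <- sqrt(tapply(model$sds^2, key, mean))
  ord <- kmer_from_index(0:(4^m - 1L), m)
  list(means = as.numeric(means[ord]), sds = as.numeric(sds[ord]))
}

full_band <- function(n_events, n_ref) {
  list(top = rep(0L, n_ref), bottom = rep(as.integer(n_events), n_ref))
}

# small shared simulation setup for unit tests
tiny_setup <- function(n_reads = 6, ref_len = 400, noise_sd = 0.25,
                       seed = 42, ...) {
  model <- synthetic_pore_model(5, seed = seed)
  ref <- random_reference(ref_len, seed = seed + 1)
  p <- sim_params(noise_sd = noise_sd, ...)
  sims <- simulate_reads(ref, model, n_reads, params = p, seed = seed + 2)
  list(model = model, ref = ref, params = p, sims = sims)
}

# exact, identifiable regime: no noise, no skips, exact moves, fine DAC
noiseless_params <- function(...) {
  sim_params(noise_sd = 0, skip_prob = 0, move_jitter = 0, dwell_min = 6,
             dwell_mean = 8, scale_sd = 0.02, shift_sd = 0.02,
             digitisation = 2^22, range = 1500, ...)
}

truth_sample_map <- function(sr, n) {
  tm <- rep(NA_integer_, n)
  for (i in seq_len(nrow(sr$truth)))
    if (sr$truth$hi[i] > sr$truth$lo[i])
      tm[(sr$truth$lo[i] + 1L):sr$truth$hi[i]] <- sr$truth$ref_pos[i]
  tm
}

interval_aln <- function(iv, ref_start = 0L, signal_len = NULL) {
  # build a signal_aln whose position sample intervals are exactly iv
  # (list of c(lo, hi)), with masked gaps in between
  n <- length(iv)
  lens <- vapply(iv, function(x) x[2] - x[1], 0L)
  mr <- data.frame(slot = integer(0), length = integer(0))
  cursor <- 0L
  for (i in seq_len(n)) {
    gap <- iv[[i]][1] - cursor
    if (gap > 0) mr <- rbind(mr, data.frame(slot = i, length = gap))
    cursor <- iv[[i]][2]
  }
  total <- if (is.null(signal_len)) cursor else signal_len
  if (total > cursor)
    mr <- rbind(mr, data.frame(slot = n + 1L, length = total - cursor))
  pos <- data.frame(ref_pos = ref_start + 0:(n - 1L), length = lens,
                    current = 0, current_sd = 0, event_count = 1,
                    mvcmp_dist = 0, masked = FALSE)
  signal_aln("r", "ref", "+", cbind(ref_start, ref_start + n), pos, mr,
             signal_len = total)
}

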