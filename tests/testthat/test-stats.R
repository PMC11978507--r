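test_that("signal Jaccard distance follows interval set arithmetic", {
  a <- interval_aln(list(c(0L, 6L), c(6L, 10L)), signal_len = 10L)
  b <- interval_aln(list(c(3L, 9L), c(9L, 10L)), signal_len = 10L)
  j <- jaccard_distance(a, b)
  expect_equal(j$jaccard[1], 1 - 3 / 9, tolerance = 1e-12) # [0,6) vs [3,9)
  expect_equal(jaccard_distance(a, a)$jaccard, c(0, 0))    # identical
  d <- interval_aln(list(c(6L, 9L), c(9L, 10L)), signal_len = 10L)
  expect_equal(jaccard_distance(a, d)$jaccard[1], 1)        # disjoint
  # range and symmetry
  expect_equal(jaccard_distance(b, a)$jaccard, j$jaccard)
  expect_true(all(j$jaccard >= 0 & j$jaccard <= 1))
})

test_that("signal-to-reference distance matches hand enumeration", {
  # A: samples 0-9 at r; B: 5 at r, 5 at r+1
  a <- interval_aln(list(c(0L, 10L), c(10L, 12L)), signal_len = 12L)
  b <- interval_aln(list(c(0L, 5L), c(5L, 12L)), signal_len = 12L)
  one <- sig2ref_distance(a, b, reciprocal = FALSE)
  expect_equal(one$dist[1], 0.5)
  rec <- sig2ref_distance(a, b)
  expect_equal(rec$dist[1], 0.25) # (0.5 + 0) / 2
  expect_equal(sig2ref_distance(a, a)$dist, c(0, 0))

  # uniform +k shift -> distance k in the interior
  n <- 10
  iv1 <- lapply(0:(n - 1), function(i) c(4L * i, 4L * (i + 1L)))
  a2 <- interval_aln(iv1)
  b2 <- interval_aln(iv1, ref_start = 2L)  # same samples, positions + 2
  d2 <- sig2ref_distance(a2, b2)
  interior <- d2$ref_pos %in% 2:7
  expect_equal(d2$dist[interior], rep(2, sum(interior)))
})

test_that("move-projection distance is one-sided", {
  iv <- lapply(0:4, function(i) c(5L * i, 5L * (i + 1L)))
  a <- interval_aln(iv)
  rm_same <- list(tab = data.frame(ref_pos = 0:4, lo = seq(0, 20, 5),
                                   hi = seq(5, 25, 5)))
  expect_equal(mvcmp_dist(a, rm_same)$dist, rep(0, 5))
  rm_shift <- list(tab = data.frame(ref_pos = 1:5, lo = seq(0, 20, 5),
                                    hi = seq(5, 25, 5)))
  expect_equal(mvcmp_dist(a, rm_shift)$dist, rep(1, 5))
})

test_that("KS statistic matches hand values and the double-loop oracle", {
  tr <- function(vals, pos = 0L)
    data.frame(read_id = seq_along(vals), ref_name = "ref", ref_pos = pos,
               current = vals, current_sd = 0, dwell = 1, event_count = 1,
               mvcmp_dist = 0)
  expect_equal(ks_refstats(tr(c(1, 2, 3, 4)), tr(c(1, 2, 3, 4)),
                           min_coverage = 1)$value, 0)
  expect_equal(ks_refstats(tr(rep(0, 4)), tr(rep(1, 4)),
                           min_coverage = 1)$value, 1)
  expect_equal(ks_refstats(tr(c(1, 2, 3, 4)), tr(c(3, 4, 5, 6)),
                           min_coverage = 1)$value, 0.5)
  set.seed(81)
  for (i in 1:25) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.3)
    got <- ks_refstats(tr(x), tr(y), min_coverage = 1)$value
    expect_equal(got, ks_oracle(x, y), tolerance = 1e-12)
    expect_true(got >= 0 && got <= 1)
  }
  # under-covered positions are null
  expect_true(is.na(ks_refstats(tr(1:5), tr(1:5), min_coverage = 10)$value))
})

test_that("z-scores use Welch pooling and are antisymmetric", {
  tr <- function(vals)
    data.frame(read_id = seq_along(vals), ref_name = "ref", ref_pos = 0L,
               current = vals, current_sd = 0, dwell = 1, event_count = 1,
               mvcmp_dist = 0)
  expect_equal(zscore_refstats(tr(c(1, 3)), tr(c(3, 1)),
                               min_coverage = 1)$value, 0)
  z <- zscore_refstats(tr(c(0, 2)), tr(c(4, 6)), min_coverage = 1)$value
  expect_equal(z, -4 / sqrt(2), tolerance = 1e-12)
  z2 <- zscore_refstats(tr(c(4, 6)), tr(c(0, 2)), min_coverage = 1)$value
  expect_equal(z2, -z)
  expect_warning(
    zn <- zscore_refstats(tr(c(1, 1)), tr(c(1, 1)), min_coverage = 1)$value,
    "pooled variance")
  expect_true(is.na(zn))
})

test_that("summary refstats cover the standard statistics", {
  tr <- data.frame(read_id = 1:3, ref_name = "ref", ref_pos = 0L,
                   current = c(1, 2, 3), current_sd = 0, dwell = 5,
                   event_count = 1, mvcmp_dist = 0)
  expect_equal(summary_refstats(tr, "current", "mean")$value, 2)
  expect_equal(summary_refstats(tr, "current", "median")$value, 2)
  expect_equal(summary_refstats(tr, "dwell", "stdv")$value, 0)
  expect_equal(summary_refstats(tr, "current", "var")$value, 1)
})

test_that("model MAD is zero at the model and tracks a location shift", {
  model <- synthetic_pore_model(5, seed = 57)
  ref <- random_reference(80, seed = 58)
  es <- expected_signal(model, ref)
  keep <- which(!is.na(es$mean))
  mk <- function(shift) {
    pos <- data.frame(ref_pos = keep - 1L, length = 5L,
                      current = es$mean[keep] + shift, current_sd = 0.1,
                      event_count = 1, mvcmp_dist = 0, masked = FALSE)
    signal_aln("r", "ref", "+", cbind(keep[1] - 1L, keep[length(keep)]),
               pos, signal_len = 5L * length(keep))
  }
  mads <- model_mad(list(mk(0), mk(0.2)), model, c(ref = ref))
  expect_equal(mads$model_mad, c(0, 0.2))
})

test_that("dwell-offset variability localizes a planted dwell effect", {
  model <- synthetic_pore_model(5, seed = 59)
  ref <- random_reference(1200, seed = 60)
  set.seed(90)
  lf <- stats::rnorm(4^5, 0, 0.6) # per-5-mer dwell modulation
  p_null <- sim_params(noise_sd = 0.2, dwell_mean = 8)
  p_eff <- sim_params(noise_sd = 0.2, dwell_mean = 8,
                      dwell_effect = list(offset = -11L, log_factors = lf))
  mk_track <- function(params, seed) {
    sims <- simulate_reads(ref, model, 8, params = params, seed = seed)
    do.call(rbind, lapply(sims, function(sr)
      data.frame(read_id = sr$read_id, ref_name = "ref",
                 ref_pos = sr$truth$ref_pos,
                 current = 0, current_sd = 0,
                 dwell = sr$truth$hi - sr$truth$lo,
                 event_count = 1, mvcmp_dist = 0)))
  }
  offs <- -14:0
  v_eff <- dwell_offset_variability(mk_track(p_eff, 91), ref, 5, offs)
  expect_equal(v_eff$offset[which.max(v_eff$value)], -11L)
  v_null <- dwell_offset_variability(mk_track(p_null, 92), ref, 5, offs)
  expect_lt(max(v_null$value), max(v_eff$value) / 2)
  # homogeneity: uniform dwell rescaling rescales the statistic
  tr <- mk_track(p_eff, 93)
  tr2 <- tr; tr2$dwell <- tr2$dwell * 3
  expect_equal(dwell_offset_variability(tr2, ref, 5, offs)$value,
               3 * dwell_offset_variability(tr, ref, 5, offs)$value)
})
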