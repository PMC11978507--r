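test_that("move projection maps bases to sample intervals through the cigar", {
  # 4M, stride 5, one move per base at steps 0..3
  rm <- project_moves(rep(1L, 4), 5L, 0L, "4M", 10L)
  expect_equal(rm$tab$ref_pos, 10:13)
  expect_equal(rm$tab$lo, c(0, 5, 10, 15))
  expect_equal(rm$tab$hi, c(5, 10, 15, 20))

  # deletion: interpolated interval, monotone and contained
  rmd <- project_moves(rep(1L, 4), 5L, 0L, "2M1D2M", 0L)
  expect_equal(rmd$tab$ref_pos, 0:4)
  expect_false(is.unsorted(rmd$tab$lo))
  expect_false(is.unsorted(rmd$tab$hi))
  expect_true(all(rmd$tab$lo >= 0 & rmd$tab$hi <= 20))
  expect_true(rmd$tab$lo[3] >= rmd$tab$hi[2] - 1 &&
                rmd$tab$hi[3] <= rmd$tab$lo[4] + 1)

  # insertion: samples merged into the preceding position's interval
  rmi <- project_moves(rep(1L, 4), 5L, 0L, "2M1I1M", 0L)
  expect_equal(rmi$tab$ref_pos, 0:2)
  expect_equal(rmi$tab$hi[2], 15)  # base 2's 5 samples appended to position 1
  expect_equal(nrow(rmi$ins), 1)
  expect_error(project_moves(rep(1L, 3), 5L, 0L, "4M", 0L), "mismatch")
})

test_that("splice_indels excises only indels above the threshold", {
  rm <- project_moves(rep(1L, 5), 5L, 0L, "5M", 0L, signal_len = 25L)
  s <- splice_indels(rm, 10L)
  expect_equal(s$tab, rm$tab)                      # no-op without indels
  expect_equal(nrow(s$masked_ranges), 0)

  # 3M15D3M: 15 > 10, reference gap excised -> two blocks
  rmd <- project_moves(rep(1L, 6), 5L, 0L, "3M15D3M", 0L)
  sd_ <- splice_indels(rmd, 10L)
  expect_equal(nrow(sd_$blocks), 2)
  expect_equal(sd_$blocks[, 1], c(0, 18))
  expect_equal(nrow(sd_$tab), 6)

  # 3M15I3M: 15 read bases' samples masked, one reference block
  rmi <- project_moves(rep(1L, 21), 5L, 0L, "3M15I3M", 0L)
  si <- splice_indels(rmi, 10L)
  expect_equal(nrow(si$blocks), 1)
  expect_equal(nrow(si$masked_ranges), 1)
  expect_equal(si$masked_ranges[1, 2] - si$masked_ranges[1, 1], 75)
  # small indels are left for the DTW
  rms <- project_moves(rep(1L, 8), 5L, 0L, "3M2I3M", 0L)
  ss <- splice_indels(rms, 10L)
  expect_equal(nrow(ss$masked_ranges), 0)
})

test_that("band placement follows, translates with, and repairs the moves", {
  events <- data.frame(start = seq(0, 95, by = 5), length = 5)
  tab <- data.frame(ref_pos = 0:19, lo = seq(0, 95, by = 5),
                    hi = seq(5, 100, by = 5))
  b <- place_band(list(tab = tab), events, width = 5)
  j <- 10
  expect_true(b$top[j] <= j - 1 && j - 1 < b$bottom[j]) # centered on diagonal
  expect_equal(b$bottom[j] - b$top[j], 5)

  # uniform +2-event offset in the moves offsets the band centers by +2
  tab2 <- tab; tab2$lo <- tab2$lo + 10; tab2$hi <- tab2$hi + 10
  b2 <- place_band(list(tab = tab2), events, width = 5)
  mid <- 5:15
  expect_equal(b2$top[mid], b$top[mid] + 2)

  # monotonicity repair on constructed center violation (centers 5 then 3)
  tab3 <- data.frame(ref_pos = 0:1, lo = c(25, 15), hi = c(30, 20))
  b3 <- place_band(list(tab = tab3), events, width = 3)
  expect_true(all(diff(b3$top) >= 0))
  expect_true(all(diff(b3$bottom) >= 0))
  expect_error(place_band(list(tab = tab), events[0, ], 5), "empty event")
})

test_that("banded DTW reproduces the printed examples", {
  # diagonal path with zero cost
  r <- banded_dtw(c(0, 1), list(mean = c(0, 1)), full_band(2, 2), 2)
  expect_equal(r$cost, 0)
  expect_equal(r$path$event, c(0L, 1L))
  expect_equal(r$path$ref, c(0L, 1L))
  # one event, two reference positions: single skip, zero total cost
  r2 <- banded_dtw(0, list(mean = c(0, 0)), full_band(1, 2), 2)
  expect_equal(r2$cost, 0)
  expect_equal(r2$path$ref, c(0L, 1L))
  expect_equal(r2$path$move, c("origin", "skip"))
})

test_that("full-width banded DTW equals the unbanded brute-force oracle", {
  set.seed(101)
  for (trial in 1:100) {
    N <- sample(2:15, 1); M <- sample(2:15, 1)
    ev <- rnorm(N); em <- rnorm(M)
    sc <- sample(c(1, 1.5, 2, 4), 1)
    got <- banded_dtw(ev, list(mean = em), full_band(N, M), sc)
    expect_equal(got$cost, dtw_oracle_cost(ev, em, sc), tolerance = 1e-12)
  }
})

test_that("DP optimum matches exhaustive path enumeration on tiny instances", {
  set.seed(102)
  for (trial in 1:20) {
    N <- sample(2:5, 1); M <- sample(2:5, 1)
    ev <- rnorm(N); em <- rnorm(M)
    got <- banded_dtw(ev, list(mean = em), full_band(N, M), 2)
    expect_equal(got$cost, dtw_enum_cost(ev, em, 2), tolerance = 1e-12)
  }
})

test_that("paths are monotone, complete, and stable under band shrinking", {
  set.seed(103)
  for (trial in 1:25) {
    N <- sample(5:20, 1); M <- sample(5:20, 1)
    ev <- rnorm(N); em <- rnorm(M)
    r <- banded_dtw(ev, list(mean = em), full_band(N, M), 2)
    expect_equal(r$path$event[1], 0L)
    expect_equal(r$path$ref[1], 0L)
    expect_equal(r$path$event[nrow(r$path)], N - 1L)
    expect_equal(r$path$ref[nrow(r$path)], M - 1L)
    expect_true(all(diff(r$path$event) %in% 0:1))
    expect_true(all(diff(r$path$ref) %in% 0:1))
    expect_true(all(diff(r$path$event) + diff(r$path$ref) >= 1))
    # shrink the band around the optimal path: cost may not increase
    top <- pmax(0L, vapply(0:(M - 1), function(j)
      min(r$path$event[r$path$ref == j]), 0L) - 1L)
    bottom <- pmin(N, vapply(0:(M - 1), function(j)
      max(r$path$event[r$path$ref == j]), 0L) + 2L)
    r2 <- banded_dtw(ev, list(mean = em),
                     list(top = cummax(top), bottom = cummax(bottom)), 2)
    expect_equal(r2$cost, r$cost, tolerance = 1e-12)
  }
})

test_that("skip masking keeps the best of a run and masks per mode", {
  # construct a path: event 0 at ref 0, then skips to refs 1 and 2,
  # then event 1 at ref 3
  path <- data.frame(event = c(0L, 0L, 0L, 1L),
                     ref = c(0L, 1L, 2L, 3L),
                     move = c("origin", "skip", "skip", "match"))
  expected <- c(0.1, 1.0, 2.0, 5.0)
  observed <- c(0.9, 0.9, 0.9, 5.0)
  expect_equal(mask_skips(path, "none", expected, observed),
               rep(FALSE, 4))
  mk <- mask_skips(path, "keep_best", expected, observed)
  expect_equal(mk, c(TRUE, FALSE, TRUE, FALSE)) # keeps expected 1.0 (~0.9)
  ma <- mask_skips(path, "all", expected, observed)
  expect_equal(ma, c(TRUE, TRUE, TRUE, FALSE))
  # no skips -> unchanged under every mode
  p2 <- data.frame(event = 0:1, ref = 0:1, move = c("origin", "match"))
  for (mode in c("none", "all", "keep_best"))
    expect_equal(mask_skips(p2, mode, c(0, 1), c(0, 1)), c(FALSE, FALSE))
})

test_that("noiseless reads with exact moves are recovered exactly", {
  model <- synthetic_pore_model(5, seed = 31)
  ref <- random_reference(600, seed = 32)
  sr <- simulate_read(ref, model, params = noiseless_params(), seed = 33)
  a <- align_read(sr$read, sr, model, ref, align_params())
  got <- sample_ref_map(a)
  want <- truth_sample_map(sr, a$signal_len)
  agree <- mean(got == want, na.rm = TRUE)
  expect_gt(agree, 0.999)
})

test_that("alignment tolerates noise with small per-sample coordinate error", {
  s <- tiny_setup(n_reads = 5, ref_len = 500, noise_sd = 0.3, seed = 61)
  errs <- unlist(lapply(s$sims, function(sr) {
    a <- align_read(sr$read, sr, s$model, s$ref)
    expect_equal(sum(a$pos$length) + sum(a$masked_runs$length), a$signal_len)
    abs(sample_ref_map(a) - truth_sample_map(sr, a$signal_len))
  }))
  expect_lte(stats::median(errs, na.rm = TRUE), 1)
})

test_that("a large insertion is spliced without disturbing the rest", {
  model <- synthetic_pore_model(5, seed = 41)
  ref <- random_reference(400, seed = 42)
  p0 <- noiseless_params()
  base <- simulate_read(ref, model, params = p0, seed = 43)
  ins <- simulate_read(ref, model, params = p0, seed = 43,
                       indels = data.frame(op = "I", at = 200L, len = 15L))
  a1 <- align_read(base$read, base, model, ref, align_params())
  a2 <- align_read(ins$read, ins, model, ref, align_params())
  away <- a1$pos$ref_pos < 190 | a1$pos$ref_pos > 210
  i2 <- match(a1$pos$ref_pos[away], a2$pos$ref_pos)
  expect_true(all(!is.na(i2)))
  expect_equal(a2$pos$current[i2], a1$pos$current[away], tolerance = 1e-6)
  expect_equal(a2$pos$length[i2], a1$pos$length[away])
})
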