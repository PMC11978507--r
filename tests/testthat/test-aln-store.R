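make_test_aln <- function(lengths, currents = NULL, ref_start = 100L,
                          masked_runs = data.frame(slot = integer(0),
                                                   length = integer(0)),
                          masked = FALSE, strand = "+") {
  n <- length(lengths)
  if (is.null(currents)) currents <- seq(-1, 1, length.out = n)
  pos <- data.frame(ref_pos = ref_start + 0:(n - 1L), length = lengths,
                    current = currents, current_sd = abs(currents) / 2,
                    event_count = 1, mvcmp_dist = 0, masked = masked)
  signal_aln("r1", "ref", strand,
             cbind(ref_start, ref_start + n), pos, masked_runs,
             norm = list(scale = 0.1, shift = -9.5), model_name = "m",
             signal_len = sum(lengths) + sum(masked_runs$length))
}

test_that("compute_layers aggregates samples, skips, and stays", {
  # one position with samples [1, 3]
  path <- data.frame(event = 0L, ref = 0L, move = "origin")
  events <- data.frame(start = 0L, length = 2L)
  lay <- compute_layers(path, c(1, 3), events)
  expect_equal(lay$current, 2)
  expect_equal(lay$current_sd, 1)
  expect_equal(lay$length, 2L)

  # skip group of 2 sharing one event
  path2 <- data.frame(event = c(0L, 0L, 1L), ref = c(0L, 1L, 2L),
                      move = c("origin", "skip", "match"))
  ev2 <- data.frame(start = c(0L, 4L), length = c(4L, 2L))
  lay2 <- compute_layers(path2, c(2, 2, 2, 2, 9, 9), ev2)
  expect_equal(lay2$current[1], lay2$current[2])
  expect_equal(lay2$event_count[1:2], c(0.5, 0.5))
  expect_equal(lay2$length, c(4L, 0L, 2L))

  # stay of 3 events on one position
  path3 <- data.frame(event = 0:2, ref = c(0L, 0L, 0L),
                      move = c("origin", "stay", "stay"))
  ev3 <- data.frame(start = c(0L, 3L, 5L), length = c(3L, 2L, 4L))
  lay3 <- compute_layers(path3, rep(1, 9), ev3)
  expect_equal(lay3$event_count, 3)
  expect_equal(lay3$length, 9L)
})

test_that("derived layers compute differences and honor offsets", {
  model <- synthetic_pore_model(5, seed = 51)
  ref <- random_reference(60, seed = 52)
  es <- expected_signal(model, ref)
  keep <- which(!is.na(es$mean))
  a <- make_test_aln(rep(5L, length(keep)), es$mean[keep],
                     ref_start = keep[1] - 1L)
  md <- derived_layer(a, "dtw.model_diff", model = model, refseq = ref)
  expect_equal(md, rep(0, length(keep)))
  dw <- derived_layer(a, "dtw.dwell")
  expect_equal(derived_layer(a, "dtw.dwell", offset = 0L), dw)
  d11 <- derived_layer(a, "dtw.dwell", offset = -11L)
  expect_true(all(is.na(d11[1:11])))
  expect_equal(d11[12:length(dw)], dw[1:(length(dw) - 11)])
  expect_error(derived_layer(a, "nope"), "valid layers")
})

test_that("us encoding follows the run-length rules with sentinels", {
  a <- make_test_aln(c(5L, 0L, 3L),
                     masked_runs = data.frame(slot = 1L, length = 7L))
  tg <- encode_tags(a)
  expect_equal(tg$us, c(-7L, 5L, 0L, 3L))
  expect_equal(sum(abs(tg$us)), 15)
  expect_equal(tg$ur, c(100L, 103L))

  # fixed-point endpoints and null
  expect_equal(squigalign:::quantize_current(c(-5, 0, 5)),
               c(0L, 32767L, 65534L), ignore_attr = TRUE)
  expect_equal(squigalign:::quantize_current(NA_real_), 65535L,
               ignore_attr = TRUE)

  # sentinel chaining for lengths >= 65535
  expect_equal(squigalign:::encode_len16(70000L), c(65535L, 4465L))
  expect_equal(squigalign:::encode_len16(65535L), c(65535L, 0L))
  big <- make_test_aln(c(70000L, 4L))
  tgb <- encode_tags(big)
  expect_equal(tgb$us, c(65535L, 4465L, 4L))
  dec <- decode_tags(tgb, signal_len = 70004L)
  expect_equal(dec$pos$length, c(70000L, 4L))
  # negative (masked) runs chain symmetrically
  bigm <- make_test_aln(c(4L, 4L),
                        masked_runs = data.frame(slot = 2L, length = 70000L))
  expect_equal(encode_tags(bigm)$us, c(4L, -65535L, -4465L, 4L))
})

test_that("decode is the inverse of encode and checks integrity", {
  a <- make_test_aln(c(5L, 0L, 3L, 8L),
                     masked_runs = data.frame(slot = c(1L, 5L),
                                              length = c(7L, 2L)))
  tg <- encode_tags(a)
  b <- decode_tags(tg, signal_len = a$signal_len)
  expect_equal(b$pos$length, a$pos$length)
  expect_equal(b$pos$ref_pos, a$pos$ref_pos)
  expect_equal(b$masked_runs, a$masked_runs)
  expect_lt(max(abs(b$pos$current - a$pos$current)), 7.7e-5)
  expect_equal(b$norm$scale, a$norm$scale)

  # corrupted us: one entry dropped
  tg2 <- tg; tg2$us <- tg2$us[-2]
  expect_error(decode_tags(tg2, signal_len = a$signal_len), "integrity")
  # wrong declared signal length
  expect_error(decode_tags(tg, signal_len = a$signal_len + 1L), "integrity")
  # null quantum decodes to a masked (null-current) position
  am <- make_test_aln(c(5L, 3L), masked = c(TRUE, FALSE))
  bm <- decode_tags(encode_tags(am), signal_len = am$signal_len)
  expect_true(is.na(bm$pos$current[1]))
  expect_true(bm$pos$masked[1])
  expect_false(is.na(bm$pos$current[2]))
})

test_that("tag round trip through SAM/BAM is exact for many alignments", {
  set.seed(71)
  alns <- lapply(1:40, function(i) {
    n <- sample(20:60, 1)
    lens <- sample(0:12, n, replace = TRUE)
    lens[c(1, n)] <- pmax(lens[c(1, n)], 1L)
    mr <- data.frame(slot = sample(n, 2), length = sample(1:9, 2))
    make_test_aln(lens, runif(n, -4.9, 4.9), ref_start = sample(1e6, 1),
                  masked_runs = mr)
  })
  meta <- lapply(alns, function(a)
    list(flag = 0L, pos = a$blocks[1, 1] + 1L, mapq = 60L,
         cigar = paste0(nrow(a$pos), "M"),
         seq = paste(rep("A", nrow(a$pos)), collapse = "")))
  bam <- tempfile(fileext = ".bam")
  write_signal_sam(alns, meta, c(ref = 2e6), bam)
  back <- read_signal_alns(bam)
  expect_length(back, 40)
  ids <- vapply(back, `[[`, "", "read_id")
  for (i in seq_along(alns)) {
    b <- back[[1]] # all same read id; rely on order
    b <- back[[i]]
    expect_equal(b$pos$length, alns[[i]]$pos$length)
    expect_equal(b$pos$ref_pos, alns[[i]]$pos$ref_pos)
    expect_lt(max(abs(b$pos$current - alns[[i]]$pos$current)), 7.7e-5)
    expect_equal(b$masked_runs, alns[[i]]$masked_runs)
  }
})

test_that("eventalign output has one row per unmasked position", {
  model <- synthetic_pore_model(5, seed = 53)
  ref <- random_reference(80, seed = 54)
  es <- expected_signal(model, ref)
  keep <- which(!is.na(es$mean))
  n <- length(keep)
  masked <- rep(FALSE, n); masked[5] <- TRUE
  a <- make_test_aln(rep(4L, n), es$mean[keep] + 0.25,
                     ref_start = keep[1] - 1L, masked = masked)
  p <- tempfile(fileext = ".tsv")
  write_eventalign(list(a), model, c(ref = ref), p)
  tab <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), sum(!masked))
  expect_false(a$pos$ref_pos[5] %in% tab$position)
  expect_equal(tab$standardized_level,
               (tab$event_level_mean - tab$model_mean) / tab$model_stdv)
  expect_equal(tab$reference_kmer[1],
               kmer_from_index(es$kmer[keep[1]], model$k))
})

test_that("convert round-trips bam -> eventalign -> bam within a quantum", {
  model <- synthetic_pore_model(5, seed = 55)
  ref <- random_reference(100, seed = 56)
  es <- expected_signal(model, ref)
  keep <- which(!is.na(es$mean))
  a <- make_test_aln(sample(3:9, length(keep), replace = TRUE),
                     pmax(pmin(es$mean[keep] + rnorm(length(keep), 0, 0.2),
                               4.9), -4.9),
                     ref_start = keep[1] - 1L)
  b1 <- tempfile(fileext = ".bam")
  write_signal_sam(list(a), list(list(flag = 0L, pos = a$blocks[1, 1] + 1L,
                                      mapq = 60L,
                                      cigar = paste0(nrow(a$pos), "M"))),
                   c(ref = 200L), b1)
  # identity conversion preserves tag payloads
  b2 <- tempfile(fileext = ".bam")
  convert(b1, b2)
  t1 <- read_bam_records(b1)[[1]]; t2 <- read_bam_records(b2)[[1]]
  expect_identical(t1$us, t2$us)
  expect_identical(t1$uc, t2$uc)
  # via eventalign
  ea <- tempfile(fileext = ".eventalign.tsv")
  convert(b1, ea, model = model, refseqs = c(ref = ref))
  b3 <- tempfile(fileext = ".bam")
  convert(ea, b3)
  a3 <- read_signal_alns(b3)[[1]]
  expect_equal(a3$pos$length, a$pos$length)
  expect_equal(a3$pos$current, a$pos$current, tolerance = 2 * 10 / 65534)
  expect_error(read_eventalign({
    tab <- utils::read.table(ea, header = TRUE, sep = "\t")
    p2 <- tempfile(); utils::write.table(tab[rev(seq_len(nrow(tab))), ], p2,
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE); p2
  }), "sorted")
})

test_that("per-event eventalign rows collapse to dwell-weighted means", {
  hdr <- paste(squigalign:::EVENTALIGN_COLS, collapse = "\t")
  rows <- c(
    "ref\t10\tAAAAA\trx\tt\t0\t1.0\t0.1\t6\tAAAAA\t0\t1\t1\t0\t6",
    "ref\t10\tAAAAA\trx\tt\t1\t4.0\t0.1\t2\tAAAAA\t0\t1\t4\t6\t8",
    "ref\t11\tAAAAT\trx\tt\t2\t2.0\t0.1\t4\tAAAAT\t0\t1\t2\t8\t12")
  p <- tempfile()
  writeLines(c(hdr, rows), p)
  alns <- read_eventalign(p)
  a <- alns[[1]]
  expect_equal(nrow(a$pos), 2)
  expect_equal(a$pos$current[1], (1.0 * 6 + 4.0 * 2) / 8) # weighted mean
  expect_equal(a$pos$length, c(8L, 4L))
})
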