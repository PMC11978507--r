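#' Collect per-position layers across reads ("track")
#'
#' Long-format table of per-read, per-position alignment layers, the input
#' to the reference-level statistics. Masked positions are dropped.
#'
#' @param alns list of [signal_aln()] objects.
#' @return data.frame with `read_id`, `ref_name`, `ref_pos`, `current`,
#'   `current_sd`, `dwell`, `event_count`, `mvcmp_dist`.
#' @export
collect_track <- function(alns) {
  do.call(rbind, lapply(alns, function(a) {
    keep <- !a$pos$masked & is.finite(a$pos$current)
    data.frame(read_id = a$read_id, ref_name = a$ref_name,
               ref_pos = a$pos$ref_pos[keep],
               current = a$pos$current[keep],
               current_sd = a$pos$current_sd[keep],
               dwell = a$pos$length[keep],
               event_count = a$pos$event_count[keep],
               mvcmp_dist = a$pos$mvcmp_dist[keep])
  }))
}

#' Per-position signal Jaccard distance between two alignments of one read
#'
#' `1 - |A intersect B| / |A union B|` where A and B are the raw-sample sets
#' the two methods assign to the same reference position (stored as
#' intervals, so set operations are O(1)). 0 means perfect overlap, 1 no
#' overlap; positions where either set is empty are skipped.
#'
#' @param a,b two [signal_aln()] objects for the same read.
#' @return data.frame `ref_pos`, `jaccard`.
#' @export
jaccard_distance <- function(a, b) {
  ia <- position_sample_intervals(a)
  ib <- position_sample_intervals(b)
  shared <- intersect(ia$ref_pos, ib$ref_pos)
  ia <- ia[match(shared, ia$ref_pos), ]
  ib <- ib[match(shared, ib$ref_pos), ]
  ok <- ia$hi > ia$lo & ib$hi > ib$lo
  inter <- pmax(0, pmin(ia$hi, ib$hi) - pmax(ia$lo, ib$lo))
  uni <- (ia$hi - ia$lo) + (ib$hi - ib$lo) - inter
  data.frame(ref_pos = shared[ok], jaccard = (1 - inter / uni)[ok])
}

#' Per-position signal-to-reference distance
#'
#' For each reference coordinate `r` under alignment `a`, the mean over the
#' raw samples `a` assigns to `r` of the absolute distance (in reference
#' bases) to the coordinate alignment `b` assigns the same sample. With
#' `reciprocal = TRUE` the `a`->`b` and `b`->`a` values at `r` are averaged.
#' Samples unaligned in the other method are excluded and counted.
#'
#' @param a,b two [signal_aln()] objects for the same read.
#' @param reciprocal average the two directions (the move-projection
#'   comparison `mvcmp.dist` uses `FALSE`).
#' @return data.frame `ref_pos`, `dist`, `n_unaligned`.
#' @export
sig2ref_distance <- function(a, b, reciprocal = TRUE) {
  one_sided <- function(x, ymap) {
    iv <- position_sample_intervals(x)
    own <- iv[iv$own_hi > iv$own_lo, , drop = FALSE]
    d <- vapply(seq_len(nrow(own)), function(i) {
      r <- ymap[(own$own_lo[i] + 1L):own$own_hi[i]]
      mean(abs(own$ref_pos[i] - r), na.rm = TRUE)
    }, 0)
    nu <- vapply(seq_len(nrow(own)), function(i)
      sum(is.na(ymap[(own$own_lo[i] + 1L):own$own_hi[i]])), 0L)
    data.frame(ref_pos = own$ref_pos, dist = d, n_unaligned = nu)
  }
  ab <- one_sided(a, sample_ref_map(b))
  if (!reciprocal) return(ab)
  ba <- one_sided(b, sample_ref_map(a))
  shared <- intersect(ab$ref_pos, ba$ref_pos)
  i <- match(shared, ab$ref_pos); j <- match(shared, ba$ref_pos)
  data.frame(ref_pos = shared,
             dist = (ab$dist[i] + ba$dist[j]) / 2,
             n_unaligned = ab$n_unaligned[i] + ba$n_unaligned[j])
}

#' Distance from the basecaller move projection
#'
#' One-sided [sig2ref_distance()] from the alignment's raw samples to the
#' move-projected positions (not computed reciprocally, since the
#' projection's resolution is one stride). Used as the position filter
#' during pore-model training.
#'
#' @param aln a [signal_aln()].
#' @param rm the read's `ref_moves` (after [splice_indels()]).
#' @return data.frame `ref_pos`, `dist`.
#' @export
mvcmp_dist <- function(aln, rm) {
  mvmap <- rep(NA_integer_, aln$signal_len)
  for (i in seq_len(nrow(rm$tab)))
    if (rm$tab$hi[i] > rm$tab$lo[i])
      mvmap[(rm$tab$lo[i] + 1L):rm$tab$hi[i]] <- rm$tab$ref_pos[i]
  iv <- position_sample_intervals(aln)
  own <- iv[iv$own_hi > iv$own_lo, , drop = FALSE]
  data.frame(ref_pos = own$ref_pos,
             dist = vapply(seq_len(nrow(own)), function(i)
               mean(abs(own$ref_pos[i] -
                          mvmap[(own$own_lo[i] + 1L):own$own_hi[i]]),
                    na.rm = TRUE), 0))
}

per_position_stat <- function(track1, track2 = NULL, layer, min_coverage,
                              fn) {
  positions <- sort(unique(c(track1$ref_pos,
                             if (!is.null(track2)) track2$ref_pos)))
  v1 <- split(track1[[layer]], factor(track1$ref_pos, levels = positions))
  v2 <- if (!is.null(track2))
    split(track2[[layer]], factor(track2$ref_pos, levels = positions))
  val <- vapply(seq_along(positions), function(i) {
    x <- v1[[i]]
    if (length(x) < min_coverage) return(NA_real_)
    if (is.null(v2)) return(fn(x))
    y <- v2[[i]]
    if (length(y) < min_coverage) return(NA_real_)
    fn(x, y)
  }, 0)
  data.frame(ref_pos = positions, value = val)
}

#' Two-sample Kolmogorov-Smirnov statistic per reference position
#'
#' `sup_x |F1(x) - F2(x)|` between the empirical distributions of per-read
#' current means (or any requested layer) of two samples; positions below
#' `min_coverage` reads in either sample are emitted as `NA`.
#'
#' @param track1,track2 tracks from [collect_track()].
#' @param layer layer column to compare (default `current`).
#' @param min_coverage minimum reads per position in each track.
#' @return data.frame `ref_pos`, `value` (KS statistic in `[0, 1]`).
#' @export
ks_refstats <- function(track1, track2, layer = "current",
                        min_coverage = 20L) {
  per_position_stat(track1, track2, layer, min_coverage, function(x, y)
    unname(suppressWarnings(stats::ks.test(x, y))$statistic))
}

#' Welch z-score per reference position
#'
#' `(mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)` with unbiased sample
#' variances; positions with zero pooled variance are `NA` with a warning.
#'
#' @inheritParams ks_refstats
#' @return data.frame `ref_pos`, `value`.
#' @export
zscore_refstats <- function(track1, track2, layer = "current",
                            min_coverage = 20L) {
  warned <- FALSE
  out <- per_position_stat(track1, track2, layer, min_coverage,
    function(x, y) {
      pv <- stats::var(x) / length(x) + stats::var(y) / length(y)
      if (!is.finite(pv) || pv == 0) {
        if (!warned) { warning("zero pooled variance at some positions");
                       warned <<- TRUE }
        return(NA_real_)
      }
      (mean(x) - mean(y)) / sqrt(pv)
    })
  out
}

#' Per-position summary statistics of a track layer
#'
#' @param track a track from [collect_track()].
#' @param layer layer column name.
#' @param stat one of `mean`, `median`, `stdv`, `var`, `skew`, `kurt`.
#' @param min_coverage minimum reads per position.
#' @return data.frame `ref_pos`, `value`.
#' @export
summary_refstats <- function(track, layer = "current",
                             stat = c("mean", "median", "stdv", "var",
                                      "skew", "kurt"),
                             min_coverage = 1L) {
  stat <- match.arg(stat)
  fn <- switch(stat, mean = mean, median = stats::median,
               stdv = stats::sd, var = stats::var,
               skew = function(x) e1071::skewness(x),
               kurt = function(x) e1071::kurtosis(x))
  per_position_stat(track, NULL, layer, min_coverage, fn)
}

#' Per-read median absolute model difference ("model MAD")
#'
#' The median over a read's positions of the absolute difference between the
#' per-position current mean and the pore-model mean: an alignment-quality
#' proxy where values nearer zero indicate a closer model fit.
#'
#' @param alns list of [signal_aln()] objects.
#' @param model a [pore_model()].
#' @param refseqs named character vector of reference sequences.
#' @return data.frame `read_id`, `model_mad`.
#' @export
model_mad <- function(alns, model, refseqs) {
  data.frame(
    read_id = vapply(alns, `[[`, "", "read_id"),
    model_mad = vapply(alns, function(a) {
      d <- derived_layer(a, "dtw.model_diff", model = model,
                         refseq = refseqs[[a$ref_name]])
      stats::median(d[!a$pos$masked], na.rm = TRUE)
    }, 0))
}

#' Positional influence of sequence on dwell time
#'
#' For each coordinate offset `d`, positions are grouped by the m-mer
#' starting at `r + d`, the median dwell is taken per group (pooled over
#' reads), and the standard deviation of those medians is returned: a large
#' value at offset `d` means the sequence `d` bases away strongly modulates
#' sequencing speed (in real pores, typically 11-13 bases upstream where the
#' motor protein binds).
#'
#' @param track a track from [collect_track()].
#' @param refseq reference nucleotide string.
#' @param m m-mer length (default 5).
#' @param offsets integer vector of coordinate offsets.
#' @return data.frame `offset`, `value` (`NA` where fewer than 2 m-mers
#'   observed).
#' @export
dwell_offset_variability <- function(track, refseq, m = 5L,
                                     offsets = -15:5) {
  L <- nchar(refseq)
  kidx <- seq_kmer_indices(refseq, m)
  vapply_one <- function(d) {
    start <- track$ref_pos + d
    ok <- start >= 0L & start <= L - m
    if (!any(ok)) return(NA_real_)
    grp <- kidx[start[ok] + 1L]
    med <- tapply(track$dwell[ok], grp, stats::median)
    if (length(med) < 2) return(NA_real_)
    stats::sd(med)
  }
  data.frame(offset = offsets,
             value = vapply(offsets, vapply_one, 0))
}

#' Benjamini-Hochberg helper for per-position statistics
#'
#' Optional multiple-testing correction for KS p-values; raw statistics are
#' reported by default throughout the package.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (`stats::p.adjust`, method `"BH"`).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
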