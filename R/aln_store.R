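FIXED_LO <- -5
FIXED_HI <- 5
NULL_Q <- 65535L
SENTINEL <- 65535L

#' Signal alignment container
#'
#' A `signal_aln` stores one read's signal alignment as per-reference-position
#' layers: `length` (aligned sample count, 0 for a skip), `current` (mean
#' normalized current), `current_sd`, `event_count` (fractional `1/g` within
#' a skip group of `g`), and `mvcmp_dist` (distance from the basecaller
#' move projection). Rows are in signal order (`ref_pos` descends for
#' reverse-strand reads); masked signal runs are interleaved by `slot` (a run
#' with slot `i` precedes position row `i`). `norm` holds the final
#' pA-to-normalized `scale`/`shift`.
#'
#' @param read_id,ref_name,strand read metadata.
#' @param blocks matrix of `[start, stop)` reference coordinate intervals.
#' @param pos data.frame with columns `ref_pos`, `length`, `current`,
#'   `current_sd`, `event_count`, `mvcmp_dist`, `masked`.
#' @param masked_runs data.frame with columns `slot`, `length`.
#' @param norm list with `scale` and `shift`.
#' @param model_name pore model label.
#' @param signal_len total raw samples consumed.
#' @return object of class `signal_aln`.
#' @export
signal_aln <- function(read_id, ref_name, strand, blocks, pos,
                       masked_runs = data.frame(slot = integer(0),
                                                length = integer(0)),
                       norm = list(scale = 1, shift = 0),
                       model_name = "custom", signal_len) {
  stopifnot(is.data.frame(pos), all(c("ref_pos", "length", "current",
                                      "current_sd") %in% names(pos)))
  if (is.null(pos$event_count)) pos$event_count <- NA_real_
  if (is.null(pos$mvcmp_dist)) pos$mvcmp_dist <- NA_real_
  if (is.null(pos$masked)) pos$masked <- FALSE
  if (nrow(masked_runs)) {
    masked_runs <- masked_runs[order(masked_runs$slot), , drop = FALSE]
    rownames(masked_runs) <- NULL
  }
  total <- sum(pos$length) + sum(masked_runs$length)
  if (total != signal_len)
    stop("alignment does not conserve signal: layers cover ", total,
         " of ", signal_len, " samples")
  if (sum(blocks[, 2] - blocks[, 1]) != nrow(pos))
    stop("reference blocks span ", sum(blocks[, 2] - blocks[, 1]),
         " positions but ", nrow(pos), " layer rows present")
  structure(list(read_id = read_id, ref_name = ref_name, strand = strand,
                 blocks = blocks, pos = pos, masked_runs = masked_runs,
                 norm = norm, model_name = model_name,
                 signal_len = as.integer(signal_len)),
            class = "signal_aln")
}

#' @export
print.signal_aln <- function(x, ...) {
  cat(sprintf("signal_aln %s: %s%s %d positions in %d block(s), %d samples\n",
              x$read_id, x$ref_name, x$strand, nrow(x$pos), nrow(x$blocks),
              x$signal_len))
  invisible(x)
}

#' Per-reference-position layers from a DTW path
#'
#' Aggregates the raw samples between the assigned event boundaries for each
#' reference index: `length` is the aligned sample count, `current` the mean
#' and `current_sd` the population sd of those samples. Positions reached by
#' a skip copy the values of the position that owns the shared signal and get
#' `length` 0; every member of a skip group of `g` positions sharing `e`
#' events receives `event_count = e / g`.
#'
#' @param path DTW path from [banded_dtw()].
#' @param samples normalized raw samples.
#' @param events alignable event table (rows referenced by `path$event`).
#' @return data.frame, one row per reference index in traversal order:
#'   `length`, `current`, `current_sd`, `event_count`, `lo`, `hi`, `owner`.
#' @export
compute_layers <- function(path, samples, events) {
  n_ref <- max(path$ref) + 1L
  assign <- path_assignments(path, n_ref)
  run <- skip_run_ids(assign)
  ends <- events$start + events$length
  cs <- c(0, cumsum(samples))
  cs2 <- c(0, cumsum(samples^2))
  # per-event sums so positions whose events are separated by masked signal
  # aggregate only their own samples
  ev_n <- events$length
  ev_s <- cs[ends + 1L] - cs[events$start + 1L]
  ev_s2 <- cs2[ends + 1L] - cs2[events$start + 1L]
  out <- data.frame(length = integer(n_ref), current = NA_real_,
                    current_sd = NA_real_, event_count = NA_real_,
                    lo = NA_integer_, hi = NA_integer_,
                    owner = !is.na(assign$first))
  for (j in which(out$owner)) {
    e <- (assign$first[j] + 1L):(assign$last[j] + 1L)
    len <- sum(ev_n[e])
    m <- sum(ev_s[e]) / len
    v <- sum(ev_s2[e]) / len - m^2
    out$length[j] <- len
    out$current[j] <- m
    out$current_sd[j] <- sqrt(max(v, 0))
    out$lo[j] <- events$start[e[1]]
    out$hi[j] <- ends[e[length(e)]]
    out$event_count[j] <- length(e)
  }
  for (g in split(seq_len(n_ref), run)) {
    if (length(g) < 2) next
    ow <- g[1]
    out$current[g] <- out$current[ow]
    out$current_sd[g] <- out$current_sd[ow]
    out$lo[g] <- out$lo[ow]; out$hi[g] <- out$hi[ow]
    out$event_count[g] <- out$event_count[ow] / length(g)
  }
  out
}

#' Derived alignment layers
#'
#' Looks up a base or derived layer, optionally offset by a fixed number of
#' reference coordinates: the value reported at position `r` with offset `d`
#' is the base layer at `r + d` (`NA` off the ends). `dtw.dwell` is the
#' aligned sample count; `dtw.model_diff` the absolute difference between the
#' read current and the model current; `mvcmp.dist` the distance from the
#' move projection; `seq.kmer` the reference k-mer index.
#'
#' @param aln a [signal_aln()].
#' @param name one of `current`, `current_sd`, `dtw.dwell`, `length`,
#'   `dtw.model_diff`, `mvcmp.dist`, `event_count`, `seq.kmer`.
#' @param offset coordinate offset `d`.
#' @param model,refseq required for `dtw.model_diff` and `seq.kmer`.
#' @return numeric vector aligned with `aln$pos` rows.
#' @export
derived_layer <- function(aln, name, offset = 0L, model = NULL, refseq = NULL) {
  pos <- aln$pos
  base <- switch(name,
    current = pos$current,
    current_sd = pos$current_sd,
    length = , dtw.dwell = as.numeric(pos$length),
    event_count = pos$event_count,
    mvcmp.dist = pos$mvcmp_dist,
    dtw.model_diff = {
      if (is.null(model) || is.null(refseq))
        stop("dtw.model_diff requires model and refseq")
      es <- expected_signal(model, refseq, strand = aln$strand)
      abs(pos$current - es$mean[match(pos$ref_pos, es$position)])
    },
    seq.kmer = {
      if (is.null(model) || is.null(refseq))
        stop("seq.kmer requires model and refseq")
      es <- expected_signal(model, refseq, strand = aln$strand)
      as.numeric(es$kmer[match(pos$ref_pos, es$position)])
    },
    stop("unknown layer '", name, "'; valid layers: current, current_sd, ",
         "dtw.dwell, length, event_count, mvcmp.dist, dtw.model_diff, seq.kmer"))
  if (offset == 0L) return(base)
  base[match(pos$ref_pos + offset, pos$ref_pos)]
}

# 16-bit run-length encoding with sentinel chaining: any magnitude >= 65535
# is emitted as sentinel entries followed by the remainder.
encode_len16 <- function(v) {
  s <- sign(v)
  a <- abs(v)
  if (a < SENTINEL) return(as.integer(v))
  as.integer(s * c(rep(SENTINEL, a %/% SENTINEL), a %% SENTINEL))
}

quantize_current <- function(x, lo = FIXED_LO, hi = FIXED_HI) {
  q <- round((x - lo) / (hi - lo) * 65534)
  clipped <- sum(q < 0 | q > 65534, na.rm = TRUE)
  q <- pmin(pmax(q, 0), 65534)
  q[is.na(q)] <- NULL_Q
  structure(as.integer(q), clipped = clipped)
}

dequantize_current <- function(q, lo = FIXED_LO, hi = FIXED_HI) {
  attributes(q) <- NULL
  x <- q / 65534 * (hi - lo) + lo
  x[q == NULL_Q] <- NA_real_
  x
}

#' Encode a signal alignment as BAM auxiliary tags
#'
#' `us`: signal-order 16-bit run lengths — positive entries give the aligned
#' sample count of consecutive reference positions, negative entries masked
#' signal runs, zeros reference skips; magnitudes of 65535 or more chain the
#' sentinel 65535 with the following entry. `ur`: flattened `[start, stop)`
#' reference blocks. `uc`/`ud`: current mean/sd as 16-bit fixed-point over
#' `[-5, 5]` with 65535 reserved as null (masked positions). `un`:
#' `(scale, shift)`. The accompanying JSON header fragment records the tag
#' names, fixed-point range and model metadata.
#'
#' @param aln a [signal_aln()].
#' @return list with integer vectors `us`, `ur`, `uc`, `ud`, numeric `un`,
#'   and `json` (header fragment as a list).
#' @export
encode_tags <- function(aln) {
  pos <- aln$pos
  n <- nrow(pos)
  us <- integer(0)
  for (slot in seq_len(n + 1L)) {
    runs <- aln$masked_runs[aln$masked_runs$slot == slot, , drop = FALSE]
    for (len in runs$length) us <- c(us, encode_len16(-len))
    if (slot <= n) us <- c(us, encode_len16(pos$length[slot]))
  }
  cur <- pos$current
  csd <- pos$current_sd
  cur[pos$masked] <- NA_real_
  csd[pos$masked] <- NA_real_
  list(us = us,
       ur = as.integer(t(aln$blocks)),
       uc = quantize_current(cur),
       ud = quantize_current(csd),
       un = c(aln$norm$scale, aln$norm$shift),
       json = list(tags = c("us", "ur", "uc", "ud", "un"),
                   fixed_range = c(FIXED_LO, FIXED_HI),
                   model = aln$model_name))
}

# parse a us tag into segments: sign (+1 position, -1 masked) and magnitude,
# resolving sentinel chains.
parse_us <- function(us) {
  segs_sign <- integer(0); segs_len <- numeric(0)
  i <- 1L
  while (i <= length(us)) {
    v <- us[i]
    s <- if (v < 0) -1L else 1L
    acc <- abs(v)
    while (abs(us[i]) == SENTINEL) {
      i <- i + 1L
      if (i > length(us)) stop("truncated sentinel chain in us tag")
      acc <- acc + abs(us[i])
    }
    segs_sign <- c(segs_sign, s)
    segs_len <- c(segs_len, acc)
    i <- i + 1L
  }
  data.frame(sign = segs_sign, length = segs_len)
}

#' Decode BAM auxiliary tags back into a signal alignment
#'
#' Inverse of [encode_tags()]: lengths and reference coordinates are
#' reproduced exactly; currents within half a fixed-point quantum
#' (`10/65534/2`). Integrity checks: the sum of `|us|` must equal the
#' declared raw signal length, and the total `ur` span must equal the number
#' of non-negative `us` entries.
#'
#' @param tags list with `us`, `ur`, `uc`, `ud`, `un`.
#' @param read_id,ref_name,strand read metadata.
#' @param signal_len declared raw signal length (integrity check; optional).
#' @param model_name pore model label.
#' @return a [signal_aln()].
#' @export
decode_tags <- function(tags, read_id = "read", ref_name = "ref",
                        strand = "+", signal_len = NULL,
                        model_name = "custom") {
  segs <- parse_us(tags$us)
  npos <- sum(segs$sign > 0)
  blocks <- matrix(tags$ur, ncol = 2, byrow = TRUE)
  span <- sum(blocks[, 2] - blocks[, 1])
  if (span != npos)
    stop("integrity error for read ", read_id, ": ur span ", span,
         " != ", npos, " non-negative us entries")
  total <- sum(segs$length)
  if (!is.null(signal_len) && total != signal_len)
    stop("integrity error for read ", read_id, ": sum(|us|) = ", total,
         " != declared signal length ", signal_len)
  ref_pos <- unlist(lapply(seq_len(nrow(blocks)),
                           function(b) blocks[b, 1]:(blocks[b, 2] - 1L)))
  if (strand == "-") ref_pos <- rev(ref_pos)
  cur <- dequantize_current(tags$uc)
  csd <- dequantize_current(tags$ud)
  pos <- data.frame(ref_pos = ref_pos,
                    length = as.integer(segs$length[segs$sign > 0]),
                    current = cur, current_sd = csd,
                    event_count = NA_real_, mvcmp_dist = NA_real_,
                    masked = is.na(cur))
  slot <- cumsum(segs$sign > 0) + 1L
  mr <- data.frame(slot = slot[segs$sign < 0],
                   length = as.integer(segs$length[segs$sign < 0]))
  signal_aln(read_id, ref_name, strand, blocks, pos, mr,
             norm = list(scale = tags$un[1], shift = tags$un[2]),
             model_name = model_name, signal_len = total)
}

# sample intervals per position row (skips share the owner's interval)
position_sample_intervals <- function(aln) {
  pos <- aln$pos
  n <- nrow(pos)
  lo <- integer(n); hi <- integer(n)
  cursor <- 0L
  for (i in seq_len(n)) {
    runs <- aln$masked_runs[aln$masked_runs$slot == i, , drop = FALSE]
    cursor <- cursor + sum(runs$length)
    lo[i] <- cursor
    hi[i] <- cursor + pos$length[i]
    cursor <- hi[i]
  }
  # skips (length 0) share the previous owner's interval
  owner_lo <- lo; owner_hi <- hi
  for (i in seq_len(n)) {
    if (pos$length[i] == 0L && i > 1L) {
      j <- max(which(pos$length[seq_len(i)] > 0L), 0L)
      if (j > 0L) { owner_lo[i] <- lo[j]; owner_hi[i] <- hi[j] }
    }
  }
  data.frame(ref_pos = pos$ref_pos, lo = owner_lo, hi = owner_hi,
             own_lo = lo, own_hi = hi)
}

#' Per-sample reference coordinates of an alignment
#'
#' Expands the run-length layers into a vector with one entry per raw
#' sample: the reference position the sample is aligned to, or `NA` inside
#' masked signal runs. Element `i` corresponds to 0-based sample `i - 1`.
#'
#' @param aln a [signal_aln()].
#' @return integer vector of length `aln$signal_len`.
#' @export
sample_ref_map <- function(aln) {
  pos <- aln$pos
  map <- rep(NA_integer_, aln$signal_len)
  iv <- position_sample_intervals(aln)
  for (i in seq_len(nrow(pos))) {
    if (pos$length[i] > 0L)
      map[(iv$own_lo[i] + 1L):iv$own_hi[i]] <- pos$ref_pos[i]
  }
  map
}
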