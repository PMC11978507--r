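#' Align one raw signal read to a reference
#'
#' Full basecaller-guided alignment of a single read: event detection,
#' projection of the basecaller move table through the cigar, splicing of
#' large indels, method-of-moments normalization against the covered model
#' k-mers, banded DTW, optional regression re-normalization with a second
#' DTW pass, skip masking, and per-position layer computation. Per-position
#' current statistics are computed from the raw samples between the assigned
#' event boundaries, not from event summaries.
#'
#' @param read a [raw_read()] or a numeric vector of pA samples.
#' @param bam basecalled record: list with `read_id`, `strand`, `ref_name`,
#'   `ref_start` (0-based), `cigar`, `moves`, `stride`, `ts`.
#' @param model a [pore_model()].
#' @param refseq reference nucleotide string for `bam$ref_name`.
#' @param params an [align_params()] list.
#' @return a [signal_aln()] with `mvcmp_dist` populated.
#' @export
align_read <- function(read, bam, model, refseq, params = align_params()) {
  if (is.null(bam$moves))
    stop("read ", bam$read_id, ": missing basecaller move table")
  pa <- if (inherits(read, "raw_read")) calibrate_signal(read) else
    as.numeric(read)
  n_samp <- length(pa)
  ev_all <- detect_events(pa, params$event_params)

  rm <- project_moves(bam$moves, bam$stride, bam$ts %||% 0L, bam$cigar,
                      bam$ref_start, strand = bam$strand,
                      signal_len = n_samp,
                      reverse_signal = model$reverse_signal)
  rm <- splice_indels(rm, params$del_max)

  es <- expected_signal(model, refseq, strand = bam$strand)
  emean <- es$mean[match(rm$tab$ref_pos, es$position)]
  keep <- is.finite(emean)
  tab <- rm$tab[keep, , drop = FALSE]
  emean <- emean[keep]
  esd <- es$sd[match(tab$ref_pos, es$position)]
  if (nrow(tab) < 2)
    stop("read ", bam$read_id, ": fewer than 2 alignable reference positions")

  # classify events: alignable vs masked (outside the projected span or
  # inside a spliced-out insertion)
  amin <- min(tab$lo); amax <- max(tab$hi)
  mids <- ev_all$start + ev_all$length / 2
  maskev <- mids < amin | mids >= amax
  # spliced-insertion ranges are stride-quantized (both ends biased early);
  # an event belongs to the insertion iff it fits in the range grown by one
  # stride on the right — exact whenever dwells exceed the stride
  ev_end <- ev_all$start + ev_all$length
  for (i in seq_len(nrow(rm$masked_ranges)))
    maskev <- maskev | (ev_all$start >= rm$masked_ranges[i, 1] &
                          ev_end <= rm$masked_ranges[i, 2] + rm$stride)
  evs <- ev_all[!maskev, , drop = FALSE]
  if (nrow(evs) < 2)
    stop("read ", bam$read_id, ": fewer than 2 alignable events")

  nrm <- mom_normalize(evs$mean, emean)
  band <- place_band(list(tab = tab), evs, params$bandwidth)
  expd <- list(mean = emean, sd = esd)
  d <- banded_dtw(nrm$scale * evs$mean + nrm$shift, expd, band,
                  params$skip_cost, params$z_cost)
  total <- nrm
  if (params$norm_iterations == 2L) {
    lay1 <- compute_layers(d$path, nrm$scale * pa + nrm$shift, evs)
    reg <- tryCatch(
      regression_normalize(lay1$current[lay1$owner], emean[lay1$owner]),
      error = function(e) list(scale = 1, shift = 0, iteration = 2L))
    total <- compose_norm(nrm, reg)
    d <- banded_dtw(total$scale * evs$mean + total$shift, expd, band,
                    params$skip_cost, params$z_cost)
  }
  nsamp_norm <- total$scale * pa + total$shift
  lay <- compute_layers(d$path, nsamp_norm, evs)

  masked <- mask_skips(d$path, params$mask_skips, emean, lay$current)
  if (!params$unmask_splice && nrow(rm$excised) > 0) {
    k <- model$k; cp <- model$central_pos
    for (i in seq_len(nrow(rm$excised))) {
      a <- rm$excised[i, 1]; b <- rm$excised[i, 2]
      masked <- masked | (tab$ref_pos - cp < b & tab$ref_pos - cp + k > a)
    }
  }

  # one-sided signal-to-reference distance from the move projection
  mvmap <- rep(NA_integer_, n_samp)
  for (i in seq_len(nrow(tab)))
    if (tab$hi[i] > tab$lo[i])
      mvmap[(tab$lo[i] + 1L):tab$hi[i]] <- tab$ref_pos[i]
  mv_d <- vapply(seq_len(nrow(lay)), function(j) {
    if (is.na(lay$lo[j]) || lay$hi[j] <= lay$lo[j]) return(NA_real_)
    r <- mvmap[(lay$lo[j] + 1L):lay$hi[j]]
    mean(abs(tab$ref_pos[j] - r), na.rm = TRUE)
  }, 0)

  # masked sample runs in signal order, with the us slot they precede
  masked_ev <- which(maskev)
  mr <- data.frame(slot = integer(0), length = integer(0))
  if (length(masked_ev)) {
    runs <- split(masked_ev, cumsum(c(1L, diff(masked_ev) != 1L)))
    keyhi <- lay$hi
    keyhi[is.na(keyhi)] <- 0L # skips sort with their owner via cummax below
    keyhi <- cummax(keyhi)
    for (run in runs) {
      s <- ev_all$start[run[1]]
      len <- sum(ev_all$length[run])
      mr <- rbind(mr, data.frame(slot = sum(keyhi <= s) + 1L, length = len))
    }
  }

  pos <- data.frame(ref_pos = tab$ref_pos, length = lay$length,
                    current = lay$current, current_sd = lay$current_sd,
                    event_count = lay$event_count, mvcmp_dist = mv_d,
                    masked = masked)
  rp <- sort(pos$ref_pos)
  brk <- which(diff(rp) != 1L)
  blocks <- cbind(rp[c(1L, brk + 1L)], rp[c(brk, length(rp))] + 1L)
  signal_aln(bam$read_id, bam$ref_name %||% "ref", bam$strand, blocks, pos,
             mr, norm = list(scale = total$scale, shift = total$shift),
             model_name = model$name, signal_len = n_samp)
}

#' Align a set of reads
#'
#' Applies [align_read()] to each read, logging and counting per-read
#' failures rather than aborting.
#'
#' @param reads list of [raw_read()] objects (or numeric sample vectors).
#' @param bams list of basecalled records, parallel to `reads`.
#' @param model a [pore_model()].
#' @param refseqs named character vector of reference sequences.
#' @param params an [align_params()] list.
#' @param quiet suppress per-read failure messages.
#' @return list with `alignments` (list of [signal_aln()]), `failures`
#'   (character vector of messages), `n_failed`.
#' @export
align_reads <- function(reads, bams, model, refseqs, params = align_params(),
                        quiet = TRUE) {
  alns <- list(); fails <- character(0)
  for (i in seq_along(reads)) {
    ref <- refseqs[[bams[[i]]$ref_name %||% 1L]] %||% refseqs[[1L]]
    a <- tryCatch(align_read(reads[[i]], bams[[i]], model, ref, params),
                  error = function(e) e)
    if (inherits(a, "error")) {
      fails <- c(fails, conditionMessage(a))
      if (!quiet) message("alignment failed: ", conditionMessage(a))
    } else {
      alns[[length(alns) + 1L]] <- a
    }
  }
  list(alignments = alns, failures = fails, n_failed = length(fails))
}
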