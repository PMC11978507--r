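#' Alignment parameters
#'
#' Defaults follow the tool's printed conventions: bandwidth 25 events,
#' skip cost 2 (4 during model training), del-max 10, two normalization
#' iterations for standard alignment (one during training).
#'
#' @param bandwidth DTW band width in events.
#' @param skip_cost multiplicative penalty applied to the accumulated cost of
#'   a skip transition (`>= 1`).
#' @param del_max indels longer than this many bases are spliced out.
#' @param mask_skips one of `"none"`, `"all"`, `"keep_best"`.
#' @param unmask_splice keep (rather than mask) reference k-mers straddling a
#'   spliced-out deletion.
#' @param norm_iterations 1 (method-of-moments only) or 2 (plus regression
#'   and a second DTW pass).
#' @param z_cost use `|e - m| / sd` instead of `|e - m|` as the DTW cost.
#' @param events an [event_params()] list.
#' @return list of parameters.
#' @export
align_params <- function(bandwidth = 25L, skip_cost = 2, del_max = 10L,
                         mask_skips = c("none", "all", "keep_best"),
                         unmask_splice = FALSE, norm_iterations = 2L,
                         z_cost = FALSE, events = event_params()) {
  stopifnot(bandwidth >= 1, skip_cost >= 1, del_max >= 1,
            norm_iterations %in% 1:2)
  list(bandwidth = as.integer(bandwidth), skip_cost = skip_cost,
       del_max = as.integer(del_max), mask_skips = match.arg(mask_skips),
       unmask_splice = isTRUE(unmask_splice),
       norm_iterations = as.integer(norm_iterations),
       z_cost = isTRUE(z_cost), event_params = events)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) stop("unparsable cigar: ", cigar)
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
             op = sub("^[0-9]+", "", toks))
}

#' Project basecaller moves into reference coordinates
#'
#' The move table maps signal blocks of `stride` samples to basecalled read
#' bases; the cigar string maps read bases to reference positions. The
#' projection assigns each covered reference position a candidate raw-sample
#' interval. Insertions and soft clips merge their samples into the preceding
#' position's interval; deletions receive intervals linearly interpolated
#' between their flanks; introns (`N`) always break the projection into
#' separate blocks. For reverse-strand reads (and 3'->5' signal) the
#' projection is walked in signal order, so rows ascend in sample coordinate
#' while `ref_pos` descends.
#'
#' @param moves binary move table (one entry per stride block, 1 = new base).
#' @param stride samples per move step (5 for DNA, 10 for RNA).
#' @param signal_offset first raw sample covered by the move table.
#' @param cigar basecalled alignment cigar (M/=/X/I/D/N/S/H/P).
#' @param ref_start 0-based reference start of the alignment.
#' @param strand `"+"` or `"-"`.
#' @param signal_len total raw samples (clips the final base's interval).
#' @param reverse_signal signal traverses the read 3'->5' (direct RNA).
#' @return a `ref_moves` list: `tab` (data.frame `ref_pos`, `lo`, `hi` in
#'   signal order), `ins` (insertion records), `gaps` (deletion/intron runs),
#'   plus `stride` and `strand`.
#' @export
project_moves <- function(moves, stride, signal_offset, cigar, ref_start,
                          strand = "+", signal_len = NULL,
                          reverse_signal = FALSE) {
  ops <- parse_cigar(cigar)
  steps <- which(moves == 1L) - 1L
  nb <- length(steps)
  consumed <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  if (consumed != nb)
    stop("cigar/moves mismatch: cigar consumes ", consumed,
         " read bases but move table has ", nb)
  base_start <- signal_offset + stride * steps
  base_end <- c(base_start[-1], signal_offset + stride * length(moves))
  if (!is.null(signal_len)) base_end <- pmin(base_end, signal_len)

  mirror <- (strand == "-") != isTRUE(reverse_signal)
  if (mirror) { # walk the cigar so rows come out in signal order
    ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
    r <- ref_start + sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")]) - 1L
    rstep <- -1L
  } else {
    r <- ref_start
    rstep <- 1L
  }
  q <- 0L # signal-order base index
  ref_pos <- lo <- hi <- integer(0)
  ins <- list(); gaps <- list()
  del_rows <- integer(0)
  for (o in seq_len(nrow(ops))) {
    op <- ops$op[o]; L <- ops$len[o]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, seq(r, by = rstep, length.out = L))
      lo <- c(lo, base_start[q + seq_len(L)])
      hi <- c(hi, base_end[q + seq_len(L)])
      q <- q + L; r <- r + rstep * L
    } else if (op %in% c("I", "S")) {
      s_lo <- base_start[q + 1L]; s_hi <- base_end[q + L]
      owner <- length(ref_pos)
      if (owner > 0L) hi[owner] <- max(hi[owner], s_hi)
      ins[[length(ins) + 1L]] <-
        data.frame(owner = if (owner > 0L) owner else NA_integer_,
                   lo = s_lo, hi = s_hi, nbases = L)
      q <- q + L
    } else if (op == "D" || op == "N") {
      rlo <- min(r, r + rstep * (L - 1L))
      gaps[[length(gaps) + 1L]] <-
        data.frame(ref_lo = rlo, ref_hi = rlo + L, intron = (op == "N"))
      if (op == "D") {
        ref_pos <- c(ref_pos, seq(r, by = rstep, length.out = L))
        del_rows <- c(del_rows, length(lo) + seq_len(L))
        lo <- c(lo, rep(NA_integer_, L)); hi <- c(hi, rep(NA_integer_, L))
      }
      r <- r + rstep * L
    } # H, P consume nothing
  }
  # interpolate deletion placeholders between flanking intervals
  if (length(del_rows)) {
    runs <- split(del_rows, cumsum(c(1L, diff(del_rows) != 1L)))
    n <- length(lo)
    for (run in runs) {
      ph <- if (min(run) > 1L) hi[min(run) - 1L] else lo[max(run) + 1L]
      nl <- if (max(run) < n) lo[max(run) + 1L] else hi[min(run) - 1L]
      b <- round(seq(ph, nl, length.out = length(run) + 1L))
      lo[run] <- b[-length(b)]
      hi[run] <- b[-1L]
    }
  }
  structure(list(tab = data.frame(ref_pos = as.integer(ref_pos),
                                  lo = as.integer(lo), hi = as.integer(hi)),
                 ins = if (length(ins)) do.call(rbind, ins) else
                   data.frame(owner = integer(0), lo = integer(0),
                              hi = integer(0), nbases = integer(0)),
                 gaps = if (length(gaps)) do.call(rbind, gaps) else
                   data.frame(ref_lo = integer(0), ref_hi = integer(0),
                              intron = logical(0)),
                 stride = stride, strand = strand, mirror = mirror),
            class = "ref_moves")
}

#' Splice large indels out of a projection
#'
#' Insertions longer than `del_max` have their samples removed from the
#' alignable signal and recorded as masked ranges; deletions longer than
#' `del_max` (and all introns) have their reference positions excised,
#' breaking the projection into separate reference blocks. Indels up to
#' `del_max` are left for the DTW to resolve.
#'
#' @param rm a `ref_moves` object from [project_moves()].
#' @param del_max splice threshold in bases.
#' @return the `ref_moves` with `tab` filtered, plus `blocks` (matrix of
#'   `[start, stop)` reference intervals), `masked_ranges` (matrix of
#'   `[lo, hi)` sample intervals) and `excised` (matrix of reference ranges).
#' @export
splice_indels <- function(rm, del_max = 10L) {
  stopifnot(del_max >= 1)
  tab <- rm$tab
  masked <- matrix(integer(0), ncol = 2)
  big_ins <- rm$ins[rm$ins$nbases > del_max, , drop = FALSE]
  for (i in seq_len(nrow(big_ins))) {
    masked <- rbind(masked, c(big_ins$lo[i], big_ins$hi[i]))
    ow <- big_ins$owner[i]
    if (!is.na(ow) && tab$hi[ow] >= big_ins$hi[i] && tab$lo[ow] <= big_ins$lo[i])
      tab$hi[ow] <- big_ins$lo[i]
  }
  excise <- rm$gaps[rm$gaps$intron |
                      (rm$gaps$ref_hi - rm$gaps$ref_lo) > del_max, ,
                    drop = FALSE]
  drop <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(excise)))
    drop <- drop | (tab$ref_pos >= excise$ref_lo[i] &
                      tab$ref_pos < excise$ref_hi[i])
  tab <- tab[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  rp <- sort(tab$ref_pos)
  brk <- which(diff(rp) != 1L)
  blocks <- cbind(rp[c(1L, brk + 1L)], rp[c(brk, length(rp))] + 1L)
  rm$tab <- tab
  rm$blocks <- blocks
  rm$masked_ranges <- masked
  rm$excised <- as.matrix(excise[, c("ref_lo", "ref_hi"), drop = FALSE])
  rm
}

#' Place the DTW band on the ref-moves
#'
#' For each reference index (row of the projection, in traversal order) the
#' band is the event-index interval of `width` events centered on the event
#' containing the midpoint of the projected sample interval, clipped to valid
#' events and forced monotone so intervals never move backwards. The first
#' and last columns are widened to include the first and last event so every
#' event can be assigned.
#'
#' @param rm a spliced `ref_moves` object.
#' @param events event table from [detect_events()] (the alignable events).
#' @param width band width in events.
#' @return list with integer vectors `top` and `bottom` (0-based, half-open
#'   per reference index).
#' @export
place_band <- function(rm, events, width = 25L) {
  n_ev <- nrow(events)
  if (n_ev == 0) stop("empty event list")
  m <- nrow(rm$tab)
  if (m == 0) stop("projection spans no reference positions")
  mids <- (rm$tab$lo + rm$tab$hi) %/% 2L
  center <- findInterval(mids, events$start) - 1L
  center <- pmin(pmax(center, 0L), n_ev - 1L)
  top <- center - width %/% 2L
  bottom <- top + width
  top <- pmax(top, 0L)
  bottom <- pmin(pmax(bottom, top + 1L), n_ev)
  top <- pmin(top, bottom - 1L)
  top[1] <- 0L
  bottom[m] <- n_ev
  top <- cummax(top)
  bottom <- pmin(cummax(bottom), n_ev)
  # connectivity: entering column j requires an in-band cell in column j-1
  if (m > 1) {
    for (j in (m - 1):1)
      bottom[j] <- min(max(bottom[j], top[j + 1] + 1L), n_ev)
    bottom <- pmin(cummax(bottom), n_ev)
  }
  top <- pmin(top, bottom - 1L)
  list(top = top, bottom = bottom, width = width)
}

#' Banded dynamic time warping
#'
#' Fills the banded dynamic programming matrix with the recurrence
#' `D[i,j] = min(cost + D[i-1,j-1], cost + D[i-1,j], skip*cost + D[i,j-1])`
#' where `cost(i,j) = |event_mean[i] - expected_mean[j]|`: the skip penalty
#' multiplies the cost term of the skip step (so a skip over a
#' perfectly-matching position is free, and the penalty stays proportional
#' to the local model mismatch). Cells outside the band are infinite and
#' `D[0,0] = cost(0,0)`. The traceback breaks ties diagonal > stay > skip
#' and returns the full warping path.
#'
#' @param event_means normalized event current means (rows).
#' @param expected data.frame/list with `mean` (and `sd`) per reference index
#'   in traversal order (columns).
#' @param band band from [place_band()].
#' @param skip_cost multiplicative skip penalty.
#' @param z_cost divide the cost by the model sd.
#' @return list with `cost` and `path` (data.frame `event`, `ref` 0-based,
#'   `move` in match/stay/skip/origin).
#' @export
banded_dtw <- function(event_means, expected, band, skip_cost = 2,
                       z_cost = FALSE) {
  stopifnot(skip_cost >= 1)
  sds <- if (!is.null(expected$sd)) expected$sd else rep(1, length(expected$mean))
  res <- banded_dtw_cpp(event_means, expected$mean, sds,
                        band$top, band$bottom, skip_cost, z_cost)
  if (!is.finite(res$cost))
    stop("alignment failed: no finite path through the band")
  list(cost = res$cost,
       path = data.frame(event = res$event, ref = res$ref,
                         move = c("match", "stay", "skip", "origin")[res$move + 1L]))
}

# per-reference-index assignment summary from a DTW path:
# first/last assigned event (NA for skips) and the event shared by a skip.
path_assignments <- function(path, n_ref) {
  adv <- path$move != "skip"
  ev_ref <- rep(NA_integer_, max(path$event) + 1L)
  ev_ref[path$event[adv] + 1L] <- path$ref[adv]
  first <- last <- rep(NA_integer_, n_ref)
  for (j in unique(path$ref[adv])) {
    evs <- path$event[adv & path$ref == j]
    first[j + 1L] <- min(evs); last[j + 1L] <- max(evs)
  }
  skip_share <- rep(NA_integer_, n_ref)
  sk <- path$move == "skip"
  skip_share[path$ref[sk] + 1L] <- path$event[sk]
  list(first = first, last = last, skip_share = skip_share, ev_ref = ev_ref)
}

# group reference indices into runs sharing identical sample coordinates:
# a run is an assigned owner followed by the skip positions that share its
# signal. returns an integer run id per reference index (traversal order).
skip_run_ids <- function(assign) {
  n <- length(assign$first)
  run <- integer(n)
  cur <- 0L
  for (j in seq_len(n)) {
    if (!is.na(assign$first[j])) cur <- cur + 1L
    run[j] <- cur
  }
  run
}

#' Mask skipped reference positions
#'
#' A skip run is two or more consecutive reference positions sharing
#' identical sample coordinates. `"all"` masks every position in each run;
#' `"keep_best"` keeps only the position whose expected mean is closest to
#' the shared observed mean; `"none"` leaves runs untouched (the default for
#' alignment; training uses `keep_best`).
#'
#' @param path DTW path (from [banded_dtw()]).
#' @param mode `"none"`, `"all"` or `"keep_best"`.
#' @param expected expected means per reference index (traversal order).
#' @param observed observed mean per reference index (shared within a run).
#' @return logical vector: `TRUE` where the position is masked.
#' @export
mask_skips <- function(path, mode = c("none", "all", "keep_best"),
                       expected, observed) {
  mode <- match.arg(mode)
  n <- length(expected)
  masked <- rep(FALSE, n)
  if (mode == "none") return(masked)
  assign <- path_assignments(path, n)
  run <- skip_run_ids(assign)
  for (g in split(seq_len(n), run)) {
    if (length(g) < 2) next
    if (mode == "all") {
      masked[g] <- TRUE
    } else {
      best <- g[which.min(abs(expected[g] - observed[g]))]
      masked[setdiff(g, best)] <- TRUE
    }
  }
  masked
}
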