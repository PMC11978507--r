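#' Synthetic k-mer pore model
#'
#' Generates a realistic truth model for simulation: per-position additive
#' base effects whose magnitudes decay away from the central base (the
#' structure seen in real substitution profiles, where the central base
#' dominates and influence falls off with distance) plus a small
#' k-mer-specific interaction term, normalized to mean 0 / sd 1. Per-k-mer
#' sds are 1 so the simulator's `noise_sd` is expressed directly in
#' normalized units.
#'
#' @param k k-mer length.
#' @param central_pos central base position (default middle).
#' @param effect_sds per-position effect magnitudes; default decays from 1.0
#'   at the central base.
#' @param interaction_sd sd of the non-additive per-k-mer term.
#' @param seed optional RNG seed.
#' @param pa_mean,pa_sd calibration to a pA-like scale.
#' @return a normalized [pore_model()].
#' @export
synthetic_pore_model <- function(k = 5L, central_pos = (k - 1L) %/% 2L,
                                 effect_sds = NULL, interaction_sd = 0.05,
                                 seed = NULL, pa_mean = 100, pa_sd = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effect_sds))
    effect_sds <- 0.3^abs(seq_len(k) - 1L - central_pos)
  stopifnot(length(effect_sds) == k)
  idx <- 0:(4^k - 1L)
  means <- stats::rnorm(4^k, 0, interaction_sd)
  for (p in 0:(k - 1L)) {
    eff <- stats::rnorm(4, 0, effect_sds[p + 1L])
    d <- (idx %/% 4L^(k - 1L - p)) %% 4L
    means <- means + eff[d + 1L]
  }
  out <- normalize_pore_model(pore_model(means, 1, k, central_pos,
                                         pa_mean = pa_mean, pa_sd = pa_sd,
                                         name = sprintf("synthetic_%dmer", k)))
  out$sds <- rep(1, 4^k) # unit per-k-mer sd in normalized units
  out
}

#' Shift model currents at modified k-mers
#'
#' Emulates a nucleotide modification by shifting the expected current of
#' every k-mer matching an IUPAC motif at a fixed offset from the central
#' base; used to simulate the "modified" track for KS / z-score detection
#' tests.
#'
#' @param model a [pore_model()].
#' @param motif IUPAC motif string (e.g. `"CG"`).
#' @param offset 0-based offset of the motif start from the central base.
#' @param delta current shift in normalized units.
#' @return modified `pore_model` (not re-normalized; the shift is the planted
#'   signal).
#' @export
inject_modification <- function(model, motif, offset = 0L, delta) {
  k <- model$k
  start <- model$central_pos + offset
  n <- nchar(motif)
  if (start < 0L || start + n > k)
    stop("motif does not fit within the k-mer at offset ", offset)
  codes <- strsplit(Biostrings::IUPAC_CODE_MAP[
    strsplit(toupper(motif), "")[[1]]], "")
  idx <- 0:(4^k - 1L)
  match_mask <- rep(TRUE, 4^k)
  for (i in seq_len(n)) {
    p <- start + i - 1L
    d <- (idx %/% 4L^(k - 1L - p)) %% 4L
    match_mask <- match_mask & (BASES[d + 1L] %in% codes[[i]])
  }
  if (!any(match_mask)) warning("no k-mer matches motif ", motif)
  model$means[match_mask] <- model$means[match_mask] + delta
  model$name <- paste0(model$name, "_mod")
  model
}

#' Simulation parameters
#'
#' The generator's defaults emulate the regimes reported for real pores:
#' median dwell around 8 samples, roughly half of events being stays
#' (implied by the dwell distribution and event segmentation), skip rates of
#' a few percent, move tables at stride 5 with +/-1 step jitter, and mild
#' per-read affine scale/shift distortion.
#'
#' @param noise_sd current noise sd in normalized units (multiplies the
#'   model's per-k-mer sd).
#' @param dwell_mean mean dwell (raw samples per position;
#'   shifted-geometric).
#' @param dwell_min minimum dwell in samples; the default of 4 keeps dwells
#'   at or above the event detector's resolution so the effective skip rate
#'   stays in the few-percent regime real pores show.
#' @param skip_prob probability a position receives no signal (skip).
#' @param move_jitter move-table step jitter (+/- steps).
#' @param scale_sd,shift_sd sd of the per-read multiplicative/additive
#'   distortion (relative units).
#' @param stride move-table resolution in samples (5 DNA, 10 RNA).
#' @param digitisation,offset,range,sampling_rate DAC calibration constants.
#' @param dwell_effect optional planted dwell-sequence dependence at a fixed
#'   offset: either `list(offset, base, factor)` (dwell mean multiplied by
#'   `factor` when `ref[r + offset] == base`) or
#'   `list(offset, log_factors)` with one log-scale factor per m-mer,
#'   applied via the m-mer starting at `r + offset`.
#' @return list of parameters.
#' @export
sim_params <- function(noise_sd = 0.3, dwell_mean = 8, dwell_min = 4L,
                       skip_prob = 0.02, move_jitter = 1L, scale_sd = 0.05,
                       shift_sd = 0.05, stride = 5L, digitisation = 8192,
                       offset = 10, range = 1500, sampling_rate = 4000,
                       dwell_effect = NULL) {
  if (dwell_mean < 1) stop("impossible parameters: dwell_mean must be >= 1")
  stopifnot(noise_sd >= 0, skip_prob >= 0, skip_prob < 1, stride >= 1,
            dwell_min >= 1)
  as.list(environment())
}

#' Simulate one raw nanopore read with full ground truth
#'
#' Draws, per covered reference position, a shifted-geometric dwell (with
#' probability `skip_prob` the position is skipped), Gaussian current around
#' the model k-mer mean, a per-read affine scale/shift distortion, and a
#' low-resolution move table with step jitter; the result is returned with
#' the true sample-to-reference map so alignments can be scored exactly.
#'
#' @param refseq reference nucleotide string.
#' @param model truth [pore_model()].
#' @param read_id read name.
#' @param params a [sim_params()] list.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @param ref_start,ref_len covered span (defaults to the whole modelled
#'   range of the reference).
#' @param indels optional data.frame with columns `op` (`"I"`/`"D"`), `at`
#'   (0-based reference position) and `len`.
#' @return a `sim_read`: list with `read` ([raw_read()]), `truth`
#'   (data.frame `ref_pos`, `lo`, `hi`), `moves`, `stride`, `ts`, `cigar`,
#'   `ref_start`, `strand`, `seq`, `true_scale`, `true_shift`.
#' @export
simulate_read <- function(refseq, model, read_id = "read1",
                          params = sim_params(), seed = NULL,
                          ref_start = NULL, ref_len = NULL, indels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- model$k; cp <- model$central_pos
  L <- nchar(refseq)
  lo_valid <- cp
  hi_valid <- L - (k - 1L - cp) # exclusive
  if (is.null(ref_start)) ref_start <- lo_valid
  if (is.null(ref_len)) ref_len <- hi_valid - ref_start
  s <- max(ref_start, lo_valid)
  e <- min(ref_start + ref_len, hi_valid)
  if (e - s < k) stop("reference span too short to simulate")
  es <- expected_signal(model, refseq)
  pos <- s:(e - 1L)

  # reference-position elements, minus deletions
  mops <- data.frame(ref_pos = pos, type = "M", mean = es$mean[pos + 1L],
                     sd = es$sd[pos + 1L])
  ins_spec <- NULL
  if (!is.null(indels)) {
    for (i in seq_len(nrow(indels))) {
      at <- indels$at[i]; len <- indels$len[i]
      if (indels$op[i] == "D") {
        drop <- mops$ref_pos >= at & mops$ref_pos < at + len
        mops <- mops[!drop, , drop = FALSE]
      } else {
        ins_spec <- rbind(ins_spec, data.frame(at = at, len = len))
      }
    }
  }
  n_m <- nrow(mops)

  # Reference-position randomness is drawn before any insertion randomness,
  # so two reads with the same seed differing only by an insertion share
  # every per-position dwell and sample draw.
  dmean <- rep(params$dwell_mean, n_m)
  if (!is.null(params$dwell_effect)) {
    de <- params$dwell_effect
    tgt <- mops$ref_pos + de$offset
    if (!is.null(de$log_factors)) {
      # full m-mer dependence: dwell modulated by the m-mer at r + offset
      m_len <- as.integer(round(log(length(de$log_factors), 4)))
      kidx <- seq_kmer_indices(refseq, m_len)
      ok <- tgt >= 0 & tgt <= L - m_len
      dmean[ok] <- dmean[ok] * exp(de$log_factors[kidx[tgt[ok] + 1L] + 1L])
    } else {
      hit <- tgt >= 0 & tgt < L &
        substring(refseq, tgt + 1L, tgt + 1L) == de$base
      dmean[hit] <- dmean[hit] * de$factor
    }
  }
  dwell_m <- params$dwell_min +
    stats::rgeom(n_m, pmin(1, 1 / pmax(dmean - params$dwell_min + 1, 1)))
  skip <- stats::runif(n_m) < params$skip_prob
  skip[c(1L, n_m)] <- FALSE      # anchor the ends
  dwell_m[skip] <- 0L
  x_m <- lapply(seq_len(n_m), function(i)
    if (dwell_m[i] > 0)
      stats::rnorm(dwell_m[i], mops$mean[i], params$noise_sd * mops$sd[i])
    else numeric(0))
  sj <- max(0.1, stats::rnorm(1, 1, params$scale_sd))
  hj <- stats::rnorm(1, 0, params$shift_sd)
  jit_m <- if (params$move_jitter > 0)
    sample(-params$move_jitter:params$move_jitter, n_m, replace = TRUE)
  else integer(n_m)

  # insertion randomness (drawn last)
  ops <- cbind(mops, dwell = dwell_m, jit = jit_m)
  ops$x <- x_m
  if (!is.null(ins_spec)) {
    for (i in order(ins_spec$at, decreasing = TRUE)) {
      row <- which(ops$ref_pos == ins_spec$at[i] & ops$type == "M")[1]
      if (is.na(row)) next
      len <- ins_spec$len[i]
      ki <- sample.int(4^k, len, replace = TRUE)
      dw <- params$dwell_min +
        stats::rgeom(len, min(1, 1 / max(params$dwell_mean -
                                           params$dwell_min + 1, 1)))
      ji <- if (params$move_jitter > 0)
        sample(-params$move_jitter:params$move_jitter, len, replace = TRUE)
      else integer(len)
      ins <- data.frame(ref_pos = NA_integer_, type = "I",
                        mean = model$means[ki], sd = model$sds[ki],
                        dwell = dw, jit = ji)
      ins$x <- lapply(seq_len(len), function(j)
        stats::rnorm(dw[j], ins$mean[j], params$noise_sd * ins$sd[j]))
      ops <- rbind(ops[seq_len(row), , drop = FALSE], ins,
                   ops[-seq_len(row), , drop = FALSE])
    }
  }
  n_el <- nrow(ops)
  dwell <- ops$dwell
  x <- unlist(ops$x)
  starts <- c(0L, cumsum(dwell))[seq_len(n_el)]
  n_samp <- sum(dwell)

  pa <- (model$pa_sd * x + model$pa_mean) * sj + hj * model$pa_sd
  true_scale <- model$pa_sd * sj                 # pA per normalized unit
  true_shift <- model$pa_mean * sj + hj * model$pa_sd
  dac <- as.integer(round(pa * params$digitisation / params$range -
                            params$offset))

  # move table: one step per emitted base, strictly increasing
  n_steps <- ceiling(n_samp / params$stride)
  step <- starts %/% params$stride + ops$jit
  step <- pmin(pmax(step, 0L), n_steps - 1L)
  for (i in seq_len(n_el)[-1]) step[i] <- max(step[i], step[i - 1L] + 1L)
  if (any(step >= n_steps))
    for (i in n_el:1) step[i] <- min(step[i], n_steps - n_el + i - 1L)
  if (any(step < 0) || any(duplicated(step)))
    stop("cannot place moves: signal too short for the read length")
  moves <- integer(n_steps); moves[step + 1L] <- 1L

  # cigar: walk emitted elements, inserting D ops where the covered
  # reference positions jump
  cigar <- {
    ty <- ops$type; rp <- ops$ref_pos
    toks <- character(0)
    cur_op <- ty[1]; cur_n <- 1L; last_ref <- rp[1]
    for (ii in seq_len(n_el)[-1]) {
      gap <- if (!is.na(rp[ii]) && !is.na(last_ref)) rp[ii] - last_ref - 1L else 0L
      if (ty[ii] == "M" && gap > 0) {
        toks <- c(toks, paste0(cur_n, cur_op), paste0(gap, "D"))
        cur_op <- "M"; cur_n <- 1L
      } else if (ty[ii] == cur_op) {
        cur_n <- cur_n + 1L
      } else {
        toks <- c(toks, paste0(cur_n, cur_op))
        cur_op <- ty[ii]; cur_n <- 1L
      }
      if (!is.na(rp[ii])) last_ref <- rp[ii]
    }
    paste(c(toks, paste0(cur_n, cur_op)), collapse = "")
  }
  base_vec <- character(n_el)
  is_m <- ops$type == "M"
  base_vec[is_m] <- substring(refseq, ops$ref_pos[is_m] + 1L,
                              ops$ref_pos[is_m] + 1L)
  if (any(!is_m))
    base_vec[!is_m] <- sample(BASES, sum(!is_m), replace = TRUE)
  read_seq <- paste(base_vec, collapse = "")

  m_rows <- ops$type == "M"
  structure(list(
    read = raw_read(read_id, dac, digitisation = params$digitisation,
                    offset = params$offset, range = params$range,
                    sampling_rate = params$sampling_rate),
    truth = data.frame(ref_pos = ops$ref_pos[m_rows],
                       lo = starts[m_rows],
                       hi = starts[m_rows] + dwell[m_rows]),
    moves = moves, stride = params$stride, ts = 0L, cigar = cigar,
    ref_start = s, strand = "+", seq = read_seq, read_id = read_id,
    ref_name = "ref", true_scale = true_scale, true_shift = true_shift),
    class = "sim_read")
}

#' Simulate a read set
#'
#' All randomness flows from one seeded generator, so the same seed
#' reproduces the data bit-for-bit.
#'
#' @param refseq reference string.
#' @param model truth [pore_model()].
#' @param n_reads number of reads.
#' @param params a [sim_params()] list.
#' @param seed RNG seed.
#' @param read_len read span in reference bases (`NULL` = full reference);
#'   starts are drawn uniformly.
#' @return list of `sim_read` objects.
#' @export
simulate_reads <- function(refseq, model, n_reads, params = sim_params(),
                           seed = 1L, read_len = NULL) {
  set.seed(seed)
  k <- model$k; cp <- model$central_pos
  lo <- cp; hi <- nchar(refseq) - (k - 1L - cp)
  lapply(seq_len(n_reads), function(i) {
    if (is.null(read_len)) {
      s <- lo; len <- hi - lo
    } else {
      len <- min(read_len, hi - lo)
      s <- sample(lo:(hi - len), 1L)
    }
    simulate_read(refseq, model, read_id = sprintf("sim_%04d", i),
                  params = params, ref_start = s, ref_len = len)
  })
}

#' Random nucleotide reference
#' @param length reference length in bases.
#' @param seed optional seed.
#' @return character string of A/C/G/T.
#' @export
random_reference <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

#' Reference containing every k-mer (de Bruijn core)
#'
#' A de Bruijn sequence of order `k` over A/C/G/T (every k-mer exactly once,
#' `4^k + k - 1` bases), optionally padded with random sequence to a target
#' length. Pore-model training requires every k-mer to be observable, so
#' training references are built this way.
#'
#' @param k k-mer order.
#' @param length total length (`NULL` = bare de Bruijn sequence).
#' @param seed optional seed for the random padding.
#' @return character string.
#' @export
debruijn_reference <- function(k, length = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 4L
  a <- integer(n * k)
  seqv <- integer(0)
  db <- function(t, p) {
    if (t > k) {
      if (k %% p == 0L) seqv <<- c(seqv, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      b <- a[t - p + 1L] + 1L
      while (b < n) {
        a[t + 1L] <<- b
        db(t + 1L, t)
        b <- b + 1L
      }
    }
  }
  db(1L, 1L)
  s <- paste(BASES[c(seqv, seqv[seq_len(k - 1L)]) + 1L], collapse = "")
  if (!is.null(length)) {
    if (length < nchar(s))
      stop("length ", length, " shorter than the order-", k,
           " de Bruijn sequence (", nchar(s), ")")
    if (length > nchar(s))
      s <- paste0(s, paste(sample(BASES, length - nchar(s), replace = TRUE),
                           collapse = ""))
  }
  s
}

sim_bam_meta <- function(sr) {
  list(read_id = sr$read_id, strand = sr$strand, ref_name = sr$ref_name,
       ref_start = sr$ref_start, pos = sr$ref_start + 1L, flag = 0L,
       mapq = 60L, cigar = sr$cigar, seq = sr$seq, moves = sr$moves,
       stride = sr$stride, ts = sr$ts)
}

#' Write a simulated dataset to standard files
#'
#' Produces the file set the aligner consumes: the reference FASTA, the raw
#' signal as SLOW5 ASCII, the basecalled alignments as SAM/BAM with `mv`/`ts`
#' move tags, and the ground-truth sample-to-reference map as TSV.
#'
#' @param sims list from [simulate_reads()].
#' @param refseq reference string.
#' @param dir output directory (created).
#' @param bam write BAM (default) or SAM only.
#' @return named list of file paths.
#' @export
write_sim_dataset <- function(sims, refseq, dir, bam = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(ref = refseq)), fa)
  slow5 <- file.path(dir, "reads.slow5")
  write_slow5(lapply(sims, `[[`, "read"), slow5)
  sam <- file.path(dir, if (bam) "reads.bam" else "reads.sam")
  lines <- vapply(sims, function(sr) {
    paste(c(sr$read_id, 0L, "ref", sr$ref_start + 1L, 60L, sr$cigar, "*",
            0L, 0L, sr$seq, "*",
            fmt_tag_array("mv", "c", c(sr$stride, sr$moves)),
            sprintf("ts:i:%d", sr$ts)), collapse = "\t")
  }, "")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:ref\tLN:%d", nchar(refseq)),
           "@PG\tID:squigalign_sim")
  if (bam) {
    tmp <- file.path(dir, "reads.sam")
    writeLines(c(hdr, lines), tmp)
    Rsamtools::asBam(tmp, file.path(dir, "reads"), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    writeLines(c(hdr, lines), sam)
  }
  truth <- file.path(dir, "truth.tsv")
  tt <- do.call(rbind, lapply(sims, function(sr)
    cbind(read_id = sr$read_id, sr$truth)))
  utils::write.table(tt, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(ref = fa, slow5 = slow5, bam = sam, truth = truth)
}
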