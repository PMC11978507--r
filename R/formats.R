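fmt_tag_array <- function(tag, type, values) {
  paste0(tag, ":B:", type, ",", paste(values, collapse = ","))
}

# uint16 arrays come back from the BAM parser as signed 16-bit
uint16 <- function(v) {
  if (is.null(v)) return(NULL)
  v <- as.integer(v)
  v[v < 0L] <- v[v < 0L] + 65536L
  v
}

#' Write signal alignments to SAM (and optionally BAM)
#'
#' Emits one record per alignment carrying the conventional basecalled
#' alignment fields plus the signal tags `us`/`ur` (32-bit arrays, 16-bit
#' sentinel semantics), `uc`/`ud` (uint16 fixed-point currents), `un`
#' (scale/shift floats) and, when present in `meta`, the basecaller move
#' table `mv`/`ts`. Tag metadata (fixed-point range, model name) is stored as
#' a JSON `@CO` header line. Use [Rsamtools::asBam()]-backed
#' [read_signal_alns()] to read the result back.
#'
#' @param alns list of [signal_aln()] objects.
#' @param meta list (parallel to `alns`) of basecalled record fields:
#'   `flag`, `pos` (1-based), `mapq`, `cigar`, `seq`, and optionally
#'   `moves`, `stride`, `ts`.
#' @param refs named integer vector of reference sequence lengths.
#' @param path output path; `.sam` writes text, `.bam` converts via
#'   [Rsamtools::asBam()].
#' @return the path written, invisibly.
#' @export
write_signal_sam <- function(alns, meta, refs, path) {
  json <- jsonlite::toJSON(list(tool = "squigalign",
                                tags = c("us", "ur", "uc", "ud", "un"),
                                fixed_range = c(FIXED_LO, FIXED_HI),
                                models = unique(vapply(alns, `[[`, "",
                                                       "model_name"))),
                           auto_unbox = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)),
           "@PG\tID:squigalign\tPN:squigalign",
           paste0("@CO\tsquigalign.json=", json))
  lines <- character(length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]; m <- meta[[i]]
    tg <- encode_tags(a)
    tags <- c(
      if (!is.null(m$moves))
        fmt_tag_array("mv", "c", c(m$stride, m$moves)),
      if (!is.null(m$ts)) sprintf("ts:i:%d", as.integer(m$ts)),
      sprintf("sl:i:%d", a$signal_len),
      fmt_tag_array("us", "i", tg$us),
      fmt_tag_array("ur", "i", tg$ur),
      fmt_tag_array("uc", "S", tg$uc),
      fmt_tag_array("ud", "S", tg$ud),
      fmt_tag_array("un", "f", sprintf("%.9g", tg$un)))
    lines[i] <- paste(c(a$read_id, m$flag %||% (if (a$strand == "-") 16L else 0L),
                        a$ref_name, m$pos, m$mapq %||% 60L,
                        m$cigar, "*", 0L, 0L, m$seq %||% "*", "*", tags),
                      collapse = "\t")
  }
  if (grepl("\\.bam$", path)) {
    sam <- sub("\\.bam$", ".sam", path)
    writeLines(c(hdr, lines), sam)
    Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    writeLines(c(hdr, lines), path)
  }
  invisible(path)
}

#' Read basecalled/signal records from SAM or BAM
#'
#' Low-level reader (htslib via Rsamtools). Returns one list per record with
#' the basecalled fields and any recognized tags (`mv`, `ts`, `sl`,
#' `us`, `ur`, `uc`, `ud`, `un`); `moves`/`stride` are split out of `mv`.
#'
#' @param path SAM or BAM path (SAM is converted in a temporary file).
#' @return list of records.
#' @export
read_bam_records <- function(path) {
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("mv", "ts", "sl", "us", "ur", "uc", "ud", "un"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  lapply(seq_len(n), function(i) {
    mv <- b$tag$mv[[i]]
    list(read_id = b$qname[i], flag = b$flag[i],
         ref_name = as.character(b$rname[i]),
         pos = b$pos[i], ref_start = b$pos[i] - 1L, mapq = b$mapq[i],
         cigar = b$cigar[i], seq = as.character(b$seq[i]),
         strand = if (bitwAnd(b$flag[i], 16L) > 0L) "-" else "+",
         stride = if (!is.null(mv)) as.integer(mv[1]) else NULL,
         moves = if (!is.null(mv)) as.integer(mv[-1]) else NULL,
         ts = if (!is.null(b$tag$ts[[i]])) as.integer(b$tag$ts[[i]]) else 0L,
         signal_len = if (!is.null(b$tag$sl[[i]])) as.integer(b$tag$sl[[i]]) else NULL,
         us = b$tag$us[[i]], ur = b$tag$ur[[i]],
         uc = uint16(b$tag$uc[[i]]), ud = uint16(b$tag$ud[[i]]),
         un = b$tag$un[[i]])
  })
}

#' Read signal alignments from SAM/BAM
#'
#' Decodes every record carrying the signal tags into a [signal_aln()].
#'
#' @param path SAM or BAM path written by [write_signal_sam()].
#' @return list of [signal_aln()] objects.
#' @export
read_signal_alns <- function(path) {
  recs <- read_bam_records(path)
  recs <- Filter(function(r) !is.null(r$us), recs)
  lapply(recs, function(r)
    decode_tags(list(us = r$us, ur = r$ur, uc = r$uc, ud = r$ud, un = r$un),
                read_id = r$read_id, ref_name = r$ref_name,
                strand = r$strand, signal_len = r$signal_len))
}

EVENTALIGN_COLS <- c("contig", "position", "reference_kmer", "read_name",
                     "strand", "event_index", "event_level_mean",
                     "event_stdv", "event_length", "model_kmer",
                     "model_mean", "model_stdv", "standardized_level",
                     "start_idx", "end_idx")

#' Write eventalign-style tab-delimited output
#'
#' One row per unmasked reference position (per-position averaging;
#' `event_index` is a running counter). `event_length` is reported in raw
#' samples (the dwell). `standardized_level` is
#' `(event_level_mean - model_mean) / model_stdv`.
#'
#' @param alns list of [signal_aln()] objects.
#' @param model a [pore_model()].
#' @param refseqs named character vector of reference sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_eventalign <- function(alns, model, refseqs, path) {
  rows <- lapply(alns, function(a) {
    es <- expected_signal(model, refseqs[[a$ref_name]], strand = a$strand)
    iv <- position_sample_intervals(a)
    keep <- !a$pos$masked
    ix <- match(a$pos$ref_pos[keep], es$position)
    kmer_str <- ifelse(is.na(es$kmer[ix]), "NNNNN",
                       kmer_from_index(ifelse(is.na(es$kmer[ix]), 0L,
                                              es$kmer[ix]), model$k))
    data.frame(contig = a$ref_name, position = a$pos$ref_pos[keep],
               reference_kmer = kmer_str, read_name = a$read_id,
               strand = "t", event_index = seq_len(sum(keep)) - 1L,
               event_level_mean = a$pos$current[keep],
               event_stdv = a$pos$current_sd[keep],
               event_length = a$pos$length[keep],
               model_kmer = kmer_str,
               model_mean = es$mean[ix], model_stdv = es$sd[ix],
               standardized_level =
                 (a$pos$current[keep] - es$mean[ix]) / es$sd[ix],
               start_idx = iv$lo[keep], end_idx = iv$hi[keep])
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read eventalign rows back into signal alignments
#'
#' Rows must be sorted by position within each read; multiple rows per
#' position (per-event input) are collapsed to per-position means weighted by
#' `event_length`. Sample gaps between consecutive position intervals become
#' masked runs.
#'
#' @param path eventalign TSV path.
#' @return list of [signal_aln()] objects.
#' @export
read_eventalign <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- list()
  for (rn in unique(tab$read_name)) {
    t1 <- tab[tab$read_name == rn, , drop = FALSE]
    if (is.unsorted(t1$position))
      stop("eventalign rows out of coordinate order for read ", rn,
           "; sorted input required")
    # collapse per-event rows to per-position, dwell-weighted
    grp <- split(seq_len(nrow(t1)), t1$position)
    coll <- do.call(rbind, lapply(grp, function(ix) {
      w <- t1$event_length[ix]
      if (sum(w) == 0) w <- rep(1, length(ix))
      data.frame(position = t1$position[ix[1]],
                 current = sum(t1$event_level_mean[ix] * w) / sum(w),
                 current_sd = sum(t1$event_stdv[ix] * w) / sum(w),
                 length = sum(t1$event_length[ix]),
                 lo = min(t1$start_idx[ix]), hi = max(t1$end_idx[ix]),
                 contig = t1$contig[ix[1]])
    }))
    coll <- coll[order(coll$position), , drop = FALSE]
    p <- coll$position
    brk <- which(diff(p) != 1L)
    blocks <- cbind(p[c(1L, brk + 1L)], p[c(brk, length(p))] + 1L)
    # masked runs from gaps in sample coverage
    own <- coll[coll$length > 0, , drop = FALSE]
    gap_after <- which(diff(own$lo) - own$length[-nrow(own)] != 0)
    mr <- data.frame(slot = integer(0), length = integer(0))
    for (g in gap_after) {
      glen <- own$lo[g + 1] - (own$lo[g] + own$length[g])
      slot <- which(coll$position == own$position[g + 1])
      mr <- rbind(mr, data.frame(slot = slot, length = glen))
    }
    if (own$lo[1] > 0)
      mr <- rbind(mr, data.frame(slot = 1L, length = own$lo[1]))
    pos <- data.frame(ref_pos = coll$position, length = coll$length,
                      current = coll$current, current_sd = coll$current_sd,
                      event_count = NA_real_, mvcmp_dist = NA_real_,
                      masked = FALSE)
    out[[length(out) + 1L]] <-
      signal_aln(rn, coll$contig[1], "+", blocks, pos, mr,
                 signal_len = sum(pos$length) + sum(mr$length))
  }
  out
}

#' Export alignment layers as TSV
#'
#' One row per (read, reference position); any set of layers accepted by
#' [derived_layer()] can be requested.
#'
#' @param alns list of [signal_aln()] objects.
#' @param layers character vector of layer names (optionally `name@offset`).
#' @param path output path.
#' @param model,refseqs needed for sequence-derived layers.
#' @return the path, invisibly.
#' @export
write_layer_tsv <- function(alns, layers, path, model = NULL, refseqs = NULL) {
  rows <- lapply(alns, function(a) {
    d <- data.frame(read_id = a$read_id, ref_name = a$ref_name,
                    ref_pos = a$pos$ref_pos, masked = a$pos$masked)
    for (ly in layers) {
      parts <- strsplit(ly, "@", fixed = TRUE)[[1]]
      off <- if (length(parts) == 2) as.integer(parts[2]) else 0L
      d[[ly]] <- derived_layer(a, parts[1], offset = off, model = model,
                               refseq = refseqs[[a$ref_name]])
    }
    d
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Convert between signal alignment formats
#'
#' Dispatches on file extensions: `.sam`/`.bam` (tag-encoded alignments),
#' `.eventalign.tsv`/`.eventalign` (Nanopolish-style text), and `.tsv`
#' (layer table output only). A BAM -> eventalign -> BAM round trip preserves
#' lengths exactly and currents within one fixed-point quantum.
#'
#' @param input input path.
#' @param output output path.
#' @param model,refseqs required when sequence context must be emitted
#'   (eventalign or layer TSV output).
#' @param meta optional basecalled record metadata for SAM/BAM output
#'   (defaults to minimal records).
#' @param layers layer names for `.tsv` output.
#' @return the output path, invisibly.
#' @export
convert <- function(input, output, model = NULL, refseqs = NULL,
                    meta = NULL, layers = c("current", "current_sd",
                                            "dtw.dwell")) {
  alns <- if (grepl("\\.(sam|bam)$", input)) read_signal_alns(input)
          else read_eventalign(input)
  if (grepl("\\.(sam|bam)$", output)) {
    if (is.null(meta))
      meta <- lapply(alns, function(a)
        list(flag = if (a$strand == "-") 16L else 0L,
             pos = a$blocks[1, 1] + 1L, mapq = 60L,
             cigar = paste0(sum(a$blocks[, 2] - a$blocks[, 1]), "M")))
    refs <- vapply(alns, function(a) max(a$blocks[, 2]), 0)
    refs <- tapply(refs, vapply(alns, `[[`, "", "ref_name"), max)
    write_signal_sam(alns, meta, refs, output)
  } else if (grepl("eventalign", output)) {
    if (is.null(model) || is.null(refseqs))
      stop("eventalign output requires model and refseqs")
    write_eventalign(alns, model, refseqs, output)
  } else {
    write_layer_tsv(alns, layers, output, model = model, refseqs = refseqs)
  }
  invisible(output)
}
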