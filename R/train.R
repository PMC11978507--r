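#' Pore-model training schedule
#'
#' Training is iterative: reads are aligned (with the training parameter set
#' `skip_cost = 4`, `mask_skips = "keep_best"`, one normalization iteration)
#' until every k-mer is represented `min_kmer_count` times or the reads are
#' exhausted; per-position current means are pooled by k-mer and their
#' median / sd become the next model. The k-mer length grows every
#' `iters_per_k` iterations from `init_k` to `target_k`, averaging out the
#' one-to-two-base errors of the move projections used for de novo
#' initialization.
#'
#' @param target_k final k-mer length.
#' @param init_k starting k-mer length.
#' @param iters_per_k iterations at each k-mer length.
#' @param min_kmer_count minimum pooled observations per k-mer (default 500).
#' @param dist_max positions with move-projection distance above this are
#'   excluded (default 1 base).
#' @param skip_cost DTW skip penalty during training (default 4).
#' @param bandwidth DTW band width.
#' @param max_iterations total training iterations; iterations beyond the
#'   expansion schedule continue at `target_k` (`NULL` stops after
#'   `iters_per_k` iterations at the target length).
#' @param seed seed for the read-sampling order.
#' @return list of schedule parameters.
#' @export
train_schedule <- function(target_k = 5L, init_k = 1L, iters_per_k = 2L,
                           min_kmer_count = 500L, dist_max = 1.0,
                           skip_cost = 4, bandwidth = 25L,
                           max_iterations = NULL, seed = 1L) {
  stopifnot(init_k <= target_k, min_kmer_count >= 1, iters_per_k >= 1)
  list(target_k = as.integer(target_k), init_k = as.integer(init_k),
       iters_per_k = as.integer(iters_per_k),
       min_kmer_count = as.integer(min_kmer_count), dist_max = dist_max,
       skip_cost = skip_cost, bandwidth = as.integer(bandwidth),
       max_iterations = if (!is.null(max_iterations))
         as.integer(max_iterations),
       seed = as.integer(seed))
}

train_align_params <- function(schedule) {
  align_params(bandwidth = schedule$bandwidth,
               skip_cost = schedule$skip_cost, mask_skips = "keep_best",
               norm_iterations = 1L)
}

# pool (position current, k-mer) pairs into a model at length k
pool_model <- function(currents, kmers, k, central_pos, model_in,
                       min_kmer_count, name) {
  med <- tapply(currents, kmers, stats::median)
  sds <- tapply(currents, kmers, stats::sd)
  cnt <- tapply(currents, kmers, length)
  means_new <- model_in$means
  sds_new <- model_in$sds
  got <- as.integer(names(med)) + 1L
  covered <- got[cnt >= min_kmer_count]
  means_new[got] <- med
  sds_new[got] <- ifelse(is.na(sds) | sds == 0, model_in$sds[got], sds)
  under <- setdiff(seq_len(4^k), covered)
  means_new[under] <- model_in$means[under]
  sds_new[under] <- model_in$sds[under]
  if (length(under) > 0.1 * 4^k)
    warning(length(under), " of ", 4^k, " k-mers below min_kmer_count; ",
            "inherited from the previous model")
  if (length(covered) == 0)
    stop("zero k-mer coverage; cannot train")
  normalize_pore_model(pore_model(means_new, sds_new, k, central_pos,
                                  pa_mean = model_in$pa_mean,
                                  pa_sd = model_in$pa_sd, name = name))
}

# per-read (current, kmer) observations used by training
read_observations <- function(sr, refseq, model, params, schedule,
                              kmer_starts) {
  aln <- align_read(sr$read, sr, model, refseq, params)
  keep <- !aln$pos$masked & aln$pos$length > 0 &
    is.finite(aln$pos$mvcmp_dist) & aln$pos$mvcmp_dist <= schedule$dist_max
  start <- aln$pos$ref_pos[keep] - model$central_pos
  ok <- start >= 0L & start < length(kmer_starts)
  data.frame(current = aln$pos$current[keep][ok],
             kmer = kmer_starts[start[ok] + 1L])
}

#' One training iteration
#'
#' Aligns reads (in the schedule's seeded random order, stopping once every
#' k-mer has reached `min_kmer_count` observations), filters positions by
#' move-projection distance, pools per-position current means by k-mer, and
#' returns the re-normalized model whose means are the pooled medians and
#' sds the pooled sds. K-mers below `min_kmer_count` inherit the input
#' model's values with a warning.
#'
#' @param reads list of read bundles (each with `read`, `moves`, `stride`,
#'   `ts`, `cigar`, `ref_start`, `strand`, `read_id`; e.g. `sim_read`s).
#' @param refseq reference string.
#' @param model_in current [pore_model()].
#' @param schedule a [train_schedule()].
#' @return updated `pore_model` with attribute `n_obs` (pooled observation
#'   count).
#' @export
train_iteration <- function(reads, refseq, model_in, schedule) {
  params <- train_align_params(schedule)
  k <- model_in$k
  kmer_starts <- seq_kmer_indices(refseq, k)
  order_ <- sample.int(length(reads))
  obs <- vector("list", length(reads))
  counts <- integer(4^k)
  for (ii in seq_along(order_)) {
    i <- order_[ii]
    o <- tryCatch(read_observations(reads[[i]], refseq, model_in, params,
                                    schedule, kmer_starts),
                  error = function(e) NULL)
    if (is.null(o)) next
    obs[[ii]] <- o
    counts <- counts + tabulate(o$kmer + 1L, nbins = 4L^k)
    if (ii %% 25L == 0L && all(counts >= schedule$min_kmer_count)) break
  }
  obs <- do.call(rbind, obs)
  if (is.null(obs) || nrow(obs) == 0) stop("zero coverage: no usable reads")
  out <- pool_model(obs$current, obs$kmer, k, model_in$central_pos, model_in,
                    schedule$min_kmer_count,
                    name = sprintf("trained_%dmer", k))
  attr(out, "n_obs") <- nrow(obs)
  out
}

#' De novo model initialization from basecaller moves
#'
#' Treats the move projections as signal alignments: per-position mean
#' currents are taken directly from the projected sample intervals,
#' normalized per read to mean 0 / sd 1, and pooled by short k-mer
#' (median / sd). Projections are typically one or two bases off their true
#' position, which a short `init_k` averages out.
#'
#' @param reads list of read bundles.
#' @param refseq reference string.
#' @param init_k initialization k-mer length (warned when equal to the
#'   target length, which defeats the error averaging).
#' @param target_k intended final length (for the warning only).
#' @param del_max splice threshold applied to the projections.
#' @return a normalized [pore_model()] at length `init_k`.
#' @export
init_from_moves <- function(reads, refseq, init_k = 1L, target_k = NULL,
                            del_max = 10L) {
  if (!is.null(target_k) && init_k >= target_k)
    warning("init_k >= target_k defeats averaging of move-projection errors")
  cp <- (init_k - 1L) %/% 2L
  kmer_starts <- seq_kmer_indices(refseq, init_k)
  obs <- lapply(reads, function(sr) {
    if (is.null(sr$moves)) stop("read ", sr$read_id, ": missing move table")
    pa <- calibrate_signal(sr$read)
    rm <- splice_indels(project_moves(sr$moves, sr$stride, sr$ts %||% 0L,
                                      sr$cigar, sr$ref_start,
                                      strand = sr$strand,
                                      signal_len = length(pa)), del_max)
    tab <- rm$tab[rm$tab$hi > rm$tab$lo, , drop = FALSE]
    cur <- vapply(seq_len(nrow(tab)), function(i)
      mean(pa[(tab$lo[i] + 1L):tab$hi[i]]), 0)
    cur <- (cur - mean(cur)) / pop_sd(cur)
    start <- tab$ref_pos - cp
    ok <- start >= 0L & start < length(kmer_starts)
    data.frame(current = cur[ok], kmer = kmer_starts[start[ok] + 1L])
  })
  obs <- do.call(rbind, obs)
  draft <- pore_model(numeric(4^init_k), 1, init_k, cp, name = "draft")
  pool_model(obs$current, obs$kmer, init_k, cp, draft, 1L,
             name = sprintf("init_%dmer", init_k))
}

#' Iterative de novo pore-model training
#'
#' Runs initialization (from moves, or from `init_model`) and then training
#' iterations, expanding the k-mer length every `iters_per_k` iterations
#' until `target_k` is reached. Deterministic given `schedule$seed`.
#'
#' @param reads list of read bundles.
#' @param refseq reference string.
#' @param schedule a [train_schedule()].
#' @param init_model optional draft model (skips move initialization).
#' @param out_dir optional directory; every intermediate model is written as
#'   TSV along with a `report.tsv`.
#' @return list with `models` (one per iteration), `report` (data.frame
#'   `iteration`, `k`, `n_obs`, `corr_prev`), and `final`.
#' @export
train <- function(reads, refseq, schedule = train_schedule(),
                  init_model = NULL, out_dir = NULL) {
  set.seed(schedule$seed)
  ks <- unique(c(seq(schedule$init_k, schedule$target_k, by = 2L),
                 schedule$target_k))
  model <- if (is.null(init_model))
    init_from_moves(reads, refseq, schedule$init_k, schedule$target_k)
  else init_model
  if (model$k > schedule$init_k) ks <- ks[ks >= model$k]
  n_iter <- max(length(ks) * schedule$iters_per_k,
                schedule$max_iterations %||% 0L)
  models <- list(); report <- NULL
  it <- 0L
  for (kk in ks) {
    if (model$k < kk) model <- expand_kmer(model, kk)
    # iterate at the expansion cadence; remaining budget is spent at target_k
    reps <- if (kk == ks[length(ks)])
      n_iter - it else schedule$iters_per_k
    for (rep_ in seq_len(reps)) {
      it <- it + 1L
      prev <- model
      model <- train_iteration(reads, refseq, model, schedule)
      cor_prev <- if (prev$k == model$k)
        stats::cor(prev$means, model$means) else NA_real_
      models[[it]] <- model
      report <- rbind(report,
                      data.frame(iteration = it, k = model$k,
                                 n_obs = attr(model, "n_obs"),
                                 corr_prev = cor_prev))
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        save_model(model, file.path(out_dir,
                                    sprintf("model_it%02d_k%d.tsv", it, model$k)))
      }
    }
  }
  if (!is.null(out_dir))
    utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(models = models, report = report, final = model)
}
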