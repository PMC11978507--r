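#' Construct a k-mer pore model
#'
#' A pore model maps every length-k nucleotide word to the expected current
#' mean and standard deviation while that word occupies the pore. Currents are
#' usually in normalized units (mean 0, sd 1 across k-mers); `pa_mean`/`pa_sd`
#' calibrate normalized units back to picoamps via `pA = x * pa_sd + pa_mean`.
#'
#' @param means numeric vector of length `4^k`, indexed by [kmer_index()].
#' @param sds numeric vector of per-k-mer current sds (strictly positive);
#'   a scalar is recycled.
#' @param k k-mer length.
#' @param central_pos 0-based offset of the most current-influential base
#'   within the k-mer (see [central_base()]).
#' @param pa_mean,pa_sd calibration constants mapping normalized units to pA.
#' @param name free-text chemistry label.
#' @param reverse_signal `TRUE` when the signal traverses the sequence 3'->5'
#'   relative to the reference (direct RNA).
#' @return object of class `pore_model`.
#' @export
pore_model <- function(means, sds = 1, k, central_pos = (k - 1L) %/% 2L,
                       pa_mean = 0, pa_sd = 1, name = "custom",
                       reverse_signal = FALSE) {
  k <- as.integer(k)
  central_pos <- as.integer(central_pos)
  if (length(means) != 4^k)
    stop("means must have exactly 4^k = ", 4^k, " entries")
  if (length(sds) == 1L) sds <- rep(sds, 4^k)
  if (length(sds) != 4^k) stop("sds must have 1 or 4^k entries")
  if (any(sds <= 0)) stop("sds must be strictly positive")
  if (central_pos < 0L || central_pos >= k)
    stop("central_pos must satisfy 0 <= central_pos < k")
  structure(list(k = k, central_pos = central_pos,
                 means = as.numeric(means), sds = as.numeric(sds),
                 pa_mean = pa_mean, pa_sd = pa_sd, name = name,
                 reverse_signal = isTRUE(reverse_signal)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore_model '%s': k=%d central_pos=%d reverse_signal=%s\n",
              x$name, x$k, x$central_pos, x$reverse_signal))
  cat(sprintf("  means: mean=%.4g sd=%.4g; calibration pa_mean=%.4g pa_sd=%.4g\n",
              mean(x$means), pop_sd(x$means), x$pa_mean, x$pa_sd))
  invisible(x)
}

# population (n-denominator) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Normalize a pore model to mean 0 / sd 1
#'
#' Rescales the per-k-mer means to have population mean 0 and sd 1 over all
#' k-mers, scales the sds by the same factor, and folds the inverse transform
#' into the pA calibration constants so physical units are preserved.
#'
#' @param model a [pore_model()].
#' @return normalized `pore_model`.
#' @export
normalize_pore_model <- function(model) {
  mu <- mean(model$means)
  sig <- pop_sd(model$means)
  if (sig == 0) stop("cannot normalize a constant model")
  model$means <- (model$means - mu) / sig
  model$sds <- model$sds / sig
  model$pa_mean <- model$pa_mean + model$pa_sd * mu
  model$pa_sd <- model$pa_sd * sig
  model
}

#' Read / write pore model TSV files
#'
#' Models are stored as Nanopolish-style TSV with columns
#' `kmer`, `level_mean`, `level_stdv` and one row per k-mer (all `4^k` k-mers
#' required). Metadata ride in `#key<TAB>value` header lines
#' (`central_pos`, `pa_mean`, `pa_sd`, `name`, `reverse_signal`).
#'
#' @param path file path.
#' @return [load_model()] returns a `pore_model`.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  if (length(body) < 2 || !grepl("^kmer\tlevel_mean\tlevel_stdv", body[1]))
    stop("model format error: expected 'kmer<TAB>level_mean<TAB>level_stdv' header")
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric"))
  ks <- unique(nchar(tab$kmer))
  if (length(ks) != 1)
    stop("model format error: inconsistent k-mer lengths (", paste(ks, collapse = ","), ")")
  k <- ks
  if (nrow(tab) != 4^k)
    stop("model format error: expected ", 4^k, " rows for k=", k, ", got ", nrow(tab))
  idx <- kmer_index(tab$kmer, k)
  if (anyDuplicated(idx))
    stop("model format error: duplicate k-mer entries")
  means <- sds <- numeric(4^k)
  means[idx + 1L] <- tab$level_mean
  sds[idx + 1L] <- tab$level_stdv
  pore_model(means, sds, k,
             central_pos = as.integer(meta$central_pos %||% ((k - 1L) %/% 2L)),
             pa_mean = as.numeric(meta$pa_mean %||% 0),
             pa_sd = as.numeric(meta$pa_sd %||% 1),
             name = meta$name %||% "custom",
             reverse_signal = identical(meta$reverse_signal, "TRUE"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_model
#' @param model a [pore_model()] to write.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#central_pos\t%d", model$central_pos),
               sprintf("#pa_mean\t%.17g", model$pa_mean),
               sprintf("#pa_sd\t%.17g", model$pa_sd),
               sprintf("#name\t%s", model$name),
               sprintf("#reverse_signal\t%s", model$reverse_signal),
               "kmer\tlevel_mean\tlevel_stdv"), con)
  writeLines(sprintf("%s\t%.17g\t%.17g",
                     kmer_from_index(0:(4^model$k - 1L), model$k),
                     model$means, model$sds), con)
  invisible(path)
}

#' Expected current per reference position
#'
#' Translates a nucleotide sequence into expected current using the pore
#' model. Position `r` (0-based) is assigned the k-mer starting at
#' `r - central_pos`; the `central_pos` leading and `k - 1 - central_pos`
#' trailing positions have no k-mer and are returned as `NA`. For
#' `strand = "-"` the k-mers are those of the reverse complement, reported on
#' ascending forward-reference coordinates. When the model's `reverse_signal`
#' flag is set, rows are emitted in reverse order so that row 1 is the first
#' k-mer to traverse the pore.
#'
#' @param model a [pore_model()].
#' @param seq reference nucleotide string.
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `position` (0-based forward coordinate),
#'   `kmer` (integer index or `NA`), `mean`, `sd`.
#' @export
expected_signal <- function(model, seq, strand = "+") {
  L <- nchar(seq)
  k <- model$k
  out <- data.frame(position = 0:(max(L, 1) - 1L), kmer = NA_integer_,
                    mean = NA_real_, sd = NA_real_)
  if (L < k) {
    warning("sequence shorter than k; empty expected signal")
    return(out[0, ])
  }
  if (strand == "-") {
    idx <- seq_kmer_indices(revcomp(seq), k)
    # k-mer starting at revcomp offset s covers forward positions
    # [L-1-s-(k-1), L-1-s]; its central base sits at forward coordinate
    # L-1-s-central_pos.
    pos <- L - 1L - (seq_len(length(idx)) - 1L) - model$central_pos
  } else {
    idx <- seq_kmer_indices(seq, k)
    pos <- (seq_len(length(idx)) - 1L) + model$central_pos
  }
  keep <- pos >= 0L & pos < L
  out$kmer[pos[keep] + 1L] <- idx[keep]
  out$mean <- model$means[out$kmer + 1L]
  out$sd <- model$sds[out$kmer + 1L]
  if (model$reverse_signal) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Substitution profile of a pore model
#'
#' Entry `(b, p)` is the mean absolute change in expected current observed by
#' substituting base `b` at k-mer position `p`, averaged over all `4^k` k-mers
#' (self-substitutions contribute zero and are included in the average).
#'
#' @param model a [pore_model()].
#' @return 4 x k numeric matrix with rownames A, C, G, T.
#' @export
substitution_profile <- function(model) {
  k <- model$k
  idx <- 0:(4^k - 1L)
  prof <- matrix(0, nrow = 4L, ncol = k, dimnames = list(BASES, NULL))
  for (p in 0:(k - 1L)) {
    place <- 4L^(k - 1L - p)
    d <- (idx %/% place) %% 4L
    for (b in 0:3L) {
      sub <- idx + (b - d) * place
      prof[b + 1L, p + 1L] <- mean(abs(model$means[idx + 1L] - model$means[sub + 1L]))
    }
  }
  prof
}

#' Central base of a pore model
#'
#' The k-mer position with the highest average per-position change in the
#' model's substitution profile (ties broken toward the smaller index).
#'
#' @param model a [pore_model()].
#' @return 0-based position within the k-mer.
#' @export
central_base <- function(model) {
  cm <- colMeans(substitution_profile(model))
  if (all(cm == 0)) {
    warning("degenerate model: constant current, central base undefined")
    return(0L)
  }
  which.max(cm) - 1L
}

#' Reduce a pore model to a shorter k-mer length
#'
#' Averages the values of k-mers that share the bases in a kept window of
#' `m` contiguous positions: the reduced mean of each m-mer is the arithmetic
#' mean of the means of all k-mers spelling that m-mer in the window; sds are
#' combined as root-mean-square. The window contains the central position by
#' default.
#'
#' @param model a [pore_model()].
#' @param m reduced k-mer length, `1 <= m <= k`.
#' @param anchor 0-based start of the kept window; default centers it on
#'   `central_pos`.
#' @return reduced `pore_model` with `central_pos` remapped into the window.
#' @export
reduce_model <- function(model, m, anchor = NULL) {
  k <- model$k
  m <- as.integer(m)
  if (m < 1L || m > k) stop("m must satisfy 1 <= m <= k")
  if (is.null(anchor))
    anchor <- min(max(model$central_pos - (m - 1L) %/% 2L, 0L), k - m)
  anchor <- as.integer(anchor)
  if (anchor < 0L || anchor + m > k)
    stop("kept window [", anchor, ",", anchor + m, ") not within [0,", k, ")")
  idx <- 0:(4^k - 1L)
  sub <- (idx %/% 4L^(k - anchor - m)) %% 4L^m
  means <- as.numeric(tapply(model$means, sub, mean))
  sds <- sqrt(as.numeric(tapply(model$sds^2, sub, mean)))
  pore_model(means, sds, m,
             central_pos = min(max(model$central_pos - anchor, 0L), m - 1L),
             pa_mean = model$pa_mean, pa_sd = model$pa_sd,
             name = paste0(model$name, "_m", m),
             reverse_signal = model$reverse_signal)
}

#' Expand a pore model to a longer k-mer length
#'
#' Every expanded k-mer inherits the mean/sd of the k-mer it contains, with
#' the window placed so the central positions coincide; expanding then
#' reducing with the same window is the identity.
#'
#' @param model a [pore_model()].
#' @param k_new target k-mer length, `> model$k`.
#' @param central_pos_new central position of the expanded model; default
#'   keeps the old central position centered in the grown window.
#' @return expanded `pore_model`.
#' @export
expand_kmer <- function(model, k_new,
                        central_pos_new = model$central_pos + (k_new - model$k) %/% 2L) {
  k <- model$k
  k_new <- as.integer(k_new)
  if (k_new <= k) stop("k_new must exceed the model's k")
  anchor <- as.integer(central_pos_new) - model$central_pos
  if (anchor < 0L || anchor + k > k_new)
    stop("window placement impossible: central positions cannot coincide")
  idx <- 0:(4^k_new - 1L)
  old <- (idx %/% 4L^(k_new - anchor - k)) %% 4L^k
  pore_model(model$means[old + 1L], model$sds[old + 1L], k_new,
             central_pos = as.integer(central_pos_new),
             pa_mean = model$pa_mean, pa_sd = model$pa_sd,
             name = paste0(model$name, "_k", k_new),
             reverse_signal = model$reverse_signal)
}
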