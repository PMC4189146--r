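# Digital normalization: streaming read rejection by median k-mer abundance.
#
# A unit (read pair, or single read) is accepted iff the median abundance of
# its canonical k-mers — counted over the units accepted SO FAR — is below
# the coverage cutoff C; only accepted units contribute their k-mers to the
# counter. This one-pass rule drives observed coverage towards C and is what
# makes the exact-duplicate law hold (the (C+1)-th copy of a read sees
# median C and is rejected).

#' Parameters for digital normalization
#'
#' @param k K-mer size in bp (default 25).
#' @param C Coverage cutoff: a unit is kept iff its median k-mer abundance
#'   is `< C` (default 30). `Inf` keeps everything.
#' @param Q 3' quality-trimming threshold on the Phred scale (default 24);
#'   used when trimming is enabled.
#' @param abund_cutoff Minimum trusted k-mer count for
#'   [filter_low_abundance()] (default 2).
#' @param paired_policy `"keep-if-either"` (default: a pair is kept if either
#'   mate's median is below `C`), `"keep-if-both"`, or `"unpaired"` (mates
#'   are interleaved and judged independently).
#' @param min_read_length Reads shorter than this after trimming are skipped
#'   (default 25).
#' @param shuffle_seed If non-NULL, units are shuffled with this seed before
#'   the pass (the streaming decision is order-dependent).
#' @return A `normalization_params` list.
#' @export
normalization_params <- function(k = 25, C = 30, Q = 24, abund_cutoff = 2,
                                 paired_policy = c("keep-if-either",
                                                   "keep-if-both", "unpaired"),
                                 min_read_length = 25, shuffle_seed = NULL) {
  paired_policy <- match.arg(paired_policy)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (!(is.numeric(C) && length(C) == 1L && (is.infinite(C) || C >= 1)))
    stopf("C must be >= 1 (or Inf)")
  if (!is.numeric(Q) || Q < 0 || Q > 41) stopf("Q must lie in [0, 41]")
  structure(
    list(k = as.integer(k), C = C, Q = Q, abund_cutoff = abund_cutoff,
         paired_policy = paired_policy,
         min_read_length = as.integer(min_read_length),
         shuffle_seed = shuffle_seed),
    class = "normalization_params"
  )
}

#' Trim low-quality 3' ends
#'
#' Removes the maximal suffix in which every base has quality below `Q`;
#' the 5' end is never altered. A read whose bases are all below `Q`
#' becomes empty (and is then dropped downstream by `min_read_length`).
#'
#' @param seq Character vector of sequences, or a `data.frame` with `seq`
#'   and `qual` columns.
#' @param qual Parallel vector of Phred+33 quality strings (ignored when
#'   `seq` is a `data.frame`).
#' @param Q Phred threshold (default 24): bases with quality `< Q` are
#'   trimmable.
#' @return Same shape as the input (`data.frame` in, `data.frame` out) with
#'   sequences and qualities truncated.
#' @export
trim_quality_3prime <- function(seq, qual = NULL, Q = 24) {
  df_in <- is.data.frame(seq)
  if (df_in) {
    reads <- seq
    seq <- reads$seq
    qual <- reads$qual
  }
  if (length(qual) != length(seq) || any(nchar(qual) != nchar(seq)))
    stopf("sequence and quality lengths differ")
  keep_len <- vapply(qual, function(q) {
    qs <- phred_ints(q)
    good <- which(qs >= Q)
    if (length(good) == 0L) 0L else good[length(good)]
  }, 0L, USE.NAMES = FALSE)
  seq_t <- substr(seq, 1L, keep_len)
  qual_t <- substr(qual, 1L, keep_len)
  if (df_in) {
    reads$seq <- seq_t
    reads$qual <- qual_t
    reads
  } else {
    list(seq = seq_t, qual = qual_t)
  }
}

as_reads_df <- function(x, what = "reads") {
  if (is.data.frame(x)) {
    if (!"seq" %in% names(x)) stopf("%s data.frame needs a 'seq' column", what)
    if (is.null(x$id)) x$id <- sprintf("read%06d", seq_len(nrow(x)))
    if (is.null(x$qual)) x$qual <- strrep("I", nchar(x$seq))
    x[, c("id", "seq", "qual")]
  } else if (is.character(x)) {
    data.frame(id = names(x) %||% sprintf("read%06d", seq_along(x)),
               seq = unname(x), qual = strrep("I", nchar(x)),
               stringsAsFactors = FALSE)
  } else {
    stopf("%s must be a character vector or a data.frame with id/seq/qual", what)
  }
}

median_from_counts <- function(cts) {
  cts <- sort(cts)
  cts[[as.integer(length(cts) %/% 2) + 1L]]
}

#' Stream digital normalization over reads or read pairs
#'
#' Performs the single-pass accept/reject rule: for each unit, the median
#' canonical k-mer abundance of each usable mate is computed against the
#' counts accumulated from previously kept units; the unit is kept per
#' `paired_policy`, and only then are its k-mers counted. Reads shorter
#' than `min_read_length` (or `k`) are unusable; a unit with no usable mate
#' is skipped and logged.
#'
#' @param r1 Reads (character vector or `data.frame` with id/seq/qual).
#' @param r2 Optional mates, parallel to `r1`.
#' @param params A [normalization_params()] object.
#' @param trim If TRUE, apply [trim_quality_3prime()] with `params$Q`
#'   before the pass.
#' @param counter Optionally a pre-populated [kmer_counter()] to continue
#'   from; default a fresh one.
#' @return List with `r1`, `r2` (kept units, same format as the input),
#'   `log` (a `normalization_log`: unit tallies, retention fraction and a
#'   per-unit decision `data.frame` id/median/kept) and `counter`.
#' @export
normalize_stream <- function(r1, r2 = NULL, params = normalization_params(),
                             trim = FALSE, counter = NULL) {
  r1 <- as_reads_df(r1, "r1")
  if (!is.null(r2)) {
    r2 <- as_reads_df(r2, "r2")
    if (nrow(r2) != nrow(r1)) stopf("r1 and r2 must have the same number of reads")
  }
  if (trim) {
    r1 <- trim_quality_3prime(r1, Q = params$Q)
    if (!is.null(r2)) r2 <- trim_quality_3prime(r2, Q = params$Q)
  }
  if (params$paired_policy == "unpaired" && !is.null(r2)) {
    inter <- rbind(r1, r2)
    r1 <- inter[as.vector(rbind(seq_len(nrow(r1)), nrow(r1) + seq_len(nrow(r1)))), ]
    r2 <- NULL
  }
  n <- nrow(r1)
  ord <- seq_len(n)
  if (!is.null(params$shuffle_seed))
    ord <- with_seed(params$shuffle_seed, sample.int(n))
  counter <- counter %||% kmer_counter(params$k)
  k <- params$k
  min_len <- max(params$min_read_length, k)

  kept_flag <- logical(n)
  med_log <- rep(NA_real_, n)
  n_kept <- 0L; n_disc <- 0L; n_skip <- 0L
  for (u in ord) {
    kms1 <- if (nchar(r1$seq[u]) >= min_len) canonical_kmers(r1$seq[u], k) else NULL
    kms2 <- if (!is.null(r2) && nchar(r2$seq[u]) >= min_len)
      canonical_kmers(r2$seq[u], k) else NULL
    if (is.null(kms1) && is.null(kms2)) {
      n_skip <- n_skip + 1L
      next
    }
    meds <- c(
      if (!is.null(kms1)) median_from_counts(kmer_counts(counter, kms1)),
      if (!is.null(kms2)) median_from_counts(kmer_counts(counter, kms2))
    )
    keep <- if (params$paired_policy == "keep-if-both") all(meds < params$C)
            else any(meds < params$C)
    med_log[u] <- min(meds)
    kept_flag[u] <- keep
    if (keep) {
      n_kept <- n_kept + 1L
      if (!is.null(kms1)) kmer_add(counter, kms1)
      if (!is.null(kms2)) kmer_add(counter, kms2)
    } else {
      n_disc <- n_disc + 1L
    }
  }
  decided <- !is.na(med_log)
  decisions <- data.frame(
    id = sub("/[12]$", "", r1$id),
    median = med_log,
    kept = ifelse(decided, kept_flag, NA),
    stringsAsFactors = FALSE
  )[ord, ]
  log <- structure(
    list(reads_in = n, reads_kept = n_kept, reads_discarded = n_disc,
         reads_skipped_short = n_skip,
         retention_fraction = if (n > 0) n_kept / n else NA_real_,
         decisions = decisions),
    class = "normalization_log"
  )
  keep_idx <- which(kept_flag)
  list(r1 = r1[keep_idx, , drop = FALSE],
       r2 = if (!is.null(r2)) r2[keep_idx, , drop = FALSE],
       log = log, counter = counter)
}

#' @export
print.normalization_log <- function(x, ...) {
  cat(sprintf(
    "normalization_log: %d units in, %d kept (%.1f%%), %d discarded, %d skipped short\n",
    x$reads_in, x$reads_kept, 100 * x$retention_fraction,
    x$reads_discarded, x$reads_skipped_short))
  invisible(x)
}

#' Write a normalization decision log
#'
#' @param log A `normalization_log`.
#' @param path Output TSV (id, median, kept).
#' @return `path`, invisibly.
#' @export
write_normalization_log <- function(log, path) {
  utils::write.table(log$decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Replay a normalization log and validate every decision
#'
#' Re-scans the units in their decision order with a fresh counter built
#' only from the units the log says were kept, and checks that every
#' discarded unit indeed had median abundance `>= C` — and every kept unit
#' `< C` — at its decision time.
#'
#' @param r1,r2 The same reads given to [normalize_stream()] (same order).
#' @param log The `normalization_log` it returned.
#' @param params The same [normalization_params()] (shuffling is honored).
#' @return TRUE if every decision is consistent; otherwise FALSE with a
#'   warning naming the first offending unit.
#' @export
replay_normalization <- function(r1, r2 = NULL, log, params = normalization_params()) {
  r1 <- as_reads_df(r1, "r1")
  if (!is.null(r2)) r2 <- as_reads_df(r2, "r2")
  n <- nrow(r1)
  ord <- seq_len(n)
  if (!is.null(params$shuffle_seed))
    ord <- with_seed(params$shuffle_seed, sample.int(n))
  dec <- log$decisions
  counter <- kmer_counter(params$k)
  min_len <- max(params$min_read_length, params$k)
  for (j in seq_along(ord)) {
    u <- ord[j]
    if (is.na(dec$kept[j])) next
    kms1 <- if (nchar(r1$seq[u]) >= min_len) canonical_kmers(r1$seq[u], params$k) else NULL
    kms2 <- if (!is.null(r2) && nchar(r2$seq[u]) >= min_len)
      canonical_kmers(r2$seq[u], params$k) else NULL
    meds <- c(
      if (!is.null(kms1)) median_from_counts(kmer_counts(counter, kms1)),
      if (!is.null(kms2)) median_from_counts(kmer_counts(counter, kms2))
    )
    dec_keep <- if (params$paired_policy == "keep-if-both") all(meds < params$C)
                else any(meds < params$C)
    if (dec_keep != dec$kept[j]) {
      warnf("replay mismatch at unit %s: recomputed %s, logged %s",
            dec$id[j], dec_keep, dec$kept[j])
      return(FALSE)
    }
    if (dec$kept[j]) {
      if (!is.null(kms1)) kmer_add(counter, kms1)
      if (!is.null(kms2)) kmer_add(counter, kms2)
    }
  }
  TRUE
}

#' Trim reads at low-abundance k-mers
#'
#' Replaces each read by its longest prefix in which every canonical k-mer
#' has count at least `abund_cutoff` in `counter` (which should have been
#' populated from the retained read set, see [count_kmers()]); reads whose
#' surviving prefix falls below `min_read_length` are dropped. This removes
#' likely-erroneous k-mers, which are overwhelmingly singletons.
#'
#' @param reads Character vector or `data.frame` with id/seq/qual.
#' @param counter A populated [kmer_counter()].
#' @param abund_cutoff Minimum trusted count (default 2).
#' @param min_read_length Drop reads shorter than this after trimming.
#' @return `data.frame` of surviving (possibly truncated) reads, with
#'   attribute `n_dropped`.
#' @export
filter_low_abundance <- function(reads, counter, abund_cutoff = 2,
                                 min_read_length = 25) {
  reads <- as_reads_df(reads)
  k <- counter$k
  new_len <- vapply(reads$seq, function(s) {
    kms <- canonical_kmers(s, k)
    if (length(kms) == 0L) return(0L)
    cts <- kmer_counts(counter, kms)
    bad <- which(cts < abund_cutoff)
    if (length(bad) == 0L) nchar(s)
    else as.integer(bad[1L] - 1L + k - 1L) # prefix holding k-mers 1..bad-1
  }, 0L, USE.NAMES = FALSE)
  keep <- new_len >= max(min_read_length, k)
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, 1L, new_len[keep])
  out$qual <- substr(out$qual, 1L, new_len[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Normalize FASTQ files end to end
#'
#' File-level convenience over [trim_quality_3prime()], [normalize_stream()]
#' and optionally [filter_low_abundance()]: reads FASTQ (gzip accepted),
#' trims 3' ends at `params$Q`, streams the accept/reject pass, optionally
#' abundance-trims the kept set against its own counter, and writes kept
#' reads plus a decision-log TSV.
#'
#' @param in1,in2 Input FASTQ paths (`in2` optional).
#' @param out1,out2 Output FASTQ paths.
#' @param log_path Optional decision-log TSV path.
#' @param params A [normalization_params()].
#' @param filter_abund If TRUE, run the low-abundance k-mer trim on the
#'   kept reads.
#' @return The `normalization_log`, invisibly.
#' @export
normalize_fastq <- function(in1, in2 = NULL, out1, out2 = NULL,
                            log_path = NULL, params = normalization_params(),
                            filter_abund = FALSE) {
  r1 <- read_fastq(in1)
  r2 <- if (!is.null(in2)) read_fastq(in2)
  res <- normalize_stream(r1, r2, params, trim = TRUE)
  k1 <- res$r1
  k2 <- res$r2
  if (filter_abund) {
    fc <- kmer_counter(params$k)
    count_kmers(fc, k1$seq)
    if (!is.null(k2)) count_kmers(fc, k2$seq)
    k1 <- filter_low_abundance(k1, fc, params$abund_cutoff, params$min_read_length)
    if (!is.null(k2))
      k2 <- filter_low_abundance(k2, fc, params$abund_cutoff, params$min_read_length)
  }
  write_fastq(k1, out1)
  if (!is.null(k2) && !is.null(out2)) write_fastq(k2, out2)
  if (!is.null(log_path)) write_normalization_log(res$log, log_path)
  invisible(res$log)
}
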