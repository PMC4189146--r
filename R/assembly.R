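# Descriptive statistics of contig sets.

contig_lengths <- function(contigs) {
  if (inherits(contigs, "XStringSet")) Biostrings::width(contigs)
  else if (is.character(contigs)) nchar(contigs)
  else if (is.numeric(contigs)) as.integer(contigs)
  else stopf("contigs must be an XStringSet, character sequences, or lengths")
}

#' Summary statistics of a contig set
#'
#' Total count, maximum, minimum, mean (rounded to whole bp) and median
#' length of the contigs at or above `min_length`. The median of an
#' even-sized set is the arithmetic mean of the two middle lengths. An
#' empty surviving set yields a zero-total summary with NA lengths rather
#' than an error.
#'
#' @param contigs A `DNAStringSet`, a character vector of sequences, or a
#'   numeric vector of lengths.
#' @param min_length Minimum contig length counted (default 201 bp, the
#'   conventional floor for Trinity assemblies).
#' @return A `stats_summary` list: `total`, `max_len`, `min_len`,
#'   `mean_len`, `median_len`.
#' @export
contig_stats <- function(contigs, min_length = 201) {
  lens <- contig_lengths(contigs)
  lens <- lens[lens >= min_length]
  if (length(lens) == 0L) {
    out <- list(total = 0L, max_len = NA_real_, min_len = NA_real_,
                mean_len = NA_real_, median_len = NA_real_)
  } else {
    out <- list(total = length(lens),
                max_len = as.numeric(max(lens)),
                min_len = as.numeric(min(lens)),
                mean_len = round(mean(lens)),
                median_len = as.numeric(stats::median(lens)))
  }
  structure(out, class = "stats_summary")
}

#' @export
print.stats_summary <- function(x, ...) {
  cat(sprintf("contigs: %d | length min/median/mean/max: %s/%s/%s/%s bp\n",
              x$total, x$min_len, x$median_len, x$mean_len, x$max_len))
  invisible(x)
}

#' Contig length histogram
#'
#' Bins contig lengths into half-open `[lo, hi)` bins; the final edge may
#' be `Inf` so the last bin is open-ended. The default doubling ladder
#' (200, 400, ..., 6400, Inf) matches the conventional reporting of contig
#' size distributions. Contigs below the first edge are not counted.
#'
#' @param contigs As in [contig_stats()].
#' @param bin_edges Strictly ascending numeric edges.
#' @return A `length_histogram` data.frame with `bin_lo`, `bin_hi`,
#'   `count`, `proportion` (counts over total counted contigs).
#' @export
length_histogram <- function(contigs, bin_edges = c(200, 400, 800, 1600,
                                                    3200, 6400, Inf)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stopf("bin_edges must be strictly ascending")
  lens <- contig_lengths(contigs)
  lens <- lens[lens >= bin_edges[1L] & lens < bin_edges[length(bin_edges)]]
  bin <- findInterval(lens, bin_edges) # [lo, hi) by default
  counts <- tabulate(bin, nbins = length(bin_edges) - 1L)
  total <- sum(counts)
  structure(
    data.frame(
      bin_lo = bin_edges[-length(bin_edges)],
      bin_hi = bin_edges[-1L],
      count = counts,
      proportion = if (total > 0) counts / total else rep(NA_real_, length(counts))
    ),
    class = c("length_histogram", "data.frame")
  )
}

#' Mean number of alternative reconstructions per assembly component
#'
#' Groups Trinity-style contig identifiers (`compX_cY_seqZ`) by the prefix
#' before `_seq` — the assembly-graph component whose alternative `seqZ`
#' reconstructions are putative isoforms (isotigs) — and returns the mean
#' group size. Identifiers without a `_seq` part form singleton groups and
#' raise a warning with their count.
#'
#' @param contig_ids Character vector of contig identifiers.
#' @return Mean group size (>= 1), with attribute `n_unmatched`.
#' @export
isotig_mean <- function(contig_ids) {
  if (length(contig_ids) == 0L) stopf("contig_ids must be non-empty")
  matched <- grepl("_seq", contig_ids, fixed = TRUE)
  if (any(!matched))
    warnf("%d contig ids lack a '_seq' part; treated as singleton components",
          sum(!matched))
  key <- ifelse(matched, sub("_seq.*$", "", contig_ids), contig_ids)
  out <- length(contig_ids) / length(unique(key))
  attr(out, "n_unmatched") <- sum(!matched)
  out
}
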