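# Exact canonical k-mer counting.
#
# Counts are kept in a hash environment keyed by the canonical k-mer (the
# lexicographic minimum of a k-mer and its reverse complement), so a read
# and its reverse complement contribute identical k-mer multisets. An exact
# map keeps the normalization decisions deterministic at the scales this
# package targets; any structure honoring the same query/increment contract
# (e.g. a probabilistic counter) could stand in.

#' Create an exact canonical k-mer counter
#'
#' @param k K-mer size in bp (default 25).
#' @return A `kmer_counter` object. Querying an unseen k-mer returns 0.
#' @export
kmer_counter <- function(k = 25) {
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  structure(
    list(k = as.integer(k), env = new.env(hash = TRUE, parent = emptyenv())),
    class = "kmer_counter"
  )
}

#' @export
print.kmer_counter <- function(x, ...) {
  cat(sprintf("kmer_counter: k = %d, %d distinct canonical k-mers\n",
              x$k, length(x$env)))
  invisible(x)
}

#' Canonical k-mers of a sequence
#'
#' Returns the sequence's k-mers in positional order, each replaced by the
#' lexicographic minimum of itself and its reverse complement.
#'
#' @param seq Nucleotide string.
#' @param k K-mer size.
#' @return Character vector of length `nchar(seq) - k + 1` (empty if the
#'   sequence is shorter than `k`).
#' @export
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  idx <- seq_len(n - k + 1L)
  fwd <- substring(seq, idx, idx + k - 1L)
  rc <- revcomp_chr(seq)
  rck <- rev(substring(rc, idx, idx + k - 1L))
  pmin(fwd, rck)
}

# counts for a vector of canonical k-mers (0 if unseen)
kmer_counts <- function(counter, kmers) {
  if (length(kmers) == 0L) return(integer(0))
  unlist(mget(kmers, envir = counter$env, ifnotfound = 0L), use.names = FALSE)
}

# increment counts for a vector of canonical k-mers (duplicates accumulate)
kmer_add <- function(counter, kmers) {
  if (length(kmers) == 0L) return(invisible(counter))
  tab <- table(kmers)
  keys <- names(tab)
  cur <- unlist(mget(keys, envir = counter$env, ifnotfound = 0L), use.names = FALSE)
  list2env(stats::setNames(as.list(cur + as.integer(tab)), keys), envir = counter$env)
  invisible(counter)
}

#' Count all k-mers of a set of sequences
#'
#' Populates (or augments) a counter with every canonical k-mer of `seqs`,
#' as needed before [filter_low_abundance()].
#'
#' @param counter A `kmer_counter`.
#' @param seqs Character vector of sequences (or a `data.frame` with a
#'   `seq` column).
#' @return The counter, invisibly (counts are updated in place).
#' @export
count_kmers <- function(counter, seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  for (s in seqs) kmer_add(counter, canonical_kmers(s, counter$k))
  invisible(counter)
}

#' Median k-mer abundance of a read
#'
#' Looks up the counts of the read's canonical k-mers and returns the
#' element at index `floor(m/2)` (0-based) of their ascending sort, `m`
#' being the number of k-mers — the integer-valued, deterministic median
#' used by the streaming normalization rule.
#'
#' @param seq Nucleotide string, at least `k` long.
#' @param counter A `kmer_counter`.
#' @return Integer abundance (0 for a read of entirely unseen k-mers).
#' @export
kmer_median_abundance <- function(seq, counter) {
  kms <- canonical_kmers(seq, counter$k)
  if (length(kms) == 0L)
    stopf("sequence shorter than k = %d: median abundance undefined", counter$k)
  cts <- sort(kmer_counts(counter, kms))
  cts[[as.integer(length(cts) %/% 2) + 1L]]
}
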