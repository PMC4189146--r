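# Independent oracles and small fixture builders used across test files.

# Per-residue bitmap coverage: mark every residue of a length-L protein
# touched by any 0-based half-open interval, count marks. The brute-force
# counterpart of interval-union coverage.
bitmap_coverage <- function(starts0, ends_open, L) {
  marks <- logical(L)
  for (i in seq_along(starts0)) {
    if (ends_open[i] > starts0[i])
      marks[(starts0[i] + 1L):ends_open[i]] <- TRUE
  }
  sum(marks) / L
}

# Exhaustive upper-tail hypergeometric: P[X >= k] when drawing n from N
# with K successes, summed term by term from binomial coefficients.
hyper_upper_enum <- function(k, K, N, n) {
  lo <- max(k, 0L)
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), 0))
}

# hit_records rows built directly in memory (0-based half-open intervals).
make_hits <- function(qseqid, sseqid, sstart, send, evalue = 1e-50,
                      library = NA_character_) {
  n <- length(qseqid)
  structure(
    data.frame(qseqid = qseqid, sseqid = sseqid,
               pident = rep_len(99, n), evalue = rep_len(evalue, n),
               sstart = as.integer(sstart), send = as.integer(send),
               library = rep_len(library, n), stringsAsFactors = FALSE),
    class = c("hit_records", "data.frame")
  )
}

# protein_db straight from named lengths and a parallel gene assignment.
make_db <- function(lengths, genes) {
  protein_db(lengths,
             data.frame(protein_id = names(lengths), gene_id = genes,
                        stringsAsFactors = FALSE))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Benjamini-Hochberg step-up, written out literally: sort ascending, scale
# p_(i) by m/i, then enforce monotonicity by taking running minima from the
# largest p downwards.
bh_step_up <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Phred integer vector -> Phred+33 string
int_q <- function(q) intToUtf8(q + 33L)

# test-local reverse complement, independent of the package's helper
revcomp_chr <- function(s) {
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", s)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), "", USE.NAMES = FALSE)
}

# m random 0-based half-open intervals on a length-L protein.
random_intervals <- function(L, m) {
  s <- sample.int(L, m, replace = TRUE) - 1L
  e <- s + vapply(L - s, function(r) sample.int(r, 1L), 0L)
  list(s = s, e = e)
}

# A random reconstruction plan with total <= n_genes, at least one contig.
random_plan <- function(n_genes) {
  repeat {
    counts <- c(
      "0.99" = sample(0:5, 1), "0.90" = sample(0:5, 1), "0.80" = sample(0:5, 1),
      "0.50" = sample(0:5, 1), "sub" = sample(0:3, 1)
    )
    if (sum(counts) >= 1 && sum(counts) <= n_genes) return(counts)
  }
}
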