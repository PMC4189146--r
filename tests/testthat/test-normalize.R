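# Quality trimming, median k-mer abundance, the streaming accept/reject
# rule and low-abundance k-mer trimming.

test_that("3' trimming removes exactly the maximal low-quality suffix", {
  # qualities 30,30,20,20 with Q=24: last two bases trimmed
  r <- trim_quality_3prime("ACGT", int_q(c(30, 30, 20, 20)), Q = 24)
  expect_identical(r$seq, "AC")
  expect_identical(nchar(r$qual), 2L)
  # all good: unchanged; all bad: empty; interior dips survive
  expect_identical(trim_quality_3prime("ACGT", int_q(rep(30, 4)))$seq, "ACGT")
  expect_identical(trim_quality_3prime("ACGT", int_q(rep(10, 4)))$seq, "")
  expect_identical(trim_quality_3prime("ACGTA", int_q(c(30, 5, 30, 5, 5)))$seq,
                   "ACG")
  expect_error(trim_quality_3prime("ACGT", "II"), "lengths differ")
})

test_that("median abundance follows the floor(m/2) index rule", {
  kc <- kmer_counter(3)
  # empty counter: all counts zero
  expect_identical(kmer_median_abundance("ACGGCA", kc), 0L)
  # constant counts (ACGGCA's four 3-mers are distinct after canonicalization)
  count_kmers(kc, rep("ACGGCA", 5))
  expect_identical(kmer_median_abundance("ACGGCA", kc), 5L)
  # counts {1,2,9} -> sorted index floor(3/2) (0-based) = 2
  kms <- canonical_kmers("AAACC", 3)
  kc3 <- kmer_counter(3)
  kmer_add(kc3, c(rep(kms[1], 1), rep(kms[2], 2), rep(kms[3], 9)))
  expect_identical(kmer_median_abundance("AAACC", kc3), 2L)
  expect_error(kmer_median_abundance("AC", kc), "shorter than k")
})

test_that("canonical k-mers collapse strands", {
  s <- "ACGTTGCA"
  expect_identical(canonical_kmers(s, 4), rev(canonical_kmers(revcomp_chr(s), 4)))
  expect_true(all(canonical_kmers(s, 4) <=
                    revcomp_chr(canonical_kmers(s, 4))))
})

test_that("exact-duplicate law: C < D keeps exactly C copies", {
  withr::local_seed(99)
  read <- random_dna(60)
  for (D in c(10, 50, 100)) {
    for (C in c(1, 5, 30)) {
      if (C >= D) next
      res <- normalize_stream(rep(read, D),
                              params = normalization_params(k = 25, C = C))
      expect_identical(res$log$reads_kept, as.integer(C))
      expect_identical(res$log$reads_in, as.integer(D))
    }
  }
})

test_that("C = 1 keeps one copy per distinct read; C = Inf keeps everything", {
  withr::local_seed(7)
  reads <- c(rep(random_dna(50), 4), rep(random_dna(50), 3), random_dna(50))
  res1 <- normalize_stream(reads, params = normalization_params(C = 1))
  expect_identical(res1$log$reads_kept, 3L)
  resInf <- normalize_stream(reads, params = normalization_params(C = Inf))
  expect_identical(resInf$log$reads_kept, length(reads))
  expect_identical(resInf$log$retention_fraction, 1)
})

test_that("log tallies are conserved and short reads are skipped", {
  withr::local_seed(13)
  reads <- c(random_dna(60), "ACGT", random_dna(60), random_dna(10))
  res <- normalize_stream(reads, params = normalization_params(C = 30))
  log <- res$log
  expect_identical(log$reads_in,
                   log$reads_kept + log$reads_discarded + log$reads_skipped_short)
  expect_identical(log$reads_skipped_short, 2L)
  expect_identical(sum(is.na(log$decisions$median)), 2L)
})

test_that("paired policies decide on the pair as a unit", {
  withr::local_seed(21)
  a <- random_dna(60); b <- random_dna(60)
  # saturate a's k-mers so a's median is >= 1 while b is novel
  p <- normalization_params(C = 1)
  res_either <- normalize_stream(rep(a, 3), rep(b, 3), params = p)
  # pair 1 novel -> kept; later pairs: both mates seen -> discarded
  expect_identical(res_either$log$reads_kept, 1L)
  expect_identical(nrow(res_either$r1), 1L)
  expect_identical(nrow(res_either$r2), 1L)
  # keep-if-both: mate a saturated, mate b fresh each time -> discard
  reads_a <- rep(a, 3)
  reads_b <- c(b, random_dna(60), random_dna(60))
  res_both <- normalize_stream(reads_a, reads_b,
                               params = normalization_params(
                                 C = 1, paired_policy = "keep-if-both"))
  res_eith <- normalize_stream(reads_a, reads_b, params = p)
  expect_lte(res_both$log$reads_kept, res_eith$log$reads_kept)
  expect_identical(res_both$log$reads_kept, 1L)
  expect_identical(res_eith$log$reads_kept, 3L)
})

test_that("normalizing reverse-complemented reads retains identical k-mer sets", {
  withr::local_seed(31)
  reads <- vapply(1:40, function(i) random_dna(60), "")
  reads <- c(reads, reads[1:10]) # some duplicates
  p <- normalization_params(k = 25, C = 2)
  res_f <- normalize_stream(reads, params = p)
  res_r <- normalize_stream(revcomp_chr(reads), params = p)
  expect_identical(res_f$log$decisions$kept, res_r$log$decisions$kept)
  kms_f <- sort(unlist(lapply(res_f$r1$seq, canonical_kmers, k = 25)))
  kms_r <- sort(unlist(lapply(res_r$r1$seq, canonical_kmers, k = 25)))
  expect_identical(kms_f, kms_r)
})

test_that("replay validates every logged decision", {
  withr::local_seed(41)
  reads <- c(rep(random_dna(60), 40), vapply(1:20, function(i) random_dna(60), ""))
  p <- normalization_params(k = 25, C = 5)
  res <- normalize_stream(reads, params = p)
  expect_gt(res$log$reads_discarded, 0L)
  expect_true(replay_normalization(reads, log = res$log, params = p))
  # a corrupted log is caught
  bad <- res$log
  flip <- which(!bad$decisions$kept)[1L]
  bad$decisions$kept[flip] <- TRUE
  expect_warning(ok <- replay_normalization(reads, log = bad, params = p),
                 "mismatch")
  expect_false(ok)
})

test_that("shuffling changes order deterministically under its seed", {
  withr::local_seed(51)
  reads <- vapply(1:30, function(i) random_dna(60), "")
  p1 <- normalization_params(C = 1, shuffle_seed = 5)
  res1 <- normalize_stream(c(reads, reads), params = p1)
  res2 <- normalize_stream(c(reads, reads), params = p1)
  expect_identical(res1$log$decisions, res2$log$decisions)
  expect_true(replay_normalization(c(reads, reads), log = res1$log, params = p1))
})

test_that("low-abundance trimming keeps the longest trusted prefix", {
  withr::local_seed(61)
  k <- 5L
  kc <- kmer_counter(k)
  good <- random_dna(40)
  count_kmers(kc, rep(good, 3)) # all k-mers at count 3
  # untouched read passes unchanged
  out <- filter_low_abundance(good, kc, abund_cutoff = 2, min_read_length = 10)
  expect_identical(out$seq, good)
  expect_identical(attr(out, "n_dropped"), 0L)
  # read whose FIRST k-mer is unseen is dropped entirely
  novel <- random_dna(40)
  out2 <- filter_low_abundance(novel, kc, abund_cutoff = 2, min_read_length = 10)
  expect_identical(nrow(out2), 0L)
  expect_identical(attr(out2, "n_dropped"), 1L)
  # first bad k-mer at position p: prefix holds k-mers 1..p-1, i.e.
  # p + k - 2 bases; expected p found by enumerating the chimera's k-mers
  # by hand against hand-tallied counts of the trusted read
  chimera <- paste0(substr(good, 1, 20), substr(novel, 1, 15))
  canon <- function(s) pmin(s, revcomp_chr(s))
  idx <- seq_len(nchar(good) - k + 1L)
  good_tab <- table(canon(substring(good, idx, idx + k - 1L))) * 3L
  idx <- seq_len(nchar(chimera) - k + 1L)
  ch_kms <- canon(substring(chimera, idx, idx + k - 1L))
  cts <- as.integer(good_tab[ch_kms])
  cts[is.na(cts)] <- 0L
  p_bad <- which(cts < 2L)[1L]
  expect_gte(p_bad, 20L - k + 2L) # trusted prefix k-mers all pass
  out3 <- filter_low_abundance(chimera, kc, abund_cutoff = 2, min_read_length = 5)
  expect_identical(nchar(out3$seq), p_bad + k - 2L)
  expect_identical(out3$seq, substr(chimera, 1, p_bad + k - 2L))
})

test_that("normalization parameters are validated", {
  expect_error(normalization_params(k = 0), "positive integer")
  expect_error(normalization_params(C = 0.5), ">= 1")
  expect_error(normalization_params(Q = 60), "\\[0, 41\\]")
})

test_that("fastq-level normalization trims, filters and writes round-trippable files", {
  withr::local_seed(71)
  ref <- simulate_reference(1, 1, 400, seed = 72)
  rd <- simulate_reads(ref, depth = 40, error_rate = 0, seed = 73)
  d <- withr::local_tempdir()
  in1 <- file.path(d, "r1.fastq"); in2 <- file.path(d, "r2.fastq")
  write_fastq(rd$r1, in1); write_fastq(rd$r2, in2)
  out1 <- file.path(d, "n1.fastq"); out2 <- file.path(d, "n2.fastq")
  log <- normalize_fastq(in1, in2, out1, out2,
                         log_path = file.path(d, "log.tsv"),
                         params = normalization_params(C = 5),
                         filter_abund = TRUE)
  expect_lt(log$reads_kept, log$reads_in)
  kept <- read_fastq(out1)
  expect_gt(nrow(kept), 0L)
  expect_true(file.exists(file.path(d, "log.tsv")))
})
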