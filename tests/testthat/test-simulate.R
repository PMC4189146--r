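# Generators: construction identities, determinism, planted ground truth.

test_that("reference generation is deterministic and structurally consistent", {
  ref1 <- simulate_reference(10, 1, 100, seed = 1)
  ref2 <- simulate_reference(10, 1, 100, seed = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_reference(ref1, d1)
  p2 <- write_reference(ref2, d2)
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])))
  }
  # CDS length is 3x protein length, by construction, for every isoform
  expect_identical(unname(Biostrings::width(ref1$transcripts)),
                   unname(3L * Biostrings::width(ref1$proteins)))
  # and each CDS translates to its protein
  expect_identical(as.character(Biostrings::translate(ref1$transcripts[1])),
                   as.character(ref1$proteins[1]))
})

test_that("gene map covers all isoforms with unique ids", {
  ref <- simulate_reference(5, 3, c(80, 120), seed = 7)
  expect_identical(nrow(ref$gene_map), 15L)
  expect_false(anyDuplicated(ref$gene_map$protein_id) > 0)
  expect_setequal(unique(ref$gene_map$gene_id), ref$genes)
  expect_setequal(ref$gene_map$protein_id, names(ref$proteins))
})

test_that("degenerate reference parameters are rejected", {
  expect_error(simulate_reference(0), "positive integer")
  expect_error(simulate_reference(3, isoforms_per_gene = 0, seed = 1), "positive")
  expect_error(simulate_reference(3, protein_length = c(50, 10), seed = 1),
               "degenerate")
})

test_that("planted contigs land strictly inside their band and tally to plan", {
  ref <- simulate_reference(20, c(1, 3), c(150, 400), seed = 11)
  plan <- c("0.99" = 2, "0.90" = 3, "0.80" = 1, "0.50" = 2, "sub" = 1)
  res <- simulate_contigs(ref, plan, seed = 12)
  expect_length(res$contigs, 9L)
  expect_identical(unname(planted_tallies(res$truth)[names(plan)]),
                   unname(as.integer(plan)))
  prov <- res$truth$provenance
  bands <- list("0.99" = c(0.99, 1.0000001), "0.90" = c(0.90, 0.99),
                "0.80" = c(0.80, 0.90), "0.50" = c(0.50, 0.80),
                "sub" = c(0.10, 0.50))
  for (i in seq_len(nrow(prov))) {
    b <- bands[[prov$level[i]]]
    expect_gte(prov$planted_fraction[i], b[1])
    expect_lt(prov$planted_fraction[i], b[2])
  }
  # fraction equals covered interval length over protein length, exactly
  plens <- stats::setNames(Biostrings::width(ref$proteins), names(ref$proteins))
  expect_identical(prov$fraction,
                   (prov$send - prov$sstart + 1) / unname(plens[prov$protein_id]))
  # contig sequence is the CDS slice of the planted interval
  i <- 1L
  expect_identical(
    as.character(res$contigs[[prov$contig_id[i]]]),
    as.character(Biostrings::subseq(ref$transcripts[[prov$protein_id[i]]],
                                    3L * (prov$sstart[i] - 1L) + 1L,
                                    3L * prov$send[i])))
})

test_that("a one-gene plan yields a single near-complete contig", {
  ref <- simulate_reference(1, 1, 200, seed = 3)
  res <- simulate_contigs(ref, c("0.99" = 1), seed = 4)
  expect_length(res$contigs, 1L)
  expect_gte(res$truth$provenance$planted_fraction, 0.99)
})

test_that("full fragmentation splits every plant into two pieces covering it", {
  ref <- simulate_reference(10, 1, c(150, 300), seed = 5)
  res <- simulate_contigs(ref, c("0.90" = 4, "0.50" = 3), fragmentation = 1,
                          seed = 6)
  prov <- res$truth$provenance
  expect_identical(nrow(prov), 14L)
  for (u in unique(prov$planted_id)) {
    pieces <- prov[prov$planted_id == u, ]
    expect_identical(nrow(pieces), 2L)
    # contiguous partition of the planted interval
    pieces <- pieces[order(pieces$sstart), ]
    expect_identical(pieces$sstart[2L], pieces$send[1L] + 1L)
    expect_identical(sum(pieces$send - pieces$sstart + 1L),
                     pieces$send[2L] - pieces$sstart[1L] + 1L)
  }
})

test_that("a plan larger than the gene count is rejected", {
  ref <- simulate_reference(3, 1, 150, seed = 1)
  expect_error(simulate_contigs(ref, c("0.99" = 4), seed = 1), "requests 4 genes")
  expect_error(simulate_contigs(ref, c("0.95" = 1), seed = 1), "plan names")
})

test_that("alignments biject with contig pieces and carry planted coordinates", {
  ref <- simulate_reference(15, c(1, 2), c(150, 300), seed = 21)
  res <- simulate_contigs(ref, c("0.99" = 3, "0.50" = 4, "sub" = 2), seed = 22)
  aln <- simulate_alignments(res$truth, ref, spurious_rate = 0, seed = 23)
  prov <- res$truth$provenance
  expect_identical(nrow(aln$hits), nrow(prov))
  expect_identical(aln$hits$qseqid, prov$contig_id)
  expect_identical(aln$hits$sstart, prov$sstart)
  expect_identical(aln$hits$send, prov$send)
  expect_false(any(aln$truth$spurious))
  # a full-length plant on protein of length L reports sstart=1, send=L
  full <- which(prov$fraction == 1)
  if (length(full) > 0) {
    L <- Biostrings::width(ref$proteins)[match(prov$protein_id[full[1]],
                                               names(ref$proteins))]
    expect_identical(prov$sstart[full[1]], 1L)
    expect_identical(prov$send[full[1]], L)
  }
})

test_that("spurious hits stay below half coverage and are flagged", {
  ref <- simulate_reference(30, 1, c(150, 300), seed = 31)
  res <- simulate_contigs(ref, c("0.99" = 10, "0.90" = 10), seed = 32)
  aln <- simulate_alignments(res$truth, ref, spurious_rate = 1, seed = 33)
  spur <- aln$hits[aln$truth$spurious, ]
  expect_gt(nrow(spur), 0L)
  plens <- stats::setNames(Biostrings::width(ref$proteins), names(ref$proteins))
  expect_true(all((spur$send - spur$sstart + 1) / plens[spur$sseqid] < 0.5))
  expect_true(all(spur$evalue < 1e-10)) # they do perturb the totals
})

test_that("read simulation is exact at zero error and depth-accurate", {
  ref <- simulate_reference(1, 1, 1000, seed = 41) # 3 kb transcript
  rd <- simulate_reads(ref, depth = 50, error_rate = 0, seed = 42)
  tx <- as.character(ref$transcripts[[1]])
  expect_true(all(vapply(rd$r1$seq, grepl, TRUE, x = tx, fixed = TRUE)))
  expect_true(all(vapply(revcomp_chr(rd$r2$seq), grepl, TRUE, x = tx, fixed = TRUE)))
  # mate ids share a stem
  expect_identical(sub("/1$", "", rd$r1$id), sub("/2$", "", rd$r2$id))
  # same seed, byte-identical FASTQ
  rd2 <- simulate_reads(ref, depth = 50, error_rate = 0, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd$r1, f1)
  write_fastq(rd2$r1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("interior depth tracks the requested depth within 10%", {
  ref <- simulate_reference(1, 1, 3334, seed = 43) # ~10 kb
  rd <- simulate_reads(ref, depth = 100, error_rate = 0, seed = 44)
  L <- Biostrings::width(ref$transcripts)[1]
  cov <- integer(L)
  rl <- 101L
  for (i in seq_len(nrow(rd$layout))) {
    s <- rd$layout$start[i]; ins <- rd$layout$insert[i]
    cov[s:(s + rl - 1L)] <- cov[s:(s + rl - 1L)] + 1L
    cov[(s + ins - rl):(s + ins - 1L)] <- cov[(s + ins - rl):(s + ins - 1L)] + 1L
  }
  interior <- cov[(3L * rl):(L - 3L * rl)]
  expect_gte(mean(interior), 90)
  expect_lte(mean(interior), 110)
})

test_that("too-short transcripts are skipped with a warning", {
  ref <- simulate_reference(1, 1, 25, seed = 45) # 75 bp CDS < 101 bp reads
  expect_warning(
    expect_error(simulate_reads(ref, depth = 10, seed = 46), "no reads"),
    "shorter than read length")
})

test_that("expression counts honor the planted core under vanishing noise", {
  ref <- simulate_reference(50, 1, c(150, 200), seed = 51)
  core <- ref$genes[1:5]
  ex <- simulate_expression(ref, n_libraries = 13, core_genes = core,
                            core_multiplier = 10, dispersion = 0, seed = 52)
  expect_identical(dim(ex$counts), c(50L, 13L))
  expect_length(ex$libraries, 13L)
  is_core <- rownames(ex$counts) %in% core
  # length-normalized rates separate perfectly in the Poisson limit
  rate <- ex$counts / ex$eff_lengths[rownames(ex$counts)]
  for (l in seq_len(13L))
    expect_gt(min(rate[is_core, l]), max(rate[!is_core, l]))
  expect_warning(simulate_expression(ref, 2, character(0), 10, 0, seed = 1),
                 "empty core")
  expect_error(simulate_expression(ref, 2, "NOPE", seed = 1), "subset")
})

test_that("expression tables round-trip through the TSV writers", {
  ref <- simulate_reference(8, 1, 150, seed = 61)
  ex <- simulate_expression(ref, 3, ref$genes[1], seed = 62)
  d <- withr::local_tempdir()
  paths <- write_expression(ex, d)
  expect_length(list.files(d, "^counts_"), 3L)
  back <- read_counts_tsv(paths[["lib02"]])
  expect_identical(unname(back), unname(ex$counts[, "lib02"]))
  eff <- read_eff_lengths(paths[["eff_lengths"]])
  expect_identical(unname(eff), unname(ex$eff_lengths))
})
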