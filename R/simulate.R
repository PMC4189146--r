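# Synthetic-data generators with planted ground truth.
#
# Every downstream stage (normalization, assembly metrics, homology
# evaluation, core expressed-gene selection) can be exercised on data whose
# correct answer is known by construction: which protein each contig
# reconstructs and at what fraction, which genes form the universally
# highly-expressed core, and what per-transcript read depth to expect.

# Reconstruction-level bands. Each planted gene's coverage fraction falls
# strictly inside one band, so it is counted at exactly one report level;
# "sub" plants sub-threshold contigs that only the totals rows see. The sub
# floor of 0.10 keeps planted alignments long enough to pass the default
# e-value cutoff on realistically sized proteins.
level_bands <- list(
  "0.99" = c(0.99, 1.00),
  "0.90" = c(0.90, 0.99),
  "0.80" = c(0.80, 0.90),
  "0.50" = c(0.50, 0.80),
  "sub"  = c(0.10, 0.50)
)

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulate a multi-isoform reference proteome
#'
#' Generates a reference set in the style of an orthology-browser protein
#' database: genes with one or more protein isoforms, the coding nucleotide
#' sequence of each isoform (built from sense codons, so the CDS translates
#' to the protein and its length is exactly 3x the protein length), and the
#' two-column protein-to-gene map used to group homology hits into genes.
#'
#' @param n_genes Number of genes (>= 1).
#' @param isoforms_per_gene Integer distribution spec: a scalar, a
#'   `c(lo, hi)` range sampled uniformly, or a `function(n)`.
#' @param protein_length Distribution spec for protein lengths in amino
#'   acids, same forms as `isoforms_per_gene`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `reference_set`: list with `genes` (character), `proteins`
#'   (`AAStringSet`), `transcripts` (`DNAStringSet`, one CDS per protein)
#'   and `gene_map` (`data.frame` protein_id/gene_id).
#' @seealso [write_reference()], [simulate_contigs()]
#' @export
simulate_reference <- function(n_genes, isoforms_per_gene = 1,
                               protein_length = c(150, 600), seed = NULL) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be a positive integer")
  with_seed(seed, {
    n_genes <- as.integer(n_genes)
    genes <- sprintf("G%05d", seq_len(n_genes))
    n_iso <- resolve_int_spec(isoforms_per_gene, n_genes, "isoforms_per_gene")
    prot_ids <- unlist(lapply(seq_len(n_genes), function(i)
      sprintf("%s.%d", genes[i], seq_len(n_iso[i]))))
    gene_map <- data.frame(
      protein_id = prot_ids,
      gene_id = rep(genes, n_iso),
      stringsAsFactors = FALSE
    )
    lens <- resolve_int_spec(protein_length, length(prot_ids), "protein_length")
    codons <- sense_codons()
    cds <- vapply(lens, function(L)
      paste(codons[sample.int(length(codons), L, replace = TRUE)], collapse = ""), "")
    transcripts <- Biostrings::DNAStringSet(cds)
    names(transcripts) <- prot_ids
    proteins <- Biostrings::translate(transcripts)
    names(proteins) <- prot_ids
    structure(
      list(genes = genes, proteins = proteins, transcripts = transcripts,
           gene_map = gene_map),
      class = "reference_set"
    )
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d genes, %d protein isoforms (%d-%d aa)\n",
              length(x$genes), length(x$proteins),
              min(Biostrings::width(x$proteins)),
              max(Biostrings::width(x$proteins))))
  invisible(x)
}

#' Write a reference set to disk
#'
#' Writes `proteins.faa`, `transcripts.fna` and `gene_map.tsv` under `dir`.
#'
#' @param ref A `reference_set`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteins = file.path(dir, "proteins.faa"),
    transcripts = file.path(dir, "transcripts.fna"),
    gene_map = file.path(dir, "gene_map.tsv")
  )
  Biostrings::writeXStringSet(ref$proteins, paths[["proteins"]])
  Biostrings::writeXStringSet(ref$transcripts, paths[["transcripts"]])
  write_gene_map(ref$gene_map, paths[["gene_map"]])
  invisible(paths)
}

# Smallest/largest covered length (aa) whose fraction of L lies in the band
# [lo, hi) (hi = 1 closes the band). Integer search around the float edge
# avoids representation artifacts like ceiling(0.99 * L) overshooting.
band_len_range <- function(L, lo, hi) {
  lo_len <- as.integer(ceiling(lo * L - 1e-9))
  while (lo_len / L < lo) lo_len <- lo_len + 1L
  if (hi >= 1) {
    hi_len <- L
  } else {
    hi_len <- as.integer(floor(hi * L + 1e-9))
    while (hi_len / L >= hi) hi_len <- hi_len - 1L
  }
  c(max(1L, lo_len), hi_len)
}

#' Plant contigs reconstructing known fractions of known CDSs
#'
#' For each gene requested in `plan`, emits one contig whose subject-coverage
#' fraction of one of the gene's isoforms falls strictly inside the requested
#' reconstruction band: `"0.99"` = \[0.99, 1\], `"0.90"` = \[0.90, 0.99),
#' `"0.80"` = \[0.80, 0.90), `"0.50"` = \[0.50, 0.80) and `"sub"` =
#' \[0.10, 0.50). The contig sequence is the corresponding slice of the CDS,
#' so its nucleotide length is 3x the covered amino-acid interval. Contig
#' identifiers follow the Trinity `compX_cY_seqZ` convention.
#'
#' @param ref A `reference_set`.
#' @param plan Named numeric vector of gene counts per band, names among
#'   `c("0.99", "0.90", "0.80", "0.50", "sub")`; missing bands default to 0.
#'   The total must not exceed the number of genes.
#' @param fragmentation Probability that a planted contig is emitted as two
#'   pieces whose subject intervals partition the planted interval.
#' @param seed Integer seed.
#' @return List with `contigs` (`DNAStringSet`) and `truth`
#'   (a `planted_truth`: `$provenance` has one row per emitted contig with
#'   its source protein, 1-based inclusive subject interval, exact coverage
#'   fraction, planted band and planted-unit id).
#' @export
simulate_contigs <- function(ref, plan, fragmentation = 0, seed = NULL) {
  plan <- normalize_plan(plan)
  if (sum(plan) > length(ref$genes))
    stopf("plan requests %d genes but reference has %d", sum(plan), length(ref$genes))
  if (sum(plan) < 1) stopf("plan must request at least one contig")
  with_seed(seed, {
    gene_pool <- resample(ref$genes, length(ref$genes))
    iso_of <- split(ref$gene_map$protein_id, ref$gene_map$gene_id)
    plens <- stats::setNames(Biostrings::width(ref$proteins), names(ref$proteins))

    rows <- list()
    seqs <- character(0)
    ids <- character(0)
    comp <- 0L
    unit <- 0L
    gi <- 0L
    for (lev in names(plan)) {
      band <- level_bands[[lev]]
      for (j in seq_len(plan[[lev]])) {
        gi <- gi + 1L
        unit <- unit + 1L
        gene <- gene_pool[gi]
        prot <- resample(iso_of[[gene]])
        L <- plens[[prot]]
        rng <- band_len_range(L, band[1L], band[2L])
        if (rng[1L] > rng[2L])
          stopf("protein %s (%d aa) too short to plant band %s", prot, L, lev)
        len <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
        start <- sample.int(L - len + 1L, 1L)
        end <- start + len - 1L

        pieces <- list(c(start, end))
        if (len >= 2L && stats::runif(1) < fragmentation) {
          cut <- start + sample.int(len - 1L, 1L) - 1L
          pieces <- list(c(start, cut), c(cut + 1L, end))
        }
        tx <- ref$transcripts[[prot]]
        for (p in pieces) {
          comp <- comp + 1L
          cid <- sprintf("comp%d_c0_seq1", comp)
          ids <- c(ids, cid)
          seqs <- c(seqs, as.character(
            Biostrings::subseq(tx, 3L * (p[1L] - 1L) + 1L, 3L * p[2L])))
          rows[[length(rows) + 1L]] <- data.frame(
            contig_id = cid, planted_id = unit, gene_id = gene,
            protein_id = prot, sstart = p[1L], send = p[2L],
            fraction = (p[2L] - p[1L] + 1L) / L,
            planted_fraction = len / L, level = lev,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- ids
    truth <- structure(
      list(provenance = do.call(rbind, rows), plan = plan,
           core_genes = character(0), depth_profile = NULL),
      class = "planted_truth"
    )
    list(contigs = contigs, truth = truth)
  })
}

normalize_plan <- function(plan) {
  full <- stats::setNames(integer(length(level_bands)), names(level_bands))
  if (length(plan) == 0L) return(full)
  if (is.null(names(plan)) || !all(names(plan) %in% names(full)))
    stopf("plan names must be among: %s", paste(names(full), collapse = ", "))
  if (any(plan < 0) || any(plan != floor(plan)))
    stopf("plan counts must be non-negative integers")
  full[names(plan)] <- as.integer(plan)
  full
}

#' Tallies and expected report for a planted contig set
#'
#' `planted_tallies()` counts planted units per band. `planted_report()`
#' converts them into the cumulative level-by-level shape produced by
#' [reconstruction_report()] (valid for unfragmented plants, where each unit
#' is a single contig on its own isoform): a gene/CDS/contig counts at level
#' L iff its planted fraction is >= L, and every planted unit appears in the
#' totals.
#'
#' @param truth A `planted_truth` from [simulate_contigs()].
#' @param levels Report levels, descending.
#' @return `planted_tallies()`: named integer vector (one entry per band).
#'   `planted_report()`: list with `table` (`data.frame` level/n_genes/
#'   n_cds/n_contigs) and `totals`.
#' @export
planted_tallies <- function(truth) {
  prov <- truth$provenance
  units <- prov[!duplicated(prov$planted_id), ]
  vapply(names(level_bands), function(lev) sum(units$level == lev), 0L)
}

#' @rdname planted_tallies
#' @export
planted_report <- function(truth, levels = c(0.99, 0.90, 0.80, 0.50)) {
  prov <- truth$provenance
  units <- prov[!duplicated(prov$planted_id), ]
  tab <- data.frame(
    level = levels,
    n_genes = vapply(levels, function(L)
      length(unique(units$gene_id[units$planted_fraction >= L])), 0L),
    n_cds = vapply(levels, function(L)
      length(unique(units$protein_id[units$planted_fraction >= L])), 0L),
    n_contigs = vapply(levels, function(L)
      sum(units$planted_fraction >= L), 0L)
  )
  list(table = tab,
       totals = c(genes = length(unique(units$gene_id)),
                  cds = length(unique(units$protein_id)),
                  contigs = nrow(prov)))
}

#' Emit a BLAST-style tabular hit file consistent with planted contigs
#'
#' Produces one outfmt-6 row per emitted contig piece, with subject
#' coordinates equal to the planted interval (1-based inclusive) and an
#' e-value given by a decreasing function of alignment length, so that
#' feeding the table to [reconstruction_report()] recovers the planted
#' tallies. Optionally adds spurious short hits (subject coverage < 0.5,
#' still below the usual e-value cutoff) that perturb only the totals rows;
#' these are flagged in the returned truth table.
#'
#' @param truth `planted_truth` from [simulate_contigs()].
#' @param ref The `reference_set` the truth was planted on.
#' @param spurious_rate Per-contig probability of adding one random short
#'   hit against an unrelated protein.
#' @param evalue_model `function(len_aa)` returning e-values, decreasing in
#'   alignment length; default `max(1e-180, 10^-len)`.
#' @param seed Integer seed.
#' @return List with `hits` (12-column outfmt-6 `data.frame`, writable with
#'   [write_outfmt6()]) and `truth` (`data.frame` qseqid/sseqid/spurious).
#' @export
simulate_alignments <- function(truth, ref, spurious_rate = 0,
                                evalue_model = NULL, seed = NULL) {
  prov <- truth$provenance
  if (!all(prov$protein_id %in% names(ref$proteins)))
    stopf("truth refers to proteins absent from the reference")
  evalue_model <- evalue_model %||% function(len) pmax(1e-180, 10^(-as.numeric(len)))
  plens <- stats::setNames(Biostrings::width(ref$proteins), names(ref$proteins))
  with_seed(seed, {
    len <- prov$send - prov$sstart + 1L
    pident <- round(stats::runif(nrow(prov), 95, 100), 2)
    genuine <- data.frame(
      qseqid = prov$contig_id, sseqid = prov$protein_id,
      pident = pident, length = len,
      mismatch = as.integer(round(len * (100 - pident) / 100)), gapopen = 0L,
      qstart = 1L, qend = 3L * len,
      sstart = prov$sstart, send = prov$send,
      evalue = evalue_model(len), bitscore = round(1.9 * len, 1),
      stringsAsFactors = FALSE
    )
    spur <- NULL
    if (spurious_rate > 0) {
      host <- names(plens)[plens >= 25L]
      pick <- which(stats::runif(nrow(prov)) < spurious_rate)
      srows <- lapply(pick, function(i) {
        cand <- setdiff(host, prov$protein_id[i])
        if (length(cand) == 0L) return(NULL)
        sp <- resample(cand)
        Ls <- plens[[sp]]
        slen <- 12L + sample.int(min(20L, as.integer(0.49 * Ls)) - 11L, 1L) - 1L
        st <- sample.int(Ls - slen + 1L, 1L)
        spi <- round(stats::runif(1, 70, 90), 2)
        data.frame(
          qseqid = prov$contig_id[i], sseqid = sp, pident = spi, length = slen,
          mismatch = as.integer(round(slen * (100 - spi) / 100)), gapopen = 0L,
          qstart = 1L, qend = 3L * slen, sstart = st, send = st + slen - 1L,
          evalue = evalue_model(slen), bitscore = round(1.2 * slen, 1),
          stringsAsFactors = FALSE
        )
      })
      spur <- do.call(rbind, srows)
      if (!is.null(spur)) {
        dup <- paste(spur$qseqid, spur$sseqid) %in% paste(genuine$qseqid, genuine$sseqid)
        spur <- spur[!dup, , drop = FALSE]
        if (nrow(spur) == 0L) spur <- NULL
      }
    }
    hits <- rbind(genuine, spur)
    truth_tab <- data.frame(
      qseqid = hits$qseqid, sseqid = hits$sseqid,
      spurious = c(rep(FALSE, nrow(genuine)), rep(TRUE, nrow(hits) - nrow(genuine))),
      stringsAsFactors = FALSE
    )
    list(hits = hits, truth = truth_tab)
  })
}

#' Simulate paired-end reads at controlled per-transcript depth
#'
#' Draws uniformly positioned fragments and reports both mates (forward /
#' reverse-complement) with Phred+33 qualities. The number of pairs per
#' transcript is chosen so the expected interior per-base depth matches the
#' requested depth. Transcripts shorter than the read length are skipped
#' with a warning. The true fragment layout is returned alongside the reads
#' so coverage of any retained subset can be recomputed exactly.
#'
#' @param ref A `reference_set` (reads are drawn from its CDS transcripts).
#' @param depth Target mean depth: a scalar applied to all transcripts, or a
#'   named vector naming the transcripts to sequence.
#' @param read_length Read length in bp (default 101).
#' @param error_rate Per-base substitution probability (default 0.01, the
#'   conventional 1-in-100 short-read figure).
#' @param insert_size Fragment length; default `2 * read_length + 51`,
#'   clamped to the transcript length.
#' @param seed Integer seed.
#' @return List with `r1`, `r2` (`data.frame`s of id/seq/qual; mate ids
#'   share a stem and end `/1`, `/2`) and `layout` (`data.frame`
#'   stem/transcript/start/insert).
#' @export
simulate_reads <- function(ref, depth, read_length = 101, error_rate = 0.01,
                           insert_size = NULL, seed = NULL) {
  txs <- ref$transcripts
  if (!is.null(names(depth))) {
    miss <- setdiff(names(depth), names(txs))
    if (length(miss) > 0L) stopf("unknown transcripts in depth: %s", miss[1L])
    txs <- txs[names(depth)]
    dp <- as.numeric(depth)
  } else {
    dp <- rep(as.numeric(depth), length(txs))
  }
  read_length <- as.integer(read_length)
  with_seed(seed, {
    r1s <- list(); r2s <- list(); lay <- list()
    qchars <- strsplit(int_phred(30:40), "")[[1L]]
    pair <- 0L
    for (t in seq_along(txs)) {
      L <- Biostrings::width(txs)[t]
      if (L < read_length) {
        warnf("transcript %s (%d bp) shorter than read length; skipped",
              names(txs)[t], L)
        next
      }
      ins <- min(L, as.integer(insert_size %||% (2L * read_length + 51L)))
      n_pairs <- as.integer(round(dp[t] * L / (2 * read_length)))
      if (n_pairs < 1L) next
      tx <- as.character(txs[[t]])
      starts <- sample.int(L - ins + 1L, n_pairs, replace = TRUE)
      fwd <- substring(tx, starts, starts + read_length - 1L)
      rev <- revcomp_chr(substring(tx, starts + ins - read_length, starts + ins - 1L))
      if (error_rate > 0) {
        fwd <- apply_errors(fwd, error_rate)
        rev <- apply_errors(rev, error_rate)
      }
      stems <- sprintf("p%07d_%s", pair + seq_len(n_pairs), names(txs)[t])
      pair <- pair + n_pairs
      q1 <- vapply(seq_len(n_pairs), function(i)
        paste(qchars[sample.int(length(qchars), read_length, replace = TRUE)],
              collapse = ""), "")
      q2 <- vapply(seq_len(n_pairs), function(i)
        paste(qchars[sample.int(length(qchars), read_length, replace = TRUE)],
              collapse = ""), "")
      r1s[[length(r1s) + 1L]] <- data.frame(
        id = paste0(stems, "/1"), seq = fwd, qual = q1, stringsAsFactors = FALSE)
      r2s[[length(r2s) + 1L]] <- data.frame(
        id = paste0(stems, "/2"), seq = rev, qual = q2, stringsAsFactors = FALSE)
      lay[[length(lay) + 1L]] <- data.frame(
        stem = stems, transcript = names(txs)[t], start = starts, insert = ins,
        stringsAsFactors = FALSE)
    }
    if (length(r1s) == 0L) stopf("no reads generated; depth too low or transcripts too short")
    list(r1 = do.call(rbind, r1s), r2 = do.call(rbind, r2s),
         layout = do.call(rbind, lay))
  })
}

apply_errors <- function(seqs, rate) {
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1L]]
    pos <- resample(seq_along(ch), n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) resample(setdiff(bases, b)), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate per-library gene counts with a planted high-expression core
#'
#' Emulates a multi-library expression design with a deliberately minimal
#' overdispersed model: counts are drawn from a negative binomial with
#' `size = 1/dispersion` (`dispersion = 0` degenerates to Poisson) around a
#' baseline mean shared by all non-core genes, and core genes get
#' `core_multiplier` times that baseline in every library. Setting
#' `baseline_sdlog > 0` layers a per-gene lognormal expression spread
#' shared across libraries on top; note that persistent high-baseline
#' non-core genes then enter every library's top expression fraction, so
#' the cross-library intersection becomes a superset of the planted core. Gene-level effective lengths are
#' the mean CDS length over the gene's isoforms, and mean counts scale with
#' effective length so that TPM recovers relative expression.
#'
#' @param ref A `reference_set`.
#' @param n_libraries Number of libraries (default 13).
#' @param core_genes Character vector of planted core genes (subset of
#'   `ref$genes`).
#' @param core_multiplier Fold increase of core genes' means (default 10).
#' @param dispersion Negative-binomial dispersion; 0 means Poisson.
#' @param baseline_mean Mean count of an average-length, average-expression
#'   gene.
#' @param baseline_sdlog Lognormal sdlog of an optional per-gene relative
#'   expression spread shared across libraries (default 0: the minimal
#'   model, all non-core genes exchangeable).
#' @param seed Integer seed.
#' @return An `expression_sim`: list with `counts` (genes x libraries
#'   integer matrix), `eff_lengths` (named, bp), `core_genes`, `libraries`.
#' @export
simulate_expression <- function(ref, n_libraries = 13, core_genes = character(0),
                                core_multiplier = 10, dispersion = 0.1,
                                baseline_mean = 100, baseline_sdlog = 0,
                                seed = NULL) {
  if (!is_count(n_libraries) || n_libraries < 1)
    stopf("n_libraries must be a positive integer")
  if (!all(core_genes %in% ref$genes))
    stopf("core_genes must be a subset of the reference genes")
  if (length(core_genes) == 0L && core_multiplier != 1)
    warnf("empty core with core_multiplier != 1: no genes will be boosted")
  with_seed(seed, {
    genes <- ref$genes
    G <- length(genes)
    libs <- sprintf("lib%02d", seq_len(n_libraries))
    txw <- Biostrings::width(ref$transcripts)
    eff <- vapply(split(txw, ref$gene_map$gene_id)[genes], function(w)
      round(mean(w)), 0)
    rel <- stats::rlnorm(G, 0, baseline_sdlog)
    mu <- baseline_mean * rel * eff / mean(eff)
    mu[genes %in% core_genes] <- mu[genes %in% core_genes] * core_multiplier
    draw <- function(mu) {
      if (dispersion <= 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    }
    counts <- vapply(libs, function(l) draw(mu), numeric(G))
    rownames(counts) <- genes
    structure(
      list(counts = counts, eff_lengths = stats::setNames(eff, genes),
           core_genes = core_genes, libraries = libs),
      class = "expression_sim"
    )
  })
}

#' Write a simulated expression design to disk
#'
#' One `counts_<library>.tsv` per library (header `gene_id<TAB><library>`)
#' plus `eff_lengths.tsv`.
#'
#' @param sim An `expression_sim` from [simulate_expression()].
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_expression <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in sim$libraries) {
    p <- file.path(dir, sprintf("counts_%s.tsv", l))
    df <- data.frame(gene_id = rownames(sim$counts), count = sim$counts[, l])
    names(df)[2L] <- l
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[l] <- p
  }
  pe <- file.path(dir, "eff_lengths.tsv")
  utils::write.table(
    data.frame(gene_id = names(sim$eff_lengths), eff_length = sim$eff_lengths),
    pe, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["eff_lengths"] <- pe
  invisible(paths)
}
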