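# Homology-based evaluation of contigs against a reference proteome:
# subject-coverage fractions from tabular BLAST hits, classification at CDS
# reconstruction levels, and ortholog-based aggregation to genes.

#' Build a reference protein database
#'
#' The fixed frame of the evaluation: protein lengths (amino acids) plus
#' the protein-to-gene grouping used to report gene-level counts.
#'
#' @param proteins An `AAStringSet`, or a named numeric vector of protein
#'   lengths in amino acids.
#' @param gene_map `data.frame` with columns `protein_id`, `gene_id`
#'   (see [read_gene_map()]); every protein must map to exactly one gene.
#' @return A `protein_db`: list with `lengths` (named), `gene_of` (named),
#'   `isoforms_of` (list gene -> protein ids), `n_proteins`.
#' @export
protein_db <- function(proteins, gene_map) {
  lens <- if (inherits(proteins, "XStringSet")) {
    stats::setNames(Biostrings::width(proteins), names(proteins))
  } else if (is.numeric(proteins) && !is.null(names(proteins))) {
    proteins
  } else {
    stopf("proteins must be an AAStringSet or a named length vector")
  }
  if (any(lens < 1)) stopf("protein lengths must be >= 1")
  if (anyDuplicated(names(lens))) stopf("protein ids must be unique")
  if (!all(c("protein_id", "gene_id") %in% names(gene_map)))
    stopf("gene_map needs protein_id and gene_id columns")
  if (anyDuplicated(gene_map$protein_id))
    stopf("gene_map maps some protein to more than one gene")
  miss <- setdiff(names(lens), gene_map$protein_id)
  if (length(miss) > 0L)
    stopf("gene_map does not cover %d proteins (first: %s)", length(miss), miss[1L])
  gene_of <- stats::setNames(gene_map$gene_id, gene_map$protein_id)[names(lens)]
  structure(
    list(lengths = lens, gene_of = gene_of,
         isoforms_of = split(names(gene_of), gene_of),
         n_proteins = length(lens)),
    class = "protein_db"
  )
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("protein_db: %d proteins, %d genes\n",
              x$n_proteins, length(x$isoforms_of)))
  invisible(x)
}

#' Parse a BLAST tabular file into filtered hit records
#'
#' Reads an outfmt-6 table (see [read_outfmt6()]), drops rows with e-value
#' `>= evalue_max`, and converts the 1-based inclusive subject interval to
#' the 0-based half-open convention used internally. Rows with
#' `sstart > send` are rejected as malformed: protein-subject searches
#' never produce reversed subject coordinates (minus-frame hits reverse the
#' query side, which is kept as-is).
#'
#' @param path Path to a 12-column tabular hit file.
#' @param evalue_max Significance cutoff; rows must satisfy
#'   `evalue < evalue_max` (default 1e-10).
#' @param library Optional library tag stored with each record.
#' @return A `hit_records` data.frame: `qseqid`, `sseqid`, `pident`,
#'   `evalue`, `sstart`, `send` (0-based half-open), `library`.
#' @export
parse_blast_table <- function(path, evalue_max = 1e-10, library = NA_character_) {
  raw <- read_outfmt6(path)
  bad <- which(raw$sstart > raw$send)
  if (length(bad) > 0L)
    stopf("%s: line %d has sstart > send (malformed for a protein subject)",
          path, bad[1L])
  raw <- raw[raw$evalue < evalue_max, , drop = FALSE]
  structure(
    data.frame(
      qseqid = raw$qseqid, sseqid = raw$sseqid, pident = raw$pident,
      evalue = raw$evalue,
      sstart = as.integer(raw$sstart) - 1L, send = as.integer(raw$send),
      library = rep(library, nrow(raw)),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    class = c("hit_records", "data.frame")
  )
}

#' @rdname parse_blast_table
#' @param hits A 12-column outfmt-6 `data.frame` already in memory (1-based
#'   inclusive coordinates), e.g. from [simulate_alignments()].
#' @export
as_hit_records <- function(hits, evalue_max = 1e-10, library = NA_character_) {
  stopifnot(all(c("qseqid", "sseqid", "evalue", "sstart", "send") %in% names(hits)))
  if (any(hits$sstart > hits$send)) stopf("hits contain sstart > send rows")
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  structure(
    data.frame(
      qseqid = hits$qseqid, sseqid = hits$sseqid,
      pident = hits$pident %||% rep(NA_real_, nrow(hits)),
      evalue = hits$evalue,
      sstart = as.integer(hits$sstart) - 1L, send = as.integer(hits$send),
      library = rep(library, nrow(hits)),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    class = c("hit_records", "data.frame")
  )
}

#' Subject coverage of one (contig, protein) pair
#'
#' Merges the subject intervals of all HSPs the pair produced (interval
#' union, so overlapping HSPs are not double-counted) and divides the
#' united length by the protein length.
#'
#' @param hits `hit_records` rows sharing one `qseqid`/`sseqid` pair.
#' @param db A [protein_db()] containing the subject.
#' @return Coverage fraction in \[0, 1\].
#' @export
subject_coverage <- function(hits, db) {
  if (nrow(hits) == 0L) stopf("no hits given")
  if (length(unique(hits$qseqid)) != 1L || length(unique(hits$sseqid)) != 1L)
    stopf("subject_coverage expects hits of a single (query, subject) pair")
  covg <- coverage_table(hits, db)
  covg$coverage[[1L]]
}

#' Per-pair coverage fractions for a hit table
#'
#' @param hits A `hit_records` data.frame (any number of pairs).
#' @param db A [protein_db()].
#' @return `data.frame` with one row per (qseqid, sseqid) pair and its
#'   merged-interval `coverage` fraction.
#' @export
coverage_table <- function(hits, db) {
  if (nrow(hits) == 0L)
    return(data.frame(qseqid = character(), sseqid = character(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(hits$sseqid), names(db$lengths))
  if (length(unknown) > 0L)
    stopf("subjects absent from the protein database: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  grp <- split(seq_len(nrow(hits)), key)
  first <- vapply(grp, `[[`, 0L, 1L)
  union_len <- vapply(grp, function(ii) {
    if (length(ii) == 1L) as.numeric(hits$send[ii] - hits$sstart[ii])
    else sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = hits$sstart[ii] + 1L, end = hits$send[ii]))))
  }, 0)
  out <- data.frame(
    qseqid = hits$qseqid[first], sseqid = hits$sseqid[first],
    coverage = union_len / as.numeric(db$lengths[hits$sseqid[first]]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(out$coverage > 1 + 1e-12))
    stopf("hit intervals exceed protein length for %s",
          out$sseqid[which(out$coverage > 1 + 1e-12)[1L]])
  out
}

#' CDS reconstruction report at coverage levels
#'
#' For each reconstruction level L (coverage thresholds, descending), counts
#' (i) genes with at least one isoform reconstructed at coverage `>= L` by
#' some contig, (ii) distinct coding sequences (proteins) so reconstructed,
#' and (iii) distinct contigs achieving `>= L` on some protein. The totals
#' row counts everything with any significant hit regardless of coverage.
#' Per-gene aggregation always takes the best-covered isoform.
#'
#' @param hits `hit_records` (already e-value filtered).
#' @param db A [protein_db()].
#' @param levels Coverage thresholds, descending (default
#'   `c(0.99, 0.90, 0.80, 0.50)`).
#' @return A `reconstruction_report`: list with `table` (`data.frame`
#'   level/n_genes/n_cds/n_contigs), `totals` (genes/cds/contigs),
#'   `coverage` (the per-pair [coverage_table()]) and `gene_best` (named
#'   vector: per-gene maximum coverage over all isoforms and contigs).
#' @export
reconstruction_report <- function(hits, db, levels = c(0.99, 0.90, 0.80, 0.50)) {
  levels <- sort(levels, decreasing = TRUE)
  covg <- coverage_table(hits, db)
  gene <- unname(db$gene_of[covg$sseqid])
  tab <- data.frame(
    level = levels,
    n_genes = vapply(levels, function(L)
      length(unique(gene[covg$coverage >= L])), 0L),
    n_cds = vapply(levels, function(L)
      length(unique(covg$sseqid[covg$coverage >= L])), 0L),
    n_contigs = vapply(levels, function(L)
      length(unique(covg$qseqid[covg$coverage >= L])), 0L)
  )
  gene_best <- if (nrow(covg) > 0L)
    vapply(split(covg$coverage, gene), max, 0) else stats::setNames(numeric(0), character(0))
  structure(
    list(table = tab,
         totals = c(genes = length(unique(gene)),
                    cds = length(unique(covg$sseqid)),
                    contigs = length(unique(covg$qseqid))),
         coverage = covg,
         gene_best = gene_best),
    class = "reconstruction_report"
  )
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat("CDS reconstruction report (coverage >= level)\n")
  hdr <- x$table
  hdr$level <- sprintf(">= %d%%", round(100 * hdr$level))
  print(hdr, row.names = FALSE)
  cat(sprintf("totals (any significant hit): genes %d, cds %d, contigs %d\n",
              x$totals[["genes"]], x$totals[["cds"]], x$totals[["contigs"]]))
  invisible(x)
}

#' Write a reconstruction report as TSV and/or JSON
#'
#' The TSV mirrors the level-by-level layout (level rows, gene/CDS/contig
#' columns, totals row with level NA).
#'
#' @param report A `reconstruction_report`.
#' @param tsv,json Optional output paths.
#' @return Written paths, invisibly.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  out <- rbind(
    report$table,
    data.frame(level = NA, n_genes = report$totals[["genes"]],
               n_cds = report$totals[["cds"]],
               n_contigs = report$totals[["contigs"]])
  )
  if (!is.null(tsv))
    utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(levels = report$table, totals = as.list(report$totals)),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Merge hit tables across libraries and re-report
#'
#' Contig identifiers restart in every assembly, so query ids are
#' namespaced as `<library>:<contig>` before merging; the report is then
#' recomputed on the merged hits, which makes per-gene best coverage the
#' maximum over libraries.
#'
#' @param per_library_hits Named list of `hit_records` (names are the
#'   library tags; must be unique).
#' @param db A [protein_db()].
#' @param levels As in [reconstruction_report()].
#' @return A `reconstruction_report` for the union.
#' @export
union_reports <- function(per_library_hits, db, levels = c(0.99, 0.90, 0.80, 0.50)) {
  if (length(per_library_hits) < 1L) stopf("need at least one library")
  tags <- names(per_library_hits) %||% as.character(seq_along(per_library_hits))
  if (anyDuplicated(tags)) stopf("duplicate library tags")
  merged <- do.call(rbind, lapply(seq_along(per_library_hits), function(i) {
    h <- per_library_hits[[i]]
    h$qseqid <- paste(tags[i], h$qseqid, sep = ":")
    h$library <- tags[i]
    h
  }))
  reconstruction_report(merged, db, levels)
}

#' Histogram of per-gene best coverage
#'
#' Bins the per-gene maximum coverage fractions (the best reconstructed CDS
#' of each gene) into `[lo, lo + bin_width)` bins; the last bin is closed
#' at 1.0 so fully reconstructed genes are counted with it.
#'
#' @param best Named numeric vector of per-gene best coverage (the
#'   `gene_best` field of a report).
#' @param bin_width Bin width as a fraction (default 0.01).
#' @return `data.frame` with `bin_lo`, `bin_hi`, `count`, `frequency`
#'   (counts over total genes).
#' @export
coverage_histogram <- function(best, bin_width = 0.01) {
  if (!(bin_width > 0 && bin_width <= 1)) stopf("bin_width must lie in (0, 1]")
  nb <- as.integer(ceiling(1 / bin_width - 1e-9))
  bin <- pmin(as.integer(floor(best / bin_width + 1e-12)), nb - 1L)
  counts <- tabulate(bin + 1L, nbins = nb)
  data.frame(
    bin_lo = bin_width * (seq_len(nb) - 1L),
    bin_hi = pmin(bin_width * seq_len(nb), 1),
    count = counts,
    frequency = if (length(best) > 0) counts / length(best) else rep(NA_real_, nb)
  )
}
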