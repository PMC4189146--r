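#' Read a FASTQ file into a data frame
#'
#' Thin wrapper around [Biostrings::readQualityScaledDNAStringSet()] that
#' returns reads as a plain `data.frame` with columns `id`, `seq` and `qual`
#' (Phred+33 quality string), the in-memory interchange format used by the
#' normalization functions. Gzipped input is accepted.
#'
#' @param path FASTQ file path.
#' @return `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # muffle Biostrings' benign note about dropping the qualities mcol while
  # it builds the QualityScaledDNAStringSet
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns .* dropped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(
    id   = names(x),
    seq  = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads `data.frame` with columns `id`, `seq`, `qual`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  qs <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(
    qs, filepath = path, compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

outfmt6_cols <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a BLAST tabular (outfmt 6) file without interpretation
#'
#' Validates the 12-column layout line by line (reporting the first offending
#' line number) and returns the raw table with standard column names and
#' 1-based inclusive coordinates exactly as BLAST wrote them. Use
#' [parse_blast_table()] for the filtered, convention-converted hit records
#' the evaluation functions consume.
#'
#' @param path Tab-separated file with the 12 standard columns
#'   (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore) and no header.
#' @return `data.frame` with those 12 columns; zero rows for an empty file.
#' @export
read_outfmt6 <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    out <- as.data.frame(
      stats::setNames(
        c(list(character(), character()), rep(list(numeric()), 10L)),
        outfmt6_cols
      )
    )
    return(out)
  }
  bad <- which(nf != 12L)
  if (length(bad) > 0L)
    stopf("%s: line %d has %d fields, expected 12", path, bad[1L], nf[bad[1L]])
  out <- utils::read.table(
    path, sep = "\t", quote = "", comment.char = "",
    col.names = outfmt6_cols, colClasses = "character",
    stringsAsFactors = FALSE
  )
  for (cc in outfmt6_cols[-(1:2)]) {
    vals <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(vals))
      stopf("%s: line %d has unparsable numeric fields",
            path, which(is.na(vals))[1L])
    out[[cc]] <- vals
  }
  out
}

#' Write a BLAST tabular (outfmt 6) file
#'
#' @param hits `data.frame` carrying the 12 standard columns (1-based
#'   inclusive coordinates, as from [read_outfmt6()] or
#'   [simulate_alignments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outfmt6 <- function(hits, path) {
  stopifnot(all(outfmt6_cols %in% names(hits)))
  out <- hits[outfmt6_cols]
  for (cc in outfmt6_cols[-(1:2)]) out[[cc]] <- format(out[[cc]], trim = TRUE, scientific = NA)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein-to-gene mapping table
#'
#' Two tab-separated columns, protein id then gene id, no header (the layout
#' of an oma-ensembl style orthology export).
#'
#' @param path TSV path.
#' @return `data.frame` with columns `protein_id`, `gene_id`.
#' @export
read_gene_map <- function(path) {
  out <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           col.names = c("protein_id", "gene_id"),
                           colClasses = "character", stringsAsFactors = FALSE)
  out
}

#' @rdname read_gene_map
#' @param gene_map `data.frame` with columns `protein_id`, `gene_id`.
#' @export
write_gene_map <- function(gene_map, path) {
  utils::write.table(gene_map[, c("protein_id", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' Two tab-separated columns, term then gene id, no header. Returns the
#' list-of-gene-sets form [enrich()] consumes.
#'
#' @param path TSV path.
#' @return Named list of character vectors (term -> gene ids).
#' @export
read_term_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                         col.names = c("term", "gene_id"),
                         colClasses = "character", stringsAsFactors = FALSE)
  lapply(split(x$gene_id, x$term), unique)
}

#' Read a per-library gene count table
#'
#' @param path TSV with a header line `gene_id<TAB><library>` and one row per
#'   gene, as written by [write_expression()].
#' @return Named numeric vector of counts.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = c("character", "numeric"))
  stats::setNames(x[[2L]], x[[1L]])
}

#' Read an effective-length table
#'
#' @param path TSV with header `gene_id<TAB>eff_length`.
#' @return Named numeric vector of effective lengths (bp).
#' @export
read_eff_lengths <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = c("character", "numeric"))
  stats::setNames(x[[2L]], x[[1L]])
}
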