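# Gene-level TPM, per-library top-fraction sets, cross-library core-set
# intersection and fold-enrichment statistics.

#' Transcripts-per-million from counts and effective lengths
#'
#' `TPM_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6`: counts are first
#' length-normalized to per-base read rates, then scaled so each library
#' sums to one million. Gene-level counts (e.g. from an upstream
#' multi-mapping-aware quantifier) are taken as given.
#'
#' @param counts Non-negative counts: a named vector (one library) or a
#'   genes x libraries matrix.
#' @param eff_lengths Named positive effective lengths (bp), matched by
#'   name when both are named.
#' @return TPM in the same shape as `counts`. Each library sums to 1e6.
#' @export
tpm <- function(counts, eff_lengths) {
  if (is.matrix(counts)) {
    out <- apply(counts, 2L, tpm, eff_lengths = eff_lengths)
    rownames(out) <- rownames(counts)
    return(out)
  }
  if (any(eff_lengths <= 0)) stopf("effective lengths must be positive")
  if (!is.null(names(counts)) && !is.null(names(eff_lengths))) {
    miss <- setdiff(names(counts), names(eff_lengths))
    if (length(miss) > 0L) stopf("no effective length for gene %s", miss[1L])
    eff_lengths <- eff_lengths[names(counts)]
  } else if (length(eff_lengths) != length(counts)) {
    stopf("counts and eff_lengths differ in length and are not named")
  }
  if (all(counts == 0)) stopf("library has no expressed genes")
  rate <- counts / eff_lengths
  rate / sum(rate) * 1e6
}

#' Top expressed fraction of one library
#'
#' Ranks genes with TPM > 0 in descending order and returns the first
#' `ceiling(q * G)` gene ids, `G` being the number of expressed genes; ties
#' at the boundary are broken by ascending gene id, making the set
#' deterministic.
#'
#' @param tpm_vec Named TPM vector for one library.
#' @param q Top fraction in (0, 1\] (default 0.05).
#' @return Character vector of gene ids.
#' @export
top_fraction <- function(tpm_vec, q = 0.05) {
  if (!(q > 0 && q <= 1)) stopf("q must lie in (0, 1]")
  if (is.null(names(tpm_vec))) stopf("tpm_vec must be named by gene id")
  expressed <- tpm_vec[tpm_vec > 0]
  if (length(expressed) == 0L) stopf("no expressed genes in this library")
  n <- as.integer(ceiling(q * length(expressed)))
  ids <- names(expressed)
  ord <- order(-expressed, ids)
  ids[ord][seq_len(n)]
}

#' Cross-library core set of highly expressed genes
#'
#' Intersects the per-library top sets and annotates each member with its
#' unweighted mean TPM across libraries, sorted descending.
#'
#' @param per_library_top List of gene-id sets (one per library).
#' @param tpm_mat Genes x libraries TPM matrix used for the averages.
#' @param q The top fraction the sets were built with (recorded on the
#'   result).
#' @return A `core_set` data.frame with columns `gene_id`, `avg_tpm`, and
#'   attributes `q` and `n_libraries`. An empty intersection is valid.
#' @export
core_set <- function(per_library_top, tpm_mat = NULL, q = NA_real_) {
  if (length(per_library_top) < 1L) stopf("need at least one library set")
  genes <- Reduce(intersect, per_library_top)
  avg <- if (!is.null(tpm_mat) && length(genes) > 0L)
    rowMeans(tpm_mat[genes, , drop = FALSE]) else rep(NA_real_, length(genes))
  ord <- order(-avg, genes)
  structure(
    data.frame(gene_id = genes[ord], avg_tpm = unname(avg[ord]),
               stringsAsFactors = FALSE),
    q = q, n_libraries = length(per_library_top),
    class = c("core_set", "data.frame")
  )
}

#' Overlap of a core set with an external gene list
#'
#' @param core A `core_set` (or plain character vector of gene ids).
#' @param reference_list Character vector of gene ids sharing the same
#'   namespace.
#' @return List with `genes` (the intersection, sorted), `n_overlap`,
#'   `n_core`, `n_reference`.
#' @export
overlap_with_list <- function(core, reference_list) {
  ids <- if (is.data.frame(core)) core$gene_id else core
  if (length(reference_list) == 0L) warnf("reference list is empty")
  ov <- sort(intersect(ids, reference_list))
  list(genes = ov, n_overlap = length(ov), n_core = length(ids),
       n_reference = length(unique(reference_list)))
}

#' Term enrichment of a study set by hypergeometric test
#'
#' For each term, computes the fold enrichment `(k/n) / (K/N)` of the study
#' set over the background and the upper-tail hypergeometric p-value
#' `P[X >= k]` (sampling `n` genes from `N` of which `K` carry the term);
#' p-values are adjusted across all tested terms by Benjamini-Hochberg, and
#' terms with adjusted p below `alpha` are flagged enriched. Term sets are
#' clipped to the background; terms with no background member are dropped
#' with a warning.
#'
#' @param term_map Named list of gene-id sets per term (see
#'   [read_term_map()]).
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids.
#' @param alpha Adjusted-p threshold for the `enriched` flag (default 0.05).
#' @return An `enrichment_result` data.frame: `term`, `k`, `n`, `K`, `N`,
#'   `fold`, `p`, `p_adj`, `enriched`, sorted by `p`.
#' @export
enrich <- function(term_map, study, background, alpha = 0.05) {
  study <- unique(study)
  background <- unique(background)
  extra <- setdiff(study, background)
  if (length(extra) > 0L)
    stopf("study set is not a subset of the background (e.g. %s)", extra[1L])
  N <- length(background)
  n <- length(study)
  Ks <- vapply(term_map, function(g) length(intersect(g, background)), 0L)
  empty <- Ks == 0L
  if (any(empty)) {
    warnf("%d terms have no background member; dropped", sum(empty))
    term_map <- term_map[!empty]
    Ks <- Ks[!empty]
  }
  if (length(term_map) == 0L) stopf("no testable terms")
  ks <- vapply(term_map, function(g) length(intersect(g, study)), 0L)
  fold <- (ks / n) / (Ks / N)
  p <- stats::phyper(ks - 1L, Ks, N - Ks, n, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    term = names(term_map), k = ks, n = n, K = Ks, N = N,
    fold = fold, p = p, p_adj = p_adj, enriched = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
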