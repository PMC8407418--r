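# Single-copy-gene completeness/contamination and the bin-retention filter.
#
# Completeness = % of the marker set present at least once in the bin;
# contamination = % of the set present in two or more copies (a CheckM-like
# duplication notion restricted to the set). Marker detection itself (HMM
# search) is upstream: input is a gene-hit table from annotation. Two
# identical hit rows count as two copies.

#' Read a single-copy-gene set from a one-identifier-per-line file
#'
#' Lines starting with `#` are comments. The packaged default
#' (`scg_set = NULL`) is a 43-marker ribosomal-protein-centric set suited to
#' reduced CPR genomes, shipped as an editable data file; any set can be
#' supplied instead.
#'
#' @param path file of gene identifiers, or `NULL` for the packaged default.
#' @return character vector of unique identifiers.
#' @export
read_scg_set <- function(path = NULL) {
  path <- path %||% system.file("extdata", "scg_set_cpr43.txt",
                                package = "microcensus")
  lines <- trimws(readLines(path))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(ids)) stop_mc("duplicate identifiers in SCG set: ", path)
  if (length(ids) == 0L) stop_mc("empty SCG set: ", path)
  ids
}

#' Score one bin's completeness and contamination
#'
#' Identifiers are matched exactly after case-folding; hits outside the set
#' are ignored.
#'
#' @param gene_hits data.frame with columns bin_id, gene_id (rows for one
#'   bin; extra bins are an error — use [score_bins()] for tables).
#' @param scg_set character vector of marker identifiers (non-empty).
#' @param contamination_mode `"multicopy_fraction"` (default: % of set with
#'   >= 2 copies) or `"excess_copies"` (% of set counted as copies minus one,
#'   summed).
#' @return one-row data.frame: bin_id, completeness, contamination, n_markers,
#'   n_present, n_multicopy; per-gene copy counts in attribute
#'   `"copy_counts"`.
#' @export
score_bin <- function(gene_hits, scg_set,
                      contamination_mode = c("multicopy_fraction", "excess_copies")) {
  contamination_mode <- match.arg(contamination_mode)
  if (length(scg_set) == 0L) stop_mc("SCG set is empty")
  if (anyDuplicated(tolower(scg_set))) stop_mc("SCG set has duplicate identifiers")
  bins <- unique(gene_hits$bin_id)
  if (length(bins) > 1L) stop_mc("score_bin got hits for multiple bins")
  set_lc <- tolower(scg_set)
  hits_lc <- tolower(gene_hits$gene_id)
  counts <- vapply(set_lc, function(g) sum(hits_lc == g), integer(1))
  names(counts) <- scg_set
  n <- length(scg_set)
  n_present <- sum(counts >= 1L)
  n_multi <- sum(counts >= 2L)
  contamination <- switch(contamination_mode,
    multicopy_fraction = 100 * n_multi / n,
    excess_copies = 100 * sum(pmax(counts - 1L, 0L)) / n)
  out <- data.frame(
    bin_id = if (length(bins)) bins else NA_character_,
    completeness = 100 * n_present / n,
    contamination = contamination,
    n_markers = n, n_present = n_present, n_multicopy = n_multi,
    stringsAsFactors = FALSE
  )
  attr(out, "copy_counts") <- counts
  out
}

#' Score every bin in a gene-hit table
#'
#' @inheritParams score_bin
#' @param gene_hits data.frame with columns bin_id, gene_id.
#' @return data.frame with one [score_bin()] row per bin.
#' @export
score_bins <- function(gene_hits, scg_set,
                       contamination_mode = c("multicopy_fraction", "excess_copies")) {
  contamination_mode <- match.arg(contamination_mode)
  parts <- split(gene_hits, gene_hits$bin_id)
  out <- do.call(rbind, lapply(parts, score_bin, scg_set = scg_set,
                               contamination_mode = contamination_mode))
  rownames(out) <- NULL
  out
}

#' Retain bins passing the draft-genome quality filter
#'
#' Strict inequalities on both sides: completeness must exceed
#' `min_completeness` and contamination must be below `max_contamination`
#' (so a bin at exactly 70% completeness or exactly 10% contamination is
#' rejected).
#'
#' @param reports a [score_bins()] data.frame.
#' @param min_completeness,max_contamination thresholds in `[0, 100]`
#'   (defaults 70 and 10).
#' @return `reports` with a logical `retained` column added.
#' @export
filter_bins <- function(reports, min_completeness = 70, max_contamination = 10) {
  stopifnot(min_completeness >= 0, min_completeness <= 100,
            max_contamination >= 0, max_contamination <= 100)
  reports$retained <- reports$completeness > min_completeness &
    reports$contamination < max_contamination
  reports
}
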