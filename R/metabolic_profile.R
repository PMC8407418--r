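# Metabolic marker presence and pathway percent-completeness per bin.
#
# Matching is identifier-based (gene symbols / EC numbers emitted by upstream
# annotation), exact after case-folding; pathway definitions are flat gene
# sets scored as percent of members present (no boolean module logic).

#' Read a marker/pathway panel definition
#'
#' The panel TSV has three columns: `type` (`marker` or `pathway`), `name`,
#' and `member` (one identifier alias or pathway member per row). The
#' packaged default (`path = NULL`) covers the conserved glycolysis trio
#' (TIM, GAPDH, PGK), electron-transport-chain markers (NADH dehydrogenase,
#' ctaB heme O synthase EC 2.5.1.141, PPA inorganic pyrophosphatase
#' EC 3.6.1.1, sdhA succinate dehydrogenase/fumarate reductase EC 1.3.5.1 /
#' 1.3.5.4), and percent-completeness pathways (F-type ATPase, TCA cycle,
#' amino acid / lipid / purine / pyrimidine biosynthesis). The pathway gene
#' memberships are editable reconstructions of standard definitions, not a
#' published list.
#'
#' @param path panel TSV, or `NULL` for the packaged default.
#' @return an object of class `marker_panel`: list with `markers` (named list
#'   of alias vectors) and `pathways` (named list of member vectors).
#' @export
read_marker_panel <- function(path = NULL) {
  path <- path %||% system.file("extdata", "marker_panel.tsv",
                                package = "microcensus")
  tab <- read_tsv_mc(path)
  stopifnot(all(c("type", "name", "member") %in% names(tab)))
  mk <- tab[tab$type == "marker", ]
  pw <- tab[tab$type == "pathway", ]
  panel <- structure(list(
    markers = split(mk$member, mk$name),
    pathways = split(pw$member, pw$name)
  ), class = "marker_panel")
  if (any(!lengths(panel$markers)) || any(!lengths(panel$pathways))) {
    stop_mc("panel has an empty marker alias list or pathway set: ", path)
  }
  panel
}

match_any <- function(hit_ids, aliases) {
  any(tolower(hit_ids) %in% tolower(aliases))
}

#' Marker presence flags for one bin
#'
#' A marker is present iff at least one hit identifier matches any of its
#' aliases (exact, case-folded).
#'
#' @param gene_hits data.frame with a `gene_id` column (hits of one bin), or
#'   a character vector of identifiers.
#' @param panel a [read_marker_panel()] panel.
#' @param markers which markers to flag; default all in the panel. Referencing
#'   a marker absent from the panel is an error.
#' @return named logical vector.
#' @export
marker_presence <- function(gene_hits, panel, markers = NULL) {
  ids <- if (is.data.frame(gene_hits)) gene_hits$gene_id else gene_hits
  markers <- markers %||% names(panel$markers)
  unknown <- setdiff(markers, names(panel$markers))
  if (length(unknown)) stop_mc("unknown panel marker(s): ",
                               paste(unknown, collapse = ", "))
  vapply(panel$markers[markers], function(al) match_any(ids, al), logical(1))
}

#' Percent completeness of a pathway for one bin
#'
#' `100 * |members present| / |members defined|`; duplicate hits count once.
#'
#' @inheritParams marker_presence
#' @param pathway_definition character vector of member identifiers
#'   (non-empty).
#' @return percentage in `[0, 100]`.
#' @export
pathway_completeness <- function(gene_hits, pathway_definition) {
  if (length(pathway_definition) == 0L) stop_mc("empty pathway definition")
  ids <- if (is.data.frame(gene_hits)) gene_hits$gene_id else gene_hits
  present <- unique(tolower(pathway_definition)) %in% tolower(ids)
  100 * sum(present) / length(unique(tolower(pathway_definition)))
}

#' Build the per-bin metabolic profile table
#'
#' One row per bin with a logical presence column per marker and a numeric
#' percent-completeness column per pathway, in stable panel order.
#'
#' @param gene_hits data.frame with columns bin_id, gene_id.
#' @param panel a [read_marker_panel()] panel.
#' @param bins bins to report (default: those in `gene_hits`); bins with no
#'   hits get all-false / 0 rows.
#' @return data.frame, one row per bin.
#' @export
build_profile_table <- function(gene_hits, panel, bins = NULL) {
  bins <- sort(unique(bins %||% gene_hits$bin_id))
  rows <- lapply(bins, function(b) {
    ids <- gene_hits$gene_id[gene_hits$bin_id == b]
    flags <- marker_presence(ids, panel)
    pcts <- vapply(panel$pathways, function(p) pathway_completeness(ids, p),
                   numeric(1))
    cbind(data.frame(bin_id = b, stringsAsFactors = FALSE),
          as.data.frame(as.list(flags)),
          as.data.frame(as.list(pcts)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot the metabolic profile as a heat map
#'
#' Marker flags and pathway percentages on a common 0-100 grayscale, in the
#' style of per-genome metabolic summary figures. Requires the `pheatmap`
#' package.
#'
#' @param profile a [build_profile_table()] data.frame.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_metabolic_profile <- function(profile, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop_mc("plot_metabolic_profile requires the 'pheatmap' package")
  }
  m <- as.matrix(data.frame(lapply(profile[, -1, drop = FALSE], as.numeric),
                            check.names = FALSE))
  m[, vapply(profile[, -1, drop = FALSE], is.logical, logical(1))] <-
    m[, vapply(profile[, -1, drop = FALSE], is.logical, logical(1))] * 100
  rownames(m) <- profile$bin_id
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = grDevices::gray.colors(100, start = 1, end = 0), ...)
}
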