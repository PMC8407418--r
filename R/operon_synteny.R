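# Gene-order synteny of candidate cyo operon clusters against a reference.
#
# Order conservation is scored as longest-common-subsequence (LCS) over gene
# labels against the reference order — the comparison is a gene-order
# diagram, not a sequence alignment. Classes:
#   identical               full reference order, no insertions
#   identical_with_insertion full reference order with unlabeled ORF(s) inside
#   partial                 a proper ordered subset, relative order preserved
#   rearranged              >= 2 shared labels whose relative order disagrees
#   fragmented              reference labels split across clusters (genome level)
#   absent                  no reference labels

#' Define a reference operon model
#'
#' @param genes ordered reference gene labels; default the E. coli K-12
#'   cytochrome bo3 ubiquinol oxidase operon cyoA, cyoB, cyoC, cyoD, cyoE.
#' @param max_intergenic_gap_bp maximum gap between successive genes for them
#'   to be chained into one cluster (default 500 bp).
#' @return an object of class `operon_model`.
#' @export
operon_model <- function(genes = c("cyoA", "cyoB", "cyoC", "cyoD", "cyoE"),
                         max_intergenic_gap_bp = 500) {
  if (length(genes) == 0L) stop_mc("reference gene list must be non-empty")
  if (anyDuplicated(genes)) stop_mc("reference gene labels must be unique")
  structure(list(genes = genes,
                 max_intergenic_gap_bp = max_intergenic_gap_bp),
            class = "operon_model")
}

# longest common subsequence length, dynamic programming
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Extract candidate operon clusters from gene annotations
#'
#' Groups same-scaffold genes that carry a model label, or that lie between
#' two model genes, chaining neighbors whose intergenic gap is at most the
#' model's `max_intergenic_gap_bp`. Minus-strand clusters are reported in
#' transcriptional order (coordinate order reversed).
#'
#' @param annotations data.frame with columns scaffold, start, end
#'   (1-based inclusive), strand (`"+"`/`"-"`), label (non-model genes may
#'   carry any label, conventionally `"ORF"`).
#' @param model an [operon_model()].
#' @return list of clusters; each a data.frame of the member annotations in
#'   transcriptional order with attributes `"scaffold"` and
#'   `"strand_consistent"`.
#' @export
extract_clusters <- function(annotations, model) {
  needed <- c("scaffold", "start", "end", "strand", "label")
  if (!all(needed %in% names(annotations))) {
    stop_mc("annotations need columns: ", paste(needed, collapse = ", "))
  }
  key <- paste(annotations$scaffold, annotations$start, annotations$end,
               annotations$label)
  if (anyDuplicated(key)) {
    stop_mc("overlapping duplicate annotation with identical label and span: ",
            key[duplicated(key)][1])
  }
  clusters <- list()
  for (sc in unique(annotations$scaffold)) {
    a <- annotations[annotations$scaffold == sc, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    gap <- c(Inf, a$start[-1] - a$end[-nrow(a)] - 1)
    chain_id <- cumsum(gap > model$max_intergenic_gap_bp)
    for (ch in split(a, chain_id)) {
      in_model <- which(ch$label %in% model$genes)
      if (length(in_model) == 0L) next
      cl <- ch[min(in_model):max(in_model), , drop = FALSE]
      strands <- cl$strand[cl$label %in% model$genes]
      if (sum(strands == "-") > sum(strands == "+")) {
        cl <- cl[rev(seq_len(nrow(cl))), , drop = FALSE]
      }
      rownames(cl) <- NULL
      attr(cl, "scaffold") <- sc
      attr(cl, "strand_consistent") <- length(unique(cl$strand)) == 1L
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  clusters
}

#' Classify one cluster against the reference operon
#'
#' @param cluster a cluster from [extract_clusters()] (annotations in
#'   transcriptional order).
#' @param model an [operon_model()].
#' @return one-row data.frame: scaffold_id, classification, order_score,
#'   n_insertions, n_model_genes, strand_consistent.
#' @export
classify_cluster <- function(cluster, model) {
  if (is.null(cluster) || nrow(cluster) == 0L) stop_mc("empty cluster")
  ref <- model$genes
  labels <- cluster$label
  labeled <- labels[labels %in% ref]
  n_ins <- sum(!labels %in% ref)
  lcs <- lcs_length(labeled, ref)
  # multiset overlap between cluster labels and the reference
  shared <- sum(pmin(table(factor(labeled, levels = ref)), 1L))
  classification <- if (length(labeled) == 0L) {
    "absent"
  } else if (identical(labeled, ref)) {
    if (n_ins == 0L) "identical" else "identical_with_insertion"
  } else if (shared >= 2L && lcs < shared) {
    "rearranged"
  } else {
    "partial"
  }
  data.frame(
    scaffold_id = attr(cluster, "scaffold") %||% cluster$scaffold[1],
    classification = classification,
    order_score = lcs / length(ref),
    n_insertions = n_ins,
    n_model_genes = length(labeled),
    strand_consistent = isTRUE(attr(cluster, "strand_consistent")),
    stringsAsFactors = FALSE
  )
}

#' Classify operon synteny across a genome's annotations
#'
#' Runs [extract_clusters()] and [classify_cluster()], then applies the
#' genome-level rule: when the reference labels are split across two or more
#' clusters (each holding a proper, order-consistent subset and jointly
#' covering more of the reference than any single cluster), the genome is
#' classified `fragmented`.
#'
#' @inheritParams extract_clusters
#' @return list with `clusters` (data.frame of per-cluster comparisons) and
#'   `genome_class` (single classification string; `"absent"` when no model
#'   genes occur).
#' @export
classify_synteny <- function(annotations, model = operon_model()) {
  cls <- extract_clusters(annotations, model)
  if (length(cls) == 0L) {
    return(list(clusters = data.frame(), genome_class = "absent"))
  }
  rows <- do.call(rbind, lapply(cls, classify_cluster, model = model))
  genome_class <- if (nrow(rows) == 1L) {
    rows$classification
  } else {
    per_cluster_labels <- lapply(cls, function(cl) {
      unique(cl$label[cl$label %in% model$genes])
    })
    combined <- unique(unlist(per_cluster_labels))
    split_cover <- length(combined) > max(lengths(per_cluster_labels))
    if (split_cover && all(rows$classification %in% c("partial", "identical")))
      "fragmented"
    else
      rows$classification[which.max(rows$order_score)]
  }
  list(clusters = rows, genome_class = genome_class)
}

#' Render a one-line text synteny diagram of a cluster
#'
#' @param cluster a cluster from [extract_clusters()].
#' @return character scalar, genes joined in transcriptional order.
#' @export
format_synteny <- function(cluster) {
  paste0(attr(cluster, "scaffold") %||% cluster$scaffold[1], ": ",
         paste(cluster$label, collapse = " > "))
}

# default synonym table: product strings -> cyo labels
CYO_SYNONYMS <- c(
  "cytochrome o ubiquinol oxidase subunit ii" = "cyoA",
  "cytochrome o ubiquinol oxidase subunit i" = "cyoB",
  "cytochrome o ubiquinol oxidase subunit iii" = "cyoC",
  "cytochrome o ubiquinol oxidase subunit iv" = "cyoD",
  "protoheme ix farnesyltransferase" = "cyoE",
  "heme o synthase" = "cyoE"
)

#' Read gene annotations from GFF3
#'
#' Labels are taken from the `gene=` attribute when present, otherwise the
#' `product=` attribute is mapped through a synonym table (long product names
#' to short labels, matched case-insensitively); anything unmapped is labeled
#' `"ORF"`.
#'
#' @param path GFF3 file (1-based inclusive coordinates; strand column
#'   honored).
#' @param synonyms named character vector mapping lower-cased product strings
#'   to labels; defaults to a cytochrome-o-ubiquinol-oxidase table.
#' @return data.frame: scaffold, start, end, strand, label.
#' @export
read_gff3_annotations <- function(path, synonyms = CYO_SYNONYMS) {
  if (!file.exists(path)) stop_mc("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 9L)
  if (length(bad)) stop_mc("malformed GFF3 line ", bad[1], " in ", path)
  attr_field <- vapply(f, `[[`, "", 9L)
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  gene <- get_attr(attr_field, "gene")
  product <- get_attr(attr_field, "product")
  label <- ifelse(!is.na(gene), gene,
                  ifelse(!is.na(product) & tolower(product) %in% names(synonyms),
                         unname(synonyms[tolower(product)]), "ORF"))
  data.frame(
    scaffold = vapply(f, `[[`, "", 1L),
    start = as.numeric(vapply(f, `[[`, "", 4L)),
    end = as.numeric(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    label = label,
    stringsAsFactors = FALSE
  )
}
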