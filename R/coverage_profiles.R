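# Per-scaffold depth/breadth profiles and relative-abundance tables.
#
# Depth inputs follow the samtools-depth convention: tab-separated
# scaffold / 1-based position / depth, with or without zero-depth rows.
# Scaffold lengths must come from a lengths TSV or FASTA: a depth file alone
# cannot distinguish a short scaffold from an uncovered tail.

#' Read a samtools-depth-style TSV
#'
#' Accepts both dialects: with or without rows for zero-depth positions, with
#' or without a header line.
#'
#' @param path depth TSV (columns: scaffold, 1-based position, depth).
#' @return data.frame with columns scaffold, pos, depth.
#' @export
read_depth_tsv <- function(path) {
  if (!file.exists(path)) stop_mc("depth file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = "auto")
  if (ncol(dt) < 3L) stop_mc("depth TSV must have >= 3 columns: ", path)
  dt <- dt[, 1:3]
  data.table::setnames(dt, c("scaffold", "pos", "depth"))
  as.data.frame(dt)
}

#' Read scaffold lengths from a TSV or FASTA
#'
#' @param path either a two-column TSV (scaffold, length_bp) or a FASTA file
#'   (extension .fa/.fasta/.fna), from which sequence lengths are taken.
#' @return named numeric vector scaffold -> length.
#' @export
read_lengths <- function(path) {
  if (!file.exists(path)) stop_mc("lengths file not found: ", path)
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.numeric(Biostrings::width(seqs)),
                           sub("\\s.*$", "", names(seqs))))
  }
  tab <- read_tsv_mc(path)
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

profile_from_depths <- function(depths, scaffold_id, sample_id,
                                breadth_min_depth = 1L) {
  L <- length(depths)
  data.frame(
    scaffold_id = scaffold_id,
    sample_id = sample_id,
    length_bp = as.numeric(L),
    mean_depth = sum(as.numeric(depths)) / L,
    breadth = sum(depths >= breadth_min_depth) / L,
    stringsAsFactors = FALSE
  )
}

#' Profile one scaffold from depth records
#'
#' Mean depth averages over all positions of the scaffold (positions absent
#' from the records count as depth 0); breadth is the fraction of positions
#' with depth at or above `breadth_min_depth`. The result is invariant to
#' record order and to whether zero-depth positions are listed or omitted.
#'
#' @param depth_records data.frame with columns scaffold, pos (1-based),
#'   depth, or `NULL` for a fully uncovered scaffold.
#' @param scaffold_id scaffold to profile (other scaffolds' rows are ignored).
#' @param length_bp scaffold length (bp, > 0); authoritative for the position
#'   range.
#' @param sample_id sample label attached to the profile.
#' @param breadth_min_depth minimum depth for a position to count as covered
#'   (default 1: any coverage counts).
#' @return one-row data.frame: scaffold_id, sample_id, length_bp, mean_depth,
#'   breadth.
#' @export
profile_scaffold <- function(depth_records, scaffold_id, length_bp,
                             sample_id = "sample", breadth_min_depth = 1L) {
  if (!is_count(length_bp) || length_bp < 1) stop_mc("length_bp must be a positive count")
  if (is.null(depth_records) || nrow(depth_records) == 0L) {
    return(profile_from_depths(integer(length_bp), scaffold_id, sample_id,
                               breadth_min_depth))
  }
  rec <- depth_records[depth_records$scaffold == scaffold_id, , drop = FALSE]
  if (any(rec$pos < 1 | rec$pos > length_bp)) {
    bad <- rec$pos[rec$pos < 1 | rec$pos > length_bp][1]
    stop_mc("position ", bad, " outside scaffold '", scaffold_id,
            "' (length ", length_bp, ")")
  }
  if (anyDuplicated(rec$pos)) {
    stop_mc("duplicate position ", rec$pos[duplicated(rec$pos)][1],
            " for scaffold '", scaffold_id, "'")
  }
  depths <- integer(length_bp)
  depths[rec$pos] <- rec$depth
  profile_from_depths(depths, scaffold_id, sample_id, breadth_min_depth)
}

#' Profile every scaffold of a sample
#'
#' @inheritParams profile_scaffold
#' @param lengths named vector scaffold -> length (bp); defines the scaffold
#'   universe — scaffolds with no depth rows get zero profiles.
#' @return data.frame of per-scaffold profiles.
#' @export
profile_sample <- function(depth_records, lengths, sample_id = "sample",
                           breadth_min_depth = 1L) {
  unknown <- setdiff(unique(depth_records$scaffold), names(lengths))
  if (length(unknown)) {
    stop_mc("depth records for scaffolds without lengths: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  do.call(rbind, lapply(names(lengths), function(sc) {
    profile_scaffold(depth_records, sc, lengths[[sc]], sample_id,
                     breadth_min_depth)
  }))
}

#' Profile in-memory depth vectors (simulator output)
#'
#' @param depth_vectors named list of integer depth vectors.
#' @inheritParams profile_scaffold
#' @return data.frame of per-scaffold profiles.
#' @export
profile_depth_vectors <- function(depth_vectors, sample_id = "sample",
                                  breadth_min_depth = 1L) {
  do.call(rbind, lapply(names(depth_vectors), function(sc) {
    profile_from_depths(depth_vectors[[sc]], sc, sample_id, breadth_min_depth)
  }))
}

#' Relative abundance of scaffolds within one sample
#'
#' Base-fraction flavor: `depth * length / sum(depth * length)` — the share of
#' sequenced bases attributable to each scaffold. If every scaffold has zero
#' depth the abundances are undefined and returned as `NA` with
#' `undefined = TRUE`, never as 0/0.
#'
#' @param profiles per-scaffold profiles for a single sample.
#' @return data.frame: scaffold_id, sample_id, base_fraction, undefined.
#' @export
relative_abundance <- function(profiles) {
  if (nrow(profiles) < 1L) stop_mc("need at least one profile")
  if (length(unique(profiles$sample_id)) != 1L) {
    stop_mc("profiles mix samples: ",
            paste(unique(profiles$sample_id), collapse = ", "))
  }
  bases <- profiles$mean_depth * profiles$length_bp
  tot <- sum(bases)
  undefined <- tot <= 0
  data.frame(
    scaffold_id = profiles$scaffold_id,
    sample_id = profiles$sample_id,
    base_fraction = if (undefined) NA_real_ else bases / tot,
    undefined = undefined,
    stringsAsFactors = FALSE
  )
}

#' Aggregate scaffold profiles to genome bins
#'
#' Bin mean depth is the length-weighted mean of scaffold depths
#' (`sum(depth_i * L_i) / sum(L_i)`); bin breadth is total covered bases over
#' total length. Two abundance flavors are attached: `base_fraction`
#' (share of sequenced bases) and `cell_fraction` (bin mean depth over the sum
#' of bin mean depths — depth is proportional to cell count, so this is the
#' organism-level abundance the census consumes).
#'
#' @param profiles per-scaffold profiles for one sample.
#' @param bin_membership data.frame with columns scaffold, bin_id; a scaffold
#'   assigned to two bins is an error. Scaffolds in the membership but absent
#'   from the profiles are treated as zero-depth, in which case the membership
#'   must carry a `length_bp` column for them.
#' @return data.frame: bin_id, sample_id, length_bp, mean_depth, breadth,
#'   base_fraction, cell_fraction.
#' @export
aggregate_bins <- function(profiles, bin_membership) {
  if (anyDuplicated(bin_membership$scaffold)) {
    dup <- bin_membership$scaffold[duplicated(bin_membership$scaffold)][1]
    stop_mc("scaffold '", dup, "' assigned to more than one bin")
  }
  if (length(unique(profiles$sample_id)) != 1L) stop_mc("profiles mix samples")
  sample_id <- profiles$sample_id[1]
  missing <- setdiff(bin_membership$scaffold, profiles$scaffold_id)
  if (length(missing)) {
    if (!"length_bp" %in% names(bin_membership)) {
      stop_mc("scaffolds without profiles need a length_bp column in the ",
              "membership: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    extra <- bin_membership[bin_membership$scaffold %in% missing, ]
    zero <- data.frame(scaffold_id = extra$scaffold, sample_id = sample_id,
                       length_bp = as.numeric(extra$length_bp),
                       mean_depth = 0, breadth = 0, stringsAsFactors = FALSE)
    profiles <- rbind(profiles[, names(zero)], zero)
  }
  m <- merge(profiles, bin_membership[, c("scaffold", "bin_id")],
             by.x = "scaffold_id", by.y = "scaffold")
  dt <- data.table::as.data.table(m)
  length_bp <- mean_depth <- breadth <- NULL  # data.table NSE
  agg <- dt[, list(
    length_bp = sum(length_bp),
    mean_depth = sum(mean_depth * length_bp) / sum(length_bp),
    breadth = sum(breadth * length_bp) / sum(length_bp)
  ), by = "bin_id"]
  agg <- as.data.frame(agg)[order(as.data.frame(agg)$bin_id), ]
  agg$sample_id <- sample_id
  bases <- agg$mean_depth * agg$length_bp
  depth_tot <- sum(agg$mean_depth)
  agg$base_fraction <- if (sum(bases) > 0) bases / sum(bases) else NA_real_
  agg$cell_fraction <- if (depth_tot > 0) agg$mean_depth / depth_tot else NA_real_
  rownames(agg) <- NULL
  agg[, c("bin_id", "sample_id", "length_bp", "mean_depth", "breadth",
          "base_fraction", "cell_fraction")]
}
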