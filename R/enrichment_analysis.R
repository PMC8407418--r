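# Concentrate-over-bulk enrichment factors with detection-limit handling.
#
# Ultrasmall genomes are typically absent or at trace coverage in the bulk
# sample, so zero bulk abundance is the common case, not an edge case. It is
# handled by an explicit one-read detection floor and a lower-bound flag,
# never by a silent pseudocount.

#' Enrichment factor of concentrate over bulk relative abundance
#'
#' `E = ra_concentrate / ra_bulk` when the unit is detected in the bulk
#' sample. When `ra_bulk` is exactly 0 the ratio is undefined; the abundance
#' is replaced by `detection_floor` (the smallest abundance the bulk sample
#' could have registered) and `E` is reported as a lower bound with
#' `bulk_below_detection = TRUE`.
#'
#' @param ra_concentrate,ra_bulk relative abundances in `[0, 1]` (vectors
#'   recycle to common length).
#' @param detection_floor positive abundance floor used when `ra_bulk == 0`;
#'   see [default_detection_floor()]. May be `NULL` if no bulk abundance is 0.
#' @param unit_id optional unit labels for the result.
#' @return data.frame: unit_id, ra_bulk, ra_concentrate, E,
#'   bulk_below_detection, floor_used.
#' @export
enrichment_factor <- function(ra_concentrate, ra_bulk, detection_floor = NULL,
                              unit_id = NULL) {
  n <- max(length(ra_concentrate), length(ra_bulk))
  ra_concentrate <- rep_len(ra_concentrate, n)
  ra_bulk <- rep_len(ra_bulk, n)
  unit_id <- unit_id %||% as.character(seq_len(n))
  if (any(ra_concentrate < 0 | ra_concentrate > 1 | ra_bulk < 0 | ra_bulk > 1,
          na.rm = TRUE)) {
    stop_mc("relative abundances must lie in [0, 1]")
  }
  both_zero <- ra_concentrate == 0 & ra_bulk == 0
  if (any(both_zero)) {
    stop_mc("enrichment undefined (both abundances 0) for unit(s): ",
            paste(utils::head(unit_id[both_zero], 5), collapse = ", "))
  }
  below <- ra_bulk == 0
  if (any(below)) {
    if (is.null(detection_floor)) {
      stop_mc("ra_bulk is 0 for unit(s) ",
              paste(utils::head(unit_id[below], 5), collapse = ", "),
              " but no detection_floor was given")
    }
    if (detection_floor <= 0) stop_mc("detection_floor must be > 0")
  }
  E <- ifelse(below, ra_concentrate / (detection_floor %||% NA_real_),
              ra_concentrate / ra_bulk)
  data.frame(
    unit_id = unit_id,
    ra_bulk = ra_bulk,
    ra_concentrate = ra_concentrate,
    E = E,
    bulk_below_detection = below,
    floor_used = ifelse(below, detection_floor %||% NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' One-read detection floor for a bulk sample
#'
#' The smallest relative abundance the bulk sample could have registered: the
#' base fraction contributed by a single read,
#' `read_length / total_mapped_bases_bulk`. Monotone decreasing in sequencing
#' effort.
#'
#' @param total_mapped_bases_bulk total mapped bases in the bulk sample (> 0).
#' @param read_length read length in bp (> 0).
#' @return detection floor as a fraction.
#' @export
default_detection_floor <- function(total_mapped_bases_bulk, read_length) {
  if (!is_scalar_num(total_mapped_bases_bulk) || total_mapped_bases_bulk <= 0) {
    stop_mc("total_mapped_bases_bulk must be > 0")
  }
  if (!is_scalar_num(read_length) || read_length <= 0) {
    stop_mc("read_length must be > 0")
  }
  read_length / total_mapped_bases_bulk
}

#' Summarize per-scaffold enrichment within bins
#'
#' Median and quartiles are computed over finite (detected-in-bulk) E values
#' only; lower-bound results are counted separately and never averaged in.
#' Bins whose every scaffold is below the bulk detection limit are flagged
#' `lower_bound_only`.
#'
#' @param results an [enrichment_factor()] data.frame.
#' @param bin_of optional named vector unit_id -> bin_id; by default every
#'   unit is its own bin.
#' @return data.frame: bin_id, n, n_lower_bound, median_E, q1_E, q3_E,
#'   lower_bound_only.
#' @export
summarize_enrichment <- function(results, bin_of = NULL) {
  if (nrow(results) < 1L) stop_mc("need at least one enrichment result")
  bins <- if (is.null(bin_of)) results$unit_id else unname(bin_of[results$unit_id])
  if (anyNA(bins)) stop_mc("bin_of is missing entries for some unit_ids")
  split_idx <- split(seq_len(nrow(results)), bins)
  out <- lapply(names(split_idx), function(b) {
    r <- results[split_idx[[b]], ]
    fin <- r$E[!r$bulk_below_detection]
    lbo <- length(fin) == 0L
    qs <- if (lbo) rep(NA_real_, 3) else stats::quantile(fin, c(.25, .5, .75),
                                                         names = FALSE, type = 7)
    data.frame(bin_id = b, n = nrow(r),
               n_lower_bound = sum(r$bulk_below_detection),
               median_E = qs[2], q1_E = qs[1], q3_E = qs[3],
               lower_bound_only = lbo, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
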