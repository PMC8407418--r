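# In-silico PCR detectability of marker-gene sequences.
#
# Matching rule: a primer IUPAC code matches any base in its expansion; an N
# in the subject matches nothing (counts as a mismatch); other subject
# ambiguity codes match iff the expansions intersect — deliberately
# conservative for detectability claims. A sequence is detectable by a pair
# iff a forward site and a correctly oriented (reverse-complement) reverse
# site occur with at most k mismatches each and a product length (inclusive
# of both primer footprints) inside the pair's range.

BASES <- c("A", "C", "G", "T")
BITS <- c(1L, 2L, 4L, 8L)

IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

# bit complement: A<->T, C<->G
comp_mask <- function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftL(bitwAnd(m, 2L), 1L)),
         bitwOr(bitwShiftR(bitwAnd(m, 4L), 1L), bitwShiftR(bitwAnd(m, 8L), 3L)))
}

iupac_masks <- function(x, role = c("primer", "subject")) {
  role <- match.arg(role)
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% names(IUPAC_MASK))
  if (length(bad)) {
    stop_mc("invalid character '", chars[bad[1]], "' at offset ", bad[1],
            " in sequence")
  }
  m <- unname(IUPAC_MASK[chars])
  if (role == "subject") m[chars == "N"] <- 0L  # subject N matches nothing
  m
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# mismatch counts of a primer mask vector at every window start of a subject
# mask vector; O(primer length) vectorized passes
scan_mismatches <- function(subj_masks, primer_masks) {
  n <- length(subj_masks); m <- length(primer_masks)
  if (n < m) return(integer(0))
  mism <- integer(n - m + 1L)
  for (j in seq_len(m)) {
    mism <- mism + as.integer(bitwAnd(subj_masks[j:(n - m + j)],
                                      primer_masks[j]) == 0L)
  }
  mism
}

#' Define a primer pair
#'
#' @param name pair label.
#' @param forward,reverse primer sequences, IUPAC, written 5'->3'.
#' @param max_mismatches mismatch tolerance k per primer (default 0).
#' @param product_length_range `[min, max]` amplicon length in bp, both
#'   primer footprints included.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, max_mismatches = 0L,
                        product_length_range = c(100, 2000)) {
  if (!nzchar(forward) || !nzchar(reverse)) stop_mc("primers must be non-empty")
  iupac_masks(forward); iupac_masks(reverse)  # alphabet validation
  if (length(product_length_range) != 2L ||
      product_length_range[1] > product_length_range[2]) {
    stop_mc("product_length_range must be [min, max] with min <= max")
  }
  if (max_mismatches < 0) stop_mc("max_mismatches must be >= 0")
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches),
                 product_length_range = as.numeric(product_length_range)),
            class = "primer_pair")
}

#' Read primer pairs from a TSV
#'
#' Columns: name, forward, reverse, max_mismatches, min_product, max_product.
#' The packaged example file (`path = NULL`) carries widely used 16S rRNA
#' amplicon pairs (e.g. 515F/806R).
#'
#' @param path primer TSV, or `NULL` for the packaged examples.
#' @return list of [primer_pair()] objects.
#' @export
read_primer_pairs <- function(path = NULL) {
  path <- path %||% system.file("extdata", "primer_pairs.tsv",
                                package = "microcensus")
  tab <- read_tsv_mc(path)
  lapply(seq_len(nrow(tab)), function(i) {
    primer_pair(tab$name[i], tab$forward[i], tab$reverse[i],
                tab$max_mismatches[i], c(tab$min_product[i], tab$max_product[i]))
  })
}

#' Find primer binding sites on both strands
#'
#' Scans the subject for windows matching the primer with at most `k`
#' mismatches. Strand `"+"` hits are occurrences of the primer itself;
#' strand `"-"` hits are occurrences of its reverse complement (i.e. the
#' primer anneals to the minus strand). Positions are 1-based window starts
#' on the given sequence. Hits are sorted by (mismatches, position).
#'
#' @param sequence subject DNA (IUPAC allowed; N matches nothing).
#' @param primer primer sequence (IUPAC, 5'->3').
#' @param k mismatch tolerance.
#' @return data.frame: position, strand, mismatches.
#' @export
find_primer_sites <- function(sequence, primer, k = 0L) {
  subj <- iupac_masks(sequence, role = "subject")
  hits <- list()
  for (strand in c("+", "-")) {
    pm <- if (strand == "+") iupac_masks(primer)
          else rev(comp_mask(iupac_masks(primer)))
    mism <- scan_mismatches(subj, pm)
    ok <- which(mism <= k)
    if (length(ok)) {
      hits[[strand]] <- data.frame(position = ok, strand = strand,
                                   mismatches = mism[ok],
                                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(position = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$mismatches, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# plus-orientation amplification only: forward site on the plus strand with
# the reverse primer annealing to the minus strand downstream
assess_plus_orientation <- function(sequence, pair) {
  k <- pair$max_mismatches
  subj <- iupac_masks(sequence, role = "subject")
  fmask <- iupac_masks(pair$forward)
  rmask <- rev(comp_mask(iupac_masks(pair$reverse)))  # revcomp occurrence
  fm <- scan_mismatches(subj, fmask)
  rm_ <- scan_mismatches(subj, rmask)
  fpos <- which(fm <= k); rpos <- which(rm_ <= k)
  best <- NULL
  m_r <- length(rmask)
  for (i in fpos) {
    for (j in rpos) {
      prod_len <- j + m_r - i
      if (j >= i && prod_len >= pair$product_length_range[1] &&
          prod_len <= pair$product_length_range[2]) {
        tot <- fm[i] + rm_[j]
        if (is.null(best) || tot < best$total_mismatches) {
          best <- list(forward_position = i, forward_mismatches = fm[i],
                       reverse_position = j, reverse_mismatches = rm_[j],
                       product_length = prod_len, total_mismatches = tot)
        }
      }
    }
  }
  best
}

#' Assess amplicon detectability of one sequence
#'
#' Detectable iff some forward site and some reverse-complement-correct
#' reverse site occur in amplifiable orientation with a product length inside
#' the pair's range and at most `k` mismatches per primer. Both template
#' orientations are considered, so detectability is invariant under
#' reverse-complementing the sequence. The minimal-total-mismatch qualifying
#' site pair is reported.
#'
#' @param sequence template DNA.
#' @param pair a [primer_pair()].
#' @param sequence_id optional label.
#' @return one-row data.frame: sequence_id, detectable, forward_position,
#'   forward_mismatches, reverse_position, reverse_mismatches,
#'   product_length.
#' @export
assess_detectability <- function(sequence, pair, sequence_id = "seq") {
  b1 <- assess_plus_orientation(sequence, pair)
  b2 <- assess_plus_orientation(revcomp_dna(sequence), pair)
  best <- if (is.null(b1)) b2 else if (is.null(b2)) b1 else
    if (b2$total_mismatches < b1$total_mismatches) b2 else b1
  if (is.null(best)) {
    return(data.frame(sequence_id = sequence_id, detectable = FALSE,
                      forward_position = NA_integer_,
                      forward_mismatches = NA_integer_,
                      reverse_position = NA_integer_,
                      reverse_mismatches = NA_integer_,
                      product_length = NA_integer_, stringsAsFactors = FALSE))
  }
  data.frame(sequence_id = sequence_id, detectable = TRUE,
             forward_position = best$forward_position,
             forward_mismatches = best$forward_mismatches,
             reverse_position = best$reverse_position,
             reverse_mismatches = best$reverse_mismatches,
             product_length = best$product_length, stringsAsFactors = FALSE)
}

#' Screen a set of sequences against a primer pair
#'
#' @param sequences named character vector of DNA sequences.
#' @param pair a [primer_pair()].
#' @return data.frame with one [assess_detectability()] row per sequence.
#' @export
screen_sequences <- function(sequences, pair) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  out <- do.call(rbind, Map(assess_detectability, sequences,
                            MoreArgs = list(pair = pair), sequence_id = ids))
  rownames(out) <- NULL
  out
}

#' Summarize detectability over a sequence set
#'
#' @param records a [screen_sequences()] data.frame.
#' @return list: n_sequences, n_detectable, n_undetectable,
#'   fraction_undetectable.
#' @export
summarize_detectability <- function(records) {
  if (nrow(records) < 1L) stop_mc("need at least one detectability record")
  n <- nrow(records)
  nd <- sum(!records$detectable)
  list(n_sequences = n, n_detectable = n - nd, n_undetectable = nd,
       fraction_undetectable = nd / n)
}
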