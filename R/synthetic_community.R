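# Synthetic paired bulk/concentrate communities with known ground truth.
#
# The simulator emulates the rare-biosphere structure the downstream analysis
# assumes: a community of genomes with log-normal cell abundances, a designated
# "ultrasmall" subset that is rare in the bulk sample (rarity-down-weighted so
# sub-1x bulk depth is reachable) and boosted 100-1000-fold in relative
# abundance in the concentrate sample, and independent per-base Poisson
# coverage (the Lander-Waterman regime, expected breadth 1 - exp(-c)).

#' Specify a synthetic community
#'
#' Builds a validated specification for [build_community()]. Cell abundances
#' are drawn log-normal; `n_ultrasmall` genomes are flagged as ultrasmall,
#' down-weighted in the bulk sample by `ultrasmall_rarity`, and planted with a
#' per-genome fold-enrichment drawn uniformly from `enrichment_range`.
#'
#' In the concentrate sample the unnormalized mass of an ultrasmall genome is
#' its bulk cell fraction times its planted enrichment; every other genome's
#' mass is its bulk fraction times `concentrate_capture_of_large` (the fraction
#' of large-cell material passing the 0.2-micron filtration; 0 means perfect
#' size exclusion). Masses are renormalized to cell fractions. With carryover
#' near 1 the concentrate stays dominated by background DNA and the realized
#' relative-abundance enrichment equals the planted fold-change; with perfect
#' exclusion the concentrate contains only ultrasmall genomes and the realized
#' enrichment is far larger than the planted factor (both are recorded in the
#' truth table).
#'
#' @param n_genomes number of genomes in the community.
#' @param genome_length_bp length-2 numeric, uniform range for genome lengths
#'   (bp). Ultrasmall genomes are scaled by `ultrasmall_length_scale`.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma log-normal
#'   parameters for cell abundances (`sigma > 0`).
#' @param n_ultrasmall number of ultrasmall genomes (`<= n_genomes`).
#' @param enrichment_range length-2 numeric `[low, high]`, planted
#'   concentrate-over-bulk fold-enrichment range; `1 <= low <= high`.
#' @param seq_bases_bulk,seq_bases_concentrate sequencing effort per sample (bp).
#' @param concentrate_capture_of_large fraction in `[0, 1]` of non-ultrasmall
#'   cell material retained in the concentrate.
#' @param ultrasmall_rarity multiplicative down-weight applied to ultrasmall
#'   bulk abundances before normalization (default `1e-4`).
#' @param ultrasmall_length_scale length scale for ultrasmall genomes relative
#'   to the `genome_length_bp` draw (default 0.3).
#' @param seed integer master seed; every stochastic draw derives from it.
#' @return an object of class `community_spec`.
#' @seealso [build_community()]
#' @export
community_spec <- function(n_genomes = 50,
                           genome_length_bp = c(5e4, 1.5e5),
                           abundance_lognormal_mu = 0,
                           abundance_lognormal_sigma = 1,
                           n_ultrasmall = 5,
                           enrichment_range = c(100, 1000),
                           seq_bases_bulk = 2e9,
                           seq_bases_concentrate = 2e9,
                           concentrate_capture_of_large = 0,
                           ultrasmall_rarity = 1e-4,
                           ultrasmall_length_scale = 0.3,
                           seed = 1L) {
  if (!is_count(n_genomes) || n_genomes < 1) stop_mc("n_genomes must be a positive count")
  if (!is_count(n_ultrasmall)) stop_mc("n_ultrasmall must be a count")
  if (n_ultrasmall > n_genomes) {
    stop_mc("invalid spec: n_ultrasmall (", n_ultrasmall,
            ") exceeds n_genomes (", n_genomes, ")")
  }
  if (length(genome_length_bp) != 2L || any(genome_length_bp <= 0) ||
      genome_length_bp[1] > genome_length_bp[2]) {
    stop_mc("genome_length_bp must be a positive [min, max] range")
  }
  if (!is_scalar_num(abundance_lognormal_sigma) || abundance_lognormal_sigma <= 0) {
    stop_mc("abundance_lognormal_sigma must be > 0")
  }
  if (length(enrichment_range) != 2L || enrichment_range[1] < 1 ||
      enrichment_range[1] > enrichment_range[2]) {
    stop_mc("enrichment_range must satisfy 1 <= low <= high")
  }
  if (seq_bases_bulk <= 0 || seq_bases_concentrate <= 0) {
    stop_mc("sequencing effort must be > 0")
  }
  if (concentrate_capture_of_large < 0 || concentrate_capture_of_large > 1) {
    stop_mc("concentrate_capture_of_large must be in [0, 1]")
  }
  if (ultrasmall_rarity <= 0 || ultrasmall_rarity > 1) {
    stop_mc("ultrasmall_rarity must be in (0, 1]")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    genome_length_bp = as.numeric(genome_length_bp),
    abundance_lognormal_mu = abundance_lognormal_mu,
    abundance_lognormal_sigma = abundance_lognormal_sigma,
    n_ultrasmall = as.integer(n_ultrasmall),
    enrichment_range = as.numeric(enrichment_range),
    seq_bases_bulk = as.numeric(seq_bases_bulk),
    seq_bases_concentrate = as.numeric(seq_bases_concentrate),
    concentrate_capture_of_large = concentrate_capture_of_large,
    ultrasmall_rarity = ultrasmall_rarity,
    ultrasmall_length_scale = ultrasmall_length_scale,
    seed = as.integer(seed)
  ), class = "community_spec")
}

#' Build a community with known ground truth
#'
#' Draws genome lengths and log-normal cell abundances under the spec's seed,
#' down-weights the ultrasmall subset in the bulk sample, plants per-genome
#' fold-enrichments, and derives renormalized concentrate cell fractions.
#' Deterministic under a fixed seed.
#'
#' @param spec a [community_spec()].
#' @return an object of class `community`: list with `genomes` (data.frame
#'   with per-genome truth: lengths, bulk/concentrate cell fractions, planted
#'   and realized enrichment) and the `spec`.
#' @export
build_community <- function(spec) {
  if (!inherits(spec, "community_spec")) stop_mc("spec must be a community_spec")
  genomes <- with_seed_mc(spec$seed, {
    n <- spec$n_genomes
    len <- round(stats::runif(n, spec$genome_length_bp[1], spec$genome_length_bp[2]))
    ab <- stats::rlnorm(n, spec$abundance_lognormal_mu, spec$abundance_lognormal_sigma)
    small <- rep(FALSE, n)
    if (spec$n_ultrasmall > 0) small[sample.int(n, spec$n_ultrasmall)] <- TRUE
    len[small] <- pmax(1, round(len[small] * spec$ultrasmall_length_scale))
    ab[small] <- ab[small] * spec$ultrasmall_rarity
    enr <- rep(NA_real_, n)
    enr[small] <- stats::runif(spec$n_ultrasmall,
                               spec$enrichment_range[1], spec$enrichment_range[2])
    data.frame(
      genome_id = sprintf("genome_%03d", seq_len(n)),
      length_bp = as.numeric(len),
      is_ultrasmall = small,
      cell_fraction_bulk = ab / sum(ab),
      planted_enrichment = enr,
      stringsAsFactors = FALSE
    )
  })
  mass <- ifelse(genomes$is_ultrasmall,
                 genomes$cell_fraction_bulk * genomes$planted_enrichment,
                 genomes$cell_fraction_bulk * spec$concentrate_capture_of_large)
  if (sum(mass) <= 0) stop_mc("concentrate sample has zero total mass; ",
                              "need n_ultrasmall > 0 or capture > 0")
  genomes$cell_fraction_concentrate <- mass / sum(mass)
  genomes$realized_enrichment <-
    genomes$cell_fraction_concentrate / genomes$cell_fraction_bulk
  structure(list(genomes = genomes, spec = spec), class = "community")
}

#' @export
print.community <- function(x, ...) {
  g <- x$genomes
  cat("Synthetic community:", nrow(g), "genomes,",
      sum(g$is_ultrasmall), "ultrasmall\n")
  cat(sprintf("  bulk cell fraction (ultrasmall): %.3g-%.3g\n",
              min(g$cell_fraction_bulk[g$is_ultrasmall]),
              max(g$cell_fraction_bulk[g$is_ultrasmall])))
  cat(sprintf("  planted enrichment: %.1f-%.1f fold\n",
              min(g$planted_enrichment, na.rm = TRUE),
              max(g$planted_enrichment, na.rm = TRUE)))
  invisible(x)
}

#' Expected per-genome sequencing depth in a sample
#'
#' Converts cell fractions into expected mean depths at a given sequencing
#' effort: `depth_g = p_g * seq_bases / sum_h(p_h * L_h)`, so that
#' `sum(depth_g * L_g) == seq_bases` exactly.
#'
#' @param community a [build_community()] result.
#' @param sample_id `"bulk"` or `"concentrate"`.
#' @param seq_bases total sequenced bases attributed to the sample; defaults to
#'   the spec's value for that sample.
#' @return named numeric vector of expected depths, one per genome.
#' @export
expected_depth <- function(community, sample_id, seq_bases = NULL) {
  if (!inherits(community, "community")) stop_mc("community must be a community")
  if (!sample_id %in% c("bulk", "concentrate")) {
    stop_mc("unknown sample_id: '", sample_id, "' (expected 'bulk' or 'concentrate')")
  }
  g <- community$genomes
  p <- switch(sample_id, bulk = g$cell_fraction_bulk,
              concentrate = g$cell_fraction_concentrate)
  seq_bases <- seq_bases %||% switch(sample_id,
                                     bulk = community$spec$seq_bases_bulk,
                                     concentrate = community$spec$seq_bases_concentrate)
  if (!is_scalar_num(seq_bases) || seq_bases <= 0) stop_mc("seq_bases must be > 0")
  stats::setNames(p * seq_bases / sum(p * g$length_bp), g$genome_id)
}

#' Sequencing effort needed to reach a target depth
#'
#' Solves [expected_depth()] for `seq_bases` so that the shallowest of the
#' selected genomes reaches `target_depth` in the given sample. Convenient for
#' setting up recovery experiments ("bulk 2x / concentrate 20x for planted
#' genomes").
#'
#' @inheritParams expected_depth
#' @param target_depth desired minimum expected depth (fold coverage).
#' @param genome_ids genomes the target applies to; default all ultrasmall.
#' @export
seq_bases_for_depth <- function(community, sample_id, target_depth,
                                genome_ids = NULL) {
  g <- community$genomes
  genome_ids <- genome_ids %||% g$genome_id[g$is_ultrasmall]
  d1 <- expected_depth(community, sample_id, seq_bases = 1)
  if (!all(genome_ids %in% names(d1))) stop_mc("unknown genome_ids")
  target_depth / min(d1[genome_ids])
}

#' Simulate a per-base depth profile
#'
#' Independent per-base Poisson draws at the expected depth (the
#' Lander-Waterman coverage model: expected breadth `1 - exp(-c)` at mean
#' depth `c`). Read placement is not simulated; the downstream analysis only
#' consumes depth and breadth statistics.
#'
#' @param length_bp scaffold length (bp).
#' @param expected_depth mean per-base depth (`>= 0`).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return integer vector of length `length_bp` (depth at positions 1..L).
#' @export
simulate_depth_profile <- function(length_bp, expected_depth, seed = NULL) {
  if (!is_count(length_bp) || length_bp < 1) stop_mc("length_bp must be a positive count")
  if (!is_scalar_num(expected_depth) || expected_depth < 0) {
    stop_mc("expected_depth must be >= 0")
  }
  draw <- function() stats::rpois(length_bp, expected_depth)
  if (is.null(seed)) draw() else with_seed_mc(seed, draw())
}

#' Simulate depth profiles for a whole sample
#'
#' One Poisson depth vector per genome at that genome's [expected_depth()].
#' Per-genome sub-seeds derive from `seed`, so the result is reproducible and
#' independent of genome order.
#'
#' @inheritParams expected_depth
#' @param seed master seed for the sample (defaults to the spec seed offset by
#'   sample).
#' @return named list of integer depth vectors.
#' @export
simulate_coverage <- function(community, sample_id, seq_bases = NULL, seed = NULL) {
  depths <- expected_depth(community, sample_id, seq_bases)
  seed <- seed %||% (community$spec$seed + match(sample_id, c("bulk", "concentrate")))
  subseeds <- derive_seeds(seed, length(depths))
  out <- lapply(seq_along(depths), function(i) {
    simulate_depth_profile(community$genomes$length_bp[i], depths[[i]],
                           seed = subseeds[i])
  })
  names(out) <- names(depths)
  out
}

# ---- planted 16S sequences -------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Plant a 16S-like sequence with controlled primer-site mismatches
#'
#' Emits a synthetic marker sequence containing the forward primer site and
#' the reverse-complemented reverse primer site in amplifiable orientation,
#' separated so the product has the requested length, with exactly
#' `mutate_forward_mismatches` substitutions planted inside the forward-primer
#' site (each substitution is chosen to violate the primer's IUPAC expansion
#' at that position, so it is a true mismatch). The truth flag records
#' detectability at the pair's mismatch threshold `k`.
#'
#' @param pair a [primer_pair()].
#' @param mutate_forward_mismatches number of substitutions to plant in the
#'   forward site (`<=` number of non-N primer positions).
#' @param product_length total amplicon length, both primer footprints
#'   included; must fit both primers and lie within the pair's product range
#'   for the planted truth to read "detectable".
#' @param flank_length bases of random sequence added on each side.
#' @param seed optional seed.
#' @return list with `sequence`, `detectable_truth`, `planted_mismatches`,
#'   `forward_start` (1-based), `product_length`.
#' @export
plant_16s <- function(pair, mutate_forward_mismatches = 0,
                      product_length = 292, flank_length = 50, seed = NULL) {
  stopifnot(inherits(pair, "primer_pair"))
  run <- function() {
    fwd <- pair$forward
    # realize the reverse-complemented reverse-primer site as concrete bases
    # (degenerate positions are drawn from the code's expansion)
    rev_masks <- rev(comp_mask(iupac_masks(pair$reverse)))
    rev_site <- paste(vapply(rev_masks, function(m) {
      sample(BASES[bitwAnd(m, BITS) > 0L], 1L)
    }, ""), collapse = "")
    m_f <- nchar(fwd)
    m_r <- nchar(rev_site)
    if (product_length < m_f + m_r) {
      stop_mc("product_length (", product_length, ") shorter than combined primer ",
              "footprints (", m_f + m_r, ")")
    }
    fwd_masks <- iupac_masks(fwd)
    mutable <- which(fwd_masks != 15L)  # N primer positions match any base
    if (mutate_forward_mismatches > length(mutable)) {
      stop_mc("cannot plant ", mutate_forward_mismatches, " mismatches: only ",
              length(mutable), " non-degenerate-universal primer positions")
    }
    # realize the forward site as concrete bases satisfying the primer
    site <- vapply(fwd_masks, function(m) sample(BASES[bitwAnd(m, BITS) > 0L], 1L), "")
    if (mutate_forward_mismatches > 0) {
      at <- sample(mutable, mutate_forward_mismatches)
      for (i in at) {
        bad <- BASES[bitwAnd(fwd_masks[i], BITS) == 0L]
        site[i] <- sample(bad, 1L)
      }
    }
    insert <- random_dna(product_length - m_f - m_r)
    seq <- paste0(random_dna(flank_length), paste(site, collapse = ""),
                  insert, rev_site, random_dna(flank_length))
    list(sequence = seq,
         detectable_truth = mutate_forward_mismatches <= pair$max_mismatches &&
           product_length >= pair$product_length_range[1] &&
           product_length <= pair$product_length_range[2],
         planted_mismatches = as.integer(mutate_forward_mismatches),
         forward_start = flank_length + 1L,
         product_length = as.integer(product_length))
  }
  if (is.null(seed)) run() else with_seed_mc(seed, run())
}

# ---- planted operon layouts ------------------------------------------------

# approximate E. coli K-12 cyo gene lengths (bp)
CYO_LENGTHS <- c(cyoA = 945, cyoB = 1992, cyoC = 615, cyoD = 330, cyoE = 891)

#' Plant a cyo-operon gene cluster in a chosen layout
#'
#' Emits ordered, strand-consistent gene annotations (1-based inclusive
#' coordinates, GFF3 convention) for a cytochrome ubiquinol oxidase operon:
#' \describe{
#'   \item{reference}{cyoA, cyoB, cyoC, cyoD, cyoE in order.}
#'   \item{inserted_orf}{the reference order with one unlabeled ORF inside.}
#'   \item{reordered}{a non-identity permutation of the five genes.}
#'   \item{fragmented}{the cluster split across two scaffolds.}
#'   \item{partial}{a proper prefix or suffix of the reference order.}
#' }
#'
#' @param layout one of `"reference"`, `"inserted_orf"`, `"reordered"`,
#'   `"fragmented"`, `"partial"`.
#' @param scaffold_id base scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param start_bp coordinate of the first gene.
#' @param gap_bp intergenic gap between successive genes.
#' @param seed optional seed (drives the permutation / split / prefix choice).
#' @return data.frame with columns scaffold, start, end, strand, label
#'   (unlabeled ORFs carry label `"ORF"`), plus attribute `"layout"`.
#' @export
plant_operon <- function(layout = c("reference", "inserted_orf", "reordered",
                                    "fragmented", "partial"),
                         scaffold_id = "scaffold_cyo", strand = "+",
                         start_bp = 1000, gap_bp = 60, seed = NULL) {
  layout <- match.arg(layout)
  run <- function() {
    ref <- names(CYO_LENGTHS)
    labels <- switch(layout,
      reference = ref,
      inserted_orf = append(ref, "ORF", after = sample(1:4, 1L)),
      reordered = {
        p <- ref
        while (identical(p, ref)) p <- sample(ref)
        p
      },
      fragmented = ref,
      partial = if (sample(c(TRUE, FALSE), 1L)) {
        ref[seq_len(sample(2:4, 1L))]
      } else {
        ref[(sample(2:4, 1L)):5]
      })
    lens <- ifelse(labels == "ORF", 450, CYO_LENGTHS[labels])
    starts <- start_bp + cumsum(c(0, head(lens + gap_bp, -1)))
    ann <- data.frame(
      scaffold = scaffold_id, start = starts, end = starts + lens - 1,
      strand = strand, label = labels, stringsAsFactors = FALSE
    )
    if (layout == "fragmented") {
      cut <- sample(2:4, 1L)
      ann$scaffold <- ifelse(seq_len(nrow(ann)) <= cut,
                             paste0(scaffold_id, "_frag1"),
                             paste0(scaffold_id, "_frag2"))
      # second fragment restarts its own coordinate system
      second <- ann$scaffold == paste0(scaffold_id, "_frag2")
      shift <- min(ann$start[second]) - start_bp
      ann$start[second] <- ann$start[second] - shift
      ann$end[second] <- ann$end[second] - shift
    }
    if (strand == "-") {
      # on the minus strand transcriptional order is right-to-left: flip the
      # coordinates within each scaffold so the label order is preserved
      for (sc in unique(ann$scaffold)) {
        i <- ann$scaffold == sc
        lo <- min(ann$start[i]); hi <- max(ann$end[i])
        s <- lo + hi - ann$end[i]; e <- lo + hi - ann$start[i]
        ann$start[i] <- s; ann$end[i] <- e
      }
    }
    attr(ann, "layout") <- layout
    ann
  }
  if (is.null(seed)) run() else with_seed_mc(seed, run())
}

# ---- planted gene-hit tables (QC / metabolic truth) ------------------------

#' Plant single-copy-gene hits for a bin
#'
#' Builds a gene-hit table in which a chosen fraction of the single-copy-gene
#' set is present and a chosen fraction is duplicated, giving exact expected
#' completeness and contamination scores for round-trip tests.
#'
#' @param bin_id bin identifier.
#' @param scg_set character vector of marker identifiers.
#' @param present_fraction fraction of the set present at least once.
#' @param duplicated_fraction fraction of the set present twice (subset of the
#'   present genes).
#' @param seed optional seed.
#' @return data.frame with columns bin_id, gene_id.
#' @export
plant_scg_hits <- function(bin_id, scg_set, present_fraction = 1,
                           duplicated_fraction = 0, seed = NULL) {
  stopifnot(present_fraction >= 0, present_fraction <= 1,
            duplicated_fraction >= 0, duplicated_fraction <= present_fraction)
  run <- function() {
    n <- length(scg_set)
    n_present <- round(present_fraction * n)
    n_dup <- round(duplicated_fraction * n)
    present <- sample(scg_set, n_present)
    dup <- if (n_dup > 0) sample(present, n_dup) else character()
    data.frame(bin_id = bin_id, gene_id = c(present, dup),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed_mc(seed, run())
}

# ---- writers ---------------------------------------------------------------

#' Write a depth table in samtools-depth format
#'
#' Three tab-separated columns: scaffold, 1-based position, depth; no header
#' (the samtools dialect). Zero-depth positions are omitted when
#' `omit_zero = TRUE`; readers must tolerate both dialects.
#'
#' @param depths named list of integer depth vectors (one per scaffold).
#' @param path output file.
#' @param omit_zero drop rows with depth 0 (default TRUE).
#' @export
write_depth_tsv <- function(depths, path, omit_zero = TRUE) {
  dt <- data.table::rbindlist(lapply(names(depths), function(sc) {
    d <- depths[[sc]]
    data.table::data.table(scaffold = sc, pos = seq_along(d), depth = d)
  }))
  if (omit_zero) dt <- dt[dt$depth > 0L, ]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write scaffold lengths as a two-column TSV
#' @param lengths named numeric vector (scaffold -> length in bp).
#' @param path output file.
#' @export
write_lengths_tsv <- function(lengths, path) {
  write_tsv_mc(data.frame(scaffold = names(lengths),
                          length_bp = as.numeric(lengths)), path)
}

#' Write bin membership as a two-column TSV (scaffold, bin_id)
#' @param membership data.frame with columns scaffold, bin_id.
#' @param path output file.
#' @export
write_bins_tsv <- function(membership, path) {
  write_tsv_mc(membership[, c("scaffold", "bin_id")], path)
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write annotations as GFF3
#'
#' Minimal GFF3 with 1-based inclusive coordinates and the label carried in
#' the `gene=` attribute (`product=hypothetical protein` for unlabeled ORFs).
#'
#' @param annotations data.frame with scaffold, start, end, strand, label.
#' @param path output file.
#' @export
write_gff3 <- function(annotations, path) {
  a <- annotations
  attrs <- ifelse(a$label == "ORF",
                  sprintf("ID=orf%02d;product=hypothetical protein", seq_len(nrow(a))),
                  sprintf("ID=gene%02d;gene=%s", seq_len(nrow(a)), a$label))
  lines <- sprintf("%s\tmicrocensus\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   a$scaffold, a$start, a$end, a$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write community ground truth as JSON
#' @param community a [build_community()] result.
#' @param path output file.
#' @export
write_truth_json <- function(community, path) {
  jsonlite::write_json(
    list(spec = unclass(community$spec), genomes = community$genomes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
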