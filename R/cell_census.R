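# Absolute abundance census: from relative abundance to cells per gram.
#
# Two parameterized models:
#   cell_fraction — cells/g = cell_fraction * N_total (default; reproduces the
#     chain 1e-7 of 1e9 cells/g = 100 cells/g = 1e-5 % of the community).
#   dna_mass     — genome copies/g from DNA yield, genome length and the mass
#     of a base pair, under a one-genome-per-cell assumption.

#' Census model parameters
#'
#' @param total_cells_per_gram total microbial cells per gram of soil
#'   (default `1e9`, the standard order-of-magnitude estimate for soils).
#' @param dna_yield_ng_per_gram DNA yield in ng per gram of soil (required by
#'   the `dna_mass` model).
#' @param mass_per_bp_g mass of one double-stranded base pair in grams
#'   (default `650 g/mol / Avogadro = 1.079e-21 g`).
#' @return an object of class `census_parameters`.
#' @export
census_parameters <- function(total_cells_per_gram = 1e9,
                              dna_yield_ng_per_gram = NULL,
                              mass_per_bp_g = 650 / 6.02214076e23) {
  if (!is_scalar_num(total_cells_per_gram) || total_cells_per_gram <= 0) {
    stop_mc("total_cells_per_gram must be > 0")
  }
  if (!is.null(dna_yield_ng_per_gram) &&
      (!is_scalar_num(dna_yield_ng_per_gram) || dna_yield_ng_per_gram <= 0)) {
    stop_mc("dna_yield_ng_per_gram must be > 0")
  }
  if (mass_per_bp_g <= 0) stop_mc("mass_per_bp_g must be > 0")
  structure(list(total_cells_per_gram = total_cells_per_gram,
                 dna_yield_ng_per_gram = dna_yield_ng_per_gram,
                 mass_per_bp_g = mass_per_bp_g),
            class = "census_parameters")
}

census_estimate <- function(bin_id, cells_per_gram, percent, model, params) {
  data.frame(
    bin_id = bin_id,
    model = model,
    cells_per_gram = cells_per_gram,
    percent_of_community = percent,
    sub_unity = cells_per_gram < 1,
    n_total = params$total_cells_per_gram,
    stringsAsFactors = FALSE
  )
}

#' Cells per gram from a community cell fraction
#'
#' `cells/g = cell_fraction * N_total`; the community percentage is
#' `100 * cell_fraction`. Estimates below one cell per gram are reported
#' as-is with a `sub_unity` flag, not rounded.
#'
#' @param cell_fraction fraction of community cells in `[0, 1]` (vectorized).
#' @param params a [census_parameters()].
#' @param bin_id optional labels.
#' @return data.frame: bin_id, model, cells_per_gram, percent_of_community,
#'   sub_unity, n_total.
#' @export
cells_per_gram_cellfraction <- function(cell_fraction, params = census_parameters(),
                                        bin_id = NULL) {
  if (any(cell_fraction < 0 | cell_fraction > 1, na.rm = TRUE)) {
    stop_mc("cell_fraction must lie in [0, 1]")
  }
  bin_id <- bin_id %||% as.character(seq_along(cell_fraction))
  census_estimate(bin_id, cell_fraction * params$total_cells_per_gram,
                  cell_fraction * 100, "cell_fraction", params)
}

#' Percent of the community represented by an absolute cell count
#'
#' @param cells_per_gram cells per gram (`>= 0`, vectorized).
#' @param n_total total cells per gram (> 0).
#' @return percentage, `100 * cells_per_gram / n_total`.
#' @export
percent_of_community <- function(cells_per_gram, n_total = 1e9) {
  if (!is_scalar_num(n_total) || n_total <= 0) stop_mc("n_total must be > 0")
  if (any(cells_per_gram < 0, na.rm = TRUE)) stop_mc("cells_per_gram must be >= 0")
  100 * cells_per_gram / n_total
}

#' Cells per gram from DNA mass
#'
#' Genome copies per gram of soil:
#' `(dna_yield * base_fraction) / (genome_length * mass_per_bp)`, reported as
#' cells per gram under a one-genome-per-cell assumption (polyploidy is out of
#' scope).
#'
#' @param base_fraction fraction of sequenced bases attributed to the genome,
#'   in `[0, 1]` (vectorized).
#' @param genome_length_bp genome length in bp (> 0).
#' @param params a [census_parameters()] with `dna_yield_ng_per_gram` set.
#' @param bin_id optional labels.
#' @return data.frame as in [cells_per_gram_cellfraction()].
#' @export
cells_per_gram_dnamass <- function(base_fraction, genome_length_bp,
                                   params, bin_id = NULL) {
  if (is.null(params$dna_yield_ng_per_gram)) {
    stop_mc("dna_mass model requires dna_yield_ng_per_gram in census_parameters()")
  }
  if (any(base_fraction < 0 | base_fraction > 1, na.rm = TRUE)) {
    stop_mc("base_fraction must lie in [0, 1]")
  }
  if (any(genome_length_bp <= 0)) stop_mc("genome_length_bp must be > 0")
  bin_id <- bin_id %||% as.character(seq_along(base_fraction))
  yield_g <- params$dna_yield_ng_per_gram * 1e-9
  copies <- (yield_g * base_fraction) / (genome_length_bp * params$mass_per_bp_g)
  census_estimate(bin_id, copies,
                  percent_of_community(copies, params$total_cells_per_gram),
                  "dna_mass", params)
}
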