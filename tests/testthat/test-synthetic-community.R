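test_that("community_spec validates its invariants", {
  expect_error(community_spec(n_genomes = 3, n_ultrasmall = 4), "invalid spec")
  expect_error(community_spec(enrichment_range = c(0.5, 10)), "enrichment_range")
  expect_error(community_spec(enrichment_range = c(100, 10)), "enrichment_range")
  expect_error(community_spec(seq_bases_bulk = 0), "sequencing effort")
  expect_error(community_spec(abundance_lognormal_sigma = 0), "sigma")
  expect_error(community_spec(concentrate_capture_of_large = 1.5), "capture")
})

test_that("normalization forces a single genome to cell fraction 1", {
  comm <- build_community(community_spec(n_genomes = 1, n_ultrasmall = 1, seed = 3))
  expect_equal(comm$genomes$cell_fraction_bulk, 1.0)
  expect_equal(comm$genomes$cell_fraction_concentrate, 1.0)
})

test_that("cell fractions sum to 1 per sample and enrichments stay in range", {
  for (seed in c(1, 7, 23, 99)) {
    comm <- build_community(community_spec(
      n_genomes = 30, n_ultrasmall = 4, enrichment_range = c(100, 1000),
      concentrate_capture_of_large = 0.5, seed = seed))
    g <- comm$genomes
    expect_equal(sum(g$cell_fraction_bulk), 1, tolerance = 1e-9)
    expect_equal(sum(g$cell_fraction_concentrate), 1, tolerance = 1e-9)
    enr <- g$planted_enrichment[g$is_ultrasmall]
    expect_true(all(enr >= 100 & enr <= 1000))
    expect_true(all(is.na(g$planted_enrichment[!g$is_ultrasmall])))
  }
})

test_that("identical seeds give identical communities and byte-identical files", {
  spec <- community_spec(n_genomes = 10, n_ultrasmall = 2,
                         concentrate_capture_of_large = 0.9, seed = 7)
  c1 <- build_community(spec)
  c2 <- build_community(spec)
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_depth_tsv(simulate_coverage(c1, "bulk", 1e6), f1)
  write_depth_tsv(simulate_coverage(c2, "bulk", 1e6), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("expected depth follows p * seq_bases / sum(p * L) and conserves bases", {
  # single genome of 1 Mb at 10 Mb sequencing: depth 10
  one <- build_community(community_spec(
    n_genomes = 1, n_ultrasmall = 1, genome_length_bp = c(1e6, 1e6),
    ultrasmall_length_scale = 1, seed = 5))
  expect_equal(unname(expected_depth(one, "bulk", 1e7)), 10.0)

  # two genomes at equal cell fraction, lengths 1 Mb and 3 Mb, 8 Mb sequenced:
  # both get depth 0.5 * 8e6 / (0.5 * 1e6 + 0.5 * 3e6) = 2.0
  two <- structure(list(
    genomes = data.frame(genome_id = c("a", "b"), length_bp = c(1e6, 3e6),
                         is_ultrasmall = FALSE,
                         cell_fraction_bulk = c(0.5, 0.5),
                         cell_fraction_concentrate = c(0.5, 0.5)),
    spec = community_spec(n_genomes = 2, n_ultrasmall = 0,
                          concentrate_capture_of_large = 1)
  ), class = "community")
  d <- expected_depth(two, "bulk", 8e6)
  expect_equal(unname(d), c(2.0, 2.0))

  # conservation holds for arbitrary specs
  for (seed in c(2, 11, 31)) {
    comm <- build_community(community_spec(n_genomes = 25, n_ultrasmall = 3,
                                           seed = seed))
    for (s in c("bulk", "concentrate")) {
      d <- expected_depth(comm, s, 3.3e8)
      expect_equal(sum(d * comm$genomes$length_bp), 3.3e8, tolerance = 1e-6)
    }
  }
  expect_error(expected_depth(one, "soil"), "unknown sample_id")
})

test_that("depth profiles are Poisson with the Lander-Waterman breadth", {
  expect_identical(simulate_depth_profile(100, 0), integer(100))
  expect_error(simulate_depth_profile(100, -1), "expected_depth")

  L <- 1e5
  p <- simulate_depth_profile(L, 10, seed = 8)
  expect_lt(abs(mean(p) - 10), 3 * sqrt(10 / L))

  for (cvg in c(0.1, 0.5, 1, 2, 5)) {
    p <- simulate_depth_profile(L, cvg, seed = 100 + cvg * 10)
    expected <- 1 - exp(-cvg)
    se <- sqrt(expected * (1 - expected) / L)
    expect_lt(abs(mean(p >= 1) - expected), 3 * se)
  }
})

test_that("planted 16S sequences carry the requested primer-site mismatches", {
  pair <- read_primer_pairs()[[1]]
  x0 <- plant_16s(pair, 0, seed = 21)
  expect_true(x0$detectable_truth)
  # planted site recovered verbatim: exact forward hit at the planted start
  hits <- find_primer_sites(x0$sequence, pair$forward, 0)
  expect_gte(nrow(hits), 1L)
  expect_true(x0$forward_start %in% hits$position[hits$strand == "+"])

  kfull <- sum(strsplit(pair$forward, "")[[1]] != "N")
  xfull <- plant_16s(pair, kfull, seed = 22)
  expect_false(xfull$detectable_truth)

  expect_error(plant_16s(pair, 0, product_length = 10), "shorter")
  expect_identical(plant_16s(pair, 2, seed = 5), plant_16s(pair, 2, seed = 5))
})

test_that("planted operon layouts have the promised gene orders", {
  ref <- c("cyoA", "cyoB", "cyoC", "cyoD", "cyoE")
  expect_identical(plant_operon("reference", seed = 1)$label, ref)

  part <- plant_operon("partial", seed = 3)$label
  expect_lt(length(part), length(ref))
  expect_true(identical(part, ref[seq_along(part)]) ||
                identical(part, ref[(5 - length(part) + 1):5]))

  reord <- plant_operon("reordered", seed = 4)$label
  expect_setequal(reord, ref)
  expect_false(identical(reord, ref))

  ins <- plant_operon("inserted_orf", seed = 5)$label
  expect_identical(ins[ins != "ORF"], ref)
  expect_identical(sum(ins == "ORF"), 1L)

  frag <- plant_operon("fragmented", seed = 6)
  expect_identical(length(unique(frag$scaffold)), 2L)
  expect_identical(frag$label, ref)

  expect_error(plant_operon("scrambled"), "arg")
})

test_that("minus-strand planted operons keep transcriptional order", {
  ann <- plant_operon("reference", strand = "-", seed = 9)
  # coordinates descend along the label order on the minus strand
  expect_true(all(diff(ann$start) < 0))
  expect_identical(ann$label, c("cyoA", "cyoB", "cyoC", "cyoD", "cyoE"))
})
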