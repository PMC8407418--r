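test_that("profile_scaffold computes mean depth and breadth over all positions", {
  p0 <- profile_scaffold(NULL, "s1", 100)
  expect_equal(c(p0$mean_depth, p0$breadth), c(0, 0))

  full <- depth_records("s1", 1:100, 5L)
  p <- profile_scaffold(full, "s1", 100)
  expect_equal(c(p$mean_depth, p$breadth), c(5, 1))

  half <- depth_records("s1", 1:50, 4L)
  p <- profile_scaffold(half, "s1", 100)
  expect_equal(c(p$mean_depth, p$breadth), c(2.0, 0.5))
})

test_that("profile_scaffold rejects out-of-range and duplicate positions", {
  expect_error(profile_scaffold(depth_records("s1", c(1, 101), 2L), "s1", 100),
               "position 101 outside scaffold 's1'")
  expect_error(profile_scaffold(depth_records("s1", c(5, 5), 2L), "s1", 100),
               "duplicate position 5")
})

test_that("profiles are invariant to record order and zero-row dialect", {
  set.seed(19)
  pos <- sample(1:200, 80)
  rec <- depth_records("sc", pos, rpois(80, 4) + 1L)
  shuffled <- rec[sample(nrow(rec)), ]
  zeros <- depth_records("sc", setdiff(1:200, pos), 0L)
  with_zeros <- rbind(rec, zeros)
  base <- profile_scaffold(rec, "sc", 200)
  expect_equal(profile_scaffold(shuffled, "sc", 200), base)
  expect_equal(profile_scaffold(with_zeros, "sc", 200), base)
})

test_that("depth TSV writing and reading round-trips both dialects", {
  depths <- list(a = c(0L, 3L, 0L, 2L), b = c(1L, 0L, 0L))
  for (omit in c(TRUE, FALSE)) {
    f <- withr::local_tempfile(fileext = ".tsv")
    write_depth_tsv(depths, f, omit_zero = omit)
    rec <- read_depth_tsv(f)
    pa <- profile_scaffold(rec, "a", 4)
    expect_equal(pa$mean_depth, 5 / 4)
    expect_equal(pa$breadth, 0.5)
  }
})

test_that("relative abundance is the base fraction and handles degenerate input", {
  one <- profile_scaffold(depth_records("s", 1:10, 2L), "s", 10)
  expect_equal(relative_abundance(one)$base_fraction, 1.0)

  # (depth 3, L 100) and (depth 1, L 300): 300 base-units each -> 0.5 / 0.5
  profs <- rbind(
    profile_scaffold(depth_records("x", 1:100, 3L), "x", 100),
    profile_scaffold(depth_records("y", 1:300, 1L), "y", 300))
  expect_equal(relative_abundance(profs)$base_fraction, c(0.5, 0.5))

  three <- do.call(rbind, lapply(c("a", "b", "c"), function(s) {
    profile_scaffold(depth_records(s, 1:60, 2L), s, 60)
  }))
  expect_equal(relative_abundance(three)$base_fraction, rep(1 / 3, 3))

  zero <- rbind(profile_scaffold(NULL, "a", 50), profile_scaffold(NULL, "b", 50))
  ra <- relative_abundance(zero)
  expect_true(all(ra$undefined))
  expect_true(all(is.na(ra$base_fraction)))

  mixed <- rbind(profile_scaffold(NULL, "a", 50, sample_id = "s1"),
                 profile_scaffold(NULL, "b", 50, sample_id = "s2"))
  expect_error(relative_abundance(mixed), "mix samples")
})

test_that("bin aggregation uses length-weighted means", {
  prof <- profile_scaffold(depth_records("s1", 1:80, 6L), "s1", 80)
  solo <- aggregate_bins(prof, data.frame(scaffold = "s1", bin_id = "b1"))
  expect_equal(solo$mean_depth, prof$mean_depth)
  expect_equal(solo$breadth, prof$breadth)

  two <- rbind(profile_scaffold(depth_records("s1", 1:100, 10L), "s1", 100),
               profile_scaffold(NULL, "s2", 100))
  agg <- aggregate_bins(two, data.frame(scaffold = c("s1", "s2"), bin_id = "b"))
  expect_equal(agg$mean_depth, 5.0)
  expect_equal(agg$breadth, two$breadth[1] / 2)

  pair <- rbind(profile_scaffold(depth_records("s1", 1:50, 4L), "s1", 50),
                profile_scaffold(depth_records("s2", 1:200, 4L), "s2", 200))
  agg2 <- aggregate_bins(pair, data.frame(scaffold = c("s1", "s2"),
                                          bin_id = c("b1", "b2")))
  expect_equal(agg2$cell_fraction, c(0.5, 0.5))

  expect_error(
    aggregate_bins(pair, data.frame(scaffold = c("s1", "s1"),
                                    bin_id = c("b1", "b2"))),
    "more than one bin")
})

test_that("scaffolds missing a profile are zero-filled using their stated length", {
  prof <- profile_scaffold(depth_records("s1", 1:100, 8L), "s1", 100)
  memb <- data.frame(scaffold = c("s1", "s2"), bin_id = "b",
                     length_bp = c(100, 300))
  agg <- aggregate_bins(prof, memb)
  expect_equal(agg$mean_depth, 8 * 100 / 400)
  expect_error(aggregate_bins(prof, memb[, 1:2]), "length_bp")
})

test_that("abundance flavors sum to one per sample on simulated communities", {
  for (seed in c(4, 14)) {
    comm <- build_community(community_spec(
      n_genomes = 12, n_ultrasmall = 2, genome_length_bp = c(2e3, 6e3),
      concentrate_capture_of_large = 0.9, seq_bases_bulk = 2e5,
      seq_bases_concentrate = 2e5, seed = seed))
    prof <- profile_depth_vectors(simulate_coverage(comm, "bulk"), "bulk")
    expect_equal(sum(relative_abundance(prof)$base_fraction), 1, tolerance = 1e-9)
    bins <- data.frame(scaffold = prof$scaffold_id, bin_id = prof$scaffold_id)
    agg <- aggregate_bins(prof, bins)
    expect_equal(sum(agg$base_fraction), 1, tolerance = 1e-9)
    expect_equal(sum(agg$cell_fraction), 1, tolerance = 1e-9)
  }
})

test_that("bin cell fractions recover planted fractions at high depth", {
  comm <- build_community(community_spec(
    n_genomes = 15, n_ultrasmall = 3, genome_length_bp = c(2e4, 5e4),
    concentrate_capture_of_large = 0.9, seed = 27))
  sb <- seq_bases_for_depth(comm, "concentrate", 20,
                            genome_ids = comm$genomes$genome_id)
  prof <- profile_depth_vectors(
    simulate_coverage(comm, "concentrate", sb, seed = 28), "concentrate")
  bins <- data.frame(scaffold = prof$scaffold_id, bin_id = prof$scaffold_id)
  agg <- aggregate_bins(prof, bins)
  est <- agg$cell_fraction[match(comm$genomes$genome_id, agg$bin_id)]
  rel_err <- abs(est - comm$genomes$cell_fraction_concentrate) /
    comm$genomes$cell_fraction_concentrate
  expect_true(all(rel_err < 0.05))
})
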