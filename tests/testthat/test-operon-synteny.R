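ref_genes <- c("cyoA", "cyoB", "cyoC", "cyoD", "cyoE")

cluster_of <- function(labels, scaffold = "sc") {
  n <- length(labels)
  lens <- rep(500, n)
  starts <- 100 + cumsum(c(0, head(lens + 50, -1)))
  ann <- data.frame(scaffold = scaffold, start = starts,
                    end = starts + lens - 1, strand = "+", label = labels,
                    stringsAsFactors = FALSE)
  cl <- extract_clusters(ann, operon_model())
  expect_length(cl, 1L)
  cl[[1]]
}

test_that("clusters chain genes within the intergenic gap and honor strand", {
  model <- operon_model()
  ann <- plant_operon("reference", gap_bp = 50, seed = 1)
  cl <- extract_clusters(ann, model)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$label, ref_genes)

  minus <- plant_operon("reference", strand = "-", gap_bp = 50, seed = 1)
  clm <- extract_clusters(minus, model)
  expect_identical(clm[[1]]$label, ref_genes)

  # a 10 kb gap between cyoC and cyoD splits the locus in two
  gapped <- plant_operon("reference", gap_bp = 50, seed = 1)
  gapped$start[4:5] <- gapped$start[4:5] + 10000
  gapped$end[4:5] <- gapped$end[4:5] + 10000
  expect_length(extract_clusters(gapped, model), 2L)

  dup <- rbind(ann, ann[1, ])
  expect_error(extract_clusters(dup, model), "duplicate annotation")
})

test_that("classification matches the reference-order taxonomy", {
  model <- operon_model()
  exact <- classify_cluster(cluster_of(ref_genes), model)
  expect_equal(exact$classification, "identical")
  expect_identical(exact$order_score, 1)

  ins <- classify_cluster(cluster_of(c("cyoA", "cyoB", "ORF", "cyoC", "cyoD",
                                       "cyoE")), model)
  expect_equal(ins$classification, "identical_with_insertion")
  expect_equal(ins$n_insertions, 1L)
  expect_identical(ins$order_score, 1)

  part <- classify_cluster(cluster_of(c("cyoA", "cyoB", "cyoC", "cyoD")), model)
  expect_equal(part$classification, "partial")
  expect_equal(part$order_score, 0.8)

  rev_cl <- classify_cluster(cluster_of(rev(ref_genes)), model)
  expect_equal(rev_cl$classification, "rearranged")
  expect_equal(rev_cl$order_score, 0.2)

  expect_error(classify_cluster(cluster_of(ref_genes)[0, ], model), "empty")
})

test_that("two shared out-of-order labels distinguish rearranged from partial", {
  model <- operon_model()
  swapped <- classify_cluster(cluster_of(c("cyoB", "cyoA")), model)
  expect_equal(swapped$classification, "rearranged")
  single <- classify_cluster(cluster_of(c("ORF", "cyoB")), model)
  expect_equal(single$classification, "partial")
})

test_that("reverse-complementing a scaffold leaves the classification unchanged", {
  model <- operon_model()
  for (layout in c("reference", "inserted_orf", "reordered", "partial")) {
    ann <- plant_operon(layout, seed = 12)
    plus <- classify_synteny(ann, model)
    L <- max(ann$end) + 500
    flipped <- ann
    flipped$start <- L - ann$end + 1
    flipped$end <- L - ann$start + 1
    flipped$strand <- ifelse(ann$strand == "+", "-", "+")
    minus <- classify_synteny(flipped, model)
    expect_identical(minus$genome_class, plus$genome_class)
    expect_identical(minus$clusters$order_score, plus$clusters$order_score)
  }
})

test_that("every planted layout maps to its intended class across seeds", {
  intended <- c(reference = "identical",
                inserted_orf = "identical_with_insertion",
                reordered = "rearranged",
                fragmented = "fragmented",
                partial = "partial")
  model <- operon_model()
  for (seed in 1:20) {
    for (layout in names(intended)) {
      ann <- plant_operon(layout, seed = seed)
      got <- classify_synteny(ann, model)$genome_class
      expect_identical(got, unname(intended[layout]))
    }
  }
})

test_that("order score equals brute-force LCS for small clusters", {
  model <- operon_model()
  labels_pool <- c(ref_genes, "ORF")
  for (seed in 1:30) {
    labels <- withr::with_seed(seed, {
      sample(labels_pool, sample(1:6, 1), replace = TRUE)
    })
    if (!any(labels %in% ref_genes)) next
    cl <- cluster_of(labels)
    got <- classify_cluster(cl, model)$order_score
    labeled <- labels[labels %in% ref_genes]
    expect_equal(got, brute_lcs(labeled, ref_genes) / length(ref_genes))
  }
})

test_that("GFF3 writing and reading preserve labels and classification", {
  for (layout in c("reference", "inserted_orf", "partial")) {
    ann <- plant_operon(layout, seed = 7)
    f <- withr::local_tempfile(fileext = ".gff3")
    write_gff3(ann, f)
    back <- read_gff3_annotations(f)
    expect_identical(back$label, ann$label)
    expect_identical(classify_synteny(back)$genome_class,
                     classify_synteny(ann)$genome_class)
  }
})

test_that("product-name synonyms map to cyo labels", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc\tx\tCDS\t100\t600\t.\t+\t0\tID=g1;product=cytochrome o ubiquinol oxidase subunit II",
    "sc\tx\tCDS\t700\t1200\t.\t+\t0\tID=g2;product=Heme O synthase"), f)
  ann <- read_gff3_annotations(f)
  expect_identical(ann$label, c("cyoA", "cyoE"))
})
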