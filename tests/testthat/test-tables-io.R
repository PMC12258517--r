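test_that("DE tables round-trip through TSV and enforce their invariants", {
  d <- tiny_de()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(d, f)
  back <- read_de_table(f, quiet = TRUE)
  expect_equal(back, d)

  # unparseable numeric fields come back NA, records retained
  writeLines(c("gene\tlog2fc\tpadj", "a\tNA\t0.1", "b\t1.5\tNA", "c\t0.2\t0.5"),
             f)
  d2 <- read_de_table(f, quiet = TRUE)
  expect_equal(nrow(d2), 3L)
  expect_true(is.na(d2$log2fc[d2$gene == "a"]))
  expect_true(is.na(d2$padj[d2$gene == "b"]))

  # missing required column and duplicate gene are named in the error
  writeLines(c("gene\tlfc", "a\t1"), f)
  expect_error(read_de_table(f, quiet = TRUE), "log2fc")
  writeLines(c("gene\tlog2fc\tpadj", "a\t1\t0.1", "a\t2\t0.2"), f)
  expect_error(read_de_table(f, quiet = TRUE), "a")

  # orientation flag negates fold changes on load
  write_de_table(d, f)
  flipped <- read_de_table(f, orientation = "ko_wt", quiet = TRUE)
  expect_equal(flipped$log2fc, -d$log2fc)
})

test_that("expression filter keeps genes above the TPM floor in enough samples", {
  tpm <- rbind(boundary = c(2, 2, 2, 0, 0, 0),
               allzero = rep(0, 6),
               low = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
               high = rep(10, 6))
  expect_setequal(filter_expressed(tpm, min_tpm = 1, min_samples = 3),
                  c("boundary", "high"))
  expect_false("allzero" %in% filter_expressed(tpm, min_tpm = 1, min_samples = 1))
  expect_setequal(filter_expressed(tpm, min_tpm = 0, min_samples = 1),
                  rownames(tpm))
  expect_error(filter_expressed(tpm, min_samples = 7), "min_samples")

  # monotone: raising either threshold never adds genes
  set.seed(41)
  m <- matrix(rexp(200, 1 / 2), nrow = 25,
              dimnames = list(sprintf("g%02d", 1:25), NULL))
  for (tp in c(0.5, 1, 2)) for (ns in 1:4) {
    keep <- filter_expressed(m, tp, ns)
    expect_true(all(filter_expressed(m, tp * 2, ns) %in% keep))
    expect_true(all(filter_expressed(m, tp, ns + 1) %in% keep))
  }
})

test_that("merge joins on exact gene name and is symmetric in its row set", {
  a <- de_table(c("x", "y", "z"), c(1, 2, 3), c(0.1, 0.2, 0.3))
  b <- de_table(c("y", "z", "w"), c(4, 5, 6), c(0.4, 0.5, 0.6))
  m <- merge_by_gene(a, b, c("A", "B"), quiet = TRUE)
  expect_setequal(m$gene, c("y", "z"))
  expect_equal(m$log2fc_A[m$gene == "y"], 2)
  expect_equal(m$log2fc_B[m$gene == "y"], 4)

  m2 <- merge_by_gene(b, a, c("B", "A"), quiet = TRUE)
  expect_setequal(m$gene, m2$gene)

  # self-join reproduces both columns
  ms <- merge_by_gene(a, a, c("L", "R"), quiet = TRUE)
  expect_equal(ms$log2fc_L, ms$log2fc_R)

  # case-sensitive, exact matching: no silent case-folding
  cased <- de_table("CCNA2", 1, 0.1)
  lower <- de_table(c("Ccna2", "CCNA2"), c(2, 3), c(0.1, 0.1))
  mc <- merge_by_gene(lower, cased, c("A", "B"), quiet = TRUE)
  expect_equal(mc$gene, "CCNA2")

  expect_error(merge_by_gene(de_table("a", 1, 0.1), de_table("b", 1, 0.1),
                             quiet = TRUE), "no genes shared")
})

test_that("regulated-set classification uses strict inequalities", {
  d <- tiny_de()
  up <- classify_regulated(d, "up")
  down <- classify_regulated(d, "down")
  expect_setequal(up, c("Meiosin", "Sycp3"))
  expect_setequal(down, c("Ccna2", "Rec8"))

  # |lfc| below the GO-dialect threshold is excluded
  expect_false("Rec8" %in% classify_regulated(d, "down", lfc_threshold = 0.1))
  # boundary padj == alpha is excluded (strict)
  db <- de_table("edge", 0.5, 0.05)
  expect_length(classify_regulated(db, "up", alpha = 0.05), 0L)
  # missing padj never qualifies
  dm <- de_table("m", 3, NA_real_)
  expect_length(classify_regulated(dm, "up"), 0L)
  expect_error(classify_regulated(d, "up", alpha = 1), "alpha")

  # up and down are disjoint for any thresholds
  set.seed(5)
  for (i in 1:20) {
    dr <- de_table(sprintf("g%03d", 1:100), rnorm(100), runif(100))
    thr <- runif(1, 0, 0.5)
    expect_length(intersect(classify_regulated(dr, "up", lfc_threshold = thr),
                            classify_regulated(dr, "down", lfc_threshold = thr)),
                  0L)
  }
})

test_that("gene-set files round-trip through GMT and two-column TSV", {
  sets <- list(`G1/S` = c("Ccne1", "Cdc6"), S = c("Pcna", "Rrm2", "Mcm2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, f, description = "phase")
  expect_equal(read_gene_sets(f), sets)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("set\tgene", "S\tPcna", "S\tRrm2", "G2\tCcnb1"), f2)
  got <- read_gene_sets(f2)
  expect_setequal(got$S, c("Pcna", "Rrm2"))
  expect_equal(got$G2, "Ccnb1")
})

test_that("EdU count tables validate counts and groups", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group,edu_pos,edu_neg", "WT,30,70", "KO,10,90"), f)
  d <- read_edu_counts(f)
  expect_equal(d$edu_pos, c(30, 10))
  writeLines(c("group,edu_pos,edu_neg", "WT,-1,70", "KO,10,90"), f)
  expect_error(read_edu_counts(f), "non-negative")
  writeLines(c("group,edu_pos,edu_neg", "WT,1,1"), f)
  expect_error(read_edu_counts(f), "2 groups")
})
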