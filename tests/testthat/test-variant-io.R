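test_that("VCF round-trip is the identity on valid matrices", {
  set.seed(42)
  for (rep in 1:5) {
    gm <- random_gm(5, 4)
    gm$sites$gene_id <- c("g1", "g1", NA, "g2", NA)
    gm$sites$region <- c("exon", "intron", "intergenic", "exon", "intergenic")
    gm$sites$effect <- c("nonsynonymous", "noncoding", NA, "synonymous", NA)
    path <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(gm, path)
    back <- read_vcf(path)
    expect_equal(back$geno, gm$geno)
    expect_equal(back$samples, gm$samples)
    expect_equal(back$sites$pos, gm$sites$pos)
    expect_equal(back$sites$gene_id, gm$sites$gene_id)
    expect_equal(back$sites$region,
                 ifelse(is.na(gm$sites$region), NA, gm$sites$region))
    expect_equal(back$sites$effect, gm$sites$effect)
  }
})

test_that("an empty matrix round-trips to a header-only file", {
  gm <- geno_matrix(tibble::tibble(chrom = character(), pos = integer(),
                                   ref = character(), alt = character()),
                    matrix(integer(), 0, 3), c("a", "b", "c"))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(nrow(back$sites), 0)
  expect_equal(back$samples, c("a", "b", "c"))
})

test_that("missing and multiallelic records are handled as specified", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tA,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t300\t.\tG\tC\t.\tPASS\t.\tGT\t./.\t0|1\t1/1"
  ), path)
  expect_message(gm <- read_vcf(path), "skipped 1")
  expect_equal(attr(gm, "n_skipped"), 1L)
  expect_equal(nrow(gm$sites), 2)
  expect_equal(gm$geno[1, ], c(s1 = 0L, s2 = 1L, s3 = 2L))
  expect_equal(gm$geno[2, ], c(s1 = NA_integer_, s2 = 1L, s3 = 2L))
})

test_that("malformed GT fields raise a parse error naming the record", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/9"
  ), path)
  expect_error(read_vcf(path), "chr1:100")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a vcf", path2)
  expect_error(read_vcf(path2), "fileformat")
})

test_that("a depth mask sets low-coverage calls to missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:3\t1/1:30"
  ), path)
  gm <- read_vcf(path, min_depth = 8)
  expect_equal(gm$geno[1, ], c(s1 = NA_integer_, s2 = 2L))
  gm2 <- read_vcf(path)
  expect_equal(gm2$geno[1, ], c(s1 = 1L, s2 = 2L))
})

test_that("the MAF/missingness filter applies both thresholds strictly", {
  # 20 samples, one het carrier: MAF 0.025 <= 0.05 -> removed
  g1 <- c(1L, rep(0L, 19))
  # 5 of 20 missing (0.25 >= 0.20) but common otherwise -> removed
  g2 <- c(rep(NA_integer_, 5), rep(c(0L, 2L), length.out = 15))
  # MAF 0.5, no missing -> retained
  g3 <- rep(c(0L, 2L), 10)
  gm <- make_gm(rbind(g1, g2, g3))
  out <- filter_variants(gm)
  expect_equal(out$sites$pos, gm$sites$pos[3])
  counts <- attr(out, "filter_counts")
  expect_equal(unname(counts["removed_maf"]), 1)
  expect_equal(unname(counts["removed_missing"]), 1)

  # an all-missing site is removed without division by zero
  gm2 <- make_gm(rbind(rep(NA_integer_, 4), c(0L, 1L, 2L, 1L)))
  out2 <- filter_variants(gm2)
  expect_equal(nrow(out2$sites), 1)
  expect_equal(unname(attr(out2, "filter_counts")["removed_all_missing"]), 1)
})

test_that("filtering is idempotent and every survivor meets the thresholds", {
  set.seed(7)
  gm <- random_gm(200, 20, miss_rate = 0.15)
  once <- filter_variants(gm)
  twice <- filter_variants(once)
  expect_equal(once$sites, twice$sites)
  expect_equal(once$geno, twice$geno)
  # survivors are a subsequence of the input
  expect_true(all(once$sites$pos %in% gm$sites$pos))
  expect_false(is.unsorted(match(once$sites$pos, gm$sites$pos)))
  # direct recomputation of both thresholds
  for (i in seq_len(nrow(once$sites))) {
    row <- once$geno[i, ]
    n <- sum(!is.na(row))
    p <- sum(row, na.rm = TRUE) / (2 * n)
    expect_gt(min(p, 1 - p), 0.05)
    expect_lt(1 - n / length(row), 0.20)
  }
})

test_that("gene models parse from GFF3 and BED with coordinate conventions", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\texon\t1501\t2000\t.\t+\t.\tID=gA.e2;Parent=gA",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tID=gA.e1;Parent=gA"
  ), gff)
  genes <- read_gene_models(gff)
  expect_equal(genes$gene_id, "gA")
  expect_equal(genes$exons[[1]],
               cbind(start = c(1001L, 1501L), end = c(1200L, 2000L)))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr2\t1000\t2000\tgB\t0\t-", bed)
  gb <- read_gene_models(bed)
  expect_equal(gb$start, 1001L)
  expect_equal(gb$end, 2000L)
  expect_equal(gb$strand, "-")
})

test_that("overlapping exons merge with a warning and bad spans error", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gC",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=gC",
    "chr1\tsrc\texon\t150\t250\t.\t+\t.\tParent=gC"
  ), gff)
  expect_warning(genes <- read_gene_models(gff), "merged")
  expect_equal(genes$exons[[1]], cbind(start = 100L, end = 250L))

  gff2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=gD",
    "chr1\tsrc\texon\t50\t200\t.\t+\t.\tParent=gD"
  ), gff2)
  expect_error(read_gene_models(gff2), "gD")
})

test_that("site-to-gene assignment honours regions and the tie-break", {
  genes <- tibble::tibble(
    gene_id = c("big", "small"),
    chrom = "chr1",
    start = c(1001L, 1051L), end = c(11000L, 3050L),
    strand = "+",
    exons = list(cbind(start = c(1001L, 1501L), end = c(1200L, 2000L)),
                 cbind(start = 1051L, end = 3050L))
  )
  gm <- make_gm(matrix(0L, 4, 2), pos = c(1100, 1300, 2500, 50000))
  out <- assign_sites_to_genes(gm, genes)
  # pos 1100: inside both genes; smaller span wins; exonic in both
  expect_equal(out$sites$gene_id, c("small", "small", "small", NA))
  expect_equal(out$sites$region, c("exon", "exon", "exon", "intergenic"))

  # without the small gene, 1300 is intronic in "big"
  out2 <- assign_sites_to_genes(gm, genes[1, ])
  expect_equal(out2$sites$gene_id[1:2], c("big", "big"))
  expect_equal(out2$sites$region[1:2], c("exon", "intron"))
})
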