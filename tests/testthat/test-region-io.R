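test_that("VCF reading filters non-bi-allelic records and builds the phased matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path)
  region <- genomic_region("chr6", 1, 10000)
  smap <- data.frame(sample = c("S1", "S2"), pop = c("P1", "P1"))
  expect_message(panel <- read_vcf_region(path, region, smap),
                 "non-bi-allelic")
  expect_equal(n_sites(panel), 2)          # tri-allelic record dropped
  expect_equal(panel$positions, c(1000L, 3000L))
  # genotypes 0|1 and 1|1 -> column (0,1,1,1)
  expect_equal(unname(panel$mat[, 1]), c(0L, 1L, 1L, 1L))
  expect_error(read_vcf_region(path, region,
                               data.frame(sample = "S9", pop = "P1")),
               "S9")
})

test_that("unphased genotypes drop the site (or error in strict mode)", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, extra_records = paste(
    c("chr6", 4000, ".", "A", "C", ".", "PASS", "AA=A", "GT", "0/1", "0|0"),
    collapse = "\t"))
  region <- genomic_region("chr6", 1, 10000)
  smap <- data.frame(sample = c("S1", "S2"), pop = c("P1", "P1"))
  expect_warning(panel <- suppressMessages(read_vcf_region(path, region, smap)),
                 "unphased")
  expect_false(4000 %in% panel$positions)
  expect_error(suppressWarnings(suppressMessages(
    read_vcf_region(path, region, smap, strict = TRUE))), "unphased")
})

test_that("write/read round trip preserves the matrix and positions exactly", {
  sim <- make_neutral_region(n = 20, theta = 5, L = 5000, seed = 7,
                             pops = "SIMPOP")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(sim$panel, path)
  smap <- read.table(paste0(path, ".samples.tsv"), header = TRUE, sep = "\t")
  back <- read_vcf_region(path, genomic_region("chr6", 1, 5000), smap)
  back <- polarize_panel(back)
  expect_identical(back$positions, sim$panel$positions)
  expect_identical(unname(back$mat), unname(sim$panel$mat))
  expect_identical(back$pops, sim$panel$pops)
})

test_that("polarization handles both orientations, unknowns, and is idempotent", {
  mat <- rbind(c(0, 0, 0), c(1, 1, 1))
  sites <- data.frame(ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                      aa = c("A", "G", "C"), stringsAsFactors = FALSE)
  p <- hap_panel(c(10, 20, 30), mat, c("X", "X"), sites = sites)
  q <- polarize_panel(p)
  expect_equal(unname(q$mat[, 1]), c(0L, 1L))  # aa == ref: unchanged
  expect_equal(unname(q$mat[, 2]), c(1L, 0L))  # aa == alt: flipped
  expect_equal(q$sites$polarized, c(TRUE, TRUE, FALSE))
  q2 <- polarize_panel(q)                       # involution on the flip
  expect_identical(q2$mat, q$mat)
  expect_identical(q2$sites$flipped, q$sites$flipped)
})

test_that("site classification partitions the region classes", {
  # gene at 101..220: exons 1-40 and 81-120 (gene-local), CDS from +21, 60 bp
  gene <- gene_model(gene_start = 101,
                     exons_local = rbind(c(1, 40), c(81, 120)),
                     cds_start_offset = 21, cds_length = 60)
  pos <- c(50, 105, 130, 150, 190, 300)
  mat <- matrix(0L, nrow = 2, ncol = length(pos)); mat[1, ] <- 1L
  sites <- data.frame(ref = rep("A", 6), alt = rep("G", 6),
                      stringsAsFactors = FALSE)
  p <- classify_sites(hap_panel(pos, mat, c("X", "X"), sites = sites), gene)
  # 50 upstream; 105 exon1 before CDS -> UTR; 130 in CDS (exon1 21..40);
  # 150 intron; 190 exon2 CDS; 300 past gene end -> upstream/intergenic
  expect_equal(p$sites$region_class,
               c("upstream", "UTR", "CDS", "intron", "CDS", "upstream"))
  expect_equal(sum(table(p$sites$region_class)), length(pos))
  # CDS offsets: position 130 is gene-local 30 -> coding offset 10;
  # position 190 is gene-local 90 -> exon2 coding continues at 21
  expect_equal(p$sites$cds_offset[3], 10L)
  expect_equal(p$sites$cds_offset[5], 30L)
  expect_error(gene_model(101, rbind(c(1, 40)), 21, 61), "divisible by 3")
})

test_that("archaic sharing flags derived alleles and tolerates missing data", {
  mat <- rbind(c(1, 0), c(0, 1))
  sites <- data.frame(ref = c("A", "C"), alt = c("G", "T"),
                      aa = c("A", "C"), stringsAsFactors = FALSE)
  p <- polarize_panel(hap_panel(c(5, 9), mat, c("X", "X"), sites = sites))
  arch <- archaic_panel(c(5, 9), matrix(c("G", "A", "N", "T"), nrow = 2,
                                        byrow = TRUE,
                                        dimnames = list(c("N1", "N2"), NULL)))
  sh <- share_with_archaic(p, arch)
  # N1 carries (G, A): shares the derived G, not the derived T
  expect_equal(sh$shared_derived[sh$source == "N1"], c(TRUE, FALSE))
  # N2 carries (N, T): missing at site 1, shares the derived T
  expect_equal(sh$shared_derived[sh$source == "N2"], c(NA, TRUE))
})

test_that("simulated archaic pair sharing matches the genealogical truth", {
  fx <- make_archaic_pair(n = 30, theta = 8, split_gens = 20000, seed = 3)
  sh <- share_with_archaic(fx$panel, fx$archaic)
  for (src in c("Neandertal", "Denisovan")) {
    got <- sh$shared_derived[sh$source == src]
    expect_equal(got, unname(fx$truth_shared[match(src, rownames(fx$archaic$alleles)), ]))
  }
  frac <- mean(sh$shared_derived, na.rm = TRUE)
  expect_gte(frac, 0); expect_lte(frac, 1)
})
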