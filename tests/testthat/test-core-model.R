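# Record construction, VCF round trips, gene-model readers, coordinate
# conversions.

test_that("sv_records enforces its invariants", {
  expect_error(sv_records("chr1", 0, 100, "DEL"), "start")
  expect_error(sv_records("chr1", 200, 100, "DEL"), "end < start")
  expect_error(sv_records("chr1", 100, 200, "MEI", mei_family = "SINE"),
               "end == start")
  expect_error(sv_records("chr1", 100, 100, "MEI", mei_family = "none"),
               "mei_family")
  expect_error(sv_records("chr1", 100, 200, "DEL", mei_family = "SINE"),
               "mei_family")
  expect_error(sv_records("chr1", 100, 200, "TRA"), "unknown svtype")
  rec <- sv_records("chr1", 1000, 1500, "DEL")
  expect_equal(rec$length, 501)   # inclusive length convention
})

test_that("VCF round trip is lossless and byte-stable", {
  set.seed(11)
  cfg <- sim_config(seed = 3, n_chrom = 1, chrom_length = 5e6,
                    n_sv = c(DEL = 5, DUP = 3, INV = 2, MEI = 2), n_f2 = 10)
  truth <- simulate_truth(cfg)
  rec <- simulate_callsets(truth, cfg)[1:12, ]
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(rec, f1)
  back <- read_sv_vcf(f1)
  write_sv_vcf(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # two writes of the same input are byte-identical
  f3 <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(rec, f3)
  expect_identical(readLines(f1), readLines(f3))
  # field content survives (records are re-sorted deterministically)
  ord <- order(chrom_rank(rec$chrom), rec$start, rec$svtype)
  sorted <- as.data.frame(rec)[ord, ]
  for (col in c("chrom", "start", "end", "svtype", "mei_family", "length",
                "filter", "orientation", "caller", "sample")) {
    expect_equal(back[[col]], sorted[[col]], ignore_attr = TRUE)
  }
  expect_equal(back$qual, sorted$qual, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("VCF with no data lines reads as an empty record set", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(sv_records(character(0), integer(0), integer(0),
                          character(0)), f)
  expect_equal(nrow(read_sv_vcf(f)), 0)
})

test_that("records lacking or with unknown SVTYPE are skipped and counted", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t1000\t.\tN\t<DEL>\t300\tPASS\tSVTYPE=DEL;END=1500;SVLEN=-501",
    "chr1\t2000\t.\tN\t<DEL>\t300\tPASS\tEND=2500",
    "chr1\t3000\t.\tN\t<TRA>\t300\tPASS\tSVTYPE=TRA;END=3500"), f)
  expect_message(rec <- read_sv_vcf(f), "lacking SVTYPE")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "n_skipped"), 2)
})

test_that("stated SVLEN disagreements with breakpoints are counted", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t1000\t.\tN\t<DEL>\t300\tPASS\tSVTYPE=DEL;END=1500;SVLEN=-400",
    "chr1\t2000\t.\tN\t<DUP>\t300\tPASS\tSVTYPE=DUP;END=2500;SVLEN=501"), f)
  rec <- read_sv_vcf(f)
  expect_equal(attr(rec, "n_svlen_discrepant"), 1)
  expect_equal(rec$length, c(501L, 501L))   # breakpoints win
})

test_that("malformed VCF header is a parse error", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "chr1\t1\t.\tN\t<DEL>\t1\tPASS\tSVTYPE=DEL"), f)
  expect_error(read_sv_vcf(f), "malformed")
})

test_that("GT columns round-trip through the dosage encoding", {
  loci <- data.frame(locus_id = c("L1", "L2", "L3"), chrom = "chr1",
                     start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L),
                     svtype = "DEL", length = 101L, qual = 300,
                     filter = "PASS")
  dos <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2,
                dimnames = list(loci$locus_id, c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(loci, f, genotypes = dos)
  gt_field <- vapply(strsplit(grep("^chr", readLines(f), value = TRUE),
                              "\t"), function(x) x[10], "")
  expect_true(all(gt_field %in% c("0/0", "0/1", "1/1", "./.")))
  expect_equal(attr(read_sv_vcf(f), "genotypes"), dos)
})

test_that("GFF3 gene model derives introns as the span minus features", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1000\t5000\t.\t+\t.\tID=g1",
               "chr1\tx\texon\t1000\t1200\t.\t+\t.\tParent=g1",
               "chr1\tx\texon\t4800\t5000\t.\t+\t.\tParent=g1"), f)
  gm <- read_gene_model(f)
  expect_equal(nrow(gm$introns), 1)
  expect_equal(gm$introns$start, 1201)
  expect_equal(gm$introns$end, 4799)
})

test_that("equivalent BED12 and GFF3 produce identical models", {
  fb <- withr::local_tempfile(fileext = ".bed")
  # blocks 1000-1299 and 4601-5000; thick 1200-4800 (1-based)
  writeLines(paste("chr1", 999, 5000, "geneA", 0, "+", 1199, 4800, "0",
                   2, "300,400", "0,3601", sep = "\t"), fb)
  fg <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1000\t5000\t.\t+\t.\tID=geneA",
               "chr1\tx\texon\t1200\t1299\t.\t+\t.\tParent=geneA",
               "chr1\tx\texon\t4601\t4800\t.\t+\t.\tParent=geneA",
               "chr1\tx\tfive_prime_UTR\t1000\t1199\t.\t+\t.\tParent=geneA",
               "chr1\tx\tthree_prime_UTR\t4801\t5000\t.\t+\t.\tParent=geneA"),
             fg)
  mb <- read_gene_model(fb)
  mg <- read_gene_model(fg)
  for (part in c("genes", "exons", "utr5", "utr3", "introns")) {
    expect_equal(mb[[part]], mg[[part]], ignore_attr = TRUE)
  }
})

test_that("an exon outside its gene span is a model error naming the gene", {
  genes <- data.frame(gene_id = "gX", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "+")
  exons <- data.frame(gene_id = "gX", chrom = "chr1", start = 900L,
                      end = 1100L)
  expect_error(gene_model(genes, exons), "gX")
})

test_that("empty gene model annotates everything intergenic", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  gm <- read_gene_model(f)
  loci <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                     end = c(200L, 6000L), svtype = c("DEL", "INV"))
  expect_equal(locate_sv(loci, gm)$category, c("intergenic", "intergenic"))
})

test_that("BED/VCF coordinate conversions are exact inverses", {
  set.seed(7)
  s0 <- sample.int(1e8, 10000)
  e0 <- s0 + sample.int(1e5, 10000)
  v <- bed_to_vcf_coords(s0, e0)
  b <- vcf_to_bed_coords(v$start, v$end)
  expect_identical(b$start0, as.integer(s0))
  expect_identical(b$end0, as.integer(e0))
  # widths agree: half-open width == inclusive width
  expect_identical(e0 - s0, v$end - v$start + 1L)
})
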