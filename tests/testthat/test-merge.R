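# Union merge: breakpoint-distance clustering, inversion reciprocal-overlap
# merge, two-stage callset merging, database novelty.

test_that("breakpoint-distance rule links and separates DEL pairs", {
  near <- sv_records("chr1", c(10000, 10300), c(12000, 12300), "DEL",
                     caller = c("c1", "c2"))
  expect_equal(nrow(cluster_calls(near)), 1)
  far <- sv_records("chr1", c(10000, 11500), c(12000, 13500), "DEL",
                    caller = c("c1", "c2"))
  expect_equal(nrow(cluster_calls(far)), 2)
  # one offset within distance is not enough under the both-breakpoint rule
  mixed <- sv_records("chr1", c(10000, 10300), c(12000, 13500), "DEL",
                      caller = c("c1", "c2"))
  expect_equal(nrow(cluster_calls(mixed)), 2)
  expect_equal(nrow(cluster_calls(mixed, merge_config(link_mode = "start"))),
               1)
})

test_that("representative breakpoints are lower medians of the members", {
  rec <- sv_records("chr1", c(1000, 1100, 1220, 1390), c(5000, 5100, 5220, 5390),
                    "DEL", caller = paste0("c", 1:4))
  loci <- cluster_calls(rec)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 1100)   # lower of the two middle values
  expect_equal(loci$end, 5100)
})

test_that("jittered copies of separated true loci recover exactly, matching
           the brute-force transitive closure", {
  set.seed(21)
  rec <- make_jittered_records(n_true = 5, copies = 10, jitter = 400)
  loci <- cluster_calls(rec)
  expect_equal(nrow(loci), 5)
  got <- partition_sets(loci_membership(loci, nrow(rec)))
  want <- partition_sets(oracle_cluster_membership(rec, 1000))
  expect_identical(got, want)
})

test_that("clustering equals the brute-force oracle on random instances and
           is permutation invariant", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    rec <- sv_records("chr1",
                      start = sample.int(50000, n, replace = TRUE),
                      end = 60000 + sample.int(50000, n, replace = TRUE),
                      svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
                      qual = 500, caller = "c1", sample = "s1")
    loci <- cluster_calls(rec)
    expect_identical(partition_sets(loci_membership(loci, n)),
                     partition_sets(oracle_cluster_membership(rec, 1000)))
    # conservation: every record in exactly one locus
    expect_identical(sort(unlist(loci$member_ids)), seq_len(n))
    expect_equal(sum(loci$n_members), n)
    # permutation invariance of the locus table
    perm <- sample(n)
    loci_p <- cluster_calls(rec[perm, ])
    expect_equal(loci_p[, c("chrom", "start", "end", "svtype", "qual")],
                 loci[, c("chrom", "start", "end", "svtype", "qual")],
                 ignore_attr = TRUE)
  }
})

test_that("reciprocal overlap is symmetric inclusive-interval arithmetic", {
  expect_equal(reciprocal_overlap(1000, 2000, 1100, 2100), 901 / 1001)
  expect_equal(reciprocal_overlap(1000, 2000, 1000, 2000), 1)
  expect_equal(reciprocal_overlap(1000, 2000, 3000, 4000), 0)
  expect_equal(reciprocal_overlap(1000, 2000, 1100, 2100),
               reciprocal_overlap(1100, 2100, 1000, 2000))
  expect_error(reciprocal_overlap(1000, 999, 1000, 2000), "zero-length")
})

test_that("inversions merge on strict reciprocal overlap within strata", {
  ab <- sv_records("chr1", c(1000, 1100), c(2000, 2100), "INV",
                   caller = c("c1", "c2"))
  expect_equal(nrow(merge_inversions(ab)), 1)    # RO ~ 0.9 > 0.75
  cd <- sv_records("chr1", c(1000, 1700), c(2000, 2700), "INV",
                   caller = c("c1", "c2"))
  expect_equal(nrow(merge_inversions(cd)), 2)    # RO ~ 0.3
  # a 50 kb inversion inside a 150 kb one: different strata, never merged
  nested <- sv_records("chr1", c(100000, 90000), c(149999, 239999), "INV",
                       caller = c("c1", "c2"))
  loci <- merge_inversions(nested)
  expect_equal(nrow(loci), 2)
  # boundary length exactly at the split goes to the lower stratum
  at_boundary <- sv_records("chr1", c(10000, 10000), c(109999, 110000), "INV",
                            caller = c("c1", "c2"))
  expect_equal(nrow(merge_inversions(at_boundary)), 2)
})

test_that("INV clustering matches the brute-force oracle with stratum
           isolation", {
  set.seed(23)
  for (i in 1:10) {
    n <- 60
    start <- sample.int(1e6, n, replace = TRUE)
    len <- sample(c(500, 5000, 90000, 150000), n, replace = TRUE) +
      sample.int(2000, n, replace = TRUE)
    rec <- sv_records("chr1", start, start + len - 1, "INV", qual = 300,
                      caller = "c1", sample = "s1")
    loci <- merge_inversions(rec)
    expect_identical(partition_sets(loci_membership(loci, n)),
                     partition_sets(oracle_inv_membership(rec, 0.75, 1e5)))
    # no locus mixes the two strata
    lens <- rec$end - rec$start + 1
    for (k in seq_len(nrow(loci))) {
      expect_equal(length(unique(lens[loci$member_ids[[k]]] <= 1e5)), 1)
    }
  }
})

test_that("callset merging is union semantics with support sets", {
  base <- sv_records("chr1", 20000, 21000, "DEL", qual = 300)
  four <- do.call(rbind, lapply(1:4, function(i) {
    r <- base
    r$caller <- paste0("c", i)
    r$start <- r$start + i * 50L
    r$end <- r$end + i * 50L
    r
  }))
  lone <- sv_records("chr1", 100000, 101000, "DEL", qual = 250,
                     caller = "c9")
  loci <- merge_callsets(rbind(four, lone))
  expect_equal(nrow(loci), 2)
  expect_equal(lengths(loci$callers), c(4, 1))
  # union, not intersection: the single-caller call is retained
  expect_true("c9" %in% unlist(loci$callers))
})

test_that("merging already-merged loci is idempotent", {
  set.seed(24)
  rec <- make_jittered_records(n_true = 6, copies = 8)
  loci <- merge_callsets(rec)
  again <- merge_callsets(loci)
  expect_equal(again[, c("chrom", "start", "end", "svtype", "length")],
               loci[, c("chrom", "start", "end", "svtype", "length")],
               ignore_attr = TRUE)
})

test_that("exact duplicate records are collapsed with a warning", {
  rec <- sv_records("chr1", c(1000, 1000), c(2000, 2000), "DEL",
                    caller = "c1", sample = "s1")
  expect_warning(loci <- merge_callsets(rec), "duplicate")
  expect_equal(sum(loci$n_members), 1)
})

test_that("database comparison labels known loci by reciprocal overlap and
           MEIs by insertion-point distance", {
  loci <- data.frame(locus_id = c("a", "b", "c"), chrom = "chr1",
                     start = c(1000L, 50000L, 90000L),
                     end = c(2000L, 51000L, 90000L),
                     svtype = c("DEL", "DEL", "MEI"))
  ref <- data.frame(chrom = "chr1", start = c(1000L, 89500L),
                    end = c(2000L, 89500L), svtype = c("DEL", "MEI"))
  out <- compare_to_database(loci, ref)
  expect_equal(out$known, c(TRUE, FALSE, TRUE))
  expect_warning(all_novel <- compare_to_database(loci, ref[0, ]), "empty")
  expect_false(any(all_novel$known))
})

test_that("novelty counts equal a brute-force scan with a planted reference", {
  set.seed(25)
  n <- 100
  start <- sort(sample.int(5e6, n)) * 10L
  len <- sample(200:2000, n, replace = TRUE)
  loci <- data.frame(locus_id = sprintf("L%03d", 1:n), chrom = "chr1",
                     start = start, end = start + len - 1L, svtype = "DEL")
  hidden <- sample(n, 60)
  ref <- loci[hidden, c("chrom", "start", "end", "svtype")]
  # jitter the reference by < 12.5% of length: RO stays >= 75%
  shift <- round(len[hidden] * runif(60, -0.1, 0.1))
  ref$start <- ref$start + shift
  ref$end <- ref$end + shift
  out <- compare_to_database(loci, ref)
  expect_equal(sum(!out$known), 40)
  # brute-force all-pairs check
  brute <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(nrow(ref)), function(j) {
      ov <- min(loci$end[i], ref$end[j]) - max(loci$start[i], ref$start[j]) + 1
      ov > 0 && min(ov / (loci$end[i] - loci$start[i] + 1),
                    ov / (ref$end[j] - ref$start[j] + 1)) >= 0.75
    }, logical(1)))
  }, logical(1))
  expect_identical(out$known, brute)
})
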