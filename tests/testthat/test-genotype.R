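test_that("segment overlap fraction follows half-open interval arithmetic", {
  seg <- cnv_segment("s", "chr1", 150, 250)
  # partial overlap computed by hand: [150,200) / 100
  expect_equal(segment_overlap_fraction(
    list(chrom = "chr1", start = 100, end = 200), seg), 0.5)
  # containment
  expect_equal(segment_overlap_fraction(
    list(chrom = "chr1", start = 0, end = 1000), seg), 1.0)
  # other chromosome
  expect_equal(segment_overlap_fraction(
    list(chrom = "chr2", start = 100, end = 200), seg), 0.0)
  # abutting half-open intervals do not overlap
  expect_equal(segment_overlap_fraction(
    list(chrom = "chr1", start = 100, end = 150), seg), 0.0)
})

test_that("union rule genotypes a 22q11.2-style locus", {
  locus <- default_catalog()[["22q11.2"]]
  b <- function(nm) {
    for (s in locus$segments) if (s$name == nm) return(s)
  }
  # one DEL covering A-B, B-C, C-D entirely, nothing beyond D
  calls <- data.frame(chrom = "chr22", start = b("A-B")$start,
                      end = b("C-D")$end, state = "DEL")
  expect_equal(as.character(assign_genotype(calls, locus, "A-D")), "DEL")
  # flanking exclusion: extending over D-E disqualifies A-D ...
  calls2 <- data.frame(chrom = "chr22", start = b("A-B")$start,
                       end = b("D-E")$end, state = "DEL")
  expect_equal(as.character(assign_genotype(calls2, locus, "A-D")), "REF")
  # ... and the flanking test uses the same coverage threshold
  calls3 <- data.frame(chrom = "chr22", start = b("A-B")$start,
                       end = b("D-E")$start +
                         0.4 * (b("D-E")$end - b("D-E")$start),
                       state = "DEL")
  expect_equal(as.character(assign_genotype(calls3, locus, "A-D")), "DEL")
  # fragmented same-state calls are merged before coverage
  frag <- data.frame(chrom = "chr22",
                     start = c(b("A-B")$start, b("B-C")$start + 10),
                     end = c(b("B-C")$start, b("C-D")$end),
                     state = "DEL")
  expect_equal(as.character(assign_genotype(frag, locus, "A-D")), "DEL")
  # no calls -> REF; conflicting DEL+DUP positivity -> NO_CALL
  expect_equal(as.character(assign_genotype(frag[0, ], locus, "A-D")), "REF")
  both <- rbind(calls, transform(calls, state = "DUP"))
  expect_equal(as.character(assign_genotype(both, locus, "A-D")), "NO_CALL")
  expect_error(assign_genotype(calls, locus, "Z-Z"), "unknown span")
})

test_that("genotyper matches the brute-force base-wise oracle", {
  set.seed(101)
  for (rep in 1:400) {
    locus <- random_locus()
    calls <- random_calls(locus)
    for (sp in locus$spans) {
      got <- as.character(assign_genotype(calls, locus, sp$name))
      want <- oracle_genotype(calls, locus, sp$name)
      if (!identical(got, want)) {
        fail(sprintf("mismatch at span %s: got %s, oracle %s",
                     sp$name, got, want))
      }
    }
  }
  succeed()
})

test_that("A-D deletion implies DEL positivity at each core span without flanking", {
  set.seed(7)
  locus <- default_catalog()[["22q11.2"]]
  stripped <- segmented_locus(locus$locus_id, locus$chrom, locus$segments,
    lapply(locus$spans, function(sp) { sp$flanking <- character(0); sp }))
  b <- function(nm) for (s in locus$segments) if (s$name == nm) return(s)
  for (i in 1:20) {
    s0 <- b("A-B")$start - round(runif(1, 0, 5e4))
    e0 <- b("C-D")$end + round(runif(1, 0, 4e5))
    calls <- data.frame(chrom = "chr22", start = s0, end = e0, state = "DEL")
    if (as.character(assign_genotype(calls, locus, "A-D")) == "DEL") {
      for (sp in c("A-B", "B-C", "C-D")) {
        expect_equal(as.character(assign_genotype(calls, stripped, sp)), "DEL")
      }
    }
  }
})

test_that("genotype matrix is order-invariant and defaults to REF", {
  set.seed(11)
  cat_ <- default_catalog()[c("1q21.1_TAR", "22q11.2")]
  class(cat_) <- "cnv_catalog"
  locus <- cat_[["22q11.2"]]
  b <- function(nm) for (s in locus$segments) if (s$name == nm) return(s)
  calls <- data.frame(
    chrom = "chr22",
    start = c(b("A-B")$start, b("A-B")$start, 18e6),
    end = c(b("C-D")$end, b("B-C")$end, 18.5e6),
    sample_id = c("s1", "s2", "s3"),
    state = c("DEL", "DUP", "DEL"), stringsAsFactors = FALSE)
  m1 <- genotype_matrix(calls, cat_, samples = c("s1", "s2", "s3", "s4"))
  m2 <- genotype_matrix(calls[c(3, 1, 2), ], cat_,
                        samples = c("s4", "s3", "s2", "s1"))
  expect_identical(m1, m2)
  expect_equal(m1$call[m1$sample_id == "s1" & m1$span == "A-D"], "DEL")
  expect_equal(m1$call[m1$sample_id == "s2" & m1$span == "A-C"], "DUP")
  # s4 has no calls at all, s3's call is outside every segment
  expect_true(all(m1$call[m1$sample_id %in% c("s3", "s4")] == "REF"))
  # empty callset with explicit samples -> all-REF matrix
  m0 <- genotype_matrix(calls[0, ], cat_, samples = c("a", "b"))
  expect_true(all(m0$call == "REF"))
  expect_equal(nrow(m0), 2 * 7)           # 2 samples x (1 + 6) spans
})

test_that("DEL/DUP conflicts are reported, not dropped", {
  cat_ <- default_catalog()["1q21.1_TAR"]
  class(cat_) <- "cnv_catalog"
  seg <- cat_[[1]]$segments[[1]]
  calls <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                      sample_id = "s1", state = c("DEL", "DUP"),
                      stringsAsFactors = FALSE)
  expect_message(m <- genotype_matrix(calls, cat_), "conflicting")
  expect_equal(m$call[m$sample_id == "s1"], "NO_CALL")
  expect_equal(nrow(attr(m, "conflicts")), 1)
})

test_that("enlarging a DEL call keeps the focal genotype until a flank trips", {
  set.seed(23)
  locus <- random_locus()
  # pick a span with at least one flanking segment if available
  sp <- locus$spans[[which.max(vapply(locus$spans, function(s)
    length(s$flanking), integer(1)))]]
  segs <- lapply(locus$segments, function(s) s)
  bounds <- range(unlist(lapply(segs, function(s) c(s$start, s$end))))
  base <- data.frame(chrom = "chrT", start = bounds[1], end = bounds[2],
                     state = "DEL")
  prev <- as.character(assign_genotype(base, locus, sp$name))
  for (grow in seq(0, 400, by = 25)) {
    g <- base
    g$end <- g$end + grow
    cur <- as.character(assign_genotype(g, locus, sp$name))
    expect_equal(cur, oracle_genotype(g, locus, sp$name))
  }
})

test_that("fraction-of-call mode is available as the bedtools-style variant", {
  seg <- cnv_segment("s", "chr1", 0, 1000)
  locus <- segmented_locus("L", "chr1", list(seg),
                           list(list(name = "s", segments = "s")))
  # huge call covering the whole segment: target-mode positive,
  # call-mode negative (only 10% of the call is in the segment)
  calls <- data.frame(chrom = "chr1", start = 0, end = 10000, state = "DEL")
  expect_equal(as.character(assign_genotype(calls, locus, "s")), "DEL")
  expect_equal(as.character(
    assign_genotype(calls, locus, "s", overlap_mode = "call")), "REF")
})
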