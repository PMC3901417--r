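test_that("collapsing conserves counts and tallies the length window", {
  s21 <- randomRna(21)
  reads <- data.frame(seq = c(s21, s21, randomRna(17)),
                      count = c(3L, 2L, 4L), stringsAsFactors = FALSE)
  tags <- collapseReads(reads)
  expect_equal(nrow(tags), 1)
  expect_equal(tags$count, 5L)
  expect_equal(attr(tags, "dropped_reads"), 4L)
  expect_equal(attr(tags, "raw_reads"), 9L)

  empty <- collapseReads(data.frame(seq = character(), count = integer()))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "raw_reads"), 0L)

  expect_error(collapseReads(data.frame(seq = "ACGXACGUACGUACGUACGU",
                                        count = 1L)), "non-alphabet")
})

test_that("the 18-25 preprocessing preset drops 26-nt reads", {
  reads <- data.frame(seq = c(randomRna(24), randomRna(26)),
                      count = c(1L, 1L))
  tags <- collapseReads(reads, minLen = 18, maxLen = 25)
  expect_equal(nchar(tags$seq), 24)
})

test_that("perfect mapping finds hits on both strands", {
  set.seed(31)
  genome <- c(chr1 = randomRna(400))
  tagF <- substr(genome[["chr1"]], 101, 121)
  tagR <- revCompRna(substr(genome[["chr1"]], 201, 222))
  tags <- data.frame(seq = c(tagF, tagR, randomRna(21)),
                     count = c(1L, 1L, 1L), stringsAsFactors = FALSE)
  mapped <- mapPerfect(tags, genome)
  h1 <- mapped$hits[[1]]
  expect_true(any(h1$start == 101 & h1$strand == "+"))
  h2 <- mapped$hits[[2]]
  expect_true(any(h2$start == 201 & h2$strand == "-"))
})

test_that("perfect mapping agrees with a naive scan on random tags", {
  set.seed(32)
  genome <- c(chr1 = randomRna(30000), chr2 = randomRna(20000))
  # mix genuine substrings (+/-) and random tags
  pick <- function() {
    w <- sample(18:25, 1)
    chrom <- sample(names(genome), 1)
    st <- sample(nchar(genome[[chrom]]) - w, 1)
    s <- substr(genome[[chrom]], st, st + w - 1)
    if (runif(1) < 0.5) s else revCompRna(s)
  }
  tags <- data.frame(seq = c(replicate(150, pick()),
                             replicate(50, randomRna(21))),
                     count = 1L, stringsAsFactors = FALSE)
  tags <- tags[!duplicated(tags$seq), ]
  mapped <- mapPerfect(tags, genome)
  for (i in seq_len(nrow(mapped))) {
    ref <- naiveScan(mapped$seq[i], genome)
    got <- mapped$hits[[i]]
    expect_equal(nrow(got), nrow(ref), info = mapped$seq[i])
    if (nrow(ref)) {
      o1 <- order(got$chrom, got$start, got$strand)
      o2 <- order(ref$chrom, ref$start, ref$strand)
      expect_equal(got[o1, ], ref[o2, ], ignore_attr = TRUE)
    }
  }
})

test_that("class assignment follows the structural-RNA precedence", {
  genome <- c(chr1 = paste(rep("A", 50), collapse = ""))
  tag <- paste(rep("A", 20), collapse = "")
  tags <- mapPerfect(data.frame(seq = tag, count = 1L), genome)
  track <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1), c(50, 50)))
  S4Vectors::mcols(track)$klass <- c("repeat", "rRNA")
  out <- classifyTags(tags, track)
  expect_equal(out$klass, "rRNA")

  S4Vectors::mcols(track)$klass <- c("exon", "repeat")
  expect_equal(classifyTags(tags, track)$klass, "repeat")

  far <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 50))
  S4Vectors::mcols(far)$klass <- "exon"
  expect_equal(classifyTags(tags, far)$klass, "unannotated")
})

test_that("the class partition is exhaustive and disjoint on random tracks", {
  set.seed(33)
  sim <- smallSim(seed = 14)
  reads <- simulateSrnaReads(sim$truth, sim$cfg)
  cen <- runCensus(reads, sim$genome, sim$annotation)
  part <- censusClasses(cen$report)
  tot <- censusTotals(cen$report)
  expect_equal(sum(part$distinct), unname(tot["mapped_distinct"]))
  expect_equal(sum(part$frac_distinct), 1)
  expect_equal(sum(part$frac_reads), 1)
  # conservation through the census
  expect_equal(unname(tot["filtered_reads"]), sum(cen$tags$count))
  expect_equal(unname(tot["mapped_reads"] + tot["unmapped_reads"]),
               unname(tot["filtered_reads"]))
  # random annotation never breaks the partition
  rnd <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 30, replace = TRUE),
    IRanges::IRanges(start = sample(1e4, 30), width = sample(50:500, 30)))
  S4Vectors::mcols(rnd)$klass <- sample(
    c("rRNA", "tRNA", "snRNA", "snoRNA", "other_sRNA", "repeat", "exon"),
    30, replace = TRUE)
  tags2 <- classifyTags(cen$tags, rnd)
  mapped <- tags2$n_hits > 0
  expect_true(all(!is.na(tags2$klass[mapped])))
  expect_true(all(is.na(tags2$klass[!mapped])))
})

test_that("simulated class read-fractions track the generator config", {
  cfg <- simConfig(nMirnas = 0, genomeLength = 5e4, nBackgroundLoci = 10,
                   readDepth = 3e4, seed = 15)
  g <- generateGenome(cfg)
  reads <- simulateSrnaReads(g$truth, cfg)
  cen <- runCensus(reads, g$genome, g$annotation)
  part <- censusClasses(cen$report)
  props <- cfg@backgroundClassProps
  for (k in setdiff(names(props), "unannotated")) {
    got <- part$frac_reads[part$klass == k]
    expect_lt(abs(got - props[[k]]), 0.02)
  }
})

test_that("size distribution is read-weighted and sums to one", {
  tags <- data.frame(seq = c(randomRna(21), randomRna(24)),
                     count = c(1L, 3L))
  sd <- sizeDistribution(tags)
  expect_equal(unname(sd[c("21", "24")]), c(0.25, 0.75))
  expect_equal(sum(sd), 1)
  one <- sizeDistribution(data.frame(seq = randomRna(22), count = 5L))
  expect_equal(unname(one), 1)
  expect_length(sizeDistribution(data.frame(seq = character(),
                                            count = integer())), 0)
})

test_that("default synthetic background length distribution peaks at 24 nt", {
  cfg <- simConfig(nMirnas = 0, genomeLength = 3e4, nBackgroundLoci = 5,
                   readDepth = 5000, seed = 16)
  g <- generateGenome(cfg)
  reads <- simulateSrnaReads(g$truth, cfg)
  sd <- sizeDistribution(collapseReads(reads))
  expect_equal(names(which.max(sd)), "24")
})

test_that("positional base bias is computed over long-enough tags", {
  tags <- data.frame(seq = c("UAGC", "GAGC"), count = c(1L, 1L))
  nb <- nucleotideBias(tags, positions = 1:4)
  expect_equal(nb["1", "U"], 0.5)
  expect_equal(nb["1", "G"], 0.5)
  expect_equal(rowSums(nb), c(`1` = 1, `2` = 1, `3` = 1, `4` = 1))

  allU <- data.frame(seq = c("UAAA", "UGGG"), count = c(2L, 1L))
  expect_equal(nucleotideBias(allU, positions = 1)["1", "U"], 1)
})

test_that("the printed novel-miRNA sequences start with U in 19/26 cases", {
  t1 <- loadFixture("table1")
  nb <- nucleotideBias(data.frame(seq = t1$sequence, count = 1L),
                       positions = 1, weighted = FALSE)
  expect_equal(nb["1", "U"], 19 / 26)
})
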