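test_that("the fold DP reproduces hand-derived minimum energies", {
  f <- foldHairpin("GGGGGAAAACCCCC")
  expect_equal(mfe(f), -15)
  expect_equal(nrow(basePairs(f)), 5)

  allA <- foldHairpin(paste(rep("A", 30), collapse = ""))
  expect_equal(mfe(allA), 0)
  expect_equal(nrow(basePairs(allA)), 0)

  expect_error(foldHairpin(randomRna(700)), "outside")
})

test_that("reported structure energy always equals the reported MFE", {
  set.seed(41)
  energy <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  for (rep in 1:25) {
    s <- randomRna(sample(20:80, 1))
    f <- foldHairpin(s)
    p <- basePairs(f)
    e <- 0
    if (nrow(p)) {
      ch <- strsplit(s, "")[[1]]
      e <- sum(energy[paste0(ch[p[, 1]], ch[p[, 2]])])
    }
    expect_equal(e, mfe(f))
    expect_lte(mfe(f), 0)
    if (nrow(p)) expect_true(all(p[, 2] - p[, 1] >= 4))
  }
})

test_that("the fold DP matches exhaustive enumeration on short sequences", {
  set.seed(42)
  for (rep in 1:50) {
    s <- randomRna(sample(8:18, 1))
    expect_equal(mfe(foldHairpin(s)), enumMfe(s), info = s)
  }
})

test_that("precursor excision returns oriented, clipped windows", {
  set.seed(43)
  genome <- c(chr1 = randomRna(1000))
  w <- excisePrecursor(genome, "chr1", 400, "+", 21)
  expect_equal(nchar(w$upstream$seq), 271)
  expect_equal(nchar(w$downstream$seq), 271)
  expect_equal(substr(w$upstream$seq, w$upstream$matureOffset,
                      w$upstream$matureOffset + 20),
               substr(genome[["chr1"]], 400, 420))

  # minus strand: the oriented window is the reverse complement
  wm <- excisePrecursor(genome, "chr1", 400, "-", 21)
  tag <- revCompRna(substr(genome[["chr1"]], 400, 420))
  expect_equal(substr(wm$upstream$seq, wm$upstream$matureOffset,
                      wm$upstream$matureOffset + 20), tag)

  # chromosome-start clipping
  wc <- excisePrecursor(genome, "chr1", 5, "+", 21)
  expect_equal(nchar(wc$upstream$seq), 25)
})

test_that("the exclusion ledger flags overlaps and the MFE threshold", {
  sim <- smallSim(seed = 17)
  mir <- truthMirnas(sim$truth)
  mk <- function(i, chrom, start, end) {
    f <- foldHairpin(mir$precursor[i])
    new("HairpinCandidate", chrom = chrom, start = start, end = end,
        strand = "+", sequence = mir$precursor[i], fold = f,
        matureSeq = mir$mature[i], matureOffset = mir$matureOffset[i],
        arm = mir$arm[i], matureCount = 10, starSeq = NA_character_,
        starOffset = NA_real_, starCount = NA_real_,
        ledger = c(exon_overlap = FALSE, repeat_overlap = FALSE,
                   mfe_fail = FALSE, pseudo = FALSE, not_hairpin = FALSE),
        status = "candidate", family = NA_character_)
  }
  ann <- sim$annotation
  exon <- ann[S4Vectors::mcols(ann)$klass == "exon"][1]
  inExon <- mk(1, as.character(GenomicRanges::seqnames(exon)),
               GenomicRanges::start(exon) + 2, GenomicRanges::start(exon) + 60)
  clean <- mk(2, "chr1", 1, 70)
  led <- applyExclusionLedger(list(inExon, clean), ann)
  expect_true(led$candidates[[1]]@ledger["exon_overlap"])
  expect_equal(led$candidates[[1]]@status, "excluded")
  expect_false(any(led$candidates[[2]]@ledger))
  expect_equal(led$summary$retained, 1)
  expect_equal(led$summary$total - led$summary$excluded,
               led$summary$retained)

  # MFE threshold direction: stable hairpins retained by default
  weak <- mk(3, "chr1", 500, 560)
  weak@fold@mfe <- -12
  strong <- mk(3, "chr1", 600, 660)
  strong@fold@mfe <- -25
  led2 <- applyExclusionLedger(list(weak, strong), NULL)
  expect_true(led2$candidates[[1]]@ledger["mfe_fail"])
  expect_false(led2$candidates[[2]]@ledger["mfe_fail"])
  # literal reading flips the comparison
  led3 <- applyExclusionLedger(list(weak, strong), NULL, mfeLiteral = TRUE)
  expect_false(led3$candidates[[1]]@ledger["mfe_fail"])
  expect_true(led3$candidates[[2]]@ledger["mfe_fail"])
})

test_that("duplex detection recovers the planted star with 2-nt overhangs", {
  sim <- smallSim(seed = 18)
  mir <- truthMirnas(sim$truth)
  tags <- data.frame(seq = c(mir$star[1], randomRna(21)),
                     count = c(6L, 2L), stringsAsFactors = FALSE)
  f <- foldHairpin(mir$precursor[1])
  dup <- detectDuplex(f, mir$matureOffset[1], nchar(mir$mature[1]),
                      tags = tags)
  expect_equal(dup$starSeq, mir$star[1])
  expect_equal(dup$starCount, 6L)
  # both duplex ends carry exactly 2-nt 3' overhangs by construction:
  # star spans partner(mature_end - 2) .. partner(mature_start) + 2
  p <- basePairs(f)
  partner <- integer(nchar(mir$precursor[1]))
  partner[p[, 1]] <- p[, 2]
  partner[p[, 2]] <- p[, 1]
  p1 <- mir$matureOffset[1]
  p2 <- p1 + nchar(mir$mature[1]) - 1
  expect_equal(dup$starStart, partner[p2 - 2])
  expect_equal(dup$starEnd, partner[p1] + 2)
})

test_that("duplexes with too many unpaired mature bases are rejected", {
  # hairpin whose 3' arm mismatches 5 mature bases: pairs drop out
  mature <- "GGGGGGGGGGGGGGGGGGGGG"          # 21 G
  star <- paste(c(rep("C", 14), rep("A", 5)), collapse = "")  # 5 unpaired
  prec <- paste0(mature, "AAAAAAAA", star, "AA")
  f <- foldHairpin(prec)
  expect_null(detectDuplex(f, 1, 21))
})

test_that("a mature spanning the terminal loop is a duplex error", {
  prec <- paste0(strrep("G", 15), "AAAA", strrep("C", 15))
  f <- foldHairpin(prec)
  expect_error(detectDuplex(f, 10, 12), "spans the terminal loop")
  expect_equal(classifyNovel(f, 10, 12), "pseudo")
})

test_that("known-family assignment respects the edit-distance threshold", {
  ref <- referenceMature()
  hit <- assignKnown(ref$mature[ref$family == "miR156"], ref)
  expect_equal(hit, "miR156")

  # distance exactly 3 (three insertions) is assigned, 4 is not
  q <- ref$mature[ref$family == "miR156"]
  q3 <- paste0(q, "GGA")
  expect_equal(assignKnown(q3, ref), "miR156")
  q4 <- paste0(q, "GGAC")
  expect_true(is.na(assignKnown(q4, ref)))

  # ties break to the lexicographically smallest family
  ref2 <- data.frame(family = c("miRB", "miRA"),
                     mature = c("UGACAGAAGAGAGUGAGCAC",
                                "UGACAGAAGAGAGUGAGCAC"))
  expect_equal(assignKnown("UGACAGAAGAGAGUGAGCAC", ref2), "miRA")
  expect_error(assignKnown("UGACAGAAGAGAGUGAGCAC",
                           ref2[integer(), ]), "empty")
})

test_that("shuffled precursors are overwhelmingly rejected as novel", {
  sim <- smallSim(seed = 19)
  mir <- truthMirnas(sim$truth)
  set.seed(44)
  n <- 200
  novel <- 0
  for (r in seq_len(n)) {
    i <- ((r - 1) %% nrow(mir)) + 1
    ch <- strsplit(mir$precursor[i], "")[[1]]
    shuf <- paste(sample(ch), collapse = "")
    f <- foldHairpin(shuf)
    off <- min(mir$matureOffset[i], nchar(shuf) - nchar(mir$mature[i]) + 1)
    if (classifyNovel(f, off, nchar(mir$mature[i])) == "novel")
      novel <- novel + 1
  }
  expect_lte(novel / n, 0.05)
})

test_that("mature deduplication pools loci without multiplying abundance", {
  rec <- data.frame(
    mature = c("UGGAAC", "UGGAAC", "UCCGGA"),
    loci = c(2L, 3L, 1L), abundance = c(10, 10, 4),
    family = c("famX", "famX", NA), stringsAsFactors = FALSE)
  out <- dedupeMature(rec)
  expect_equal(nrow(out), 2)
  merged <- out[out$mature == "UGGAAC", ]
  expect_equal(merged$nLoci, 5L)
  expect_equal(merged$abundance, 10)
})

test_that("deduplicating the printed novel-miRNA table gives 21 matures over 36 loci", {
  t1 <- loadFixture("table1")
  rec <- data.frame(mature = t1$sequence, loci = t1$loci,
                    abundance = t1$mirna_abundance, name = t1$mirna,
                    star = t1$star_seq, starCount = t1$star_abundance,
                    locus = t1$precursor_location, stringsAsFactors = FALSE)
  out <- dedupeMature(rec)
  expect_equal(nrow(out), 21)
  expect_equal(sum(out$nLoci), 36)
  expect_equal(sum(!is.na(out$star)), 3)  # 4 starred rows, s6a/b share one
})

test_that("discovery recovers planted miRNAs on a small clean simulation", {
  sim <- smallSim(seed = 20, jitterFraction = 0)
  reads <- simulateSrnaReads(sim$truth, sim$cfg)
  res <- discoverMirnas(reads, sim$genome, sim$annotation,
                        referenceMature())
  sc <- scoreDiscovery(res, sim$truth)
  expect_equal(sc$sensitivity, 1)
  # at this toy scale a single background hairpin dominates precision;
  # the study-scale precision bound lives in the acceptance suite
  expect_gte(sc$precision, 0.8)
  # ledger arithmetic holds
  led <- res$ledger
  expect_equal(led$total - led$excluded, led$retained)
  # star evidence: recovered planted calls carry the planted star
  mir <- truthMirnas(sim$truth)
  tab <- res$table
  hit <- tab[tab$mature == mir$mature[1] & tab$status == "novel", ]
  if (nrow(hit)) expect_equal(hit$star[1], mir$star[1])
})
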