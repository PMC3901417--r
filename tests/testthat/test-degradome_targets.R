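mkTx <- function(seqs, u5 = 0.15, u3 = 0.25) {
  segs <- do.call(rbind, lapply(names(seqs), function(tx) {
    L <- nchar(seqs[[tx]])
    a <- round(u5 * L)
    b <- round((1 - u3) * L)
    data.frame(transcript_id = tx, gene_id = sub("tx", "gene", tx),
               region = c("five_prime_utr", "cds", "three_prime_utr"),
               tx_start = c(1, a + 1, b + 1), tx_end = c(a, b, L),
               stringsAsFactors = FALSE)
  }))
  new("TranscriptSet", sequences = seqs, segments = segs)
}

mkProfile <- function(posCounts, stage = "I", transcript = "tx1") {
  pos <- as.integer(names(posCounts))
  new("DegradomeProfile", transcript = transcript, stage = stage,
      positions = data.frame(pos = pos, raw = as.numeric(posCounts),
                             norm = as.numeric(posCounts))[order(pos), ])
}

test_that("tag placement applies repeat normalization and conserves counts", {
  set.seed(51)
  block <- randomRna(40)
  seqs <- c(tx1 = paste0(randomRna(60), block, randomRna(30)),
            tx2 = paste0(randomRna(20), block, randomRna(80)),
            tx3 = paste0(block, randomRna(90)))
  txs <- mkTx(seqs)
  shared <- substr(block, 5, 24)         # places once in each transcript
  unique1 <- substr(seqs[["tx1"]], 5, 24)
  tags <- data.frame(seq = c(shared, unique1, randomRna(20)),
                     count = c(6L, 3L, 9L), stringsAsFactors = FALSE)
  pl <- placeTags(tags, txs)
  expect_equal(pl$tags$nPlacements, c(3L, 1L, 0L))
  expect_equal(pl$unplaced, 1L)
  # each of the 3 placements of the shared tag receives 6/3 = 2
  expect_true(all(pl$placements$norm[pl$placements$tag == 1] == 2))
  # conservation: summed normalized abundance = summed placed raw counts
  expect_equal(sum(pl$placements$norm), 6 + 3)

  # count 1 on 3 placements -> 0.33 each
  tags2 <- data.frame(seq = shared, count = 1L)
  pl2 <- placeTags(tags2, txs)
  expect_equal(pl2$placements$norm, rep(1 / 3, 3))
})

test_that("placement rejects short transcripts and odd tag lengths", {
  txsShort <- mkTx(c(tx1 = randomRna(15)))
  expect_error(placeTags(data.frame(seq = randomRna(20), count = 1L),
                         txsShort), ">= 20 nt")
  txs <- mkTx(c(tx1 = randomRna(100)))
  expect_error(placeTags(data.frame(seq = randomRna(25), count = 1L),
                         txs), "unaccepted length")
})

test_that("alignment scoring follows the plant-target penalty scheme", {
  set.seed(52)
  mir <- randomRna(21)
  site <- revCompRna(mir)
  al <- alignMirnaSite(mir, site)
  expect_equal(al$score, 0)

  # G:U wobble at miRNA position 5 (core): 0.5 x 2
  m <- strsplit(mir, "")[[1]]
  m[5] <- "G"
  mir2 <- paste(m, collapse = "")
  site2 <- strsplit(revCompRna(mir2), "")[[1]]
  site2[21 - 5 + 1] <- "U"
  al2 <- alignMirnaSite(mir2, paste(site2, collapse = ""))
  expect_equal(al2$score, 1)

  # mismatch at position 20 (outside the core): 1, undoubled. A base never
  # pairs itself, so copying the miRNA base into the site is a mismatch.
  site3 <- strsplit(revCompRna(mir), "")[[1]]
  site3[21 - 20 + 1] <- substr(mir, 20, 20)
  al3 <- alignMirnaSite(mir, paste(site3, collapse = ""))
  expect_equal(al3$score, 1)
})

test_that("alignment equals brute-force enumeration on random windows", {
  set.seed(53)
  for (r in 1:25) {
    mir <- randomRna(sample(20:22, 1))
    window <- if (r %% 2) paste0(randomRna(4), revCompRna(mir),
                                 randomRna(4)) else randomRna(30)
    got <- alignMirnaSite(mir, window, threshold = Inf)
    expect_equal(got$score, bruteAlignScore(mir, window), info = window)
  }
})

test_that("the cleavage site sits opposite miRNA nt 10", {
  mir <- randomRna(21)
  al <- alignMirnaSite(mir, revCompRna(mir), windowStart = 101)
  expect_equal(al$siteStart, 101)
  expect_equal(al$siteEnd, 121)
  expect_equal(predictedCleavageSite(al), 112)  # e - 9

  al2 <- alignMirnaSite(mir, revCompRna(mir), windowStart = 1)
  expect_equal(predictedCleavageSite(al2), 12)

  mir22 <- randomRna(22)
  al3 <- alignMirnaSite(mir22, revCompRna(mir22), windowStart = 50)
  expect_equal(al3$siteEnd, 71)
  expect_equal(predictedCleavageSite(al3), 62)
})

test_that("category classification follows the tiered definitions", {
  p1 <- mkProfile(c(`10` = 5, `50` = 2, `90` = 1))
  expect_equal(categorizeTarget(p1, 10)$category, 0L)

  p2 <- mkProfile(c(`10` = 5, `50` = 5, `90` = 1))
  expect_equal(categorizeTarget(p2, 10)$category, 1L)

  p3 <- mkProfile(c(`10` = 3, `20` = 5, `30` = 1, `40` = 1))
  c3 <- categorizeTarget(p3, 10)
  expect_equal(c3$median, 2)
  expect_equal(c3$category, 2L)
  expect_equal(categorizeTarget(p3, 30)$category, 4L)  # raw = 1 wins
  p4 <- mkProfile(c(`10` = 3, `20` = 5, `30` = 2, `40` = 1))
  expect_equal(categorizeTarget(p4, 30)$category, 3L)

  # single raw read -> category 4 regardless of being the maximum
  p5 <- mkProfile(c(`10` = 1))
  expect_equal(categorizeTarget(p5, 10)$category, 4L)

  # no raw signal is distinct from category 3
  expect_true(is.na(categorizeTarget(p1, 77)$category))
  expect_equal(categorizeTarget(p1, 77)$status, "no_signal")

  # all-tied profiles resolve by the maximum tests, not category 3
  p6 <- mkProfile(c(`10` = 4, `20` = 4, `30` = 4))
  expect_equal(categorizeTarget(p6, 20)$category, 1L)
})

test_that("categories 0-3 are invariant to scaling normalized abundance", {
  set.seed(54)
  for (r in 1:30) {
    n <- sample(3:12, 1)
    pos <- sort(sample(500, n))
    raw <- sample(2:50, n, replace = TRUE)  # raw > 1 avoids category 4
    for (c0 in c(0.01, 1, 137)) {
      prof <- new("DegradomeProfile", transcript = "tx", stage = "I",
                  positions = data.frame(pos = pos, raw = raw,
                                         norm = raw * c0))
      s <- sample(pos, 1)
      base <- categorizeTarget(
        new("DegradomeProfile", transcript = "tx", stage = "I",
            positions = data.frame(pos = pos, raw = raw, norm = raw)), s)
      expect_equal(categorizeTarget(prof, s)$category, base$category)
    }
  }
})

test_that("target calling recovers a planted site with its region label", {
  set.seed(55)
  mir <- c(guide1 = randomRna(21))
  tx <- randomRna(300)
  b <- 231                                  # inside the 3'-UTR (226-300)
  e <- b + 20
  substr(tx, b, e) <- revCompRna(mir[[1]])
  s <- e - 9
  txs <- mkTx(c(tx1 = tx))
  counts <- setNames(c(20, 2, 2, 1), c(s, 40, 90, 150))
  profs <- list(I = list(tx1 = mkProfile(counts)))
  calls <- callTargets(mir, txs, profs)
  hit <- calls[calls$site == s & calls$mirna == "guide1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$category, 0L)
  expect_equal(hit$region, "3'-UTR")
  # an unrelated guide produces no call at the threshold
  none <- callTargets(c(x = randomRna(21)), txs, profs)
  expect_equal(nrow(none), 0)
})

test_that("random guides essentially never score under the cutoff", {
  set.seed(56)
  tx <- randomRna(500)
  txs <- mkTx(c(tx1 = tx))
  counts <- setNames(rep(3, 20), sample(30:470, 20))
  profs <- list(I = list(tx1 = mkProfile(counts)))
  guides <- setNames(vapply(1:40, function(i) randomRna(21), ""),
                     paste0("g", 1:40))
  calls <- callTargets(guides, txs, profs)
  expect_lte(nrow(calls), 1)  # 800 guide x site trials, cutoff 7
})

test_that("cross-stage merging reproduces the printed table layout", {
  set.seed(57)
  mir <- c(gA = randomRna(21))
  tx <- randomRna(200)
  b <- 100; e <- 120
  substr(tx, b, e) <- revCompRna(mir[[1]])
  s <- e - 9
  txs <- mkTx(c(tx1 = tx))
  profs <- list(
    I = list(tx1 = mkProfile(setNames(c(20, 2), c(s, 30)))),
    III = list(tx1 = mkProfile(setNames(c(8, 8), c(s, 30)))))
  calls <- callTargets(mir, txs, profs)
  mg <- mergeStages(calls)
  expect_equal(nrow(mg$table), 1)
  expect_match(mg$table$I, "^20\\.00 \\(0\\)$")
  expect_match(mg$table$III, "\\(1\\)$")
  expect_equal(mg$table$II, "")
  expect_equal(mg$summary$n_genes, 1)
  expect_equal(mg$summary$genes_all_stages, 0)
})

test_that("fixture target tables give the printed per-family gene counts", {
  t3 <- loadFixture("table3")
  st3 <- targetSummary(t3)
  expect_equal(unname(st3$perMirna["miR156"]), 13L)
  expect_equal(unname(st3$perMirna["miR529"]), 18L)

  t4 <- loadFixture("table4")
  st4 <- targetSummary(t4)
  expect_equal(st4$nMirnas, 7L)
})
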