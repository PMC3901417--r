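# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Pure recursive enumeration of nested structures (no memoisation): the
# minimum total pair energy over every nested structure with hairpin loops
# of at least minLoop unpaired bases.
enumMfe <- function(seq, minLoop = 3) {
  ch <- strsplit(seq, "")[[1]]
  pairE <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(-1)
    NA_real_
  }
  rec <- function(i, j) {
    if (j - i < minLoop + 1) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - minLoop - 1)) {
      e <- pairE(ch[k], ch[j])
      if (is.na(e)) next
      cand <- e + (if (k > i) rec(i, k - 1) else 0) + rec(k + 1, j - 1)
      if (cand < best) best <- cand
    }
    best
  }
  rec(1, length(ch))
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

revCompRna <- function(x) {
  ch <- rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]])
  paste(ch, collapse = "")
}

# Naive O(n*m) perfect-match scan over both strands.
naiveScan <- function(tag, genome) {
  hits <- data.frame(chrom = character(), start = integer(),
                     strand = character(), stringsAsFactors = FALSE)
  w <- nchar(tag)
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < w) next
    starts <- seq_len(L - w + 1)
    kmers <- substring(s, starts, starts + w - 1)
    fw <- starts[kmers == tag]
    rv <- starts[kmers == revCompRna(tag)]
    if (length(fw))
      hits <- rbind(hits, data.frame(chrom = chrom, start = fw,
                                     strand = "+"))
    if (length(rv))
      hits <- rbind(hits, data.frame(chrom = chrom, start = rv,
                                     strand = "-"))
  }
  hits
}

# Brute-force plant-target alignment score: every placement and every
# single-gap variant, scored by independent loops.
bruteAlignScore <- function(mir, window, mismatch = 1, wobble = 0.5,
                            gapPen = 1) {
  m <- strsplit(mir, "")[[1]]
  win <- strsplit(window, "")[[1]]
  L <- length(m)
  W <- length(win)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  pen1 <- function(i, sb) {
    mult <- if (i >= 2 && i <= 13) 2 else 1
    if (sb == comp[[m[i]]]) 0
    else if ((m[i] == "G" && sb == "U") || (m[i] == "U" && sb == "G"))
      wobble * mult
    else mismatch * mult
  }
  best <- Inf
  for (o in seq_len(max(0, W - L + 1))) {
    s <- sum(vapply(seq_len(L), function(i) pen1(i, win[o + L - i]), 0))
    best <- min(best, s)
  }
  if (W >= L + 1) {
    for (o in seq_len(W - L)) {
      site <- win[o:(o + L)]
      for (g in 2:L) {
        i0 <- L + 1 - g
        s <- gapPen * (if (i0 >= 2 && i0 <= 13) 2 else 1)
        for (i in seq_len(L)) {
          j <- if (L + 2 - i > g) L + 2 - i else L + 1 - i
          s <- s + pen1(i, site[j])
        }
        best <- min(best, s)
      }
    }
  }
  if (W >= L - 1 && L > 2) {
    for (o in seq_len(W - (L - 1) + 1)) {
      site <- win[o:(o + L - 2)]
      for (g in 2:(L - 1)) {
        s <- gapPen * (if (g >= 2 && g <= 13) 2 else 1)
        jj <- L - 1
        for (i in seq_len(L)) {
          if (i == g) next
          s <- s + pen1(i, site[jj])
          jj <- jj - 1
        }
        best <- min(best, s)
      }
    }
  }
  best
}

# Small shared simulation for cross-module tests (kept light on purpose).
smallSim <- function(seed = 7, ...) {
  cfg <- simConfig(nMirnas = 5, genomeLength = 3e4, nBackgroundLoci = 5,
                   readDepth = 5000, nTranscripts = 20, seed = seed, ...)
  g <- generateGenome(cfg)
  list(cfg = cfg, genome = g$genome, annotation = g$annotation,
       truth = g$truth)
}
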