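#' @include AllClasses.R
#' @importFrom stats rpois rnorm runif aggregate median pf pt qt setNames
NULL

RNA_BASES <- c("A", "C", "G", "U")
STAGES <- c("I", "II", "III", "IV")

.rnaComp <- function(x) chartr("ACGU", "UGCA", x)
.rnaRevComp <- function(x) {
  vapply(strsplit(.rnaComp(x), ""),
         function(ch) paste(rev(ch), collapse = ""), "")
}
.randSeq <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                              collapse = "")

#' Build a simulation configuration
#'
#' See \code{\linkS4class{SimConfig}} for the meaning of each parameter.
#' Defaults are the package's standard study conditions; the background
#' read-length distribution peaks at 24 nt with secondary modes at 21/22 nt,
#' echoing the observed shape of plant small-RNA libraries.
#'
#' @param genomeLength,nChromosomes,nMirnas,nBackgroundLoci,readDepth see slots
#' @param matureStarRatio,plantedReadFraction,jitterFraction see slots
#' @param backgroundClassProps,backgroundLengthProbs,matureLengthProbs see slots
#' @param loopLenRange,nTranscripts,transcriptLength see slots
#' @param degradomeSignalRatio,degradomeBackgroundMean,degradomeOccupancy see slots
#' @param nStages,nReplicates,nProbes,nDEProbes,stageEffect,noiseSd see slots
#' @param baselineMean,exactCounts,seed see slots
#' @return a validated \code{SimConfig}
#' @export
simConfig <- function(genomeLength = 1e5, nChromosomes = 2, nMirnas = 30,
                      nBackgroundLoci = 30, readDepth = 5e4,
                      matureStarRatio = 100, plantedReadFraction = 0.3,
                      jitterFraction = 0.1,
                      backgroundClassProps = c(
                        exon = 0.25, "repeat" = 0.35, rRNA = 0.05,
                        tRNA = 0.01, snRNA = 0.005, snoRNA = 0.005,
                        other_sRNA = 0.08, unannotated = 0.25),
                      backgroundLengthProbs = c(
                        "18" = 0.025, "19" = 0.025, "20" = 0.05,
                        "21" = 0.088, "22" = 0.142, "23" = 0.07,
                        "24" = 0.486, "25" = 0.04, "26" = 0.025,
                        "27" = 0.02, "28" = 0.012, "29" = 0.009,
                        "30" = 0.008),
                      matureLengthProbs = c(
                        "20" = 0.12, "21" = 0.60, "22" = 0.28),
                      loopLenRange = c(8, 15), nTranscripts = 100,
                      transcriptLength = 600, degradomeSignalRatio = 10,
                      degradomeBackgroundMean = 2, degradomeOccupancy = 0.15,
                      nStages = 4, nReplicates = 4, nProbes = 200,
                      nDEProbes = 20, stageEffect = 2, noiseSd = 0.5,
                      baselineMean = 10, exactCounts = FALSE, seed = 1) {
  new("SimConfig", genomeLength = genomeLength, nChromosomes = nChromosomes,
      nMirnas = nMirnas, nBackgroundLoci = nBackgroundLoci,
      readDepth = readDepth, matureStarRatio = matureStarRatio,
      plantedReadFraction = plantedReadFraction,
      jitterFraction = jitterFraction,
      backgroundClassProps = backgroundClassProps,
      backgroundLengthProbs = backgroundLengthProbs,
      matureLengthProbs = matureLengthProbs, loopLenRange = loopLenRange,
      nTranscripts = nTranscripts, transcriptLength = transcriptLength,
      degradomeSignalRatio = degradomeSignalRatio,
      degradomeBackgroundMean = degradomeBackgroundMean,
      degradomeOccupancy = degradomeOccupancy, nStages = nStages,
      nReplicates = nReplicates, nProbes = nProbes, nDEProbes = nDEProbes,
      stageEffect = stageEffect, noiseSd = noiseSd,
      baselineMean = baselineMean, exactCounts = exactCounts, seed = seed)
}

# Build one precursor around a mature sequence: the duplex is constructed
# first (star = shifted complement of the mature, leaving 2-nt 3' overhangs
# on both duplex ends), then a terminal loop, a perfectly paired lower stem
# and the arm order. G:U wobbles are planted by swapping the star base
# where the mature base is G.
.buildPrecursor <- function(matureLen, loopRange, wobbleProb = 0.1,
                            extLen = 10) {
  L <- matureLen
  firstBase <- sample(c("U", RNA_BASES), 1, prob = c(0.8, rep(0.05, 4)))
  mature <- paste0(firstBase, .randSeq(L - 1))
  mch <- strsplit(mature, "")[[1]]
  star <- character(L)
  for (j in seq_len(L - 2)) {
    b <- mch[L - j - 1]
    star[j] <- .rnaComp(b)
    if (b == "G" && runif(1) < wobbleProb) star[j] <- "U"
  }
  # 2-nt star 3' overhang: avoid bases that could pair the first mature
  # bases and extend the duplex past the planted geometry
  wob <- function(b) switch(b, G = "U", U = "G", NA_character_)
  forbid <- stats::na.omit(c(.rnaComp(mch[1]), wob(mch[1]),
                             .rnaComp(mch[2]), wob(mch[2])))
  pool <- setdiff(c("A", "C"), forbid)
  if (!length(pool)) pool <- setdiff(RNA_BASES, forbid)
  if (!length(pool)) pool <- "A"
  star[c(L - 1, L)] <- sample(pool, 2, replace = TRUE)
  star <- paste(star, collapse = "")
  loopLen <- sample(seq(loopRange[1], loopRange[2]), 1)
  loop <- .randSeq(loopLen)
  ext5 <- .randSeq(extLen)
  ext3 <- .rnaRevComp(ext5)
  arm <- sample(c("5p", "3p"), 1)
  if (arm == "5p") {
    seq <- paste0(ext5, mature, loop, star, ext3)
    matureOffset <- extLen + 1L
  } else {
    seq <- paste0(ext5, star, loop, mature, ext3)
    matureOffset <- extLen + L + loopLen + 1L
  }
  list(mature = mature, star = star, sequence = seq, arm = arm,
       matureOffset = matureOffset, loopLen = loopLen)
}

.placeLoci <- function(occupied, chromLens, width, tries = 1000) {
  for (i in seq_len(tries)) {
    chrom <- sample(seq_along(chromLens), 1)
    if (chromLens[chrom] < width) next
    start <- sample(chromLens[chrom] - width + 1, 1)
    iv <- c(start, start + width - 1)
    hits <- occupied[[chrom]]
    if (!nrow(hits) || all(iv[2] < hits[, 1] - 1 | iv[1] > hits[, 2] + 1)) {
      return(list(chrom = chrom, start = start, end = iv[2]))
    }
  }
  NULL
}

#' Generate a toy genome with planted miRNA precursors
#'
#' Precursors are built duplex-first so they are foldable by construction,
#' then each is certified against the package's own discovery rules
#' (\code{\link{foldHairpin}}, \code{\link{detectDuplex}},
#' \code{\link{classifyNovel}}) before being embedded; background loci of
#' the seven annotation classes are placed disjoint from the precursors.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with elements \code{genome} (\code{RNAStringSet}),
#'   \code{annotation} (\code{GRanges} with klass), \code{truth}
#'   (\code{TruthSet})
#' @export
generateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nMir <- config@nMirnas
  nChrom <- config@nChromosomes
  chromLens <- rep(floor(config@genomeLength / nChrom), nChrom)
  chromNames <- paste0("chr", seq_len(nChrom))

  bgClasses <- setdiff(names(config@backgroundClassProps), "unannotated")
  bgWidths <- if (length(bgClasses) && config@nBackgroundLoci > 0) {
    sample(80:200, length(bgClasses) * config@nBackgroundLoci,
           replace = TRUE)
  } else integer()
  precWidthMax <- 2 * 22 + config@loopLenRange[2]
  needed <- nMir * precWidthMax + sum(bgWidths)
  if (needed > 0.6 * config@genomeLength)
    stop("capacity error: cannot place ", nMir, " precursors and ",
         length(bgWidths), " background loci in a ", config@genomeLength,
         "-nt genome without overlap")

  occupied <- replicate(nChrom, matrix(numeric(0), 0, 2), simplify = FALSE)
  mirnas <- NULL
  if (nMir > 0) {
    rows <- vector("list", nMir)
    lens <- as.integer(sample(names(config@matureLengthProbs), nMir,
                              replace = TRUE,
                              prob = config@matureLengthProbs))
    for (i in seq_len(nMir)) {
      prec <- NULL
      for (try in 1:50) {
        cand <- .buildPrecursor(lens[i], config@loopLenRange)
        fold <- foldHairpin(cand$sequence)
        dup <- tryCatch(
          detectDuplex(fold, cand$matureOffset, nchar(cand$mature)),
          error = function(e) NULL)
        cls <- classifyNovel(fold, cand$matureOffset, nchar(cand$mature))
        if (!is.null(dup) && cls == "novel" &&
            identical(dup$starSeq, cand$star)) { prec <- cand; break }
      }
      if (is.null(prec))
        stop("could not certify a planted precursor after 50 attempts")
      pos <- .placeLoci(occupied, chromLens, nchar(prec$sequence))
      if (is.null(pos))
        stop("capacity error: no room left for precursor ", i)
      occupied[[pos$chrom]] <- rbind(occupied[[pos$chrom]],
                                     c(pos$start, pos$end))
      strand <- sample(c("+", "-"), 1)
      rows[[i]] <- data.frame(
        name = sprintf("miRsim%d", i), mature = prec$mature,
        star = prec$star, arm = prec$arm,
        matureOffset = prec$matureOffset,
        chrom = chromNames[pos$chrom], start = pos$start, end = pos$end,
        strand = strand, family = "novel", precursor = prec$sequence,
        stringsAsFactors = FALSE)
    }
    mirnas <- do.call(rbind, rows)
  } else {
    mirnas <- data.frame(name = character(), mature = character(),
                         star = character(), arm = character(),
                         matureOffset = numeric(), chrom = character(),
                         start = numeric(), end = numeric(),
                         strand = character(), family = character(),
                         precursor = character(), stringsAsFactors = FALSE)
  }

  bgRows <- list()
  k <- 0
  for (klass in bgClasses) {
    for (j in seq_len(config@nBackgroundLoci)) {
      k <- k + 1
      pos <- .placeLoci(occupied, chromLens, bgWidths[k])
      if (is.null(pos))
        stop("capacity error: no room left for background loci")
      occupied[[pos$chrom]] <- rbind(occupied[[pos$chrom]],
                                     c(pos$start, pos$end))
      bgRows[[k]] <- data.frame(
        chrom = chromNames[pos$chrom], start = pos$start, end = pos$end,
        klass = klass, strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE)
    }
  }
  background <- if (length(bgRows)) do.call(rbind, bgRows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               klass = character(), strand = character(),
               stringsAsFactors = FALSE)

  # unannotated source regions for the unannotated read class
  if ("unannotated" %in% names(config@backgroundClassProps) &&
      config@backgroundClassProps[["unannotated"]] > 0) {
    for (j in seq_len(max(5, config@nBackgroundLoci))) {
      pos <- .placeLoci(occupied, chromLens, 150)
      if (is.null(pos)) break
      occupied[[pos$chrom]] <- rbind(occupied[[pos$chrom]],
                                     c(pos$start, pos$end))
      background <- rbind(background, data.frame(
        chrom = chromNames[pos$chrom], start = pos$start, end = pos$end,
        klass = "unannotated", strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE))
    }
  }

  genome <- vapply(chromLens, .randSeq, "")
  names(genome) <- chromNames
  if (nrow(mirnas)) {
    for (i in seq_len(nrow(mirnas))) {
      ins <- mirnas$precursor[i]
      if (mirnas$strand[i] == "-") ins <- .rnaRevComp(ins)
      ci <- mirnas$chrom[i]
      substr(genome[[ci]], mirnas$start[i], mirnas$end[i]) <- ins
    }
  }
  background$seq <- vapply(seq_len(nrow(background)), function(i) {
    s <- substr(genome[[background$chrom[i]]], background$start[i],
                background$end[i])
    if (background$strand[i] == "-") .rnaRevComp(s) else s
  }, "")

  ann <- background[background$klass != "unannotated", ]
  annotation <- GRanges(ann$chrom, IRanges(ann$start, ann$end), strand = "*")
  mcols(annotation)$klass <- ann$klass

  truth <- new("TruthSet", mirnas = mirnas,
               cleavages = data.frame(mirna = character(),
                                      transcript = character(),
                                      site = numeric(), strength = numeric(),
                                      stringsAsFactors = FALSE),
               de = .plantDe(config), background = background,
               config = config)
  list(genome = Biostrings::RNAStringSet(genome), annotation = annotation,
       truth = truth)
}

.plantDe <- function(config) {
  if (config@nDEProbes == 0 || config@stageEffect == 0)
    return(data.frame(probe = character(), I = numeric(), II = numeric(),
                      III = numeric(), IV = numeric(),
                      stringsAsFactors = FALSE))
  off <- matrix(0, config@nDEProbes, config@nStages)
  up <- sample(seq_len(config@nStages), config@nDEProbes, replace = TRUE)
  off[cbind(seq_len(config@nDEProbes), up)] <- config@stageEffect
  de <- data.frame(probe = sprintf("probe_%d", seq_len(config@nDEProbes)),
                   stringsAsFactors = FALSE)
  for (s in seq_len(config@nStages)) de[[STAGES[s]]] <- off[, s]
  de
}

.maybePois <- function(lambda, exact) {
  if (exact) round(lambda) else rpois(length(lambda), lambda)
}

#' Simulate a small-RNA read multiset
#'
#' Planted mature/star reads are drawn at the configured mature:star ratio;
#' a configurable fraction of planted reads receives 1-2 nt 5'/3' end
#' jitter (the jittered sequence is the correspondingly shifted precursor
#' substring, so it still maps). Background reads are sampled from the
#' annotation-class loci with the configured class and length distributions.
#'
#' @param truth \code{TruthSet} from \code{\link{generateGenome}}
#' @param config the same \code{SimConfig}
#' @return data.frame of distinct tags (seq, count); total read count is
#'   within 1 percent of \code{readDepth}
#' @export
simulateSrnaReads <- function(truth, config) {
  stopifnot(is(truth, "TruthSet"))
  set.seed(config@seed + 1L)
  mir <- truth@mirnas
  out <- list()

  nPlanted <- config@plantedReadFraction * config@readDepth
  if (nrow(mir) && nPlanted > 0) {
    perMature <- nPlanted / (nrow(mir) * (1 + 1 / config@matureStarRatio))
    perStar <- perMature / config@matureStarRatio
    for (i in seq_len(nrow(mir))) {
      mcount <- .maybePois(perMature, config@exactCounts)
      scount <- .maybePois(perStar, config@exactCounts)
      mlen <- nchar(mir$mature[i])
      njit <- if (config@jitterFraction > 0)
        round(mcount * config@jitterFraction) else 0
      if (njit > 0) {
        shifts <- expand.grid(s5 = -2:2, s3 = -2:2)
        shifts <- shifts[!(shifts$s5 == 0 & shifts$s3 == 0), ]
        pick <- shifts[sample(nrow(shifts), njit, replace = TRUE), ]
        from <- pmax(1, mir$matureOffset[i] + pick$s5)
        to <- pmin(nchar(mir$precursor[i]),
                   mir$matureOffset[i] + mlen - 1 + pick$s3)
        jseq <- substr(rep(mir$precursor[i], njit), from, to)
        out[[length(out) + 1]] <- data.frame(seq = jseq, count = 1L,
                                             stringsAsFactors = FALSE)
      }
      out[[length(out) + 1]] <- data.frame(
        seq = c(mir$mature[i], mir$star[i]),
        count = c(mcount - njit, scount), stringsAsFactors = FALSE)
    }
  }

  nBg <- round(config@readDepth - nPlanted)
  props <- config@backgroundClassProps
  if (nBg > 0 && nrow(truth@background)) {
    classCounts <- as.vector(stats::rmultinom(1, nBg, props))
    names(classCounts) <- names(props)
    lens <- as.integer(names(config@backgroundLengthProbs))
    for (klass in names(classCounts)) {
      n <- classCounts[[klass]]
      if (n == 0) next
      loci <- truth@background[truth@background$klass == klass, ]
      if (!nrow(loci)) next
      li <- sample(nrow(loci), n, replace = TRUE)
      rl <- sample(lens, n, replace = TRUE,
                   prob = config@backgroundLengthProbs)
      width <- nchar(loci$seq[li])
      rl <- pmin(rl, width)
      st <- floor(runif(n) * (width - rl + 1)) + 1
      out[[length(out) + 1]] <- data.frame(
        seq = substr(loci$seq[li], st, st + rl - 1), count = 1L,
        stringsAsFactors = FALSE)
    }
  }

  reads <- do.call(rbind, out)
  reads <- reads[reads$count > 0 & nchar(reads$seq) > 0, ]
  agg <- aggregate(count ~ seq, data = reads, FUN = sum)
  agg <- agg[order(-agg$count, agg$seq), ]
  rownames(agg) <- NULL
  agg
}

#' Simulate target transcripts and plant cleavage sites
#'
#' Each transcript carries the exact reverse complement of one planted
#' mature miRNA; the planted cleavage coordinate is the transcript position
#' pairing miRNA nt 10 (site 3' end minus 9), the expected 5' end of the
#' degradome tag.
#'
#' @param truth \code{TruthSet} from \code{\link{generateGenome}}
#' @param config the same \code{SimConfig}
#' @return list with \code{transcripts} (\code{TranscriptSet}) and
#'   \code{truth} (updated with planted cleavages)
#' @export
simulateTranscripts <- function(truth, config) {
  stopifnot(is(truth, "TruthSet"))
  set.seed(config@seed + 2L)
  L <- config@transcriptLength
  n <- config@nTranscripts
  u5 <- round(0.15 * L)
  u3start <- round(0.75 * L) + 1
  seqs <- character(n)
  segs <- vector("list", n)
  clv <- list()
  mir <- truth@mirnas
  for (t in seq_len(n)) {
    tx <- sprintf("tx_%03d", t)
    seqs[t] <- .randSeq(L)
    segs[[t]] <- data.frame(
      transcript_id = tx, gene_id = sprintf("gene_%03d", t),
      region = c("five_prime_utr", "cds", "three_prime_utr"),
      tx_start = c(1, u5 + 1, u3start),
      tx_end = c(u5, u3start - 1, L), stringsAsFactors = FALSE)
    if (nrow(mir)) {
      i <- (t - 1) %% nrow(mir) + 1
      ml <- nchar(mir$mature[i])
      b <- sample(seq(20, L - 40 - ml), 1)
      e <- b + ml - 1
      substr(seqs[t], b, e) <- .rnaRevComp(mir$mature[i])
      clv[[length(clv) + 1]] <- data.frame(
        mirna = mir$name[i], transcript = tx, site = e - 9,
        site_start = b, site_end = e,
        strength = config@degradomeSignalRatio, stringsAsFactors = FALSE)
    }
  }
  names(seqs) <- sprintf("tx_%03d", seq_len(n))
  ts <- new("TranscriptSet", sequences = seqs,
            segments = do.call(rbind, segs))
  truth@cleavages <- if (length(clv)) do.call(rbind, clv) else
    truth@cleavages
  list(transcripts = ts, truth = truth)
}

#' Simulate per-stage degradome tag sets
#'
#' Background tag 5' ends are placed with an exponential decay toward the
#' transcript 3' end; at each planted cleavage site the expected tag count
#' is \code{degradomeSignalRatio} times the mean background count. Every
#' tag is the exact 20-nt transcript substring starting at its coordinate.
#'
#' @param truth \code{TruthSet} with planted cleavages
#' @param transcripts \code{TranscriptSet} holding every planted transcript
#' @param config the same \code{SimConfig}
#' @return named list (stages I-IV) of data.frames with columns transcript,
#'   coordinate, tag, count
#' @export
simulateDegradome <- function(truth, transcripts, config) {
  stopifnot(is(truth, "TruthSet"), is(transcripts, "TranscriptSet"))
  set.seed(config@seed + 3L)
  seqs <- txSequences(transcripts)
  clv <- truth@cleavages
  if (nrow(clv) && !all(clv$transcript %in% names(seqs)))
    stop("planted cleavage on a transcript absent from the set")
  bgMean <- config@degradomeBackgroundMean
  out <- vector("list", config@nStages)
  for (s in seq_len(config@nStages)) {
    rows <- list()
    for (tx in names(seqs)) {
      L <- nchar(seqs[[tx]])
      if (L < 20) next
      navail <- L - 19
      tau <- L / 2
      w <- exp(-(seq_len(navail)) / tau)
      nOcc <- max(1, round(config@degradomeOccupancy * navail))
      pos <- sort(sample(navail, min(nOcc, navail), prob = w))
      cnt <- 1L + .maybePois(rep(bgMean - 1, length(pos)),
                             config@exactCounts)
      sites <- clv[clv$transcript == tx, ]
      if (nrow(sites) && config@degradomeSignalRatio > 0) {
        for (j in seq_len(nrow(sites))) {
          sc <- sites$site[j]
          if (sc + 19 > L)
            stop("placement error: transcript ", tx,
                 " too short for a 20-nt tag at site ", sc)
          lam <- sites$strength[j] * bgMean
          scount <- max(1L, .maybePois(lam, config@exactCounts))
          hit <- which(pos == sc)
          if (length(hit)) cnt[hit] <- cnt[hit] + scount else {
            pos <- c(pos, sc); cnt <- c(cnt, scount)
          }
        }
        ord <- order(pos); pos <- pos[ord]; cnt <- cnt[ord]
      }
      rows[[length(rows) + 1]] <- data.frame(
        transcript = tx, coordinate = pos,
        tag = substr(rep(seqs[[tx]], length(pos)), pos, pos + 19),
        count = as.integer(cnt), stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  names(out) <- STAGES[seq_len(config@nStages)]
  out
}

#' Simulate a probe x (stage x replicate) expression matrix
#'
#' Null probes share a common baseline mean with iid Gaussian noise;
#' planted DE probes add the per-stage mean offsets recorded in the truth
#' set. Column names are \code{<stage>_<replicate>}.
#'
#' @param truth \code{TruthSet}
#' @param config the same \code{SimConfig}
#' @return numeric matrix with a \code{design} data.frame and a
#'   \code{family} probe-family map attached as attributes
#' @export
simulateExpressionMatrix <- function(truth, config) {
  stopifnot(is(truth, "TruthSet"))
  if (config@nReplicates < 2) stop("need >= 2 replicates per stage")
  set.seed(config@seed + 4L)
  k <- config@nStages
  n <- config@nReplicates
  probes <- sprintf("probe_%d", seq_len(config@nProbes))
  design <- data.frame(
    sample = paste0(rep(STAGES[seq_len(k)], each = n), "_",
                    rep(seq_len(n), k)),
    stage = rep(STAGES[seq_len(k)], each = n),
    replicate = rep(seq_len(n), k), stringsAsFactors = FALSE)
  mu <- matrix(config@baselineMean, config@nProbes, k,
               dimnames = list(probes, STAGES[seq_len(k)]))
  de <- truth@de
  if (nrow(de)) {
    idx <- match(de$probe, probes)
    ok <- !is.na(idx)
    mu[idx[ok], ] <- mu[idx[ok], ] +
      as.matrix(de[ok, STAGES[seq_len(k)], drop = FALSE])
  }
  m <- mu[, design$stage, drop = FALSE] +
    matrix(rnorm(config@nProbes * k * n, sd = config@noiseSd),
           config@nProbes, k * n)
  dimnames(m) <- list(probes, design$sample)
  attr(m, "design") <- design
  attr(m, "family") <- setNames(
    sprintf("fam%d", ceiling(seq_len(config@nProbes) / 2)), probes)
  m
}
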