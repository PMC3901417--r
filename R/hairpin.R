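#' @include AllClasses.R
#' @useDynLib earpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' A dynamic program over base-pair energies (GC = -3, AU = -2,
#' GU = -1 kcal/mol) with hairpin loops of at least \code{minLoop} unpaired
#' bases and no pseudoknots. This is a shape-level folding model, not full
#' nearest-neighbor thermodynamics: the discovery criteria downstream
#' depend only on hairpin geometry and an MFE threshold. Ties are broken
#' deterministically in favor of the 5'-most pairing partner.
#'
#' @param seq RNA sequence (character; T is accepted and mapped to U)
#' @param minLoop minimum hairpin-loop size in unpaired bases
#' @param maxLen guard on sequence length
#' @return a \code{\linkS4class{FoldResult}}
#' @export
foldHairpin <- function(seq, minLoop = 3, maxLen = 600) {
  seq <- .canonRna(seq)
  n <- nchar(seq)
  if (n < minLoop + 2 || n > maxLen)
    stop("sequence length ", n, " outside foldable range [",
         minLoop + 2, ", ", maxLen, "]")
  if (grepl("[^ACGUN]", seq)) stop("non-alphabet characters in sequence")
  r <- .fold_dp(seq, as.integer(minLoop))
  pairs <- cbind(i = r$pair_i, j = r$pair_j)
  if (!nrow(pairs)) pairs <- matrix(integer(), 0, 2,
                                    dimnames = list(NULL, c("i", "j")))
  stopifnot(abs(r$energy_check - r$mfe) < 1e-6)
  new("FoldResult", sequence = seq, structure = r$structure, mfe = r$mfe,
      pairs = pairs[order(pairs[, 1]), , drop = FALSE])
}

#' Excise candidate precursor windows around a genomic tag hit
#'
#' Returns the two flanking windows (tag plus 250 nt upstream; tag plus
#' 250 nt downstream), clipped at chromosome ends and strand-oriented
#' (minus-strand windows are reverse complemented so the tag reads 5'->3').
#'
#' @param genome named character vector or \code{RNAStringSet}
#' @param chrom,start,strand genomic hit of the tag (1-based plus-strand
#'   start)
#' @param tagLen tag length
#' @param flank flanking length in nt
#' @return list of two windows, each a list with \code{seq},
#'   \code{matureOffset} (1-based tag offset in the oriented window) and
#'   the genomic \code{gStart}/\code{gEnd} of the window
#' @export
excisePrecursor <- function(genome, chrom, start, strand, tagLen,
                            flank = 250) {
  genome <- .asNamedChar(genome)
  chromSeq <- genome[[chrom]]
  chromLen <- nchar(chromSeq)
  end <- start + tagLen - 1
  # genomic windows: tag plus flank on either genomic side
  gwin <- list(c(max(1, start - flank), end),
               c(start, min(chromLen, end + flank)))
  out <- lapply(gwin, function(w) {
    s <- substr(chromSeq, w[1], w[2])
    if (strand == "-") {
      s <- .rnaRevComp(s)
      off <- w[2] - end + 1
    } else {
      off <- start - w[1] + 1
    }
    list(seq = s, matureOffset = off, gStart = w[1], gEnd = w[2])
  })
  # orient so that element 1 is the tag-upstream window in tag coordinates
  if (strand == "-") out <- rev(out)
  names(out) <- c("upstream", "downstream")
  out
}

# Group base pairs into stem components: consecutive nested pairs within a
# bulge tolerance belong to one stem.
.stemComponents <- function(pairs, gapTol = 4) {
  n <- nrow(pairs)
  if (!n) return(integer())
  comp <- integer(n)
  comp[1] <- 1L
  for (k in seq_len(n)[-1]) {
    same <- pairs[k, 1] > pairs[k - 1, 1] &&
      pairs[k, 2] < pairs[k - 1, 2] &&
      (pairs[k, 1] - pairs[k - 1, 1]) <= gapTol + 1 &&
      (pairs[k - 1, 2] - pairs[k, 2]) <= gapTol + 1
    comp[k] <- if (same) comp[k - 1] else comp[k - 1] + 1L
  }
  comp
}

# Locate the candidate precursor span inside an excised window: scan for
# the best antisense (star-arm) match of the mature outside the mature
# span, and return the span covering both arms plus a pad for the lower
# stem. Complementarity is scored without the core doubling used for
# targets (mismatch 1, G:U 0.5). NULL when no segment is complementary
# enough to form a duplex.
.findHairpinSpan <- function(windowSeq, matureOffset, matureLen,
                             maxStarScore = 5, pad = 12, minLoop = 3) {
  W <- nchar(windowSeq)
  starLen <- matureLen - 2
  if (W < matureLen + starLen + minLoop) return(NULL)
  p1 <- matureOffset
  p2 <- matureOffset + matureLen - 1
  mature5 <- substr(windowSeq, p1, p1 + starLen - 1)
  starts <- seq_len(W - starLen + 1)
  # the star arm cannot overlap the mature or sit closer than the loop
  ok <- (starts + starLen - 1 < p1 - minLoop) | (starts > p2 + minLoop)
  if (!any(ok)) return(NULL)
  starts <- starts[ok]
  sites <- substring(windowSeq, starts, starts + starLen - 1)
  scores <- .scoreSitesGapFree(mature5, sites, corePenalty = FALSE)
  best <- which.min(scores)
  if (scores[best] > maxStarScore) return(NULL)
  o <- starts[best]
  c(max(1, min(p1, o) - pad),
    min(W, max(p2, o + starLen - 1) + pad))
}

#' Detect the miRNA* partner of a mature sequence on a folded hairpin
#'
#' The star is the stem segment pairing the mature, shifted to leave the
#' canonical 2-nt 3' overhangs on both duplex ends. The duplex is accepted
#' when at most \code{maxUnpaired} mature bases are unpaired and no
#' asymmetric bulge exceeds \code{maxBulge} nt.
#'
#' @param fold \code{FoldResult} of the precursor
#' @param matureOffset,matureLen 1-based mature placement on the precursor
#' @param tags optional tag data.frame (seq, count) used to count reads
#'   exactly matching the star segment
#' @param maxUnpaired maximum unpaired mature bases
#' @param maxBulge maximum asymmetric bulge within the duplex
#' @return list with starSeq, starStart, starEnd, unpairedMature, maxBulge,
#'   starCount, or \code{NULL} when the duplex rules fail
#' @export
detectDuplex <- function(fold, matureOffset, matureLen, tags = NULL,
                         maxUnpaired = 4, maxBulge = 2) {
  seq <- fold@sequence
  n <- nchar(seq)
  p1 <- matureOffset
  p2 <- matureOffset + matureLen - 1
  if (p1 < 1 || p2 > n) stop("mature outside precursor")
  partner <- integer(n)
  if (nrow(fold@pairs)) {
    partner[fold@pairs[, 1]] <- fold@pairs[, 2]
    partner[fold@pairs[, 2]] <- fold@pairs[, 1]
  }
  mpos <- p1:p2
  mpart <- partner[mpos]
  paired <- mpos[mpart != 0]
  if (length(paired) < 2) return(NULL)
  partnersIn <- partner[paired] >= p1 & partner[paired] <= p2
  sideUp <- partner[paired] < p1
  sideDown <- partner[paired] > p2
  if (any(partnersIn) || (any(sideUp) && any(sideDown)))
    stop("duplex error: mature spans the terminal loop")
  unpaired <- matureLen - length(paired)
  if (unpaired > maxUnpaired) return(NULL)
  # asymmetric bulges between consecutive paired mature bases
  bulge <- 0
  if (length(paired) > 1) {
    gm <- diff(paired) - 1
    gs <- abs(diff(partner[paired])) - 1
    bulge <- max(abs(gm - gs))
    if (bulge > maxBulge) return(NULL)
  }
  q1 <- min(paired[paired >= p1])
  inner <- paired[paired <= p2 - 2]
  if (!length(inner)) return(NULL)
  q2 <- max(inner)
  s1 <- partner[q2] - ((p2 - 2) - q2)
  s2 <- partner[q1] + (q1 - p1) + 2
  if (s1 < 1 || s2 > n || s1 >= s2) return(NULL)
  starSeq <- substr(seq, s1, s2)
  starCount <- if (!is.null(tags) && nrow(tags)) {
    hit <- tags$seq == starSeq
    if (any(hit)) sum(tags$count[hit]) else 0L
  } else 0L
  list(starSeq = starSeq, starStart = s1, starEnd = s2,
       unpairedMature = unpaired, maxBulge = bulge,
       starCount = as.integer(starCount))
}

#' Apply the exclusion ledger to folded candidates
#'
#' Flags each candidate for exon overlap, repeat overlap and an MFE
#' threshold; a candidate is excluded when any flag is set. By standard
#' criteria stable hairpins are retained (MFE <= \code{mfeMax});
#' \code{mfeLiteral = TRUE} flips the comparison to the literal reading
#' that discards free energies below the threshold.
#'
#' @param candidates list of \code{HairpinCandidate}
#' @param track annotation \code{GRanges} with klass (may be empty/NULL)
#' @param mfeMax MFE threshold in kcal/mol
#' @param mfeLiteral flip the MFE comparison (see above)
#' @return list with \code{candidates} (flags and status updated) and
#'   \code{summary} (counts per flag, total, retained)
#' @export
applyExclusionLedger <- function(candidates, track, mfeMax = -20,
                                 mfeLiteral = FALSE) {
  exonTrack <- repTrack <- NULL
  if (!is.null(track) && length(track)) {
    exonTrack <- track[mcols(track)$klass == "exon"]
    repTrack <- track[mcols(track)$klass == "repeat"]
  }
  candidates <- lapply(candidates, function(cd) {
    gr <- GRanges(cd@chrom, IRanges(cd@start, cd@end))
    cd@ledger["exon_overlap"] <- !is.null(exonTrack) &&
      length(exonTrack) > 0 &&
      length(GenomicRanges::findOverlaps(gr, exonTrack,
                                         ignore.strand = TRUE)) > 0
    cd@ledger["repeat_overlap"] <- !is.null(repTrack) &&
      length(repTrack) > 0 &&
      length(GenomicRanges::findOverlaps(gr, repTrack,
                                         ignore.strand = TRUE)) > 0
    cd@ledger["mfe_fail"] <- if (mfeLiteral) cd@fold@mfe < mfeMax else
      cd@fold@mfe > mfeMax
    if (any(cd@ledger[c("exon_overlap", "repeat_overlap", "mfe_fail")]))
      cd@status <- "excluded"
    cd
  })
  flags <- t(vapply(candidates, function(cd)
    cd@ledger[c("exon_overlap", "repeat_overlap", "mfe_fail")],
    logical(3)))
  summary <- data.frame(
    total = length(candidates),
    exon_overlap = sum(flags[, 1]), repeat_overlap = sum(flags[, 2]),
    mfe_fail = sum(flags[, 3]),
    excluded = sum(apply(flags, 1, any)),
    retained = sum(!apply(flags, 1, any)))
  list(candidates = candidates, summary = summary)
}

#' Assign a mature sequence to a known miRNA family
#'
#' Nearest reference by edit distance; the family is assigned when the
#' distance is at most \code{maxDist}, ties broken by the lexicographically
#' smallest family label.
#'
#' @param matureSeq query mature sequence
#' @param reference data.frame with columns family, mature
#' @param maxDist maximum edit distance
#' @return family label, or \code{NA_character_} when no reference is close
#'   enough
#' @export
assignKnown <- function(matureSeq, reference, maxDist = 3) {
  if (is.null(reference) || !nrow(reference)) stop("empty reference")
  d <- as.vector(adist(.canonRna(matureSeq), .canonRna(reference$mature)))
  best <- min(d)
  if (best > maxDist) return(NA_character_)
  sort(reference$family[d == best])[1]
}

#' Classify an unassigned hairpin candidate
#'
#' Deterministic replacement for a trained pre-miRNA classifier:
#' \code{not_hairpin} when no single stem holds at least
#' \code{stemFraction} of the structure's pairs or the stem arms are
#' shorter than the mature; \code{pseudo} when hairpin-shaped but the
#' duplex rules fail (mature across the loop, too many unpaired mature
#' bases, oversized bulge) or the precursor is shorter than
#' \code{minPrecursorLen}; \code{novel} otherwise. Star read support is not
#' required.
#'
#' @param fold \code{FoldResult} of the candidate precursor
#' @param matureOffset,matureLen mature placement on the precursor
#' @param minPrecursorLen minimum precursor length in nt
#' @param stemFraction minimum fraction of pairs in the main stem
#' @return one of "novel", "pseudo", "not_hairpin"
#' @export
classifyNovel <- function(fold, matureOffset, matureLen,
                          minPrecursorLen = 60, stemFraction = 0.6) {
  p <- fold@pairs
  if (!nrow(p)) return("not_hairpin")
  comp <- .stemComponents(p)
  tab <- table(comp)
  main <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) / nrow(p) < stemFraction) return("not_hairpin")
  sel <- p[comp == main, , drop = FALSE]
  armI <- diff(range(sel[, 1])) + 1
  armJ <- diff(range(sel[, 2])) + 1
  if (min(armI, armJ) < matureLen) return("not_hairpin")
  if (nchar(fold@sequence) < minPrecursorLen) return("pseudo")
  dup <- tryCatch(detectDuplex(fold, matureOffset, matureLen),
                  error = function(e) NULL)
  if (is.null(dup)) return("pseudo")
  "novel"
}

#' Merge per-locus calls into non-redundant mature records
#'
#' Identical mature sequences are merged into one record: loci are pooled,
#' the abundance is the shared tag count (not multiplied by the locus
#' number) and same-family records with distinct sequences receive
#' suffixed names (a, b, ...).
#'
#' @param records data.frame with at least a \code{mature} column;
#'   optional: name, family, loci (locus count, default 1), abundance,
#'   star, starCount, locus (label)
#' @return data.frame: name, mature, family, nLoci, loci, abundance, star,
#'   starCount
#' @export
dedupeMature <- function(records) {
  if (!nrow(records))
    return(data.frame(name = character(), mature = character(),
                      family = character(), nLoci = integer(),
                      loci = character(), abundance = numeric(),
                      star = character(), starCount = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(records$loci)) records$loci <- 1L
  if (is.null(records$abundance)) records$abundance <- NA_real_
  if (is.null(records$family)) records$family <- NA_character_
  if (is.null(records$name)) records$name <- NA_character_
  if (is.null(records$star)) records$star <- NA_character_
  if (is.null(records$starCount)) records$starCount <- NA_real_
  if (is.null(records$locus)) records$locus <- NA_character_
  grp <- split(seq_len(nrow(records)), records$mature)
  rows <- lapply(grp, function(ix) {
    r <- records[ix, , drop = FALSE]
    star <- r$star[!is.na(r$star) & r$star != "NO"]
    data.frame(
      name = r$name[1], mature = r$mature[1], family = r$family[1],
      nLoci = sum(r$loci),
      loci = paste(stats::na.omit(r$locus), collapse = ";"),
      abundance = max(r$abundance),
      star = if (length(star)) star[1] else NA_character_,
      starCount = max(c(r$starCount, 0), na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # suffix same-family multi-sequence records the way families are named
  out <- out[order(out$family, out$mature), ]
  fam <- out$family
  fam[is.na(fam)] <- paste0(".anon", seq_len(sum(is.na(fam))))
  for (f in unique(fam)) {
    ix <- which(fam == f)
    if (length(ix) > 1 && !startsWith(f, ".anon"))
      out$name[ix] <- paste0(ifelse(is.na(out$name[ix]), f,
                                    out$name[ix]),
                             letters[seq_along(ix)])
  }
  miss <- is.na(out$name)
  out$name[miss] <- sprintf("mir_%d", which(miss))
  rownames(out) <- NULL
  out
}

#' Discover miRNA loci from mapped small-RNA tags
#'
#' The full discovery pipeline: seed tags in the miRNA length window are
#' mapped, structural-RNA tags are removed, flanking windows are excised
#' and folded, each fold is trimmed to the stem-loop containing the tag and
#' refolded, the exclusion ledger is applied, and retained candidates are
#' assigned to known families or classified as novel by the duplex rules.
#'
#' @param tags collapsed tag data.frame (seq, count)
#' @param genome named character vector or \code{RNAStringSet}
#' @param track annotation \code{GRanges} (or NULL)
#' @param reference known-miRNA reference data.frame (family, mature) or NULL
#' @param minCount minimum tag count to seed a candidate
#' @param lenRange mature length window for seed tags
#' @param flank flanking length for excision
#' @param mfeMax,mfeLiteral see \code{\link{applyExclusionLedger}}
#' @param maxDist known-assignment edit-distance threshold
#' @return list with \code{candidates}, \code{table} (one row per
#'   candidate), \code{mature} (deduplicated records of known/novel calls)
#'   and \code{ledger} (exclusion summary)
#' @export
discoverMirnas <- function(tags, genome, track = NULL, reference = NULL,
                           minCount = 5, lenRange = c(20, 24), flank = 250,
                           mfeMax = -20, mfeLiteral = FALSE, maxDist = 3) {
  genome <- .asNamedChar(genome)
  len <- nchar(tags$seq)
  seeds <- tags[len >= lenRange[1] & len <= lenRange[2] &
                  tags$count >= minCount, , drop = FALSE]
  seeds <- mapPerfect(seeds, genome)
  seeds <- classifyTags(seeds, if (is.null(track)) GRanges() else track)
  structural <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  seeds <- seeds[seeds$n_hits > 0 &
                   !(seeds$klass %in% structural), , drop = FALSE]

  candidates <- list()
  for (i in seq_len(nrow(seeds))) {
    h <- seeds$hits[[i]]
    for (r in seq_len(nrow(h))) {
      wins <- excisePrecursor(genome, h$chrom[r], h$start[r], h$strand[r],
                              nchar(seeds$seq[i]), flank)
      tagLen <- nchar(seeds$seq[i])
      tagEnd <- h$start[r] + tagLen - 1
      chromSeq <- genome[[h$chrom[r]]]
      best <- NULL
      for (w in wins) {
        if (nchar(w$seq) < 40) next
        span <- .findHairpinSpan(w$seq, w$matureOffset, tagLen)
        if (is.null(span)) next
        # when the span was clipped at a window edge, re-excise from the
        # genome with extra room so the lower stem is not truncated
        extL <- if (span[1] == 1) 12 else 0
        extR <- if (span[2] == nchar(w$seq)) 12 else 0
        if (h$strand[r] == "+") {
          gs <- max(1, w$gStart + span[1] - 1 - extL)
          ge <- min(nchar(chromSeq), w$gStart + span[2] - 1 + extR)
          sub <- substr(chromSeq, gs, ge)
          mOff <- h$start[r] - gs + 1
        } else {
          ge <- min(nchar(chromSeq), w$gEnd - span[1] + 1 + extL)
          gs <- max(1, w$gEnd - span[2] + 1 - extR)
          sub <- .rnaRevComp(substr(chromSeq, gs, ge))
          mOff <- ge - tagEnd + 1
        }
        if (mOff < 1) next
        refold <- foldHairpin(sub)
        # prefer the window whose candidate satisfies the hairpin/duplex
        # rules; fall back to the lower MFE
        rank <- switch(classifyNovel(refold, mOff, tagLen),
                       novel = 3, pseudo = 2, not_hairpin = 1)
        if (is.null(best) || rank > best$rank ||
            (rank == best$rank && refold@mfe < best$fold@mfe))
          best <- list(fold = refold, matureOffset = mOff,
                       gStart = gs, gEnd = ge, rank = rank)
      }
      if (is.null(best)) next
      gs <- best$gStart
      ge <- best$gEnd
      candidates[[length(candidates) + 1]] <- new(
        "HairpinCandidate", chrom = h$chrom[r], start = gs, end = ge,
        strand = h$strand[r], sequence = best$fold@sequence,
        fold = best$fold, matureSeq = seeds$seq[i],
        matureOffset = best$matureOffset,
        arm = if (best$matureOffset <
                  (nchar(best$fold@sequence) / 2)) "5p" else "3p",
        matureCount = seeds$count[i], starSeq = NA_character_,
        starOffset = NA_real_, starCount = NA_real_,
        ledger = c(exon_overlap = FALSE, repeat_overlap = FALSE,
                   mfe_fail = FALSE, pseudo = FALSE, not_hairpin = FALSE),
        status = "candidate", family = NA_character_)
    }
  }

  # merge overlapping candidate loci, keeping the most abundant mature
  if (length(candidates) > 1) {
    loci <- GRanges(
      vapply(candidates, function(cd) cd@chrom, ""),
      IRanges(vapply(candidates, function(cd) cd@start, 0),
              vapply(candidates, function(cd) cd@end, 0)),
      strand = vapply(candidates, function(cd) cd@strand, ""))
    counts <- vapply(candidates, function(cd) cd@matureCount, 0)
    keep <- rep(TRUE, length(candidates))
    ov <- GenomicRanges::findOverlaps(loci, loci)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (k in which(qh < sh)) {
      a <- qh[k]; b <- sh[k]
      if (!keep[a] || !keep[b]) next
      if (counts[a] >= counts[b]) keep[b] <- FALSE else keep[a] <- FALSE
    }
    candidates <- candidates[keep]
  }

  led <- applyExclusionLedger(candidates, track, mfeMax, mfeLiteral)
  candidates <- led$candidates

  allTags <- tags
  candidates <- lapply(candidates, function(cd) {
    if (cd@status == "excluded") return(cd)
    fam <- if (!is.null(reference) && nrow(reference))
      assignKnown(cd@matureSeq, reference, maxDist) else NA_character_
    if (!is.na(fam)) {
      cd@family <- fam
      cd@status <- "known"
    } else {
      cls <- classifyNovel(cd@fold, cd@matureOffset, nchar(cd@matureSeq))
      if (cls == "novel") {
        cd@status <- "novel"
      } else {
        cd@status <- "rejected"
        cd@ledger[cls] <- TRUE
      }
    }
    if (cd@status %in% c("known", "novel")) {
      dup <- tryCatch(
        detectDuplex(cd@fold, cd@matureOffset, nchar(cd@matureSeq),
                     tags = allTags),
        error = function(e) NULL)
      if (!is.null(dup)) {
        cd@starSeq <- dup$starSeq
        cd@starOffset <- dup$starStart
        cd@starCount <- dup$starCount
      }
    }
    cd
  })

  tab <- do.call(rbind, lapply(candidates, function(cd) data.frame(
    chrom = cd@chrom, start = cd@start, end = cd@end, strand = cd@strand,
    mature = cd@matureSeq, count = cd@matureCount, arm = cd@arm,
    mfe = cd@fold@mfe, status = cd@status, family = cd@family,
    star = cd@starSeq, starCount = cd@starCount,
    stringsAsFactors = FALSE)))
  if (is.null(tab)) tab <- data.frame()

  calls <- tab[tab$status %in% c("known", "novel"), , drop = FALSE]
  mature <- if (nrow(calls)) dedupeMature(data.frame(
    mature = calls$mature, family = calls$family,
    abundance = calls$count, star = calls$star,
    starCount = calls$starCount,
    locus = sprintf("%s:%d-%d(%s)", calls$chrom, calls$start, calls$end,
                    calls$strand),
    stringsAsFactors = FALSE)) else dedupeMature(data.frame(
      mature = character(), stringsAsFactors = FALSE))

  rejSummary <- led$summary
  rejSummary$pseudo <- sum(vapply(candidates, function(cd)
    cd@ledger["pseudo"], logical(1)))
  rejSummary$not_hairpin <- sum(vapply(candidates, function(cd)
    cd@ledger["not_hairpin"], logical(1)))
  rejSummary$known <- sum(tab$status == "known")
  rejSummary$novel <- sum(tab$status == "novel")
  list(candidates = candidates, table = tab, mature = mature,
       ledger = rejSummary)
}

#' Score a discovery run against the planted truth
#'
#' A planted miRNA is recovered when a known/novel call overlaps its
#' precursor locus on the same strand (the mature may carry end jitter).
#' Precision is the fraction of novel calls that are planted.
#'
#' @param result output of \code{\link{discoverMirnas}}
#' @param truth the \code{TruthSet}
#' @return list with sensitivity, precision, nRecovered, nPlanted
#' @export
scoreDiscovery <- function(result, truth) {
  mir <- truthMirnas(truth)
  tab <- result$table
  calls <- tab[tab$status %in% c("known", "novel"), , drop = FALSE]
  if (!nrow(mir))
    return(list(sensitivity = NA_real_, precision = NA_real_,
                nRecovered = 0L, nPlanted = 0L))
  recovered <- logical(nrow(mir))
  callPlanted <- rep(FALSE, nrow(calls))
  if (nrow(calls)) {
    planted <- GRanges(mir$chrom, IRanges(mir$start, mir$end),
                       strand = mir$strand)
    callGr <- GRanges(calls$chrom, IRanges(calls$start, calls$end),
                      strand = calls$strand)
    ov <- GenomicRanges::findOverlaps(callGr, planted)
    recovered[unique(S4Vectors::subjectHits(ov))] <- TRUE
    callPlanted[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  novel <- calls$status == "novel"
  list(sensitivity = mean(recovered),
       precision = if (any(novel)) mean(callPlanted[novel]) else NA_real_,
       nRecovered = sum(recovered), nPlanted = nrow(mir))
}
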