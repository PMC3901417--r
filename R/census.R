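#' @include AllClasses.R
#' @importFrom Biostrings PDict matchPDict DNAStringSet DNAString width
NULL

KLASS_PRECEDENCE <- c("rRNA", "tRNA", "snRNA", "snoRNA", "other_sRNA",
                      "repeat", "exon")

#' Collapse a read multiset into distinct tags
#'
#' One tag per distinct sequence with its total read count; reads outside
#' the length window are excluded and tallied separately in the attributes.
#'
#' @param reads data.frame with seq (and optionally count; missing counts
#'   are 1), e.g. from \code{\link{readReadsFasta}}
#' @param minLen,maxLen retained length window (the 18-25 preset of small-RNA
#'   pre-processing is available by setting \code{maxLen = 25})
#' @return data.frame of tags (seq, count) with attributes
#'   \code{raw_reads}, \code{raw_distinct}, \code{dropped_reads}
#' @export
collapseReads <- function(reads, minLen = 18, maxLen = 30) {
  if (is.character(reads)) reads <- data.frame(seq = reads, count = 1L,
                                               stringsAsFactors = FALSE)
  if (!nrow(reads)) {
    out <- data.frame(seq = character(), count = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "raw_reads") <- 0L
    attr(out, "raw_distinct") <- 0L
    attr(out, "dropped_reads") <- 0L
    return(out)
  }
  if (is.null(reads$count)) reads$count <- 1L
  seqs <- .canonRna(reads$seq)
  if (any(grepl("[^ACGUN]", seqs)))
    stop("non-alphabet characters in reads")
  len <- nchar(seqs)
  keep <- len >= minLen & len <= maxLen
  rawReads <- sum(reads$count)
  rawDistinct <- length(unique(seqs))
  kept <- data.frame(seq = seqs[keep], count = reads$count[keep],
                     stringsAsFactors = FALSE)
  out <- if (nrow(kept)) {
    agg <- aggregate(count ~ seq, data = kept, FUN = sum)
    agg[order(-agg$count, agg$seq), ]
  } else data.frame(seq = character(), count = integer(),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "raw_reads") <- rawReads
  attr(out, "raw_distinct") <- rawDistinct
  attr(out, "dropped_reads") <- rawReads - sum(out$count)
  out
}

#' Map tags to the genome by perfect full-length matching
#'
#' Every exact occurrence on either strand is reported (minus-strand hits
#' match the reverse complement); there is no mismatch tolerance. Matching
#' is delegated to \code{Biostrings::matchPDict}.
#'
#' @param tags data.frame from \code{\link{collapseReads}}
#' @param genome named character vector or \code{RNAStringSet}
#' @return \code{tags} with a list-column \code{hits} of data.frames
#'   (chrom, start, strand; start is the 1-based plus-strand coordinate of
#'   the leftmost matched base)
#' @export
mapPerfect <- function(tags, genome) {
  genome <- .asNamedChar(genome)
  hits <- replicate(nrow(tags), data.frame(
    chrom = character(), start = integer(), strand = character(),
    stringsAsFactors = FALSE), simplify = FALSE)
  if (nrow(tags)) {
    dnaTags <- chartr("U", "T", tags$seq)
    byLen <- split(seq_len(nrow(tags)), nchar(dnaTags))
    for (chrom in names(genome)) {
      subject <- DNAString(chartr("U", "T", genome[[chrom]]))
      subjectRc <- reverseComplement(subject)
      chromLen <- length(subject)
      for (idx in byLen) {
        pd <- PDict(DNAStringSet(dnaTags[idx]))
        fwd <- matchPDict(pd, subject)
        rev <- matchPDict(pd, subjectRc)
        for (q in seq_along(idx)) {
          i <- idx[q]
          fs <- IRanges::start(fwd[[q]])
          rs <- IRanges::start(rev[[q]])
          if (length(fs))
            hits[[i]] <- rbind(hits[[i]], data.frame(
              chrom = chrom, start = fs, strand = "+",
              stringsAsFactors = FALSE))
          if (length(rs)) {
            w <- nchar(dnaTags[i])
            hits[[i]] <- rbind(hits[[i]], data.frame(
              chrom = chrom, start = chromLen - (rs + w - 1) + 1,
              strand = "-", stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  tags$hits <- hits
  tags$n_hits <- vapply(hits, nrow, 0L)
  tags
}

#' Assign each mapped tag to one annotation class
#'
#' Classes are assigned by fixed precedence (structural RNAs first):
#' rRNA > tRNA > snRNA > snoRNA > other_sRNA > repeat > exon > unannotated,
#' considering every genomic hit of the tag; multi-hit tags count once, by
#' their highest-precedence overlap. The partition is exhaustive and
#' disjoint over mapped tags.
#'
#' @param tags mapped tags from \code{\link{mapPerfect}}
#' @param track annotation \code{GRanges} with a \code{klass} column
#' @param precedence class precedence, highest first
#' @return \code{tags} with a \code{klass} column (NA for unmapped tags)
#' @export
classifyTags <- function(tags, track, precedence = KLASS_PRECEDENCE) {
  mapped <- which(tags$n_hits > 0)
  klass <- rep(NA_character_, nrow(tags))
  if (length(mapped) && length(track)) {
    hitTab <- do.call(rbind, lapply(mapped, function(i) {
      h <- tags$hits[[i]]
      data.frame(tag = i, chrom = h$chrom, start = h$start,
                 end = h$start + nchar(tags$seq[i]) - 1L,
                 stringsAsFactors = FALSE)
    }))
    gr <- GRanges(hitTab$chrom, IRanges(hitTab$start, hitTab$end))
    # hits on chromosomes the track does not mention are simply unannotated
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, track, ignore.strand = TRUE))
    if (length(ov)) {
      kl <- mcols(track)$klass[S4Vectors::subjectHits(ov)]
      rank <- match(kl, precedence)
      tagIdx <- hitTab$tag[S4Vectors::queryHits(ov)]
      best <- tapply(rank, tagIdx, min)
      klass[as.integer(names(best))] <- precedence[best]
    }
    klass[mapped][is.na(klass[mapped])] <- "unannotated"
  } else if (length(mapped)) {
    klass[mapped] <- "unannotated"
  }
  tags$klass <- klass
  tags
}

#' Read-length distribution of a tag set
#'
#' @param tags data.frame with seq, count
#' @param weighted read-weighted (default) or distinct-weighted
#' @return named numeric vector (length -> fraction, sums to 1)
#' @export
sizeDistribution <- function(tags, weighted = TRUE) {
  if (!nrow(tags)) return(setNames(numeric(), character()))
  w <- if (weighted) tags$count else rep(1L, nrow(tags))
  tab <- tapply(w, nchar(tags$seq), sum)
  out <- setNames(as.numeric(tab) / sum(tab), names(tab))
  out[order(as.integer(names(out)))]
}

#' Positional nucleotide bias of a tag set
#'
#' @param tags data.frame with seq, count
#' @param positions positions to tabulate (default 1-24)
#' @param weighted read-weighted (default) or per-distinct-sequence
#' @return positions x base (A/C/G/U) frequency matrix; each row sums to 1
#'   over tags long enough to have that position
#' @export
nucleotideBias <- function(tags, positions = 1:24, weighted = TRUE) {
  m <- matrix(0, length(positions), 4,
              dimnames = list(positions, RNA_BASES))
  if (!nrow(tags)) return(m)
  w <- if (weighted) tags$count else rep(1L, nrow(tags))
  len <- nchar(tags$seq)
  for (p in seq_along(positions)) {
    pos <- positions[p]
    ok <- len >= pos
    if (!any(ok)) next
    b <- substr(tags$seq[ok], pos, pos)
    tot <- tapply(w[ok], factor(b, levels = RNA_BASES), sum)
    tot[is.na(tot)] <- 0
    m[p, ] <- tot / sum(tot)
  }
  m
}

#' Run the full small-RNA census
#'
#' Collapse, perfect-match map, partition by annotation class and compute
#' the descriptive statistics (size distribution, positional base bias).
#'
#' @param reads read data.frame (seq, count)
#' @param genome named character vector or \code{RNAStringSet}
#' @param track annotation \code{GRanges} (may be empty)
#' @param minLen,maxLen length window passed to \code{\link{collapseReads}}
#' @return list with \code{tags} (classified tag table) and \code{report}
#'   (\code{CensusReport})
#' @export
runCensus <- function(reads, genome, track, minLen = 18, maxLen = 30) {
  tags <- collapseReads(reads, minLen, maxLen)
  rawReads <- attr(tags, "raw_reads")
  rawDistinct <- attr(tags, "raw_distinct")
  dropped <- attr(tags, "dropped_reads")
  tags <- mapPerfect(tags, genome)
  tags <- classifyTags(tags, track)
  mapped <- tags$n_hits > 0
  totals <- c(
    raw_reads = rawReads, raw_distinct = rawDistinct,
    filtered_reads = sum(tags$count), filtered_distinct = nrow(tags),
    dropped_reads = dropped,
    mapped_reads = sum(tags$count[mapped]), mapped_distinct = sum(mapped),
    unmapped_reads = sum(tags$count[!mapped]),
    unmapped_distinct = sum(!mapped))
  klasses <- c(KLASS_PRECEDENCE, "unannotated")
  part <- data.frame(klass = klasses, stringsAsFactors = FALSE)
  part$distinct <- vapply(klasses, function(k)
    sum(tags$klass == k, na.rm = TRUE), 0)
  part$reads <- vapply(klasses, function(k)
    sum(tags$count[tags$klass == k & !is.na(tags$klass)]), 0)
  part$frac_distinct <- if (sum(mapped)) part$distinct / sum(mapped) else 0
  part$frac_reads <- if (sum(tags$count[mapped]))
    part$reads / sum(tags$count[mapped]) else 0
  report <- new("CensusReport", totals = totals, classPartition = part,
                sizeDistribution = sizeDistribution(tags),
                firstBase = nucleotideBias(tags))
  list(tags = tags, report = report)
}
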