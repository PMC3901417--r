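#' @include AllClasses.R
NULL

REGION_LABELS <- c(five_prime_utr = "5'-UTR", cds = "CDS",
                   three_prime_utr = "3'-UTR")

#' Place degradome tags on transcripts and build profiles
#'
#' Exact-match placements on the sense strand only. Repeat normalization: a
#' tag placing at k locations across all transcripts contributes count/k at
#' each placement, so summed normalized abundance equals summed placed raw
#' counts.
#'
#' @param tags data.frame with seq (20-nt, 21 accepted via \code{widths})
#'   and count
#' @param transcripts a \code{TranscriptSet}
#' @param stage stage label attached to the profiles
#' @param widths accepted tag lengths
#' @return list with \code{tags} (placement count added), \code{placements}
#'   (tag/transcript/pos table), \code{profiles} (named list of
#'   \code{DegradomeProfile}) and \code{unplaced} (tally)
#' @export
placeTags <- function(tags, transcripts, stage = "I", widths = c(20, 21)) {
  seqs <- txSequences(transcripts)
  if (any(nchar(seqs) < 20)) stop("transcripts must be >= 20 nt")
  bad <- !nchar(tags$seq) %in% widths
  if (any(bad)) stop(sum(bad), " tags with unaccepted length")
  plc <- list()
  for (w in intersect(widths, unique(nchar(tags$seq)))) {
    idx <- which(nchar(tags$seq) == w)
    for (tx in names(seqs)) {
      L <- nchar(seqs[[tx]])
      if (L < w) next
      starts <- seq_len(L - w + 1)
      kmers <- substring(seqs[[tx]], starts, starts + w - 1)
      posByKmer <- split(starts, kmers)
      hit <- posByKmer[tags$seq[idx]]
      nh <- lengths(hit)
      if (!sum(nh)) next
      plc[[length(plc) + 1]] <- data.frame(
        tag = rep(idx, nh), transcript = tx, pos = unlist(hit, use.names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  placements <- if (length(plc)) do.call(rbind, plc) else
    data.frame(tag = integer(), transcript = character(), pos = integer(),
               stringsAsFactors = FALSE)
  k <- tabulate(placements$tag, nbins = nrow(tags))
  tags$nPlacements <- k
  profiles <- list()
  if (nrow(placements)) {
    placements$raw <- tags$count[placements$tag]
    placements$norm <- placements$raw / k[placements$tag]
    for (tx in unique(placements$transcript)) {
      p <- placements[placements$transcript == tx, ]
      raw <- tapply(p$raw, p$pos, sum)
      norm <- tapply(p$norm, p$pos, sum)
      pos <- as.integer(names(raw))
      ord <- order(pos)
      profiles[[tx]] <- new("DegradomeProfile", transcript = tx,
                            stage = stage,
                            positions = data.frame(
                              pos = pos[ord],
                              raw = as.numeric(raw)[ord],
                              norm = as.numeric(norm)[ord]))
    }
  }
  list(tags = tags, placements = placements, profiles = profiles,
       unplaced = sum(k == 0), unplaced_reads = sum(tags$count[k == 0]))
}

.penalty <- function(mirBase, siteBase, mismatch = 1, wobble = 0.5) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  if (siteBase == comp[[mirBase]]) return(0)
  if ((mirBase == "G" && siteBase == "U") ||
      (mirBase == "U" && siteBase == "G")) return(wobble)
  mismatch
}

.coreMult <- function(i, coreFrom = 2, coreTo = 13) {
  ifelse(i >= coreFrom & i <= coreTo, 2, 1)
}

# Score one gapless duplex; mir and site are 5'->3' character vectors of
# equal length, mir nt i pairing site position L - i + 1.
.scoreDuplex <- function(mir, site, mismatch = 1, wobble = 0.5) {
  L <- length(mir)
  s <- 0
  pat <- character(L)
  for (i in seq_len(L)) {
    p <- .penalty(mir[i], site[L - i + 1], mismatch, wobble)
    s <- s + p * .coreMult(i)
    pat[i] <- if (p == 0) ":" else if (p == wobble) "o" else "."
  }
  list(score = s, pattern = paste(pat, collapse = ""))
}

#' Align a miRNA against a transcript window
#'
#' Antisense alignment under the standard plant-target penalty scheme:
#' mismatch 1, G:U wobble 0.5, gap 1 (at most one gap), every penalty
#' doubled at miRNA positions 2-13. All placements and single-gap variants
#' inside the window are enumerated; the best-scoring alignment is
#' returned if its score is at most \code{threshold}.
#'
#' @param mirna guide sequence (5'->3')
#' @param window transcript window sequence (5'->3')
#' @param threshold maximum accepted score
#' @param windowStart transcript coordinate of the window's first base
#' @param mismatch,wobble,gapPen penalty constants
#' @return list with siteStart, siteEnd (transcript coords), score,
#'   pattern, pairedPos (transcript coordinate paired to each miRNA nt; NA
#'   for a gapped miRNA base), or \code{NULL} if no alignment scores within
#'   the threshold
#' @export
alignMirnaSite <- function(mirna, window, threshold = 7, windowStart = 1,
                           mismatch = 1, wobble = 0.5, gapPen = 1) {
  mir <- strsplit(.canonRna(mirna), "")[[1]]
  win <- strsplit(.canonRna(window), "")[[1]]
  L <- length(mir)
  W <- length(win)
  if (W < L) stop("window shorter than the miRNA")
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$score < best$score) best <<- cand
  }
  # gap-free placements
  for (o in seq_len(W - L + 1)) {
    site <- win[o:(o + L - 1)]
    sc <- .scoreDuplex(mir, site, mismatch, wobble)
    consider(list(score = sc$score, pattern = sc$pattern,
                  siteStart = windowStart + o - 1,
                  siteEnd = windowStart + o + L - 2,
                  pairedPos = windowStart + o + L - 2 - (seq_len(L) - 1)))
  }
  # one unpaired (bulged) transcript base at site index g (not terminal)
  if (W >= L + 1) {
    for (o in seq_len(W - L)) {
      site <- win[o:(o + L)]
      for (g in 2:L) {
        i0 <- L + 1 - g  # mir position 3' of the bulge
        s <- gapPen * .coreMult(i0)
        pat <- character(L)
        paired <- integer(L)
        for (i in seq_len(L)) {
          j <- if (L + 2 - i > g) L + 2 - i else L + 1 - i
          p <- .penalty(mir[i], site[j], mismatch, wobble)
          s <- s + p * .coreMult(i)
          pat[i] <- if (p == 0) ":" else if (p == wobble) "o" else "."
          paired[i] <- windowStart + o - 1 + j - 1
        }
        consider(list(score = s, pattern = paste(pat, collapse = ""),
                      siteStart = windowStart + o - 1,
                      siteEnd = windowStart + o + L - 1,
                      pairedPos = paired))
      }
    }
  }
  # one unpaired miRNA base at mir index g (not terminal)
  if (W >= L - 1 && L > 2) {
    for (o in seq_len(W - (L - 1) + 1)) {
      site <- win[o:(o + L - 2)]
      for (g in 2:(L - 1)) {
        s <- gapPen * .coreMult(g)
        pat <- character(L)
        paired <- rep(NA_integer_, L)
        jj <- L - 1
        for (i in seq_len(L)) {
          if (i == g) { pat[i] <- "-"; next }
          p <- .penalty(mir[i], site[jj], mismatch, wobble)
          s <- s + p * .coreMult(i)
          pat[i] <- if (p == 0) ":" else if (p == wobble) "o" else "."
          paired[i] <- windowStart + o - 1 + jj - 1
          jj <- jj - 1
        }
        consider(list(score = s, pattern = paste(pat, collapse = ""),
                      siteStart = windowStart + o - 1,
                      siteEnd = windowStart + o + L - 3,
                      pairedPos = paired))
      }
    }
  }
  if (is.null(best) || best$score > threshold) return(NULL)
  best
}

#' Predicted cleavage site of a target alignment
#'
#' The degradome-supported slicing position: the transcript coordinate
#' paired with miRNA nt 10 (cleavage occurs between the bases opposite
#' miRNA nt 10 and 11). For gap-free alignments this is the site 3' end
#' minus 9.
#'
#' @param alignment result of \code{\link{alignMirnaSite}}
#' @return transcript coordinate (1-based)
#' @export
predictedCleavageSite <- function(alignment) {
  s <- alignment$pairedPos[10]
  if (is.na(s)) s <- alignment$pairedPos[11] + 1L
  as.integer(s)
}

#' Classify a cleavage site into degradome categories 0-4
#'
#' Over the transcript's occupied positions (raw count >= 1) with maximum
#' normalized abundance M and median med: category 4 when the site is
#' supported by a single raw read; else 0 when the site equals a unique
#' maximum, 1 when it equals a tied maximum, 2 when between the median and
#' the maximum, 3 when at or below the median. A site with no raw signal
#' is reported as no-signal, distinct from category 3.
#'
#' @param profile a \code{DegradomeProfile}
#' @param s cleavage-site coordinate
#' @return list with category (NA for no-signal), raw, norm, max, median
#' @export
categorizeTarget <- function(profile, s) {
  pos <- profilePositions(profile)
  row <- pos[pos$pos == s, ]
  if (!nrow(row) || row$raw < 1)
    return(list(category = NA_integer_, raw = 0, norm = 0,
                max = NA_real_, median = NA_real_, status = "no_signal"))
  M <- max(pos$norm)
  med <- median(pos$norm)
  tol <- 1e-9
  category <- if (row$raw == 1) 4L
  else if (abs(row$norm - M) < tol) {
    if (sum(abs(pos$norm - M) < tol) > 1) 1L else 0L
  } else if (row$norm > med) 2L else 3L
  list(category = category, raw = row$raw, norm = row$norm, max = M,
       median = med, status = "ok")
}

# Vectorized gap-free duplex scores of one guide against many sites.
# corePenalty = FALSE drops the position-2..13 doubling (plain
# complementarity, used for star-arm scanning).
.scoreSitesGapFree <- function(mir, sites, mismatch = 1, wobble = 0.5,
                               corePenalty = TRUE) {
  L <- nchar(mir)
  m <- strsplit(mir, "")[[1]]
  sm <- matrix(unlist(strsplit(sites, ""), use.names = FALSE),
               nrow = length(sites), byrow = TRUE)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  total <- numeric(length(sites))
  for (i in seq_len(L)) {
    sb <- sm[, L - i + 1]
    pen <- ifelse(sb == comp[[m[i]]], 0,
                  ifelse((m[i] == "G" & sb == "U") |
                           (m[i] == "U" & sb == "G"), wobble, mismatch))
    total <- total + pen * (if (corePenalty) .coreMult(i) else 1)
  }
  total
}

.regionLabel <- function(segments, tx, b, e) {
  seg <- segments[segments$transcript_id == tx, ]
  hit <- seg[seg$tx_end >= b & seg$tx_start <= e, ]
  if (!nrow(hit)) return(NA_character_)
  paste(REGION_LABELS[unique(hit$region)], collapse = "/")
}

#' Call miRNA targets from degradome profiles
#'
#' For every occupied profile position s, the window covering 15 nt
#' upstream of s plus 15 nt from s is extracted and every guide is scored
#' with nt 10 constrained to pair s (gap-free; near-threshold sites are
#' re-scored with the single-gap alignment when \code{allowGap}). Calls
#' within the score threshold are annotated with their degradome category
#' and the transcript region of the site.
#'
#' @param guides named character vector of guide (miRNA / ta-siRNA)
#'   sequences, any 20-24 nt
#' @param transcripts a \code{TranscriptSet}
#' @param profilesByStage named list (stage -> named list of
#'   \code{DegradomeProfile})
#' @param scoreThreshold maximum alignment score
#' @param minRaw minimum raw count at the site
#' @param allowGap re-score near-threshold sites with one gap allowed
#' @return data.frame of target calls (stage, mirna, gene, transcript,
#'   site coordinates, score, raw, norm, category, region)
#' @export
callTargets <- function(guides, transcripts, profilesByStage,
                        scoreThreshold = 7, minRaw = 1, allowGap = TRUE) {
  seqs <- txSequences(transcripts)
  segments <- txSegments(transcripts)
  geneOf <- setNames(segments$gene_id, segments$transcript_id)
  rows <- list()
  for (stage in names(profilesByStage)) {
    profs <- profilesByStage[[stage]]
    for (tx in names(profs)) {
      if (!tx %in% names(seqs)) next
      pos <- profilePositions(profs[[tx]])
      occ <- pos$pos[pos$raw >= minRaw]
      if (!length(occ)) next
      L <- nchar(seqs[[tx]])
      for (g in seq_along(guides)) {
        mir <- guides[[g]]
        ml <- nchar(mir)
        e <- occ + 9
        b <- e - ml + 1
        valid <- b >= 1 & e <= L
        if (!any(valid)) next
        sv <- occ[valid]
        sites <- substring(seqs[[tx]], b[valid], e[valid])
        scores <- .scoreSitesGapFree(mir, sites)
        for (q in seq_along(sv)) {
          sc <- scores[q]
          siteStart <- b[valid][q]
          siteEnd <- e[valid][q]
          if (sc > scoreThreshold && allowGap &&
              sc <= scoreThreshold + 2 * 1) {
            winStart <- max(1, sv[q] - 15)
            winEnd <- min(L, sv[q] + 14)
            al <- alignMirnaSite(mir, substr(seqs[[tx]], winStart, winEnd),
                                 threshold = scoreThreshold,
                                 windowStart = winStart)
            if (!is.null(al) && predictedCleavageSite(al) == sv[q]) {
              sc <- al$score
              siteStart <- al$siteStart
              siteEnd <- al$siteEnd
            }
          }
          if (sc > scoreThreshold) next
          cat0 <- categorizeTarget(profs[[tx]], sv[q])
          if (is.na(cat0$category)) next
          rows[[length(rows) + 1]] <- data.frame(
            stage = stage, mirna = names(guides)[g], gene = geneOf[[tx]],
            transcript = tx, site_start = siteStart, site_end = siteEnd,
            site = sv[q], score = sc, raw = cat0$raw, norm = cat0$norm,
            category = cat0$category,
            region = .regionLabel(segments, tx, siteStart, siteEnd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stage = character(), mirna = character(),
               gene = character(), transcript = character(),
               site_start = integer(), site_end = integer(),
               site = integer(), score = numeric(), raw = numeric(),
               norm = numeric(), category = integer(),
               region = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge per-stage target calls into a cross-stage table
#'
#' One row per (miRNA, gene) with per-stage "abundance (category)" cells
#' (the best-supported site of that stage), plus summary counts.
#'
#' @param calls data.frame from \code{\link{callTargets}} (all stages)
#' @return list with \code{table} and \code{summary}
#' @export
mergeStages <- function(calls) {
  stages <- STAGES
  key <- paste(calls$mirna, calls$gene, sep = "\r")
  rows <- lapply(split(seq_len(nrow(calls)), key), function(ix) {
    cc <- calls[ix, ]
    cells <- setNames(rep("", length(stages)), stages)
    for (st in intersect(stages, unique(cc$stage))) {
      cs <- cc[cc$stage == st, ]
      bestRow <- cs[which.max(cs$norm), ]
      cells[st] <- sprintf("%.2f (%d)", bestRow$norm, bestRow$category)
    }
    data.frame(mirna = cc$mirna[1], gene = cc$gene[1],
               region = paste(unique(unlist(strsplit(cc$region, "/"))),
                              collapse = "/"),
               I = cells["I"], II = cells["II"], III = cells["III"],
               IV = cells["IV"],
               n_stages = length(unique(cc$stage)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summary <- list(
    n_genes = length(unique(calls$gene)),
    n_transcripts = length(unique(calls$transcript)),
    n_mirnas = length(unique(calls$mirna)),
    genes_all_stages = sum(vapply(
      split(calls$stage, calls$gene),
      function(s) length(unique(s)) == length(stages), logical(1))),
    genes_per_mirna = vapply(split(calls$gene, calls$mirna),
                             function(g) length(unique(g)), 0L))
  list(table = tab, summary = summary)
}

#' Summary statistics of a printed target table
#'
#' Works on the packaged table3/table4 fixtures (or any table in their
#' layout): distinct target genes per guide, overall distinct counts, and
#' genes detected in all four stages.
#'
#' @param fixture data.frame with columns mirna, target_gene and the four
#'   stage columns I-IV
#' @return list with perMirna (named counts), nGenes, nMirnas,
#'   genesAllStages
#' @export
targetSummary <- function(fixture) {
  stages <- intersect(STAGES, names(fixture))
  filled <- function(x) !is.na(x) & nzchar(trimws(x)) & trimws(x) != "-"
  perMirna <- vapply(split(fixture$target_gene, fixture$mirna),
                     function(g) length(unique(g)), 0L)
  allStages <- vapply(split(seq_len(nrow(fixture)), fixture$target_gene),
                      function(ix) {
                        any(vapply(ix, function(i)
                          all(vapply(stages, function(st)
                            filled(fixture[[st]][i]), logical(1))),
                          logical(1)))
                      }, logical(1))
  list(perMirna = perMirna,
       nGenes = length(unique(fixture$target_gene)),
       nMirnas = length(unique(fixture$mirna)),
       genesAllStages = sum(allStages))
}
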