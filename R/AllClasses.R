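#' @import methods
#' @importFrom S4Vectors isSingleNumber
NULL

ANNOTATION_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "other_sRNA",
                        "repeat", "exon")

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults describe the
#' study conditions the package is tested under: a two-chromosome 100-kb toy
#' genome carrying 30 planted miRNA precursors plus background loci from the
#' seven annotation classes, 5e4 small-RNA reads with a 100:1 mature:star
#' ratio, 100 target transcripts with one planted cleavage site each at a
#' 10x signal:background ratio, and a 4-stage x 4-replicate expression
#' matrix.
#'
#' @slot genomeLength total genome length in nt (split across chromosomes)
#' @slot nChromosomes number of chromosomes
#' @slot nMirnas number of planted miRNA precursors
#' @slot nBackgroundLoci background loci per annotation class
#' @slot readDepth total small-RNA read count
#' @slot matureStarRatio expected mature:star read-count ratio
#' @slot plantedReadFraction fraction of reads drawn from planted precursors
#' @slot jitterFraction fraction of planted reads receiving 1-2 nt end jitter
#' @slot backgroundClassProps read proportions per background class
#' @slot backgroundLengthProbs length distribution of background reads (18-30)
#' @slot matureLengthProbs length distribution of planted mature miRNAs
#' @slot loopLenRange min/max terminal-loop length of planted precursors
#' @slot nTranscripts number of simulated target transcripts
#' @slot transcriptLength transcript length in nt
#' @slot degradomeSignalRatio planted-site tag count over mean background count
#' @slot degradomeBackgroundMean mean background tag count per occupied position
#' @slot degradomeOccupancy fraction of transcript positions with background tags
#' @slot nStages number of developmental stages
#' @slot nReplicates replicates per stage on the expression matrix
#' @slot nProbes total probes on the expression matrix
#' @slot nDEProbes probes with a planted stage effect
#' @slot stageEffect planted stage effect magnitude (log2 units)
#' @slot noiseSd residual standard deviation of expression values
#' @slot baselineMean baseline log2 intensity
#' @slot exactCounts disable Poisson sampling of counts (deterministic means)
#' @slot seed integer seed used by every generator
#' @exportClass SimConfig
setClass("SimConfig", representation(
  genomeLength = "numeric", nChromosomes = "numeric", nMirnas = "numeric",
  nBackgroundLoci = "numeric", readDepth = "numeric",
  matureStarRatio = "numeric", plantedReadFraction = "numeric",
  jitterFraction = "numeric", backgroundClassProps = "numeric",
  backgroundLengthProbs = "numeric", matureLengthProbs = "numeric",
  loopLenRange = "numeric", nTranscripts = "numeric",
  transcriptLength = "numeric", degradomeSignalRatio = "numeric",
  degradomeBackgroundMean = "numeric", degradomeOccupancy = "numeric",
  nStages = "numeric", nReplicates = "numeric", nProbes = "numeric",
  nDEProbes = "numeric", stageEffect = "numeric", noiseSd = "numeric",
  baselineMean = "numeric", exactCounts = "logical", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c("genomeLength", "nChromosomes", "readDepth", "matureStarRatio",
           "transcriptLength", "nStages", "nReplicates", "nProbes",
           "noiseSd")
  for (s in pos)
    if (slot(object, s) <= 0) msg <- c(msg, paste0(s, " must be > 0"))
  nonneg <- c("nMirnas", "nBackgroundLoci", "nDEProbes", "jitterFraction",
              "degradomeSignalRatio")
  for (s in nonneg)
    if (slot(object, s) < 0) msg <- c(msg, paste0(s, " must be >= 0"))
  if (object@degradomeBackgroundMean <= 0)
    msg <- c(msg, "degradomeBackgroundMean must be > 0")
  if (object@plantedReadFraction < 0 || object@plantedReadFraction > 1)
    msg <- c(msg, "plantedReadFraction must be in [0, 1]")
  if (abs(sum(object@backgroundClassProps) - 1) > 1e-6)
    msg <- c(msg, "backgroundClassProps must sum to 1")
  if (!all(names(object@backgroundClassProps) %in%
           c(ANNOTATION_CLASSES, "unannotated")))
    msg <- c(msg, "backgroundClassProps names must be annotation classes")
  if (length(object@loopLenRange) != 2 || diff(object@loopLenRange) < 0)
    msg <- c(msg, "loopLenRange must be c(min, max)")
  if (length(msg)) msg else TRUE
})

#' Planted truth of a simulation
#'
#' Holds what the generator planted: precursor loci with mature/star
#' sequences, cleavage sites on the simulated transcripts, and the probes
#' carrying a stage effect, so downstream discovery, target calling and
#' differential-expression results can be scored against known truth.
#'
#' @slot mirnas data.frame: name, mature, star, arm, chrom, start, end,
#'   strand, family, precursor sequence
#' @slot cleavages data.frame: mirna, transcript, site, strength (filled by
#'   \code{\link{simulateTranscripts}})
#' @slot de data.frame: probe plus per-stage mean offsets
#' @slot background data.frame of background loci (chrom, start, end, klass,
#'   strand, seq) the read generator samples from
#' @slot config the \code{SimConfig} that produced this truth
#' @exportClass TruthSet
setClass("TruthSet", representation(
  mirnas = "data.frame", cleavages = "data.frame", de = "data.frame",
  background = "data.frame", config = "SimConfig"))

#' Result of folding one RNA sequence
#'
#' @slot sequence the folded RNA sequence
#' @slot structure dot-bracket string (nested, no pseudoknots)
#' @slot mfe minimum free energy, kcal/mol (<= 0 when at least one pair)
#' @slot pairs two-column integer matrix of 1-based pair indices (i < j)
#' @exportClass FoldResult
setClass("FoldResult", representation(
  sequence = "character", structure = "character", mfe = "numeric",
  pairs = "matrix"))

setValidity("FoldResult", function(object) {
  msg <- character()
  n <- nchar(object@structure)
  if (nchar(object@sequence) != n)
    msg <- c(msg, "sequence and structure lengths differ")
  if (object@mfe > 1e-9) msg <- c(msg, "mfe must be <= 0")
  p <- object@pairs
  if (nrow(p)) {
    if (any(p < 1) || any(p > n)) msg <- c(msg, "pair index out of range")
    if (any(p[, 2] - p[, 1] < 4)) msg <- c(msg, "hairpin loop < 3 nt")
  }
  op <- sum(strsplit(object@structure, "")[[1]] == "(")
  cl <- sum(strsplit(object@structure, "")[[1]] == ")")
  if (op != cl || op != nrow(p)) msg <- c(msg, "unbalanced brackets")
  if (length(msg)) msg else TRUE
})

#' A candidate miRNA precursor locus
#'
#' One excised, folded hairpin candidate with its exclusion-ledger flags,
#' mature placement, optional miRNA* call and final status.
#'
#' @slot chrom,start,end,strand genomic locus (1-based closed interval)
#' @slot sequence precursor RNA sequence (strand-oriented)
#' @slot fold \code{FoldResult} of the precursor
#' @slot matureSeq,matureOffset,arm mature miRNA and its 1-based offset and
#'   arm (5p/3p) on the precursor
#' @slot matureCount read count supporting the mature sequence
#' @slot starSeq,starOffset,starCount miRNA* call (NA when absent)
#' @slot ledger named logical flags: exon_overlap, repeat_overlap, mfe_fail,
#'   pseudo, not_hairpin
#' @slot status one of excluded, known, novel, rejected, candidate
#' @slot family known-family label (NA unless status == "known")
#' @exportClass HairpinCandidate
setClass("HairpinCandidate", representation(
  chrom = "character", start = "numeric", end = "numeric",
  strand = "character", sequence = "character", fold = "FoldResult",
  matureSeq = "character", matureOffset = "numeric", arm = "character",
  matureCount = "numeric", starSeq = "character", starOffset = "numeric",
  starCount = "numeric", ledger = "logical", status = "character",
  family = "character"))

setValidity("HairpinCandidate", function(object) {
  msg <- character()
  if (object@start > object@end) msg <- c(msg, "start > end")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "bad strand")
  if (!object@status %in% c("candidate", "excluded", "known", "novel",
                            "rejected"))
    msg <- c(msg, "bad status")
  need <- c("exon_overlap", "repeat_overlap", "mfe_fail", "pseudo",
            "not_hairpin")
  if (!all(need %in% names(object@ledger)))
    msg <- c(msg, "ledger flags incomplete")
  if (length(msg)) msg else TRUE
})

#' Descriptive census of a small-RNA library
#'
#' @slot totals named counts: raw_reads, raw_distinct, filtered_reads,
#'   filtered_distinct, dropped_reads, mapped_reads, mapped_distinct,
#'   unmapped_reads, unmapped_distinct
#' @slot classPartition data.frame: klass, distinct, reads, frac_distinct,
#'   frac_reads (over mapped tags; includes "unannotated")
#' @slot sizeDistribution read-weighted fraction per length (sums to 1)
#' @slot firstBase position x base read-weighted frequency matrix
#' @exportClass CensusReport
setClass("CensusReport", representation(
  totals = "numeric", classPartition = "data.frame",
  sizeDistribution = "numeric", firstBase = "matrix"))

#' Per-transcript degradome profile
#'
#' Positions are 1-based transcript coordinates of degradome-tag 5' ends.
#' \code{norm} is the repeat-normalized abundance: a tag placing at k
#' locations (across all transcripts) contributes count/k at each.
#'
#' @slot transcript transcript id
#' @slot stage developmental stage label (I-IV)
#' @slot positions data.frame: pos, raw, norm (ascending pos)
#' @exportClass DegradomeProfile
setClass("DegradomeProfile", representation(
  transcript = "character", stage = "character", positions = "data.frame"))

setValidity("DegradomeProfile", function(object) {
  p <- object@positions
  if (!all(c("pos", "raw", "norm") %in% names(p)))
    return("positions needs pos/raw/norm")
  if (is.unsorted(p$pos, strictly = TRUE)) return("positions must ascend")
  TRUE
})

#' A set of transcript models
#'
#' Sequences plus 5'-UTR/CDS/3'-UTR segmentation in 1-based inclusive
#' transcript coordinates. Segments of each transcript tile [1, length]
#' without overlap.
#'
#' @slot sequences named character vector of RNA sequences
#' @slot segments data.frame: transcript_id, gene_id, region, tx_start, tx_end
#' @exportClass TranscriptSet
setClass("TranscriptSet", representation(
  sequences = "character", segments = "data.frame"))

setValidity("TranscriptSet", function(object) {
  seg <- object@segments
  need <- c("transcript_id", "gene_id", "region", "tx_start", "tx_end")
  if (!all(need %in% names(seg))) return("segments columns incomplete")
  if (!all(seg$region %in% c("five_prime_utr", "cds", "three_prime_utr")))
    return("bad region label")
  for (tx in unique(seg$transcript_id)) {
    s <- seg[seg$transcript_id == tx, ]
    s <- s[order(s$tx_start), ]
    if (s$tx_start[1] != 1) return(paste0(tx, ": segments must start at 1"))
    if (nrow(s) > 1 && any(s$tx_start[-1] != head(s$tx_end, -1) + 1))
      return(paste0(tx, ": segments must tile without gaps/overlap"))
    if (!tx %in% names(object@sequences))
      return(paste0(tx, ": no sequence"))
    if (max(s$tx_end) != nchar(object@sequences[[tx]]))
      return(paste0(tx, ": segment span != sequence length"))
  }
  TRUE
})
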