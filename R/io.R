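#' @include AllClasses.R
#' @importFrom Biostrings readBStringSet writeXStringSet RNAStringSet
#'   DNAStringSet reverseComplement
#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table head adist
NULL

.canonRna <- function(x) chartr("tT u", "UU U", toupper(gsub("\\s", "", x)))

# Coerce an XStringSet or character vector to character, preserving names
# (the S4 as.character generic visible inside the namespace drops names on
# plain character input).
.asNamedChar <- function(x) {
  n <- names(x)
  y <- as.character(x)
  if (is.null(names(y))) names(y) <- n
  y
}

#' Read a FASTA file into the canonical RNA alphabet
#'
#' Sequences are canonicalized to RNA on ingest (T mapped to U); record
#' order is preserved and duplicate ids are rejected.
#'
#' @param path FASTA file
#' @return named \code{RNAStringSet}
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1])
    stop("malformed FASTA: first line is not a header (line 1)")
  idx <- which(hdr)
  ends <- c(idx[-1] - 1, length(lines))
  for (k in seq_along(idx)) {
    if (nchar(sub("^>\\s*", "", lines[idx[k]])) == 0)
      stop("malformed FASTA: empty header at line ", idx[k])
    body <- lines[seq(idx[k] + 1, length.out = max(0, ends[k] - idx[k]))]
    if (!length(body) || !nzchar(paste(gsub("\\s", "", body), collapse = "")))
      stop("malformed FASTA: empty sequence for record at line ", idx[k])
  }
  x <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .canonRna(as.character(x))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stop("non-alphabet characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  out <- RNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or XStringSet (RNA alphabet)
#' @param path output file
#' @param asDna write in the DNA alphabet (U mapped back to T)
#' @export
writeFasta <- function(seqs, path, asDna = FALSE) {
  s <- .asNamedChar(seqs)
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop("all sequences must be named")
  if (asDna) {
    x <- DNAStringSet(chartr("U", "T", s))
  } else {
    x <- RNAStringSet(s)
  }
  names(x) <- names(s)
  writeXStringSet(x, path)
  invisible(path)
}

.defaultKlassMap <- c(
  exon = "exon", CDS = "exon", repeat_region = "repeat", `repeat` = "repeat",
  transposable_element = "repeat", rRNA = "rRNA", tRNA = "tRNA",
  snRNA = "snRNA", snoRNA = "snoRNA", siRNA = "other_sRNA",
  other_sRNA = "other_sRNA")

#' Read an annotation track (BED or GFF3)
#'
#' Coordinate dialect is declared by the file extension: BED is 0-based
#' half-open, GFF3 is 1-based inclusive; both are returned as standard
#' 1-based closed \code{GRanges} (the conversion is handled by
#' \code{rtracklayer}). Feature names absent from \code{klassMap} are
#' dropped with a message stating how many.
#'
#' @param path BED (feature name in the name column) or GFF3 file
#' @param klassMap named character vector mapping source feature names to the
#'   class vocabulary (exon, repeat, rRNA, tRNA, snRNA, snoRNA, other_sRNA)
#' @return \code{GRanges} with a \code{klass} metadata column
#' @export
readAnnotation <- function(path, klassMap = .defaultKlassMap) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "bed") {
    gr <- import(path, format = "BED")
    feat <- mcols(gr)$name
  } else if (ext %in% c("gff", "gff3")) {
    gr <- import(path, format = "GFF3")
    feat <- as.character(mcols(gr)$type)
  } else stop("unknown annotation format: .", ext)
  if (any(start(gr) < 1)) stop("negative or zero coordinates in ", path)
  if (!all(klassMap %in% ANNOTATION_CLASSES))
    stop("klassMap values must be in the class vocabulary")
  klass <- unname(klassMap[feat])
  drop <- is.na(klass)
  if (any(drop))
    message(sum(drop), " intervals with unmapped feature names dropped")
  gr <- gr[!drop]
  mcols(gr) <- S4Vectors::DataFrame(klass = klass[!drop])
  gr
}

#' Write an annotation track as BED
#' @param track \code{GRanges} with a \code{klass} column
#' @param path output BED file
#' @export
writeAnnotation <- function(track, path) {
  mcols(track)$name <- mcols(track)$klass
  export(track, path, format = "BED")
  invisible(path)
}

.fixtureFiles <- c(
  table1 = "table1_novel_mirnas.tsv",
  table2_families = "table2_de_families.tsv",
  table3 = "table3_conserved_targets.tsv",
  table4 = "table4_nonconserved_targets.tsv")

#' Load a packaged table fixture
#'
#' The four main-text tables of the source study are shipped as
#' tab-separated fixtures transcribed verbatim: the 26 newly identified
#' miRNAs (table1), the differentially expressed miRNA families
#' (table2_families), and the conserved (table3) and non-conserved (table4)
#' degradome target tables.
#'
#' @param name one of "table1", "table2_families", "table3", "table4"
#' @return data.frame mirroring the printed columns
#' @export
loadFixture <- function(name) {
  if (!name %in% names(.fixtureFiles))
    stop("unknown fixture: ", name, " (use ",
         paste(names(.fixtureFiles), collapse = "/"), ")")
  path <- system.file("extdata", "fixtures", .fixtureFiles[[name]],
                      package = "earpipe", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  num <- intersect(c("size_nt", "loci", "mirna_abundance",
                     "star_abundance"), names(df))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  if (name == "table1" && nrow(df) != 26)
    stop("table1 fixture must have 26 rows")
  if (name == "table4" && nrow(df) != 14)
    stop("table4 fixture must have 14 rows")
  df
}

#' Write a t-plot table for one transcript profile
#'
#' One row per occupied position (ascending): position, raw tag count,
#' repeat-normalized abundance and a flag marking the predicted cleavage
#' site, the tabular form of the degradome "target plot".
#'
#' @param profile a \code{DegradomeProfile}
#' @param site predicted cleavage-site coordinate (1-based)
#' @param path output TSV
#' @param txLength optional transcript length for range checking
#' @export
writeTplot <- function(profile, site, path, txLength = NA) {
  pos <- profilePositions(profile)
  if (!nrow(pos)) stop("empty profile")
  lim <- if (is.na(txLength)) max(pos$pos) else txLength
  if (site < 1 || site > lim)
    stop("site ", site, " outside transcript (length ", lim, ")")
  out <- data.frame(position = pos$pos, raw = pos$raw, normalized = pos$norm,
                    is_predicted_site = pos$pos == site)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read small-RNA reads from a count-encoded FASTA
#'
#' Headers of the form \code{tag_<i>_x<count>} carry the read multiplicity;
#' headers without the \code{_x<count>} suffix count as single reads.
#'
#' @param path FASTA file
#' @return data.frame with columns seq, count
#' @export
readReadsFasta <- function(path) {
  x <- readFasta(path)
  cnt <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", names(x))))
  cnt[is.na(cnt)] <- 1L
  data.frame(seq = as.character(x), count = cnt, stringsAsFactors = FALSE)
}

#' Write reads as a count-encoded FASTA
#' @param reads data.frame with seq, count
#' @param path output FASTA
#' @export
writeReadsFasta <- function(reads, path) {
  s <- reads$seq
  names(s) <- sprintf("tag_%d_x%d", seq_along(s), reads$count)
  writeFasta(s, path)
}

#' Read transcript models (FASTA + transcript-space GFF3)
#'
#' The GFF3 is expected in transcript coordinates (seqid = transcript id)
#' with feature types five_prime_UTR / CDS / three_prime_UTR and a
#' \code{gene_id} attribute; projection of genome-space annotation through
#' exon chains is out of scope.
#'
#' @param fastaPath transcript FASTA
#' @param gffPath transcript-space GFF3
#' @return a \code{TranscriptSet}
#' @export
readTranscripts <- function(fastaPath, gffPath) {
  seqs <- .asNamedChar(readFasta(fastaPath))
  gr <- import(gffPath, format = "GFF3")
  regMap <- c(five_prime_UTR = "five_prime_utr", CDS = "cds",
              three_prime_UTR = "three_prime_utr")
  type <- as.character(mcols(gr)$type)
  keep <- type %in% names(regMap)
  gr <- gr[keep]
  gene <- mcols(gr)$gene_id
  if (is.null(gene)) gene <- as.character(seqnames(gr))
  seg <- data.frame(
    transcript_id = as.character(seqnames(gr)),
    gene_id = as.character(gene),
    region = unname(regMap[type[keep]]),
    tx_start = start(gr), tx_end = end(gr), stringsAsFactors = FALSE)
  seg <- seg[order(seg$transcript_id, seg$tx_start), ]
  rownames(seg) <- NULL
  new("TranscriptSet", sequences = seqs, segments = seg)
}

#' Write transcript models to FASTA + transcript-space GFF3
#' @param ts a \code{TranscriptSet}
#' @param fastaPath,gffPath output paths
#' @export
writeTranscripts <- function(ts, fastaPath, gffPath) {
  writeFasta(txSequences(ts), fastaPath)
  seg <- txSegments(ts)
  regMap <- c(five_prime_utr = "five_prime_UTR", cds = "CDS",
              three_prime_utr = "three_prime_UTR")
  gr <- GRanges(seg$transcript_id,
                IRanges(seg$tx_start, seg$tx_end), strand = "+")
  mcols(gr)$type <- unname(regMap[seg$region])
  mcols(gr)$phase <- ifelse(seg$region == "cds", 0L, NA_integer_)
  mcols(gr)$gene_id <- seg$gene_id
  mcols(gr)$ID <- sprintf("%s.%s", seg$transcript_id, seg$region)
  export(gr, gffPath, format = "GFF3")
  invisible(gffPath)
}
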