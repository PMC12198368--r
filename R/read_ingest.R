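#' Aligned long-read ingestion
#'
#' A `read_set` is an immutable container for the primary alignment spans of
#' one sample: a data.frame of reads (`read_id`, `start`, `end`, `strand`,
#' `sample_id`, `mapq`) plus the total aligned count, which serves as the
#' denominator of all per-sample fractions.
#'
#' @param reads data.frame with columns `read_id`, `start`, `end`, `strand`
#'   and optionally `mapq`.
#' @param sample_id sample identifier attached to every read.
#' @return an object of class `read_set`.
#' @export
read_set <- function(reads, sample_id) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  need <- c("read_id", "start", "end", "strand")
  stopifnot(all(need %in% names(reads)))
  if (!"mapq" %in% names(reads)) reads$mapq <- rep(NA_integer_, nrow(reads))
  reads$start <- as.integer(reads$start)
  reads$end <- as.integer(reads$end)
  if (nrow(reads)) {
    if (any(reads$start >= reads$end)) stop("read with end <= start")
    if (!all(reads$strand %in% c("+", "-"))) stop("read with undefined strand")
  }
  reads$sample_id <- rep(sample_id, nrow(reads))
  reads <- reads[, c("read_id", "start", "end", "strand", "sample_id", "mapq")]
  rownames(reads) <- NULL
  structure(list(sample_id = sample_id, reads = reads,
                 total_aligned = nrow(reads)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$sample_id, "-", x$total_aligned, "aligned reads\n")
  invisible(x)
}

#' Read aligned reads from a BED6 file
#'
#' Each BED record (one interval per primary alignment, as produced by
#' `bedtools bamtobed` on a sorted BAM) becomes one aligned read. Malformed
#' lines abort the load with their line numbers; an empty file yields an
#' empty set with a warning.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param sample_id sample identifier.
#' @param contig if non-`NULL`, keep only records on this contig; the number
#'   of dropped records is reported via `message()`.
#' @return a `read_set`.
#' @export
read_bed <- function(path, sample_id, contig = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (!length(lines_keep)) {
    warning("empty BED file: ", path)
    return(read_set(data.frame(read_id = character(), start = integer(),
                               end = integer(), strand = character()),
                    sample_id))
  }
  parts <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop("BED line(s) with fewer than 6 fields (missing strand): line ",
         paste(lines_keep[nf < 6L], collapse = ", "))
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- is.na(start) | is.na(end) | end <= start
  if (any(bad))
    stop("malformed BED interval (end <= start or non-numeric) at line ",
         paste(lines_keep[bad], collapse = ", "))
  if (!all(m[, 6] %in% c("+", "-")))
    stop("invalid strand at line ",
         paste(lines_keep[!m[, 6] %in% c("+", "-")], collapse = ", "))
  df <- data.frame(chrom = m[, 1], read_id = m[, 4], start = start, end = end,
                   strand = m[, 6],
                   mapq = suppressWarnings(as.integer(m[, 5])),
                   stringsAsFactors = FALSE)
  if (!is.null(contig)) {
    dropped <- sum(df$chrom != contig)
    if (dropped > 0)
      message(dropped, " read(s) on other contigs ignored (keeping ", contig, ")")
    df <- df[df$chrom == contig, , drop = FALSE]
  }
  read_set(df[, c("read_id", "start", "end", "strand", "mapq")], sample_id)
}

#' Read aligned reads directly from SAM/BAM
#'
#' Convenience equivalent of the BAM-to-BED conversion step: primary
#' alignments only (secondary and supplementary records dropped), each
#' reduced to its outer reference span — spliced alignments are collapsed
#' across reference skips, matching what `bamtobed` emits per alignment.
#' With `split = TRUE` each aligned block is emitted as its own interval
#' instead, for sensitivity analysis.
#'
#' @param path SAM or BAM file (BAM need not be indexed; the whole file is
#'   streamed).
#' @param sample_id sample identifier.
#' @param min_mapq minimum mapping quality (default 0: no filter, matching a
#'   pipeline that applies none).
#' @param contig if non-`NULL`, keep only this contig.
#' @param split emit one interval per aligned block rather than one per
#'   alignment.
#' @return a `read_set`; [read_bed()] on the `bamtobed` conversion of the
#'   same file yields an identical set (oracle equivalence, tested).
#' @export
read_alignments <- function(path, sample_id, min_mapq = 0, contig = NULL,
                            split = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("mapq"))
  aln <- GenomicAlignments::readGAlignments(path, use.names = TRUE, param = param)
  mapq <- S4Vectors::mcols(aln)$mapq
  keep <- is.na(mapq) | mapq >= min_mapq
  aln <- aln[keep]; mapq <- mapq[keep]
  if (!is.null(contig)) {
    on_contig <- as.character(GenomeInfoDb::seqnames(aln)) == contig
    dropped <- sum(!on_contig)
    if (dropped > 0)
      message(dropped, " alignment(s) on other contigs ignored (keeping ", contig, ")")
    aln <- aln[on_contig]; mapq <- mapq[on_contig]
  }
  if (split) {
    blocks <- GenomicAlignments::grglist(aln, drop.D.ranges = FALSE)
    gr <- unlist(blocks, use.names = TRUE)
    df <- data.frame(read_id = names(gr),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     mapq = rep(mapq, lengths(blocks)),
                     stringsAsFactors = FALSE)
  } else {
    gr <- GenomicRanges::granges(aln)
    df <- data.frame(read_id = names(aln),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     mapq = mapq, stringsAsFactors = FALSE)
  }
  read_set(df, sample_id)
}

#' Write a read set to BED6
#'
#' @param rs a `read_set`.
#' @param path output file.
#' @param chrom contig name for column 1.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(rs, path, chrom = "chrM") {
  r <- rs$reads
  score <- ifelse(is.na(r$mapq), 0L, r$mapq)
  bed <- data.frame(chrom = chrom, start = r$start, end = r$end,
                    name = r$read_id, score = score, strand = r$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
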