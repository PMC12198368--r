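#' Build a validated mitochondrial genome annotation
#'
#' Constructs a `mito_annotation` object from a table of gene features on a
#' circular genome, derives the processed transcript units (single genes by
#' default, multi-gene units such as bicistrons where declared), and derives
#' the ordered unit-to-unit junctions together with their canonical status
#' under the tRNA punctuation model: a junction is canonical when a tRNA gene
#' abuts the cleavage site on either side, and non-canonical otherwise (as at
#' mRNA-mRNA boundaries of the mtAtp8/6-mtCo3 type, or a 5' leader boundary).
#'
#' Coordinates are 0-based half-open throughout. A feature may span the
#' circular origin: supply `start > end` and it is stored as two linear arcs
#' (`arc` 1 covering `[start, genome_length)` and `arc` 2 covering
#' `[0, end)`); all interval queries then operate on the linearisation.
#'
#' @param features data.frame with columns `name`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `biotype` (one of `"mRNA"`, `"rRNA"`, `"tRNA"`,
#'   `"leader"`, `"noncoding"`).
#' @param genome_length genome length in nt.
#' @param genome_id identifier string for the reference sequence.
#' @param unit_spec optional list describing multi-gene units and UTR
#'   extensions: `merge` is a list of character vectors of member gene names
#'   (contiguous, same strand); `utr5`/`utr3` are named numeric vectors of
#'   nt extensions applied to a unit's span at its transcriptional 5'/3' end.
#' @param origin_junction declare a junction between the last and first unit
#'   across the circular origin (per strand).
#' @return an object of class `mito_annotation` with elements `genome_id`,
#'   `genome_length`, `features`, `units` and `junctions`.
#' @export
mito_annotation <- function(features, genome_length, genome_id = "custom",
                            unit_spec = NULL, origin_junction = FALSE) {
  stopifnot(is.data.frame(features),
            all(c("name", "start", "end", "strand", "biotype") %in% names(features)))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  features$name <- as.character(features$name)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  features$biotype <- as.character(features$biotype)

  if (anyDuplicated(features$name))
    stop("duplicate gene names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  ok_biotype <- c("mRNA", "rRNA", "tRNA", "leader", "noncoding")
  if (!all(features$biotype %in% ok_biotype))
    stop("unknown biotype(s): ",
         paste(setdiff(features$biotype, ok_biotype), collapse = ", "))

  # split origin-spanning features (start > end) into two linear arcs
  wraps <- features$start > features$end
  if (any(wraps)) {
    w <- features[wraps, , drop = FALSE]
    arc1 <- transform(w, end = as.integer(genome_length), arc = 1L)
    arc2 <- transform(w, start = 0L, arc = 2L)
    features <- rbind(transform(features[!wraps, , drop = FALSE], arc = 1L),
                      arc1, arc2)
  } else {
    features$arc <- 1L
  }
  bad <- features$start < 0 | features$end > genome_length |
    features$start >= features$end
  if (any(bad))
    stop("coordinates outside [0, genome_length) or empty for: ",
         paste(features$name[bad], collapse = ", "))
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL

  units <- .derive_units(features, unit_spec, genome_length)
  junctions <- .derive_junctions(features, units, genome_length, origin_junction)

  structure(list(genome_id = genome_id,
                 genome_length = as.integer(genome_length),
                 features = features,
                 units = units,
                 junctions = junctions),
            class = "mito_annotation")
}

# units: one row per processed transcript unit; members kept as a comma string
.derive_units <- function(features, unit_spec, genome_length) {
  merge_sets <- unit_spec$merge %||% list()
  utr5 <- unit_spec$utr5 %||% numeric()
  utr3 <- unit_spec$utr3 %||% numeric()

  for (m in merge_sets) {
    missing <- setdiff(m, features$name)
    if (length(missing))
      stop("unit member(s) not in annotation: ", paste(missing, collapse = ", "))
  }
  assigned <- unlist(merge_sets)
  if (anyDuplicated(assigned))
    stop("gene assigned to more than one unit: ",
         paste(unique(assigned[duplicated(assigned)]), collapse = ", "))

  singles <- setdiff(unique(features$name), assigned)
  member_sets <- c(as.list(singles), merge_sets)

  rows <- lapply(member_sets, function(m) {
    f <- features[features$name %in% m, , drop = FALSE]
    if (length(unique(f$strand)) != 1L)
      stop("unit members on mixed strands: ", paste(m, collapse = ", "))
    strand <- f$strand[1]
    if (any(f$arc == 2L)) {
      # origin-spanning gene: one unit row per linear arc
      if (length(m) > 1L)
        stop("origin-spanning gene cannot be merged into a multi-gene unit: ",
             paste(m, collapse = ", "))
      return(data.frame(unit = m, span_start = f$start, span_end = f$end,
                        strand = strand, members = m, first_member = m,
                        last_member = m, arc = f$arc, stringsAsFactors = FALSE))
    }
    # contiguity: no same-strand feature of another unit may lie inside the span
    span <- c(min(f$start), max(f$end))
    others <- features[features$strand == strand & !(features$name %in% m), , drop = FALSE]
    inside <- others$start >= span[1] & others$end <= span[2]
    if (any(inside))
      stop("unit members not contiguous (", paste(m, collapse = ","),
           " encloses ", paste(others$name[inside], collapse = ","), ")")
    # order members along the genome
    m_ord <- f$name[order(f$start)]
    uname <- if (length(m) == 1L) m else paste(m_ord, collapse = "/")
    u5 <- if (uname %in% names(utr5)) utr5[[uname]] else 0
    u3 <- if (uname %in% names(utr3)) utr3[[uname]] else 0
    if (strand == "+") {
      span[1] <- span[1] - u5; span[2] <- span[2] + u3
    } else {
      span[1] <- span[1] - u3; span[2] <- span[2] + u5
    }
    span[1] <- max(0L, span[1]); span[2] <- min(genome_length, span[2])
    data.frame(unit = uname, span_start = as.integer(span[1]),
               span_end = as.integer(span[2]), strand = strand,
               members = paste(m_ord, collapse = ","),
               first_member = m_ord[1], last_member = m_ord[length(m_ord)],
               arc = 1L, stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, rows)
  units <- units[order(units$span_start), , drop = FALSE]
  rownames(units) <- NULL

  for (s in c("+", "-")) {
    u <- units[units$strand == s, , drop = FALSE]
    if (nrow(u) > 1L) {
      u <- u[order(u$span_start), , drop = FALSE]
      ovl <- u$span_start[-1] < u$span_end[-nrow(u)]
      if (any(ovl))
        stop("overlapping same-strand units: ",
             paste(u$unit[which(ovl)], u$unit[which(ovl) + 1L],
                   sep = " / ", collapse = "; "))
    }
  }
  units
}

# junctions in transcription order per strand; kind from flanking biotypes
.derive_junctions <- function(features, units, genome_length, origin_junction) {
  biotype_of <- stats::setNames(features$biotype[!duplicated(features$name)],
                                features$name[!duplicated(features$name)])
  out <- list()
  for (s in c("+", "-")) {
    u <- units[units$strand == s, , drop = FALSE]
    if (nrow(u) < 2L) next
    u <- u[order(u$span_start), , drop = FALSE]
    if (s == "-") u <- u[rev(seq_len(nrow(u))), , drop = FALSE]  # transcription order
    n <- nrow(u)
    idx <- seq_len(n - 1L)
    if (origin_junction) idx <- c(idx, n)
    for (i in idx) {
      j <- if (i == n) 1L else i + 1L
      up <- u[i, ]; down <- u[j, ]
      # cut_up / cut_down: the transcriptional 3' edge of the upstream unit
      # and 5' edge of the downstream unit; equal when the units abut, and
      # both are cleavage points when a gap separates them
      cut_up <- if (s == "+") up$span_end else up$span_start
      cut_down <- if (s == "+") down$span_start else down$span_end
      pos <- if (i == n) cut_up else cut_down
      flank_bt <- c(biotype_of[[up$last_member]], biotype_of[[down$first_member]])
      if (s == "-") flank_bt <- c(biotype_of[[up$first_member]], biotype_of[[down$last_member]])
      kind <- if ("tRNA" %in% flank_bt) "canonical" else "non-canonical"
      out[[length(out) + 1L]] <- data.frame(
        label = paste(up$unit, down$unit, sep = ","),
        upstream_unit = up$unit, downstream_unit = down$unit,
        position = as.integer(pos), cut_up = as.integer(cut_up),
        cut_down = as.integer(cut_down), strand = s, kind = kind,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(label = character(), upstream_unit = character(),
                      downstream_unit = character(), position = integer(),
                      cut_up = integer(), cut_down = integer(),
                      strand = character(), kind = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mito_annotation <- function(x, ...) {
  cat("mito_annotation:", x$genome_id, sprintf("(%d nt)\n", x$genome_length))
  cat(" ", nrow(x$features), "features;", nrow(x$units), "units;",
      nrow(x$junctions), "junctions (",
      sum(x$junctions$kind == "canonical"), "canonical )\n")
  invisible(x)
}

#' Load a genome annotation from GFF3 or BED
#'
#' GFF3 input (1-based closed coordinates) is converted to the internal
#' 0-based half-open convention on load; the gene name is taken from the
#' `Name` (or `ID`) attribute and the biotype from a `biotype`,
#' `gene_biotype` or `type` field. BED input must be BED6 plus a seventh
#' column holding the biotype.
#'
#' @param path annotation file (`.gff`/`.gff3` or `.bed`).
#' @param genome_length genome length in nt (required for BED; for GFF3 it is
#'   read from the `##sequence-region` pragma when present).
#' @param genome_id reference identifier; defaults to the contig name.
#' @param unit_spec as in [mito_annotation()].
#' @param origin_junction as in [mito_annotation()].
#' @return a `mito_annotation`.
#' @export
load_annotation <- function(path, genome_length = NULL, genome_id = NULL,
                            unit_spec = NULL, origin_junction = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    name <- if ("Name" %in% names(md)) as.character(md$Name) else as.character(md$ID)
    biotype <- if ("biotype" %in% names(md)) as.character(md$biotype)
      else if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype)
      else as.character(md$type)
    feats <- data.frame(
      name = name,
      start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = biotype, stringsAsFactors = FALSE)
    if (is.null(genome_length)) {
      genome_length <- .gff3_sequence_region_length(path)
      if (is.na(genome_length))
        stop("genome_length not given and no ##sequence-region pragma in GFF3")
    }
    if (is.null(genome_id))
      genome_id <- as.character(GenomeInfoDb::seqnames(gr))[1]
  } else if (ext == "bed") {
    if (is.null(genome_length)) stop("genome_length is required for BED input")
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 7L) stop("annotation BED must be BED6 + biotype column")
    feats <- data.frame(name = tab[[4]], start = tab[[2]], end = tab[[3]],
                        strand = tab[[6]], biotype = tab[[7]],
                        stringsAsFactors = FALSE)
    if (is.null(genome_id)) genome_id <- tab[[1]][1]
  } else {
    stop("unsupported annotation format: .", ext)
  }
  mito_annotation(feats, genome_length = genome_length, genome_id = genome_id,
                  unit_spec = unit_spec, origin_junction = origin_junction)
}

# "##sequence-region <id> <start> <end>" -> end (1-based closed = length)
.gff3_sequence_region_length <- function(path) {
  hdr <- grep("^##sequence-region", readLines(path, n = 50L), value = TRUE)
  if (!length(hdr)) return(NA_integer_)
  as.integer(strsplit(trimws(hdr[1]), "\\s+")[[1]][4])
}

#' Write an annotation back to BED6 + biotype
#'
#' The inverse of [load_annotation()] for BED input: reloading the written
#' file with the same `genome_length` and `unit_spec` reproduces the
#' annotation (round-trip identity). Origin-spanning features are written as
#' their two arcs.
#'
#' @param annotation a `mito_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  f <- annotation$features
  bed <- data.frame(chrom = annotation$genome_id, start = f$start, end = f$end,
                    name = f$name, score = 0L, strand = f$strand,
                    biotype = f$biotype)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Canonical status of a junction
#'
#' @param annotation a `mito_annotation`.
#' @param junction a junction label (`"upstream,downstream"`), or a position
#'   given as a single number (matched on the junction's nt position).
#' @return `"canonical"` or `"non-canonical"`.
#' @export
junction_kind <- function(annotation, junction) {
  j <- annotation$junctions
  hit <- if (is.numeric(junction)) which(j$position == junction)
         else which(j$label == junction)
  if (!length(hit)) stop("unknown junction: ", junction)
  j$kind[hit[1]]
}

#' Centre positions of annotated tRNAs
#'
#' Returns `floor((start + end) / 2)` for every tRNA feature, named by gene.
#' Used by the read-through statistic, which asks whether a read passes
#' through at least the centre of a tRNA.
#'
#' @param annotation a `mito_annotation`.
#' @return named integer vector (empty when the annotation has no tRNAs).
#' @export
trna_centres <- function(annotation) {
  f <- annotation$features
  t <- f[f$biotype == "tRNA" & f$arc == 1L, , drop = FALSE]
  stats::setNames(as.integer(floor((t$start + t$end) / 2)), t$name)
}
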