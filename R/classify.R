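#' Analysis parameters
#'
#' Bundles the thresholds of the boundary-tolerance classification and the
#' downstream summary statistics.
#'
#' @param tol boundary tolerance in nt: a read is processed when both of its
#'   ends fall within `tol` nt of one transcript unit's annotated boundaries
#'   (default 20 nt, which also absorbs the systematic ~12 nt 5' truncation
#'   of direct-RNA nanopore reads).
#' @param pool_threshold compositions pool junction groups below this share
#'   of the unprocessed pool into an "other" category (default 0.02).
#' @param delta_vis_threshold delta records with absolute value at or below
#'   this many percentage points are flagged as not visualised (default 0.5).
#' @param abundance_cutoff tRNA read-through species are reported only when
#'   the passing reads exceed this fraction of total reads (default 1e-4,
#'   i.e. 0.01 %).
#' @param contain_rule how a read "contains" a unit or gene: `"centre"`
#'   (spans the unit's midpoint; default), `"full"` (covers the whole span),
#'   or `"frac50"` (overlaps at least half of the span).
#' @return an object of class `analysis_params`.
#' @export
analysis_params <- function(tol = 20, pool_threshold = 0.02,
                            delta_vis_threshold = 0.5,
                            abundance_cutoff = 1e-4,
                            contain_rule = c("centre", "full", "frac50")) {
  contain_rule <- match.arg(contain_rule)
  stopifnot(tol >= 0, pool_threshold >= 0, pool_threshold <= 1,
            delta_vis_threshold >= 0, abundance_cutoff >= 0,
            abundance_cutoff <= 1)
  structure(list(tol = as.integer(tol), pool_threshold = pool_threshold,
                 delta_vis_threshold = delta_vis_threshold,
                 abundance_cutoff = abundance_cutoff,
                 contain_rule = contain_rule),
            class = "analysis_params")
}

#' Classify reads as processed or unprocessed
#'
#' A read is *processed* when there is a transcript unit on its strand whose
#' span boundaries both lie within `tol` nt of the read's ends; otherwise it
#' is *unprocessed*. Unprocessed reads are assigned to junction groups: after
#' trimming `tol` nt off each read end (so that end jitter cannot create
#' spurious membership), the set of same-strand units the read still overlaps
#' by at least 1 nt, in genome order, labelled `"unit1,unit2,..."`. Finer
#' categories keep the partition exact:
#' \describe{
#'   \item{`junction`}{two or more units overlapped — a genuine uncleaved
#'     junction read.}
#'   \item{`single_unit_extended`}{one unit overlapped but one read end
#'     extends more than `tol` nt beyond the unit span into a featureless
#'     flank; labelled `"flank_5p,unit"` or `"unit,flank_3p"` (genome order
#'     on the plus strand).}
#'   \item{`internal_fragment`}{both ends strictly inside one unit beyond
#'     `tol`; no junction involved, reported as its own category.}
#'   \item{`intergenic_antisense`}{no same-strand unit overlapped; the label
#'     lists any opposite-strand units under an `antisense:` prefix.}
#' }
#' Each read also carries tRNA flags: whether its strand-aware 5' and 3'
#' termini lie inside a same-strand tRNA gene, and which tRNA centres its
#' span covers.
#'
#' @param reads a `read_set` or a read data.frame.
#' @param annotation a `mito_annotation`.
#' @param params an `analysis_params`.
#' @return data.frame with one row per read: `read_id`, `sample_id`,
#'   `start`, `end`, `strand`, `status`, `category`, `unit`, `group`,
#'   `n_units`, `trna_5prime`, `trna_3prime`, `trna_centres_covered`.
#' @export
classify_reads <- function(reads, annotation, params = analysis_params()) {
  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  n <- nrow(r)
  units <- annotation$units
  tol <- params$tol

  status <- rep("unprocessed", n)
  category <- rep(NA_character_, n)
  unit_hit <- rep(NA_character_, n)
  group <- rep(NA_character_, n)
  n_units <- integer(n)
  if (n == 0L)
    return(data.frame(read_id = character(), sample_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      status = character(), category = character(),
                      unit = character(), group = character(),
                      n_units = integer(), trna_5prime = logical(),
                      trna_3prime = logical(),
                      trna_centres_covered = character(),
                      stringsAsFactors = FALSE))

  # processed test: both read ends within tol of one same-strand unit span
  best_dev <- rep(Inf, n)
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    dev5 <- abs(r$start - u$span_start)
    dev3 <- abs(r$end - u$span_end)
    ok <- r$strand == u$strand & dev5 <= tol & dev3 <= tol
    better <- ok & (dev5 + dev3) < best_dev
    unit_hit[better] <- u$unit
    best_dev[better] <- (dev5 + dev3)[better]
  }
  processed <- !is.na(unit_hit)
  status[processed] <- "processed"
  category[processed] <- "processed"

  # junction-group membership on tol-trimmed spans
  tstart <- pmin(r$start + tol, r$end - 1L)
  tend <- pmax(r$end - tol, r$start + 1L)
  collapsed <- tstart >= tend
  mid <- (r$start + r$end) %/% 2L
  tstart[collapsed] <- mid[collapsed]
  tend[collapsed] <- mid[collapsed] + 1L

  same_members <- vector("list", n)   # unit indices, genome order
  anti_members <- vector("list", n)
  uq <- IRanges::IRanges(start = units$span_start + 1L, end = units$span_end)
  rq <- IRanges::IRanges(start = tstart + 1L, end = tend)
  hits <- IRanges::findOverlaps(rq, uq, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- r$strand[qh] == units$strand[sh]
  same_members <- split(sh[same], factor(qh[same], levels = seq_len(n)))
  anti_members <- split(sh[!same], factor(qh[!same], levels = seq_len(n)))

  unproc <- which(!processed)
  for (k in unproc) {
    mem <- same_members[[k]]
    if (length(mem) >= 2L) {
      category[k] <- "junction"
      group[k] <- paste(units$unit[sort(mem)], collapse = ",")
      n_units[k] <- length(mem)
    } else if (length(mem) == 1L) {
      u <- units[mem, ]
      left_ext <- u$span_start - r$start[k]
      right_ext <- r$end[k] - u$span_end
      if (left_ext > tol || right_ext > tol) {
        category[k] <- "single_unit_extended"
        lab <- u$unit
        if (left_ext > tol) lab <- paste("flank_5p", lab, sep = ",")
        if (right_ext > tol) lab <- paste(lab, "flank_3p", sep = ",")
        group[k] <- lab
      } else {
        category[k] <- "internal_fragment"
      }
      n_units[k] <- 1L
    } else {
      category[k] <- "intergenic_antisense"
      anti <- anti_members[[k]]
      group[k] <- if (length(anti))
        paste0("antisense:", paste(units$unit[sort(anti)], collapse = ","))
      else "intergenic"
      n_units[k] <- 0L
    }
  }
  n_units[processed] <- 1L

  flags <- trna_terminal_flags(r, annotation)
  centres <- trna_centres(annotation)
  covered <- rep("", n)
  if (length(centres)) {
    cov_mat <- outer(r$start, centres, `<=`) & outer(r$end, centres, `>`)
    # strand-aware: only same-strand tRNAs count
    tfeat <- annotation$features[annotation$features$biotype == "tRNA" &
                                   annotation$features$arc == 1L, ]
    tstrand <- stats::setNames(tfeat$strand, tfeat$name)[colnames(cov_mat)]
    cov_mat <- cov_mat & outer(r$strand, tstrand, `==`)
    covered <- apply(cov_mat, 1L, function(z)
      paste(colnames(cov_mat)[z], collapse = ","))
  }

  data.frame(read_id = r$read_id,
             sample_id = if ("sample_id" %in% names(r)) r$sample_id else NA_character_,
             start = r$start, end = r$end, strand = r$strand,
             status = status, category = category, unit = unit_hit,
             group = group, n_units = n_units,
             trna_5prime = flags$trna_5prime, trna_3prime = flags$trna_3prime,
             trna_centres_covered = covered,
             stringsAsFactors = FALSE)
}

#' Classify a single read
#'
#' Single-read convenience wrapper around [classify_reads()].
#'
#' @param read one-row data.frame (or list) with `start`, `end`, `strand`.
#' @param annotation a `mito_annotation`.
#' @param params an `analysis_params`.
#' @return a one-row classification data.frame.
#' @export
classify_read <- function(read, annotation, params = analysis_params()) {
  df <- as.data.frame(read, stringsAsFactors = FALSE)
  if (!"read_id" %in% names(df)) df$read_id <- "read1"
  classify_reads(df, annotation, params)
}

#' tRNA presence at read termini
#'
#' The strand-aware 5' terminus of a plus-strand read is its start
#' coordinate and its 3' terminus the last covered base (`end - 1`); on the
#' minus strand the two are swapped. A flag is true when that terminus lies
#' inside a same-strand tRNA gene.
#'
#' @param reads read data.frame (or one-row read) with `start`, `end`,
#'   `strand`.
#' @param annotation a `mito_annotation`.
#' @return data.frame with logical columns `trna_5prime`, `trna_3prime`.
#' @export
trna_terminal_flags <- function(reads, annotation) {
  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  t <- annotation$features[annotation$features$biotype == "tRNA", , drop = FALSE]
  pos5 <- ifelse(r$strand == "+", r$start, r$end - 1L)
  pos3 <- ifelse(r$strand == "+", r$end - 1L, r$start)
  inside <- function(pos) {
    res <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(t)))
      res <- res | (r$strand == t$strand[i] & pos >= t$start[i] & pos < t$end[i])
    res
  }
  data.frame(trna_5prime = inside(pos5), trna_3prime = inside(pos3))
}

# does each read "contain" the interval [s, e) on the given strand?
.contains_span <- function(r, s, e, strand, rule) {
  same <- r$strand == strand
  switch(rule,
         centre = {
           c0 <- (s + e) %/% 2L
           same & r$start <= c0 & r$end > c0
         },
         full = same & r$start <= s & r$end >= e,
         frac50 = {
           ovl <- pmax(0L, pmin(r$end, e) - pmax(r$start, s))
           same & ovl >= (e - s) / 2
         },
         stop("unknown contain_rule: ", rule))
}

#' Fraction of a unit's reads that are fully processed
#'
#' Denominator: reads containing the unit under `params$contain_rule`
#' (default: spanning the unit's centre). Numerator: those classified as
#' processed with that unit. Returns `NA` when no read contains the unit.
#'
#' @param reads a `read_set`.
#' @param unit unit name.
#' @param annotation a `mito_annotation`.
#' @param params an `analysis_params`.
#' @param classifications optional precomputed output of [classify_reads()]
#'   for `reads` (recomputed when missing).
#' @return a fraction in `[0, 1]`, or `NA`.
#' @export
fully_processed_fraction <- function(reads, unit, annotation,
                                     params = analysis_params(),
                                     classifications = NULL) {
  u <- annotation$units[annotation$units$unit == unit, ]
  if (!nrow(u)) stop("unknown unit: ", unit)
  if (is.null(classifications))
    classifications <- classify_reads(reads, annotation, params)
  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  contains <- .contains_span(r, u$span_start, u$span_end, u$strand,
                             params$contain_rule)
  denom <- sum(contains)
  if (denom == 0L) return(NA_real_)
  numer <- sum(contains & classifications$status == "processed" &
                 !is.na(classifications$unit) & classifications$unit == unit)
  numer / denom
}
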