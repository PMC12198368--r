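#' Summarise per-read classifications for one sample
#'
#' Tallies the classification output into exact counts: total, processed and
#' unprocessed reads, per-junction-group counts (internal fragments excluded
#' — they involve no junction and are counted separately), and per-unit
#' processed counts. `processed_count + unprocessed_count = total_reads`
#' always holds.
#'
#' @param classifications output of [classify_reads()] for one sample.
#' @param sample_id sample identifier (defaults to the one in the table).
#' @return an object of class `sample_summary` with elements `sample_id`,
#'   `total_reads`, `processed_count`, `unprocessed_count`,
#'   `internal_count`, `group_counts` (named integer vector) and
#'   `unit_counts`.
#' @export
summarize_sample <- function(classifications, sample_id = NULL) {
  cl <- classifications
  if (is.null(sample_id)) {
    sid <- unique(stats::na.omit(cl$sample_id))
    sample_id <- if (length(sid) == 1L) sid else "sample"
  }
  if (nrow(cl) == 0L) warning("empty classification table for ", sample_id)
  processed <- sum(cl$status == "processed")
  unprocessed <- sum(cl$status == "unprocessed")
  internal <- sum(cl$category == "internal_fragment")
  grp <- cl$group[cl$status == "unprocessed" & !is.na(cl$group)]
  group_counts <- if (length(grp)) {
    tab <- table(grp)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  un <- cl$unit[cl$status == "processed"]
  unit_counts <- if (length(un)) {
    tab <- table(un)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(), character())
  structure(list(sample_id = sample_id,
                 total_reads = nrow(cl),
                 processed_count = processed,
                 unprocessed_count = unprocessed,
                 internal_count = internal,
                 group_counts = group_counts,
                 unit_counts = unit_counts),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  frac <- if (x$total_reads > 0) x$unprocessed_count / x$total_reads else NA
  cat(sprintf("sample_summary: %s - %d reads, %.1f%% unprocessed, %d junction groups\n",
              x$sample_id, x$total_reads, 100 * frac, length(x$group_counts)))
  invisible(x)
}

#' Unprocessed fraction of a sample
#'
#' @param summary a `sample_summary`.
#' @return `unprocessed_count / total_reads` (`NA` for an empty sample).
#' @export
unprocessed_fraction <- function(summary) {
  if (summary$total_reads == 0L) return(NA_real_)
  summary$unprocessed_count / summary$total_reads
}

#' Composition of the unprocessed pool with pooling
#'
#' Expresses every unprocessed category (junction groups plus, when present,
#' an `internal_fragment` category) as a share of the unprocessed pool;
#' shares sum to 1 before pooling. Categories below `pool_threshold` are
#' merged into `"other"`.
#'
#' @param summary a `sample_summary`.
#' @param pool_threshold minimum share kept as its own category
#'   (default 0.02).
#' @return data.frame with columns `label` and `share`, ordered by
#'   decreasing share ("other" last). Empty when the sample has no
#'   unprocessed reads.
#' @export
composition <- function(summary, pool_threshold = 0.02) {
  if (summary$unprocessed_count == 0L)
    return(data.frame(label = character(), share = numeric()))
  counts <- summary$group_counts
  if (summary$internal_count > 0L)
    counts <- c(counts, internal_fragment = summary$internal_count)
  shares <- counts / summary$unprocessed_count
  small <- shares < pool_threshold
  out <- data.frame(label = names(shares)[!small], share = shares[!small],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share, out$label), , drop = FALSE]
  if (any(small))
    out <- rbind(out, data.frame(label = "other", share = sum(shares[small])))
  rownames(out) <- NULL
  out
}

#' Per-junction difference of unprocessed fractions (knockout vs control)
#'
#' For every junction-group label present in either sample,
#' `delta = 100 * (count_ko / total_ko - count_ctrl / total_ctrl)` in
#' percentage points of *total* aligned reads (labels absent from one sample
#' count as zero there). Records with `|delta|` at or below `vis_threshold`
#' are retained but flagged as not visualised.
#'
#' @param ko `sample_summary` of the knockout sample.
#' @param ctrl `sample_summary` of the control sample.
#' @param vis_threshold visualisation threshold in percentage points
#'   (default 0.5).
#' @return data.frame with columns `junction_label`, `ko_fraction`,
#'   `ctrl_fraction` (both in % of total reads), `delta` (pp) and
#'   `visualised`, ordered by decreasing `delta`.
#' @export
delta_unprocessed <- function(ko, ctrl, vis_threshold = 0.5) {
  if (ko$total_reads == 0L || ctrl$total_reads == 0L)
    stop("delta_unprocessed requires non-zero totals in both samples")
  labels <- sort(union(names(ko$group_counts), names(ctrl$group_counts)))
  kc <- ifelse(labels %in% names(ko$group_counts),
               ko$group_counts[labels], 0L)
  cc <- ifelse(labels %in% names(ctrl$group_counts),
               ctrl$group_counts[labels], 0L)
  ko_fraction <- 100 * kc / ko$total_reads
  ctrl_fraction <- 100 * cc / ctrl$total_reads
  delta <- ko_fraction - ctrl_fraction
  out <- data.frame(junction_label = labels,
                    ko_fraction = unname(ko_fraction),
                    ctrl_fraction = unname(ctrl_fraction),
                    delta = unname(delta),
                    visualised = unname(abs(delta) > vis_threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, out$junction_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Composition of the positive delta signal
#'
#' Sums the positive per-junction deltas into a total unprocessed signal and
#' expresses each positive delta as a percentage of it (contributions sum to
#' 100 before filtering); junctions contributing less than
#' `min_contribution` are flagged as excluded from visualisation but kept in
#' the table.
#'
#' @param deltas output of [delta_unprocessed()].
#' @param min_contribution minimum contribution kept for visualisation, as a
#'   fraction of the total positive signal (default 0.02).
#' @return data.frame with columns `junction_label`, `delta`,
#'   `contribution_pct`, `included`; empty (with a warning) when no delta is
#'   positive.
#' @export
positive_delta_composition <- function(deltas, min_contribution = 0.02) {
  pos <- deltas[deltas$delta > 0, , drop = FALSE]
  if (!nrow(pos)) {
    warning("no positive deltas")
    return(data.frame(junction_label = character(), delta = numeric(),
                      contribution_pct = numeric(), included = logical()))
  }
  total <- sum(pos$delta)
  contribution <- 100 * pos$delta / total
  out <- data.frame(junction_label = pos$junction_label, delta = pos$delta,
                    contribution_pct = contribution,
                    included = contribution >= 100 * min_contribution,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution_pct, out$junction_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' tRNA read-through fraction
#'
#' Fraction of transcripts passing through at least the centre of a tRNA,
#' relative to the reads in the next same-strand mRNA/rRNA unit downstream
#' in the direction of transcription: the denominator is the reads
#' containing that neighbouring unit (under `params$contain_rule`), the
#' numerator the subset whose span also covers the tRNA's centre. The
#' species is flagged as reported only when the passing reads exceed
#' `params$abundance_cutoff` of total reads.
#'
#' @param reads a `read_set`.
#' @param trna tRNA gene name.
#' @param annotation a `mito_annotation`.
#' @param params an `analysis_params`.
#' @param neighbour_rule `"downstream"` (default) or `"nearest"` flanking
#'   mRNA/rRNA unit.
#' @return one-row data.frame: `trna`, `neighbour`, `n_neighbour`,
#'   `n_passing`, `fraction`, `reported`.
#' @export
trna_passthrough_fraction <- function(reads, trna, annotation,
                                      params = analysis_params(),
                                      neighbour_rule = c("downstream", "nearest")) {
  neighbour_rule <- match.arg(neighbour_rule)
  f <- annotation$features
  tf <- f[f$name == trna & f$biotype == "tRNA" & f$arc == 1L, ]
  if (!nrow(tf)) stop("unknown tRNA: ", trna)
  centre <- as.integer(floor((tf$start + tf$end) / 2))

  units <- annotation$units
  cand <- units[units$strand == tf$strand, , drop = FALSE]
  has_mr <- vapply(strsplit(cand$members, ",", fixed = TRUE), function(m) {
    bt <- f$biotype[match(m, f$name)]
    any(bt %in% c("mRNA", "rRNA"))
  }, logical(1))
  cand <- cand[has_mr, , drop = FALSE]
  if (tf$strand == "+") {
    down <- cand[cand$span_start >= tf$end, , drop = FALSE]
    down <- down[order(down$span_start), , drop = FALSE]
    up <- cand[cand$span_end <= tf$start, , drop = FALSE]
    up <- up[order(-up$span_end), , drop = FALSE]
  } else {
    down <- cand[cand$span_end <= tf$start, , drop = FALSE]
    down <- down[order(-down$span_end), , drop = FALSE]
    up <- cand[cand$span_start >= tf$end, , drop = FALSE]
    up <- up[order(up$span_start), , drop = FALSE]
  }
  pick <- if (nrow(down)) down[1, ] else NULL
  if (neighbour_rule == "nearest" && nrow(up)) {
    gap_down <- if (!is.null(pick)) {
      if (tf$strand == "+") pick$span_start - tf$end else tf$start - pick$span_end
    } else Inf
    gap_up <- if (tf$strand == "+") tf$start - up$span_end[1]
              else up$span_start[1] - tf$end
    if (gap_up < gap_down) pick <- up[1, ]
  }
  if (is.null(pick))
    stop("tRNA ", trna, " has no same-strand mRNA/rRNA neighbour")

  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  total <- nrow(r)
  in_neigh <- .contains_span(r, pick$span_start, pick$span_end, pick$strand,
                             params$contain_rule)
  passing <- in_neigh & r$start <= centre & r$end > centre
  n_neigh <- sum(in_neigh)
  data.frame(trna = trna, neighbour = pick$unit,
             n_neighbour = n_neigh, n_passing = sum(passing),
             fraction = if (n_neigh > 0) sum(passing) / n_neigh else NA_real_,
             reported = total > 0 && sum(passing) / total > params$abundance_cutoff,
             stringsAsFactors = FALSE)
}

#' 5' start-site table for reads containing a gene
#'
#' Selects the reads containing `gene` (under `contain_rule`), bins their
#' strand-aware 5' positions and reports counts and percentages of the
#' selected reads. When reference start sites are supplied (e.g. the
#' heavy-strand promoter position), each bin is annotated with the nearest
#' reference and the signed offset from it — direct-RNA nanopore reads are
#' expected ~12 nt downstream of the true 5' end.
#'
#' @param reads a `read_set`.
#' @param gene gene (feature) name whose containing reads are selected.
#' @param annotation a `mito_annotation`.
#' @param params an `analysis_params`.
#' @param ref_starts optional named numeric vector of reference start
#'   positions.
#' @return data.frame with columns `position`, `count`, `pct` and, when
#'   `ref_starts` is given, `nearest_ref` and `offset` (signed nt downstream
#'   of the reference in the direction of transcription).
#' @export
five_prime_start_table <- function(reads, gene, annotation,
                                   params = analysis_params(),
                                   ref_starts = NULL) {
  f <- annotation$features
  gf <- f[f$name == gene & f$arc == 1L, ]
  if (!nrow(gf)) stop("unknown gene: ", gene)
  r <- if (inherits(reads, "read_set")) reads$reads else as.data.frame(reads)
  sel <- .contains_span(r, gf$start, gf$end, gf$strand, params$contain_rule)
  r <- r[sel, , drop = FALSE]
  if (!nrow(r))
    return(data.frame(position = integer(), count = integer(), pct = numeric()))
  pos5 <- ifelse(r$strand == "+", r$start, r$end - 1L)
  tab <- table(pos5)
  out <- data.frame(position = as.integer(names(tab)),
                    count = as.integer(tab),
                    pct = 100 * as.integer(tab) / nrow(r))
  out <- out[order(out$position), , drop = FALSE]
  if (!is.null(ref_starts) && length(ref_starts)) {
    nearest <- vapply(out$position, function(p)
      which.min(abs(ref_starts - p)), integer(1))
    out$nearest_ref <- names(ref_starts)[nearest]
    sign <- if (gf$strand == "+") 1 else -1
    out$offset <- sign * (out$position - unname(ref_starts[nearest]))
  }
  rownames(out) <- NULL
  out
}
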