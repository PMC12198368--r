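# Independent brute-force oracles, kept deliberately naive (nested loops,
# no shared code with the package internals) so they can arbitrate.

# Brute-force re-derivation of the processed/unprocessed verdict and the
# junction group of a single read.
oracle_classify <- function(start, end, strand, ann, tol) {
  u <- ann$units
  status <- "unprocessed"; unit <- NA_character_
  best <- Inf
  for (i in seq_len(nrow(u))) {
    if (u$strand[i] != strand) next
    d5 <- abs(start - u$span_start[i]); d3 <- abs(end - u$span_end[i])
    if (d5 <= tol && d3 <= tol && d5 + d3 < best) {
      status <- "processed"; unit <- u$unit[i]; best <- d5 + d3
    }
  }
  ts <- min(start + tol, end - 1L); te <- max(end - tol, start + 1L)
  if (ts >= te) { m <- (start + end) %/% 2L; ts <- m; te <- m + 1L }
  members <- character(0)
  for (i in order(u$span_start)) {
    if (u$strand[i] != strand) next
    if (max(ts, u$span_start[i]) < min(te, u$span_end[i]))
      members <- c(members, u$unit[i])
  }
  group <- NA_character_; category <- "processed"
  if (status == "unprocessed") {
    if (length(members) >= 2L) {
      category <- "junction"; group <- paste(members, collapse = ",")
    } else if (length(members) == 1L) {
      i <- which(u$unit == members)
      lext <- u$span_start[i] - start; rext <- end - u$span_end[i]
      if (lext > tol || rext > tol) {
        category <- "single_unit_extended"
        group <- members
        if (lext > tol) group <- paste("flank_5p", group, sep = ",")
        if (rext > tol) group <- paste(group, "flank_3p", sep = ",")
      } else category <- "internal_fragment"
    } else {
      category <- "intergenic_antisense"
      anti <- character(0)
      for (i in order(u$span_start)) {
        if (u$strand[i] == strand) next
        if (max(ts, u$span_start[i]) < min(te, u$span_end[i]))
          anti <- c(anti, u$unit[i])
      }
      group <- if (length(anti)) paste0("antisense:", paste(anti, collapse = ","))
               else "intergenic"
    }
  }
  list(status = status, unit = unit, category = category, group = group)
}

# random reads over an annotation's genome, fixed layout for property tests
random_reads <- function(n, genome_length, seed) {
  set.seed(seed)
  a <- sample.int(genome_length - 1L, n, replace = TRUE) - 1L
  len <- pmax(1L, as.integer(round(stats::rexp(n, 1 / 300))))
  b <- pmin(genome_length, a + len)
  a <- pmin(a, b - 1L)
  data.frame(read_id = sprintf("r%05d", seq_len(n)), start = a, end = b,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Enumeration oracle for the generative model: probability that the emitted
# read's source fragment retains junction `label` uncut, marginal over TSS
# choice, cleavage patterns and fragment selection. Independent loops over
# all 2^J patterns.
enum_span_prob <- function(config, label) {
  ann <- config$annotation
  tssw <- config$tss$weight / sum(config$tss$weight)
  total <- 0
  for (i in seq_len(nrow(config$tss))) {
    strand <- config$tss$strand[i]
    term <- config$terminators[[strand]]
    lo <- min(config$tss$position[i], term)
    hi <- max(config$tss$position[i], term)
    u <- ann$units[ann$units$strand == strand, , drop = FALSE]
    u <- u[u$span_start < hi & u$span_end > lo, , drop = FALSE]
    jn <- ann$junctions[ann$junctions$strand == strand, , drop = FALSE]
    jn <- jn[jn$position > lo & jn$position < hi, , drop = FALSE]
    J <- nrow(jn)
    p_span <- 0
    for (mask in 0:(2^J - 1)) {
      cut <- as.logical(bitwAnd(mask, 2^(seq_len(J) - 1L)) > 0)
      if (config$hierarchical && J > 0) cut <- cut & cumsum(!cut) == 0
      pr <- prod(ifelse(cut, config$cleavage_prob[jn$label],
                        1 - config$cleavage_prob[jn$label]))
      cuts <- unique(c(jn$cut_up[cut], jn$cut_down[cut]))
      cuts <- cuts[cuts > lo & cuts < hi]
      b <- sort(unique(c(lo, hi, cuts)))
      w <- numeric(length(b) - 1L); spans <- logical(length(b) - 1L)
      for (q in seq_len(length(b) - 1L)) {
        flo <- b[q]; fhi <- b[q + 1L]
        mem <- u[u$span_start < fhi & u$span_end > flo, , drop = FALSE]
        f <- ann$features[ann$features$strand == strand &
                            ann$features$start < fhi &
                            ann$features$end > flo, , drop = FALSE]
        cls <- if (any(f$biotype == "mRNA")) "mRNA"
               else if (any(f$biotype == "rRNA")) "rRNA"
               else if (any(f$biotype == "tRNA")) "tRNA" else "noncoding"
        proc <- nrow(mem) == 1L && mem$span_start == flo && mem$span_end == fhi
        stab <- if (proc) config$stability[["processed"]]
                else config$stability[["unprocessed"]]
        w[q] <- (fhi - flo) * stab * config$polya_capture[[cls]]
        k <- which(jn$label == label)
        spans[q] <- length(k) == 1L && jn$position[k] > flo && jn$position[k] < fhi
      }
      if (all(w <= 0)) w <- rep(1, length(w))
      p_span <- p_span + pr * sum(w[spans]) / sum(w)
    }
    total <- total + tssw[i] * p_span
  }
  total
}
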