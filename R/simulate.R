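#' Configuration for the polycistronic read simulator
#'
#' Describes a generative model of strand-specific long direct-RNA reads
#' from a polycistronic genome: a nascent transcript is drawn from a
#' transcription start site and runs to the strand's terminator; every
#' internal unit junction is then cleaved independently with its junction's
#' cleavage probability; one resulting fragment is sampled with probability
#' proportional to length x stability x poly(A) capture; finally nanopore
#' end noise is applied — a systematic 5' truncation (default 12 +/- 2 nt,
#' clipped at 0) and a symmetric 3' jitter.
#'
#' @param annotation a `mito_annotation`.
#' @param tss data.frame of transcription start sites with columns
#'   `position`, `strand`, `weight`; defaults to one start at the 5' end of
#'   the first unit of each strand that has units, with the minus-strand
#'   start down-weighted to 0.1 (reads from light-strand transcripts, mostly
#'   tRNA, are rare in a poly(A)-selected library).
#' @param cleavage_prob named numeric vector of cleavage probabilities per
#'   junction label (defaults from [default_cleavage_probs()]).
#' @param stability relative retention weights,
#'   `c(processed = , unprocessed = )`: processed species persist at least
#'   as long as unprocessed intermediates, which are cleared faster.
#' @param polya_capture capture probability per fragment content class
#'   (`mRNA`, `rRNA`, `tRNA`, `noncoding`); models poly(A)-selection bias.
#'   Fragments containing no gene (excised spacers, lone leaders) default to
#'   0: without a poly(A) tail they are not captured.
#' @param five_prime_trunc `c(mean = , sd = )` of the 5' truncation in nt.
#' @param three_prime_jitter_sd sd of the 3' end jitter in nt.
#' @param n_reads number of reads to emit.
#' @param seed RNG seed; identical configs and seeds give byte-identical
#'   output.
#' @param terminators named vector of terminator positions per strand;
#'   defaults to the far end of the last unit on each strand.
#' @param hierarchical require 5' junctions (in transcription order) to be
#'   cleaved before 3' ones: a junction can only be cut when all junctions
#'   upstream of it are cut. Contrasts a strict 5'-to-3' processing
#'   hierarchy with the default independent-cleavage model.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(annotation, tss = NULL, cleavage_prob = NULL,
                              stability = c(processed = 1, unprocessed = 0.6),
                              polya_capture = c(mRNA = 1, rRNA = 0.7,
                                                tRNA = 0.25, noncoding = 0),
                              five_prime_trunc = c(mean = 12, sd = 2),
                              three_prime_jitter_sd = 5,
                              n_reads = 10000, seed = 1,
                              terminators = NULL, hierarchical = FALSE) {
  stopifnot(inherits(annotation, "mito_annotation"), n_reads > 0,
            all(stability > 0), all(polya_capture >= 0),
            five_prime_trunc[["sd"]] >= 0, three_prime_jitter_sd >= 0)
  units <- annotation$units
  if (is.null(tss)) {
    rows <- list()
    for (s in c("+", "-")) {
      u <- units[units$strand == s, , drop = FALSE]
      if (!nrow(u)) next
      pos <- if (s == "+") min(u$span_start) else max(u$span_end)
      rows[[s]] <- data.frame(position = pos, strand = s,
                              weight = if (s == "+") 1 else 0.1)
    }
    tss <- do.call(rbind, rows)
  }
  stopifnot(all(tss$weight > 0), all(tss$strand %in% c("+", "-")))
  if (is.null(cleavage_prob)) cleavage_prob <- default_cleavage_probs(annotation)
  stopifnot(all(cleavage_prob >= 0 & cleavage_prob <= 1))
  missing <- setdiff(annotation$junctions$label, names(cleavage_prob))
  if (length(missing))
    stop("cleavage_prob missing for junction(s): ",
         paste(missing, collapse = "; "))
  if (is.null(terminators)) {
    terminators <- c()
    for (s in c("+", "-")) {
      u <- units[units$strand == s, , drop = FALSE]
      if (!nrow(u)) next
      terminators[s] <- if (s == "+") max(u$span_end) else min(u$span_start)
    }
  }
  structure(list(annotation = annotation, tss = tss,
                 cleavage_prob = cleavage_prob, stability = stability,
                 polya_capture = polya_capture,
                 five_prime_trunc = five_prime_trunc,
                 three_prime_jitter_sd = three_prime_jitter_sd,
                 n_reads = as.integer(n_reads), seed = as.integer(seed),
                 terminators = terminators, hierarchical = hierarchical),
            class = "simulation_config")
}

#' Default per-junction cleavage probabilities
#'
#' One probability per junction label, by junction kind. The defaults model
#' a control sample with near-complete processing at every site; lowering
#' the canonical value emulates loss of the tRNA-directed nucleolytic
#' machinery.
#'
#' @param annotation a `mito_annotation`.
#' @param canonical probability at tRNA-flanked junctions (default 0.97).
#' @param noncanonical probability at junctions without a flanking tRNA
#'   (default 0.97).
#' @return named numeric vector over junction labels.
#' @export
default_cleavage_probs <- function(annotation, canonical = 0.97,
                                   noncanonical = 0.97) {
  j <- annotation$junctions
  stats::setNames(ifelse(j$kind == "canonical", canonical, noncanonical),
                  j$label)
}

# transcription-ordered units and interior junctions for one TSS
.transcript_layout <- function(annotation, pos, strand, term) {
  lo <- min(pos, term); hi <- max(pos, term)
  u <- annotation$units
  u <- u[u$strand == strand & u$span_start < hi & u$span_end > lo, , drop = FALSE]
  u <- u[order(u$span_start * ifelse(strand == "+", 1L, -1L)), , drop = FALSE]
  j <- annotation$junctions
  j <- j[j$strand == strand & j$position > lo & j$position < hi, , drop = FALSE]
  ord <- order(j$position * ifelse(strand == "+", 1L, -1L))
  list(units = u, junctions = j[ord, , drop = FALSE], lo = lo, hi = hi)
}

# content class of a fragment for poly(A)-capture weighting
.fragment_class <- function(frag_lo, frag_hi, strand, features) {
  f <- features[features$strand == strand &
                  features$start < frag_hi & features$end > frag_lo, , drop = FALSE]
  if (any(f$biotype == "mRNA")) "mRNA"
  else if (any(f$biotype == "rRNA")) "rRNA"
  else if (any(f$biotype == "tRNA")) "tRNA"
  else "noncoding"
}

#' Simulate aligned long reads with ground truth
#'
#' Runs the generative model of [simulation_config()] and returns both the
#' emitted alignment spans and a per-read truth table from which every
#' per-junction quantity can be recomputed. Deterministic for a fixed seed.
#'
#' @param config a `simulation_config`.
#' @param sample_id sample identifier for the emitted `read_set`.
#' @return list with elements `reads` (a `read_set`), `truth` (data.frame:
#'   `read_id`, `strand`, `frag_start`, `frag_end` — the pre-noise fragment
#'   —, `members`, `n_members`, `truly_processed`, `uncleaved`
#'   (semicolon-joined labels of junctions left uncut inside the fragment))
#'   and `config`.
#' @export
simulate_reads <- function(config, sample_id = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  ann <- config$annotation
  set.seed(config$seed)

  tss <- config$tss
  layouts <- lapply(seq_len(nrow(tss)), function(i)
    .transcript_layout(ann, tss$position[i], tss$strand[i],
                       config$terminators[[tss$strand[i]]]))
  n <- config$n_reads
  tss_idx <- sample.int(nrow(tss), n, replace = TRUE, prob = tss$weight)

  read_start <- integer(n); read_end <- integer(n); read_strand <- character(n)
  frag_lo_v <- integer(n); frag_hi_v <- integer(n)
  members_v <- character(n); nmem_v <- integer(n)
  proc_v <- logical(n); uncleaved_v <- character(n)

  tmean <- config$five_prime_trunc[["mean"]]
  tsd <- config$five_prime_trunc[["sd"]]
  trunc5 <- pmax(0L, as.integer(round(stats::rnorm(n, tmean, tsd))))
  jit3 <- as.integer(round(stats::rnorm(n, 0, config$three_prime_jitter_sd)))

  for (k in seq_len(n)) {
    i <- tss_idx[k]
    lay <- layouts[[i]]
    strand <- tss$strand[i]
    jn <- lay$junctions
    cut <- if (nrow(jn)) stats::runif(nrow(jn)) <
      config$cleavage_prob[jn$label] else logical(0)
    if (config$hierarchical && length(cut)) {
      # a junction is only cut when all transcription-upstream ones are cut
      cut <- cut & (cumsum(!cut) == 0L)
    }
    cutpos <- unique(c(jn$cut_up[cut], jn$cut_down[cut]))
    cutpos <- cutpos[cutpos > lay$lo & cutpos < lay$hi]
    bounds <- sort(unique(c(lay$lo, lay$hi, cutpos)))
    nf <- length(bounds) - 1L
    flo <- bounds[-length(bounds)]; fhi <- bounds[-1]

    w <- numeric(nf)
    fproc <- logical(nf); fmem <- character(nf); fnm <- integer(nf)
    for (q in seq_len(nf)) {
      u <- lay$units
      inside <- u$span_start < fhi[q] & u$span_end > flo[q]
      mem <- u[inside, , drop = FALSE]
      fnm[q] <- nrow(mem)
      ord <- order(mem$span_start * ifelse(strand == "+", 1L, -1L))
      fmem[q] <- paste(mem$unit[ord], collapse = ",")
      fproc[q] <- nrow(mem) == 1L && mem$span_start == flo[q] &&
        mem$span_end == fhi[q]
      cls <- .fragment_class(flo[q], fhi[q], strand, ann$features)
      stab <- if (fproc[q]) config$stability[["processed"]]
              else config$stability[["unprocessed"]]
      w[q] <- (fhi[q] - flo[q]) * stab * config$polya_capture[[cls]]
    }
    if (all(w <= 0)) w <- rep(1, nf)
    q <- if (nf == 1L) 1L else sample.int(nf, 1L, prob = w)

    frag_lo_v[k] <- flo[q]; frag_hi_v[k] <- fhi[q]
    members_v[k] <- fmem[q]; nmem_v[k] <- fnm[q]; proc_v[k] <- fproc[q]
    inj <- jn$position > flo[q] & jn$position < fhi[q]
    uncleaved_v[k] <- paste(jn$label[inj], collapse = ";")

    s <- flo[q]; e <- fhi[q]
    if (strand == "+") {
      s <- s + trunc5[k]; e <- e + jit3[k]
    } else {
      e <- e - trunc5[k]; s <- s - jit3[k]
    }
    s <- max(0L, min(s, ann$genome_length - 1L))
    e <- max(s + 1L, min(e, ann$genome_length))
    read_start[k] <- s; read_end[k] <- e; read_strand[k] <- strand
  }

  ids <- sprintf("sim_%06d", seq_len(n))
  rs <- read_set(data.frame(read_id = ids, start = read_start, end = read_end,
                            strand = read_strand, stringsAsFactors = FALSE),
                 sample_id)
  truth <- data.frame(read_id = ids, strand = read_strand,
                      frag_start = frag_lo_v, frag_end = frag_hi_v,
                      members = members_v, n_members = nmem_v,
                      truly_processed = proc_v, uncleaved = uncleaved_v,
                      stringsAsFactors = FALSE)
  list(reads = rs, truth = truth, config = config)
}

#' Realised per-junction uncleaved fractions of a simulated read set
#'
#' @param truth truth table from [simulate_reads()].
#' @param annotation the `mito_annotation` the reads were simulated from.
#' @return data.frame with `junction_label`, `n_spanning` (emitted reads
#'   whose source fragment retains the junction uncut) and `true_fraction`
#'   of all emitted reads.
#' @export
junction_truth <- function(truth, annotation) {
  labels <- annotation$junctions$label
  lists <- strsplit(truth$uncleaved, ";", fixed = TRUE)
  n_span <- vapply(labels, function(l)
    sum(vapply(lists, function(x) l %in% x, logical(1))), integer(1))
  data.frame(junction_label = labels, n_spanning = unname(n_span),
             true_fraction = unname(n_span) / nrow(truth),
             stringsAsFactors = FALSE)
}

#' Compare estimated per-junction unprocessed incidence with simulation truth
#'
#' For every annotated junction, the estimated incidence is the fraction of
#' all reads classified unprocessed whose junction group spans the junction
#' (its two flanking units adjacent in the group's member list); the true
#' value is the realised uncleaved fraction from the generator. Estimates
#' are monotone in the generative cleavage probability.
#'
#' @param truth truth table from [simulate_reads()].
#' @param summary `sample_summary` of the classified simulated reads.
#' @param annotation the shared `mito_annotation`.
#' @return data.frame with `junction_label`, `kind`, `true_fraction`,
#'   `estimated_fraction`, `abs_error`.
#' @export
recovery_report <- function(truth, summary, annotation) {
  jt <- junction_truth(truth, annotation)
  j <- annotation$junctions
  groups <- names(summary$group_counts)
  glists <- strsplit(groups, ",", fixed = TRUE)
  est <- vapply(seq_len(nrow(j)), function(i) {
    up <- j$upstream_unit[i]; down <- j$downstream_unit[i]
    spans <- vapply(glists, function(m) {
      k <- which(m == up)
      any(c(m[k + 1L], m[k - 1L]) == down, na.rm = TRUE)
    }, logical(1))
    sum(summary$group_counts[spans]) / summary$total_reads
  }, numeric(1))
  data.frame(junction_label = j$label, kind = j$kind,
             true_fraction = jt$true_fraction[match(j$label, jt$junction_label)],
             estimated_fraction = est,
             abs_error = abs(est - jt$true_fraction[match(j$label, jt$junction_label)]),
             stringsAsFactors = FALSE)
}
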