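#' Five-gene toy annotation
#'
#' A minimal plus-strand annotation for examples and tests: tF [0,70),
#' rnS [70,370), tV [370,440), rnL [440,900), tL1 [900,970) on a 1,000 nt
#' genome — the 5' half of the mitochondrial rRNA gene cluster in
#' miniature, with tRNAs punctuating the two rRNAs.
#'
#' @param unit_spec optional unit specification as in [mito_annotation()].
#' @return a `mito_annotation`.
#' @export
toy_annotation <- function(unit_spec = NULL) {
  feats <- data.frame(
    name = c("tF", "rnS", "tV", "rnL", "tL1"),
    start = c(0L, 70L, 370L, 440L, 900L),
    end = c(70L, 370L, 440L, 900L, 970L),
    strand = "+",
    biotype = c("tRNA", "rRNA", "tRNA", "rRNA", "tRNA"),
    stringsAsFactors = FALSE)
  mito_annotation(feats, genome_length = 1000L, genome_id = "toyM",
                  unit_spec = unit_spec)
}

#' Mouse-like mitochondrial annotation fixture
#'
#' A stylised mouse mitochondrial heavy/light-strand annotation with
#' synthetic round-number coordinates (the gene order follows the mouse
#' genome — 5' leader, mtF, 12S, mtV, 16S, mtL1, mtNd1, the WANCY tRNA
#' cluster, and the mtAtp8/6 bicistron abutting mtCo3 at a non-canonical
#' mRNA-mRNA junction — but the coordinates are not the reference ones).
#' Loaded from the BED fixture shipped with the package; the mtAtp8/6
#' bicistron is declared as a merged unit by default.
#'
#' @param bicistrons merge mtAtp8 and mtAtp6 into one processed unit
#'   (default `TRUE`).
#' @return a `mito_annotation` on a 9,000 nt genome.
#' @export
example_annotation <- function(bicistrons = TRUE) {
  path <- system.file("extdata", "mouse_like_mtdna_synthetic.bed",
                      package = "mitopunct", mustWork = TRUE)
  unit_spec <- if (bicistrons) list(merge = list(c("mtAtp8", "mtAtp6"))) else NULL
  load_annotation(path, genome_length = 9000L, genome_id = "chrM_synth",
                  unit_spec = unit_spec)
}

#' Study-condition simulator configurations
#'
#' `control_sim_config()` emulates a control sample: near-complete cleavage
#' (0.97) at every junction. `ko_sim_config()` emulates loss of the
#' methylation-dependent canonical processing machinery: cleavage drops to
#' 0.55 at tRNA-flanked (canonical) junctions and to 0.85 at non-canonical
#' ones, so unprocessed intermediates accumulate preferentially at
#' tRNA-punctuated sites. Both share the nanopore end-noise model (5'
#' truncation 12 +/- 2 nt) and the turnover/poly(A) weights of
#' [simulation_config()].
#'
#' @param annotation a `mito_annotation` (default [example_annotation()]).
#' @param n_reads reads to simulate (default 10,000).
#' @param seed RNG seed.
#' @param ... passed on to [simulation_config()].
#' @return a `simulation_config`.
#' @export
control_sim_config <- function(annotation = example_annotation(),
                               n_reads = 10000, seed = 1, ...) {
  simulation_config(annotation,
                    cleavage_prob = default_cleavage_probs(annotation,
                                                           canonical = 0.97,
                                                           noncanonical = 0.97),
                    n_reads = n_reads, seed = seed, ...)
}

#' @rdname control_sim_config
#' @export
ko_sim_config <- function(annotation = example_annotation(),
                          n_reads = 10000, seed = 1, ...) {
  simulation_config(annotation,
                    cleavage_prob = default_cleavage_probs(annotation,
                                                           canonical = 0.55,
                                                           noncanonical = 0.85),
                    n_reads = n_reads, seed = seed, ...)
}
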