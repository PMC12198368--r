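# in-code fixtures: tiny BED and SAM inputs written to tempfiles at test time

write_toy_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# minimal SAM over the 1,000 nt toy genome:
#   r1: primary 100M at 1-based 73 -> [72,172) plus a secondary alignment
#   r2: spliced 30M200N40M at 1-based 11 -> outer span [10,280)
#   r3: reverse strand 50M at 1-based 401 -> [400,450), strand -
#   r4: mapq 5, for the min_mapq filter
write_toy_sam <- function(path = tempfile(fileext = ".sam"),
                          include_secondary = TRUE) {
  recs <- c(
    "r2\t0\ttoyM\t11\t60\t30M200N40M\t*\t0\t0\t*\t*",
    "r1\t0\ttoyM\t73\t60\t100M\t*\t0\t0\t*\t*",
    if (include_secondary) "r1\t256\ttoyM\t201\t0\t100M\t*\t0\t0\t*\t*",
    "r3\t16\ttoyM\t401\t60\t50M\t*\t0\t0\t*\t*",
    "r4\t0\ttoyM\t501\t5\t60M\t*\t0\t0\t*\t*")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:toyM\tLN:1000", recs),
             path)
  path
}

# reads matching constructed per-unit counts on the toy annotation:
# `spec` is a list of c(start, end, strand) repeated `n` times each
build_reads <- function(spec) {
  rows <- do.call(rbind, lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    n <- if (length(s) >= 4) as.integer(s[[4]]) else 1L
    data.frame(start = rep(as.integer(s[[1]]), n),
               end = rep(as.integer(s[[2]]), n),
               strand = rep(as.character(s[[3]]), n),
               stringsAsFactors = FALSE)
  }))
  rows$read_id <- sprintf("c%04d", seq_len(nrow(rows)))
  rows
}

# full pipeline fixture: simulated ko/ctrl BEDs plus a YAML run config;
# returns the config path
make_run <- function(dir, seed_ko = 61, seed_ctrl = 62, n = 800) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann_path <- system.file("extdata", "mouse_like_mtdna_synthetic.bed",
                          package = "mitopunct")
  ann <- example_annotation()
  ko <- simulate_reads(ko_sim_config(ann, n_reads = n, seed = seed_ko), "ko1")
  ct <- simulate_reads(control_sim_config(ann, n_reads = n, seed = seed_ctrl),
                       "ctrl1")
  ko_bed <- file.path(dir, "ko1.bed"); ct_bed <- file.path(dir, "ctrl1.bed")
  write_reads_bed(ko$reads, ko_bed, chrom = "chrM_synth")
  write_reads_bed(ct$reads, ct_bed, chrom = "chrM_synth")
  cfg <- list(
    genome = list(annotation = ann_path, genome_length = 9000L,
                  genome_id = "chrM_synth", contig = "chrM_synth"),
    units = list(merge = list(list("mtAtp8", "mtAtp6"))),
    params = list(tol = 20L),
    samples = list(list(id = "ko1", role = "ko", bed = ko_bed),
                   list(id = "ctrl1", role = "ctrl", bed = ct_bed)),
    start_site_genes = list("mtF"),
    ref_starts = list(HSP = 100L),
    seed = 7L)
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_path
}
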