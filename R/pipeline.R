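#' Run the full processing analysis from a structured config file
#'
#' Orchestrates annotation loading, read ingestion, classification and the
#' junction statistics for a set of samples, writing plain TSV tables plus a
#' JSON run manifest (file hashes, package version, seed) to the output
#' directory. Stages fail fast with stage-labelled errors; per-stage read
#' counts are logged to stderr so filter effects are auditable. For a fixed
#' config the run is deterministic, so reruns reproduce the tables
#' byte-identically.
#'
#' The YAML config has sections:
#' \preformatted{
#' genome:  {annotation: path, genome_length: int, genome_id: str, contig: str}
#' units:   {merge: [[geneA, geneB], ...], utr5: {unit: nt}, utr3: {unit: nt}}
#' params:  {tol: 20, pool_threshold: 0.02, delta_vis_threshold: 0.5,
#'           abundance_cutoff: 0.0001, contain_rule: centre}
#' samples: [{id: str, role: ko|ctrl|other, bed: path}, ...]
#' start_site_genes: [mtF]
#' ref_starts: {HSP: 100}
#' out_dir: path
#' }
#' Samples sharing a role are pooled (replicates merged before analysis);
#' the delta tables are produced when both a `ko` and a `ctrl` role are
#' present.
#'
#' @param config_path path to the YAML config.
#' @param out_dir output directory (overrides `out_dir` in the config).
#' @return invisibly, a list with the loaded annotation, per-role summaries,
#'   the delta table (or `NULL`) and the manifest; tables are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage:", name, "] ", conditionMessage(e), call. = FALSE))
  }
  cfg <- stage("config", {
    if (!file.exists(config_path)) stop("config not found: ", config_path)
    yaml::read_yaml(config_path)
  })
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- stage("annotation", {
    g <- cfg$genome %||% stop("config lacks a genome section")
    if (!is.null(g$annotation) && !file.exists(g$annotation))
      stop("annotation file not found: ", g$annotation)
    unit_spec <- cfg$units
    if (!is.null(unit_spec$merge))
      unit_spec$merge <- lapply(unit_spec$merge, unlist)
    load_annotation(g$annotation, genome_length = g$genome_length,
                    genome_id = g$genome_id, unit_spec = unit_spec)
  })
  params <- stage("params", do.call(analysis_params, cfg$params %||% list()))

  samples <- cfg$samples %||% stop("[stage:config] no samples declared")
  read_sets <- stage("ingest", {
    lapply(samples, function(s) {
      if (is.null(s$bed) || !file.exists(s$bed %||% ""))
        stop("sample '", s$id, "': BED not found: ", s$bed)
      rs <- read_bed(s$bed, s$id, contig = cfg$genome$contig)
      message("[ingest] ", s$id, ": ", rs$total_aligned, " reads")
      rs
    })
  })
  roles <- vapply(samples, function(s) s$role %||% s$id, character(1))

  # pool replicate read sets per role
  pooled <- stage("pool", {
    out <- list()
    for (role in unique(roles)) {
      dfs <- lapply(read_sets[roles == role], `[[`, "reads")
      out[[role]] <- read_set(do.call(rbind, dfs), role)
      message("[pool] role ", role, ": ", out[[role]]$total_aligned, " reads")
    }
    out
  })

  summaries <- list()
  classifications <- list()
  for (role in names(pooled)) {
    cl <- stage("classify", classify_reads(pooled[[role]], ann, params))
    classifications[[role]] <- cl
    .write_tsv(cl, file.path(out_dir, paste0("classified_", role, ".tsv")))
    summaries[[role]] <- stage("summarize", summarize_sample(cl, role))
    comp <- composition(summaries[[role]], params$pool_threshold)
    .write_tsv(comp, file.path(out_dir, paste0("composition_", role, ".tsv")))
    message("[classify] ", role, ": ",
            summaries[[role]]$unprocessed_count, "/",
            summaries[[role]]$total_reads, " unprocessed")
  }
  sumtab <- data.frame(
    sample = names(summaries),
    total_reads = vapply(summaries, `[[`, 0L, "total_reads"),
    processed = vapply(summaries, `[[`, 0L, "processed_count"),
    unprocessed = vapply(summaries, `[[`, 0L, "unprocessed_count"),
    internal_fragments = vapply(summaries, `[[`, 0L, "internal_count"),
    unprocessed_fraction = vapply(summaries, unprocessed_fraction, 0),
    stringsAsFactors = FALSE)
  .write_tsv(sumtab, file.path(out_dir, "summary.tsv"))

  deltas <- NULL
  if (all(c("ko", "ctrl") %in% names(summaries))) {
    deltas <- stage("delta", delta_unprocessed(summaries$ko, summaries$ctrl,
                                               params$delta_vis_threshold))
    .write_tsv(deltas, file.path(out_dir, "delta.tsv"))
    pdc <- stage("delta", positive_delta_composition(deltas))
    .write_tsv(pdc, file.path(out_dir, "positive_delta.tsv"))
  }

  pass <- stage("trna-metrics", {
    trnas <- ann$features$name[ann$features$biotype == "tRNA" &
                                 ann$features$arc == 1L]
    rows <- list()
    for (role in names(pooled)) for (t in trnas) {
      row <- tryCatch(trna_passthrough_fraction(pooled[[role]], t, ann, params),
                      error = function(e) NULL)  # tRNA without a neighbour
      if (!is.null(row)) rows[[length(rows) + 1L]] <- cbind(sample = role, row)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(pass)) .write_tsv(pass, file.path(out_dir, "trna_passthrough.tsv"))

  for (gene in cfg$start_site_genes %||% character()) {
    for (role in names(pooled)) {
      tab <- stage("start-sites",
                   five_prime_start_table(pooled[[role]], gene, ann, params,
                                          ref_starts = unlist(cfg$ref_starts)))
      .write_tsv(tab, file.path(out_dir,
                                paste0("start_sites_", gene, "_", role, ".tsv")))
    }
  }

  manifest <- stage("manifest", {
    inputs <- vapply(samples, function(s) unname(tools::md5sum(s$bed)), character(1))
    names(inputs) <- vapply(samples, `[[`, "", "id")
    list(config_hash = unname(tools::md5sum(config_path)),
         annotation_hash = unname(tools::md5sum(cfg$genome$annotation)),
         input_hashes = as.list(inputs),
         tool_version = as.character(utils::packageVersion("mitopunct")),
         seed = cfg$seed %||% NA,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(annotation = ann, summaries = summaries, deltas = deltas,
                 classifications = classifications, manifest = manifest))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
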