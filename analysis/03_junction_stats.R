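#!/usr/bin/env Rscript
# Step 3: aggregate the classifications into the junction statistics —
# unprocessed compositions with <2% pooling, the per-junction knockout
# minus control delta (in percentage points of total reads, 0.5 pp
# visualisation threshold), the positive-delta composition (>=2%
# inclusion), tRNA read-through fractions and the 5' start-site table of
# mtF-containing reads.

library(mitopunct)

cls <- "results/classified"; out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- example_annotation()
params <- analysis_params()

sums <- list(); sets <- list()
for (id in c("ctrl", "ko")) {
  cl <- read.delim(file.path(cls, paste0(id, "_classified.tsv")))
  sums[[id]] <- summarize_sample(cl, id)
  sets[[id]] <- read_bed(file.path("results/sim", paste0(id, ".bed")), id)
  comp <- composition(sums[[id]], params$pool_threshold)
  write.table(comp, file.path(out, paste0("composition_", id, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(id, "unprocessed pool, top categories:\n")
  print(utils::head(comp, 4), row.names = FALSE)
}

d <- delta_unprocessed(sums$ko, sums$ctrl, params$delta_vis_threshold)
write.table(d, file.path(out, "delta.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\n%d junction groups, %d above the %.1f pp threshold; top:\n",
            nrow(d), sum(d$visualised), params$delta_vis_threshold))
print(utils::head(d, 5), row.names = FALSE)

pd <- positive_delta_composition(d, params$pool_threshold)
write.table(pd, file.path(out, "positive_delta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\npositive delta signal split over %d groups (%d >= 2%%)\n",
            nrow(pd), sum(pd$included)))

# read-through at every tRNA with a downstream mRNA/rRNA neighbour
rows <- list()
for (id in c("ctrl", "ko"))
  for (t in ann$features$name[ann$features$biotype == "tRNA" &
                                ann$features$arc == 1L]) {
    r <- tryCatch(trna_passthrough_fraction(sets[[id]], t, ann, params),
                  error = function(e) NULL)
    if (!is.null(r)) rows[[length(rows) + 1L]] <- cbind(sample = id, r)
  }
pass <- do.call(rbind, rows)
write.table(pass, file.path(out, "trna_passthrough.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
wide <- reshape(pass[, c("sample", "trna", "fraction")], idvar = "trna",
                timevar = "sample", direction = "wide")
cat("\ntRNA read-through (fraction of neighbour-unit reads):\n")
print(wide, row.names = FALSE)

# 5' start sites of mtF-containing reads: control starts sit ~12 nt inside
# the gene, knockout reads retain the 5' leader back to the promoter
for (id in c("ctrl", "ko")) {
  tab <- five_prime_start_table(sets[[id]], "mtF", ann, params,
                                ref_starts = c(HSP = 0, mtF_start = 100))
  write.table(tab, file.path(out, paste0("start_sites_mtF_", id, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- tab[order(-tab$count), ][1:3, ]
  cat(sprintf("\n%s: top mtF 5' start positions (n=%d reads):\n",
              id, sum(tab$count)))
  print(top, row.names = FALSE)
}
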