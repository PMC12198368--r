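# mitopunct

Classification and junction accounting of mitochondrial transcripts from
long direct-RNA (nanopore) reads.

Mammalian mitochondrial genes are transcribed as near-genome-length
polycistronic precursors and released by cleavage at the tRNAs punctuating
the gene order. When that processing fails, partially cleaved intermediates
accumulate, and long reads show them directly: each read is one molecule,
and its alignment span tells which genes it still carries. `mitopunct`
takes aligned long reads (BED6 from `bedtools bamtobed`, or SAM/BAM
directly) plus a transcript-unit annotation and computes:

* **processed / unprocessed classification** per read: a read is processed
  when both ends fall within ±τ nt (default τ = 20) of one transcript
  unit's boundaries — units are single genes, or declared multi-gene units
  such as the mtAtp8/6 bicistron, with optional UTR extents;
* **junction groups**: each unprocessed read is labelled with the
  genome-ordered units it spans (`"rnS,mtV,rnL"`), i.e. the cleavage sites
  it retains;
* **summary statistics**: unprocessed fraction of total reads; composition
  of the unprocessed pool with <2 % categories pooled into `other`; the
  knockout-versus-control per-junction difference in percentage points of
  total reads,
  `Δ_j = 100·(u_j^ko/N^ko − u_j^ctrl/N^ctrl)`,
  with a 0.5 pp visualisation threshold and a positive-Δ composition
  (≥2 % inclusion); tRNA read-through fractions ("reads passing through at
  least the centre of a tRNA, relative to reads in the next mRNA/rRNA");
  per-unit fully processed fractions; and 5′ start-site tables;
* **a generative read simulator** — per-junction cleavage probabilities,
  processed/unprocessed turnover weights, poly(A)-capture bias, and the
  systematic ~12 ± 2 nt nanopore 5′ truncation — with exported ground
  truth, so the whole analysis chain is validated by parameter recovery.

See `vignettes/mitopunct-methods.Rmd` for the model, parameter rationale
and limitations.

## Worked example

```r
library(mitopunct)

ann    <- example_annotation()          # mouse-like fixture, 20 units
params <- analysis_params(tol = 20)

ko  <- simulate_reads(ko_sim_config(ann, n_reads = 10000, seed = 102), "ko")
cl  <- classify_reads(ko$reads, ann, params)
s   <- summarize_sample(cl, "ko")
s
#> sample_summary: ko - 10000 reads, 54.4% unprocessed, 106 junction groups
```

About half the knockout's reads retain at least one uncleaved junction
(compare ~3.5 % in `control_sim_config()`). Against a matched control the
per-junction Δ table ranks the affected sites:

```r
ctrl <- simulate_reads(control_sim_config(ann, n_reads = 10000, seed = 101), "ctrl")
sc   <- summarize_sample(classify_reads(ctrl$reads, ann, params), "ctrl")
head(delta_unprocessed(s, sc), 3)
#>    junction_label ko_fraction ctrl_fraction delta visualised
#> 1       mtW,mtCo1        2.50          0.34  2.16       TRUE
#> 2       mtCo1,mtD        2.18          0.28  1.90       TRUE
#> 3 mtNd2,mtW,mtCo1        1.78          0.01  1.77       TRUE
```

Every top junction group is tRNA-flanked, as expected when the canonical
(tRNA-directed) machinery is impaired: `ko_fraction`/`ctrl_fraction` are
per-junction unprocessed reads as % of *total* reads in each sample, and
`delta` their difference in percentage points. The 5′ start-site table of
mtF-containing reads separates the nanopore truncation from true leader
retention: control starts sit ~11–12 nt inside the gene (offset from the
annotated start), knockout reads also start back at the promoter:

```r
tab <- five_prime_start_table(ko$reads, "mtF", ann, params,
                              ref_starts = c(HSP = 0, mtF_start = 100))
head(tab[order(-tab$count), ], 2)
#>    position count       pct nearest_ref offset
#> 20      111    53 10.192308   mtF_start     11
#> 7        12    50  9.615385         HSP     12
```

The numbered scripts under `analysis/` run the same study end to end
(simulate → classify → junction statistics → parameter recovery), writing
their tables under `results/`. `run_pipeline("run.yaml")` does the same
from a single config file and writes a run manifest with input hashes.

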