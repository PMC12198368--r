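toy <- toy_annotation()
p <- analysis_params()

# helper: a sample_summary built from raw counts (bypassing classification)
make_summary <- function(sample_id, total, processed, groups = integer(),
                         internal = 0L) {
  structure(list(sample_id = sample_id, total_reads = as.integer(total),
                 processed_count = as.integer(processed),
                 unprocessed_count = as.integer(total - processed),
                 internal_count = as.integer(internal),
                 group_counts = groups,
                 unit_counts = stats::setNames(integer(), character())),
            class = "sample_summary")
}

test_that("summaries tally classifications exactly", {
  reads <- build_reads(list(
    c(72, 368, "+", 961),        # processed rnS
    c(72, 500, "+", 25),         # rnS,tV,rnL
    c(380, 900, "+", 14)))       # tV,rnL
  cl <- classify_reads(read_set(reads, "mef_ko"), toy, p)
  s <- summarize_sample(cl)
  expect_equal(s$sample_id, "mef_ko")
  expect_equal(s$total_reads, 1000L)
  expect_equal(s$processed_count + s$unprocessed_count, s$total_reads)
  expect_equal(unprocessed_fraction(s), 0.039)
  expect_equal(sort(names(s$group_counts)), sort(c("rnS,tV,rnL", "tV,rnL")))
  expect_equal(sum(s$group_counts), 39L)
  expect_warning(summarize_sample(cl[0, ], "empty"), "empty")
})

test_that("summaries match a naive single-pass tally oracle", {
  r <- random_reads(500, 1000, seed = 23)
  cl <- classify_reads(read_set(r, "s"), toy, p)
  s <- summarize_sample(cl)
  naive_groups <- table(cl$group[cl$status == "unprocessed" & !is.na(cl$group)])
  expect_equal(s$processed_count, sum(cl$status == "processed"))
  expect_equal(s$group_counts[sort(names(s$group_counts))],
               stats::setNames(as.integer(naive_groups[sort(names(naive_groups))]),
                               sort(names(naive_groups))))
  expect_true(sum(s$group_counts) <= s$unprocessed_count)
})

test_that("composition shares sum to one and pool below threshold", {
  s <- make_summary("s", 1100, 100,
                    groups = c(A = 500L, B = 300L, C = 180L, D = 15L, E = 5L))
  comp <- composition(s, 0.02)
  expect_equal(sum(comp$share), 1, tolerance = 1e-12)
  expect_equal(comp$share[comp$label == "A"], 0.5)
  expect_equal(comp$share[comp$label == "other"], 0.02)
  expect_false(any(c("D", "E") %in% comp$label))

  single <- composition(make_summary("s", 110, 100, groups = c(G = 10L)), 0.02)
  expect_equal(single, data.frame(label = "G", share = 1.0))

  allsmall <- composition(make_summary("s", 10100, 10000,
                                       groups = c(a = 30L, b = 30L, c = 40L)), 0.5)
  expect_equal(allsmall$label, "other")
  expect_equal(allsmall$share, 1.0)

  expect_equal(nrow(composition(make_summary("s", 100, 100))), 0L)
})

test_that("internal fragments appear as their own composition category", {
  s <- make_summary("s", 200, 100, groups = c(A = 80L), internal = 20L)
  comp <- composition(s, 0.02)
  expect_equal(comp$share[comp$label == "internal_fragment"], 0.2)
  expect_equal(sum(comp$share), 1)
})

test_that("delta of unprocessed fractions reproduces hand-computed values", {
  ko <- make_summary("ko", 1000, 608, groups = c(J = 392L))
  ctrl <- make_summary("ctrl", 1000, 964, groups = c(J = 36L))
  d <- delta_unprocessed(ko, ctrl)
  expect_equal(d$delta, 35.6)
  expect_equal(d$ko_fraction, 39.2)
  expect_equal(d$ctrl_fraction, 3.6)
  expect_true(d$visualised)

  # identical samples give all-zero deltas
  expect_true(all(delta_unprocessed(ko, ko)$delta == 0))

  # swapping the samples negates every delta
  ko2 <- make_summary("ko", 2000, 1500, groups = c(A = 300L, B = 200L))
  ct2 <- make_summary("ctrl", 1500, 1400, groups = c(B = 60L, C = 40L))
  ab <- delta_unprocessed(ko2, ct2)
  ba <- delta_unprocessed(ct2, ko2)
  m <- match(ab$junction_label, ba$junction_label)
  expect_equal(ab$delta, -ba$delta[m])
  # labels absent from one sample count as zero there
  expect_equal(ab$ctrl_fraction[ab$junction_label == "A"], 0)

  expect_error(delta_unprocessed(make_summary("x", 0, 0), ctrl), "non-zero")
})

test_that("deltas and compositions are invariant under count scaling", {
  ko <- make_summary("ko", 1000, 700, groups = c(A = 200L, B = 100L))
  ctrl <- make_summary("ctrl", 800, 760, groups = c(A = 30L, B = 10L))
  scale <- function(s, k) make_summary(s$sample_id, s$total_reads * k,
                                       s$processed_count * k,
                                       s$group_counts * k)
  expect_equal(delta_unprocessed(ko, ctrl)$delta,
               delta_unprocessed(scale(ko, 7L), scale(ctrl, 7L))$delta)
  expect_equal(composition(ko)$share, composition(scale(ko, 7L))$share)
})

test_that("positive-delta composition filters and normalises correctly", {
  d <- data.frame(junction_label = c("J1", "J2", "J3"),
                  ko_fraction = 0, ctrl_fraction = 0,
                  delta = c(8, 2, -5), visualised = TRUE)
  pc <- positive_delta_composition(d)
  expect_equal(pc$junction_label, c("J1", "J2"))
  expect_equal(pc$contribution_pct, c(80, 20))
  expect_equal(sum(pc$contribution_pct), 100)

  one <- positive_delta_composition(transform(d, delta = c(5, -1, -2)))
  expect_equal(one$contribution_pct, 100)

  skew <- positive_delta_composition(
    transform(d, delta = c(98, 1, 1)), min_contribution = 0.02)
  expect_equal(skew$included, c(TRUE, FALSE, FALSE))
  expect_equal(sum(skew$contribution_pct), 100)   # before the filter

  expect_warning(none <- positive_delta_composition(
    transform(d, delta = c(-1, -2, -3))), "no positive")
  expect_equal(nrow(none), 0L)
})

test_that("tRNA read-through is measured against the downstream mRNA/rRNA", {
  # 100 reads contain rnL; 12 of them also pass the tV centre (405)
  reads <- read_set(build_reads(list(
    c(445, 900, "+", 88), c(380, 900, "+", 12))), "s")
  res <- trna_passthrough_fraction(reads, "tV", toy, p)
  expect_equal(res$neighbour, "rnL")
  expect_equal(res$n_neighbour, 100L)
  expect_equal(res$fraction, 0.12)
  expect_true(res$reported)

  none <- trna_passthrough_fraction(
    read_set(build_reads(list(c(445, 900, "+", 50))), "s"), "tV", toy, p)
  expect_equal(none$fraction, 0)
  expect_false(none$reported)

  all_through <- trna_passthrough_fraction(
    read_set(build_reads(list(c(380, 900, "+", 50))), "s"), "tV", toy, p)
  expect_equal(all_through$fraction, 1.0)

  # tL1 has no downstream mRNA/rRNA on the toy genome
  expect_error(trna_passthrough_fraction(reads, "tL1", toy, p), "neighbour")
  expect_error(trna_passthrough_fraction(reads, "nope", toy, p), "unknown tRNA")
})

test_that("the abundance cut-off marks rare species as not reported", {
  # 2 passing reads out of 30,000 total: 0.0067% > 0.01%? no -> not reported
  reads <- read_set(build_reads(list(
    c(445, 900, "+", 29998), c(380, 900, "+", 2))), "s")
  res <- trna_passthrough_fraction(reads, "tV", toy, p)
  expect_false(res$reported)
  res2 <- trna_passthrough_fraction(reads, "tV", toy,
                                    analysis_params(abundance_cutoff = 1e-5))
  expect_true(res2$reported)
})

test_that("5' start-site tables bin strand-aware read starts", {
  reads <- read_set(build_reads(list(c(12, 370, "+", 10))), "s")
  tab <- five_prime_start_table(reads, "tF", toy, p)
  expect_equal(tab, data.frame(position = 12L, count = 10L, pct = 100))

  # leader-retaining reads report negative offsets from the annotated start
  reads2 <- read_set(build_reads(list(
    c(12, 370, "+", 6), c(0, 370, "+", 4))), "s")
  tab2 <- five_prime_start_table(reads2, "tF", toy, p,
                                 ref_starts = c(annotated = 12))
  expect_equal(tab2$offset, c(-12, 0))
  expect_equal(tab2$count, c(4L, 6L))
  expect_equal(sum(tab2$pct), 100)

  empty <- five_prime_start_table(
    read_set(build_reads(list(c(500, 600, "+", 3))), "s"), "tF", toy, p)
  expect_equal(nrow(empty), 0L)
})

test_that("simulated 5' truncation shows up as the modal start-site offset", {
  ann <- toy_annotation()
  cfg <- simulation_config(ann,
                           cleavage_prob = default_cleavage_probs(ann, 0.5, 0.5),
                           n_reads = 3000, seed = 29)
  sim <- simulate_reads(cfg)
  tab <- five_prime_start_table(sim$reads, "tF", ann, p)
  modal <- tab$position[which.max(tab$count)]
  expect_true(modal >= 10 && modal <= 14)   # truncation ~N(12, 2) from 0
})
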