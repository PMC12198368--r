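toy <- toy_annotation()
p20 <- analysis_params(tol = 20)

test_that("reads within tolerance of one unit's boundaries are processed", {
  cl <- classify_read(data.frame(start = 72, end = 368, strand = "+"), toy, p20)
  expect_equal(cl$status, "processed")
  expect_equal(cl$unit, "rnS")
  # exact boundary identity
  cl0 <- classify_read(data.frame(start = 70, end = 370, strand = "+"), toy, p20)
  expect_equal(cl0$status, "processed")
  expect_equal(cl0$unit, "rnS")
})

test_that("junction-spanning reads get genome-ordered groups and tRNA centres", {
  cl <- classify_read(data.frame(start = 72, end = 500, strand = "+"), toy, p20)
  expect_equal(cl$status, "unprocessed")
  expect_equal(cl$category, "junction")
  expect_equal(cl$group, "rnS,tV,rnL")
  expect_equal(cl$trna_centres_covered, "tV")   # centre 405 in [72,500)

  full <- classify_read(data.frame(start = 0, end = 970, strand = "+"), toy, p20)
  expect_equal(full$group, "tF,rnS,tV,rnL,tL1")
  expect_true(full$trna_5prime)                 # starts in tF
  expect_true(full$trna_3prime)                 # ends in tL1
  expect_equal(full$trna_centres_covered, "tF,tV,tL1")
})

test_that("tRNA terminal flags are strand-aware", {
  f <- trna_terminal_flags(data.frame(start = 0, end = 970, strand = "+"), toy)
  expect_true(f$trna_5prime && f$trna_3prime)
  f2 <- trna_terminal_flags(data.frame(start = 72, end = 368, strand = "+"), toy)
  expect_false(f2$trna_5prime || f2$trna_3prime)
  # on the minus strand the 5' terminus is the end coordinate
  mir <- mito_annotation(data.frame(
    name = c("t1", "g1"), start = c(430L, 100L), end = c(500L, 430L),
    strand = "-", biotype = c("tRNA", "rRNA")), 1000)
  f3 <- trna_terminal_flags(data.frame(start = 120, end = 470, strand = "-"), mir)
  expect_true(f3$trna_5prime)    # 5' terminus 469 inside t1 [430,500)
  expect_false(f3$trna_3prime)   # 3' terminus 120 inside g1
})

test_that("single-unit unprocessed reads split into internal and extended", {
  internal <- classify_read(data.frame(start = 120, end = 300, strand = "+"),
                            toy, p20)
  expect_equal(internal$category, "internal_fragment")
  expect_true(is.na(internal$group))

  # gap fixture: unit g1 [100,400) with empty flanks beyond tol
  gap <- mito_annotation(data.frame(
    name = c("g1", "g2"), start = c(100L, 700L), end = c(400L, 900L),
    strand = "+", biotype = "mRNA"), 1000)
  ext <- classify_read(data.frame(start = 95, end = 480, strand = "+"), gap, p20)
  expect_equal(ext$category, "single_unit_extended")
  expect_equal(ext$group, "g1,flank_3p")
})

test_that("reads with no same-strand unit are intergenic/antisense", {
  cl <- classify_read(data.frame(start = 100, end = 300, strand = "-"), toy, p20)
  expect_equal(cl$status, "unprocessed")
  expect_equal(cl$category, "intergenic_antisense")
  expect_equal(cl$group, "antisense:rnS")
})

test_that("classification partitions every read set", {
  r <- random_reads(400, 1000, seed = 7)
  cl <- classify_reads(r, toy, p20)
  expect_equal(sum(cl$status == "processed") + sum(cl$status == "unprocessed"),
               nrow(r))
  expect_false(any(is.na(cl$status)))
  # exactly one of unit/group populated outside internal fragments
  expect_true(all(is.na(cl$unit[cl$status == "unprocessed"])))
  expect_true(all(!is.na(cl$group[cl$category %in%
    c("junction", "single_unit_extended", "intergenic_antisense")])))
})

test_that("the processed set grows monotonically with tolerance", {
  r <- random_reads(500, 1000, seed = 11)
  prev <- rep(FALSE, nrow(r))
  for (tol in c(0, 5, 10, 20, 40)) {
    now <- classify_reads(r, toy, analysis_params(tol = tol))$status == "processed"
    expect_true(all(now[prev]))   # subset relation
    prev <- now
  }
})

test_that("tol = 0 reduces to exact boundary equality", {
  r <- random_reads(500, 1000, seed = 13)
  cl <- classify_reads(r, toy, analysis_params(tol = 0))
  u <- toy$units
  exact <- vapply(seq_len(nrow(r)), function(i)
    any(u$strand == r$strand[i] & u$span_start == r$start[i] &
          u$span_end == r$end[i]), logical(1))
  expect_equal(cl$status == "processed", exact)
})

test_that("classification matches the brute-force oracle on random reads", {
  r <- random_reads(600, 1000, seed = 17)
  cl <- classify_reads(r, toy, p20)
  for (i in seq_len(nrow(r))) {
    o <- oracle_classify(r$start[i], r$end[i], r$strand[i], toy, 20)
    expect_identical(cl$status[i], o$status)
    expect_identical(cl$category[i], o$category)
    expect_identical(cl$group[i], o$group)
    expect_identical(cl$unit[i], o$unit)
  }
})

test_that("statuses are invariant under mirror-image strand flip", {
  L <- toy$genome_length
  f <- toy$features[, c("name", "start", "end", "strand", "biotype")]
  mf <- data.frame(name = f$name, start = L - f$end, end = L - f$start,
                   strand = "-", biotype = f$biotype)
  mirror <- mito_annotation(mf, L)
  r <- random_reads(400, 1000, seed = 19)
  mr <- data.frame(read_id = r$read_id, start = L - r$end, end = L - r$start,
                   strand = ifelse(r$strand == "+", "-", "+"))
  cl <- classify_reads(r, toy, p20)
  mcl <- classify_reads(mr, mirror, p20)
  expect_equal(mcl$status, cl$status)
  expect_equal(mcl$category, cl$category)
})

test_that("fully processed fraction counts containment and processing", {
  # 10 reads covering the rnS centre (220), 9 within tolerance of rnS
  reads <- build_reads(list(c(72, 368, "+", 9), c(60, 500, "+", 1)))
  expect_equal(fully_processed_fraction(reads, "rnS", toy, p20), 0.9)
  expect_equal(fully_processed_fraction(
    build_reads(list(c(70, 370, "+", 5))), "rnS", toy, p20), 1.0)
  expect_true(is.na(fully_processed_fraction(
    build_reads(list(c(0, 60, "+", 3))), "rnS", toy, p20)))
  expect_error(fully_processed_fraction(reads, "nope", toy, p20), "unknown unit")
})

test_that("contain rules differ as documented", {
  # read covers the centre of rnS but less than half of it
  reads <- build_reads(list(c(200, 240, "+", 1)))
  expect_equal(fully_processed_fraction(reads, "rnS", toy,
                                        analysis_params(contain_rule = "centre")), 0)
  expect_true(is.na(fully_processed_fraction(reads, "rnS", toy,
                                             analysis_params(contain_rule = "full"))))
  expect_true(is.na(fully_processed_fraction(reads, "rnS", toy,
                                             analysis_params(contain_rule = "frac50"))))
})
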