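# Variant-panel summary statistics.

test_that("transitions are purine<->purine or pyrimidine<->pyrimidine", {
  expect_true(is_transition("A", "G"))
  expect_true(is_transition("G", "A"))
  expect_true(is_transition("C", "T"))
  expect_false(is_transition("A", "C"))
  expect_false(is_transition("G", "T"))
  expect_error(is_transition("N", "A"))
  expect_error(is_transition("AG", "A"))
  expect_error(is_transition("A", "A"))
})

test_that("ts_tv_ratio counts per alt row and skips non-SNPs", {
  rec <- make_records("c1", 1:3, c("A", "C", "A"), c("G", "T", "C"))
  tt <- ts_tv_ratio(rec)
  expect_equal(tt$transitions, 2L)
  expect_equal(tt$transversions, 1L)
  expect_equal(tt$ratio, 2.00)

  # ts + tv conserves the counted SNP rows, indels skipped
  rec2 <- rbind(rec, make_records("c1", 4, "AT", "A"))
  tt2 <- ts_tv_ratio(rec2)
  expect_equal(tt2$transitions + tt2$transversions, 3L)

  all_tv <- make_records("c1", 1:2, "A", c("C", "T"))
  expect_equal(ts_tv_ratio(all_tv)$ratio, 0.00)
  expect_warning(ts_tv_ratio(make_records("c1", 1, "A", "G")),
                 "no transversions")
})

test_that("variant rates are floor(length / count) with a pooled average row", {
  # worked examples from a published maize RNA-seq variant table
  lengths <- c(chr1 = 307041717, chr4 = 246994605, chr10 = 150982314)
  counts <- c(chr1 = 73811, chr4 = 44735, chr10 = 34529)
  tab <- variant_rate_table(lengths, counts)
  expect_equal(tab$variant_rate[1:3], c(4159, 5521, 4372))

  # floor-rate bound holds wherever the count is positive
  with(tab, expect_true(all(
    variant_rate * variant_count <= length_bp &
      length_bp < (variant_rate + 1) * variant_count
  )))

  expect_true(is.na(variant_rate(100, 0)))
})

test_that("chrom_variant_rates tabulates records and validates contigs", {
  rec <- make_records(c("c1", "c1", "c2"), c(10, 20, 10), "A", "G")
  tab <- chrom_variant_rates(rec, c(c1 = 100, c2 = 50, c3 = 80))
  expect_equal(tab$variant_count, c(2, 1, 0, 3))
  expect_equal(tab$variant_rate, c(50, 50, NA, floor(230 / 3)))
  expect_error(chrom_variant_rates(rec, c(c1 = 100)), "c2")
})

test_that("mapping percentages reproduce printed mapping-summary arithmetic", {
  leaf <- mapping_percentages(list(
    input_reads = 27014405, uniquely_mapped = 24077296,
    multi_mapped = 1291087, unmapped_too_short = 1434465,
    unmapped_other = 75645
  ))
  expect_equal(leaf$uniquely_mapped_pct, 89.13)

  ovule <- mapping_percentages(list(
    input_reads = 21603284, uniquely_mapped = 10875298,
    multi_mapped = 5902841, unmapped_too_short = 1181700,
    unmapped_other = 689145
  ))
  expect_equal(ovule$uniquely_mapped_pct, 50.34)
  expect_equal(ovule$multi_mapped_pct, 27.32)

  zero <- mapping_percentages(list(input_reads = 100, uniquely_mapped = 0,
                                   multi_mapped = 0, unmapped_too_short = 0,
                                   unmapped_other = 0))
  expect_equal(zero$uniquely_mapped_pct, 0)

  expect_error(mapping_percentages(list(input_reads = 10, uniquely_mapped = -1,
                                        multi_mapped = 0,
                                        unmapped_too_short = 0,
                                        unmapped_other = 0)), "negative")
})

test_that("percentages of exhaustive disjoint categories sum to ~100", {
  set.seed(21)
  for (i in 1:20) {
    parts <- as.vector(stats::rmultinom(1, sample(1e6, 1), runif(4)))
    m <- mapping_percentages(list(
      input_reads = sum(parts), uniquely_mapped = parts[1],
      multi_mapped = parts[2], unmapped_too_short = parts[3],
      unmapped_other = parts[4]
    ))
    total <- m$uniquely_mapped_pct + m$multi_mapped_pct +
      m$unmapped_too_short_pct + m$unmapped_other_pct
    expect_lt(abs(total - 100), 0.021)
  }
})

test_that("a STAR-style mapping log can feed mapping_percentages", {
  log <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "                          Number of input reads |\t1000",
    "                   Uniquely mapped reads number |\t800",
    "        Number of reads mapped to multiple loci |\t100",
    "             Number of reads unmapped: too short |\t60",
    "                  Number of reads unmapped: other |\t40"
  ), log)
  m <- mapping_percentages(log)
  expect_equal(m$uniquely_mapped_pct, 80)
  expect_equal(m$unmapped_other_pct, 4)
})

test_that("window densities tile from position 1 and conserve counts", {
  rec <- make_records("c1", c(1, 999999, 1000001), "A", "G")
  d <- window_densities(rec, c(c1 = 2e6), window_bp = 1e6)
  expect_equal(d$variant_count, c(2L, 1L))
  expect_equal(d$window_start, c(1, 1000001))
  expect_equal(d$window_end, c(1e6, 2e6))

  empty <- window_densities(rec[0, ], c(c1 = 2.5e6))
  expect_equal(empty$variant_count, c(0L, 0L, 0L))
  expect_equal(empty$window_end[3], 2.5e6)  # truncated final window

  set.seed(9)
  rnd <- make_records("c1", sort(sample(1e6, 500)), "A", "G")
  for (w in c(1e3, 12345, 1e5)) {
    expect_equal(sum(window_densities(rnd, c(c1 = 1e6), w)$variant_count),
                 500L)
  }
})

test_that("impact_summary counts one per ANN entry and maps effect keywords", {
  one <- make_records("c1", 1, "A", "G",
                      ann = "G|stop_gained|HIGH|gene1|")
  s <- impact_summary(one)
  expect_equal(s$impact$count[s$impact$class == "high"], 1L)
  expect_equal(sum(s$impact$count), 1L)

  two <- make_records("c1", 1, "A", "G",
    ann = "G|downstream_gene_variant|MODIFIER|g1|,G|synonymous_variant|LOW|g2|")
  s2 <- impact_summary(two)
  expect_equal(s2$n_annotations, 2L)
  expect_equal(s2$impact$count[s2$impact$class %in% c("modifier", "low")],
               c(1L, 1L))
  expect_equal(s2$effect$count[s2$effect$category == "downstream"], 1L)
  expect_equal(s2$effect$count[s2$effect$category == "synonymous"], 1L)

  expect_warning(s3 <- impact_summary(make_records("c1", 1, "A", "G",
                                                   ann = "oops")),
                 "malformed")
  expect_equal(s3$n_malformed, 1L)
})

test_that("planted impact-class proportions come back as percentages", {
  spec <- fixture_spec(
    seed = 13, contig_lengths = c(c1 = 5e4, c2 = 5e4),
    unique_a = 60, unique_b = 10, shared = 30, overlap = 10,
    n_indel_adjacent = 0, n_ambiguous = 0, n_low_depth = 0, n_repeat = 0,
    n_heterozygous = 0, n_close_pairs = 0, n_lowqual = 0,
    impact_counts = c(modifier = 68, low = 13, moderate = 9, high = 10)
  )
  fx <- simulate_fixture(spec)
  s <- impact_summary(fx$vcf_a)
  expect_equal(s$impact$count, c(68L, 13L, 9L, 10L))
  expect_equal(s$impact$pct, c(68, 13, 9, 10))
  expect_equal(sum(s$impact$pct), 100)
})
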