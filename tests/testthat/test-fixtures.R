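# Synthetic-data generator: reproducibility and planted-truth recovery.

test_that("the same seed reproduces every artifact byte for byte", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- small_spec(seed = 99)
  simulate_fixture(spec, dir1)
  simulate_fixture(small_spec(seed = 99), dir2)
  for (f in c("genome.fa", "line_a.vcf", "line_b.vcf", "depth.bedgraph",
              "priority.bed", "truth.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # a different seed gives different sequence
  other <- simulate_fixture(small_spec(seed = 100))
  expect_false(identical(other$genome, simulate_fixture(spec)$genome))
})

test_that("planted genome features land where recorded", {
  spec <- small_spec(seed = 15)
  fx <- simulate_fixture(spec)
  plan <- fx$truth$site_plan

  rep_sites <- plan[plan$label == "ua_repeat", ]
  for (i in seq_len(nrow(rep_sites))) {
    win <- substr(fx$genome[[rep_sites$chrom[i]]],
                  rep_sites$pos[i] - 50, rep_sites$pos[i] + 50)
    expect_gte(max_tandem_copies(win), 5L)
  }
  amb_sites <- plan[plan$label == "ua_ambig", ]
  for (i in seq_len(nrow(amb_sites))) {
    fl <- extract_flanks(fx$genome, amb_sites$chrom[i], amb_sites$pos[i])
    expect_false(criterion_ambiguity(fl$left, fl$right))
  }
  # clean sites carry repeat-free windows by construction
  clean <- plan[plan$label == "ua_plain", ][1:10, ]
  for (i in seq_len(nrow(clean))) {
    win <- substr(fx$genome[[clean$chrom[i]]],
                  clean$pos[i] - 50, clean$pos[i] + 50)
    expect_lte(max_tandem_copies(win), 4L)
  }
})

test_that("a 1-Mb contig has near-uniform base composition", {
  spec <- fixture_spec(seed = 8, contig_lengths = c(c1 = 1e6),
                       unique_a = 10, unique_b = 5, shared = 5, overlap = 2,
                       n_indel_adjacent = 0, n_ambiguous = 0, n_low_depth = 0,
                       n_repeat = 0, n_heterozygous = 0, n_close_pairs = 0,
                       n_lowqual = 0)
  g <- simulate_genome(spec)
  gc <- nchar(gsub("[AT]", "", g[[1]])) / nchar(g[[1]])
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
})

test_that("planted class counts, Ts/Tv and genotypes are recovered exactly", {
  spec <- fixture_spec(
    seed = 12, contig_lengths = c(c1 = 8e4, c2 = 8e4),
    unique_a = 50, unique_b = 40, shared = 30, overlap = 10,
    n_indel_adjacent = 0, n_ambiguous = 0, n_low_depth = 0, n_repeat = 0,
    n_heterozygous = 6, n_close_pairs = 0, n_lowqual = 4,
    ts_a = 56, tv_a = 34
  )
  fx <- simulate_fixture(spec)
  pass_a <- filter_pass(fx$vcf_a, keep_unfiltered = FALSE)
  pass_b <- filter_pass(fx$vcf_b, keep_unfiltered = FALSE)
  expect_equal(nrow(fx$vcf_a) - nrow(pass_a), 4L)  # planted LowQual records

  s <- summarize_comparison(diff_sites(pass_a, pass_b))
  expect_equal(s$totals, c(unique_a = 50L, unique_b = 40L,
                           concordant_shared = 30L,
                           discordant_overlap = 10L))

  tt <- ts_tv_ratio(pass_a)
  expect_equal(tt$transitions, 56L)
  expect_equal(tt$transversions, 34L)
  expect_equal(tt$ratio, round_half_up(56 / 34, 2))

  # planted heterozygous sites are exactly the criterion-e rejections
  expect_equal(sum(!criterion_homozygous(pass_a$gt1, pass_a$gt2)), 6L)
})

test_that("planted Ts/Tv composition of 162:100 yields the 1.62 ratio", {
  spec <- fixture_spec(
    seed = 4, contig_lengths = c(c1 = 9e4, c2 = 9e4),
    unique_a = 162, unique_b = 20, shared = 80, overlap = 20,
    n_indel_adjacent = 0, n_ambiguous = 0, n_low_depth = 0, n_repeat = 0,
    n_heterozygous = 0, n_close_pairs = 0, n_lowqual = 0,
    ts_a = 162, tv_a = 100
  )
  fx <- simulate_fixture(spec)
  expect_equal(ts_tv_ratio(fx$vcf_a)$ratio, 1.62)
})

test_that("infeasible specs fail before any artifact is written", {
  expect_error(fixture_spec(unique_a = 10, n_indel_adjacent = 20),
               "infeasible")
  expect_error(fixture_spec(ts_a = 1, tv_a = 1), "ts_a \\+ tv_a")
  expect_error(fixture_spec(contig_lengths = c(c1 = 2000), unique_a = 500),
               "too short")
})

test_that("simulated F2 plates recover planted statuses at missing rate zero", {
  spec <- small_spec(seed = 30, missing_rate = 0)
  ids <- sprintf("MK%03d", 1:60)
  sim <- simulate_f2_calls(ids, spec)
  got <- classify_panel(sim$table)
  expect_equal(got, sim$statuses)
  expect_true(all(c("polymorphic", "monomorphic", "partial", "failed")
                  %in% sim$statuses))

  # explicit planted statuses are honoured
  forced <- simulate_f2_calls(c("A1", "A2"), spec,
                              statuses = c("failed", "monomorphic"))
  expect_equal(unname(classify_panel(forced$table)),
               c("failed", "monomorphic"))
})

test_that("F2 segregation is 1:2:1 within binomial tolerance at n = 10,000", {
  spec <- fixture_spec(seed = 64, f2_size = 10000L, missing_rate = 0,
                       contig_lengths = c(c1 = 5e4),
                       unique_a = 10, unique_b = 5, shared = 5, overlap = 2,
                       n_indel_adjacent = 0, n_ambiguous = 0, n_low_depth = 0,
                       n_repeat = 0, n_heterozygous = 0, n_close_pairs = 0,
                       n_lowqual = 0)
  sim <- simulate_f2_calls("MK1", spec, statuses = "polymorphic")
  f2 <- sim$table$calls["MK1", sim$table$roles$f2]
  hom_x <- mean(f2 == "X")
  het <- mean(f2 == "HET")
  expect_lt(abs(hom_x - 0.25), 0.02)
  expect_lt(abs(het - 0.50), 0.02)
})
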