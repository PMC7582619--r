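# Stepwise KASP suitability criteria, proximity cull and panel selection.

test_that("InDel proximity is screened over the 101-bp window", {
  indels <- data.frame(chrom = "c1", pos = 510L)
  expect_false(criterion_no_indel("c1", 500L, indels))          # +10
  expect_true(criterion_no_indel("c1", 459L, indels))           # +51
  expect_false(criterion_no_indel("c1", 460L, indels))          # +50 boundary
  expect_true(criterion_no_indel("c1", 500L, NULL))
  expect_true(criterion_no_indel("c2", 510L, indels))           # other contig
})

test_that("ambiguity budget is at most four non-ACGT bases across both flanks", {
  flank <- function(n_amb, len = 50) {
    paste(c(rep("N", n_amb), rep("A", len - n_amb)), collapse = "")
  }
  expect_true(criterion_ambiguity(flank(2), flank(2)))
  expect_false(criterion_ambiguity(flank(2), flank(3)))
  expect_true(criterion_ambiguity(flank(0), flank(0)))
  # any IUPAC ambiguity counts, not just N
  expect_false(criterion_ambiguity("RYSWK", flank(0, 5)))
})

test_that("depth criterion requires min coverage at every window position", {
  v <- rep(5L, 200)
  track <- structure(list(c1 = v), class = "depth_track")
  r <- criterion_depth("c1", 100L, dp = 99L, track)
  expect_true(r$pass)
  expect_false(r$approximate)

  v2 <- v; v2[130] <- 4L
  track2 <- structure(list(c1 = v2), class = "depth_track")
  expect_false(criterion_depth("c1", 100L, 99L, track2)$pass)

  # fallback mode: per-variant DP, flagged approximate
  fb <- criterion_depth("c1", 100L, dp = 12L, NULL)
  expect_true(fb$pass)
  expect_true(fb$approximate)
  expect_false(criterion_depth("c1", 100L, dp = 4L, NULL)$pass)
})

test_that("max_tandem_copies finds the boundary cases", {
  expect_equal(max_tandem_copies("TATATATATA"), 5L)   # TA x 5 fails
  expect_equal(max_tandem_copies("TATATATA"), 4L)     # TA x 4 passes
  expect_equal(max_tandem_copies("AAAAA"), 5L)        # homopolymer run
  expect_equal(max_tandem_copies("ACGTACGTACGT"), 3L) # 4-mer x 3
  expect_equal(max_tandem_copies("ACGT"), 1L)
  expect_equal(max_tandem_copies(""), 1L)
})

test_that("max_tandem_copies equals the brute-force oracle", {
  # exhaustive over all {A,C} strings of length <= 12
  s <- all_strings(12, c("A", "C"))
  expect_identical(max_tandem_copies(s),
                   vapply(s, oracle_max_tandem, 1L, USE.NAMES = FALSE))
  # random 101-mers over the full alphabet
  set.seed(77)
  r <- vapply(1:60, function(i) {
    paste(sample(c("A", "C", "G", "T"), 101, TRUE), collapse = "")
  }, "")
  expect_identical(max_tandem_copies(r),
                   vapply(r, oracle_max_tandem, 1L, USE.NAMES = FALSE))
})

test_that("homozygous-alternate genotypes pass criterion e", {
  expect_true(criterion_homozygous(1L, 1L))
  expect_false(criterion_homozygous(0L, 1L))
  expect_false(criterion_homozygous(0L, 0L))
  expect_true(criterion_homozygous(2L, 2L))
  expect_warning(res <- criterion_homozygous(NA_integer_, 1L), "missing")
  expect_false(res)
})

test_that("apply_filter recovers planted per-criterion rejections exactly", {
  spec <- small_spec()
  fx <- simulate_fixture(spec)
  cls <- diff_sites(filter_pass(fx$vcf_a, keep_unfiltered = FALSE),
                    filter_pass(fx$vcf_b, keep_unfiltered = FALSE))
  ua <- cls[cls$class == "unique_a", ]
  in_ua <- paste(fx$vcf_a$chrom, fx$vcf_a$pos) %in% paste(ua$chrom, ua$pos)
  snps <- fx$vcf_a[in_ua & fx$vcf_a$is_snp & fx$vcf_a$filter == "PASS", ]
  indels <- fx$vcf_a[!fx$vcf_a$is_snp, c("chrom", "pos")]

  res <- apply_filter(snps, fx$genome, indels, fx$depth_track)
  r <- res$report
  expect_equal(c(a = r$rejected_a, b = r$rejected_b, c = r$rejected_c,
                 d = r$rejected_d, e = r$rejected_e),
               fx$truth$rejections)
  # monotone survivor counts through the pipeline
  seqs <- c(r$candidates, r$after_a, r$after_b, r$after_c, r$after_d,
            r$after_e)
  expect_true(all(diff(seqs) <= 0))

  culled <- proximity_cull(res$survivors)
  expect_equal(nrow(res$survivors) - nrow(culled), fx$truth$n_culled)
  expect_equal(nrow(culled), fx$truth$clean_unique_a)
  # depth fallback mode flags candidates as approximate
  fb <- apply_filter(snps, fx$genome, indels, depth_track = NULL)
  expect_true(all(fb$survivors$depth_approximate))
  expect_equal(fb$report$rejected_c, spec$n_low_depth)
})

test_that("apply_filter edge cases: empty input, all-clean input, multi-allelics", {
  spec <- fixture_spec(seed = 3, contig_lengths = c(c1 = 4e4),
                       unique_a = 20, unique_b = 5, shared = 5, overlap = 2,
                       n_indel_adjacent = 0, n_ambiguous = 0, n_low_depth = 0,
                       n_repeat = 0, n_heterozygous = 0, n_close_pairs = 0,
                       n_lowqual = 0)
  fx <- simulate_fixture(spec)
  snps <- fx$vcf_a[fx$vcf_a$is_snp, ]

  clean <- apply_filter(snps, fx$genome, NULL, fx$depth_track)
  expect_equal(nrow(clean$survivors), nrow(snps))

  empty <- apply_filter(snps[0, ], fx$genome, NULL, fx$depth_track)
  expect_equal(nrow(empty$survivors), 0L)
  expect_equal(empty$report$after_e, 0L)

  multi <- rbind(snps,
                 make_records("c1", snps$pos[1], snps$ref[1],
                              setdiff(c("A", "C", "G", "T"),
                                      c(snps$ref[1], snps$alt[1]))[1]))
  res <- apply_filter(multi, fx$genome, NULL, fx$depth_track)
  expect_equal(res$report$rejected_multiallelic, 2L)
  expect_equal(nrow(res$survivors), nrow(snps) - 1L)
})

test_that("proximity_cull drops both members of close pairs and is idempotent", {
  mk <- function(pos, chrom = "c1") {
    data.frame(chrom = chrom, pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(proximity_cull(mk(c(100, 119)))), 0L)   # 19 apart
  expect_equal(nrow(proximity_cull(mk(c(100, 120)))), 0L)   # exactly 20
  expect_equal(nrow(proximity_cull(mk(c(100, 121)))), 2L)   # 21 apart
  # chains: middle SNP close to both neighbours takes them all out
  expect_equal(proximity_cull(mk(c(100, 115, 130, 400)))$pos, 400L)
  # contig boundaries are independent
  two <- rbind(mk(100), mk(110, "c2"))
  expect_equal(nrow(proximity_cull(two)), 2L)

  set.seed(41)
  for (i in 1:100) {
    pos <- sort(sample(5000, sample(10:80, 1)))
    cand <- mk(pos)
    once <- proximity_cull(cand)
    expect_equal(proximity_cull(once), once)        # idempotent
    expect_true(nrow(once) <= nrow(cand))           # monotone
    if (nrow(once) > 1L) expect_true(all(diff(once$pos) > 20))
  }
})

test_that("select_genomewide picks one SNP per even quantile bin", {
  cand <- data.frame(chrom = "c1", pos = seq(5000, 995000, by = 10000),
                     stringsAsFactors = FALSE)
  sel <- select_genomewide(cand, c(c1 = 1e6), per_chrom = 10)
  expect_equal(nrow(sel), 10L)
  bins <- floor((sel$pos - 1) / 1e5) + 1
  expect_equal(sort(bins), 1:10)  # one per decile

  # fewer candidates than requested: all selected, with a warning elsewhere
  few <- cand[1:3, ]
  expect_equal(nrow(select_genomewide(few, c(c1 = 1e6), 10)), 3L)
  expect_warning(select_genomewide(few, c(c1 = 1e6, c2 = 1e6), 10),
                 "no candidates on contig c2")

  # deterministic and invariant to input order
  shuffled <- cand[sample(nrow(cand)), ]
  expect_equal(select_genomewide(shuffled, c(c1 = 1e6), 10), sel)
})

test_that("priority intervals steer selection", {
  cand <- data.frame(chrom = "c1", pos = c(10000, 40000, 60000, 90000),
                     stringsAsFactors = FALSE)
  pri <- data.frame(chrom = "c1", start = 35000, end = 65000)
  sel <- select_genomewide(cand, c(c1 = 1e5), per_chrom = 2,
                           priority_intervals = pri)
  # both bins contain a priority candidate; both picks come from the interval
  expect_equal(sel$pos, c(40000, 60000))
  expect_true(all(sel$priority))
})
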