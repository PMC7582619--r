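# Seeded synthetic-data generator. Produces a random reference genome, two
# variant call sets whose two-line classification is known by construction
# (planted counts per site class), planted violations of each KASP filter
# criterion, a matching depth track, priority intervals and F2 plate-call
# tables - so every pipeline stage can be tested against exact truth with
# no external data.
#
# One integer seed drives a separate derived RNG stream per artifact kind
# (site plan, genome, F2 draws), so adding a generator does not perturb
# existing fixtures, and every artifact is byte-reproducible from
# (seed, spec).

#' Fixture specification
#'
#' Defines the synthetic study: contig sizes, planted counts per site
#' class, planted per-criterion violations, close pairs for the proximity
#' cull, Ts/Tv composition and F2 panel shape. Violation sites and close
#' pairs are carved out of the unique-to-A sites, so `unique_a` must be at
#' least the sum of violations plus twice `n_close_pairs`. The site plan
#' (positions, classes, violation types) is drawn here, deterministically
#' from `seed`.
#'
#' @param seed integer seed; the single source of randomness.
#' @param contig_lengths named integer vector of contig lengths.
#' @param unique_a,unique_b,shared,overlap planted SNP-site counts per
#'   two-line comparison class.
#' @param n_indel_adjacent,n_ambiguous,n_low_depth,n_repeat,n_heterozygous
#'   planted violations of filter criteria a-e (all unique-to-A sites).
#' @param n_close_pairs pairs of otherwise-clean unique-to-A SNPs planted
#'   10-20 bp apart to exercise the proximity cull.
#' @param n_lowqual extra line-A records with FILTER "LowQual" (removed by
#'   PASS filtering, excluded from planted class counts).
#' @param ts_a,tv_a exact transition / transversion counts across line A's
#'   PASS SNP records; both NULL (the default) draws each site as a
#'   transition with probability 0.62, roughly the Ts bias of real
#'   transcriptome variant sets. When given they must sum to
#'   `unique_a + shared + overlap`.
#' @param impact_counts optional named counts (modifier, low, moderate,
#'   high) of SnpEff-style ANN entries planted on line-A PASS records.
#' @param base_depth background read depth of the synthetic track.
#' @param f2_size number of F2 individuals on the genotyping plate.
#' @param missing_rate per-well missing-call probability applied to
#'   non-NTC wells in simulated plates.
#' @param status_proportions expected mix of planted marker statuses,
#'   named over polymorphic / monomorphic / partial / failed.
#' @return list of class `fixture_spec`, including the drawn site `plan`.
#' @export
fixture_spec <- function(seed = 1L,
                         contig_lengths = c(chr01 = 1e6, chr02 = 1e6,
                                            chr03 = 1e6),
                         unique_a = 350L, unique_b = 300L, shared = 250L,
                         overlap = 80L,
                         n_indel_adjacent = 10L, n_ambiguous = 10L,
                         n_low_depth = 10L, n_repeat = 10L,
                         n_heterozygous = 10L, n_close_pairs = 5L,
                         n_lowqual = 5L,
                         ts_a = NULL, tv_a = NULL,
                         impact_counts = NULL,
                         base_depth = 30L, f2_size = 90L,
                         missing_rate = 0.05,
                         status_proportions = c(polymorphic = 0.71,
                                                monomorphic = 0.10,
                                                partial = 0.11,
                                                failed = 0.08)) {
  n_viol <- n_indel_adjacent + n_ambiguous + n_low_depth + n_repeat +
    n_heterozygous
  if (unique_a < n_viol + 2L * n_close_pairs) {
    stop("infeasible spec: unique_a must cover all planted violations ",
         "and close pairs", call. = FALSE)
  }
  n_a_snps <- unique_a + shared + overlap
  if (!is.null(ts_a) || !is.null(tv_a)) {
    if (is.null(ts_a) || is.null(tv_a) || ts_a + tv_a != n_a_snps) {
      stop("infeasible spec: ts_a + tv_a must equal unique_a + shared + ",
           "overlap (", n_a_snps, ")", call. = FALSE)
    }
  }
  if (!is.null(impact_counts) && sum(impact_counts) > n_a_snps) {
    stop("infeasible spec: more ANN entries than line-A SNP records",
         call. = FALSE)
  }

  labels <- c(
    rep("ua_plain", unique_a - n_viol - 2L * n_close_pairs),
    rep("ua_indel", n_indel_adjacent), rep("ua_ambig", n_ambiguous),
    rep("ua_depth", n_low_depth), rep("ua_repeat", n_repeat),
    rep("ua_het", n_heterozygous), rep("ua_close", n_close_pairs),
    rep("ub", unique_b), rep("sh", shared), rep("ov", overlap),
    rep("lowqual", n_lowqual)
  )

  plan <- with_seed(seed, {
    labels <- sample(labels)
    ctg <- rep(names(contig_lengths), length.out = length(labels))
    rows <- lapply(names(contig_lengths), function(cname) {
      lab <- labels[ctg == cname]
      L <- contig_lengths[[cname]]
      grid <- seq(200L, as.integer(L) - 220L, by = 250L)
      if (length(grid) < length(lab)) {
        stop("infeasible spec: contig ", cname,
             " too short for the planted site count", call. = FALSE)
      }
      pos <- sort(sample(grid, length(lab)))
      data.frame(chrom = cname, pos = pos, label = lab,
                 stringsAsFactors = FALSE)
    })
    plan <- do.call(rbind, rows)

    # Expand close pairs: the partner sits 10-20 bp to the right.
    cp <- plan[plan$label == "ua_close", , drop = FALSE]
    if (nrow(cp)) {
      cp$pos <- cp$pos + sample(10:20, nrow(cp), replace = TRUE)
      cp$label <- "ua_close2"
      plan <- rbind(plan, cp)
    }
    plan <- plan[order(match(plan$chrom, names(contig_lengths)), plan$pos), ]
    rownames(plan) <- NULL

    # Transition/transversion assignment over line A's PASS SNP records.
    a_snp <- plan$label != "ub" & plan$label != "lowqual"
    plan$is_ts <- NA
    if (is.null(ts_a)) {
      plan$is_ts[a_snp] <- stats::runif(sum(a_snp)) < 0.62
    } else {
      plan$is_ts[a_snp] <- sample(rep(c(TRUE, FALSE), c(ts_a, tv_a)))
    }
    plan$is_ts[plan$label == "lowqual"] <-
      stats::runif(sum(plan$label == "lowqual")) < 0.62
    plan
  })

  structure(
    list(seed = as.integer(seed), contig_lengths = contig_lengths,
         unique_a = unique_a, unique_b = unique_b, shared = shared,
         overlap = overlap, n_indel_adjacent = n_indel_adjacent,
         n_ambiguous = n_ambiguous, n_low_depth = n_low_depth,
         n_repeat = n_repeat, n_heterozygous = n_heterozygous,
         n_close_pairs = n_close_pairs, n_lowqual = n_lowqual,
         ts_a = ts_a, tv_a = tv_a, impact_counts = impact_counts,
         base_depth = as.integer(base_depth), f2_size = as.integer(f2_size),
         missing_rate = missing_rate,
         status_proportions = status_proportions, plan = plan),
    class = "fixture_spec"
  )
}

# Transition partner of a base.
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
# Transversion partners of a base.
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

#' Simulate the reference genome of a fixture
#'
#' Uniform-random ACGT contigs with two deterministic adjustments around
#' planned sites: (i) 101-bp windows of sites that are not
#' repeat-violations are resampled until they are free of >4-copy tandem
#' runs, since roughly 40% of uniform-random windows contain one by
#' chance and planted rejection counts must be exact; (ii) ambiguity
#' violations get a 5-N run planted in the left flank and repeat
#' violations a TA x 5 run in the right flank.
#'
#' @param spec a [fixture_spec()].
#' @return named character vector of contig sequences (`genome_sequence`).
#' @export
simulate_genome <- function(spec) {
  plan <- spec$plan
  with_seed(spec$seed + 1L, {
    genome <- vapply(names(spec$contig_lengths), function(cname) {
      paste(sample(c("A", "C", "G", "T"), spec$contig_lengths[[cname]],
                   replace = TRUE), collapse = "")
    }, "")

    for (cname in names(genome)) {
      seq <- genome[[cname]]
      sites <- plan[plan$chrom == cname, , drop = FALSE]
      if (nrow(sites) == 0L) next
      # Group sites whose 101-bp windows overlap (close pairs) and clean
      # the group's union window together.
      ord <- order(sites$pos)
      pos <- sites$pos[ord]
      lab <- sites$label[ord]
      grp <- cumsum(c(1L, diff(pos) > 101L))
      for (g in unique(grp)) {
        idx <- which(grp == g)
        if (all(lab[idx] == "ua_repeat")) next
        lo <- min(pos[idx]) - 50L
        hi <- max(pos[idx]) + 50L
        repeat {
          windows <- substring(substr(seq, lo, hi),
                               pos[idx] - 50L - lo + 1L,
                               pos[idx] + 50L - lo + 1L)
          if (all(max_tandem_copies(windows) <= 4L)) break
          substr(seq, lo, hi) <- paste(
            sample(c("A", "C", "G", "T"), hi - lo + 1L, replace = TRUE),
            collapse = "")
        }
      }
      # Planted criterion violations that live in the reference itself.
      for (p in sites$pos[sites$label == "ua_ambig"]) {
        substr(seq, p - 30L, p - 26L) <- "NNNNN"
      }
      for (p in sites$pos[sites$label == "ua_repeat"]) {
        substr(seq, p + 5L, p + 14L) <- "TATATATATA"
      }
      genome[[cname]] <- seq
    }
    class(genome) <- c("genome_sequence", "character")
    genome
  })
}

#' Plant the two-line variant sets of a fixture
#'
#' Builds the per-line variant records that realise the planned site
#' classes exactly: unique-to-A sites (including all violation sites and
#' close pairs), unique-to-B sites, concordant-shared sites (same REF/ALT
#' in both lines) and discordant-overlap sites (same position, different
#' ALT). Criterion violations are encoded as planned: an InDel record 15
#' bp from each indel-adjacent site, DP 2 plus a depth-track dip at
#' low-depth sites, GT 0/1 at heterozygous sites, FILTER "LowQual" on the
#' extra non-PASS records.
#'
#' @param genome output of [simulate_genome()] for the same spec.
#' @param spec the [fixture_spec()].
#' @return list: `vcf_a`, `vcf_b` (variant data.frames in [read_vcf()]
#'   layout), `truth` (planted expectations: `class_counts_snp`,
#'   `class_counts_all` with helper InDels included, per-criterion
#'   rejection counts, Ts/Tv counts, close-pair and violation positions).
#' @export
plant_variants <- function(genome, spec) {
  plan <- spec$plan
  with_seed(spec$seed + 2L, {
    ref <- vapply(seq_len(nrow(plan)), function(i) {
      substr(genome[[plan$chrom[i]]], plan$pos[i], plan$pos[i])
    }, "")
    alt_for <- function(r, is_ts) {
      if (is_ts) TS_PARTNER[[r]] else sample(TV_PARTNERS[[r]], 1L)
    }
    alt_a <- vapply(seq_len(nrow(plan)), function(i) {
      if (plan$label[i] == "ub") return(NA_character_)
      alt_for(ref[i], plan$is_ts[i])
    }, "")
    # B alleles: shared sites copy A's; overlap sites take a third base;
    # unique-B sites draw their own.
    alt_b <- rep(NA_character_, nrow(plan))
    for (i in seq_len(nrow(plan))) {
      lab <- plan$label[i]
      if (lab == "sh") alt_b[i] <- alt_a[i]
      else if (lab == "ov") {
        alt_b[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                   c(ref[i], alt_a[i])), 1L)
      } else if (lab == "ub") {
        alt_b[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1L)
      }
    }

    mk_records <- function(idx, alt, gt, dp, filt) {
      data.frame(
        chrom = plan$chrom[idx], pos = plan$pos[idx], ref = ref[idx],
        alt = alt, alt_index = 1L, n_alt = 1L, filter = filt, gt = gt,
        gt1 = as.integer(substr(gt, 1L, 1L)),
        gt2 = as.integer(substr(gt, 3L, 3L)),
        dp = dp, ann = NA_character_, is_snp = TRUE,
        stringsAsFactors = FALSE
      )
    }

    a_idx <- which(!plan$label %in% c("ub", "lowqual"))
    gt_a <- ifelse(plan$label[a_idx] == "ua_het", "0/1", "1/1")
    dp_a <- ifelse(plan$label[a_idx] == "ua_depth", 2L, spec$base_depth)
    vcf_a <- mk_records(a_idx, alt_a[a_idx], gt_a, dp_a, "PASS")

    lq_idx <- which(plan$label == "lowqual")
    if (length(lq_idx)) {
      vcf_a <- rbind(vcf_a, mk_records(lq_idx, alt_a[lq_idx], "1/1",
                                       spec$base_depth, "LowQual"))
    }

    # Helper InDel records 15 bp right of each indel-adjacent site: a
    # 2-bp deletion (REF = two reference bases, ALT = the first).
    indel_pos <- plan$pos[plan$label == "ua_indel"]
    indel_chrom <- plan$chrom[plan$label == "ua_indel"]
    if (length(indel_pos)) {
      hp <- indel_pos + 15L
      href <- vapply(seq_along(hp), function(i) {
        substr(genome[[indel_chrom[i]]], hp[i], hp[i] + 1L)
      }, "")
      indels <- data.frame(
        chrom = indel_chrom, pos = hp, ref = href,
        alt = substr(href, 1L, 1L), alt_index = 1L, n_alt = 1L,
        filter = "PASS", gt = "1/1", gt1 = 1L, gt2 = 1L,
        dp = spec$base_depth, ann = NA_character_, is_snp = FALSE,
        stringsAsFactors = FALSE
      )
      vcf_a <- rbind(vcf_a, indels)
    }

    b_idx <- which(plan$label %in% c("ub", "sh", "ov"))
    vcf_b <- mk_records(b_idx, alt_b[b_idx], "1/1", spec$base_depth, "PASS")

    # Optional SnpEff-style annotations on line A's PASS SNP records.
    if (!is.null(spec$impact_counts)) {
      eff <- c(modifier = "downstream_gene_variant",
               low = "synonymous_variant",
               moderate = "missense_variant", high = "stop_gained")
      classes <- rep(names(spec$impact_counts), spec$impact_counts)
      take <- seq_along(classes)
      vcf_a$ann[take] <- sprintf("%s|%s|%s|gene%04d|", vcf_a$alt[take],
                                 eff[classes], toupper(classes), take)
    }

    ord_a <- order(match(vcf_a$chrom, names(spec$contig_lengths)), vcf_a$pos)
    vcf_a <- vcf_a[ord_a, , drop = FALSE]
    rownames(vcf_a) <- NULL
    ord_b <- order(match(vcf_b$chrom, names(spec$contig_lengths)), vcf_b$pos)
    vcf_b <- vcf_b[ord_b, , drop = FALSE]
    rownames(vcf_b) <- NULL

    is_ua <- startsWith(plan$label, "ua")
    class_counts_snp <- c(unique_a = sum(is_ua), unique_b = spec$unique_b,
                          concordant_shared = spec$shared,
                          discordant_overlap = spec$overlap)
    class_counts_all <- class_counts_snp
    class_counts_all[["unique_a"]] <-
      class_counts_all[["unique_a"]] + length(indel_pos)

    a_pass_snp <- vcf_a$is_snp & vcf_a$filter == "PASS"
    truth <- list(
      class_counts_snp = class_counts_snp,
      class_counts_all = class_counts_all,
      rejections = c(a = spec$n_indel_adjacent, b = spec$n_ambiguous,
                     c = spec$n_low_depth, d = spec$n_repeat,
                     e = spec$n_heterozygous),
      n_culled = 2L * spec$n_close_pairs,
      clean_unique_a = sum(is_ua) - spec$n_indel_adjacent -
        spec$n_ambiguous - spec$n_low_depth - spec$n_repeat -
        spec$n_heterozygous - 2L * spec$n_close_pairs,
      ts_a = sum(is_transition(vcf_a$ref[a_pass_snp],
                               vcf_a$alt[a_pass_snp])),
      tv_a = sum(!is_transition(vcf_a$ref[a_pass_snp],
                                vcf_a$alt[a_pass_snp])),
      site_plan = plan
    )
    list(vcf_a = vcf_a, vcf_b = vcf_b, truth = truth)
  })
}

# Depth track realising the planted coverage: base_depth everywhere with a
# 3-bp dip to depth 2 just right of each low-depth site.
fixture_depth_track <- function(spec) {
  plan <- spec$plan
  track <- lapply(names(spec$contig_lengths), function(cname) {
    v <- rep(spec$base_depth, spec$contig_lengths[[cname]])
    for (p in plan$pos[plan$chrom == cname & plan$label == "ua_depth"]) {
      v[(p + 7L):(p + 9L)] <- 2L
    }
    v
  })
  names(track) <- names(spec$contig_lengths)
  structure(track, class = "depth_track")
}

# One priority interval per contig, centred on the first clean unique-A
# site (so priority-aware selection has something to prefer).
fixture_priority_intervals <- function(spec) {
  plan <- spec$plan
  rows <- lapply(names(spec$contig_lengths), function(cname) {
    p <- plan$pos[plan$chrom == cname & plan$label == "ua_plain"]
    if (!length(p)) return(NULL)
    data.frame(chrom = cname, start = max(1L, p[1L] - 1000L),
               end = p[1L] + 1000L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete fixture
#'
#' Orchestrates [simulate_genome()], [plant_variants()], the depth track
#' and priority intervals; optionally writes everything to disk (FASTA,
#' two VCFs, bedGraph, BED, truth JSON).
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory (created if needed).
#' @return list: `genome`, `vcf_a`, `vcf_b`, `depth_track`,
#'   `priority_intervals`, `truth`, and `paths` when `dir` was given.
#' @export
simulate_fixture <- function(spec, dir = NULL) {
  genome <- simulate_genome(spec)
  planted <- plant_variants(genome, spec)
  track <- fixture_depth_track(spec)
  priority <- fixture_priority_intervals(spec)
  out <- list(genome = genome, vcf_a = planted$vcf_a,
              vcf_b = planted$vcf_b, depth_track = track,
              priority_intervals = priority, truth = planted$truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "genome.fa"),
      vcf_a = file.path(dir, "line_a.vcf"),
      vcf_b = file.path(dir, "line_b.vcf"),
      depth = file.path(dir, "depth.bedgraph"),
      priority = file.path(dir, "priority.bed"),
      truth = file.path(dir, "truth.json")
    )
    write_fasta(genome, paths$fasta)
    write_vcf(planted$vcf_a, paths$vcf_a, sample_name = "line_a",
              contig_lengths = spec$contig_lengths)
    write_vcf(planted$vcf_b, paths$vcf_b, sample_name = "line_b",
              contig_lengths = spec$contig_lengths)
    write_depth_bedgraph(track, paths$depth)
    if (!is.null(priority)) {
      writeLines(sprintf("%s\t%d\t%d", priority$chrom,
                         priority$start - 1L, priority$end), paths$priority)
    }
    tr <- planted$truth
    tr$site_plan <- NULL
    jsonlite::write_json(tr, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

# Compress a depth_track to bedGraph (0-based half-open) via run-length
# encoding.
write_depth_bedgraph <- function(track, path) {
  lines <- unlist(lapply(names(track), function(cname) {
    r <- rle(track[[cname]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    sprintf("%s\t%d\t%d\t%d", cname, start, end, r$values)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an F2 genotyping plate
#'
#' Builds a marker call table in the standard validation layout: the two
#' parents in duplicate, `f2_size` F2 individuals and two no-template
#' controls. Planted-polymorphic markers segregate 1:2:1 (X : HET : Y) in
#' the F2; planted-monomorphic markers show a single homozygous class;
#' planted-partial markers show one allele plus heterozygotes; planted-
#' failed markers have 80% missing wells. `missing_rate` additionally
#' blanks non-NTC wells at random (use 0 for exact status recovery).
#'
#' @param marker_ids character vector of marker names.
#' @param statuses planted status per marker (polymorphic / monomorphic /
#'   partial / failed); default draws from `spec$status_proportions`.
#' @param spec a [fixture_spec()] (seed, f2_size, missing_rate).
#' @return list: `table` (a `marker_call_table`) and `statuses` (the
#'   planted truth).
#' @export
simulate_f2_calls <- function(marker_ids, spec, statuses = NULL) {
  samples <- c("PA1", "PA2", "PB1", "PB2",
               sprintf("F2_%03d", seq_len(spec$f2_size)), "NTC1", "NTC2")
  roles <- list(parent_a = c("PA1", "PA2"), parent_b = c("PB1", "PB2"),
                f2 = sprintf("F2_%03d", seq_len(spec$f2_size)),
                ntc = c("NTC1", "NTC2"))
  non_ntc <- c(roles$parent_a, roles$parent_b, roles$f2)
  with_seed(spec$seed + 3L, {
    if (is.null(statuses)) {
      statuses <- sample(names(spec$status_proportions),
                         length(marker_ids), replace = TRUE,
                         prob = spec$status_proportions)
    }
    stopifnot(length(statuses) == length(marker_ids))
    rows <- lapply(statuses, function(st) {
      calls <- setNames(rep("MISSING", length(samples)), samples)
      if (st == "polymorphic") {
        calls[roles$parent_a] <- "X"
        calls[roles$parent_b] <- "Y"
        calls[roles$f2] <- sample(c("X", "HET", "Y"), spec$f2_size,
                                  replace = TRUE, prob = c(1, 2, 1) / 4)
      } else if (st == "monomorphic") {
        calls[non_ntc] <- sample(c("X", "Y"), 1L)
      } else if (st == "partial") {
        allele <- sample(c("X", "Y"), 1L)
        calls[roles$parent_a] <- allele
        calls[roles$parent_b] <- "HET"
        calls[roles$f2] <- sample(c(allele, "HET"), spec$f2_size,
                                  replace = TRUE)
      } else if (st == "failed") {
        show <- sample(non_ntc, ceiling(0.2 * length(non_ntc)))
        calls[show] <- sample(c("X", "Y"), 1L)
      }
      if (spec$missing_rate > 0 && st != "failed") {
        blank <- stats::runif(length(non_ntc)) < spec$missing_rate
        calls[non_ntc][blank] <- "MISSING"
      }
      calls
    })
    m <- do.call(rbind, rows)
    rownames(m) <- marker_ids
    list(table = structure(list(calls = m, roles = roles,
                                n_unknown_tokens = 0L),
                           class = "marker_call_table"),
         statuses = setNames(statuses, marker_ids))
  })
}
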