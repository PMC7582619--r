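# Stepwise KASP-suitability screen for candidate SNPs. The five criteria,
# applied in order to each biallelic SNP and its 50-bp flanks:
#   a. no InDel call within the 101-bp window around the site;
#   b. at most `max_ambiguous` non-ACGT bases in the two flanks;
#   c. read depth >= `min_depth` at every position of the window (or, when
#      no depth track is available, the variant's own DP as a flagged
#      approximation);
#   d. no more than `max_copies` consecutive copies of any 1-5 bp motif;
#   e. homozygous-alternate genotype.
# Followed by proximity culling (drop every SNP within `min_gap` bp of
# another survivor) and even-quantile genome-wide selection.

#' Default KASP filter parameters
#'
#' @param flank_width flank length each side of the SNP, bp.
#' @param max_ambiguous maximum non-ACGT bases allowed across both flanks.
#' @param min_depth minimum per-base read depth across the window.
#' @param max_copies maximum consecutive copies of any short motif.
#' @param motif_len_min,motif_len_max motif lengths screened, bp.
#' @param min_gap proximity-cull distance: SNPs within this many bp of
#'   another surviving SNP are dropped (both members of a close pair).
#' @return named list of parameters.
#' @export
kasp_params <- function(flank_width = 50L, max_ambiguous = 4L,
                        min_depth = 5L, max_copies = 4L,
                        motif_len_min = 1L, motif_len_max = 5L,
                        min_gap = 20L) {
  list(flank_width = as.integer(flank_width),
       max_ambiguous = as.integer(max_ambiguous),
       min_depth = as.integer(min_depth),
       max_copies = as.integer(max_copies),
       motif_len_min = as.integer(motif_len_min),
       motif_len_max = as.integer(motif_len_max),
       min_gap = as.integer(min_gap))
}

#' InDel-proximity criterion
#'
#' @param chrom,pos candidate SNP coordinates (vectorised).
#' @param indel_sites data.frame with columns chrom, pos: positions of
#'   InDel calls from the same line's VCF.
#' @param window half-window in bp (the screen covers `[pos-window,
#'   pos+window]`).
#' @return logical: TRUE when no InDel lies within the window.
#' @export
criterion_no_indel <- function(chrom, pos, indel_sites, window = 50L) {
  if (is.null(indel_sites) || nrow(indel_sites) == 0L) {
    return(rep(TRUE, length(pos)))
  }
  by_contig <- split(indel_sites$pos, indel_sites$chrom)
  vapply(seq_along(pos), function(i) {
    ip <- by_contig[[chrom[i]]]
    if (is.null(ip)) return(TRUE)
    !any(abs(ip - pos[i]) <= window)
  }, logical(1))
}

#' Flank-ambiguity criterion
#'
#' @param left,right flank sequences (vectorised).
#' @param max_ambiguous maximum count of non-ACGT IUPAC characters
#'   tolerated across both flanks.
#' @return logical vector.
#' @export
criterion_ambiguity <- function(left, right, max_ambiguous = 4L) {
  n_ambig <- function(s) nchar(s) - nchar(gsub("[^ACGT]", "", s))
  (n_ambig(left) + n_ambig(right)) <= max_ambiguous
}

#' Window depth criterion
#'
#' With a depth track, every base of the `2*window + 1` bp window must
#' reach `min_depth`. Without one the criterion degrades to the variant's
#' own DP, and the candidate is flagged depth-approximate.
#'
#' @param chrom,pos,dp candidate coordinates and per-variant DP.
#' @param depth_track a `depth_track` or NULL.
#' @param min_depth required depth.
#' @param window half-window in bp.
#' @return data.frame with logical `pass` and logical `approximate`.
#' @export
criterion_depth <- function(chrom, pos, dp, depth_track = NULL,
                            min_depth = 5L, window = 50L) {
  if (is.null(depth_track)) {
    pass <- !is.na(dp) & dp >= min_depth
    return(data.frame(pass = pass, approximate = rep(TRUE, length(pos))))
  }
  pass <- vapply(seq_along(pos), function(i) {
    d <- depth_at(depth_track, chrom[i], (pos[i] - window):(pos[i] + window))
    all(d >= min_depth)
  }, logical(1))
  data.frame(pass = pass, approximate = rep(FALSE, length(pos)))
}

#' Maximum consecutive copies of any short motif
#'
#' Scans a sequence for tandem runs of every motif length in
#' `[motif_len_min, motif_len_max]` and returns the largest number of
#' consecutive exact copies found anywhere. A homopolymer run of length k
#' counts as k copies of a 1-mer.
#'
#' @param seq character vector of sequences.
#' @param motif_len_min,motif_len_max motif lengths screened.
#' @return integer vector of maximum copy numbers (1 for an empty or
#'   repeat-free sequence).
#' @export
max_tandem_copies <- function(seq, motif_len_min = 1L, motif_len_max = 5L) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n == 0L) return(1L)
    ch <- strsplit(s, "")[[1]]
    best <- 1L
    for (m in motif_len_min:motif_len_max) {
      if (n < 2L * m) break
      # eq[i] <=> ch[i] == ch[i+m]; a maximal run of L consecutive TRUEs
      # is a stretch of period m and length L + m, i.e. floor(L/m) + 1
      # full copies of an m-mer.
      eq <- ch[seq_len(n - m)] == ch[(m + 1L):n]
      r <- rle(eq)
      runs <- r$lengths[r$values]
      if (length(runs)) {
        best <- max(best, as.integer(max(runs) %/% m) + 1L)
      }
    }
    best
  }, integer(1), USE.NAMES = FALSE)
}

#' Homozygous-alternate criterion
#'
#' @param gt1,gt2 integer allele indices of the diploid call (phased and
#'   unphased calls are equivalent here).
#' @return logical: TRUE when both indices are equal and non-zero.
#'   Missing genotypes fail with a warning.
#' @export
criterion_homozygous <- function(gt1, gt2) {
  miss <- is.na(gt1) | is.na(gt2)
  if (any(miss)) {
    warning(sum(miss), " candidate(s) with missing genotype rejected",
            call. = FALSE)
  }
  !miss & gt1 == gt2 & gt1 != 0L
}

#' Apply the stepwise KASP suitability filter
#'
#' Builds candidates (biallelic SNPs with full flanks) from one comparison
#' class of variant records and applies criteria a-e in order, recording
#' the count surviving each step.
#'
#' @param snps variant data.frame (rows from one line, typically the sites
#'   unique to that line); non-SNP rows are ignored, multi-allelic SNP
#'   sites are rejected with a tally.
#' @param genome named contig sequences for flank extraction.
#' @param indel_sites data.frame (chrom, pos) of InDel calls from the same
#'   line, or NULL.
#' @param depth_track a `depth_track`, or NULL for DP fallback mode.
#' @param params list from [kasp_params()].
#' @return list with `survivors` (candidate data.frame with flanks, flag
#'   columns `crit_a` .. `crit_e` and `depth_approximate`) and `report`
#'   (list: input counts, per-step survivor counts `after_a` .. `after_e`,
#'   per-criterion rejection tallies, multi-allelic and flank-unavailable
#'   rejections).
#' @export
apply_filter <- function(snps, genome, indel_sites = NULL,
                         depth_track = NULL, params = kasp_params()) {
  snp <- snps[snps$is_snp, , drop = FALSE]
  report <- list(input = nrow(snps), input_snp = nrow(snp))

  # KASP chemistry is biallelic: reject sites carrying more than one alt.
  key <- paste(snp$chrom, snp$pos)
  multi <- snp$n_alt > 1L | key %in% key[duplicated(key)]
  report$rejected_multiallelic <- sum(multi)
  cand <- snp[!multi, , drop = FALSE]

  # Flank extraction; sites too close to a contig end cannot host an assay.
  w <- params$flank_width
  flanks <- lapply(seq_len(nrow(cand)), function(i) {
    tryCatch(extract_flanks(genome, cand$chrom[i], cand$pos[i], w),
             flank_unavailable = function(e) NULL)
  })
  has_flanks <- !vapply(flanks, is.null, logical(1))
  report$rejected_flank_unavailable <- sum(!has_flanks)
  cand <- cand[has_flanks, , drop = FALSE]
  flanks <- flanks[has_flanks]
  cand$left_flank <- vapply(flanks, `[[`, "", "left")
  cand$right_flank <- vapply(flanks, `[[`, "", "right")
  report$candidates <- nrow(cand)

  # a: no InDel in the window
  cand$crit_a <- criterion_no_indel(cand$chrom, cand$pos, indel_sites, w)
  report$rejected_a <- sum(!cand$crit_a)
  cand <- cand[cand$crit_a, , drop = FALSE]
  report$after_a <- nrow(cand)

  # b: ambiguity budget
  cand$crit_b <- criterion_ambiguity(cand$left_flank, cand$right_flank,
                                     params$max_ambiguous)
  report$rejected_b <- sum(!cand$crit_b)
  cand <- cand[cand$crit_b, , drop = FALSE]
  report$after_b <- nrow(cand)

  # c: coverage across the window
  dres <- criterion_depth(cand$chrom, cand$pos, cand$dp, depth_track,
                          params$min_depth, w)
  cand$crit_c <- dres$pass
  cand$depth_approximate <- dres$approximate
  report$rejected_c <- sum(!cand$crit_c)
  cand <- cand[cand$crit_c, , drop = FALSE]
  report$after_c <- nrow(cand)

  # d: tandem repeats across the full window (flanks plus the site base,
  # so runs spanning the SNP are caught)
  window_seq <- paste0(cand$left_flank, cand$ref, cand$right_flank)
  cand$max_repeat <- max_tandem_copies(window_seq, params$motif_len_min,
                                       params$motif_len_max)
  cand$crit_d <- cand$max_repeat <= params$max_copies
  report$rejected_d <- sum(!cand$crit_d)
  cand <- cand[cand$crit_d, , drop = FALSE]
  report$after_d <- nrow(cand)

  # e: homozygous alternate
  cand$crit_e <- suppressWarnings(criterion_homozygous(cand$gt1, cand$gt2))
  report$rejected_e <- sum(!cand$crit_e)
  cand <- cand[cand$crit_e, , drop = FALSE]
  report$after_e <- nrow(cand)

  rownames(cand) <- NULL
  list(survivors = cand, report = report)
}

#' Cull SNPs that sit too close together
#'
#' Every SNP within `min_gap` bp of any other surviving SNP on the same
#' contig is removed - both members of a close pair are dropped, since
#' either would contaminate the other's primer footprint. Idempotent.
#'
#' @param survivors candidate data.frame with chrom and pos.
#' @param min_gap distance threshold in bp (a pair exactly `min_gap` apart
#'   is culled).
#' @return the retained subset, sorted by (contig, position).
#' @export
proximity_cull <- function(survivors, min_gap = 20L) {
  if (nrow(survivors) == 0L) return(survivors)
  ord <- order(match(survivors$chrom, unique(survivors$chrom)), survivors$pos)
  s <- survivors[ord, , drop = FALSE]
  keep <- unlist(lapply(split(s$pos, factor(s$chrom, levels = unique(s$chrom))),
                        function(p) {
    n <- length(p)
    if (n == 1L) return(TRUE)
    gap_prev <- c(Inf, diff(p))
    gap_next <- c(diff(p), Inf)
    gap_prev > min_gap & gap_next > min_gap
  }), use.names = FALSE)
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a genome-wide marker panel
#'
#' Picks up to `per_chrom` SNPs per contig, spread out by even-quantile
#' binning: each contig is divided into `per_chrom` equal-length bins and
#' one SNP is taken per bin (the one nearest the bin midpoint, ties broken
#' by lowest position). Candidates inside priority intervals are preferred
#' within each bin. Deterministic and invariant to input row order.
#'
#' @param candidates filtered candidate data.frame (chrom, pos, ...).
#' @param lengths named contig lengths.
#' @param per_chrom markers to pick per contig.
#' @param priority_intervals optional data.frame (chrom, start, end;
#'   1-based inclusive) or GRanges of intervals to prefer, e.g.
#'   differentially-expressed-gene loci.
#' @return selected subset of `candidates` with a logical `priority`
#'   column, ordered by (contig, position). Contigs in `lengths` with no
#'   candidates produce a warning.
#' @export
select_genomewide <- function(candidates, lengths, per_chrom = 10L,
                              priority_intervals = NULL) {
  if (!is.null(priority_intervals) && !is.data.frame(priority_intervals)) {
    priority_intervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(priority_intervals)),
      start = GenomicRanges::start(priority_intervals),
      end = GenomicRanges::end(priority_intervals),
      stringsAsFactors = FALSE
    )
  }
  flag_priority <- function(chrom, pos) {
    if (is.null(priority_intervals) || nrow(priority_intervals) == 0L) {
      return(rep(FALSE, length(pos)))
    }
    vapply(seq_along(pos), function(i) {
      pi <- priority_intervals[priority_intervals$chrom == chrom[i], ,
                               drop = FALSE]
      any(pos[i] >= pi$start & pos[i] <= pi$end)
    }, logical(1))
  }

  picks <- lapply(names(lengths), function(ctg) {
    cc <- candidates[candidates$chrom == ctg, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    cc$priority <- flag_priority(cc$chrom, cc$pos)
    if (nrow(cc) == 0L) {
      warning("no candidates on contig ", ctg, call. = FALSE)
      return(cc)
    }
    if (nrow(cc) <= per_chrom) return(cc)
    L <- as.numeric(lengths[[ctg]])
    bin <- pmin(per_chrom, floor((cc$pos - 1) / (L / per_chrom)) + 1)
    chosen <- integer(0)
    for (b in seq_len(per_chrom)) {
      idx <- which(bin == b)
      if (!length(idx)) next
      if (any(cc$priority[idx])) idx <- idx[cc$priority[idx]]
      mid <- (b - 0.5) * L / per_chrom
      d <- abs(cc$pos[idx] - mid)
      chosen <- c(chosen, idx[order(d, cc$pos[idx])][1L])
    }
    cc[sort(chosen), , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}
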