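# Variant-panel summary statistics: per-chromosome variant rates, read
# mapping percentages, non-overlapping window densities, Ts/Tv ratios and
# SnpEff impact-class summaries.

#' Is a substitution a transition?
#'
#' A transition converts a purine into the other purine (A<->G) or a
#' pyrimidine into the other pyrimidine (C<->T); every other substitution
#' is a transversion.
#'
#' @param ref,alt single-base reference and alternate alleles in
#'   {A,C,G,T}, `ref != alt`. Vectorised.
#' @return logical vector, TRUE for transitions.
#' @export
is_transition <- function(ref, alt) {
  ok <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) {
    stop("is_transition() requires distinct single bases in {A,C,G,T}",
         call. = FALSE)
  }
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Transition/transversion summary
#'
#' Non-SNP rows are skipped; each per-alt row counts once.
#'
#' @param records variant data.frame with `ref`, `alt`, `is_snp`.
#' @return list of class `tstv_summary`: `transitions`, `transversions`,
#'   `ratio` (half-up to 2 decimals; NA with a warning when there are no
#'   transversions).
#' @export
ts_tv_ratio <- function(records) {
  snps <- records[records$is_snp & records$ref != records$alt, , drop = FALSE]
  ts <- if (nrow(snps)) sum(is_transition(snps$ref, snps$alt)) else 0L
  tv <- nrow(snps) - ts
  ratio <- if (tv == 0L) {
    if (ts > 0L) warning("no transversions counted; Ts/Tv ratio undefined",
                         call. = FALSE)
    NA_real_
  } else {
    round_half_up(ts / tv, 2)
  }
  structure(list(transitions = ts, transversions = tv, ratio = ratio),
            class = "tstv_summary")
}

#' Average bases per variant
#'
#' The tabulated "variant rate": `floor(length_bp / count)`, undefined
#' (NA) when the count is zero.
#'
#' @param length_bp contig length(s) in bp.
#' @param count variant count(s).
#' @return integer rate(s).
#' @export
variant_rate <- function(length_bp, count) {
  ifelse(count > 0, floor(length_bp / count), NA_real_)
}

#' Per-chromosome variant-rate table from explicit counts
#'
#' @param lengths named vector of contig lengths in bp.
#' @param counts named vector of variant counts (same names).
#' @return data.frame with one row per contig plus a `Total` row whose
#'   rate is floor(total length / total count); columns contig,
#'   length_bp, variant_count, variant_rate.
#' @export
variant_rate_table <- function(lengths, counts) {
  stopifnot(length(lengths) == length(counts))
  counts <- counts[names(lengths)]
  if (anyNA(counts)) {
    stop("counts missing for contig(s): ",
         paste(names(lengths)[is.na(counts)], collapse = ", "), call. = FALSE)
  }
  rows <- data.frame(
    contig = names(lengths),
    length_bp = as.numeric(lengths),
    variant_count = as.numeric(counts),
    variant_rate = variant_rate(as.numeric(lengths), as.numeric(counts)),
    stringsAsFactors = FALSE
  )
  total <- data.frame(
    contig = "Total",
    length_bp = sum(rows$length_bp),
    variant_count = sum(rows$variant_count),
    variant_rate = variant_rate(sum(rows$length_bp), sum(rows$variant_count)),
    stringsAsFactors = FALSE
  )
  rbind(rows, total)
}

#' Per-chromosome variant rates from variant records
#'
#' @param records variant data.frame; every row counts as one variant.
#' @param lengths named contig lengths covering all contigs present in
#'   `records`.
#' @return see [variant_rate_table()].
#' @export
chrom_variant_rates <- function(records, lengths) {
  missing <- setdiff(unique(records$chrom), names(lengths))
  if (length(missing)) {
    stop("contig(s) missing from `lengths`: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(records$chrom, levels = names(lengths)))
  variant_rate_table(lengths, setNames(as.integer(counts), names(lengths)))
}

#' Read-mapping percentages
#'
#' Computes the derived percentages of a read-mapping summary (uniquely
#' mapped, multi-mapped, unmapped-too-short, unmapped-other), each
#' `100 * count / input_reads` rounded half-up to 2 decimals.
#'
#' @param counts either a named list/vector with elements `input_reads`,
#'   `uniquely_mapped`, `multi_mapped`, `unmapped_too_short`,
#'   `unmapped_other`, or the path of a STAR `Log.final.out`-style
#'   `key | value` text file.
#' @return list of class `mapping_summary` with the input counts and
#'   percentages `uniquely_mapped_pct`, `multi_mapped_pct`,
#'   `unmapped_too_short_pct`, `unmapped_other_pct`.
#' @export
mapping_percentages <- function(counts) {
  if (is.character(counts) && length(counts) == 1L) {
    counts <- read_star_log(counts)
  }
  counts <- as.list(counts)
  need <- c("input_reads", "uniquely_mapped", "multi_mapped",
            "unmapped_too_short", "unmapped_other")
  if (!all(need %in% names(counts))) {
    stop("mapping counts must include: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  v <- vapply(counts[need], as.numeric, 0)
  if (any(v < 0)) stop("negative mapping counts", call. = FALSE)
  if (v[["input_reads"]] <= 0) stop("input_reads must be > 0", call. = FALSE)
  if (any(v[-1L] > v[["input_reads"]])) {
    stop("category counts exceed input_reads", call. = FALSE)
  }
  pct <- round_half_up(100 * v[-1L] / v[["input_reads"]], 2)
  names(pct) <- paste0(names(v)[-1L], "_pct")
  structure(c(as.list(v), as.list(pct)), class = "mapping_summary")
}

# Parse "  Key |\tvalue" lines from a STAR-style final mapping log into the
# count fields mapping_percentages() needs.
read_star_log <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^\\s*(.+?)\\s*\\|\\s*(\\S+)\\s*$", lines))
  kv <- kv[lengths(kv) == 3L]
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  get_num <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) NA_real_ else as.numeric(gsub("[,%]", "", vals[i]))
  }
  list(
    input_reads = get_num("Number of input reads"),
    uniquely_mapped = get_num("Uniquely mapped reads number"),
    multi_mapped = get_num("Number of reads mapped to multiple loci"),
    unmapped_too_short = get_num("Number of reads unmapped: too short"),
    unmapped_other = get_num("Number of reads unmapped: other")
  )
}

#' Variant density in non-overlapping windows
#'
#' Windows tile each contig from position 1; window `k` covers
#' `[(k-1)*window_bp + 1, k*window_bp]`, the last window truncated at the
#' contig end. Every variant lands in exactly one window.
#'
#' @param records variant data.frame.
#' @param lengths named contig lengths.
#' @param window_bp window size in bp (default 1 Mb).
#' @return data.frame contig, window_start, window_end, variant_count.
#' @export
window_densities <- function(records, lengths, window_bp = 1e6) {
  stopifnot(window_bp >= 1)
  out <- lapply(names(lengths), function(ctg) {
    len <- as.numeric(lengths[[ctg]])
    nwin <- max(1L, as.integer(ceiling(len / window_bp)))
    pos <- records$pos[records$chrom == ctg]
    win <- floor((pos - 1) / window_bp) + 1
    counts <- tabulate(win, nbins = nwin)
    start <- (seq_len(nwin) - 1) * window_bp + 1
    data.frame(contig = ctg, window_start = start,
               window_end = pmin(start + window_bp - 1, len),
               variant_count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

IMPACT_CLASSES <- c("modifier", "low", "moderate", "high")

# Keyword -> reported effect category, checked in order so that compound
# SnpEff effect strings (joined with "&") resolve to their most specific
# category.
EFFECT_KEYWORDS <- c(
  missense = "missense", synonymous = "synonymous",
  "3_prime_utr" = "3_prime_UTR", "5_prime_utr" = "5_prime_UTR",
  splice = "splice_region", intron = "intron",
  upstream = "upstream", downstream = "downstream", exon = "exon"
)

effect_category <- function(effect) {
  e <- tolower(effect)
  out <- rep("other", length(e))
  for (k in rev(names(EFFECT_KEYWORDS))) {
    out[grepl(k, e, fixed = TRUE)] <- EFFECT_KEYWORDS[[k]]
  }
  out
}

#' Summarise SnpEff impact annotations
#'
#' Parses the pipe-delimited SnpEff `ANN` entries carried in the `ann`
#' column (`allele|effect|impact|gene|...`, entries comma-separated).
#' Each annotation entry counts once, so a record with several
#' annotations contributes several counts and percentages are of total
#' annotations, mirroring SnpEff's own summary convention.
#'
#' @param records variant data.frame with an `ann` column.
#' @return list of class `impact_summary`: `impact` (data.frame class /
#'   count / pct over modifier, low, moderate, high), `effect`
#'   (data.frame category / count / pct), `n_annotations`,
#'   `n_malformed` (skipped entries, warned about when > 0).
#' @export
impact_summary <- function(records) {
  ann <- records$ann[!is.na(records$ann) & records$ann != ""]
  entries <- unlist(strsplit(ann, ",", fixed = TRUE), use.names = FALSE)
  fields <- strsplit(entries, "|", fixed = TRUE)
  ok <- lengths(fields) >= 3L
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warning(n_malformed, " malformed ANN entr(y/ies) skipped", call. = FALSE)
  }
  fields <- fields[ok]
  eff <- vapply(fields, `[`, "", 2L)
  imp <- tolower(vapply(fields, `[`, "", 3L))

  imp_counts <- table(factor(imp, levels = IMPACT_CLASSES))
  n <- length(fields)
  impact <- data.frame(
    class = IMPACT_CLASSES,
    count = as.integer(imp_counts),
    pct = if (n > 0) round_half_up(100 * as.integer(imp_counts) / n, 2) else
      rep(NA_real_, length(IMPACT_CLASSES)),
    stringsAsFactors = FALSE
  )
  cat_levels <- c(unname(EFFECT_KEYWORDS), "other")
  eff_counts <- table(factor(effect_category(eff), levels = cat_levels))
  effect <- data.frame(
    category = cat_levels,
    count = as.integer(eff_counts),
    pct = if (n > 0) round_half_up(100 * as.integer(eff_counts) / n, 2) else
      rep(NA_real_, length(cat_levels)),
    stringsAsFactors = FALSE
  )
  structure(list(impact = impact, effect = effect, n_annotations = n,
                 n_malformed = n_malformed),
            class = "impact_summary")
}
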