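# Two-line site comparison: PASS filtering and classification of sites as
# unique to one line, concordant-shared between both lines (polymorphic vs
# the reference but identical between the lines) or discordant-overlapping
# (same position, different alleles).

SITE_CLASSES <- c("unique_a", "unique_b", "concordant_shared",
                  "discordant_overlap")

#' Keep PASS-filtered variant records
#'
#' @param records variant data.frame from [read_vcf()].
#' @param keep_unfiltered keep records whose FILTER is "." (emitted by
#'   callers before a filtration step)? Default TRUE.
#' @return the subset of `records` with FILTER == "PASS" (and optionally
#'   "."), input order preserved.
#' @export
filter_pass <- function(records, keep_unfiltered = TRUE) {
  keep <- records$filter == "PASS"
  if (keep_unfiltered) keep <- keep | records$filter == "."
  records[keep, , drop = FALSE]
}

# Collapse per-alt rows to one row per (chrom, pos): ref and the sorted
# comma-joined alt set.
site_keys <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt_key = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$chrom, records$pos, sep = "\r")
  split_idx <- split(seq_len(nrow(records)), key)
  first <- vapply(split_idx, `[`, 0L, 1L)
  alt_key <- vapply(split_idx, function(i) {
    paste(sort(unique(records$alt[i])), collapse = ",")
  }, "")
  ord <- order(first)
  data.frame(chrom = records$chrom[first][ord],
             pos = records$pos[first][ord],
             ref = records$ref[first][ord],
             alt_key = unname(alt_key)[ord],
             stringsAsFactors = FALSE)
}

#' Classify sites between two lines
#'
#' Implements two-file site comparison with `--diff-site` semantics: the
#' comparison key is (contig, position); at shared positions, identical
#' REF and identical ALT-allele sets mean `concordant_shared`, anything
#' else `discordant_overlap`. Genotypes are not part of the key
#' (homozygosity is a downstream assay filter) and InDels participate.
#'
#' @param records_a,records_b variant data.frames (per-alt rows) for the
#'   two lines, sorted by (contig, position).
#' @return data.frame with one row per distinct site: chrom, pos, ref,
#'   alt_a, alt_b (comma-joined allele sets, NA where the line lacks the
#'   site) and class, one of `r paste(SITE_CLASSES, collapse = ", ")`.
#'   REF disagreements at a shared position are classified
#'   `discordant_overlap` and tallied in attribute `ref_mismatches` with a
#'   warning.
#' @export
diff_sites <- function(records_a, records_b) {
  for (r in list(a = records_a, b = records_b)) {
    if (!is_sorted_sites(r$chrom, r$pos)) {
      stop("input records are not sorted by (contig, position)",
           call. = FALSE)
    }
  }
  a <- site_keys(records_a)
  b <- site_keys(records_b)
  m <- merge(a, b, by = c("chrom", "pos"), all = TRUE,
             suffixes = c("_a", "_b"), sort = FALSE)

  in_a <- !is.na(m$alt_key_a)
  in_b <- !is.na(m$alt_key_b)
  cls <- ifelse(!in_b, "unique_a",
         ifelse(!in_a, "unique_b",
         ifelse(m$ref_a == m$ref_b & m$alt_key_a == m$alt_key_b,
                "concordant_shared", "discordant_overlap")))
  ref_mismatch <- sum(in_a & in_b & m$ref_a != m$ref_b)
  if (ref_mismatch > 0L) {
    warning(ref_mismatch,
            " shared position(s) with REF mismatch classified discordant_overlap",
            call. = FALSE)
  }

  chrom_levels <- unique(c(records_a$chrom, records_b$chrom))
  ord <- order(match(m$chrom, chrom_levels), m$pos)
  out <- data.frame(
    chrom = m$chrom, pos = m$pos,
    ref = ifelse(in_a, m$ref_a, m$ref_b),
    alt_a = m$alt_key_a, alt_b = m$alt_key_b,
    class = cls, stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ref_mismatches") <- ref_mismatch
  out
}

#' Summarise a two-line site comparison
#'
#' @param classified output of [diff_sites()].
#' @return list of class `comparison_summary`: `totals` (named counts per
#'   site class), `per_contig` (contig x class count data.frame),
#'   `n_sites` (distinct compared sites) and `ref_mismatches`.
#' @export
summarize_comparison <- function(classified) {
  cls <- factor(classified$class, levels = SITE_CLASSES)
  totals <- as.integer(table(cls))
  names(totals) <- SITE_CLASSES
  per_contig <- as.data.frame.matrix(
    table(factor(classified$chrom, levels = unique(classified$chrom)), cls)
  )
  per_contig <- cbind(contig = rownames(per_contig), per_contig,
                      stringsAsFactors = FALSE)
  rownames(per_contig) <- NULL
  structure(
    list(totals = totals, per_contig = per_contig,
         n_sites = nrow(classified),
         ref_mismatches = attr(classified, "ref_mismatches") %||% 0L),
    class = "comparison_summary"
  )
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Two-line site comparison:", x$n_sites, "distinct sites\n")
  for (k in names(x$totals)) {
    cat(sprintf("  %-20s %d\n", k, x$totals[[k]]))
  }
  if (x$ref_mismatches > 0L) {
    cat("  (", x$ref_mismatches, "REF mismatches at shared positions )\n")
  }
  invisible(x)
}

#' Write a site-comparison table to TSV
#'
#' @param classified output of [diff_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(classified, path) {
  utils::write.table(classified, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
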