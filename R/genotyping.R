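# Scoring of KASP genotyping plates from discrete allele calls: per-marker
# status classification (polymorphic / monomorphic / partial / failed) and
# panel-level conversion metrics (design success rate, work success rate,
# polymorphic rate).

ALLELE_CALLS <- c("X", "Y", "HET", "MISSING")
MARKER_STATUSES <- c("polymorphic", "monomorphic", "partial", "failed")

# Default vocabulary for plate-export call tables.
DEFAULT_CALL_VOCAB <- c(
  "X:X" = "X", "Y:Y" = "Y", "X:Y" = "HET", "Y:X" = "HET",
  "?" = "MISSING", "NTC" = "MISSING",
  "X" = "X", "Y" = "Y", "HET" = "HET", "MISSING" = "MISSING"
)

validate_roles <- function(roles, samples) {
  need <- c("parent_a", "parent_b", "f2", "ntc")
  if (!all(need %in% names(roles))) {
    stop("roles must name parent_a, parent_b, f2 and ntc samples",
         call. = FALSE)
  }
  assigned <- unlist(roles[need], use.names = FALSE)
  if (anyDuplicated(assigned)) {
    stop("sample(s) assigned to more than one role: ",
         paste(unique(assigned[duplicated(assigned)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(assigned, samples)
  if (length(missing)) {
    stop("role assignment names unknown sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(roles$parent_a) < 1L || length(roles$parent_b) < 1L) {
    stop("at least one replicate of each parent is required", call. = FALSE)
  }
  invisible(roles)
}

#' Classify one marker from its plate calls
#'
#' A marker is `failed` when the fraction of MISSING calls among non-NTC
#' wells exceeds `fail_threshold` (the "majority of missing data" pattern)
#' or any no-template control amplifies. It is `polymorphic` when the
#' parent-A replicates are concordantly one homozygous class, the parent-B
#' replicates concordantly the other, and the F2 individuals contain both
#' homozygous classes. It is `monomorphic` when every non-missing call is
#' the same homozygous class. Anything else (one allele plus
#' heterozygotes, discordant parent replicates, ...) is `partial`.
#'
#' @param calls named character vector of calls in
#'   {X, Y, HET, MISSING}, one per sample.
#' @param roles list with character vectors `parent_a`, `parent_b`, `f2`,
#'   `ntc` naming the samples in each role.
#' @param fail_threshold missing-call fraction above which the marker is
#'   failed (default 0.5).
#' @return one of `"polymorphic"`, `"monomorphic"`, `"partial"`,
#'   `"failed"`.
#' @export
classify_marker <- function(calls, roles, fail_threshold = 0.5) {
  validate_roles(roles, names(calls))
  non_ntc <- c(roles$parent_a, roles$parent_b, roles$f2)
  if (!all(non_ntc %in% names(calls))) {
    stop("calls do not cover all role samples", call. = FALSE)
  }
  bad <- setdiff(unique(calls), ALLELE_CALLS)
  if (length(bad)) {
    stop("unknown call value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cc <- calls[non_ntc]
  if (mean(cc == "MISSING") > fail_threshold) return("failed")
  if (length(roles$ntc) && any(calls[roles$ntc] != "MISSING")) {
    return("failed")
  }

  pa <- calls[roles$parent_a]
  pb <- calls[roles$parent_b]
  f2 <- calls[roles$f2]
  concordant_hom <- function(x) {
    length(unique(x)) == 1L && x[[1L]] %in% c("X", "Y")
  }
  if (concordant_hom(pa) && concordant_hom(pb) && pa[[1L]] != pb[[1L]] &&
      all(c("X", "Y") %in% f2)) {
    return("polymorphic")
  }
  obs <- unique(cc[cc != "MISSING"])
  if (length(obs) == 1L && obs %in% c("X", "Y")) return("monomorphic")
  "partial"
}

#' Panel conversion metrics
#'
#' The SNP conversion rate decomposes into the design success rate (assays
#' designed / SNP sites selected) and the work success rate (assays that
#' generate genotype calls / assays designed); the polymorphic rate is the
#' fraction of designed assays scored polymorphic.
#'
#' @param statuses character vector of per-marker statuses from
#'   [classify_marker()], one per designed assay.
#' @param selected_sites number of SNP sites chosen for design.
#' @param designed_count number of assays successfully designed (default
#'   `length(statuses)`).
#' @return list of class `panel_summary`: per-status counts,
#'   `selected_sites`, `designed_count`, and `design_success_rate`,
#'   `work_success_rate`, `polymorphic_rate` in percent (half-up, 1
#'   decimal; NA when `designed_count` is 0).
#' @export
summarize_panel <- function(statuses, selected_sites,
                            designed_count = length(statuses)) {
  if (length(statuses)) {
    bad <- setdiff(unique(statuses), MARKER_STATUSES)
    if (length(bad)) {
      stop("unknown marker status(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(statuses) != designed_count) {
    stop("one status per designed assay is required", call. = FALSE)
  }
  if (designed_count > selected_sites) {
    stop("designed_count cannot exceed selected_sites", call. = FALSE)
  }
  counts <- table(factor(statuses, levels = MARKER_STATUSES))
  counts <- setNames(as.integer(counts), MARKER_STATUSES)
  rates <- if (designed_count == 0L) {
    list(design_success_rate = NA_real_, work_success_rate = NA_real_,
         polymorphic_rate = NA_real_)
  } else {
    list(
      design_success_rate =
        round_half_up(100 * designed_count / selected_sites, 1),
      work_success_rate =
        round_half_up(100 * (designed_count - counts[["failed"]]) /
                        designed_count, 1),
      polymorphic_rate =
        round_half_up(100 * counts[["polymorphic"]] / designed_count, 1)
    )
  }
  structure(c(list(counts = counts, selected_sites = selected_sites,
                   designed_count = designed_count), rates),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("KASP panel:", x$designed_count, "assays designed from",
      x$selected_sites, "selected SNP sites\n")
  for (k in names(x$counts)) cat(sprintf("  %-12s %d\n", k, x$counts[[k]]))
  cat(sprintf("  design success %.1f%%, work success %.1f%%, polymorphic %.1f%%\n",
              x$design_success_rate, x$work_success_rate,
              x$polymorphic_rate))
  invisible(x)
}

#' Read a marker call table
#'
#' Reads a CSV/TSV plate export with one row per marker (first column =
#' marker id) and one column per sample. Call tokens are normalised
#' through `vocab`; unknown tokens become MISSING with a warning tally.
#'
#' @param path path to the table (delimiter inferred from the extension:
#'   `.csv` comma, otherwise tab).
#' @param roles role assignment, see [classify_marker()].
#' @param vocab named character vector mapping raw tokens to
#'   X/Y/HET/MISSING.
#' @return list of class `marker_call_table`: `calls` (markers x samples
#'   character matrix), `roles`, `n_unknown_tokens`.
#' @export
read_call_table <- function(path, roles, vocab = DEFAULT_CALL_VOCAB) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate marker id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  mapped <- vocab[m]
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning(sum(unknown), " unknown call token(s) set to MISSING",
            call. = FALSE)
    mapped[unknown] <- "MISSING"
  }
  calls <- matrix(mapped, nrow = nrow(m), dimnames = dimnames(m))
  validate_roles(roles, colnames(calls))
  structure(list(calls = calls, roles = roles,
                 n_unknown_tokens = sum(unknown)),
            class = "marker_call_table")
}

#' Write a marker call table
#'
#' Inverse of [read_call_table()] for the normalised vocabulary.
#'
#' @param tbl a `marker_call_table`.
#' @param path output path (`.csv` for comma-separated).
#' @return `path`, invisibly.
#' @export
write_call_table <- function(tbl, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(marker = rownames(tbl$calls), tbl$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify every marker of a call table
#'
#' @param tbl a `marker_call_table`.
#' @param fail_threshold see [classify_marker()].
#' @return named character vector of statuses, one per marker.
#' @export
classify_panel <- function(tbl, fail_threshold = 0.5) {
  vapply(rownames(tbl$calls), function(mk) {
    classify_marker(tbl$calls[mk, ], tbl$roles, fail_threshold)
  }, "")
}
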