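# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages and ratios in
#' genotyping reports conventionally round half up, so summaries use this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.345, 2)  # 2.35, where round() gives 2.34
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run expr with a temporary RNG state seeded from `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Condition constructor so callers can class-match errors such as
# flank_unavailable or design_failure.
kf_error <- function(msg, class, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "kaspforge_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

# TRUE when (chrom, pos) keys come grouped by contig with non-decreasing
# positions inside each contig block.
is_sorted_sites <- function(chrom, pos) {
  if (length(chrom) <= 1L) return(TRUE)
  r <- rle(as.character(chrom))
  if (anyDuplicated(r$values)) return(FALSE)
  all(unlist(tapply(pos, factor(chrom, levels = unique(chrom)), function(p) {
    !is.unsorted(p)
  }, simplify = FALSE)))
}

stopifnot_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single string", name), call. = FALSE)
  }
}
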