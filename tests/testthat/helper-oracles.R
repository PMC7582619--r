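# Shared fixtures-in-code and independent brute-force oracles.

# Build a variant data.frame in read_vcf() layout from parallel vectors.
make_records <- function(chrom, pos, ref, alt, filter = "PASS", gt = "1/1",
                         dp = 30L, ann = NA_character_, n_alt = 1L) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  df <- data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    alt_index = 1L, n_alt = as.integer(rep_len(n_alt, n)),
    filter = rep_len(filter, n), gt = rep_len(gt, n),
    stringsAsFactors = FALSE
  )
  g <- do.call(rbind, strsplit(df$gt, "[/|]"))
  df$gt1 <- suppressWarnings(as.integer(g[, 1]))
  df$gt2 <- suppressWarnings(as.integer(g[, 2]))
  df$dp <- as.integer(rep_len(dp, n))
  df$ann <- rep_len(ann, n)
  df$is_snp <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  df
}

# Per-base complement table: the independent oracle for reverse_complement.
naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  vapply(s, function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Set-algebra oracle for two-line site classification: loops over the
# union of positions and compares allele sets directly.
oracle_diff <- function(a, b) {
  keys <- unique(rbind(a[c("chrom", "pos")], b[c("chrom", "pos")]))
  cls <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    ra <- a[a$chrom == keys$chrom[i] & a$pos == keys$pos[i], ]
    rb <- b[b$chrom == keys$chrom[i] & b$pos == keys$pos[i], ]
    cls[i] <- if (nrow(rb) == 0) "unique_a"
    else if (nrow(ra) == 0) "unique_b"
    else if (length(unique(ra$ref)) == 1 && length(unique(rb$ref)) == 1 &&
             ra$ref[1] == rb$ref[1] &&
             setequal(ra$alt, rb$alt)) "concordant_shared"
    else "discordant_overlap"
  }
  keys$class <- cls
  keys[order(match(keys$chrom, unique(c(a$chrom, b$chrom))), keys$pos), ]
}

# Random sorted variant sets sharing a pool of positions, so all four
# site classes occur.
random_record_pair <- function(n_max = 200) {
  pool <- sort(sample(1e5, n_max))
  bases <- c("A", "C", "G", "T")
  draw <- function() {
    pos <- sort(sample(pool, sample(20:n_max, 1)))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    make_records("c1", pos, ref, alt)
  }
  # Force shared positions with shared ref so concordant/discordant both
  # arise: rebuild B reusing A's (pos, ref) for sampled overlap.
  a <- draw()
  b <- draw()
  common <- intersect(a$pos, b$pos)
  b$ref[match(common, b$pos)] <- a$ref[match(common, a$pos)]
  half <- common[seq_len(length(common) %/% 2)]
  b$alt[match(half, b$pos)] <- a$alt[match(half, a$pos)]
  b$alt <- vapply(seq_len(nrow(b)), function(i) {
    if (b$alt[i] == b$ref[i]) sample(setdiff(bases, b$ref[i]), 1) else b$alt[i]
  }, "")
  list(a = a, b = b)
}

# Brute-force tandem-repeat oracle: enumerate every (start, motif length)
# and count consecutive exact copies.
oracle_max_tandem <- function(s, mmin = 1, mmax = 5) {
  n <- nchar(s)
  best <- 1L
  if (n %/% 2 < mmin) return(best)
  for (m in mmin:(n %/% 2)) {
    if (m > mmax) break
    for (start in 1:(n - 2 * m + 1)) {
      motif <- substr(s, start, start + m - 1)
      k <- 1L
      while (start + (k + 1) * m - 1 <= n &&
             substr(s, start + k * m, start + (k + 1) * m - 1) == motif) {
        k <- k + 1L
      }
      best <- max(best, k)
    }
  }
  best
}

# All strings of length 1..n over an alphabet.
all_strings <- function(n, alphabet = c("A", "C")) {
  unlist(lapply(seq_len(n), function(k) {
    do.call(paste0, expand.grid(rep(list(alphabet), k)))
  }))
}

# Small fixture spec (3 x 60 kb) for fast unit tests.
small_spec <- function(seed = 7, ...) {
  fixture_spec(
    seed = seed,
    contig_lengths = c(c1 = 6e4, c2 = 6e4, c3 = 6e4),
    unique_a = 60, unique_b = 40, shared = 30, overlap = 12,
    n_indel_adjacent = 4, n_ambiguous = 4, n_low_depth = 4, n_repeat = 4,
    n_heterozygous = 4, n_close_pairs = 3, n_lowqual = 3, ...
  )
}

# Standard plate roles for hand-built call vectors.
plate_roles <- function(n_f2 = 6) {
  list(parent_a = c("PA1", "PA2"), parent_b = c("PB1", "PB2"),
       f2 = sprintf("F2_%02d", seq_len(n_f2)), ntc = c("NTC1", "NTC2"))
}

plate_calls <- function(pa, pb, f2, ntc = c("MISSING", "MISSING")) {
  roles <- plate_roles(length(f2))
  setNames(c(pa, pb, f2, ntc),
           c(roles$parent_a, roles$parent_b, roles$f2, roles$ntc))
}
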