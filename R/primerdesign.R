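# KASP assay construction: two allele-specific forward primers that end on
# the SNP base and carry the universal FAM / HEX tail sequences, plus a
# common reverse primer taken from the right flank, under an amplicon
# length ceiling. All design is on the plus strand and deterministic.

#' Universal KASP tail sequences
#'
#' The standard 5' tails that route each allele-specific primer to the FAM
#' or HEX fluorophore of the master mix.
#'
#' @return list with elements `fam` and `hex`.
#' @export
kasp_tails <- function() {
  list(fam = "GAAGGTGACCAAGTTCATGCT",
       hex = "GAAGGTCGGAGTCAACGGATT")
}

#' Primer design parameters
#'
#' Thermodynamic defaults: annealing-temperature target 57 degC (the final
#' annealing temperature of a standard KASP touchdown program), +/- 3 degC
#' tolerance, untailed primer lengths 17-30 nt, amplicons under 100 bp so
#' no extension step is needed.
#'
#' @param tm_target target melting temperature, degC (untailed portion).
#' @param tm_tol tolerance around `tm_target`, degC.
#' @param min_len,max_len untailed primer length bounds, nt.
#' @param max_amplicon exclusive upper bound on amplicon length, bp.
#' @param tm_model `"nearest-neighbor"` or `"wallace"`.
#' @param na_conc monovalent cation concentration, mol/L.
#' @param oligo_conc total oligo concentration, mol/L.
#' @return named list of parameters.
#' @export
design_params <- function(tm_target = 57, tm_tol = 3, min_len = 17L,
                          max_len = 30L, max_amplicon = 100L,
                          tm_model = c("nearest-neighbor", "wallace"),
                          na_conc = 0.05, oligo_conc = 0.25e-6) {
  list(tm_target = tm_target, tm_tol = tm_tol,
       min_len = as.integer(min_len), max_len = as.integer(max_len),
       max_amplicon = as.integer(max_amplicon),
       tm_model = match.arg(tm_model),
       na_conc = na_conc, oligo_conc = oligo_conc)
}

# Allawi & SantaLucia (1997) unified nearest-neighbor parameters;
# dinucleotide and its reverse complement share a stack.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Oligo melting temperature
#'
#' Wallace rule (2 degC per A/T, 4 degC per G/C) or the unified
#' nearest-neighbor duplex model: Tm = 1000*dH / (dS + 0.368*(N-1)*ln[Na+]
#' + R*ln(CT/4)) - 273.15, with dH/dS summed over dinucleotide stacks plus
#' terminal initiation terms. Defaults: 50 mM monovalent salt, 0.25 uM
#' total oligo.
#'
#' @param seq character vector of sequences over {A,C,G,T}.
#' @param model `"nearest-neighbor"` (default) or `"wallace"`.
#' @param na_conc monovalent cation concentration, mol/L.
#' @param oligo_conc total oligo concentration, mol/L.
#' @return numeric vector of melting temperatures in degC.
#' @export
melting_temperature <- function(seq, model = c("nearest-neighbor", "wallace"),
                                na_conc = 0.05, oligo_conc = 0.25e-6) {
  model <- match.arg(model)
  if (any(grepl("[^ACGT]", seq))) {
    stop("melting_temperature() accepts only A/C/G/T sequences",
         call. = FALSE)
  }
  if (model == "wallace") {
    gc <- nchar(gsub("[AT]", "", seq))
    at <- nchar(seq) - gc
    return(2 * at + 4 * gc)
  }
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    if (n < 2L) stop("sequence too short for nearest-neighbor model",
                     call. = FALSE)
    di <- paste0(b[-n], b[-1L])
    dh <- sum(NN_DH[di])
    ds <- sum(NN_DS[di])
    for (e in b[c(1L, n)]) {
      if (e %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
      else { dh <- dh + 0.1; ds <- ds - 2.8 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na_conc)
    1000 * dh / (ds + 1.987 * log(oligo_conc / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Design the two tailed allele-specific forward primers
#'
#' The untailed primer is a suffix of the left flank followed by the
#' allele base, so the SNP sits at the 3' end; both allele primers share
#' the same genomic footprint and differ only at that final base. The
#' suffix length is the shortest in `[min_len, max_len]` whose
#' (weaker-allele) untailed Tm reaches `tm_target - tm_tol`; if no length
#' reaches it the longest usable primer is returned with a warning. FAM
#' and HEX tails are prepended afterwards.
#'
#' @param left_flank sequence immediately 5' of the SNP.
#' @param allele_x,allele_y the two SNP alleles; X gets the FAM tail, Y
#'   the HEX tail.
#' @param params list from [design_params()].
#' @return list: `primer_x`, `primer_y` (tailed), `untailed_x`,
#'   `untailed_y`, `genomic_length`, `tm_x`, `tm_y`, `tm_ok`.
#' @export
design_allele_specific <- function(left_flank, allele_x, allele_y,
                                   params = design_params()) {
  p <- params
  if (nchar(left_flank) < p$min_len - 1L) {
    kf_error(sprintf("left flank too short (%d < %d bases)",
                     nchar(left_flank), p$min_len - 1L), "design_failure")
  }
  tails <- kasp_tails()
  lens <- p$min_len:min(p$max_len, nchar(left_flank) + 1L)
  best <- NULL
  for (L in lens) {
    suffix <- substr(left_flank, nchar(left_flank) - (L - 2L),
                     nchar(left_flank))
    ux <- paste0(suffix, allele_x)
    uy <- paste0(suffix, allele_y)
    if (grepl("[^ACGT]", ux) || grepl("[^ACGT]", uy)) next
    tm_x <- melting_temperature(ux, p$tm_model, p$na_conc, p$oligo_conc)
    tm_y <- melting_temperature(uy, p$tm_model, p$na_conc, p$oligo_conc)
    cand <- list(ux = ux, uy = uy, L = L, tm_x = tm_x, tm_y = tm_y,
                 tm = min(tm_x, tm_y))
    if (cand$tm >= p$tm_target - p$tm_tol) { best <- cand; break }
    if (is.null(best) || cand$tm > best$tm) best <- cand
  }
  if (is.null(best)) {
    kf_error("no usable forward primer (ambiguous bases adjacent to site)",
             "design_failure")
  }
  tm_ok <- best$tm >= p$tm_target - p$tm_tol
  if (!tm_ok) {
    warning(sprintf("forward primer Tm %.1f below target band; longest usable primer returned",
                    best$tm), call. = FALSE)
  }
  list(primer_x = paste0(tails$fam, best$ux),
       primer_y = paste0(tails$hex, best$uy),
       untailed_x = best$ux, untailed_y = best$uy,
       genomic_length = best$L, tm_x = best$tm_x, tm_y = best$tm_y,
       tm_ok = tm_ok)
}

#' Design the common reverse primer
#'
#' The reverse primer is the reverse complement of a window of the right
#' flank. The window end offset (its rightmost template base, measured
#' from the SNP) is chosen minimal such that some window length in
#' `[min_len, max_len]` has Tm within `tm_target +/- tm_tol` and the
#' amplicon (forward footprint through the window end) stays under
#' `max_amplicon` bp.
#'
#' @param right_flank sequence immediately 3' of the SNP.
#' @param forward_len untailed length of the allele-specific forward
#'   primers (their footprint ends on the SNP).
#' @param params list from [design_params()].
#' @return list: `primer_common`, `genomic_length`, `end_offset`,
#'   `tm_common`, `amplicon_len`.
#' @export
design_common_reverse <- function(right_flank, forward_len,
                                  params = design_params()) {
  p <- params
  if (nchar(right_flank) < p$min_len) {
    kf_error(sprintf("right flank too short (%d < %d bases)",
                     nchar(right_flank), p$min_len), "design_failure")
  }
  for (e in p$min_len:nchar(right_flank)) {
    amplicon <- forward_len + e
    if (amplicon >= p$max_amplicon) break
    for (L in p$min_len:min(p$max_len, e)) {
      win <- substr(right_flank, e - L + 1L, e)
      if (grepl("[^ACGT]", win)) next
      tm <- melting_temperature(win, p$tm_model, p$na_conc, p$oligo_conc)
      if (abs(tm - p$tm_target) <= p$tm_tol) {
        return(list(primer_common = reverse_complement(win),
                    genomic_length = L, end_offset = e, tm_common = tm,
                    amplicon_len = amplicon))
      }
    }
  }
  kf_error(sprintf(
    "no reverse primer with Tm in %.1f +/- %.1f degC and amplicon < %d bp",
    p$tm_target, p$tm_tol, p$max_amplicon), "design_failure")
}

#' Marker identifier
#'
#' Zero-padded naming: `MKAM_<contig ordinal, 2 digits>_<serial, 3 digits>`.
#'
#' @param contig_ordinal 1-based index of the contig in genome order
#'   (1-99).
#' @param serial running assay number (1-999).
#' @return marker id string such as `"MKAM_04_031"`.
#' @export
mkam_id <- function(contig_ordinal, serial) {
  if (any(contig_ordinal < 1L | contig_ordinal > 99L)) {
    stop("contig ordinal outside the 2-digit field (1-99)", call. = FALSE)
  }
  if (any(serial < 1L | serial > 999L)) {
    stop("serial outside the 3-digit field (1-999)", call. = FALSE)
  }
  sprintf("MKAM_%02d_%03d", as.integer(contig_ordinal), as.integer(serial))
}

#' Assemble one KASP assay
#'
#' Designs both primers for a filtered candidate and assembles the marker
#' record. Allele X is line A's allele and carries the FAM tail; allele Y
#' is line B's allele and carries HEX (set `swap_dyes = TRUE` to invert).
#'
#' @param candidate one-row candidate data.frame with chrom, pos,
#'   left_flank, right_flank.
#' @param allele_x,allele_y line-A and line-B allele bases.
#' @param contig_ordinal,serial marker-id fields, see [mkam_id()].
#' @param params list from [design_params()].
#' @param swap_dyes put FAM on allele Y instead.
#' @return one-row data.frame: marker_id, chrom, pos, allele_x, allele_y,
#'   primer_x, primer_y, primer_common, len_x, len_y, len_common,
#'   amplicon_len, tm_x, tm_y, tm_common (degC, 1 decimal).
#' @export
assemble_assay <- function(candidate, allele_x, allele_y, contig_ordinal,
                           serial, params = design_params(),
                           swap_dyes = FALSE) {
  if (swap_dyes) {
    tmp <- allele_x; allele_x <- allele_y; allele_y <- tmp
  }
  fwd <- design_allele_specific(candidate$left_flank, allele_x, allele_y,
                                params)
  rev <- design_common_reverse(candidate$right_flank, fwd$genomic_length,
                               params)
  data.frame(
    marker_id = mkam_id(contig_ordinal, serial),
    chrom = candidate$chrom, pos = candidate$pos,
    allele_x = allele_x, allele_y = allele_y,
    primer_x = fwd$primer_x, primer_y = fwd$primer_y,
    primer_common = rev$primer_common,
    len_x = fwd$genomic_length, len_y = fwd$genomic_length,
    len_common = rev$genomic_length,
    amplicon_len = rev$amplicon_len,
    tm_x = round_half_up(fwd$tm_x, 1), tm_y = round_half_up(fwd$tm_y, 1),
    tm_common = round_half_up(rev$tm_common, 1),
    stringsAsFactors = FALSE
  )
}

#' Design assays for a selected marker panel
#'
#' Runs [assemble_assay()] over selected candidates. For sites unique to
#' line A the line-A allele is the ALT base and line B matches the
#' reference, so `allele_x = alt`, `allele_y = ref` (and conversely for a
#' unique-to-B panel with `line = "b"`). Serial numbers run across the
#' panel in (contig, position) order.
#'
#' @param selected candidate data.frame from [select_genomewide()].
#' @param genome_order character vector of contig names defining contig
#'   ordinals.
#' @param line `"a"` or `"b"`: which line the panel's SNPs are unique to.
#' @param params list from [design_params()].
#' @param swap_dyes see [assemble_assay()].
#' @return list: `assays` (data.frame, one row per designed assay) and
#'   `failures` (data.frame chrom / pos / reason for design failures).
#' @export
design_assays <- function(selected, genome_order, line = c("a", "b"),
                          params = design_params(), swap_dyes = FALSE) {
  line <- match.arg(line)
  ord <- order(match(selected$chrom, genome_order), selected$pos)
  selected <- selected[ord, , drop = FALSE]
  assays <- list()
  failures <- list()
  serial <- 0L
  for (i in seq_len(nrow(selected))) {
    cand <- selected[i, , drop = FALSE]
    ax <- if (line == "a") cand$alt else cand$ref
    ay <- if (line == "a") cand$ref else cand$alt
    serial <- serial + 1L
    res <- tryCatch(
      assemble_assay(cand, ax, ay,
                     contig_ordinal = match(cand$chrom, genome_order),
                     serial = serial, params = params,
                     swap_dyes = swap_dyes),
      design_failure = function(e) e
    )
    if (inherits(res, "design_failure")) {
      serial <- serial - 1L
      failures[[length(failures) + 1L]] <- data.frame(
        chrom = cand$chrom, pos = cand$pos,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      assays[[length(assays) + 1L]] <- res
    }
  }
  list(
    assays = if (length(assays)) do.call(rbind, assays) else NULL,
    failures = if (length(failures)) do.call(rbind, failures) else
      data.frame(chrom = character(), pos = integer(), reason = character(),
                 stringsAsFactors = FALSE)
  )
}
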