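# Readers/writers for the standard formats the pipeline touches and the
# primitive sequence operations (flank extraction, reverse complement).
#
# Coordinate conventions: every user-facing position is 1-based (VCF
# convention); bedGraph/BED input is converted from 0-based half-open at
# the boundary and never leaks through.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

variant_columns <- c("chrom", "pos", "ref", "alt", "alt_index", "n_alt",
                     "filter", "gt", "gt1", "gt2", "dp", "ann", "is_snp")

empty_variants <- function() {
  data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), alt_index = integer(), n_alt = integer(),
    filter = character(), gt = character(), gt1 = integer(),
    gt2 = integer(), dp = integer(), ann = character(),
    is_snp = logical(), stringsAsFactors = FALSE
  )
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masking is ignored; only non-ACGT IUPAC
#' codes count as ambiguous downstream) and contig names are taken as the
#' first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase contig sequences, with
#'   class `genome_sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  class(seqs) <- c("genome_sequence", "character")
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @param width line wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Contig lengths of a genome
#'
#' @param genome named character vector as returned by [read_fasta()].
#' @return named integer vector of contig lengths in bp.
#' @export
contig_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Read variant records from a VCF file
#'
#' Returns one row per (site, ALT allele): multi-allelic records are split
#' at ingestion so that SNP/InDel status is unambiguous per allele; the
#' original genotype and the source allele count (`n_alt`) are kept. DP is
#' taken from the sample FORMAT field, falling back to INFO/DP; SnpEff ANN
#' strings are carried verbatim in `ann`.
#'
#' @param path path to an uncompressed or bgzipped VCF (v4.x) with a GT
#'   FORMAT field.
#' @param sample sample name to extract; may be omitted for single-sample
#'   files.
#' @return data.frame of variant records (one row per alt allele) with
#'   columns chrom, pos, ref, alt, alt_index, n_alt, filter, gt, gt1, gt2,
#'   dp, ann, is_snp.
#' @export
read_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix)) return(empty_variants())
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  if (nrow(fix) == 0L) return(empty_variants())

  if (ncol(v@gt) < 2L) {
    stop("VCF has no sample columns (GT required): ", path, call. = FALSE)
  }
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) > 1L) {
      stop("multi-sample VCF: specify `sample`; available: ",
           paste(samples, collapse = ", "), call. = FALSE)
    }
    sample <- samples
  } else if (!sample %in% samples) {
    stop("unknown sample '", sample, "'; available: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))) {
    stop("GT missing from FORMAT in one or more records: ", path,
         call. = FALSE)
  }

  gt <- vcfR::extract.gt(v, element = "GT")[, sample]
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, sample]
  )
  dp_info <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  if (!is.null(dp_info) && length(dp_info) == nrow(fix)) {
    dp <- ifelse(is.na(dp), dp_info, dp)
  }
  ann <- vcfR::extract.info(v, "ANN")
  if (is.null(ann)) ann <- rep(NA_character_, nrow(fix))

  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)

  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  alt_index <- sequence(n_alt)
  g <- parse_gt(gt[idx])

  out <- data.frame(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = unlist(alts, use.names = FALSE),
    alt_index = alt_index,
    n_alt = as.integer(n_alt[idx]),
    filter = filt[idx],
    gt = unname(gt[idx]),
    gt1 = g[, 1L],
    gt2 = g[, 2L],
    dp = as.integer(dp[idx]),
    ann = unname(ann[idx]),
    stringsAsFactors = FALSE
  )
  out$is_snp <- nchar(out$ref) == 1L & nchar(out$alt) == 1L
  rownames(out) <- NULL
  out
}

# "0/1", "1|1", "./." -> two integer allele indices (NA when missing).
parse_gt <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2L) p[[2L]] else p[[1L]]
  }, "")))
  cbind(a1, a2)
}

#' Write variant records to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT:DP per record (and INFO/ANN when
#' present). One data line is written per row, so per-alt split records
#' come out as separate biallelic lines.
#'
#' @param records variant data.frame as produced by [read_vcf()] or the
#'   fixture generator.
#' @param path output path.
#' @param sample_name sample column name.
#' @param contig_lengths optional named lengths written as contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "sample",
                      contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=kaspforge",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  if (nrow(records)) {
    info <- ifelse(is.na(records$ann) | records$ann == "",
                   ".", paste0("ANN=", records$ann))
    dp <- ifelse(is.na(records$dp), ".", as.character(records$dp))
    gt <- ifelse(is.na(records$gt), "./.", records$gt)
    lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT:DP\t%s:%s",
                     records$chrom, records$pos, records$ref, records$alt,
                     records$filter, info, gt, dp)
  } else {
    lines <- character()
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a per-base depth track
#'
#' @param path path to the depth file.
#' @param dialect `"bedgraph"` (0-based half-open intervals, column 4 =
#'   depth) or `"depth-tsv"` (samtools-depth style: contig, 1-based
#'   position, depth).
#' @return a `depth_track`: named list of integer vectors, one per contig;
#'   positions absent from the input have depth 0.
#' @export
read_depth <- function(path, dialect = c("bedgraph", "depth-tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bedgraph") {
    g <- rtracklayer::import(con = path, format = "bedGraph")
    if (any(GenomicRanges::mcols(g)$score < 0)) {
      stop("negative depth in bedGraph", call. = FALSE)
    }
    by_contig <- GenomicRanges::split(g, GenomicRanges::seqnames(g), drop = TRUE)
    if (!all(vapply(as.list(by_contig), IRanges::isDisjoint, logical(1)))) {
      stop("overlapping bedGraph intervals", call. = FALSE)
    }
    track <- lapply(as.list(by_contig), function(gi) {
      v <- integer(max(GenomicRanges::end(gi)))
      for (i in seq_along(gi)) {
        v[GenomicRanges::start(gi)[i]:GenomicRanges::end(gi)[i]] <-
          as.integer(GenomicRanges::mcols(gi)$score[i])
      }
      v
    })
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "pos", "depth"),
                             colClasses = c("character", "integer", "integer"))
    if (any(tab$depth < 0)) stop("negative depth in depth TSV", call. = FALSE)
    track <- lapply(split(tab, tab$chrom), function(d) {
      v <- integer(max(d$pos))
      v[d$pos] <- d$depth
      v
    })
  }
  structure(track, class = "depth_track")
}

#' Depth at 1-based positions
#'
#' Positions beyond the end of the track (or on contigs the track does not
#' cover) return 0 by convention.
#'
#' @param track a `depth_track` from [read_depth()].
#' @param chrom contig name (scalar).
#' @param pos integer vector of 1-based positions.
#' @return integer vector of depths.
#' @export
depth_at <- function(track, chrom, pos) {
  v <- track[[chrom]]
  if (is.null(v)) return(integer(length(pos)))
  out <- integer(length(pos))
  ok <- pos >= 1L & pos <= length(v)
  out[ok] <- v[pos[ok]]
  out
}

#' Extract SNP flanking sequences
#'
#' Returns the `width` bases on each side of a 1-based site; the site base
#' itself is excluded. Sites closer than `width` to a contig end raise a
#' `flank_unavailable` error.
#'
#' @param genome named character vector of contig sequences.
#' @param chrom contig name.
#' @param pos 1-based site position.
#' @param width flank width in bp (default 50).
#' @return list with elements `left` and `right`, each a string of exactly
#'   `width` bases.
#' @export
extract_flanks <- function(genome, chrom, pos, width = 50L) {
  stopifnot(width >= 1L, pos >= 1L)
  seq <- genome[[chrom]]
  if (is.null(seq) || is.na(seq)) {
    stop("contig not in genome: ", chrom, call. = FALSE)
  }
  n <- nchar(seq)
  if (pos <= width || pos + width > n) {
    kf_error(sprintf("site %s:%d is within %d bp of a contig end (length %d)",
                     chrom, pos, width, n),
             "flank_unavailable")
  }
  list(left = substr(seq, pos - width, pos - 1L),
       right = substr(seq, pos + 1L, pos + width))
}

#' Reverse complement of nucleotide sequences
#'
#' IUPAC ambiguity codes are complemented correctly (N<->N, R<->Y, ...).
#'
#' @param seq character vector of IUPAC nucleotide strings.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  out <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))),
    error = function(e) {
      stop("non-IUPAC character in sequence: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  unname(out)
}
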