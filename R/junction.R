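# Junction builder: patient-specific "synthetic reference" construction.
#
# The junction reference is the concatenation of the two retained flanks
# around a fusion breakpoint. It is the template on which the
# breakpoint-spanning primers and the junction-overlapping probe are placed.

#' Read a genome FASTA into a named sequence set
#'
#' @param path FASTA file path.
#' @return an uppercase [Biostrings::DNAStringSet] keyed by the first
#'   whitespace-delimited token of each header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("genome FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(read_genome(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(toupper(genome)))
  if (methods::is(genome, "DNAStringSet")) return(genome)
  stopf("genome must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Fetch a genomic segment
#'
#' @param genome a [Biostrings::DNAStringSet], named character vector of
#'   chromosome sequences, or a FASTA path.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval.
#' @param strand `"+"` for the reference strand, `"-"` for its reverse
#'   complement.
#' @return uppercase sequence string.
#' @export
#' @examples
#' fetch_segment(c(chr1 = "AAAACCCC"), "chr1", 5, 8, "-")
fetch_segment <- function(genome, chrom, start, end, strand = "+") {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome))
    stopf("unknown chromosome %s (genome has: %s)", chrom,
          paste(names(genome), collapse = ", "))
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  len <- Biostrings::width(genome[chrom])
  if (!is_count(start, 1) || !is_count(end, 1) || start > end || end > len)
    stopf("interval %s:%d-%d out of bounds (chromosome length %d)",
          chrom, start, end, len)
  s <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  if (strand == "-") s <- revcomp_chr(s)
  toupper(s)
}

# One side's contribution to the junction. `retained_side` alone determines
# both the interval and the strand-as-used: a retained flank that opposes the
# reading direction of the junction must be reverse-complemented so that the
# result is a genuine derivative-allele sequence.
side_segment <- function(genome, be, flank_len, role = c("end5", "end3")) {
  role <- match.arg(role)
  chrom_len <- Biostrings::width(genome[be$chrom])
  if (be$pos > chrom_len)
    stopf("breakend %s:%d beyond chromosome end (%d)", be$chrom, be$pos,
          chrom_len)
  if (be$retained_side == "left") {
    start <- max(1L, be$pos - flank_len + 1L); end <- be$pos
    strand <- if (role == "end5") "+" else "-"
  } else {
    start <- be$pos; end <- min(chrom_len, be$pos + flank_len - 1L)
    strand <- if (role == "end3") "+" else "-"
  }
  truncated <- (end - start + 1L) < flank_len
  list(seq = fetch_segment(genome, be$chrom, start, end, strand),
       chrom = be$chrom, start = start, end = end, strand = strand,
       truncated = truncated)
}

#' Build the patient-specific junction reference
#'
#' Joins the retained flank of each breakend into the derivative junction
#' sequence. A breakend with `retained_side = "left"` contributes the bases
#' `[pos - flank_len + 1, pos]`, one with `"right"` contributes
#' `[pos, pos + flank_len - 1]`; a flank whose retained side opposes the
#' junction reading direction (same-side breakend combinations) is
#' reverse-complemented, and the strand actually used is recorded in the
#' provenance. Flanks are truncated (not errored) at chromosome ends. With
#' `assay_orientation = "rev"` the full construction is reverse-complemented
#' and the junction offset mirrored.
#'
#' @param spec a [junction_spec()].
#' @param genome genome as accepted by [fetch_segment()].
#' @param flank_len bases to retain on each side (default 300, enough for
#'   primer and probe placement).
#' @return object of class `junction_ref` with fields `sequence`,
#'   `junction_offset` (bases contributed by the `end5` side; the junction
#'   lies between `junction_offset` and `junction_offset + 1`), `flank_len`,
#'   `assay_orientation`, `provenance` (per-side data.frame), `has_n`.
#' @export
build_junction <- function(spec, genome, flank_len = 300) {
  stopifnot(inherits(spec, "junction_spec"))
  if (!is_count(flank_len, 1)) stopf("flank_len must be an integer >= 1")
  genome <- as_genome(genome)
  for (be in list(spec$end5, spec$end3)) {
    if (!be$chrom %in% names(genome))
      stopf("breakend chromosome %s not in genome", be$chrom)
    if (!is.na(be$ref_base)) {
      g <- fetch_segment(genome, be$chrom, be$pos, be$pos, "+")
      if (g != be$ref_base)
        warnf("ref_base mismatch at %s:%d: annotated %s, genome has %s",
              be$chrom, be$pos, be$ref_base, g)
    }
  }
  s5 <- side_segment(genome, spec$end5, flank_len, "end5")
  s3 <- side_segment(genome, spec$end3, flank_len, "end3")
  seq <- paste0(s5$seq, s3$seq)
  offset <- nchar(s5$seq)
  if (spec$assay_orientation == "rev") {
    seq <- revcomp_chr(seq)
    offset <- nchar(seq) - offset
  }
  prov <- data.frame(
    side = c("end5", "end3"),
    chrom = c(s5$chrom, s3$chrom),
    start = c(s5$start, s3$start),
    end = c(s5$end, s3$end),
    strand_as_used = c(s5$strand, s3$strand),
    truncated = c(s5$truncated, s3$truncated),
    stringsAsFactors = FALSE
  )
  structure(
    list(sequence = seq, junction_offset = as.integer(offset),
         flank_len = as.integer(flank_len),
         assay_orientation = spec$assay_orientation,
         provenance = prov, has_n = grepl("N", seq, fixed = TRUE)),
    class = "junction_ref"
  )
}

#' @export
print.junction_ref <- function(x, ...) {
  cat(sprintf("<junction_ref> %d bp, junction at %d|%d (%s)%s\n",
              nchar(x$sequence), x$junction_offset, x$junction_offset + 1L,
              x$assay_orientation, if (x$has_n) " [contains N]" else ""))
  invisible(x)
}

#' Write a junction reference to FASTA
#'
#' Single-record FASTA whose header encodes the junction offset and per-side
#' provenance as `key=value` tokens; sequence wrapped at 60 columns.
#'
#' @param ref a `junction_ref` from [build_junction()].
#' @param path output path.
#' @param id record id (default `"junction"`).
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(ref, path, id = "junction") {
  stopifnot(inherits(ref, "junction_ref"))
  if (!nzchar(ref$sequence)) stopf("empty junction sequence")
  p <- ref$provenance
  tok <- function(i) sprintf("%s=%s:%d-%d(%s)%s", p$side[i], p$chrom[i],
                             p$start[i], p$end[i], p$strand_as_used[i],
                             if (p$truncated[i]) ":trunc" else "")
  header <- sprintf("%s offset=%d flank=%d orientation=%s %s %s",
                    id, ref$junction_offset, ref$flank_len,
                    ref$assay_orientation, tok(1), tok(2))
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- header
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read a junction reference written by [write_junction_fasta()]
#'
#' @param path FASTA path.
#' @return a `junction_ref` (provenance reconstructed from the header).
#' @export
read_junction_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1) stopf("expected a single-record junction FASTA")
  header <- names(x)[1]
  gv <- function(key) {
    m <- regmatches(header, regexec(paste0(key, "=([^ ]+)"), header))[[1]]
    if (length(m) < 2) stopf("junction FASTA header lacks %s=", key)
    m[2]
  }
  parse_side <- function(key) {
    v <- gv(key)
    m <- regmatches(v, regexec("^([^:]+):([0-9]+)-([0-9]+)\\(([+-])\\)(:trunc)?$",
                               v))[[1]]
    data.frame(side = key, chrom = m[2], start = as.integer(m[3]),
               end = as.integer(m[4]), strand_as_used = m[5],
               truncated = nzchar(m[6]), stringsAsFactors = FALSE)
  }
  seq <- toupper(as.character(x[[1]]))
  structure(
    list(sequence = seq, junction_offset = as.integer(gv("offset")),
         flank_len = as.integer(gv("flank")),
         assay_orientation = gv("orientation"),
         provenance = rbind(parse_side("end5"), parse_side("end3")),
         has_n = grepl("N", seq, fixed = TRUE)),
    class = "junction_ref"
  )
}
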