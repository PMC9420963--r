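# Breakend model: representation and parsing of fusion breakpoints.
#
# A translocation adjacency is described by two breakends. Each breakend is a
# (chromosome, position, retained side) triple: `retained_side` says which
# flank of the position belongs to the derivative allele. VCF encodes the
# adjacency as a mated pair of BND records; assay sheets use a bracketed
# token notation ("[chr22:29288203]G" / "T [chr11:128806738]").

#' Construct a breakend
#'
#' One side of a structural-variant adjacency: the terminal retained base of
#' a derivative chromosome.
#'
#' @param chrom chromosome name.
#' @param pos 1-based coordinate of the terminal retained base.
#' @param retained_side `"left"` if the derivative allele keeps the flank to
#'   the left of `pos` (i.e. `pos` is the rightmost retained base), `"right"`
#'   if it keeps the right flank.
#' @param ref_base optional single reference nucleotide annotated at `pos`.
#' @return an object of class `breakend`.
#' @export
#' @examples
#' breakend("chr22", 29288203, "left", "G")
breakend <- function(chrom, pos, retained_side = c("left", "right"),
                     ref_base = NA_character_) {
  retained_side <- match.arg(retained_side)
  if (!is_string(chrom)) stopf("chrom must be a single string")
  if (!is_count(pos, min = 1)) stopf("pos must be an integer >= 1, got %s",
                                     deparse(pos))
  if (!is.na(ref_base)) {
    if (!is_string(ref_base) || !grepl("^[ACGTN]$", ref_base))
      stopf("ref_base must be one of A,C,G,T,N; got %s", deparse(ref_base))
  }
  structure(
    list(chrom = chrom, pos = as.integer(pos), retained_side = retained_side,
         ref_base = ref_base),
    class = "breakend"
  )
}

#' @export
print.breakend <- function(x, ...) {
  base <- if (is.na(x$ref_base)) "" else x$ref_base
  cat(sprintf("<breakend> %s:%d (%s flank retained) %s\n",
              x$chrom, x$pos, x$retained_side, base))
  invisible(x)
}

#' Construct a junction specification
#'
#' The fusion-defining adjacency: the breakend contributing the first part of
#' the junction sequence (as read in assay orientation) and its partner.
#'
#' @param end5,end3 [breakend()] objects for the 5' and 3' segments of the
#'   junction in assay orientation.
#' @param assay_orientation `"fwd"` or `"rev"`: whether the assay reads the
#'   junction in the stored orientation or its reverse complement.
#' @param support optional supporting-read count.
#' @return an object of class `junction_spec`.
#' @export
junction_spec <- function(end5, end3, assay_orientation = c("fwd", "rev"),
                          support = NA_integer_) {
  assay_orientation <- match.arg(assay_orientation)
  if (!inherits(end5, "breakend") || !inherits(end3, "breakend"))
    stopf("end5 and end3 must be breakend objects")
  if (identical(end5$chrom, end3$chrom) && end5$pos == end3$pos)
    stopf("the two breakends of a junction cannot be the same position")
  if (!is.na(support) && !is_count(support, min = 0))
    stopf("support must be a non-negative integer")
  structure(
    list(end5 = end5, end3 = end3, assay_orientation = assay_orientation,
         support = if (is.na(support)) NA_integer_ else as.integer(support)),
    class = "junction_spec"
  )
}

#' @export
print.junction_spec <- function(x, ...) {
  cat(sprintf("<junction_spec> [%s] %s:%d(%s) :: %s:%d(%s)%s\n",
              x$assay_orientation,
              x$end5$chrom, x$end5$pos, x$end5$retained_side,
              x$end3$chrom, x$end3$pos, x$end3$retained_side,
              if (is.na(x$support)) "" else sprintf(" support=%d", x$support)))
  invisible(x)
}

#' Construct a gene locus
#'
#' Coordinates of a fusion-partner gene, used as prior knowledge when
#' selecting the fusion-defining call among structural-variant candidates.
#'
#' @param name gene symbol.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `gene_locus`.
#' @export
gene_locus <- function(name, chrom, start, end, strand = "+") {
  if (!is_string(name) || !is_string(chrom)) stopf("name/chrom must be strings")
  if (!is_count(start, 1) || !is_count(end, 1) || start > end)
    stopf("locus %s: need 1 <= start <= end", name)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  structure(
    list(name = name, chrom = chrom, start = as.integer(start),
         end = as.integer(end), strand = strand),
    class = "gene_locus"
  )
}

# -- bracketed breakpoint token notation -------------------------------------

parse_bracket_token <- function(token) {
  m <- regmatches(token, regexec(
    "^\\s*([ACGTN]?)\\s*\\[([A-Za-z0-9_.]+):([0-9]+)\\]\\s*([ACGTN]?)\\s*$",
    token))[[1]]
  if (length(m) == 0)
    stopf("malformed breakpoint token: %s", deparse(token))
  base_before <- m[2]; chrom <- m[3]; pos <- as.integer(m[4]); base_after <- m[5]
  if ((nzchar(base_before) + nzchar(base_after)) != 1L)
    stopf("breakpoint token must carry exactly one base: %s", deparse(token))
  if (nzchar(base_after)) {
    # "[c:p]B": bracket first -> left flank retained at p
    breakend(chrom, pos, "left", base_after)
  } else {
    # "B [c:p]": base first -> right flank retained
    breakend(chrom, pos, "right", base_before)
  }
}

#' Parse a bracketed breakpoint token pair into a junction specification
#'
#' Assay sheets describe each patient-specific fusion by two tokens of the
#' form `"[chrom:pos]B"` or `"B [chrom:pos]"` plus an orientation. The
#' convention implemented here: a token with the coordinate bracketed first
#' retains the left flank of the position; a token with the base before the
#' bracket retains the right flank. For `"fwd"` rows the first token is the
#' 5' partner; `"rev"` rows are stored normalized to the same biological
#' adjacency (the partner token becomes `end5`) with
#' `assay_orientation = "rev"`.
#'
#' @param token,partner_token the two breakpoint tokens (first-listed partner
#'   first, e.g. the EWSR1 token, then the FLI1 token).
#' @param orientation `"fwd"` or `"rev"`.
#' @return a [junction_spec()].
#' @export
#' @examples
#' parse_bracket_notation("[chr22:29288203]G", "T [chr11:128806738]", "fwd")
parse_bracket_notation <- function(token, partner_token, orientation) {
  if (!is_string(orientation) || !orientation %in% c("fwd", "rev"))
    stopf("orientation must be 'fwd' or 'rev', got %s", deparse(orientation))
  a <- parse_bracket_token(token)
  b <- parse_bracket_token(partner_token)
  if (orientation == "fwd") junction_spec(a, b, "fwd")
  else junction_spec(b, a, "rev")
}

format_breakend_token <- function(be) {
  if (is.na(be$ref_base))
    stopf("cannot format a breakend without ref_base to bracket notation")
  if (be$retained_side == "left")
    sprintf("[%s:%d]%s", be$chrom, be$pos, be$ref_base)
  else
    sprintf("%s [%s:%d]", be$ref_base, be$chrom, be$pos)
}

#' Format a junction specification back to bracket notation
#'
#' Inverse of [parse_bracket_notation()]: returns the two tokens in sheet
#' order (for `"rev"` specs the `end3` token is listed first).
#'
#' @param spec a [junction_spec()].
#' @return character vector of length 2.
#' @export
format_bracket_notation <- function(spec) {
  stopifnot(inherits(spec, "junction_spec"))
  t5 <- format_breakend_token(spec$end5)
  t3 <- format_breakend_token(spec$end3)
  if (spec$assay_orientation == "fwd") c(t5, t3) else c(t3, t5)
}

# -- VCF BND ALT grammar -----------------------------------------------------

# The four ALT shapes map to (local retained side, mate retained side):
#   t[p[  -> (left,  right)   piece after p joined after t
#   t]p]  -> (left,  left)    piece before p, reverse-complemented, after t
#   ]p]t  -> (right, left)    piece before p joined before t
#   [p[t  -> (right, right)   piece after p, reverse-complemented, before t

#' Interpret one VCF BND ALT allele
#'
#' Maps the four breakend ALT shapes (`t[p[`, `t]p]`, `]p]t`, `[p[t`) onto
#' retained-side assignments for the local record and its mate.
#'
#' @param chrom,pos coordinates of the local record.
#' @param alt ALT string in breakend notation.
#' @param ref optional REF base used as the local ref_base annotation.
#' @return list with elements `local` and `mate`, both [breakend()]s, or
#'   `NULL` (with a warning) when `alt` is not breakend notation.
#' @export
parse_bnd_alt <- function(chrom, pos, alt, ref = NA_character_) {
  m <- regmatches(alt, regexec(
    "^([ACGTN]*)([\\[\\]])([A-Za-z0-9_.]+):([0-9]+)([\\[\\]])([ACGTN]*)$",
    alt, perl = TRUE))[[1]]
  if (length(m) == 0 || m[3] != m[6] ||
      (nzchar(m[2]) == nzchar(m[7]))) {
    warnf("record %s:%s has non-BND ALT %s; skipped", chrom, pos, alt)
    return(NULL)
  }
  t_first <- nzchar(m[2])            # sequence precedes the bracket
  bracket <- m[3]                    # "[" points right, "]" points left
  mate_chrom <- m[4]; mate_pos <- as.integer(m[5])
  local_side <- if (t_first) "left" else "right"
  mate_side <- if (bracket == "[") "right" else "left"
  local_base <- if (t_first) substr(m[2], nchar(m[2]), nchar(m[2]))
                else substr(m[7], 1, 1)
  if (!nzchar(local_base)) local_base <- ref
  list(
    local = breakend(chrom, as.integer(pos), local_side, local_base),
    mate = breakend(mate_chrom, mate_pos, mate_side)
  )
}

bnd_pair_key <- function(a, b) {
  k <- sort(c(sprintf("%s:%d:%s", a$chrom, a$pos, a$retained_side),
              sprintf("%s:%d:%s", b$chrom, b$pos, b$retained_side)))
  paste(k, collapse = "|")
}

#' Read breakend pairs from a structural-variant VCF
#'
#' Reads a VCF 4.2 file (plain or bgzipped, e.g. an SvABA result file),
#' interprets every BND ALT, and deduplicates mated records into unique
#' adjacencies. Non-BND records are skipped with a warning. When both records
#' of a mate pair are present their retained-side assignments must mirror
#' each other, otherwise a validation error is raised.
#'
#' @param path path to the VCF file.
#' @param support_field optional INFO field with supporting-read counts
#'   (tried automatically among `SUPPORT`, `SR`, `DR` when `NULL`).
#' @return list of [junction_spec()] objects (one per unique adjacency).
#'   Orientation is stored as `"fwd"`; when the two sides differ the
#'   left-retained breakend becomes `end5`, otherwise the breakends are
#'   ordered by (chrom, pos).
#' @export
read_sv_vcf <- function(path, support_field = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) > 1)
    warnf("VCF has %d samples; only the first is used", ncol(vcf))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomicRanges::seqnames(rr))
  poss <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  info <- VariantAnnotation::info(vcf)
  if (is.null(support_field)) {
    cand <- intersect(c("SUPPORT", "SR", "DR"), colnames(info))
    support_field <- if (length(cand)) cand[1] else NA_character_
  }
  pairs <- list()
  seen <- character()
  for (i in seq_along(chroms)) {
    alt_i <- as.character(unlist(alts[i]))
    for (a in alt_i) {
      pr <- parse_bnd_alt(chroms[i], poss[i], a, ref = substr(refs[i], 1, 1))
      if (is.null(pr)) next
      key <- bnd_pair_key(pr$local, pr$mate)
      if (key %in% names(pairs)) {
        # mate record: check mirrored consistency
        prev <- pairs[[key]]
        ok <- (prev$local$chrom == pr$mate$chrom &&
               prev$local$pos == pr$mate$pos &&
               prev$local$retained_side == pr$mate$retained_side &&
               prev$mate$chrom == pr$local$chrom &&
               prev$mate$pos == pr$local$pos &&
               prev$mate$retained_side == pr$local$retained_side)
        if (!ok)
          stopf("inconsistent BND mate pair at %s:%d", chroms[i], poss[i])
        # mate carries the ref_base for the other side
        if (is.na(pairs[[key]]$mate$ref_base))
          pairs[[key]]$mate$ref_base <- pr$local$ref_base
        next
      }
      sup <- NA_integer_
      if (!is.na(support_field)) {
        v <- info[[support_field]][i]
        v <- suppressWarnings(as.integer(unlist(v)[1]))
        if (!is.na(v)) sup <- v
      }
      pairs[[key]] <- list(local = pr$local, mate = pr$mate, support = sup)
    }
  }
  lapply(unname(pairs), function(p) {
    a <- p$local; b <- p$mate
    swap <- if (a$retained_side != b$retained_side) {
      a$retained_side != "left"
    } else {
      (a$chrom > b$chrom) || (a$chrom == b$chrom && a$pos > b$pos)
    }
    if (swap) { tmp <- a; a <- b; b <- tmp }
    junction_spec(a, b, "fwd", support = p$support)
  })
}

# -- fusion-call selection ---------------------------------------------------

be_in_locus <- function(be, locus) {
  be$chrom == locus$chrom && be$pos >= locus$start && be$pos <= locus$end
}

#' Select the fusion-defining call using partner-gene prior knowledge
#'
#' Among candidate adjacencies, keeps those linking the two supplied partner
#' loci (one breakend inside each). Ties are resolved by highest read
#' support, then by smallest (position-in-locusA, position-in-locusB).
#'
#' @param calls list of [junction_spec()] candidates.
#' @param locusA,locusB [gene_locus()] objects for the two fusion partners.
#' @return the selected [junction_spec()].
#' @export
select_fusion_call <- function(calls, locusA, locusB) {
  if (!length(calls)) stopf("calls must be a nonempty list")
  stopifnot(inherits(locusA, "gene_locus"), inherits(locusB, "gene_locus"))
  hits <- Filter(function(s) {
    (be_in_locus(s$end5, locusA) && be_in_locus(s$end3, locusB)) ||
    (be_in_locus(s$end5, locusB) && be_in_locus(s$end3, locusA))
  }, calls)
  if (!length(hits))
    stopf("no fusion candidate links %s (%s:%d-%d) and %s (%s:%d-%d)",
          locusA$name, locusA$chrom, locusA$start, locusA$end,
          locusB$name, locusB$chrom, locusB$start, locusB$end)
  posA <- vapply(hits, function(s)
    if (be_in_locus(s$end5, locusA)) s$end5$pos else s$end3$pos, integer(1))
  posB <- vapply(hits, function(s)
    if (be_in_locus(s$end5, locusB)) s$end5$pos else s$end3$pos, integer(1))
  sup <- vapply(hits, function(s)
    if (is.na(s$support)) 0L else s$support, integer(1))
  ord <- order(-sup, posA, posB)
  hits[[ord[1]]]
}

# -- read support ------------------------------------------------------------

cigar_ref_width <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) return(0L)
  len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Read aligned records from a SAM file
#'
#' Converts the SAM to BAM in a temporary location and extracts the fields
#' needed for split-read counting. Unmapped records are dropped.
#'
#' @param path path to a SAM file (with `@SQ` headers).
#' @return data.frame with columns `qname`, `chrom`, `pos`, `cigar`.
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  dest <- tempfile("bt_aln_")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(paste0(dest, c(".bam", ".bam.bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar")))[[1]]
  keep <- !is.na(res$pos)
  data.frame(qname = res$qname[keep],
             chrom = as.character(res$rname[keep]),
             pos = res$pos[keep],
             cigar = res$cigar[keep],
             stringsAsFactors = FALSE)
}

#' Count clipped reads supporting a junction
#'
#' Programmatic stand-in for visual breakpoint inspection: counts aligned
#' reads whose soft/hard clip boundary falls within `window` bp of either
#' breakend position. Discordant-pair evidence is not considered.
#'
#' @param alignments data.frame with columns `chrom`, `pos`, `cigar` (e.g.
#'   from [read_sam_alignments()]).
#' @param spec a [junction_spec()].
#' @param window tolerance in bp around each breakend position (default 5).
#' @return integer count of supporting reads.
#' @export
junction_read_support <- function(alignments, spec, window = 5) {
  stopifnot(inherits(spec, "junction_spec"))
  if (!is_count(window, 0)) stopf("window must be a non-negative integer")
  if (is.null(alignments) || nrow(alignments) == 0) return(0L)
  req <- c("chrom", "pos", "cigar")
  if (!all(req %in% names(alignments)))
    stopf("alignments must have columns %s", paste(req, collapse = ", "))
  ends <- list(spec$end5, spec$end3)
  n <- 0L
  for (i in seq_len(nrow(alignments))) {
    cig <- alignments$cigar[i]
    if (is.na(cig) || !grepl("[SH]", cig)) next
    bounds <- integer(0)
    if (grepl("^[0-9]+[SH]", cig)) bounds <- c(bounds, alignments$pos[i])
    if (grepl("[0-9]+[SH]$", cig))
      bounds <- c(bounds, alignments$pos[i] + cigar_ref_width(cig) - 1L)
    hit <- any(vapply(ends, function(be) {
      be$chrom == alignments$chrom[i] && any(abs(bounds - be$pos) <= window)
    }, logical(1)))
    if (hit) n <- n + 1L
  }
  n
}

# -- gene loci I/O -----------------------------------------------------------

#' Read fusion-partner gene loci from BED or TSV
#'
#' BED files (`.bed`) are imported with rtracklayer (0-based half-open
#' converted to 1-based inclusive). Tab-separated files are accepted in two
#' layouts: `name<TAB>chrom:start-end` or
#' `name<TAB>chrom<TAB>start<TAB>end[<TAB>strand]`.
#'
#' @param path input file path.
#' @return list of [gene_locus()] objects.
#' @export
read_gene_loci <- function(path) {
  if (!file.exists(path)) stopf("loci file not found: %s", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- gr$name %||% paste0("locus", seq_along(gr))
    return(lapply(seq_along(gr), function(i) {
      st <- as.character(GenomicRanges::strand(gr[i]))
      gene_locus(nm[i], as.character(GenomicRanges::seqnames(gr[i])),
                 GenomicRanges::start(gr[i]), GenomicRanges::end(gr[i]),
                 if (st %in% c("+", "-")) st else "+")
    }))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) == 2) {
    m <- regmatches(tab[[2]], regexec("^([^:]+):([0-9]+)-([0-9]+)$", tab[[2]]))
    return(lapply(seq_len(nrow(tab)), function(i) {
      mi <- m[[i]]
      if (length(mi) == 0) stopf("malformed region string: %s", tab[[2]][i])
      gene_locus(tab[[1]][i], mi[2], as.integer(mi[3]), as.integer(mi[4]))
    }))
  }
  if (ncol(tab) >= 4) {
    return(lapply(seq_len(nrow(tab)), function(i) {
      gene_locus(tab[[1]][i], tab[[2]][i], as.integer(tab[[3]][i]),
                 as.integer(tab[[4]][i]),
                 if (ncol(tab) >= 5 && tab[[5]][i] %in% c("+", "-"))
                   tab[[5]][i] else "+")
    }))
  }
  stopf("unrecognised loci file layout: %s", path)
}
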