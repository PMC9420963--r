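# Breakpoint-spanning ddPCR assay design.
#
# Primers are selected up- and downstream of the junction; a hydrolysis probe
# (FAM fluorophore / BHQ quencher) is placed overlapping the junction with
# 2-6 of its 3' bases past the breakpoint. Candidate scoring is a simplified
# penalty model (Tm deviation, amplicon length deviation, complementarity),
# not a re-implementation of a full primer-design engine.

#' Assay design constraints
#'
#' Tunable bounds and targets for primer/probe enumeration and pair scoring.
#'
#' @param primer_len primer length bounds (bases).
#' @param primer_gc allowed primer GC fraction range.
#' @param tm_target,tm_tol primer melting-temperature target and tolerance
#'   (deg C).
#' @param max_run maximum allowed homopolymer run length.
#' @param amplicon_len amplicon length bounds (bp); default caps at 150 bp,
#'   the short-amplicon regime appropriate for fragmented cell-free DNA.
#' @param amplicon_target preferred amplicon length (bp).
#' @param probe_len probe length bounds.
#' @param probe_gc allowed probe GC fraction range.
#' @param probe_overlap allowed probe 3'-overlap past the junction (bases).
#' @param probe_tm allowed probe Tm range (probes run hotter than primers).
#' @param anneal_tiers available combined anneal/extension temperatures; the
#'   tier nearest the primer-pair mean Tm is chosen (ties toward the higher
#'   tier).
#' @param na_mM,oligo_nM Tm model conditions, see [melting_temperature()].
#' @param w_tm,w_len,w_compl penalty weights.
#' @param max_pairs_per_side candidates per side entering pairwise scoring
#'   (ranked by Tm deviation; keeps scoring deterministic and fast).
#' @return object of class `design_constraints`.
#' @export
design_constraints <- function(primer_len = c(18, 25),
                               primer_gc = c(0.30, 0.70),
                               tm_target = 59, tm_tol = 6,
                               max_run = 4,
                               amplicon_len = c(60, 150),
                               amplicon_target = 80,
                               probe_len = c(18, 30),
                               probe_gc = c(0.30, 0.80),
                               probe_overlap = c(2, 6),
                               probe_tm = c(52, 78),
                               anneal_tiers = c(55, 58),
                               na_mM = 50, oligo_nM = 250,
                               w_tm = 1, w_len = 0.05, w_compl = 0.5,
                               max_pairs_per_side = 25) {
  cn <- as.list(environment())
  for (nm in c("primer_len", "primer_gc", "amplicon_len", "probe_len",
               "probe_gc", "probe_overlap", "probe_tm")) {
    v <- cn[[nm]]
    if (!is.numeric(v) || length(v) != 2 || v[1] > v[2])
      stopf("%s must be a numeric (low, high) pair", nm)
  }
  if (cn$probe_overlap[1] < 1) stopf("probe_overlap lower bound must be >= 1")
  structure(cn, class = "design_constraints")
}

oligo <- function(sequence, strand, start, end, role, tm, gc) {
  structure(
    list(sequence = sequence, strand = strand, start = as.integer(start),
         end = as.integer(end), role = role, tm_C = tm, gc_frac = gc),
    class = "oligo"
  )
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo %s> %s [%d-%d %s] Tm=%.1f GC=%.2f\n", x$role,
              x$sequence, x$start, x$end, x$strand, x$tm_C, x$gc_frac))
  invisible(x)
}

oligo_df <- function(sequence, strand, start, end, role, tm, gc, k = NA) {
  if (length(k) == 1L) k <- rep(as.integer(k), length(sequence))
  data.frame(sequence = sequence, strand = strand, start = start, end = end,
             role = role, tm_C = tm, gc_frac = gc, k = k,
             stringsAsFactors = FALSE)
}

#' Enumerate primer candidates on one side of the junction
#'
#' Scans every window of the allowed lengths lying wholly on the requested
#' side of the junction, applying GC, Tm, homopolymer-run and N filters.
#' 5'-side candidates are reported on the `"+"` strand of the junction
#' reference, 3'-side candidates on the `"-"` strand (the reverse primer's
#' actual sequence).
#'
#' @param ref a `junction_ref`.
#' @param side `"5prime"` or `"3prime"`.
#' @param constraints a [design_constraints()].
#' @return data.frame of candidate oligos (columns `sequence`, `strand`,
#'   `start`, `end`, `role`, `tm_C`, `gc_frac`); may have zero rows.
#' @export
enumerate_primer_candidates <- function(ref, side = c("5prime", "3prime"),
                                        constraints = design_constraints()) {
  side <- match.arg(side)
  stopifnot(inherits(ref, "junction_ref"))
  cn <- constraints
  sc <- thermo_scan(ref$sequence)
  L <- nchar(ref$sequence); off <- ref$junction_offset
  out <- list()
  for (len in seq(cn$primer_len[1], cn$primer_len[2])) {
    if (side == "5prime") {
      starts <- seq_len(max(0, off - len + 1))
    } else {
      starts <- if (off + 1 > L - len + 1) integer(0) else seq(off + 1, L - len + 1)
    }
    if (!length(starts)) next
    ends <- starts + len - 1L
    keep <- !sc$window_has_n(starts, ends) & !sc$window_has_run(starts, ends)
    gc <- sc$window_gc(starts, ends)
    keep <- keep & gc >= cn$primer_gc[1] & gc <= cn$primer_gc[2]
    tm <- rep(NA_real_, length(starts))
    tm[keep] <- sc$window_tm(starts[keep], ends[keep], cn$na_mM, cn$oligo_nM)
    keep <- keep & !is.na(tm) & abs(tm - cn$tm_target) <= cn$tm_tol
    if (!any(keep)) next
    s <- starts[keep]; e <- ends[keep]
    wseq <- substring(ref$sequence, s, e)
    if (side == "5prime") {
      out[[length(out) + 1]] <-
        oligo_df(wseq, "+", s, e, "primer_fwd", tm[keep], gc[keep])
    } else {
      out[[length(out) + 1]] <-
        oligo_df(revcomp_chr(wseq), "-", s, e, "primer_rev", tm[keep], gc[keep])
    }
  }
  if (!length(out))
    return(oligo_df(character(0), character(0), integer(0), integer(0),
                    character(0), numeric(0), numeric(0))[0, ])
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Enumerate junction-overlapping hydrolysis probe candidates
#'
#' Every candidate covers the junction and has its 3' terminus exactly
#' `k` bases past the junction on its strand, for `k` in the configured
#' overlap range (default 2-6). Probes starting with G are excluded
#' (hydrolysis-probe quenching convention).
#'
#' @param ref a `junction_ref`.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param constraints a [design_constraints()].
#' @return data.frame of candidates with an extra column `k` (3' overlap).
#' @export
place_probe <- function(ref, strand = c("both", "+", "-"),
                        constraints = design_constraints()) {
  strand <- match.arg(strand)
  stopifnot(inherits(ref, "junction_ref"))
  cn <- constraints
  sc <- thermo_scan(ref$sequence)
  L <- nchar(ref$sequence); off <- ref$junction_offset
  ks <- seq(cn$probe_overlap[1], cn$probe_overlap[2])
  lens <- seq(cn$probe_len[1], cn$probe_len[2])
  out <- list()
  add <- function(s, e, str, k) {
    if (s < 1 || e > L) return()
    if (s > off || e < off + 1) return() # must cover the junction
    if (sc$window_has_n(s, e) || sc$window_has_run(s, e)) return()
    gc <- sc$window_gc(s, e)
    if (gc < cn$probe_gc[1] || gc > cn$probe_gc[2]) return()
    tm <- sc$window_tm(s, e, cn$na_mM, cn$oligo_nM)
    if (is.na(tm) || tm < cn$probe_tm[1] || tm > cn$probe_tm[2]) return()
    wseq <- substring(ref$sequence, s, e)
    if (str == "+") {
      if (substr(wseq, 1, 1) == "G") return()
      out[[length(out) + 1]] <<- oligo_df(wseq, "+", s, e, "probe", tm, gc, k)
    } else {
      pseq <- revcomp_chr(wseq)
      if (substr(pseq, 1, 1) == "G") return()
      out[[length(out) + 1]] <<- oligo_df(pseq, "-", s, e, "probe", tm, gc, k)
    }
  }
  for (k in ks) for (len in lens) {
    if (strand %in% c("both", "+")) {
      e <- off + k; s <- e - len + 1L         # 3' end k bases right of junction
      add(s, e, "+", k)
    }
    if (strand %in% c("both", "-")) {
      s <- off - k + 1L; e <- s + len - 1L    # 3' end k bases left of junction
      add(s, e, "-", k)
    }
  }
  if (!length(out))
    return(oligo_df(character(0), character(0), integer(0), integer(0),
                    character(0), numeric(0), numeric(0))[0, ])
  res <- do.call(rbind, out)
  res[order(res$k, res$strand, res$start, res$end), , drop = FALSE]
}

# Longest perfectly complementary stretch between two oligos (an annealing
# heuristic): longest common substring of a and reverse-complement(b).
compl_stretch <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(revcomp_chr(b), "")[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    match_j <- which(y == x[i])
    if (length(match_j)) {
      cur[match_j] <- prev[pmax(match_j - 1L, 1L)] + 1L
      cur[match_j[match_j == 1L]] <- 1L
      best <- max(best, max(cur))
    }
    prev <- cur
  }
  best
}

#' Design the breakpoint-spanning assay
#'
#' Selects the (forward primer, reverse primer, probe) triple minimizing
#' `w_tm * (|Tm_f - target| + |Tm_r - target|) + w_len * |len - target_len| +
#' w_compl * complementarity`, where complementarity is the longest
#' self/cross complementary stretch of the primer pair. Ties are broken by
#' leftmost forward primer, then shortest amplicon; the result is fully
#' deterministic. The annealing temperature is the configured tier nearest
#' the primer-pair mean Tm.
#'
#' @param ref a `junction_ref`.
#' @param constraints a [design_constraints()].
#' @param junction_id identifier stored in the design.
#' @return object of class `assay_design` with fields `fwd_primer`,
#'   `rev_primer`, `probe` ([print.oligo()] objects), `annealing_temp_C`,
#'   `amplicon_start`, `amplicon_end`, `penalty`, `fluorophore`, `quencher`.
#' @export
design_assay <- function(ref, constraints = design_constraints(),
                         junction_id = "junction") {
  stopifnot(inherits(ref, "junction_ref"))
  cn <- constraints
  fwd <- enumerate_primer_candidates(ref, "5prime", cn)
  if (!nrow(fwd))
    stopf("no assay: forward-primer candidate pool is empty",
          class = "bt_no_assay_error")
  rev <- enumerate_primer_candidates(ref, "3prime", cn)
  if (!nrow(rev))
    stopf("no assay: reverse-primer candidate pool is empty",
          class = "bt_no_assay_error")
  probes <- place_probe(ref, "both", cn)
  if (!nrow(probes))
    stopf("no assay: probe candidate pool is empty",
          class = "bt_no_assay_error")
  top <- function(df) {
    ord <- order(abs(df$tm_C - cn$tm_target), df$start, df$end)
    df[ord[seq_len(min(nrow(df), cn$max_pairs_per_side))], , drop = FALSE]
  }
  fwd <- top(fwd); rev <- top(rev)
  pairs <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  plen <- rev$end[pairs$r] - fwd$start[pairs$f] + 1L
  ok <- plen >= cn$amplicon_len[1] & plen <= cn$amplicon_len[2]
  if (!any(ok))
    stopf("no assay: no primer pair yields an amplicon in [%d, %d] bp",
          cn$amplicon_len[1], cn$amplicon_len[2], class = "bt_no_assay_error")
  pairs <- pairs[ok, , drop = FALSE]; plen <- plen[ok]
  self_f <- vapply(fwd$sequence, function(s) compl_stretch(s, s), integer(1))
  self_r <- vapply(rev$sequence, function(s) compl_stretch(s, s), integer(1))
  cross <- mapply(function(fi, ri)
    compl_stretch(fwd$sequence[fi], rev$sequence[ri]),
    pairs$f, pairs$r)
  compl <- cross + (self_f[pairs$f] + self_r[pairs$r]) / 2
  pen <- cn$w_tm * (abs(fwd$tm_C[pairs$f] - cn$tm_target) +
                    abs(rev$tm_C[pairs$r] - cn$tm_target)) +
         cn$w_len * abs(plen - cn$amplicon_target) +
         cn$w_compl * compl
  ord <- order(pen, fwd$start[pairs$f], plen, rev$end[pairs$r])
  best <- ord[1]
  fi <- pairs$f[best]; ri <- pairs$r[best]
  # probe: nearest Tm to (primer target + 8), then smallest overlap k,
  # "+" strand preferred, then leftmost
  probe_target <- cn$tm_target + 8
  pord <- order(abs(probes$tm_C - probe_target), probes$k,
                probes$strand != "+", probes$start)
  pi <- pord[1]
  mean_tm <- (fwd$tm_C[fi] + rev$tm_C[ri]) / 2
  tiers <- sort(cn$anneal_tiers)
  anneal <- tiers[order(abs(tiers - mean_tm), -tiers)][1]
  structure(
    list(
      junction_id = junction_id,
      fwd_primer = oligo(fwd$sequence[fi], "+", fwd$start[fi], fwd$end[fi],
                         "primer_fwd", fwd$tm_C[fi], fwd$gc_frac[fi]),
      rev_primer = oligo(rev$sequence[ri], "-", rev$start[ri], rev$end[ri],
                         "primer_rev", rev$tm_C[ri], rev$gc_frac[ri]),
      probe = {
        p <- oligo(probes$sequence[pi], probes$strand[pi], probes$start[pi],
                   probes$end[pi], "probe", probes$tm_C[pi],
                   probes$gc_frac[pi])
        p$overlap3 <- probes$k[pi]
        p
      },
      annealing_temp_C = anneal,
      amplicon_start = fwd$start[fi],
      amplicon_end = rev$end[ri],
      penalty = pen[best],
      fluorophore = "FAM", quencher = "BHQ"
    ),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay_design> %s amplicon %d-%d (%d bp) anneal %.0f C penalty %.2f\n",
              x$junction_id, x$amplicon_start, x$amplicon_end,
              x$amplicon_end - x$amplicon_start + 1L, x$annealing_temp_C,
              x$penalty))
  print(x$fwd_primer); print(x$rev_primer); print(x$probe)
  invisible(x)
}

#' In-silico PCR of an assay against a template
#'
#' Finds all primer binding sites on both strands of the template
#' (either primer may act in either role) and reports every convergent site
#' pair within the maximum product length. The 3'-terminal base of a primer
#' must always match exactly; up to `max_mismatches` are allowed elsewhere.
#'
#' @param template nucleotide string.
#' @param assay an `assay_design`.
#' @param max_mismatches non-terminal mismatches tolerated (default 0).
#' @param max_product_len longest product reported (default 1000 bp).
#' @return data.frame with columns `start`, `end`, `length`, `plus_primer`,
#'   `minus_primer` (zero rows when no product forms).
#' @export
in_silico_pcr <- function(template, assay, max_mismatches = 0,
                          max_product_len = 1000) {
  assert_dna(template, "template")
  stopifnot(inherits(assay, "assay_design"))
  if (!is_count(max_mismatches, 0)) stopf("max_mismatches must be >= 0")
  subject <- Biostrings::DNAString(template)
  primers <- c(fwd = assay$fwd_primer$sequence, rev = assay$rev_primer$sequence)
  plus_sites <- list(); minus_sites <- list()
  for (nm in names(primers)) {
    p <- primers[[nm]]
    lastb <- substr(p, nchar(p), nchar(p))
    m <- Biostrings::matchPattern(p, subject, max.mismatch = max_mismatches)
    if (length(m)) {
      e <- Biostrings::end(m); s <- Biostrings::start(m)
      keep <- substring(template, e, e) == lastb
      if (any(keep))
        plus_sites[[nm]] <- data.frame(primer = nm, start = s[keep],
                                       end = e[keep])
    }
    rc <- revcomp_chr(p)
    m2 <- Biostrings::matchPattern(rc, subject, max.mismatch = max_mismatches)
    if (length(m2)) {
      s <- Biostrings::start(m2); e <- Biostrings::end(m2)
      keep <- substring(template, s, s) == substr(rc, 1, 1)
      if (any(keep))
        minus_sites[[nm]] <- data.frame(primer = nm, start = s[keep],
                                        end = e[keep])
    }
  }
  plus <- if (length(plus_sites)) do.call(rbind, plus_sites) else NULL
  minus <- if (length(minus_sites)) do.call(rbind, minus_sites) else NULL
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), plus_primer = character(0),
                      minus_primer = character(0))
  if (is.null(plus) || is.null(minus) || !nrow(plus) || !nrow(minus))
    return(empty)
  out <- list()
  for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
    if (minus$start[j] < plus$start[i] || minus$end[j] < plus$end[i]) next
    len <- minus$end[j] - plus$start[i] + 1L
    if (len > max_product_len) next
    out[[length(out) + 1]] <- data.frame(
      start = plus$start[i], end = minus$end[j], length = len,
      plus_primer = plus$primer[i], minus_primer = minus$primer[j],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$end), , drop = FALSE]
}

#' Validate an assay design against its junction reference
#'
#' Checks every structural invariant of a breakpoint-spanning assay: primer
#' placement on either side of the junction, amplicon spanning, probe
#' junction coverage and 2-6 base 3' overlap, 5'-G exclusion, length and GC
#' bounds, and sequence identity with the reference.
#'
#' @param assay an `assay_design`.
#' @param ref the `junction_ref` it was designed on.
#' @param constraints the [design_constraints()] in force.
#' @return data.frame with columns `rule`, `pass`, `detail`; attribute
#'   `ok` is `TRUE` when all rules pass.
#' @export
validate_assay <- function(assay, ref, constraints = design_constraints()) {
  stopifnot(inherits(assay, "assay_design"), inherits(ref, "junction_ref"))
  cn <- constraints
  off <- ref$junction_offset
  f <- assay$fwd_primer; r <- assay$rev_primer; p <- assay$probe
  slice <- function(s, e) substring(ref$sequence, s, e)
  seq_of <- function(o) if (o$strand == "+") slice(o$start, o$end)
                        else revcomp_chr(slice(o$start, o$end))
  k <- if (p$strand == "+") p$end - off else off - p$start + 1L
  checks <- list(
    fwd_5prime = list(f$end <= off,
                      sprintf("fwd primer ends at %d, junction at %d|%d",
                              f$end, off, off + 1L)),
    rev_3prime = list(r$start >= off + 1L,
                      sprintf("rev primer starts at %d", r$start)),
    amplicon_spans = list(assay$amplicon_start <= off &&
                          assay$amplicon_end >= off + 1L,
                          sprintf("amplicon %d-%d", assay$amplicon_start,
                                  assay$amplicon_end)),
    amplicon_len = list({
      al <- assay$amplicon_end - assay$amplicon_start + 1L
      al >= cn$amplicon_len[1] && al <= cn$amplicon_len[2]
    }, sprintf("length %d", assay$amplicon_end - assay$amplicon_start + 1L)),
    probe_covers = list(p$start <= off && p$end >= off + 1L,
                        sprintf("probe %d-%d", p$start, p$end)),
    probe_overlap_2_6 = list(k >= cn$probe_overlap[1] &&
                             k <= cn$probe_overlap[2],
                             sprintf("3' overlap %d", k)),
    probe_no_5G = list(substr(p$sequence, 1, 1) != "G", "5' base"),
    primer_len = list(all(nchar(c(f$sequence, r$sequence)) >=
                            cn$primer_len[1] &
                          nchar(c(f$sequence, r$sequence)) <=
                            cn$primer_len[2]), "primer lengths"),
    primer_gc = list(all(c(f$gc_frac, r$gc_frac) >= cn$primer_gc[1] &
                         c(f$gc_frac, r$gc_frac) <= cn$primer_gc[2]),
                     "primer GC"),
    seq_match = list(identical(seq_of(f), f$sequence) &&
                     identical(seq_of(r), r$sequence) &&
                     identical(seq_of(p), p$sequence),
                     "oligo sequences match reference")
  )
  res <- data.frame(
    rule = names(checks),
    pass = vapply(checks, function(x) isTRUE(x[[1]]), logical(1)),
    detail = vapply(checks, function(x) x[[2]], character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "ok") <- all(res$pass)
  res
}

# -- assay sheet and thermal protocol ---------------------------------------

.sheet_cols <- c("sample", "breakpoint_a", "breakpoint_b", "primer_a",
                 "primer_b", "orientation", "probe", "annealing_temp_C")

#' Build one assay-sheet row
#'
#' @param sample sample/patient identifier.
#' @param spec the [junction_spec()] of the fusion.
#' @param assay the `assay_design`.
#' @return one-row data.frame in assay-sheet layout.
#' @export
assay_sheet_row <- function(sample, spec, assay) {
  tok <- format_bracket_notation(spec)
  data.frame(sample = sample, breakpoint_a = tok[1], breakpoint_b = tok[2],
             primer_a = assay$fwd_primer$sequence,
             primer_b = assay$rev_primer$sequence,
             orientation = spec$assay_orientation,
             probe = assay$probe$sequence,
             annealing_temp_C = as.character(assay$annealing_temp_C),
             stringsAsFactors = FALSE)
}

#' Write an assay sheet as TSV
#'
#' Tab-separated UTF-8 with a fixed header row; columns: sample, the two
#' bracketed breakpoint tokens, the two primers, orientation, probe and
#' annealing temperature. [read_assay_sheet()] followed by
#' `emit_assay_sheet()` is a byte-identical round trip.
#'
#' @param sheet data.frame with the assay-sheet columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
emit_assay_sheet <- function(sheet, path) {
  if (!is.data.frame(sheet) || nrow(sheet) == 0)
    stopf("assay sheet must be a data.frame with at least one row")
  if (!all(.sheet_cols %in% names(sheet)))
    stopf("assay sheet must have columns: %s",
          paste(.sheet_cols, collapse = ", "))
  utils::write.table(sheet[, .sheet_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read an assay sheet TSV
#'
#' @param path TSV path as written by [emit_assay_sheet()].
#' @return data.frame (all columns character).
#' @export
read_assay_sheet <- function(path) {
  if (!file.exists(path)) stopf("assay sheet not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  if (!all(.sheet_cols %in% names(df)))
    stopf("file is not an assay sheet (missing columns): %s", path)
  df
}

#' Parse the junction specifications out of an assay sheet
#'
#' @param sheet data.frame from [read_assay_sheet()].
#' @return list of [junction_spec()], one per row, named by sample.
#' @export
sheet_junction_specs <- function(sheet) {
  specs <- lapply(seq_len(nrow(sheet)), function(i)
    parse_bracket_notation(sheet$breakpoint_a[i], sheet$breakpoint_b[i],
                           sheet$orientation[i]))
  names(specs) <- sheet$sample
  specs
}

#' Bundled example assay sheet
#'
#' Six patient-specific EWSR1-FLI1 breakpoint-spanning ddPCR assays
#' (breakpoint tokens, primer pairs, junction-overlapping probes and
#' annealing temperatures) from a pediatric Ewing sarcoma ctDNA monitoring
#' setting; used as a realistic parsing/round-trip fixture.
#'
#' @return data.frame in assay-sheet layout.
#' @export
example_assay_sheet <- function() {
  read_assay_sheet(system.file("extdata", "ewsr1_fli1_assays.tsv",
                               package = "breaktracer", mustWork = TRUE))
}

#' Thermal protocol for a breakpoint-spanning ddPCR assay
#'
#' Initial denaturation 96 deg C / 10 min; 40 cycles of 94 deg C / 30 s
#' denaturation plus a combined anneal/extend step at the assay's annealing
#' temperature; droplet-stabilization step 98 deg C / 10 min; hold at
#' 4 deg C.
#'
#' @param assay an `assay_design` (or a number, the annealing temperature).
#' @param cycles cycle count (default 40).
#' @param anneal_extend_s combined anneal/extend duration in seconds.
#' @return object of class `thermal_protocol`: data.frame with columns
#'   `step`, `temp_C`, `duration_s`, `cycles` (`NA` duration = hold).
#' @export
emit_protocol <- function(assay, cycles = 40, anneal_extend_s = 60) {
  anneal <- if (inherits(assay, "assay_design")) assay$annealing_temp_C
            else as.numeric(assay)
  if (!is.finite(anneal)) stopf("invalid annealing temperature")
  if (!is_count(cycles, 1)) stopf("cycle count must be >= 1")
  structure(
    data.frame(
      step = c("initial_denaturation", "denaturation", "anneal_extend",
               "stabilization", "hold"),
      temp_C = c(96, 94, anneal, 98, 4),
      duration_s = c(600, 30, anneal_extend_s, 600, NA),
      cycles = c(1L, as.integer(cycles), as.integer(cycles), 1L, 1L),
      stringsAsFactors = FALSE
    ),
    class = c("thermal_protocol", "data.frame")
  )
}

#' Serialize a thermal protocol to JSON
#'
#' @param protocol a `thermal_protocol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(as.data.frame(protocol), path, dataframe = "rows",
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
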