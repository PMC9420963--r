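# Independent oracles used across the suite. These deliberately re-derive
# quantities through a different code path than the package implementation.

# Nearest-neighbor Tm by direct table-driven summation; the parameter table
# is re-typed here so that a typo in the package table cannot self-confirm.
oracle_tm <- function(seq, na_mM = 50, oligo_nM = 250) {
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  sH <- 0; sS <- 0
  for (i in seq_len(n - 1)) {
    din <- paste0(b[i], b[i + 1])
    if (!din %in% names(dH)) # use the complementary dinucleotide, reversed
      din <- paste0(comp[b[i + 1]], comp[b[i]])
    sH <- sH + dH[[din]]; sS <- sS + dS[[din]]
  }
  for (t in b[c(1, n)]) {
    if (t %in% c("G", "C")) { sH <- sH + 0.1; sS <- sS - 2.8 }
    else { sH <- sH + 2.3; sS <- sS + 4.1 }
  }
  sS <- sS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * sH / (sS + 1.987 * log(oligo_nM * 1e-9 / 4)) - 273.15
}

# Plain-string reverse complement without Biostrings.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# VCF BND ALT truth table, enumerated by hand from the adjacency semantics:
# the bracket points at the retained mate flank; sequence-first records keep
# their own left flank.
oracle_bnd_table <- list(
  "t[p[" = c(local = "left", mate = "right"),
  "t]p]" = c(local = "left", mate = "left"),
  "]p]t" = c(local = "right", mate = "left"),
  "[p[t" = c(local = "right", mate = "right")
)
oracle_bnd_alt <- function(shape, base, chrom, pos) {
  p <- sprintf("%s:%d", chrom, pos)
  switch(shape,
         "t[p[" = sprintf("%s[%s[", base, p),
         "t]p]" = sprintf("%s]%s]", base, p),
         "]p]t" = sprintf("]%s]%s", p, base),
         "[p[t" = sprintf("[%s[%s", p, base))
}

# Brute-force re-check of every primer-candidate constraint on the raw
# window, character by character.
oracle_primer_ok <- function(window, cn) {
  b <- strsplit(window, "")[[1]]
  if (any(!b %in% c("A", "C", "G", "T"))) return(FALSE)
  gc <- mean(b %in% c("G", "C"))
  if (gc < cn$primer_gc[1] || gc > cn$primer_gc[2]) return(FALSE)
  r <- rle(b)
  if (max(r$lengths) > cn$max_run) return(FALSE)
  tm <- oracle_tm(window, cn$na_mM, cn$oligo_nM)
  abs(tm - cn$tm_target) <= cn$tm_tol
}

# A random junction reference built directly from two random flanks (no
# package code involved).
random_junction_ref <- function(seed, flank = 300) {
  set.seed(seed)
  s5 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
              collapse = "")
  s3 <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
              collapse = "")
  structure(
    list(sequence = paste0(s5, s3), junction_offset = flank,
         flank_len = flank, assay_orientation = "fwd",
         provenance = data.frame(), has_n = FALSE),
    class = "junction_ref"
  )
}

# Minimal SAM text with the given aligned records (chrom fixed to chrA).
write_toy_sam <- function(path, pos, cigar, chrom = "chrA", chrom_len = 5000) {
  qlen <- function(cig) { # query length implied by the CIGAR
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "I", "S", "=", "X")])
  }
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(
      sprintf("r%d", i), 0, chrom, pos[i], 60, cigar[i], "*", 0, 0,
      paste(rep("A", qlen(cigar[i])), collapse = ""), "*", sep = "\t"))
  }
  writeLines(lines, path)
  path
}
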