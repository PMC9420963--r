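# Breakend model: bracket tokens, VCF BND grammar, fusion-call selection,
# split-read support.

test_that("bracket notation parses published-style token pairs", {
  # fwd row: bracket-first token keeps the left flank
  s <- parse_bracket_notation("[chr22:29288203]G", "T [chr11:128806738]",
                              "fwd")
  expect_equal(s$end5$chrom, "chr22")
  expect_equal(s$end5$pos, 29288203L)
  expect_equal(s$end5$retained_side, "left")
  expect_equal(s$end5$ref_base, "G")
  expect_equal(s$end3$chrom, "chr11")
  expect_equal(s$end3$pos, 128806738L)
  expect_equal(s$end3$retained_side, "right")
  expect_equal(s$end3$ref_base, "T")
  expect_equal(s$assay_orientation, "fwd")

  # rev row: normalized so the partner (bracket-first) token becomes end5
  r <- parse_bracket_notation("G [chr22:29289258]", "[chr11:128777239] A",
                              "rev")
  expect_equal(r$end5$chrom, "chr11")
  expect_equal(r$end5$pos, 128777239L)
  expect_equal(r$end5$retained_side, "left")
  expect_equal(r$end5$ref_base, "A")
  expect_equal(r$end3$chrom, "chr22")
  expect_equal(r$end3$retained_side, "right")
  expect_equal(r$assay_orientation, "rev")
})

test_that("malformed bracket tokens are rejected with the offending token", {
  expect_error(parse_bracket_notation("chr22:123", "T [chr11:5]", "fwd"),
               "chr22:123")
  expect_error(parse_bracket_notation("[chr22:1]G", "T [chr11:5]", "sideways"),
               "orientation")
  # zero or two bases per token
  expect_error(parse_bracket_notation("[chr22:1]", "T [chr11:5]", "fwd"),
               "exactly one base")
  expect_error(parse_bracket_notation("A[chr22:1]G", "T [chr11:5]", "fwd"),
               "exactly one base")
})

test_that("bracket notation round-trips for all sheet rows and random specs", {
  sheet <- example_assay_sheet()
  expect_equal(nrow(sheet), 6L)
  for (i in seq_len(nrow(sheet))) {
    spec <- parse_bracket_notation(sheet$breakpoint_a[i],
                                   sheet$breakpoint_b[i],
                                   sheet$orientation[i])
    tok <- format_bracket_notation(spec)
    spec2 <- parse_bracket_notation(tok[1], tok[2], spec$assay_orientation)
    expect_equal(spec2, spec, info = sheet$sample[i])
  }
  set.seed(42)
  for (i in 1:25) {
    ori <- sample(c("fwd", "rev"), 1)
    spec <- junction_spec(
      breakend("chrX", sample.int(1e6, 1), sample(c("left", "right"), 1),
               sample(c("A", "C", "G", "T"), 1)),
      breakend("chrY", sample.int(1e6, 1), sample(c("left", "right"), 1),
               sample(c("A", "C", "G", "T"), 1)),
      ori)
    tok <- format_bracket_notation(spec)
    expect_equal(parse_bracket_notation(tok[1], tok[2], ori), spec)
  }
})

test_that("the four BND ALT shapes map to the hand-enumerated truth table", {
  for (shape in names(oracle_bnd_table)) {
    alt <- oracle_bnd_alt(shape, "A", "chr11", 128806738L)
    pr <- parse_bnd_alt("chr22", 29288203L, alt)
    expect_equal(pr$local$retained_side, oracle_bnd_table[[shape]][["local"]],
                 info = shape)
    expect_equal(pr$mate$retained_side, oracle_bnd_table[[shape]][["mate"]],
                 info = shape)
    expect_equal(pr$mate$chrom, "chr11")
    expect_equal(pr$mate$pos, 128806738L)
  }
  # the four shapes give four distinct side pairs
  pairs <- vapply(names(oracle_bnd_table), function(shape) {
    pr <- parse_bnd_alt("c1", 10L, oracle_bnd_alt(shape, "A", "c2", 20L))
    paste(pr$local$retained_side, pr$mate$retained_side)
  }, character(1))
  expect_equal(length(unique(pairs)), 4L)
})

test_that("mate records parse to mirrored side pairs and deduplicate", {
  # enumerate all four adjacencies; write record + mate, expect one spec each
  for (shape in names(oracle_bnd_table)) {
    sides <- oracle_bnd_table[[shape]]
    toy <- make_toy_genome(11)
    imp <- implant_translocation(toy, 2400, 2700,
                                 retained_sides = unname(sides))
    vcf <- tempfile(fileext = ".vcf")
    writeLines(imp$vcf_lines, vcf)
    specs <- read_sv_vcf(vcf)
    expect_length(specs, 1L)
    got <- specs[[1]]
    # same unordered breakend set as the implanted truth
    key <- function(s) sort(c(
      paste(s$end5$chrom, s$end5$pos, s$end5$retained_side),
      paste(s$end3$chrom, s$end3$pos, s$end3$retained_side)))
    expect_equal(key(got), key(imp$spec), info = shape)
    expect_equal(got$support, 10L)
  }
})

test_that("non-BND records are skipped with a warning", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrA,length=5000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrA\t100\tsnv1\tA\tT\t60\tPASS\t."), vcf)
  expect_warning(specs <- read_sv_vcf(vcf), "non-BND")
  expect_length(specs, 0L)
})

test_that("select_fusion_call picks the partner-linking call by support", {
  locusA <- gene_locus("EWSR1", "chr22", 29000000, 29999999)
  locusB <- gene_locus("FLI1", "chr11", 128000000, 128999999)
  mk <- function(c1, p1, c2, p2, sup = NA) junction_spec(
    breakend(c1, p1, "left"), breakend(c2, p2, "right"), "fwd", support = sup)
  linking <- mk("chr22", 29288203, "chr11", 128806738, 7)
  calls <- list(mk("chr2", 1000, "chr3", 2000, 50),   # elsewhere
                linking,
                mk("chr22", 29288300, "chr5", 1234, 90)) # only one end inside
  # brute-force scan agrees: exactly one call has both ends in the loci
  inl <- function(be, l) be$chrom == l$chrom && be$pos >= l$start && be$pos <= l$end
  brute <- Filter(function(s) (inl(s$end5, locusA) && inl(s$end3, locusB)) ||
                              (inl(s$end5, locusB) && inl(s$end3, locusA)),
                  calls)
  expect_length(brute, 1L)
  expect_equal(select_fusion_call(calls, locusA, locusB), brute[[1]])

  # two matching calls: higher support wins; invariant under permutation
  weaker <- mk("chr22", 29288100, "chr11", 128806000, 3)
  for (perm in list(c(1, 2), c(2, 1))) {
    got <- select_fusion_call(list(weaker, linking)[perm], locusA, locusB)
    expect_equal(got, linking)
  }

  expect_error(select_fusion_call(list(mk("chr2", 1, "chr3", 2)),
                                  locusA, locusB),
               "no fusion candidate")
})

test_that("junction_read_support counts clip boundaries within the window", {
  spec <- junction_spec(breakend("chrA", 2500, "left"),
                        breakend("chrB", 2600, "right"), "fwd")
  sam <- tempfile(fileext = ".sam")
  # five reads soft-clipped exactly at end5.pos: trailing clip boundary at
  # pos + 20M - 1 = 2500 when aligned from 2481
  write_toy_sam(sam, pos = rep(2481, 5), cigar = rep("20S20M10S", 5))
  aln <- read_sam_alignments(sam)
  expect_equal(junction_read_support(aln, spec, window = 5), 5L)

  # no clipped reads -> 0
  write_toy_sam(sam, pos = rep(2481, 3), cigar = rep("30M", 3))
  expect_equal(junction_read_support(read_sam_alignments(sam), spec, 5), 0L)

  # boundary enumeration: clips at pos +/- (window + 1) are not counted,
  # clips at exactly pos +/- window are
  for (delta in c(-6, -5, 5, 6)) {
    write_toy_sam(sam, pos = 2500 + delta, cigar = "10S20M")
    n <- junction_read_support(read_sam_alignments(sam), spec, window = 5)
    expect_equal(n, as.integer(abs(delta) <= 5), info = paste("delta", delta))
  }
})

test_that("gene loci read from BED and TSV layouts agree", {
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open: 29000000-29999999 inclusive
  writeLines("chr22\t28999999\t29999999\tEWSR1", bed)
  tsv <- tempfile(fileext = ".tsv")
  writeLines("EWSR1\tchr22:29000000-29999999", tsv)
  from_bed <- read_gene_loci(bed)[[1]]
  from_tsv <- read_gene_loci(tsv)[[1]]
  expect_equal(from_bed$start, 29000000L)
  expect_equal(from_bed$end, 29999999L)
  expect_equal(from_bed[c("name", "chrom", "start", "end")],
               from_tsv[c("name", "chrom", "start", "end")])
})
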