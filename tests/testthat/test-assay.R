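# Assay design: Tm model, candidate enumeration, probe placement, pair
# scoring, in-silico PCR, validation, sheet/protocol emission.

test_that("nearest-neighbor Tm matches the table-driven summation oracle", {
  seqs <- c("ACGTACGTACGTACGTACGT", "ACCAGGAAGCAGCTGATCTT",
            "TGATGGTACTGAGGCTGTGG", "TTTAAACCACAGAGTGCGCC")
  for (s in seqs)
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-10)
  # frozen spot value (independently hand-summed at 50 mM Na+, 250 nM oligo)
  expect_equal(melting_temperature("ACGTACGTACGTACGTACGT"), 55.22196,
               tolerance = 1e-5)
  # GC monotonicity at equal length
  expect_lt(melting_temperature("AAAAAAAAAAAA"),
            melting_temperature("GCGCGCGCGCGC"))
  # varied salt/oligo conditions still match the oracle
  expect_equal(melting_temperature("ACCAGGAAGCAGCTGATCTT", 100, 900),
               oracle_tm("ACCAGGAAGCAGCTGATCTT", 100, 900),
               tolerance = 1e-10)
  expect_error(melting_temperature("ACGT"), "too short")
  expect_error(melting_temperature("ACGTNACGTNAC"), "A,C,G,T")
})

test_that("primer candidates pass an exhaustive brute-force constraint check", {
  cn <- design_constraints()
  ref <- random_junction_ref(101)
  for (side in c("5prime", "3prime")) {
    cands <- enumerate_primer_candidates(ref, side, cn)
    expect_gt(nrow(cands), 0)
    for (i in seq_len(nrow(cands))) {
      window <- substr(ref$sequence, cands$start[i], cands$end[i])
      expect_true(oracle_primer_ok(window, cn),
                  info = sprintf("%s %d-%d", side, cands$start[i],
                                 cands$end[i]))
      if (side == "5prime") {
        expect_lte(cands$end[i], ref$junction_offset)
        expect_equal(cands$sequence[i], window)
        expect_equal(cands$strand[i], "+")
      } else {
        expect_gte(cands$start[i], ref$junction_offset + 1L)
        expect_equal(cands$sequence[i], oracle_revcomp(window))
        expect_equal(cands$strand[i], "-")
      }
    }
    # completeness: every brute-force-passing window on the correct side is
    # in the candidate list
    for (len in cn$primer_len[1]:cn$primer_len[2]) {
      starts <- if (side == "5prime") seq_len(ref$junction_offset - len + 1)
                else seq(ref$junction_offset + 1,
                         nchar(ref$sequence) - len + 1)
      nok <- sum(vapply(starts, function(s)
        oracle_primer_ok(substr(ref$sequence, s, s + len - 1), cn),
        logical(1)))
      expect_equal(sum(cands$end - cands$start + 1 == len), nok,
                   info = paste(side, "len", len))
    }
  }
})

test_that("degenerate flanks yield empty candidate pools", {
  allA <- structure(
    list(sequence = paste(rep("A", 600), collapse = ""),
         junction_offset = 300L, flank_len = 300L,
         assay_orientation = "fwd", provenance = data.frame(), has_n = FALSE),
    class = "junction_ref")
  expect_equal(nrow(enumerate_primer_candidates(allA, "5prime")), 0L)
  expect_equal(nrow(place_probe(allA)), 0L)
})

test_that("probe placement honours the 2-6 base 3' overlap geometry", {
  cn <- design_constraints()
  ref <- random_junction_ref(202)
  probes <- place_probe(ref, "both", cn)
  expect_gt(nrow(probes), 0)
  expect_true(all(probes$k %in% 2:6))
  expect_true(all(substr(probes$sequence, 1, 1) != "G"))
  off <- ref$junction_offset
  plus <- probes[probes$strand == "+", ]
  minus <- probes[probes$strand == "-", ]
  # geometry: 3' terminus exactly k bases past the junction on each strand,
  # and the probe covers the junction
  expect_true(all(plus$end == off + plus$k))
  expect_true(all(plus$start <= off))
  expect_true(all(minus$start == off - minus$k + 1L))
  expect_true(all(minus$end >= off + 1L))
  # exhaustive enumeration oracle: candidate count per (k, strand, length)
  # is 0 or 1 by construction, and every k in range appears somewhere on an
  # unconstrained junction
  expect_true(all(2:6 %in% probes$k))
  expect_lte(max(table(paste(probes$k, probes$strand,
                             nchar(probes$sequence)))), 1L)
  # infeasible geometry: probe cannot fit when the junction sits at offset 1
  tiny <- ref; tiny$junction_offset <- 1L
  expect_equal(nrow(place_probe(tiny, "+", cn)), 0L)
})

test_that("design_assay output is valid, deterministic, and tie-stable", {
  ref <- random_junction_ref(303)
  a1 <- design_assay(ref)
  a2 <- design_assay(ref)
  expect_equal(a1, a2)
  v <- validate_assay(a1, ref)
  expect_true(attr(v, "ok"))
  # annealing temperature comes from the configured tiers
  expect_true(a1$annealing_temp_C %in% c(55, 58))
  # junction with an all-N flank cannot be designed against
  nref <- ref
  nref$sequence <- paste0(paste(rep("N", 300), collapse = ""),
                          substr(ref$sequence, 301, 600))
  expect_error(design_assay(nref), class = "bt_no_assay_error")
})

test_that("validate_assay fails on mutated designs", {
  ref <- random_junction_ref(404)
  assay <- design_assay(ref)
  # probe shifted 5 bases toward 3': overlap rule (and sequence match) fail
  shifted <- assay
  shifted$probe$start <- shifted$probe$start + 5L
  shifted$probe$end <- shifted$probe$end + 5L
  v <- validate_assay(shifted, ref)
  expect_false(attr(v, "ok"))
  expect_false(v$pass[v$rule == "probe_overlap_2_6"])
  # primers swapped: side rules fail
  swapped <- assay
  swapped$fwd_primer <- assay$rev_primer
  swapped$rev_primer <- assay$fwd_primer
  v2 <- validate_assay(swapped, ref)
  expect_false(v2$pass[v2$rule == "fwd_5prime"])
  expect_false(v2$pass[v2$rule == "rev_3prime"])
})

test_that("in-silico PCR finds exactly the designed product on the junction", {
  ref <- random_junction_ref(505)
  assay <- design_assay(ref)
  prod <- in_silico_pcr(ref$sequence, assay)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$length,
               assay$amplicon_end - assay$amplicon_start + 1L)
  expect_equal(prod$start, assay$amplicon_start)
  expect_equal(prod$end, assay$amplicon_end)
  # direct string-search oracle: the primer and the reverse complement of
  # the reverse primer occur exactly once each
  expect_equal(
    length(gregexpr(assay$fwd_primer$sequence, ref$sequence,
                    fixed = TRUE)[[1]]), 1L)
  expect_equal(
    length(gregexpr(oracle_revcomp(assay$rev_primer$sequence), ref$sequence,
                    fixed = TRUE)[[1]]), 1L)
  # template lacking both primers
  expect_equal(nrow(in_silico_pcr(paste(rep("ACGT", 100), collapse = ""),
                                  assay)), 0L)
})

test_that("in-silico PCR respects the 3'-anchor under mismatches", {
  ref <- random_junction_ref(606)
  assay <- design_assay(ref)
  f <- assay$fwd_primer$sequence
  # mutate the template base under the fwd primer's 3' terminus
  tpl <- ref$sequence
  e <- assay$fwd_primer$end
  old <- substr(tpl, e, e)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(tpl, e, e) <- new
  expect_equal(nrow(in_silico_pcr(tpl, assay, max_mismatches = 0)), 0L)
  # even with a mismatch budget, a 3'-terminal mismatch kills the site
  expect_equal(nrow(in_silico_pcr(tpl, assay, max_mismatches = 1)), 0L)
  # one non-terminal mismatch is tolerated when allowed
  tpl2 <- ref$sequence
  m <- assay$fwd_primer$start + 2L
  old2 <- substr(tpl2, m, m)
  substr(tpl2, m, m) <- setdiff(c("A", "C", "G", "T"), old2)[1]
  expect_equal(nrow(in_silico_pcr(tpl2, assay, max_mismatches = 0)), 0L)
  expect_equal(nrow(in_silico_pcr(tpl2, assay, max_mismatches = 1)), 1L)
})

test_that("assay sheet round-trips byte-identically and specs parse", {
  src <- system.file("extdata", "ewsr1_fli1_assays.tsv",
                     package = "breaktracer")
  sheet <- read_assay_sheet(src)
  out <- tempfile(fileext = ".tsv")
  emit_assay_sheet(sheet, out)
  expect_identical(readLines(out), readLines(src))
  specs <- sheet_junction_specs(sheet)
  expect_length(specs, 6L)
  expect_equal(vapply(specs, function(s) s$assay_orientation, ""),
               c(S1 = "fwd", S97 = "fwd", S69 = "rev", S121 = "rev",
                 S101 = "rev", S70 = "rev"))
  # every stored breakpoint involves chr22 and chr11
  for (s in specs)
    expect_setequal(c(s$end5$chrom, s$end3$chrom), c("chr22", "chr11"))
  expect_error(emit_assay_sheet(sheet[0, ], out), "at least one row")
})

test_that("thermal protocol encodes the two-step cycling profile", {
  prot <- emit_protocol(58)
  expect_s3_class(prot, "thermal_protocol")
  expect_equal(prot$temp_C[prot$step == "initial_denaturation"], 96)
  expect_equal(prot$duration_s[prot$step == "initial_denaturation"], 600)
  expect_equal(prot$cycles[prot$step == "denaturation"], 40L)
  expect_equal(prot$temp_C[prot$step == "anneal_extend"], 58)
  expect_equal(prot$temp_C[prot$step == "stabilization"], 98)
  expect_true(is.na(prot$duration_s[prot$step == "hold"]))
  p <- tempfile(fileext = ".json")
  write_protocol_json(prot, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$temp_C, prot$temp_C)
})
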