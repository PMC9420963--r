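# Synthetic data with known ground truth.
#
# Everything the pipeline consumes can be generated here: toy two-chromosome
# genomes carrying one reciprocal-translocation-derived junction (plus the
# truth VCF), droplet wells at known concentrations with two-population
# fluorescence and rain, and whole patient courses mimicking the observed
# clinical trajectories (responder / recurrence / progression) within the
# 6-4,000 copies/mL dynamic range. Every generator is a pure function of
# (parameters, seed).

#' Generate a toy genome with two fusion-partner gene loci
#'
#' Uniform-random ACGT chromosomes with one disjoint "gene" locus per
#' chromosome (the middle 40% of each), deterministic per seed.
#'
#' @param seed RNG seed.
#' @param chrom_lengths named integer vector of chromosome lengths (>= 2 kb
#'   each); default two 5 kb chromosomes `chrA`, `chrB`.
#' @param gene_names names of the two partner loci.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `loci` (list of
#'   two [gene_locus()]), `seed`.
#' @export
make_toy_genome <- function(seed, chrom_lengths = c(chrA = 5000, chrB = 5000),
                            gene_names = c("EWSR1", "FLI1")) {
  if (length(chrom_lengths) < 2) stopf("need at least two chromosomes")
  if (any(chrom_lengths < 2000))
    stopf("chromosome lengths must be >= 2 kb (got %s)",
          paste(chrom_lengths, collapse = ", "))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", LETTERS[seq_along(chrom_lengths)])
  with_seed(seed, {
    seqs <- vapply(chrom_lengths, function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    loci <- lapply(1:2, function(i) {
      n <- chrom_lengths[i]
      gene_locus(gene_names[i], names(chrom_lengths)[i],
                 start = as.integer(floor(n * 0.3)),
                 end = as.integer(floor(n * 0.7)))
    })
    list(genome = genome, loci = loci, seed = seed)
  })
}

derivative_fragment5 <- function(chrom_seq, pos, side) {
  if (side == "left") substr(chrom_seq, 1, pos)
  else revcomp_chr(substr(chrom_seq, pos, nchar(chrom_seq)))
}

derivative_fragment3 <- function(chrom_seq, pos, side) {
  if (side == "right") substr(chrom_seq, pos, nchar(chrom_seq))
  else revcomp_chr(substr(chrom_seq, 1, pos))
}

bnd_alt_string <- function(local_side, mate_side, mate_chrom, mate_pos, base) {
  p <- sprintf("%s:%d", mate_chrom, mate_pos)
  if (local_side == "left" && mate_side == "right") sprintf("%s[%s[", base, p)
  else if (local_side == "left" && mate_side == "left") sprintf("%s]%s]", base, p)
  else if (local_side == "right" && mate_side == "left") sprintf("]%s]%s", p, base)
  else sprintf("[%s[%s", p, base)
}

#' Implant a translocation into a toy genome
#'
#' Builds the derivative sequence by direct string concatenation (an
#' independent oracle for the junction builder), the truth
#' [junction_spec()], and a standard-notation truth VCF with the mated BND
#' record pair.
#'
#' @param genome list from [make_toy_genome()] or a
#'   [Biostrings::DNAStringSet] with at least two chromosomes.
#' @param posA,posB breakend positions on the first/second chromosome.
#' @param retained_sides length-2 character: retained side on chromosome A
#'   and B (any of the four combinations).
#' @param vcf_path optional path; when given the truth VCF is written there.
#' @param support supporting-read count recorded in the truth VCF INFO.
#' @return list with `derivative` (string), `spec` (truth junction),
#'   `junction_pos` (last base of the 5' fragment within `derivative`),
#'   `vcf_lines` (character vector), `vcf_path`.
#' @export
implant_translocation <- function(genome, posA, posB,
                                  retained_sides = c("left", "right"),
                                  vcf_path = NULL, support = 10) {
  g <- if (is.list(genome) && !is.null(genome$genome)) genome$genome
       else as_genome(genome)
  if (length(g) < 2) stopf("genome must have at least two chromosomes")
  chrA <- names(g)[1]; chrB <- names(g)[2]
  seqA <- as.character(g[[chrA]]); seqB <- as.character(g[[chrB]])
  if (!is_count(posA, 1) || posA > nchar(seqA) ||
      !is_count(posB, 1) || posB > nchar(seqB))
    stopf("breakend positions outside chromosomes")
  if (length(retained_sides) != 2 ||
      !all(retained_sides %in% c("left", "right")))
    stopf("retained_sides must be two of 'left'/'right'")
  sideA <- retained_sides[1]; sideB <- retained_sides[2]
  frag5 <- derivative_fragment5(seqA, posA, sideA)
  frag3 <- derivative_fragment3(seqB, posB, sideB)
  derivative <- paste0(frag5, frag3)
  spec <- junction_spec(
    breakend(chrA, posA, sideA, substr(seqA, posA, posA)),
    breakend(chrB, posB, sideB, substr(seqB, posB, posB)),
    "fwd", support = support
  )
  baseA <- substr(seqA, posA, posA); baseB <- substr(seqB, posB, posB)
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrA, nchar(seqA)),
    sprintf("##contig=<ID=%s,length=%d>", chrB, nchar(seqB)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate record id\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    paste(c(chrA, posA, "bnd_1", baseA,
            bnd_alt_string(sideA, sideB, chrB, posB, baseA), "60", "PASS",
            sprintf("SVTYPE=BND;MATEID=bnd_2;SUPPORT=%d", support)),
          collapse = "\t"),
    paste(c(chrB, posB, "bnd_2", baseB,
            bnd_alt_string(sideB, sideA, chrA, posA, baseB), "60", "PASS",
            sprintf("SVTYPE=BND;MATEID=bnd_1;SUPPORT=%d", support)),
          collapse = "\t")
  )
  if (!is.null(vcf_path)) writeLines(vcf_lines, vcf_path)
  list(derivative = derivative, spec = spec,
       junction_pos = nchar(frag5), vcf_lines = vcf_lines,
       vcf_path = vcf_path)
}

#' Simulate one well of droplet fluorescence
#'
#' Each droplet is positive with probability `1 - exp(-true_lambda)`;
#' positives and negatives are drawn from two normal fluorescence
#' populations, and a configurable fraction of droplets is replaced by
#' uniform "rain" between the population means.
#'
#' @param true_lambda mean target molecules per droplet (>= 0).
#' @param n_droplets number of droplets (>= 100).
#' @param fluor_params list with `neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`
#'   (defaults 2000/100 and 8000/200).
#' @param rain_frac fraction of droplets turned into rain (default 0.005).
#' @param seed RNG seed.
#' @return data.frame with columns `fluorescence` and `true_positive`;
#'   attributes `true_lambda`, `overlap_warning`.
#' @export
simulate_droplets <- function(true_lambda, n_droplets = 20000,
                              fluor_params = list(neg_mean = 2000,
                                                  neg_sd = 100,
                                                  pos_mean = 8000,
                                                  pos_sd = 200),
                              rain_frac = 0.005, seed = 1) {
  if (!is.numeric(true_lambda) || true_lambda < 0)
    stopf("true_lambda must be >= 0")
  if (!is_count(n_droplets, 100)) stopf("need at least 100 droplets")
  if (rain_frac < 0 || rain_frac >= 1) stopf("rain_frac must be in [0, 1)")
  fp <- fluor_params
  overlap <- (fp$pos_mean - fp$neg_mean) < 2 * (fp$neg_sd + fp$pos_sd)
  if (overlap) warnf("fluorescence populations overlap (means within 2 SDs)")
  with_seed(seed, {
    pos <- stats::rbinom(n_droplets, 1, 1 - exp(-true_lambda)) == 1
    fl <- numeric(n_droplets)
    fl[!pos] <- stats::rnorm(sum(!pos), fp$neg_mean, fp$neg_sd)
    fl[pos] <- stats::rnorm(sum(pos), fp$pos_mean, fp$pos_sd)
    n_rain <- round(rain_frac * n_droplets)
    rain_idx <- if (n_rain > 0) sample.int(n_droplets, n_rain) else integer(0)
    if (n_rain > 0)
      fl[rain_idx] <- stats::runif(n_rain, fp$neg_mean, fp$pos_mean)
    out <- data.frame(fluorescence = fl, true_positive = pos)
    attr(out, "true_lambda") <- true_lambda
    attr(out, "overlap_warning") <- overlap
    attr(out, "rain_idx") <- rain_idx
    out
  })
}

# copies/mL plasma -> expected targets per droplet under the volume chain
cpm_to_lambda <- function(copies_per_mL, volumes) {
  conc <- copies_per_mL * volumes$plasma_volume_mL /
    (volumes$reaction_volume_uL *
     (volumes$eluate_volume_uL / volumes$template_per_well_uL))
  conc * volumes$droplet_volume_nL * 1e-3
}

.course_templates <- list(
  # baseline positivity clearing under therapy and staying negative
  responder = list(copies_per_mL = c(12.4, 0, 0, 0, 0, 0),
                   response_at = 2L, recurrence_at = NA_integer_,
                   rising_at = NA_integer_),
  # response followed by molecular recurrence at the last draw
  recurrence = list(copies_per_mL = c(1731, 0, 0, 0, 0, 620),
                    response_at = 2L, recurrence_at = 6L,
                    rising_at = NA_integer_),
  # steadily increasing burden despite treatment
  progression = list(copies_per_mL = c(22, 92, 221, 620, 1623, 4000),
                     response_at = NA_integer_, recurrence_at = NA_integer_,
                     rising_at = 3L)
)

#' Simulate a whole patient course
#'
#' Generates per-timepoint droplet wells (fusion assay in duplicate, a
#' reference genome-equivalents assay in duplicate, plus NTC, positive
#' control and healthy-donor companion wells per timepoint) following one of
#' three trajectory templates, and records the ground truth (true copies/mL,
#' per-well lambda, transition indices).
#'
#' @param profile `"responder"`, `"recurrence"` or `"progression"`.
#' @param volumes a [volumes_config()].
#' @param seed RNG seed.
#' @param patient patient identifier.
#' @param n_droplets droplets per well.
#' @param n_replicates replicate wells per assay (default 2, matching
#'   duplicate ddPCR practice).
#' @param reference_copies_per_mL genome-equivalents level (default 10,000
#'   copies/mL plasma, a typical cfDNA yield).
#' @param format `"counts"` emits counts-dialect wells (fast);
#'   `"fluorescence"` emits per-droplet values.
#' @param fluor_params,rain_frac see [simulate_droplets()].
#' @return list with `wells` (list of [droplet_well()] grouped by timepoint
#'   in `timepoint_wells`), `metadata` (data.frame sample/patient/date),
#'   `truth` (list: `copies_per_mL`, `lambda_per_well`, `response_at`,
#'   `recurrence_at`, `rising_at`, `seed`, `profile`).
#' @export
simulate_patient_course <- function(profile = c("responder", "recurrence",
                                                "progression"),
                                    volumes = volumes_config(), seed = 1,
                                    patient = "P1", n_droplets = 20000,
                                    n_replicates = 2,
                                    reference_copies_per_mL = 10000,
                                    format = c("counts", "fluorescence"),
                                    fluor_params = list(neg_mean = 2000,
                                                        neg_sd = 100,
                                                        pos_mean = 8000,
                                                        pos_sd = 200),
                                    rain_frac = 0.005) {
  if (!is_string(profile[1]) || !profile[1] %in% names(.course_templates))
    stopf("unknown profile %s (use %s)", deparse(profile[1]),
          paste(names(.course_templates), collapse = "/"))
  profile <- profile[1]
  format <- match.arg(format)
  tmpl <- .course_templates[[profile]]
  cpm <- tmpl$copies_per_mL
  if (length(cpm) < 4) stopf("course template needs >= 4 timepoints")
  dates <- as.Date("2020-01-01") + c(0, 60, 120, 180, 270, 360)[seq_along(cpm)]
  lam_fus <- cpm_to_lambda(cpm, volumes)
  lam_ref <- cpm_to_lambda(reference_copies_per_mL, volumes)
  lam_pc <- 0.5  # highly diluted but safely positive control
  with_seed(seed, {
    timepoint_wells <- vector("list", length(cpm))
    lambda_per_well <- list()
    for (t in seq_along(cpm)) {
      sample_id <- sprintf("%s_t%02d", patient, t)
      mk <- function(well, assay, role, lambda) {
        if (format == "counts") {
          k <- stats::rbinom(1, n_droplets, 1 - exp(-lambda))
          droplet_well(well, sample_id, assay, role,
                       n_total = n_droplets, n_positive = k)
        } else {
          sim <- simulate_droplets(lambda, n_droplets, fluor_params,
                                   rain_frac,
                                   seed = sample.int(.Machine$integer.max, 1))
          droplet_well(well, sample_id, assay, role,
                       fluorescence = sim$fluorescence)
        }
      }
      wells <- list()
      for (r in seq_len(n_replicates)) {
        wells[[length(wells) + 1]] <-
          mk(sprintf("%s_fus_%d", sample_id, r), "fusion", "sample",
             lam_fus[t])
        wells[[length(wells) + 1]] <-
          mk(sprintf("%s_ref_%d", sample_id, r), "reference", "sample",
             lam_ref)
      }
      wells[[length(wells) + 1]] <-
        mk(sprintf("%s_ntc", sample_id), "fusion", "NTC", 0)
      wells[[length(wells) + 1]] <-
        mk(sprintf("%s_pc", sample_id), "fusion", "positive_control", lam_pc)
      wells[[length(wells) + 1]] <-
        mk(sprintf("%s_hd", sample_id), "fusion", "healthy_donor", 0)
      timepoint_wells[[t]] <- wells
      lambda_per_well[[sample_id]] <-
        c(fusion = lam_fus[t], reference = lam_ref)
    }
    list(
      wells = unlist(timepoint_wells, recursive = FALSE),
      timepoint_wells = timepoint_wells,
      metadata = data.frame(
        sample = sprintf("%s_t%02d", patient, seq_along(cpm)),
        patient = patient, date = dates,
        plasma_mL = volumes$plasma_volume_mL,
        stringsAsFactors = FALSE),
      truth = list(profile = profile, copies_per_mL = cpm,
                   lambda_per_well = lambda_per_well,
                   response_at = tmpl$response_at,
                   recurrence_at = tmpl$recurrence_at,
                   rising_at = tmpl$rising_at, seed = seed)
    )
  })
}

#' Quantify and track a simulated course end-to-end
#'
#' Convenience wrapper: quantifies each timepoint of a
#' [simulate_patient_course()] output (pooling duplicates, using that
#' timepoint's run controls), builds the patient series and calls status.
#'
#' @param course output of [simulate_patient_course()].
#' @param volumes the [volumes_config()] used for the simulation.
#' @param min_droplets,min_positives QC/detectability constants.
#' @return list with `series` (a `patient_series`), `status` (calls),
#'   `called` (list with `response_at`, `recurrence_at`, `rising_at`).
#' @export
track_simulated_course <- function(course, volumes = volumes_config(),
                                   min_droplets = 12000, min_positives = 2) {
  rows <- list()
  for (t in seq_along(course$timepoint_wells)) {
    wells <- course$timepoint_wells[[t]]
    roles <- vapply(wells, `[[`, "", "role")
    assays <- vapply(wells, `[[`, "", "assay")
    q <- quantify_sample(
      fusion_wells = wells[roles == "sample" & assays == "fusion"],
      reference_wells = wells[roles == "sample" & assays == "reference"],
      run_controls = wells[roles != "sample"],
      volumes = volumes, min_droplets = min_droplets,
      min_positives = min_positives
    )
    rows[[t]] <- time_point(course$metadata$patient[t],
                            course$metadata$date[t], q)
  }
  series <- build_series(do.call(rbind, rows))
  status <- call_status(series)
  first_at <- function(s) {
    w <- which(status == s)
    if (length(w)) w[1] else NA_integer_
  }
  list(series = series, status = status,
       called = list(response_at = first_at("molecular_response"),
                     recurrence_at = first_at("molecular_recurrence"),
                     rising_at = first_at("rising")))
}
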