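# Droplet digital PCR quantification.
#
# Each droplet is an independent partition; with lambda target molecules per
# droplet on average, the fraction of positive droplets is p = 1 - exp(-lambda),
# so lambda = -ln(1 - p). Concentration in the reaction follows from the
# droplet volume, and the copies-per-millilitre-plasma chain follows from the
# reaction/template/eluate/plasma volume factors.

#' Volume configuration for the copies/mL chain
#'
#' @param droplet_volume_nL droplet partition volume (default 0.85 nL, the
#'   QX200 convention).
#' @param reaction_volume_uL ddPCR reaction volume per well.
#' @param template_per_well_uL eluate volume loaded per well.
#' @param eluate_volume_uL total cfDNA eluate volume.
#' @param plasma_volume_mL plasma volume extracted (typically 1-2 mL).
#' @return object of class `volumes_config`.
#' @export
volumes_config <- function(droplet_volume_nL = 0.85,
                           reaction_volume_uL = 20,
                           template_per_well_uL = 5,
                           eluate_volume_uL = 50,
                           plasma_volume_mL = 2) {
  v <- as.list(environment())
  bad <- names(v)[!vapply(v, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) stopf("volumes must be positive numbers: %s",
                         paste(bad, collapse = ", "))
  structure(v, class = "volumes_config")
}

#' Construct a droplet well record
#'
#' Either per-droplet fluorescence values (one channel) or summary counts.
#'
#' @param well well identifier.
#' @param sample sample identifier.
#' @param assay assay identifier (e.g. `"fusion"` or the reference
#'   genome-equivalents assay `"chr2p14"`).
#' @param role `"sample"`, `"NTC"`, `"positive_control"` or
#'   `"healthy_donor"`.
#' @param n_total,n_positive summary counts (counts dialect).
#' @param fluorescence numeric vector of per-droplet values (fluorescence
#'   dialect).
#' @return object of class `droplet_well`.
#' @export
droplet_well <- function(well, sample, assay,
                         role = c("sample", "NTC", "positive_control",
                                  "healthy_donor"),
                         n_total = NULL, n_positive = NULL,
                         fluorescence = NULL) {
  role <- match.arg(role)
  has_counts <- !is.null(n_total)
  has_fluor <- !is.null(fluorescence)
  if (!has_counts && !has_fluor)
    stopf("well %s needs counts or fluorescence", well)
  if (has_counts) {
    if (is.null(n_positive)) stopf("n_positive missing for well %s", well)
    if (!is_count(n_total, 1) || !is_count(n_positive, 0) ||
        n_positive > n_total)
      stopf("well %s: need 0 <= n_positive <= n_total", well)
  }
  if (has_fluor && any(!is.finite(fluorescence)))
    stopf("well %s: fluorescence values must be finite", well)
  structure(
    list(well = well, sample = sample, assay = assay, role = role,
         n_total = if (has_counts) as.integer(n_total) else NULL,
         n_positive = if (has_counts) as.integer(n_positive) else NULL,
         fluorescence = fluorescence),
    class = "droplet_well"
  )
}

#' Classify droplets by fluorescence threshold
#'
#' With an explicit threshold, counts values strictly above it. Otherwise the
#' threshold is the midpoint of the two cluster means of the optimal
#' two-class 1-D split (the split minimizing within-class variance over all
#' cut points), which is deterministic.
#'
#' @param fluorescence numeric vector (at least 100 droplets).
#' @param threshold optional explicit threshold.
#' @return list with `n_total`, `n_positive`, `threshold_used`.
#' @export
classify_droplets <- function(fluorescence, threshold = NULL) {
  if (!is.numeric(fluorescence) || length(fluorescence) < 100)
    stopf("need at least 100 droplets to classify (got %d)",
          length(fluorescence))
  if (any(!is.finite(fluorescence))) stopf("fluorescence must be finite")
  n <- length(fluorescence)
  if (is.null(threshold)) {
    x <- sort(fluorescence)
    if (x[1] == x[n])
      stopf("cannot classify: all fluorescence values identical")
    cs <- cumsum(x)
    i <- seq_len(n - 1)
    m1 <- cs[i] / i
    m2 <- (cs[n] - cs[i]) / (n - i)
    # maximizing the between-class term i*(n-i)*(m1-m2)^2 is equivalent to
    # minimizing total within-class variance
    between <- i * (n - i) * (m1 - m2)^2
    best <- which.max(between)
    threshold <- (m1[best] + m2[best]) / 2
  }
  list(n_total = n, n_positive = sum(fluorescence > threshold),
       threshold_used = threshold)
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Poisson-corrected concentration from droplet counts
#'
#' `p = n_positive / n_total`; `lambda = -ln(1 - p)` targets per droplet;
#' concentration is `lambda / droplet_volume` in copies/uL of reaction. The
#' 95% CI is a Wilson score interval on `p` transformed through
#' `-ln(1 - .)` (chosen for its sane zero-count behaviour).
#'
#' @param n_positive,n_total droplet counts.
#' @param volumes a [volumes_config()].
#' @return list with `lambda`, `conc_copies_per_uL`, `ci95` (copies/uL),
#'   `ci95_lambda`, `saturated`. A fully positive well returns `Inf`
#'   concentration with `saturated = TRUE` rather than an error.
#' @export
#' @examples
#' poisson_concentration(1000, 20000)
poisson_concentration <- function(n_positive, n_total,
                                  volumes = volumes_config()) {
  if (!is_count(n_total, 1)) stopf("n_total must be an integer >= 1")
  if (!is_count(n_positive, 0) || n_positive > n_total)
    stopf("need 0 <= n_positive <= n_total")
  stopifnot(inherits(volumes, "volumes_config"))
  vol_uL <- volumes$droplet_volume_nL * 1e-3
  if (n_positive == n_total) {
    ci_p <- wilson_interval(n_positive, n_total)
    return(list(lambda = Inf, conc_copies_per_uL = Inf,
                ci95 = c(low = -log1p(-ci_p[["low"]]) / vol_uL, high = Inf),
                ci95_lambda = c(low = -log1p(-ci_p[["low"]]), high = Inf),
                saturated = TRUE))
  }
  p <- n_positive / n_total
  lambda <- -log1p(-p)
  ci_p <- wilson_interval(n_positive, n_total)
  ci_lambda <- c(low = -log1p(-ci_p[["low"]]), high = -log1p(-ci_p[["high"]]))
  list(lambda = lambda, conc_copies_per_uL = lambda / vol_uL,
       ci95 = ci_lambda / vol_uL, ci95_lambda = ci_lambda,
       saturated = FALSE)
}

#' Pool replicate wells
#'
#' Replicate wells of the same sample and assay are pooled by summing total
#' and positive droplet counts before Poisson correction (exact treatment;
#' never averaged).
#'
#' @param wells list of [droplet_well()] objects (counts present or derived
#'   via [classify_droplets()]).
#' @param threshold optional classification threshold for fluorescence wells.
#' @return list with `sample`, `assay`, `n_total`, `n_positive`, `n_wells`.
#' @export
merge_replicates <- function(wells, threshold = NULL) {
  if (!length(wells)) stopf("no wells to merge")
  wells <- lapply(wells, as_droplet_well)
  samples <- unique(vapply(wells, `[[`, "", "sample"))
  assays <- unique(vapply(wells, `[[`, "", "assay"))
  if (length(samples) != 1 || length(assays) != 1)
    stopf("cannot pool wells across samples (%s) or assays (%s)",
          paste(samples, collapse = ","), paste(assays, collapse = ","))
  counts <- lapply(wells, well_counts, threshold = threshold)
  list(sample = samples, assay = assays,
       n_total = sum(vapply(counts, `[[`, 0L, "n_total")),
       n_positive = sum(vapply(counts, `[[`, 0L, "n_positive")),
       n_wells = length(wells))
}

as_droplet_well <- function(w) {
  if (inherits(w, "droplet_well")) return(w)
  stopf("expected a droplet_well object")
}

well_counts <- function(well, threshold = NULL) {
  if (!is.null(well$n_total))
    return(list(n_total = well$n_total, n_positive = well$n_positive))
  cl <- classify_droplets(well$fluorescence, threshold)
  list(n_total = cl$n_total, n_positive = cl$n_positive)
}

#' Detectability call from pooled positive-droplet count
#'
#' Zero pooled positive droplets is `"undetectable"`, exactly one is
#' `"borderline"` (a single droplet can be neither confirmed nor dismissed),
#' two or more are `"detectable"`.
#'
#' @param n_positive pooled positive-droplet count.
#' @param min_positives droplets required for `"detectable"` (default 2).
#' @return one of `"undetectable"`, `"borderline"`, `"detectable"`.
#' @export
detectability_call <- function(n_positive, min_positives = 2) {
  if (!is_count(n_positive, 0)) stopf("n_positive must be >= 0")
  if (n_positive == 0) "undetectable"
  else if (n_positive < min_positives) "borderline"
  else "detectable"
}

#' QC flags for a quantified sample within its run
#'
#' Flags: `LOW_DROPLETS` when the pooled droplet count is not over the
#' configured minimum (12,000, strict); `NTC_CONTAMINATION` when any
#' no-template control has positive droplets; `CONTROL_FAILURE` when the
#' positive control is fully negative; `HEALTHY_DONOR_POSITIVE` when a
#' healthy-donor well reaches the detectability threshold. A flagged result
#' is retained but marked invalid for downstream MRD logic.
#'
#' @param pooled pooled counts for the sample (from [merge_replicates()], or
#'   any list with `n_total`/`n_positive`).
#' @param run_controls list of [droplet_well()] control wells; must contain
#'   roles `NTC` and `positive_control` (`healthy_donor` optional).
#' @param min_droplets run-validity droplet threshold (default 12000).
#' @param min_positives detectability threshold, see [detectability_call()].
#' @param threshold optional classification threshold for fluorescence wells.
#' @return character vector of flags (length 0 when clean).
#' @export
qc_well <- function(pooled, run_controls, min_droplets = 12000,
                    min_positives = 2, threshold = NULL) {
  roles <- vapply(run_controls, `[[`, "", "role")
  if (!"NTC" %in% roles || !"positive_control" %in% roles)
    stopf("run controls must include NTC and positive_control (got: %s)",
          paste(roles, collapse = ", "))
  flags <- character(0)
  if (pooled$n_total <= min_droplets) flags <- c(flags, "LOW_DROPLETS")
  cts <- lapply(run_controls, well_counts, threshold = threshold)
  ntc_pos <- sum(vapply(cts[roles == "NTC"], `[[`, 0L, "n_positive"))
  if (ntc_pos > 0) flags <- c(flags, "NTC_CONTAMINATION")
  pc_pos <- sum(vapply(cts[roles == "positive_control"], `[[`, 0L,
                       "n_positive"))
  if (pc_pos == 0) flags <- c(flags, "CONTROL_FAILURE")
  if ("healthy_donor" %in% roles) {
    hd_pos <- sum(vapply(cts[roles == "healthy_donor"], `[[`, 0L,
                         "n_positive"))
    if (detectability_call(hd_pos, min_positives) == "detectable")
      flags <- c(flags, "HEALTHY_DONOR_POSITIVE")
  }
  flags
}

#' Convert reaction concentration to copies per mL plasma
#'
#' `copies_per_well = conc x reaction_volume`; scaled to the whole eluate by
#' `eluate_volume / template_per_well`, then divided by the plasma volume.
#'
#' @param conc_copies_per_uL concentration in the reaction (copies/uL).
#' @param volumes a [volumes_config()].
#' @return copies per mL plasma.
#' @export
#' @examples
#' copies_per_ml_plasma(1, volumes_config())  # 100 with the defaults
copies_per_ml_plasma <- function(conc_copies_per_uL,
                                 volumes = volumes_config()) {
  stopifnot(inherits(volumes, "volumes_config"))
  if (!is.numeric(conc_copies_per_uL) || any(conc_copies_per_uL < 0, na.rm = TRUE))
    stopf("concentration must be non-negative")
  conc_copies_per_uL * volumes$reaction_volume_uL *
    (volumes$eluate_volume_uL / volumes$template_per_well_uL) /
    volumes$plasma_volume_mL
}

#' Allelic fraction of fusion-positive genome equivalents
#'
#' Ratio of the fusion-assay concentration to the reference
#' (genome-equivalents) assay concentration from the same sample.
#'
#' @param fusion_conc,reference_conc concentrations in copies/uL.
#' @return the fraction; `NA` (with a warning) when the reference
#'   concentration is zero.
#' @export
allelic_fraction <- function(fusion_conc, reference_conc) {
  if (!is.numeric(fusion_conc) || !is.numeric(reference_conc) ||
      fusion_conc < 0 || reference_conc < 0)
    stopf("concentrations must be non-negative numbers")
  if (reference_conc == 0) {
    warnf("reference concentration is zero; allelic fraction undefined")
    return(NA_real_)
  }
  fusion_conc / reference_conc
}

#' Limit of detection at 95% confidence (rule of three)
#'
#' With zero positives among `N` pooled droplets, the 95% upper bound on
#' lambda is approximately `3 / N`; converted through the volume chain this
#' gives the smallest reliably detectable concentration.
#'
#' @param n_total_pooled pooled droplet count.
#' @param volumes a [volumes_config()].
#' @return list with `lambda95`, `conc95_copies_per_uL`,
#'   `lod_copies_per_mL`, `flags` (contains `"LOD_DEGENERATE"` when the
#'   droplet count is too small for the bound to be meaningful).
#' @export
limit_of_detection <- function(n_total_pooled, volumes = volumes_config()) {
  if (!is_count(n_total_pooled, 1)) stopf("n_total_pooled must be >= 1")
  stopifnot(inherits(volumes, "volumes_config"))
  lambda95 <- 3 / n_total_pooled
  conc95 <- lambda95 / (volumes$droplet_volume_nL * 1e-3)
  list(lambda95 = lambda95, conc95_copies_per_uL = conc95,
       lod_copies_per_mL = copies_per_ml_plasma(conc95, volumes),
       flags = if (lambda95 >= 1) "LOD_DEGENERATE" else character(0))
}

#' Quantify one sample within a run
#'
#' Pools the sample's replicate wells, applies Poisson correction, converts
#' to copies/mL plasma, computes the allelic fraction against an optional
#' reference (genome-equivalents) assay, the limit of detection, QC flags,
#' and the detectability call.
#'
#' @param fusion_wells list of [droplet_well()] replicates of the fusion
#'   assay for one sample.
#' @param reference_wells optional list of reference-assay replicates for the
#'   same sample.
#' @param run_controls control wells for the run (see [qc_well()]).
#' @param volumes a [volumes_config()].
#' @param min_droplets,min_positives QC/detectability constants.
#' @param threshold optional classification threshold.
#' @return object of class `quant_result`: a list with `sample`, `assay`,
#'   `n_total`, `n_positive`, `lambda`, `conc_copies_per_uL`, `ci95`,
#'   `copies_per_mL_plasma`, `allelic_fraction`, `lod_copies_per_mL`,
#'   `qc_flags`, `detectability`, `valid`.
#' @export
quantify_sample <- function(fusion_wells, reference_wells = NULL,
                            run_controls = list(),
                            volumes = volumes_config(),
                            min_droplets = 12000, min_positives = 2,
                            threshold = NULL) {
  pooled <- merge_replicates(fusion_wells, threshold)
  pc <- poisson_concentration(pooled$n_positive, pooled$n_total, volumes)
  flags <- character(0)
  if (length(run_controls)) {
    flags <- qc_well(pooled, run_controls, min_droplets, min_positives,
                     threshold)
  } else if (pooled$n_total <= min_droplets) {
    flags <- "LOW_DROPLETS"
  }
  if (pc$saturated) flags <- c(flags, "SATURATED")
  af <- NA_real_
  ref_conc <- NA_real_
  if (!is.null(reference_wells) && length(reference_wells)) {
    rp <- merge_replicates(reference_wells, threshold)
    rpc <- poisson_concentration(rp$n_positive, rp$n_total, volumes)
    ref_conc <- rpc$conc_copies_per_uL
    if (is.finite(ref_conc) && ref_conc > 0) {
      af <- pc$conc_copies_per_uL / ref_conc
    } else {
      flags <- c(flags, "AF_UNDEFINED")
    }
  }
  lod <- limit_of_detection(pooled$n_total, volumes)
  structure(
    list(sample = pooled$sample, assay = pooled$assay,
         n_total = pooled$n_total, n_positive = pooled$n_positive,
         lambda = pc$lambda, conc_copies_per_uL = pc$conc_copies_per_uL,
         ci95 = pc$ci95,
         copies_per_mL_plasma =
           if (is.finite(pc$conc_copies_per_uL))
             copies_per_ml_plasma(pc$conc_copies_per_uL, volumes) else Inf,
         allelic_fraction = af, reference_conc_copies_per_uL = ref_conc,
         lod_copies_per_mL = lod$lod_copies_per_mL,
         qc_flags = unique(flags),
         detectability = detectability_call(pooled$n_positive, min_positives),
         valid = !length(setdiff(unique(flags), "AF_UNDEFINED"))),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> %s/%s: %d/%d droplets positive, %.4g copies/uL, %.4g copies/mL plasma [%s]%s\n",
    x$sample, x$assay, x$n_positive, x$n_total, x$conc_copies_per_uL,
    x$copies_per_mL_plasma, x$detectability,
    if (length(x$qc_flags)) paste0(" flags=", paste(x$qc_flags, collapse = ";"))
    else ""))
  invisible(x)
}

# -- droplet CSV I/O ---------------------------------------------------------

#' Read a droplet CSV (fluorescence or counts dialect)
#'
#' Dialect A has columns `well, sample, assay, role, fluorescence` (one row
#' per droplet); dialect B has `well, sample, assay, role, n_total,
#' n_positive` (one row per well).
#'
#' @param path CSV path.
#' @return list of [droplet_well()] objects; attribute `dialect` is `"A"`
#'   or `"B"`.
#' @export
read_droplet_csv <- function(path) {
  if (!file.exists(path)) stopf("droplet CSV not found: %s", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  req <- c("well", "sample", "assay", "role")
  if (!all(req %in% names(dt)))
    stopf("droplet CSV must have columns %s", paste(req, collapse = ", "))
  if ("fluorescence" %in% names(dt)) {
    sp <- split(dt, by = "well")
    wells <- lapply(sp, function(d)
      droplet_well(d$well[1], d$sample[1], d$assay[1], d$role[1],
                   fluorescence = d$fluorescence))
    dialect <- "A"
  } else if (all(c("n_total", "n_positive") %in% names(dt))) {
    wells <- lapply(seq_len(nrow(dt)), function(i)
      droplet_well(dt$well[i], dt$sample[i], dt$assay[i], dt$role[i],
                   n_total = dt$n_total[i], n_positive = dt$n_positive[i]))
    dialect <- "B"
  } else {
    stopf("droplet CSV %s is neither fluorescence (A) nor counts (B) dialect",
          path)
  }
  wells <- unname(wells)
  attr(wells, "dialect") <- dialect
  wells
}

#' Write droplet wells as CSV
#'
#' Wells carrying fluorescence are written in dialect A, counts-only wells
#' in dialect B; mixing the two in one file is an error.
#'
#' @param wells list of [droplet_well()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(wells, path) {
  if (!length(wells)) stopf("no wells to write")
  has_fluor <- vapply(wells, function(w) !is.null(w$fluorescence), logical(1))
  if (all(has_fluor)) {
    dt <- data.table::rbindlist(lapply(wells, function(w)
      data.table::data.table(well = w$well, sample = w$sample,
                             assay = w$assay, role = w$role,
                             fluorescence = w$fluorescence)))
  } else if (!any(has_fluor)) {
    dt <- data.table::rbindlist(lapply(wells, function(w)
      data.table::data.table(well = w$well, sample = w$sample,
                             assay = w$assay, role = w$role,
                             n_total = w$n_total, n_positive = w$n_positive)))
  } else {
    stopf("cannot mix fluorescence and counts wells in one CSV")
  }
  data.table::fwrite(dt, path)
  invisible(path)
}
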