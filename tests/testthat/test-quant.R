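# Droplet quantification: classification, Poisson correction, pooling, QC,
# volume chain, allelic fraction, limit of detection.

test_that("droplet classification separates two seeded populations exactly", {
  set.seed(77)
  neg <- rnorm(1000, 2000, 100)
  pos <- rnorm(500, 8000, 200)
  x <- sample(c(neg, pos))
  cl <- classify_droplets(x)
  # count-above-midpoint oracle on the generated sample
  expect_equal(cl$n_positive, sum(x > cl$threshold_used))
  expect_equal(cl$n_positive, 500L)
  expect_gt(cl$threshold_used, max(neg))
  expect_lt(cl$threshold_used, min(pos))
  # an explicit threshold between the populations gives identical counts
  cl2 <- classify_droplets(x, threshold = 5000)
  expect_equal(cl2$n_positive, cl$n_positive)
  # all-negative well
  expect_equal(classify_droplets(neg, threshold = 5000)$n_positive, 0L)
  expect_error(classify_droplets(rep(1500, 200)), "identical")
  expect_error(classify_droplets(rnorm(50)), "at least 100")
})

test_that("Poisson correction matches the closed form at high precision", {
  q <- poisson_concentration(1000, 20000)
  expect_equal(q$lambda, -log(1 - 0.05), tolerance = 1e-12)
  expect_equal(q$conc_copies_per_uL, -log(1 - 0.05) / 0.00085,
               tolerance = 1e-12)
  expect_equal(round(q$conc_copies_per_uL, 4), 60.3451)
  z <- poisson_concentration(0, 20000)
  expect_equal(z$lambda, 0)
  expect_equal(z$conc_copies_per_uL, 0)
  sat <- poisson_concentration(20000, 20000)
  expect_true(sat$saturated)
  expect_equal(sat$conc_copies_per_uL, Inf)
})

test_that("the 95% CI is a transformed Wilson score interval", {
  for (case in list(c(5, 15000), c(0, 20000), c(1200, 24000))) {
    k <- case[1]; n <- case[2]
    q <- poisson_concentration(k, n)
    pt <- prop.test(k, n, correct = FALSE)$conf.int  # Wilson without cc
    expect_equal(unname(q$ci95_lambda),
                 c(-log(1 - pt[1]), -log(1 - pt[2])),
                 tolerance = 1e-9, info = paste(k, n))
    expect_true(q$ci95_lambda[["low"]] <= q$lambda + 1e-12)
    expect_true(q$lambda <= q$ci95_lambda[["high"]] + 1e-12)
  }
})

test_that("replicate pooling sums counts before correction", {
  w1 <- droplet_well("A1", "s1", "fusion", "sample",
                     n_total = 10000, n_positive = 50)
  w2 <- droplet_well("A2", "s1", "fusion", "sample",
                     n_total = 12000, n_positive = 70)
  pooled <- merge_replicates(list(w1, w2))
  expect_equal(pooled$n_total, 22000L)
  expect_equal(pooled$n_positive, 120L)
  # pooled concentration equals Poisson on pooled counts...
  qp <- poisson_concentration(120, 22000)
  expect_equal(qp$lambda, -log(1 - 120 / 22000))
  # ...and at small lambda lies within each well's CI
  for (w in list(c(50, 10000), c(70, 12000))) {
    ci <- poisson_concentration(w[1], w[2])$ci95_lambda
    expect_true(qp$lambda >= ci[["low"]] && qp$lambda <= ci[["high"]])
  }
  # single well unchanged
  single <- merge_replicates(list(w1))
  expect_equal(single$n_positive, 50L)
  # mixed assays rejected
  w3 <- droplet_well("A3", "s1", "reference", "sample",
                     n_total = 100, n_positive = 1)
  expect_error(merge_replicates(list(w1, w3)), "assays")
})

test_that("QC flags fire at the documented boundaries", {
  ctrl <- list(
    droplet_well("N", "run", "fusion", "NTC", n_total = 15000, n_positive = 0),
    droplet_well("P", "run", "fusion", "positive_control",
                 n_total = 15000, n_positive = 300),
    droplet_well("H", "run", "fusion", "healthy_donor",
                 n_total = 15000, n_positive = 0))
  # strictly over 12,000 droplets passes
  expect_length(qc_well(list(n_total = 12001, n_positive = 3), ctrl), 0L)
  expect_equal(qc_well(list(n_total = 11999, n_positive = 3), ctrl),
               "LOW_DROPLETS")
  expect_equal(qc_well(list(n_total = 12000, n_positive = 3), ctrl),
               "LOW_DROPLETS")
  # contaminated NTC
  dirty <- ctrl
  dirty[[1]] <- droplet_well("N", "run", "fusion", "NTC",
                             n_total = 15000, n_positive = 2)
  expect_true("NTC_CONTAMINATION" %in%
                qc_well(list(n_total = 13000, n_positive = 3), dirty))
  # dead positive control
  dead <- ctrl
  dead[[2]] <- droplet_well("P", "run", "fusion", "positive_control",
                            n_total = 15000, n_positive = 0)
  expect_true("CONTROL_FAILURE" %in%
                qc_well(list(n_total = 13000, n_positive = 3), dead))
  # missing mandatory controls
  expect_error(qc_well(list(n_total = 13000, n_positive = 3), ctrl[3]),
               "NTC")
})

test_that("the copies/mL volume chain follows the hand-evaluated arithmetic", {
  v <- volumes_config(reaction_volume_uL = 20, template_per_well_uL = 5,
                      eluate_volume_uL = 50, plasma_volume_mL = 2)
  expect_equal(copies_per_ml_plasma(1, v), 100)
  expect_equal(copies_per_ml_plasma(0, v), 0)
  v1 <- volumes_config(reaction_volume_uL = 20, template_per_well_uL = 5,
                       eluate_volume_uL = 50, plasma_volume_mL = 1)
  expect_equal(copies_per_ml_plasma(1, v1), 200)  # halving plasma doubles
  expect_error(volumes_config(plasma_volume_mL = 0), "positive")
})

test_that("allelic fraction is the concentration ratio, flagged at zero", {
  expect_equal(allelic_fraction(0, 100), 0)
  expect_equal(allelic_fraction(5, 100), 0.05)
  expect_warning(af <- allelic_fraction(5, 0), "undefined")
  expect_true(is.na(af))
})

test_that("limit of detection follows the rule of three", {
  lod <- limit_of_detection(20000)
  expect_equal(lod$lambda95, 1.5e-4)
  expect_equal(lod$conc95_copies_per_uL, 1.5e-4 / 0.00085, tolerance = 1e-12)
  expect_equal(round(lod$conc95_copies_per_uL, 5), 0.17647)
  # halves when the pooled droplet count doubles
  expect_equal(limit_of_detection(40000)$lambda95, lod$lambda95 / 2)
  # degenerate droplet count is flagged
  one <- limit_of_detection(1)
  expect_equal(one$lambda95, 3)
  expect_true("LOD_DEGENERATE" %in% one$flags)
})

test_that("quantify_sample assembles result, AF and flags coherently", {
  v <- volumes_config()
  mkw <- function(id, k, assay = "fusion", role = "sample")
    droplet_well(id, "s1", assay, role, n_total = 20000, n_positive = k)
  ctrl <- list(mkw("N", 0, role = "NTC"),
               mkw("P", 500, role = "positive_control"))
  q <- quantify_sample(list(mkw("F1", 40), mkw("F2", 60)),
                       reference_wells = list(mkw("R1", 2000, "reference"),
                                              mkw("R2", 2000, "reference")),
                       run_controls = ctrl, volumes = v)
  expect_equal(q$n_total, 40000L)
  expect_equal(q$n_positive, 100L)
  expect_equal(q$lambda, -log(1 - 100 / 40000))
  expect_equal(q$copies_per_mL_plasma,
               copies_per_ml_plasma(q$conc_copies_per_uL, v))
  expect_equal(q$allelic_fraction,
               q$conc_copies_per_uL / poisson_concentration(4000, 40000, v)$conc_copies_per_uL)
  expect_equal(q$detectability, "detectable")
  expect_true(q$valid)
})

test_that("droplet CSVs round-trip in both dialects", {
  wells <- list(
    droplet_well("A1", "s1", "fusion", "sample", n_total = 15000,
                 n_positive = 12),
    droplet_well("N1", "s1", "fusion", "NTC", n_total = 14000,
                 n_positive = 0))
  p <- tempfile(fileext = ".csv")
  write_droplet_csv(wells, p)
  back <- read_droplet_csv(p)
  expect_equal(attr(back, "dialect"), "B")
  expect_equal(back[[1]]$n_positive, 12L)
  sim <- simulate_droplets(0.01, 500, seed = 5)
  wf <- list(droplet_well("A1", "s1", "fusion", "sample",
                          fluorescence = sim$fluorescence))
  write_droplet_csv(wf, p)
  backf <- read_droplet_csv(p)
  expect_equal(attr(backf, "dialect"), "A")
  expect_equal(length(backf[[1]]$fluorescence), 500L)
})
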