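# Nearest-neighbor DNA melting temperature (unified parameter set, 1 M NaCl
# reference conditions, entropic salt correction). Used for primer/probe
# selection; deliberately a small, self-contained implementation rather than
# a wrapper around an external primer-design engine.

# Unified NN parameters: dH in kcal/mol, dS in cal/(mol K), per 5'->3'
# dinucleotide on the top strand (complementary pairs share values).
.nn_dH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.nn_dS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# Initiation terms per terminal base pair.
.nn_init_dH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.nn_init_dS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

.gas_const <- 1.987 # cal/(mol K)

nn_sums <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  din <- paste0(b[-length(b)], b[-1])
  list(
    dH = sum(.nn_dH[din]) + .nn_init_dH[b[1]] + .nn_init_dH[b[length(b)]],
    dS = sum(.nn_dS[din]) + .nn_init_dS[b[1]] + .nn_init_dS[b[length(b)]]
  )
}

#' Nearest-neighbor oligonucleotide melting temperature
#'
#' Unified nearest-neighbor thermodynamics with an entropic salt correction
#' (`dS + 0.368 (N-1) ln[Na+]`) and the non-self-complementary duplex factor
#' (`CT/4`):
#' `Tm = 1000 dH / (dS_salt + R ln(CT/4)) - 273.15`.
#'
#' @param seq character vector of DNA sequences (A,C,G,T only), length >= 8.
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @param oligo_nM total oligo concentration in nM (default 250).
#' @return numeric vector of melting temperatures in deg C.
#' @export
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
melting_temperature <- function(seq, na_mM = 50, oligo_nM = 250) {
  if (!is.character(seq) || !length(seq)) stopf("seq must be character")
  if (!is.numeric(na_mM) || na_mM <= 0) stopf("na_mM must be positive")
  if (!is.numeric(oligo_nM) || oligo_nM <= 0) stopf("oligo_nM must be positive")
  vapply(seq, function(s) {
    assert_dna(s, "oligo sequence", allow_n = FALSE)
    n <- nchar(s)
    if (n < 8) stopf("oligo too short for NN model (%d < 8 bases)", n)
    th <- nn_sums(s)
    dS_salt <- th$dS + 0.368 * (n - 1) * log(na_mM / 1000)
    1000 * th$dH / (dS_salt + .gas_const * log(oligo_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Cumulative-sum machinery for scanning many windows of one template.
# Returns closures evaluating window dH/dS/GC/violations in O(1) per window.
thermo_scan <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  din <- if (n >= 2) paste0(b[-n], b[-1]) else character(0)
  ok <- din %in% names(.nn_dH)
  dH_steps <- ifelse(ok, .nn_dH[din], NA_real_)
  dS_steps <- ifelse(ok, .nn_dS[din], NA_real_)
  cumH <- c(0, cumsum(ifelse(is.na(dH_steps), 0, dH_steps)))
  cumS <- c(0, cumsum(ifelse(is.na(dS_steps), 0, dS_steps)))
  gc <- cumsum(b %in% c("G", "C"))
  gc0 <- c(0, gc)
  isn <- cumsum(b == "N")
  isn0 <- c(0, isn)
  # run5[p] = TRUE when bases p-4..p are identical (a run > 4 ends at p)
  runlen <- integer(n)
  if (n) runlen[1] <- 1L
  for (i in seq_len(n)[-1]) runlen[i] <- if (b[i] == b[i - 1]) runlen[i - 1] + 1L else 1L
  run5 <- c(0, cumsum(runlen >= 5))
  list(
    n = n, bases = b,
    window_tm = function(s, e, na_mM, oligo_nM) {
      len <- e - s + 1
      dH <- cumH[e] - cumH[s] + .nn_init_dH[b[s]] + .nn_init_dH[b[e]]
      dS <- cumS[e] - cumS[s] + .nn_init_dS[b[s]] + .nn_init_dS[b[e]]
      dS_salt <- dS + 0.368 * (len - 1) * log(na_mM / 1000)
      1000 * dH / (dS_salt + .gas_const * log(oligo_nM * 1e-9 / 4)) - 273.15
    },
    window_gc = function(s, e) (gc0[e + 1] - gc0[s]) / (e - s + 1),
    window_has_n = function(s, e) (isn0[e + 1] - isn0[s]) > 0,
    # any run of >= 5 identical bases fully inside [s, e]
    window_has_run = function(s, e) {
      lo <- pmin(s + 4, e + 1)
      (run5[e + 1] - run5[lo]) > 0
    }
  )
}
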