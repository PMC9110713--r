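# Nearest-neighbor melting temperature for primer binding regions.
# Unified NN parameter set (SantaLucia 1998); salt correction applied as an
# entropic term with divalent cations converted to a monovalent equivalent
# (120 * sqrt(free Mg2+) rule, dNTPs chelating Mg stoichiometrically).

# delta-H (kcal/mol), delta-S (cal/mol/K) per top-strand dinucleotide.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# Duplex initiation per terminal base pair.
INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
GAS_CONSTANT <- 1.987  # cal/mol/K

#' Melting-temperature model parameters
#'
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param divalent_mM divalent cation (Mg2+) concentration (mM).
#' @param dntp_mM total dNTP concentration (mM); chelates Mg2+.
#' @param primer_nM primer strand concentration (nM), assumed in excess
#'   over template.
#' @return Object of class `tm_parameters`.
#' @export
tm_parameters <- function(monovalent_mM = 50, divalent_mM = 1.5,
                          dntp_mM = 0.6, primer_nM = 50) {
  vals <- c(monovalent_mM, divalent_mM, dntp_mM, primer_nM)
  if (any(vals[c(1, 4)] <= 0) || any(vals < 0))
    stop("concentrations must be positive", call. = FALSE)
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 dntp_mM = dntp_mM, primer_nM = primer_nM),
            class = "tm_parameters")
}

#' Nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature of a primer binding region
#' against its perfect complement using the unified nearest-neighbor
#' delta-H/delta-S table with duplex-initiation terms, an entropic salt
#' correction `0.368 (N-1) ln[Na+_eff]`, and the primer-in-excess strand
#' concentration term. Divalent cations enter through the monovalent
#' equivalent `[Na+_eff] = [Na+] + 120 sqrt([Mg2+] - [dNTP])` (mM).
#'
#' @param seq binding-region sequence, 8-36 nt.
#' @param params a [tm_parameters()].
#' @return Melting temperature in degrees Celsius.
#' @export
compute_tm <- function(seq, params = tm_parameters()) {
  seq <- as_dna(seq, what = "primer sequence")
  n <- nchar(seq)
  if (n < 8L || n > 36L)
    stop("compute_tm expects 8-36 nt, got ", n, call. = FALSE)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  steps <- paste0(b[-n], b[-1])
  dh <- sum(NN_DH[steps]) + INIT_DH[b[1]] + INIT_DH[b[n]]
  ds <- sum(NN_DS[steps]) + INIT_DS[b[1]] + INIT_DS[b[n]]
  selfcomp <- identical(seq, revcomp(seq))
  if (selfcomp) ds <- ds - 1.4
  mg_free <- max(params$divalent_mM - params$dntp_mM, 0)
  na_eff_mM <- params$monovalent_mM + 120 * sqrt(mg_free)
  ds <- ds + 0.368 * (n - 1L) * log(na_eff_mM / 1000)
  conc <- params$primer_nM * 1e-9  # primer in excess: no CT/4 factor
  tm_k <- (dh * 1000) / (ds + GAS_CONSTANT * log(conc))
  unname(tm_k - 273.15)
}
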