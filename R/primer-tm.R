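# Unified nearest-neighbor thermodynamic parameters for DNA duplexes
# (SantaLucia 1998): dH in kcal/mol, dS in cal/(mol K) per NN stack.
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature from unified nearest-neighbor thermodynamics:
#' stacking enthalpies and entropies are summed over adjacent base pairs,
#' duplex-initiation terms are added per terminal base pair (G*C ends:
#' dH 0.1 kcal/mol, dS -2.8 cal/mol/K; A*T ends: dH 2.3, dS 4.1), the
#' entropy is salt-corrected by `0.368 (N-1) ln[Na+]`, and
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15}
#' with R = 1.987 cal/mol/K and the total strand concentration taken as the
#' primer concentration (primer in large excess over template, as in PCR).
#'
#' Defaults reflect the assay conditions the designs are screened for:
#' 200 nM primer and 50 mM monovalent salt.
#'
#' @param seq Primer sequence, ACGT only, length >= 8.
#' @param primer_nM Primer concentration in nM.
#' @param na_mM Monovalent cation concentration in mM.
#' @return Melting temperature in degrees Celsius.
#' @export
primer_tm <- function(seq, primer_nM = 200, na_mM = 50) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 8) stop("primer shorter than 8 nt")
  bases <- strsplit(seq, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("ambiguity codes not supported; ACGT only")
  stacks <- paste0(bases[-n], bases[-1])
  dH <- sum(.nn_dh[stacks])
  dS <- sum(.nn_ds[stacks])
  for (term in bases[c(1, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- primer_nM * 1e-9
  dH * 1000 / (dS + 1.987 * log(ct / 4)) - 273.15
}
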