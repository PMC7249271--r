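# Nearest-neighbor duplex thermodynamics (SantaLucia 1998 unified parameters).
# dH in kcal/mol, dS in cal/(mol K); one row per 5'->3' dinucleotide step.
nn_dh <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
nn_ds <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
# duplex initiation at each terminal base
init_dh <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
init_ds <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
gas_const <- 1.987  # cal/(mol K)

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature from nearest-neighbor thermodynamics using the
#' unified dinucleotide parameter set with terminal-initiation terms, a
#' monovalent-salt entropy correction of `0.368 * (N - 1) * ln[Na+]`, and
#' `Tm = dH / (dS + R ln(CT/4)) - 273.15` for non-self-complementary primers
#' at total strand concentration `CT`.
#'
#' @param seq DNA string, length >= 8, over `A`,`C`,`G`,`T`.
#' @param primer_nM Total primer concentration in nM (default 50).
#' @param na_mM Effective monovalent cation concentration in mM.  The
#'   default of 200 approximates PCR annealing buffer (about 50 mM K+ plus
#'   the stabilising contribution of ~1.5 mM Mg2+), which places typical
#'   50%-GC 20-mers near 60 deg C.
#' @return Melting temperature in degrees Celsius.  Symmetric under reverse
#'   complement of `seq`.
#' @examples
#' melting_temp("CGAGCTCCGTTATCTCCGAG")
#' @export
melting_temp <- function(seq, primer_nM = 50, na_mM = 200) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) abort("melting_temp: sequence must be ACGT only")
  n <- nchar(seq)
  if (n < 8L) abort("melting_temp: sequence must be at least 8 nt")
  steps <- substring(seq, seq_len(n - 1L), 2:n)
  first <- substr(seq, 1L, 1L)
  last <- substr(seq, n, n)
  dh <- sum(nn_dh[steps]) + init_dh[[first]] + init_dh[[last]]
  ds <- sum(nn_ds[steps]) + init_ds[[first]] + init_ds[[last]]
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- primer_nM * 1e-9
  dh * 1000 / (ds + gas_const * log(ct / 4)) - 273.15
}
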