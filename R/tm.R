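#' GC content of primer sequences
#'
#' @param seq character vector of unambiguous DNA sequences (A/C/G/T only;
#'   primers must be unambiguous).
#' @return numeric vector, percent G+C (0-100).
#' @export
gc_content <- function(seq) {
  if (length(seq) == 0L) return(numeric(0))
  if (any(!nzchar(seq))) stop("gc_content: empty sequence")
  if (any(grepl("[^ACGT]", seq))) {
    stop("gc_content: ambiguous or non-ACGT base in sequence")
  }
  dss <- Biostrings::DNAStringSet(seq)
  as.numeric(Biostrings::letterFrequency(dss, "GC", as.prob = TRUE)) * 100
}

# SantaLucia & Hicks (2004) unified nearest-neighbor parameters.
# dH kcal/mol, dS cal/(mol K); one row per canonical dinucleotide stack.
NN_DH <- c(AA = -7.6, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -21.3, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
# map all 16 dinucleotides onto the 10 canonical stacks (reverse complements)
NN_CANON <- c(AA = "AA", TT = "AA", AT = "AT", TA = "TA",
              CA = "CA", TG = "CA", GT = "GT", AC = "GT",
              CT = "CT", AG = "CT", GA = "GA", TC = "GA",
              CG = "CG", GC = "GC", GG = "GG", CC = "GG")

#' Primer melting temperature
#'
#' Two methods: `"wallace"`, the rule-of-thumb 2(A+T) + 4(G+C) used for
#' hand-checkable short oligos, and `"nn"` (default), duplex nearest-neighbor
#' thermodynamics with the unified SantaLucia & Hicks (2004) parameter set,
#' duplex initiation and terminal A/T penalties, the SantaLucia (1998) entropy
#' salt correction 0.368 (N-1) ln[Na+], and
#' Tm = 1000 dH / (dS + R ln(C)) - 273.15 with R = 1.987 cal/(mol K) and
#' annealing concentration C = `primer_nM`/2 (each primer in excess at
#' `primer_nM`).
#'
#' @param seq character vector of unambiguous DNA sequences.
#' @param method `"nn"` or `"wallace"`.
#' @param monovalent_mM monovalent cation concentration (mM) for the salt
#'   correction (default 50).
#' @param primer_nM primer concentration in nM (default 250).
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(seq, method = c("nn", "wallace"),
                                monovalent_mM = 50, primer_nM = 250) {
  method <- match.arg(method)
  if (length(seq) == 0L) return(numeric(0))
  if (any(grepl("[^ACGT]", seq)) || any(!nzchar(seq))) {
    stop("melting_temperature: sequences must be non-empty and unambiguous ACGT")
  }
  dss <- Biostrings::DNAStringSet(seq)
  if (method == "wallace") {
    at <- as.numeric(Biostrings::letterFrequency(dss, "AT"))
    gc <- as.numeric(Biostrings::letterFrequency(dss, "GC"))
    return(2 * at + 4 * gc)
  }
  if (any(nchar(seq) < 2L)) {
    stop("melting_temperature: nearest-neighbor model needs >= 2 bases")
  }
  din <- Biostrings::dinucleotideFrequency(dss) # vectorized in C over seqs
  dh_vec <- NN_DH[NN_CANON[colnames(din)]]
  ds_vec <- NN_DS[NN_CANON[colnames(din)]]
  dh <- as.numeric(din %*% dh_vec)
  ds <- as.numeric(din %*% ds_vec)
  # initiation + terminal A/T penalties
  first <- substr(seq, 1L, 1L)
  last <- substr(seq, nchar(seq), nchar(seq))
  n_term_at <- (first %in% c("A", "T")) + (last %in% c("A", "T"))
  dh <- dh + 0.2 + 2.2 * n_term_at
  ds <- ds - 5.7 + 6.9 * n_term_at
  # salt correction (SantaLucia 1998) on entropy
  ds <- ds + 0.368 * (nchar(seq) - 1L) * log(monovalent_mM / 1000)
  r_gas <- 1.987
  conc <- primer_nM / 2 * 1e-9
  1000 * dh / (ds + r_gas * log(conc)) - 273.15
}
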