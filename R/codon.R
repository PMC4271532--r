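# Codon-level utilities used throughout the caller.  The standard nuclear
# genetic code is hard-coded: translation is the core of the PTC call and must
# behave identically everywhere (it is cross-checked against
# Biostrings::translate in the test suite).

#' Standard nuclear codon table
#'
#' Named character vector mapping the 64 codons to one-letter amino acids,
#' with `"*"` for the three stop codons (TAA, TAG, TGA).
#'
#' @format Named character vector of length 64.
#' @keywords internal
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' @rdname CODON_TABLE
#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' IUPAC codes used to encode heterozygous sites in pseudochromosomes
#' @keywords internal
HET_CODES <- c("R", "Y", "S", "W", "K", "M")

DNA_BASES <- c("A", "C", "G", "T")

#' Split a coding sequence into codons
#'
#' @param seq A single character string; its length must be a multiple of 3.
#' @return Character vector of codons in order.
#' @export
codons_of <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(seq, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Translates with the standard nuclear code; stop codons become `"*"`,
#' codons containing non-ACGT symbols become `"X"`.
#'
#' @param seq A single character string of length divisible by 3.
#' @return Single character string of amino acids.
#' @export
translate_cds <- function(seq) {
  aa <- CODON_TABLE[codons_of(toupper(seq))]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Complement of a base (IUPAC-aware)
#' @param b Character vector of single-character symbols.
#' @keywords internal
comp_base <- function(b) chartr("ACGTRYSWKMNacgt", "TGCAYRSWMKNtgca", b)

#' Reverse-complement of a DNA string
#'
#' Works on plain character strings and understands the IUPAC ambiguity
#' codes used for heterozygous sites.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse-complemented strings.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# random DNA of a given length (uniform base composition)
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# codons that do not encode a stop
sense_codons <- function() names(CODON_TABLE)[CODON_TABLE != "*"]

# sample() safe against the length-1 scalar expansion
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# uniform integer draw from an inclusive range given as c(min, max)
sample_range <- function(rng, n = 1L) {
  resample(seq.int(rng[1L], rng[2L]), n, replace = TRUE)
}
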