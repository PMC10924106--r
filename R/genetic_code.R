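# Standard genetic code (NCBI transl_table 1), codons ordered T,C,A,G by
# position 1 (outer) to 3 (inner). Kept as a hand-written constant so that
# tests can cross-check it against an independent source.

.BASES <- c("T", "C", "A", "G")

.codon_table <- function() {
  codons <- as.vector(t(outer(
    as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

.GENCODE <- .codon_table()
.SENSE_CODONS <- names(.GENCODE)[.GENCODE != "*"]

.is_stop <- function(codon) unname(.GENCODE[codon] == "*")

.translate_codon <- function(codon) {
  aa <- .GENCODE[codon]
  if (is.na(aa)) stop("not a valid codon: ", codon)
  unname(aa)
}

# All nine single-nucleotide neighbors of a codon.
.codon_neighbors <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(.BASES, nt[pos])) {
      mut <- nt
      mut[pos] <- b
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

.complement <- function(base) {
  c(A = "T", T = "A", G = "C", C = "G", N = "N")[toupper(base)]
}

.revcomp <- function(seq) {
  paste(rev(unname(.complement(strsplit(toupper(seq), "")[[1]]))),
        collapse = "")
}
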