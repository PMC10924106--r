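# Independent oracles used across tests. These deliberately take different
# routes than the package implementation.

# Brute-force defense-island enumerator: O(n^2) over all windows of
# defense-unit indices; a window is an island iff every consecutive gap is
# <= gap_max, it cannot be extended on either side, and it meets the unit
# and family minima.
bf_islands <- function(ord, fams, gap_max = 10, min_units = 5,
                       min_families = 3) {
  n <- length(ord)
  if (n == 0) return(NULL)
  o <- order(ord)
  ord <- ord[o]
  fams <- fams[o]
  res <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      gaps_ok <- j == i ||
        all(diff(ord[i:j]) - 1 <= gap_max)
      if (!gaps_ok) next
      left_max <- i == 1 || (ord[i] - ord[i - 1] - 1) > gap_max
      right_max <- j == n || (ord[j + 1] - ord[j] - 1) > gap_max
      if (!left_max || !right_max) next
      ff <- unique(fams[i:j])
      ff <- ff[!is.na(ff) & ff != "unknown"]
      if ((j - i + 1) >= min_units && length(ff) >= min_families)
        res[[length(res) + 1L]] <- c(first = ord[i], last = ord[j])
    }
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

# Random single-contig test case for the island caller.
random_contig_case <- function(contig, n_max = 60) {
  n <- sample(15:n_max, 1)
  n_def <- sample(3:min(n, 25), 1)
  ord <- sort(sample(0:(n - 1), n_def))
  fams <- sample(c(LETTERS[1:6], "unknown"), n_def, replace = TRUE,
                 prob = c(rep(1, 6), 0.5))
  genes <- data.frame(
    mag_id = "M", contig_id = contig,
    gene_id = sprintf("%s_g%03d", contig, 1:n),
    start = (0:(n - 1)) * 1000 + 1, end = (0:(n - 1)) * 1000 + 900,
    strand = "+", ordinal = 0:(n - 1), stringsAsFactors = FALSE)
  hits <- data.frame(
    gene_id = genes$gene_id[ord + 1], family = fams,
    gene_name = paste0(fams, "_A"), role = "mandatory",
    system_id = NA_character_, stringsAsFactors = FALSE)
  list(genes = genes, hits = hits, ord = ord, fams = fams)
}

# NG86 site-count oracle: exhaustive mutation enumeration using
# Biostrings::GENETIC_CODE as an independent genetic-code source.
oracle_ng86_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  nt <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(bases, nt[pos]), function(b) {
      x <- nt
      x[pos] <- b
      paste(x, collapse = "")
    }, character(1))
    nonstop <- muts[gc[muts] != "*"]
    if (length(nonstop) > 0)
      s <- s + sum(gc[nonstop] == gc[codon]) / length(nonstop)
  }
  c(s = s, n = 3 - s)
}

# All sense codons according to Biostrings.
oracle_sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Minimal gene/hit tables from an ordinal specification, one contig.
genes_from_ordinals <- function(n, contig = "c1", mag = "M1") {
  data.frame(
    mag_id = mag, contig_id = contig,
    gene_id = sprintf("%s_%s_g%03d", mag, contig, 1:n),
    start = (0:(n - 1)) * 1000 + 1, end = (0:(n - 1)) * 1000 + 900,
    strand = "+", ordinal = 0:(n - 1), stringsAsFactors = FALSE)
}

hits_at <- function(genes, ordinals, families,
                    gene_names = paste0(families, "_A"),
                    roles = "mandatory", system_ids = NA_character_) {
  data.frame(
    gene_id = genes$gene_id[match(ordinals, genes$ordinal)],
    family = families, gene_name = gene_names, role = roles,
    system_id = system_ids, stringsAsFactors = FALSE)
}
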