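# Pairwise dN/dS by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction. Synonymous site fractions per codon position
# are computed among non-stop mutational outcomes; multi-difference codon
# pairs are scored by equal-weight averaging over all minimal mutational
# pathways, excluding pathways that pass through a stop codon.

.ng86_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the fraction of single-nucleotide changes that
#' are synonymous, among changes not creating a stop codon; summed over
#' the three positions this gives s, with n = 3 - s.
#'
#' @param codon a sense codon (3-letter string, T not U).
#' @return named numeric vector `c(s = , n = )`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(gsub("U", "T", codon))
  if (is.na(.GENCODE[codon])) stop("not a valid codon: ", codon)
  if (.is_stop(codon)) stop("stop codon has no site counts: ", codon)
  key <- paste0("s_", codon)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  nt <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    outcomes <- vapply(setdiff(.BASES, nt[pos]), function(b) {
      mut <- nt; mut[pos] <- b; paste(mut, collapse = "")
    }, character(1))
    nonstop <- outcomes[!.is_stop(outcomes)]
    if (length(nonstop) > 0)
      s <- s + sum(.GENCODE[nonstop] == .GENCODE[codon]) / length(nonstop)
  }
  res <- c(s = s, n = 3 - s)
  .ng86_cache[[key]] <- res
  res
}

# Synonymous/nonsynonymous difference counts between two sense codons,
# averaged over minimal mutational pathways. Pathways through stop codons
# are excluded; if every pathway is blocked, all pathways are used with
# stop-involving steps counted as nonsynonymous.
.ng86_diffs <- function(c1, c2) {
  key <- paste0("d_", c1, c2)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  k <- length(pos)
  if (k == 0) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- if (k == 1) list(pos) else {
      pp <- list()
      idx <- seq_len(k)
      permute <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
          for (rest in permute(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
        out
      }
      lapply(permute(idx), function(o) pos[o])
    }
    score <- function(order, count_stops) {
      cur <- n1
      sd <- 0; nd <- 0
      for (p in order) {
        prev <- paste(cur, collapse = "")
        cur[p] <- n2[p]
        nxt <- paste(cur, collapse = "")
        if (.is_stop(nxt) && nxt != c2 && !count_stops)
          return(NULL)  # blocked pathway
        if (!.is_stop(prev) && !.is_stop(nxt) &&
            .GENCODE[prev] == .GENCODE[nxt]) sd <- sd + 1
        else nd <- nd + 1
      }
      c(sd = sd, nd = nd)
    }
    scored <- Filter(Negate(is.null),
                     lapply(perms, score, count_stops = FALSE))
    if (length(scored) == 0)
      scored <- lapply(perms, score, count_stops = TRUE)
    m <- do.call(rbind, scored)
    res <- colMeans(m)
  }
  .ng86_cache[[key]] <- res
  res
}

#' Pairwise dN/dS by Nei-Gojobori (1986)
#'
#' Both sequences must be codon-aligned (equal length, multiple of 3).
#' Codon positions containing a gap, an ambiguous base, or a stop codon in
#' either sequence are skipped pairwise. S and N site counts are averaged
#' over the two sequences; synonymous/nonsynonymous differences are
#' averaged over minimal mutational pathways. Proportions are corrected
#' with the Jukes-Cantor formula `d = -3/4 ln(1 - 4p/3)`; pairs with
#' `p >= 3/4` or with dS > 1 (substitution saturation) are flagged
#' `discarded`.
#'
#' @param seq1,seq2 nucleotide strings (T or U accepted).
#' @return one-row data.frame: n_codons (compared), S, N, Sd, Nd, pS, pN,
#'   dS, dN, omega, discarded, reason.
#' @export
ng86_pair <- function(seq1, seq2) {
  s1 <- toupper(gsub("U", "T", seq1))
  s2 <- toupper(gsub("U", "T", seq2))
  if (nchar(s1) != nchar(s2))
    stop("sequences differ in length (must be codon-aligned)")
  if (nchar(s1) %% 3 != 0)
    stop("alignment length is not a multiple of 3")
  nc <- nchar(s1) %/% 3
  S <- N <- Sd <- Nd <- 0
  used <- 0L
  for (i in seq_len(nc)) {
    c1 <- substr(s1, 3 * i - 2, 3 * i)
    c2 <- substr(s2, 3 * i - 2, 3 * i)
    if (grepl("[^TCAG]", c1) || grepl("[^TCAG]", c2)) next
    if (.is_stop(c1) || .is_stop(c2)) next
    used <- used + 1L
    st1 <- ng86_sites(c1)
    st2 <- ng86_sites(c2)
    S <- S + (st1[["s"]] + st2[["s"]]) / 2
    N <- N + (st1[["n"]] + st2[["n"]]) / 2
    if (c1 != c2) {
      dd <- .ng86_diffs(c1, c2)
      Sd <- Sd + dd[["sd"]]
      Nd <- Nd + dd[["nd"]]
    }
  }
  if (used == 0) stop("no comparable codon positions")
  # a site class can be empty on very short inputs; no differences there
  # means no divergence on that class
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  reason <- ""
  discarded <- FALSE
  if (is.na(dS) || is.na(dN)) {
    discarded <- TRUE
    reason <- "jukes_cantor_saturation"
  } else if (dS > 1) {
    discarded <- TRUE
    reason <- "dS_gt_1"
  }
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  data.frame(n_codons = used, S = S, N = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
             discarded = discarded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Read a codon-aligned FASTA file
#'
#' @param path FASTA path (sequences must be codon-aligned within each
#'   ortholog cluster).
#' @return named character vector of sequences.
#' @export
read_codon_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Per-cluster dN/dS distributions
#'
#' Estimates all within-cluster pairs (clusters of aligned putative
#' orthologs, e.g. from an 80% identity clustering; singletons are
#' dropped), discards saturated pairs (dS > 1 or Jukes-Cantor-undefined),
#' and summarizes omega per family.
#'
#' @param clusters data.frame with columns `gene_id`, `cluster_id` and
#'   optionally `family`.
#' @param seqs named character vector (or Biostrings::DNAStringSet) of
#'   codon-aligned sequences, names matching `gene_id`; sequences within
#'   a cluster must be mutually aligned.
#' @return list with `pairs` (per-pair estimates with cluster/family) and
#'   `summary` (per family: n_pairs, n_retained, discarded_fraction,
#'   median/quartiles of omega over retained pairs with defined omega).
#' @export
cluster_omega <- function(clusters, seqs) {
  if (inherits(seqs, "DNAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  tabs <- table(clusters$cluster_id)
  keep <- names(tabs)[tabs >= 2]
  rows <- list()
  for (cl in keep) {
    ids <- clusters$gene_id[clusters$cluster_id == cl]
    ids <- ids[ids %in% names(seqs)]
    if (length(ids) < 2) next
    fam <- if ("family" %in% names(clusters))
      clusters$family[match(ids[1], clusters$gene_id)] else NA_character_
    for (i in seq_len(length(ids) - 1)) {
      for (k in seq(i + 1, length(ids))) {
        est <- ng86_pair(seqs[[ids[i]]], seqs[[ids[k]]])
        est$cluster_id <- cl
        est$family <- fam
        est$gene_a <- ids[i]
        est$gene_b <- ids[k]
        rows[[length(rows) + 1L]] <- est
      }
    }
  }
  if (length(rows) == 0)
    return(list(pairs = NULL, summary = NULL))
  pairs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(pairs, ifelse(is.na(pairs$family), "(none)", pairs$family)),
    function(d) {
      ok <- !d$discarded & !is.na(d$omega)
      qs <- if (any(ok))
        stats::quantile(d$omega[ok], c(0.25, 0.5, 0.75), names = FALSE)
      else rep(NA_real_, 3)
      data.frame(family = if (is.na(d$family[1])) "(none)" else d$family[1],
                 n_pairs = nrow(d), n_retained = sum(ok),
                 discarded_fraction = mean(d$discarded),
                 omega_q1 = qs[1], omega_median = qs[2], omega_q3 = qs[3],
                 stringsAsFactors = FALSE)
    }))
  rownames(pairs) <- rownames(summary) <- NULL
  list(pairs = pairs, summary = summary)
}
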