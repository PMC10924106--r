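#' Filter high-frequency variants
#'
#' Keeps variants with allele frequency >= `min_freq` AND supporting
#' reads >= `min_reads` (both inclusive).
#'
#' @param vars variant data.frame (see [read_variants()]).
#' @param min_freq minimum allele frequency (default 0.25).
#' @param min_reads minimum supporting reads (default 10).
#' @return the retained subset.
#' @export
filter_high_frequency <- function(vars, min_freq = 0.25, min_reads = 10) {
  keep <- vars$allele_frequency >= min_freq &
    vars$supporting_reads >= min_reads
  out <- vars[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a variant by region and substitution type
#'
#' The analyzed region of a gene is its body plus the `upstream_bp`
#' window 5' of the start codon (strand-aware: positions below `start`
#' for + genes, above `end` for - genes). SNPs inside the gene body are
#' classified synonymous/nonsynonymous when the coding sequence is
#' supplied (reference codon vs the single-substituted codon under the
#' standard genetic code); otherwise they stay unclassified. Indels are
#' always typed `indel`.
#'
#' @param position genomic (contig) position of the variant, 1-based.
#' @param gene_start,gene_end gene body coordinates (1-based inclusive).
#' @param strand `"+"` or `"-"`.
#' @param ref,alt reference and alternate alleles (single bases for SNPs,
#'   in contig orientation).
#' @param cds coding sequence of the gene, 5' to 3' (string); optional.
#' @param upstream_bp upstream window size (default 200).
#' @return list with `region` (`gene_body`/`upstream`) and `var_type`.
#' @export
classify_variant <- function(position, gene_start, gene_end,
                             strand = "+", ref = NA, alt = NA,
                             cds = NULL, upstream_bp = 200) {
  stopifnot(strand %in% c("+", "-"))
  in_body <- position >= gene_start && position <= gene_end
  upstream <- if (strand == "+")
    position < gene_start && position >= gene_start - upstream_bp
  else
    position > gene_end && position <= gene_end + upstream_bp
  if (!in_body && !upstream)
    stop("variant position ", position,
         " outside the analyzed region (gene body + ", upstream_bp,
         " bp upstream)")
  region <- if (in_body) "gene_body" else "upstream"
  is_indel <- !is.na(ref) && !is.na(alt) && nchar(ref) != nchar(alt)
  if (is_indel)
    return(list(region = region, var_type = "indel"))
  if (region == "upstream" || is.null(cds) || is.na(ref) || is.na(alt))
    return(list(region = region, var_type = "SNP_unclassified"))
  offset <- if (strand == "+") position - gene_start
            else gene_end - position
  base_ref <- toupper(ref)
  base_alt <- toupper(alt)
  if (strand == "-") {
    base_ref <- unname(.complement(base_ref))
    base_alt <- unname(.complement(base_alt))
  }
  cds <- toupper(gsub("U", "T", cds))
  if (offset >= nchar(cds))
    return(list(region = region, var_type = "SNP_unclassified"))
  codon_idx <- offset %/% 3
  within <- offset %% 3 + 1
  codon <- substr(cds, codon_idx * 3 + 1, codon_idx * 3 + 3)
  if (substr(codon, within, within) != gsub("U", "T", base_ref))
    stop("reference allele does not match the coding sequence at offset ",
         offset)
  mutated <- codon
  substr(mutated, within, within) <- gsub("U", "T", base_alt)
  if (is.na(.GENCODE[codon]) || is.na(.GENCODE[mutated]))
    return(list(region = region, var_type = "SNP_unclassified"))
  type <- if (.GENCODE[codon] == .GENCODE[mutated]) "SNP_synonymous"
          else "SNP_nonsynonymous"
  list(region = region, var_type = type)
}

#' Per-gene variant summaries
#'
#' @param vars variant data.frame with `gene_id`, `var_type`, `region`
#'   columns (region/type already classified; see [classify_variant()]).
#'   Positions are interpreted per gene.
#' @param genes gene table (for gene lengths).
#' @param hits defense annotations (for family labels).
#' @param min_freq,min_reads high-frequency thresholds used to flag genes.
#' @param upstream_bp upstream window included in the analyzed length.
#' @return data.frame per gene: family, analyzed_length_bp, n_snp,
#'   n_indel, density_kb, has_high_frequency_variant, and fractions by
#'   type and region.
#' @export
gene_variant_summary <- function(vars, genes, hits, min_freq = 0.25,
                                 min_reads = 10, upstream_bp = 200) {
  glen <- genes$end - genes$start + 1
  names(glen) <- genes$gene_id
  fam <- hits$family[match(genes$gene_id, hits$gene_id)]
  names(fam) <- genes$gene_id
  hf <- filter_high_frequency(vars, min_freq, min_reads)
  out <- do.call(rbind, lapply(genes$gene_id, function(g) {
    v <- vars[vars$gene_id == g, , drop = FALSE]
    n_snp <- sum(grepl("^SNP", v$var_type))
    n_indel <- sum(v$var_type == "indel")
    alen <- unname(glen[g]) + upstream_bp
    n <- nrow(v)
    data.frame(
      gene_id = g, family = unname(fam[g]),
      analyzed_length_bp = alen, n_snp = n_snp, n_indel = n_indel,
      density_kb = density_per_kb(n_snp + n_indel, alen),
      has_high_frequency_variant = any(hf$gene_id == g),
      frac_synonymous = if (n > 0)
        sum(v$var_type == "SNP_synonymous") / n else NA_real_,
      frac_nonsynonymous = if (n > 0)
        sum(v$var_type == "SNP_nonsynonymous") / n else NA_real_,
      frac_unclassified = if (n > 0)
        sum(v$var_type == "SNP_unclassified") / n else NA_real_,
      frac_indel = if (n > 0) n_indel / n else NA_real_,
      frac_gene_body = if (n > 0)
        sum(v$region == "gene_body") / n else NA_real_,
      frac_upstream = if (n > 0)
        sum(v$region == "upstream") / n else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Family-level O/E of high-frequency variant carriage
#'
#' For each defense family with at least `min_genes` analyzed genes, the
#' expected number of genes carrying a high-frequency variant is the
#' family size times the overall (marginal) flagged fraction across all
#' analyzed defense genes. Reports O/E per family, flags families with
#' O/E >= `highlight`, and a global two-sided chi-square test on the
#' family x (flagged / not flagged) table.
#'
#' @param summaries data.frame from [gene_variant_summary()] (columns
#'   `family` and `has_high_frequency_variant`); genes without a family
#'   are dropped.
#' @param min_genes minimum genes per family (default 10).
#' @param highlight O/E threshold to flag (default 1.5).
#' @return list with `cells` (per family: n_genes, observed, expected,
#'   oe, flagged) and `chisq` (statistic, df, p_value).
#' @export
family_variant_oe <- function(summaries, min_genes = 10,
                              highlight = 1.5) {
  d <- summaries[!is.na(summaries$family), , drop = FALSE]
  sizes <- table(d$family)
  keep <- names(sizes)[sizes >= min_genes]
  if (length(keep) == 0)
    stop("no family passes the minimum gene count of ", min_genes)
  d <- d[d$family %in% keep, , drop = FALSE]
  overall <- mean(d$has_high_frequency_variant)
  if (overall == 0) {
    warning("no high-frequency variants: all O/E undefined")
    return(list(cells = data.frame(
      family = keep, n_genes = as.vector(sizes[keep]),
      observed = 0L, expected = 0, oe = NA_real_, flagged = FALSE),
      chisq = NULL))
  }
  cells <- do.call(rbind, lapply(sort(keep), function(f) {
    sub <- d[d$family == f, , drop = FALSE]
    obs <- sum(sub$has_high_frequency_variant)
    exp <- nrow(sub) * overall
    data.frame(family = f, n_genes = nrow(sub), observed = obs,
               expected = exp, oe = obs / exp,
               flagged = obs / exp >= highlight,
               stringsAsFactors = FALSE)
  }))
  tab <- rbind(flagged = cells$observed,
               unflagged = cells$n_genes - cells$observed)
  chisq <- if (ncol(tab) >= 2) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
  } else NULL
  rownames(cells) <- NULL
  list(cells = cells, chisq = chisq)
}
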