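# Defense islands: maximal arrays of defense units (genes or systems) on
# one contig, with <= gap_max intervening genes between consecutive units,
# at least min_units units and at least min_families distinct defense
# families. The island span runs from the first to the last defense member
# and includes the intervening non-defensive genes.

#' Call defense islands from gene order
#'
#' Units are either individual defense genes (`unit = "gene"`) or defense
#' systems plus solitary genes (`unit = "system"`; a system's position is
#' the ordinal of its first member gene and its family counts once).
#' Chains are maximal by construction: consecutive defense units separated
#' by more than `gap_max` intervening genes start a new chain. Genes with
#' family `"unknown"` (or NA) count toward `min_units` but not toward
#' `min_families`.
#'
#' @param genes gene table with ordinals.
#' @param hits defense annotations.
#' @param gap_max maximum intervening (strictly between) genes between
#'   consecutive units (default 10).
#' @param min_units minimum defense units per island (default 5).
#' @param min_families minimum distinct defense families (default 3).
#' @param unit `"gene"` or `"system"`.
#' @param assembly result of [assemble_systems()], required for
#'   `unit = "system"`.
#' @return data.frame of islands: island_id, mag_id, contig_id,
#'   first_ordinal, last_ordinal, n_units, n_families, length_genes (all
#'   genes in the span), families and member_gene_ids (comma-separated).
#' @export
call_islands <- function(genes, hits, gap_max = 10, min_units = 5,
                         min_families = 3, unit = c("gene", "system"),
                         assembly = NULL) {
  unit <- match.arg(unit)
  j <- match(hits$gene_id, genes$gene_id)
  h <- cbind(hits[!is.na(j), , drop = FALSE],
             genes[j[!is.na(j)], c("mag_id", "contig_id", "ordinal")])
  empty <- data.frame(
    island_id = character(0), mag_id = character(0),
    contig_id = character(0), first_ordinal = integer(0),
    last_ordinal = integer(0), n_units = integer(0),
    n_families = integer(0), length_genes = integer(0),
    families = character(0), member_gene_ids = character(0))
  if (nrow(h) == 0) return(empty)

  if (unit == "system") {
    if (is.null(assembly))
      stop("unit = 'system' requires an assembly")
    st <- assembly$gene_status
    h$system_id <- st$system_id[match(h$gene_id, st$gene_id)]
    h$status <- st$status[match(h$gene_id, st$gene_id)]
    # one unit per system (position = first member) or per solitary gene
    units <- do.call(rbind, lapply(
      split(h, ifelse(h$status == "solitary" | is.na(h$system_id),
                      paste0("g:", h$gene_id), paste0("s:", h$system_id))),
      function(d) {
        d <- d[order(d$ordinal), , drop = FALSE]
        data.frame(mag_id = d$mag_id[1], contig_id = d$contig_id[1],
                   ordinal = d$ordinal[1], last_ord = max(d$ordinal),
                   family = d$family[1],
                   gene_ids = paste(d$gene_id, collapse = ","),
                   stringsAsFactors = FALSE)
      }))
  } else {
    units <- data.frame(mag_id = h$mag_id, contig_id = h$contig_id,
                        ordinal = h$ordinal, last_ord = h$ordinal,
                        family = h$family, gene_ids = h$gene_id,
                        stringsAsFactors = FALSE)
  }

  out <- list()
  for (key in unique(paste(units$mag_id, units$contig_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    d <- units[units$mag_id == parts[1] & units$contig_id == parts[2], ,
               drop = FALSE]
    d <- d[order(d$ordinal), , drop = FALSE]
    # gap between unit k and k+1: genes strictly between the end of one
    # unit and the start of the next
    gap <- d$ordinal[-1] - d$last_ord[-nrow(d)] - 1L
    chain <- cumsum(c(0L, as.integer(gap > gap_max)))
    for (cid in unique(chain)) {
      sel <- d[chain == cid, , drop = FALSE]
      fams <- unique(sel$family)
      fams <- fams[!is.na(fams) & fams != "unknown"]
      if (nrow(sel) >= min_units && length(fams) >= min_families) {
        first <- min(sel$ordinal)
        last <- max(sel$last_ord)
        out[[length(out) + 1L]] <- data.frame(
          island_id = sprintf("%s|%s|DI%d", parts[1], parts[2],
                              length(out) + 1L),
          mag_id = parts[1], contig_id = parts[2],
          first_ordinal = first, last_ordinal = last,
          n_units = nrow(sel), n_families = length(fams),
          length_genes = last - first + 1L,
          families = paste(sort(fams), collapse = ","),
          member_gene_ids = paste(
            unlist(strsplit(sel$gene_ids, ",")), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tag defense genes with island membership
#'
#' @param genes gene table with ordinals.
#' @param hits defense annotations.
#' @param islands data.frame from [call_islands()].
#' @return `hits` with `mag_id`, `contig_id`, `ordinal`, logical
#'   `in_island` and `island_id` columns added (a gene is inside when its
#'   ordinal lies within an island span on the same contig).
#' @export
tag_island_membership <- function(genes, hits, islands) {
  j <- match(hits$gene_id, genes$gene_id)
  h <- cbind(hits, genes[j, c("mag_id", "contig_id", "ordinal")])
  h$in_island <- FALSE
  h$island_id <- NA_character_
  for (i in seq_len(nrow(islands))) {
    sel <- h$mag_id == islands$mag_id[i] &
      h$contig_id == islands$contig_id[i] &
      h$ordinal >= islands$first_ordinal[i] &
      h$ordinal <= islands$last_ordinal[i]
    h$in_island[sel] <- TRUE
    h$island_id[sel] <- islands$island_id[i]
  }
  rownames(h) <- NULL
  h
}

#' Summarize called islands
#'
#' @param islands data.frame from [call_islands()].
#' @param mags MAG metadata (cohort denominator for densities).
#' @return list with `lengths` (island length in genes, plus habitat when
#'   available), `density` (per MAG: islands per kb, zero for island-free
#'   MAGs), and `defense_content_fraction` (defense genes in islands over
#'   all genes in island spans; the complement is the non-defensive
#'   "NA" content).
#' @export
island_summary <- function(islands, mags) {
  habitat <- mags$habitat[match(islands$mag_id, mags$mag_id)]
  lengths <- data.frame(island_id = islands$island_id,
                        mag_id = islands$mag_id,
                        habitat = habitat,
                        length_genes = islands$length_genes,
                        stringsAsFactors = FALSE)
  n_isl <- vapply(mags$mag_id, function(m) sum(islands$mag_id == m),
                  numeric(1))
  dens <- data.frame(mag_id = mags$mag_id, habitat = mags$habitat,
                     n_islands = as.integer(n_isl),
                     density_kb = density_per_kb(n_isl, mags$size_bp),
                     stringsAsFactors = FALSE)
  n_def <- vapply(strsplit(islands$member_gene_ids, ","), length,
                  integer(1))
  frac <- if (nrow(islands) > 0)
    sum(n_def) / sum(islands$length_genes) else NA_real_
  list(lengths = lengths, density = dens,
       defense_content_fraction = frac)
}

#' Complete/incomplete skew ratio
#'
#' (genes in complete systems - genes in incomplete systems) /
#' (genes in complete systems + genes in incomplete systems), computed
#' over a set of defense genes (typically those inside islands). Solitary
#' genes count toward the incomplete class by default.
#'
#' @param status character vector of per-gene statuses
#'   (complete/incomplete/solitary) as produced by [assemble_systems()].
#' @param include_solitary count solitary genes as incomplete
#'   (default TRUE); when FALSE they are dropped.
#' @return skew ratio in [-1, 1], or NA (with a warning) when no genes
#'   remain.
#' @export
skew_ratio <- function(status, include_solitary = TRUE) {
  if (!include_solitary) status <- status[status != "solitary"]
  cc <- sum(status == "complete")
  ii <- sum(status %in% c("incomplete", "solitary"))
  if (cc + ii == 0) {
    warning("skew ratio undefined: no classified genes")
    return(NA_real_)
  }
  (cc - ii) / (cc + ii)
}

# Sample odds ratio with Haldane-Anscombe 0.5 correction on zero cells.
.odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Family enrichment inside defense islands
#'
#' Per-family 2x2 Fisher test of defense genes inside vs outside islands:
#' `[family f vs other families] x [in island vs out]`. The odds ratio is
#' the sample OR with a 0.5 correction applied only when a cell is zero;
#' p-values are two-sided Fisher exact, with Benjamini-Hochberg adjustment
#' across families.
#'
#' @param tagged data.frame of defense genes with columns `family` and
#'   `in_island` (see [tag_island_membership()]).
#' @return data.frame per family: counts, odds_ratio, p_value, q_value.
#' @export
family_island_enrichment <- function(tagged) {
  fams <- sort(unique(tagged$family))
  fams <- fams[!is.na(fams)]
  rows <- lapply(fams, function(f) {
    a <- sum(tagged$family == f & tagged$in_island)
    b <- sum(tagged$family != f & tagged$in_island)
    c <- sum(tagged$family == f & !tagged$in_island)
    d <- sum(tagged$family != f & !tagged$in_island)
    if (a + c == 0) return(NULL)  # family absent genome-wide
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2),
                            alternative = "two.sided")$p.value
    data.frame(family = f, in_family = a, in_other = b, out_family = c,
               out_other = d, odds_ratio = .odds_ratio(a, b, c, d),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no families to test")
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}
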