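#' Tag genes with MGE membership
#'
#' A gene is assigned to an MGE class when its span overlaps a
#' conflict-filtered interval of that class by at least one bp (optionally
#' widened by `flank_bp` on each side); otherwise it is labeled
#' `"chromosome"`. If a gene overlaps intervals of several classes (the
#' intervals themselves never overlap after conflict filtering, but a gene
#' can bridge two), the class with the largest overlap wins.
#'
#' @param genes gene table.
#' @param mge conflict-filtered MGE intervals (see
#'   [resolve_mge_conflicts()]).
#' @param flank_bp extend each interval by this many bp on both sides
#'   (default 0).
#' @return `genes` with an `mge_class` column.
#' @export
tag_mge_membership <- function(genes, mge, flank_bp = 0) {
  genes$mge_class <- "chromosome"
  if (nrow(mge) == 0) return(genes)
  for (ctg in unique(mge$contig_id)) {
    gi <- which(genes$contig_id == ctg)
    if (length(gi) == 0) next
    mi <- which(mge$contig_id == ctg)
    gr <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    ir <- IRanges::IRanges(pmax(1, mge$start[mi] - flank_bp),
                           mge$end[mi] + flank_bp)
    ov <- IRanges::findOverlaps(gr, ir)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(gr[qh], ir[sh]))
    best <- vapply(split(seq_along(qh), qh), function(k)
      k[which.max(w[k])], integer(1))
    genes$mge_class[gi[qh[best]]] <- mge$mge_class[mi[sh[best]]]
  }
  genes
}

#' Defense-gene density per genomic context
#'
#' Defense genes per kb within each MGE class and within the chromosome
#' excluding MGE spans, per MAG. Contexts with zero bp in a MAG are
#' omitted for that MAG.
#'
#' @param genes gene table tagged with [tag_mge_membership()].
#' @param hits defense annotations.
#' @param mge conflict-filtered MGE intervals.
#' @param mags MAG metadata (size_bp denominator).
#' @return data.frame: mag_id, habitat, context, n_defense_genes,
#'   context_bp, density_kb.
#' @export
mge_defense_density <- function(genes, hits, mge, mags) {
  if (!"mge_class" %in% names(genes))
    stop("genes must be tagged with tag_mge_membership() first")
  def <- genes[genes$gene_id %in% hits$gene_id, , drop = FALSE]
  mge$mag_id <- genes$mag_id[match(mge$contig_id, genes$contig_id)]
  rows <- list()
  for (i in seq_len(nrow(mags))) {
    m <- mags$mag_id[i]
    msub <- mge[!is.na(mge$mag_id) & mge$mag_id == m, , drop = FALSE]
    class_bp <- vapply(.MGE_CLASSES, function(cl)
      sum(msub$end[msub$mge_class == cl] -
            msub$start[msub$mge_class == cl] + 1), numeric(1))
    chrom_bp <- mags$size_bp[i] - sum(class_bp)
    if (chrom_bp <= 0)
      stop("MGE spans exceed MAG size for ", m, " (inconsistent annotation)")
    ctx_bp <- c(class_bp, chromosome = chrom_bp)
    for (ctx in names(ctx_bp)) {
      if (ctx_bp[[ctx]] <= 0) next
      n <- sum(def$mag_id == m & def$mge_class == ctx)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_id = m, habitat = mags$habitat[i], context = ctx,
        n_defense_genes = n, context_bp = unname(ctx_bp[[ctx]]),
        density_kb = density_per_kb(n, ctx_bp[[ctx]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Family x MGE observed/expected enrichment
#'
#' For each defense family f and genomic category m (MGE classes plus
#' chromosome), the expected count under independence is
#' `N_f x (N_.m / N_..)`: the family total times the marginal fraction of
#' all defense genes assigned to that category. Reports O/E per cell
#' (cells with zero observed counts are flagged `absent`) and a global
#' two-sided chi-square test of independence computed over cells with
#' expected >= `min_expected`.
#'
#' @param tagged_hits data.frame of defense genes with columns `family`
#'   and `mge_class`.
#' @param min_expected cells with expected below this are excluded from
#'   the chi-square statistic (default 1).
#' @return list with `cells` (family, category, observed, expected, oe,
#'   chisq_contrib, absent) and `chisq` (statistic, df, p_value).
#' @export
mge_family_oe <- function(tagged_hits, min_expected = 1) {
  tab <- table(tagged_hits$family, tagged_hits$mge_class)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 families and >= 2 categories with nonzero totals")
  N <- sum(tab)
  rowt <- rowSums(tab)
  colt <- colSums(tab)
  if (any(rowt == 0) || any(colt == 0)) stop("degenerate margins")
  expected <- outer(rowt, colt) / N
  cells <- data.frame(
    family = rep(rownames(tab), times = ncol(tab)),
    category = rep(colnames(tab), each = nrow(tab)),
    observed = as.vector(tab),
    expected = as.vector(expected),
    stringsAsFactors = FALSE)
  cells$oe <- cells$observed / cells$expected
  cells$chisq_contrib <- (cells$observed - cells$expected)^2 / cells$expected
  cells$absent <- cells$observed == 0
  use <- cells$expected >= min_expected
  stat <- sum(cells$chisq_contrib[use])
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(cells = cells,
       chisq = list(statistic = stat, df = df,
                    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                    n_cells_used = sum(use)))
}

# Enumerate unordered defense-gene pairs on one contig with at most
# pair_gap intervening genes. ord must be sorted ascending. Returns a
# two-column index matrix.
.enumerate_pairs <- function(ord, pair_gap) {
  n <- length(ord)
  if (n < 2) return(NULL)
  # two-pointer scan: for each i, the largest k with gap <= pair_gap
  upper <- findInterval(ord + pair_gap + 1L, ord)
  cnt <- pmax(upper - seq_len(n), 0L)
  if (sum(cnt) == 0) return(NULL)
  i <- rep.int(seq_len(n), cnt)
  k <- sequence(cnt) + i
  cbind(i, k)
}

#' Family-pair colocalization odds ratios
#'
#' Enumerates all unordered pairs of defense genes on the same contig
#' separated by at most `pair_gap` intervening genes, excluding pairs
#' whose genes belong to the same defense system (which are colocalized
#' by construction and would inflate the counts). Each remaining pair is
#' classified as inside (both genes within the span of one island) or
#' outside; straddling pairs count as outside by default. For every
#' unordered family pair the 2x2 table
#' `[pair is {a,b} vs any other pair] x [inside vs outside]` yields a
#' sample odds ratio (0.5 correction on zero cells) and a two-sided
#' Fisher exact p-value.
#'
#' @param genes gene table with ordinals.
#' @param hits defense annotations (with `system_id` when systems are
#'   known; genes with unknown family are excluded from per-pair
#'   statistics but retained in totals).
#' @param islands data.frame from [call_islands()].
#' @param pair_gap maximum intervening genes within a pair (default 5).
#' @param straddle how to treat pairs with exactly one gene inside an
#'   island: `"outside"` (default) or `"drop"`.
#' @return list with `pairs` (one row per qualifying pair) and
#'   `associations` (per family pair: counts, odds_ratio, p_value).
#' @export
family_pair_colocalization <- function(genes, hits, islands, pair_gap = 5,
                                       straddle = c("outside", "drop")) {
  straddle <- match.arg(straddle)
  tagged <- tag_island_membership(genes, hits, islands)
  if (!"system_id" %in% names(tagged))
    tagged$system_id <- NA_character_
  pair_rows <- lapply(
    split(tagged, paste(tagged$mag_id, tagged$contig_id, sep = "\r")),
    function(d) {
      d <- d[order(d$ordinal), , drop = FALSE]
      idx <- .enumerate_pairs(d$ordinal, pair_gap)
      if (is.null(idx)) return(NULL)
      i <- idx[, 1]; k <- idx[, 2]
      same_system <- !is.na(d$system_id[i]) & !is.na(d$system_id[k]) &
        d$system_id[i] == d$system_id[k]
      both_in <- d$in_island[i] & d$in_island[k] &
        !is.na(d$island_id[i]) & !is.na(d$island_id[k]) &
        d$island_id[i] == d$island_id[k]
      one_in <- xor(d$in_island[i], d$in_island[k])
      keep <- !same_system
      if (straddle == "drop") keep <- keep & !one_in
      if (!any(keep)) return(NULL)
      data.frame(
        gene_a = d$gene_id[i][keep], gene_b = d$gene_id[k][keep],
        family_a = d$family[i][keep], family_b = d$family[k][keep],
        inside = both_in[keep], stringsAsFactors = FALSE)
    })
  pair_rows <- Filter(Negate(is.null), pair_rows)
  if (length(pair_rows) == 0)
    return(list(pairs = NULL, associations = NULL))
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  known <- !is.na(pairs$family_a) & pairs$family_a != "unknown" &
    !is.na(pairs$family_b) & pairs$family_b != "unknown"
  kp <- pairs[known, , drop = FALSE]
  key <- paste(pmin(kp$family_a, kp$family_b),
               pmax(kp$family_a, kp$family_b), sep = "\r")
  n_in <- sum(pairs$inside)
  n_out <- sum(!pairs$inside)
  assoc <- do.call(rbind, lapply(unique(key), function(kk) {
    fams <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    sel <- key == kk
    a <- sum(kp$inside[sel])
    c <- sum(!kp$inside[sel])
    b <- n_in - a
    d <- n_out - c
    undefined <- n_out == 0 || n_in == 0
    p <- if (undefined) NA_real_ else
      stats::fisher.test(matrix(c(a, b, c, d), 2),
                         alternative = "two.sided")$p.value
    data.frame(family_a = fams[1],
               family_b = fams[length(fams)],
               pairs_in = a, other_pairs_in = b, pairs_out = c,
               other_pairs_out = d,
               odds_ratio = if (undefined) NA_real_ else
                 .odds_ratio(a, b, c, d),
               p_value = p, undefined = undefined,
               stringsAsFactors = FALSE)
  }))
  if (any(assoc$undefined))
    warning("odds ratios undefined: no pairs on one side of the ",
            "island split")
  rownames(assoc) <- NULL
  list(pairs = pairs, associations = assoc)
}
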