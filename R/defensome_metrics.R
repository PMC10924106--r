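#' Per-kilobase density
#'
#' @param count number of features (systems, genes, islands...).
#' @param size_bp denominator length in bp; must be positive.
#' @return count per kb.
#' @export
density_per_kb <- function(count, size_bp) {
  if (any(size_bp <= 0)) stop("size_bp must be positive")
  count / (size_bp / 1000)
}

#' Per-MAG defensome profiles
#'
#' @param mags MAG metadata data.frame (mag_id, habitat, size_bp, ...).
#' @param assembly result of [assemble_systems()].
#' @param genes gene table (to attribute defense genes to MAGs).
#' @param complete_only count only complete systems in `n_systems`
#'   (default TRUE; incomplete chains are reported separately).
#' @return data.frame with one row per MAG: system and gene counts and
#'   per-kb densities.
#' @export
defensome_profiles <- function(mags, assembly, genes,
                               complete_only = TRUE) {
  sys <- assembly$systems
  st <- assembly$gene_status
  st$mag_id <- genes$mag_id[match(st$gene_id, genes$gene_id)]
  n_sys <- vapply(mags$mag_id, function(m) {
    s <- sys[sys$mag_id == m, , drop = FALSE]
    if (complete_only) sum(s$completeness == "complete") else nrow(s)
  }, numeric(1))
  n_genes <- vapply(mags$mag_id, function(m)
    sum(st$mag_id == m, na.rm = TRUE), numeric(1))
  data.frame(
    mag_id = mags$mag_id,
    habitat = mags$habitat,
    size_bp = mags$size_bp,
    n_systems = as.integer(n_sys),
    n_defense_genes = as.integer(n_genes),
    density_systems_kb = density_per_kb(n_sys, mags$size_bp),
    density_genes_kb = density_per_kb(n_genes, mags$size_bp),
    stringsAsFactors = FALSE)
}

#' Family prevalence across MAGs
#'
#' Percentage of MAGs harboring at least one (complete) system of each
#' defense family.
#'
#' @param assembly result of [assemble_systems()].
#' @param mags MAG metadata data.frame (defines the cohort denominator).
#' @param complete_only when TRUE (default) only complete systems count;
#'   when FALSE any defense gene of the family counts.
#' @param genes gene table, required when `complete_only = FALSE`.
#' @return data.frame family / prevalence_pct.
#' @export
family_prevalence <- function(assembly, mags, complete_only = TRUE,
                              genes = NULL) {
  n_mags <- nrow(mags)
  if (n_mags == 0) stop("empty MAG cohort")
  if (complete_only) {
    sys <- assembly$systems
    sys <- sys[sys$completeness == "complete", , drop = FALSE]
    tab <- unique(sys[, c("mag_id", "family")])
  } else {
    if (is.null(genes))
      stop("genes required for gene-level prevalence")
    st <- assembly$gene_status
    st$mag_id <- genes$mag_id[match(st$gene_id, genes$gene_id)]
    tab <- unique(st[, c("mag_id", "family")])
  }
  fams <- sort(unique(tab$family))
  data.frame(
    family = fams,
    prevalence_pct = vapply(fams, function(f)
      100 * sum(tab$family == f) / n_mags, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation of defensome abundance/density with genome size
#'
#' Two-sided Spearman rank correlations (average ranks on ties) of the
#' per-MAG system count vs size and system density vs size.
#'
#' @param profiles data.frame from [defensome_profiles()].
#' @param count_col,density_col columns to correlate against `size_bp`.
#' @return data.frame with rows `count_vs_size` and `density_vs_size`
#'   (rho, p_value, n, constant flag).
#' @export
size_correlation <- function(profiles, count_col = "n_systems",
                             density_col = "density_systems_kb") {
  if (nrow(profiles) < 4) stop("need >= 4 MAGs for a rank correlation")
  one <- function(y, label) {
    x <- profiles$size_bp
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(data.frame(comparison = label, rho = NA_real_,
                        p_value = NA_real_, n = length(x),
                        constant = TRUE, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE,
                      alternative = "two.sided"))
    data.frame(comparison = label, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(x), constant = FALSE,
               stringsAsFactors = FALSE)
  }
  rbind(one(profiles[[count_col]], "count_vs_size"),
        one(profiles[[density_col]], "density_vs_size"))
}

#' Phylogenetic depth of a rooted tree
#'
#' Mean root-to-tip distance (branch-length path sum from the root to each
#' leaf, averaged over leaves). For a rooted tree this equals the diagonal
#' mean of the phylogenetic variance-covariance matrix.
#'
#' @param tree an [ape::phylo] object or path to a Newick file.
#' @param midpoint_root when TRUE, unrooted input is midpoint-rooted
#'   (requires \pkg{phangorn}); otherwise unrooted input is an error.
#' @return mean root-to-tip distance (substitutions/site).
#' @export
phylo_depth <- function(tree, midpoint_root = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) {
    if (!midpoint_root)
      stop("tree is unrooted; set midpoint_root = TRUE to midpoint-root")
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("midpoint rooting requires the phangorn package")
    tree <- phangorn::midpoint(tree)
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  depths <- ape::node.depth.edgelength(tree)
  mean(depths[seq_len(ape::Ntip(tree))])
}

#' Stepwise regression of defensome abundance on size and depth
#'
#' Bidirectional stepwise selection by AIC, starting from the
#' intercept-only model, of per-MAG defensome abundance on standardized
#' genome size and phylogenetic depth.
#'
#' @param df data.frame with the response column plus `size` and `depth`.
#' @param response name of the response column (defensome gene or system
#'   count per MAG).
#' @param criterion `"AIC"` (default) or `"BIC"`; BIC penalizes entry more
#'   strongly and admits spurious predictors far less often under the
#'   null.
#' @return list with `selected` (character vector of retained predictors),
#'   `coefficients`, `partial_r2` (per selected term), and the fitted
#'   model.
#' @export
stepwise_defensome <- function(df, response = "n_defense_genes",
                               criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (nrow(df) < 10) stop("need >= 10 MAGs for the stepwise regression")
  d <- data.frame(y = df[[response]],
                  size = as.numeric(scale(df$size)),
                  depth = as.numeric(scale(df$depth)))
  if (abs(stats::cor(d$size, d$depth)) > 0.999)
    warning("size and depth are collinear (|r| > 0.999)")
  null_fit <- stats::lm(y ~ 1, data = d)
  fit <- stats::step(null_fit, scope = list(lower = ~1,
                                            upper = ~ size + depth),
                     direction = "both", trace = 0,
                     k = if (criterion == "BIC") log(nrow(d)) else 2)
  selected <- setdiff(names(stats::coef(fit)), "(Intercept)")
  # partial R^2 of each retained term: drop it and compare residual SS
  partial_r2 <- vapply(selected, function(term) {
    reduced <- stats::update(fit, stats::as.formula(paste(". ~ . -", term)))
    (sum(stats::resid(reduced)^2) - sum(stats::resid(fit)^2)) /
      sum(stats::resid(reduced)^2)
  }, numeric(1))
  list(selected = selected, coefficients = stats::coef(fit),
       partial_r2 = partial_r2, model = fit)
}

#' Habitat (group) comparison of defensome densities
#'
#' Pairwise two-sided Mann-Whitney-Wilcoxon tests between groups, plus
#' boxplot descriptive statistics (median, quartiles, 1.5 x IQR whiskers)
#' per group. Groups with fewer than `min_n` observations are excluded
#' with a warning.
#'
#' @param values numeric vector (e.g. density per MAG per kb).
#' @param groups group label per value (habitat, sub-habitat, geography).
#' @param min_n minimum group size (default 3).
#' @return list with `tests` (group_a, group_b, U, p_value) and
#'   `box_stats` (per group: n, whisker_low, q1, median, q3, whisker_high).
#' @export
habitat_compare <- function(values, groups, min_n = 3) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    warning("group(s) excluded with n < ", min_n, ": ",
            paste(small, collapse = ","))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- groups[keep]
  }
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop("need >= 2 groups after exclusion")
  tests <- list()
  for (i in seq_len(length(gl) - 1)) {
    for (j in seq(i + 1, length(gl))) {
      wt <- suppressWarnings(
        stats::wilcox.test(values[groups == gl[i]],
                           values[groups == gl[j]],
                           alternative = "two.sided"))
      tests[[length(tests) + 1L]] <- data.frame(
        group_a = gl[i], group_b = gl[j],
        U = unname(wt$statistic), p_value = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  box <- do.call(rbind, lapply(gl, function(g) {
    v <- values[groups == g]
    bs <- grDevices::boxplot.stats(v)$stats
    data.frame(group = g, n = length(v), whisker_low = bs[1], q1 = bs[2],
               median = bs[3], q3 = bs[4], whisker_high = bs[5],
               stringsAsFactors = FALSE)
  }))
  list(tests = do.call(rbind, tests), box_stats = box)
}
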