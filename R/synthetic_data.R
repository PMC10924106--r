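# Seeded synthetic cohorts with ground truth. The generator emulates the
# statistical structure the defensome analyses assume: gene-order
# annotations with planted defense islands (satisfying the island
# definition exactly), planted complete systems, background solitary
# defense genes, MGE intervals with configurable defense-carriage
# multipliers, variant tables with per-family high-frequency enrichment,
# and codon pairs evolved at a known omega. A single integer seed drives a
# hierarchical stream (per-MAG substreams), so reruns are bit-identical
# and cohort-size changes do not reshuffle earlier MAGs.

#' Default defense-family catalog
#'
#' Twenty families with abundance weights decaying roughly log-uniformly.
#' Odd-indexed families are single-gene systems (one mandatory gene,
#' MG = SG = 1); even-indexed families are two-gene systems (two mandatory
#' genes, one accessory, MG = SG = 2, d_max = 3).
#'
#' @return data.frame with columns family, weight, type.
#' @export
default_family_catalog <- function() {
  fams <- c("RM", "CBASS", "CRISPR-Cas", "Gabija", "Hachiman", "Thoeris",
            "Zorya", "AbiEii", "BREX", "Druantia", "Wadjet", "Lamassu",
            "Septu", "Shedu", "Kiwa", "PsyrTA", "ShosTA", "DISARM",
            "Retron", "SoFIC")
  data.frame(family = fams,
             weight = exp(seq(log(1), log(0.05), length.out = length(fams))),
             type = rep(c("single", "double"), length.out = length(fams)),
             stringsAsFactors = FALSE)
}

#' Rules matching the default family catalog
#'
#' @param catalog data.frame from [default_family_catalog()].
#' @return a [defense_rules()] object.
#' @export
default_rules <- function(catalog = default_family_catalog()) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    f <- catalog$family[i]
    if (catalog$type[i] == "single") {
      data.frame(family = f, gene_name = paste0(f, "_A"),
                 role = "mandatory", mg = 1L, sg = 1L, d_max = 0L)
    } else {
      data.frame(family = f,
                 gene_name = paste0(f, c("_A", "_B", "_C")),
                 role = c("mandatory", "mandatory", "accessory"),
                 mg = 2L, sg = 2L, d_max = 3L)
    }
  })
  defense_rules(do.call(rbind, rows))
}

#' Simulation configuration
#'
#' @param seed master seed (integer).
#' @param n_mags number of MAGs.
#' @param contigs_per_mag contigs per MAG.
#' @param genes_per_contig genes per contig.
#' @param mean_gene_bp mean gene length (bp).
#' @param intergenic_bp fixed intergenic spacing (bp).
#' @param catalog defense-family catalog (see [default_family_catalog()]).
#' @param background_rate per-gene probability of a background (solitary)
#'   defense gene.
#' @param islands_per_mag planted defense islands per MAG.
#' @param island_units_range range of defense genes per island
#'   (min 5 enforced).
#' @param island_gap_range range of intervening genes between consecutive
#'   island members (max 10 enforced).
#' @param min_island_families minimum distinct families per planted island.
#' @param systems_per_mag planted complete two-gene systems per MAG.
#' @param strict_spacing keep every planted feature and background gene at
#'   least `gap_max + 1 = 11` intervening genes from any other, so planted
#'   islands are recovered with exact boundaries.
#' @param mge_rate expected MGE intervals per contig, named by class.
#' @param mge_len_genes range of MGE interval lengths (genes).
#' @param mge_multiplier per-class defense-carriage multiplier: sampling
#'   weight of background defense genes falling inside that class
#'   (1 = uniform placement).
#' @param habitats habitat labels cycled over MAGs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_mags = 20,
                       contigs_per_mag = 2,
                       genes_per_contig = 150,
                       mean_gene_bp = 900,
                       intergenic_bp = 100,
                       catalog = default_family_catalog(),
                       background_rate = 0.02,
                       islands_per_mag = 2,
                       island_units_range = c(5, 8),
                       island_gap_range = c(0, 3),
                       min_island_families = 3,
                       systems_per_mag = 2,
                       strict_spacing = TRUE,
                       mge_rate = c(plasmid = 0.5, prophage = 0.5,
                                    ICE_IME = 0.3, integron = 0.1),
                       mge_len_genes = c(8, 20),
                       mge_multiplier = c(plasmid = 1, prophage = 1,
                                          ICE_IME = 1, integron = 1),
                       habitats = c("soil", "marine", "human_gut")) {
  cfg <- as.list(environment())
  stopifnot(cfg$background_rate >= 0, all(cfg$mge_rate >= 0),
            all(cfg$mge_multiplier >= 1 | cfg$mge_multiplier >= 0),
            cfg$island_units_range[1] >= 5,
            cfg$island_gap_range[2] <= 10)
  structure(cfg, class = "sim_config")
}

.mag_seed <- function(seed, m) {
  as.integer((as.numeric(seed) * 1000003 + m * 7919) %% 2147483629)
}

# Place feature blocks (islands, systems, background singletons) on one
# contig of n genes with >= buffer intervening genes between features.
.place_blocks <- function(n, spans, buffer) {
  k <- length(spans)
  required <- sum(spans) + buffer * (k + 1)
  if (required > n)
    stop("infeasible density: ", required, " gene slots needed, ",
         n, " available")
  slack <- n - required
  extra <- if (slack > 0)
    as.vector(stats::rmultinom(1, slack, rep(1, k + 1))) else rep(0L, k + 1)
  gaps <- buffer + extra
  starts <- integer(k)
  cursor <- 0L
  for (i in seq_len(k)) {
    cursor <- cursor + gaps[i]
    starts[i] <- cursor            # 0-based ordinal of block start
    cursor <- cursor + spans[i]
  }
  starts
}

#' Simulate a cohort of annotated MAGs with ground truth
#'
#' @param config a [sim_config()] object.
#' @return list with `genes`, `hits`, `mge`, `mags` (the reader-level
#'   tables), `rules` (matching [default_rules()]) and `truth` (planted
#'   islands, systems, background genes, per-gene MGE class).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  genes_l <- list(); hits_l <- list(); mge_l <- list()
  mags_l <- list(); tr_isl <- list(); tr_sys <- list(); tr_bg <- list()
  fam_w <- cfg$catalog$weight / sum(cfg$catalog$weight)
  double_fams <- cfg$catalog$family[cfg$catalog$type == "double"]

  for (m in seq_len(cfg$n_mags)) {
    set.seed(.mag_seed(cfg$seed, m))
    mag <- sprintf("MAG%03d", m)
    contig_len <- numeric(cfg$contigs_per_mag)
    isl_contig <- if (cfg$islands_per_mag > 0)
      sample(rep_len(seq_len(cfg$contigs_per_mag), cfg$islands_per_mag))
    else integer(0)
    sys_contig <- if (cfg$systems_per_mag > 0)
      sample(rep_len(seq_len(cfg$contigs_per_mag), cfg$systems_per_mag))
    else integer(0)

    for (ci in seq_len(cfg$contigs_per_mag)) {
      contig <- sprintf("%s_c%d", mag, ci)
      n <- cfg$genes_per_contig
      # gene grid
      glen <- pmax(150L, round(stats::rnorm(n, cfg$mean_gene_bp, 150)))
      starts_bp <- cumsum(c(1L, glen[-n] + cfg$intergenic_bp))
      ends_bp <- starts_bp + glen - 1L
      gid <- sprintf("%s_g%04d", contig, seq_len(n))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      contig_len[ci] <- ends_bp[n] + cfg$intergenic_bp

      # planted blocks on this contig
      n_isl <- sum(isl_contig == ci)
      n_sys <- sum(sys_contig == ci)
      isl_members <- list(); isl_fams <- list()
      for (ii in seq_len(n_isl)) {
        u <- sample(seq(cfg$island_units_range[1],
                        cfg$island_units_range[2]), 1)
        gaps <- sample(seq(cfg$island_gap_range[1],
                           cfg$island_gap_range[2]),
                       u - 1, replace = TRUE)
        fams <- c(sample(cfg$catalog$family, cfg$min_island_families),
                  sample(cfg$catalog$family, u - cfg$min_island_families,
                         replace = TRUE, prob = fam_w))
        isl_members[[ii]] <- cumsum(c(0L, gaps + 1L))  # member offsets
        isl_fams[[ii]] <- sample(fams)  # shuffle order within island
      }
      spans <- c(vapply(isl_members, function(x) max(x) + 1L, integer(1)),
                 rep(2L, n_sys))
      buffer <- if (cfg$strict_spacing) 11L else 0L
      n_bg <- stats::rbinom(1, n, cfg$background_rate)
      # cap background draws so random variation cannot make a feasible
      # configuration infeasible; planted blocks must always fit
      slots_left <- n - sum(spans) - buffer * (length(spans) + 1L)
      n_bg <- max(0L, min(n_bg, slots_left %/% (1L + buffer)))
      spans <- c(spans, rep(1L, n_bg))
      ord <- sample(length(spans))  # shuffle feature order along contig
      starts <- .place_blocks(n, spans[ord], buffer)
      starts <- starts[order(ord)]  # back to feature index order

      hit_rows <- list()
      for (ii in seq_len(n_isl)) {
        offs <- starts[ii] + isl_members[[ii]]
        fams <- isl_fams[[ii]]
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          gene_id = gid[offs + 1L], family = fams,
          gene_name = paste0(fams, "_A"), role = "mandatory",
          system_id = NA_character_, stringsAsFactors = FALSE)
        tr_isl[[length(tr_isl) + 1L]] <- data.frame(
          mag_id = mag, contig_id = contig,
          first_ordinal = min(offs), last_ordinal = max(offs),
          n_units = length(offs),
          member_gene_ids = paste(gid[offs + 1L], collapse = ","),
          families = paste(sort(unique(fams)), collapse = ","),
          stringsAsFactors = FALSE)
      }
      for (si in seq_len(n_sys)) {
        st0 <- starts[n_isl + si]
        f <- sample(double_fams, 1, prob =
                      fam_w[cfg$catalog$type == "double"] /
                      sum(fam_w[cfg$catalog$type == "double"]))
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          gene_id = gid[st0 + c(1L, 2L)], family = f,
          gene_name = paste0(f, c("_A", "_B")), role = "mandatory",
          system_id = NA_character_, stringsAsFactors = FALSE)
        tr_sys[[length(tr_sys) + 1L]] <- data.frame(
          mag_id = mag, contig_id = contig, family = f,
          first_ordinal = st0, last_ordinal = st0 + 1L,
          member_gene_ids = paste(gid[st0 + c(1L, 2L)], collapse = ","),
          stringsAsFactors = FALSE)
      }

      # MGE intervals (bp spans over gene ranges), non-overlapping
      placed <- list()
      for (cl in names(cfg$mge_rate)) {
        for (r in seq_len(stats::rpois(1, cfg$mge_rate[[cl]]))) {
          for (try in 1:20) {
            L <- sample(seq(cfg$mge_len_genes[1], cfg$mge_len_genes[2]), 1)
            if (L >= n) break
            s0 <- sample(n - L, 1)
            cand <- c(starts_bp[s0], ends_bp[s0 + L - 1L])
            clash <- any(vapply(placed, function(p)
              cand[1] <= p$end && cand[2] >= p$start, logical(1)))
            if (!clash) {
              placed[[length(placed) + 1L]] <- list(
                start = cand[1], end = cand[2], class = cl)
              break
            }
          }
        }
      }
      for (p in placed)
        mge_l[[length(mge_l) + 1L]] <- data.frame(
          contig_id = contig, start = p$start, end = p$end,
          mge_class = p$class, stringsAsFactors = FALSE)

      # background solitary defense genes; sampling weight raised inside
      # MGEs by the per-class carriage multiplier
      if (n_bg > 0) {
        bg_starts <- starts[n_isl + n_sys + seq_len(n_bg)]
        if (!cfg$strict_spacing &&
            any(cfg$mge_multiplier != 1) && length(placed) > 0) {
          w <- rep(1, n)
          for (p in placed) {
            inside <- which(starts_bp <= p$end & ends_bp >= p$start)
            w[inside] <- cfg$mge_multiplier[[p$class]]
          }
          occupied <- unlist(lapply(seq_len(n_isl + n_sys), function(i)
            starts[i] + seq_len(spans[i]) - 1L))
          free <- setdiff(seq_len(n) - 1L, occupied)
          bg_starts <- sample(free, n_bg, prob = w[free + 1L])
        }
        fams <- sample(cfg$catalog$family, n_bg, replace = TRUE,
                       prob = fam_w)
        suffix <- ifelse(
          cfg$catalog$type[match(fams, cfg$catalog$family)] == "double",
          sample(c("_A", "_B"), n_bg, replace = TRUE), "_A")
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          gene_id = gid[bg_starts + 1L], family = fams,
          gene_name = paste0(fams, suffix), role = "mandatory",
          system_id = NA_character_, stringsAsFactors = FALSE)
        tr_bg[[length(tr_bg) + 1L]] <- data.frame(
          mag_id = mag, contig_id = contig,
          gene_id = gid[bg_starts + 1L], family = fams,
          stringsAsFactors = FALSE)
      }

      genes_l[[length(genes_l) + 1L]] <- data.frame(
        mag_id = mag, contig_id = contig, gene_id = gid,
        start = starts_bp, end = ends_bp, strand = strand,
        stringsAsFactors = FALSE)
      if (length(hit_rows) > 0)
        hits_l[[length(hits_l) + 1L]] <- do.call(rbind, hit_rows)
    }

    mags_l[[length(mags_l) + 1L]] <- data.frame(
      mag_id = mag,
      habitat = cfg$habitats[(m - 1) %% length(cfg$habitats) + 1],
      size_bp = sum(contig_len),
      completeness = round(stats::runif(1, 90, 100), 2),
      contamination = round(stats::runif(1, 0, 5), 2),
      trna_count = 18L + stats::rpois(1, 5),
      rrna_classes = "5S,16S,23S",
      n50 = compute_n50(contig_len),
      stringsAsFactors = FALSE)
  }

  genes <- assign_ordinals(do.call(rbind, genes_l))
  hits <- if (length(hits_l) > 0) do.call(rbind, hits_l) else
    data.frame(gene_id = character(0), family = character(0),
               gene_name = character(0), role = character(0),
               system_id = character(0))
  hits <- hits[order(hits$gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  mge <- if (length(mge_l) > 0) do.call(rbind, mge_l) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), mge_class = character(0))
  mags <- do.call(rbind, mags_l)
  rownames(mge) <- rownames(mags) <- NULL
  truth <- list(
    islands = if (length(tr_isl) > 0) do.call(rbind, tr_isl) else NULL,
    systems = if (length(tr_sys) > 0) do.call(rbind, tr_sys) else NULL,
    background = if (length(tr_bg) > 0) do.call(rbind, tr_bg) else NULL)
  list(genes = genes, hits = hits, mge = mge, mags = mags,
       rules = default_rules(cfg$catalog), truth = truth, config = cfg)
}

#' Write a simulated cohort to disk
#'
#' Emits the exact dialects the readers consume (`genes.tsv`, `hits.tsv`,
#' `mge.bed`, `mags.tsv`) plus a `truth.json` ground-truth manifest.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(cohort$genes, file.path(dir, "genes.tsv"))
  write_defense_annotations(cohort$hits, file.path(dir, "hits.tsv"))
  write_mge_bed(cohort$mge, file.path(dir, "mge.bed"))
  write_mag_metadata(cohort$mags, file.path(dir, "mags.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate variant tables with planted high-frequency enrichment
#'
#' Every defense gene receives a Poisson number of low-frequency
#' background variants; with probability `base_hf_rate` (times the
#' family's multiplier in `enriched_families`) it additionally receives
#' one high-frequency variant (frequency >= 0.25, >= 10 reads) at a
#' uniform position in its analyzed region (gene body + `upstream_bp`).
#' Positions are 1-based within the analyzed region; positions <=
#' `upstream_bp` are upstream.
#'
#' @param genes gene table.
#' @param hits defense annotations (only defense genes receive variants).
#' @param seed integer seed.
#' @param background_rate expected low-frequency variants per gene.
#' @param base_hf_rate baseline probability that a gene carries a
#'   high-frequency variant.
#' @param enriched_families named numeric vector of multipliers on
#'   `base_hf_rate` for selected families.
#' @param upstream_bp upstream window (default 200).
#' @return list with `variants` (data.frame in reader layout) and `truth`
#'   (per-gene `has_hf` flag by construction).
#' @export
simulate_variants <- function(genes, hits, seed = 1,
                              background_rate = 2,
                              base_hf_rate = 0.2,
                              enriched_families = c(),
                              upstream_bp = 200) {
  set.seed(as.integer(seed) %% 2147483629)
  def <- genes[genes$gene_id %in% hits$gene_id, , drop = FALSE]
  fam <- hits$family[match(def$gene_id, hits$gene_id)]
  rows <- list()
  has_hf <- logical(nrow(def))
  for (i in seq_len(nrow(def))) {
    alen <- def$end[i] - def$start[i] + 1 + upstream_bp
    mult <- if (fam[i] %in% names(enriched_families))
      enriched_families[[fam[i]]] else 1
    p_hf <- min(1, base_hf_rate * mult)
    n_lf <- stats::rpois(1, background_rate)
    pos <- if (n_lf > 0) sample(alen, n_lf, replace = TRUE) else integer(0)
    if (n_lf > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = def$gene_id[i], position = pos,
        ref = NA_character_, alt = NA_character_,
        var_type = sample(c("SNP_unclassified", "indel"), n_lf,
                          replace = TRUE, prob = c(0.85, 0.15)),
        region = ifelse(pos <= upstream_bp, "upstream", "gene_body"),
        allele_frequency = round(stats::runif(n_lf, 0.01, 0.2499), 4),
        supporting_reads = stats::rpois(n_lf, 30),
        stringsAsFactors = FALSE)
    if (stats::runif(1) < p_hf) {
      has_hf[i] <- TRUE
      hp <- sample(alen, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = def$gene_id[i], position = hp,
        ref = NA_character_, alt = NA_character_,
        var_type = sample(c("SNP_unclassified", "indel"), 1,
                          prob = c(0.85, 0.15)),
        region = if (hp <= upstream_bp) "upstream" else "gene_body",
        allele_frequency = round(stats::runif(1, 0.25, 1), 4),
        supporting_reads = 10L + stats::rpois(1, 20),
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(0), position = integer(0),
               ref = character(0), alt = character(0),
               var_type = character(0), region = character(0),
               allele_frequency = numeric(0), supporting_reads = integer(0))
  rownames(variants) <- NULL
  list(variants = variants,
       truth = data.frame(gene_id = def$gene_id, family = fam,
                          has_hf = has_hf, stringsAsFactors = FALSE))
}

#' Simulate codon-aligned sequence pairs at known omega
#'
#' An ancestor of `n_codons` sense codons is drawn uniformly; two
#' descendants each receive a Poisson(`t` x `n_codons`) number of
#' proposed single-nucleotide changes at uniform positions; proposals
#' creating stop codons are rejected, synonymous proposals are accepted,
#' nonsynonymous proposals are accepted with probability `omega`.
#'
#' @param n_pairs number of pairs.
#' @param n_codons codons per sequence.
#' @param omega relative acceptance probability of nonsynonymous changes.
#' @param t expected proposals per codon per lineage (divergence).
#' @param seed integer seed.
#' @return data.frame with pair_id, seq1, seq2 and an `omega` attribute.
#' @export
simulate_codon_pairs <- function(n_pairs, n_codons = 300, omega = 0.2,
                                 t = 0.2, seed = 1) {
  stopifnot(omega >= 0, t >= 0)
  set.seed(as.integer(seed) %% 2147483629)
  evolve <- function(codons) {
    n_prop <- stats::rpois(1, t * length(codons))
    for (k in seq_len(n_prop)) {
      i <- sample(length(codons), 1)
      nt <- strsplit(codons[i], "")[[1]]
      p <- sample(3, 1)
      b <- sample(setdiff(.BASES, nt[p]), 1)
      nt[p] <- b
      cand <- paste(nt, collapse = "")
      if (.is_stop(cand)) next
      syn <- .GENCODE[cand] == .GENCODE[codons[i]]
      if (syn || stats::runif(1) < omega) codons[i] <- cand
    }
    codons
  }
  out <- lapply(seq_len(n_pairs), function(pp) {
    anc <- sample(.SENSE_CODONS, n_codons, replace = TRUE)
    data.frame(pair_id = sprintf("pair%04d", pp),
               seq1 = paste(evolve(anc), collapse = ""),
               seq2 = paste(evolve(anc), collapse = ""),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "omega") <- omega
  attr(res, "t") <- t
  res
}

#' Simulate a cohort with a planted family-pair association
#'
#' Builds contigs carrying one defense island and a set of outside
#' defense-gene pairs. Each pair slot holds two adjacent defense genes;
#' inside slots sit within the island span (slots separated by 7
#' intervening genes, keeping the island chain unbroken but slots outside
#' the 5-gene pairing range of each other), outside slots are isolated.
#' A slot is the focal pair (`family_a`, `family_b`) with probability
#' `p_in` inside and `p_out` outside, where `p_in` is derived from the
#' requested odds ratio; otherwise two distinct other families are drawn.
#' Two filler genes of dedicated families guarantee the island's
#' three-family minimum.
#'
#' @param n_contigs number of contigs (one island each).
#' @param odds_ratio planted odds ratio of the focal pair inside vs
#'   outside islands (1 = no association).
#' @param seed integer seed.
#' @param p_out probability of the focal pair in an outside slot.
#' @param slots_in,slots_out pair slots inside/outside the island per
#'   contig.
#' @param family_a,family_b focal families.
#' @param n_other_families size of the non-focal family pool.
#' @return list with `genes`, `hits`, `mags`, and `truth` (slot table and
#'   the planted probabilities).
#' @export
simulate_pair_cohort <- function(n_contigs = 50, odds_ratio = 4, seed = 1,
                                 p_out = 0.2, slots_in = 5, slots_out = 5,
                                 family_a = "FamA", family_b = "FamB",
                                 n_other_families = 8) {
  set.seed(as.integer(seed) %% 2147483629)
  odds_in <- odds_ratio * p_out / (1 - p_out)
  p_in <- odds_in / (1 + odds_in)
  others <- sprintf("Oth%02d", seq_len(n_other_families))
  fillers <- c("Filler1", "Filler2")

  # deterministic per-contig ordinal layout (identical for every contig)
  in_ord <- 12L + (seq_len(slots_in) - 1L) * 9L       # slot = 2 genes + 7 gap
  after_in <- 12L + slots_in * 9L
  filler_ord <- c(after_in, after_in + 8L)
  out_start <- after_in + 8L + 1L + 12L
  out_ord <- out_start + (seq_len(slots_out) - 1L) * 14L
  n <- out_start + slots_out * 14L - 12L + 12L
  slot_ord0 <- c(in_ord, out_ord)
  inside0 <- rep(c(TRUE, FALSE), c(slots_in, slots_out))

  contigs <- sprintf("PC%04d", seq_len(n_contigs))
  all_contig <- rep(contigs, each = n)
  all_ord <- rep.int(seq_len(n) - 1L, n_contigs)
  gid <- sprintf("%s_g%04d", all_contig, all_ord + 1L)
  genes <- data.frame(
    mag_id = "PMAG", contig_id = all_contig, gene_id = gid,
    start = all_ord * 1000L + 1L, end = all_ord * 1000L + 901L,
    strand = "+", ordinal = all_ord, stringsAsFactors = FALSE)

  n_slots <- n_contigs * (slots_in + slots_out)
  slot_contig <- rep(contigs, each = slots_in + slots_out)
  slot_o <- rep.int(slot_ord0, n_contigs)
  slot_in <- rep.int(inside0, n_contigs)
  focal <- stats::runif(n_slots) < ifelse(slot_in, p_in, p_out)
  f1 <- sample(others, n_slots, replace = TRUE)
  shift <- sample(n_other_families - 1L, n_slots, replace = TRUE)
  f2 <- others[(match(f1, others) + shift - 1L) %% n_other_families + 1L]
  fam_a <- ifelse(focal, family_a, f1)
  fam_b <- ifelse(focal, family_b, f2)
  slot_fams <- as.vector(rbind(fam_a, fam_b))
  slot_gid <- sprintf("%s_g%04d", rep(slot_contig, each = 2),
                      as.vector(rbind(slot_o, slot_o + 1L)) + 1L)
  filler_gid <- sprintf("%s_g%04d", rep(contigs, each = 2),
                        rep.int(filler_ord, n_contigs) + 1L)
  hits <- data.frame(
    gene_id = c(slot_gid, filler_gid),
    family = c(slot_fams, rep.int(fillers, n_contigs)),
    gene_name = paste0(c(slot_fams, rep.int(fillers, n_contigs)), "_A"),
    role = "mandatory", system_id = NA_character_,
    stringsAsFactors = FALSE)
  slot_rows <- list(data.frame(contig_id = slot_contig, ordinal = slot_o,
                               inside = slot_in, focal = focal,
                               stringsAsFactors = FALSE))
  mags <- data.frame(mag_id = "PMAG", habitat = "synthetic",
                     size_bp = nrow(genes) * 1000,
                     completeness = 100, contamination = 0,
                     trna_count = 20L, rrna_classes = "5S,16S,23S",
                     n50 = 1e6, stringsAsFactors = FALSE)
  list(genes = genes, hits = hits, mags = mags,
       truth = list(slots = do.call(rbind, slot_rows),
                    p_in = p_in, p_out = p_out,
                    odds_ratio = odds_ratio))
}
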