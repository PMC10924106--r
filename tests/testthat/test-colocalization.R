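test_that("MGE membership tagging follows the overlap and flank rules", {
  genes <- data.frame(mag_id = "M", contig_id = "c1",
                      gene_id = c("g1", "g2"),
                      start = c(100, 100), end = c(500, 500),
                      strand = "+", ordinal = 0:1)
  mge <- data.frame(contig_id = "c1", start = 400L, end = 900L,
                    mge_class = "plasmid")
  expect_equal(tag_mge_membership(genes[1, ], mge)$mge_class, "plasmid")

  far <- data.frame(contig_id = "c1", start = 600L, end = 900L,
                    mge_class = "prophage")
  expect_equal(tag_mge_membership(genes[1, ], far)$mge_class, "chromosome")
  expect_equal(tag_mge_membership(genes[1, ], far,
                                  flank_bp = 200)$mge_class, "prophage")

  none <- far[0, ]
  expect_true(all(tag_mge_membership(genes, none)$mge_class ==
                    "chromosome"))
})

test_that("context densities use context-specific lengths", {
  genes <- genes_from_ordinals(60)
  genes$mag_id <- "M1"
  hits <- hits_at(genes, c(2, 5, 8, 11), "RM")
  # prophage covering ordinals 0..39 (bp 1..40000): 40 kb with 4 genes
  mge <- data.frame(contig_id = "c1", start = 1L, end = 40000L,
                    mge_class = "prophage")
  mags <- data.frame(mag_id = "M1", habitat = "soil", size_bp = 100000)
  tg <- tag_mge_membership(genes, mge)
  dd <- mge_defense_density(tg, hits, mge, mags)
  expect_equal(dd$density_kb[dd$context == "prophage"], 0.1)
  expect_equal(dd$density_kb[dd$context == "chromosome"], 0)

  # no MGE: only the chromosome context is emitted
  dd0 <- mge_defense_density(tag_mge_membership(genes, mge[0, ]),
                             hits, mge[0, ], mags)
  expect_equal(dd0$context, "chromosome")

  # MGE spans exceeding the MAG size are inconsistent annotation
  tiny <- data.frame(mag_id = "M1", habitat = "soil", size_bp = 30000)
  expect_error(mge_defense_density(tg, hits, mge, tiny), "inconsistent")
})

test_that("family x MGE expectation follows the marginal fraction", {
  # family F: 50 genes, 10 on plasmids; 10% of all defense genes
  # plasmid-borne -> expected 5, O/E = 2
  tagged <- data.frame(
    family = rep(c("F", "G"), c(50, 450)),
    mge_class = c(rep("plasmid", 10), rep("chromosome", 40),
                  rep("plasmid", 40), rep("chromosome", 410)))
  oe <- mge_family_oe(tagged)
  cell <- oe$cells[oe$cells$family == "F" & oe$cells$category == "plasmid", ]
  expect_equal(cell$expected, 5)
  expect_equal(cell$oe, 2)
  # margins preserved: expected-weighted mean O/E = 1 per family row
  for (f in c("F", "G")) {
    rows <- oe$cells[oe$cells$family == f, ]
    expect_equal(sum(rows$expected), sum(rows$observed))
    expect_equal(sum(rows$expected * rows$oe) / sum(rows$expected), 1)
  }
})

test_that("a table at exact independence gives chi-square zero", {
  tagged <- data.frame(
    family = rep(c("F", "G"), c(100, 300)),
    mge_class = c(rep(c("plasmid", "chromosome"), c(25, 75)),
                  rep(c("plasmid", "chromosome"), c(75, 225))))
  oe <- mge_family_oe(tagged)
  expect_equal(oe$chisq$statistic, 0)
  expect_equal(oe$chisq$p_value, 1)
  expect_error(mge_family_oe(tagged[tagged$family == "F", ]), "2 families")
})

test_that("pair enumeration respects the intervening-gene threshold", {
  genes <- genes_from_ordinals(20)
  hits <- hits_at(genes, c(3, 9), c("A", "B"))        # 5 intervening
  fp <- suppressWarnings(family_pair_colocalization(genes, hits, data.frame(
    island_id = character(0), mag_id = character(0),
    contig_id = character(0), first_ordinal = integer(0),
    last_ordinal = integer(0))))
  expect_equal(nrow(fp$pairs), 1L)

  hits2 <- hits_at(genes, c(3, 10), c("A", "B"))      # 6 intervening
  fp2 <- family_pair_colocalization(genes, hits2, data.frame(
    island_id = character(0), mag_id = character(0),
    contig_id = character(0), first_ordinal = integer(0),
    last_ordinal = integer(0)))
  expect_null(fp2$pairs)
})

test_that("genes of the same system never form a pair", {
  genes <- genes_from_ordinals(20)
  hits <- hits_at(genes, c(3, 4, 9), c("CBASS", "CBASS", "RM"),
                  system_ids = c("S1", "S1", NA))
  no_isl <- data.frame(island_id = character(0), mag_id = character(0),
                       contig_id = character(0),
                       first_ordinal = integer(0),
                       last_ordinal = integer(0))
  # with no islands every pair is outside; the OR is flagged undefined
  expect_warning(fp <- family_pair_colocalization(genes, hits, no_isl),
                 "undefined")
  # S1's internal pair dropped; each S1 gene still pairs with the RM gene
  expect_equal(nrow(fp$pairs), 2L)
  expect_false(any(fp$pairs$family_a == "CBASS" &
                     fp$pairs$family_b == "CBASS"))
})

test_that("sample odds ratio matches hand arithmetic with 0.5 on zeros", {
  expect_equal(defensomics:::.odds_ratio(10, 90, 5, 895),
               (10 * 895) / (90 * 5))
  expect_equal(defensomics:::.odds_ratio(20, 80, 10, 890), 22.25)
  expect_equal(defensomics:::.odds_ratio(0, 10, 5, 20),
               (0.5 * 20.5) / (10.5 * 5.5))
})

test_that("pair associations are symmetric in gene order", {
  pc <- simulate_pair_cohort(n_contigs = 10, odds_ratio = 3, seed = 2)
  isl <- call_islands(pc$genes, pc$hits)
  f1 <- family_pair_colocalization(pc$genes, pc$hits, isl)
  set.seed(1)
  f2 <- family_pair_colocalization(pc$genes,
                                   pc$hits[sample(nrow(pc$hits)), ], isl)
  key <- function(a) a[order(a$family_a, a$family_b), ]
  expect_equal(key(f1$associations), key(f2$associations),
               ignore_attr = "row.names")
})

test_that("uniform MGE placement yields comparable context densities", {
  co <- simulate_cohort(sim_config(seed = 55, n_mags = 30,
                                   strict_spacing = FALSE,
                                   islands_per_mag = 0,
                                   systems_per_mag = 0,
                                   background_rate = 0.2))
  mge <- resolve_mge_conflicts(co$mge)
  tg <- tag_mge_membership(co$genes, mge)
  dd <- mge_defense_density(tg, co$hits, mge, co$mags)
  pooled <- vapply(split(dd, dd$context), function(d)
    sum(d$n_defense_genes) / (sum(d$context_bp) / 1000), numeric(1))
  # binomial sampling bound: pooled MGE density within ~3 sigma of the
  # chromosome density
  n_mge <- sum(dd$n_defense_genes[dd$context != "chromosome"])
  expect_gt(n_mge, 50)
  rate <- pooled[["chromosome"]]
  mge_bp <- sum(dd$context_bp[dd$context != "chromosome"])
  sigma <- sqrt(rate / (mge_bp / 1000))
  mge_rate <- n_mge / (mge_bp / 1000)
  expect_lt(abs(mge_rate - rate), 3 * sigma)
})
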