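mkvar <- function(freq, reads) {
  data.frame(gene_id = paste0("g", seq_along(freq)), position = 1L,
             ref = NA, alt = NA, var_type = "SNP_unclassified",
             region = "gene_body", allele_frequency = freq,
             supporting_reads = reads, stringsAsFactors = FALSE)
}

test_that("the high-frequency filter is inclusive on both thresholds", {
  v <- mkvar(c(0.30, 0.30, 0.20, 0.25), c(12L, 9L, 50L, 10L))
  kept <- filter_high_frequency(v)
  expect_equal(kept$gene_id, c("g1", "g4"))
  expect_equal(nrow(filter_high_frequency(v[0, ])), 0L)
})

test_that("region assignment is strand-aware over the 200-bp window", {
  # + strand gene at 1000..1999
  expect_equal(classify_variant(850, 1000, 1999, "+")$region, "upstream")
  expect_equal(classify_variant(1500, 1000, 1999, "+")$region, "gene_body")
  expect_error(classify_variant(799, 1000, 1999, "+"), "outside")
  # mirrored - strand gene: upstream sits above the end
  expect_equal(classify_variant(2149, 1000, 1999, "-")$region, "upstream")
  expect_error(classify_variant(2200, 1000, 1999, "-"), "outside")
})

test_that("SNP typing follows the genetic code on both strands", {
  cds <- "TTTATGGCT"
  # third position of codon TTT: T>C is Phe->Phe
  expect_equal(classify_variant(1002, 1000, 1008, "+", "T", "C", cds)$var_type,
               "SNP_synonymous")
  # first position: T>C gives CTT (Leu)
  expect_equal(classify_variant(1000, 1000, 1008, "+", "T", "C", cds)$var_type,
               "SNP_nonsynonymous")
  # same gene mirrored to the - strand: CDS 5'->3' unchanged, genomic
  # coordinates reflected, alleles complemented
  expect_equal(classify_variant(1006, 1000, 1008, "-", "A", "G", cds)$var_type,
               "SNP_synonymous")
  expect_equal(classify_variant(1008, 1000, 1008, "-", "A", "G", cds)$var_type,
               "SNP_nonsynonymous")
  # indels bypass codon logic; no CDS leaves SNPs unclassified
  expect_equal(classify_variant(1004, 1000, 1008, "+", "A", "AT",
                                cds)$var_type, "indel")
  expect_equal(classify_variant(1004, 1000, 1008, "+", "T", "C")$var_type,
               "SNP_unclassified")
})

test_that("per-gene summaries conserve fractions and compute density", {
  genes <- genes_from_ordinals(2)
  genes$start <- c(1, 2001)
  genes$end <- c(800, 2800)
  hits <- hits_at(genes, 0:1, c("RM", "CBASS"))
  vars <- data.frame(
    gene_id = rep(genes$gene_id[1], 4), position = c(50, 300, 500, 700),
    ref = NA, alt = NA,
    var_type = c("SNP_synonymous", "SNP_nonsynonymous", "indel",
                 "SNP_unclassified"),
    region = c("upstream", "gene_body", "gene_body", "gene_body"),
    allele_frequency = c(0.5, 0.1, 0.3, 0.9),
    supporting_reads = c(20L, 5L, 15L, 3L))
  gs <- gene_variant_summary(vars, genes, hits)
  g1 <- gs[gs$gene_id == genes$gene_id[1], ]
  expect_equal(g1$analyzed_length_bp, 1000)
  expect_equal(g1$density_kb, 4)
  expect_equal(g1$frac_synonymous + g1$frac_nonsynonymous +
                 g1$frac_unclassified + g1$frac_indel, 1)
  expect_equal(g1$frac_gene_body + g1$frac_upstream, 1)
  expect_true(g1$has_high_frequency_variant)   # (0.5, 20) passes
  g2 <- gs[gs$gene_id == genes$gene_id[2], ]
  expect_equal(g2$n_snp + g2$n_indel, 0L)
  expect_false(g2$has_high_frequency_variant)
})

test_that("family O/E uses the marginal flagged fraction", {
  # 100-gene family with 30 flagged; overall fraction 0.2 -> expected 20
  summaries <- data.frame(
    family = rep(c("A", "B"), c(100, 400)),
    has_high_frequency_variant = c(rep(c(TRUE, FALSE), c(30, 70)),
                                   rep(c(TRUE, FALSE), c(70, 330))))
  res <- family_variant_oe(summaries)
  a <- res$cells[res$cells$family == "A", ]
  expect_equal(a$expected, 20)
  expect_equal(a$oe, 1.5)
  expect_true(a$flagged)
  expect_equal(sum(res$cells$expected), sum(res$cells$observed))

  # families under the minimum gene count are excluded
  s2 <- rbind(summaries,
              data.frame(family = "C",
                         has_high_frequency_variant = rep(TRUE, 9)))
  expect_false("C" %in% family_variant_oe(s2)$cells$family)
})

test_that("uniform flagging gives mean O/E near one", {
  set.seed(29)
  oes <- replicate(200, {
    s <- data.frame(family = sample(LETTERS[1:4], 400, replace = TRUE),
                    has_high_frequency_variant = runif(400) < 0.3)
    mean(family_variant_oe(s)$cells$oe)
  })
  expect_equal(mean(oes), 1, tolerance = 0.02)
})

test_that("simulated variant truth flags agree with the filter", {
  co <- simulate_cohort(sim_config(seed = 61, n_mags = 5))
  sv <- simulate_variants(co$genes, co$hits, seed = 2)
  hf <- filter_high_frequency(sv$variants)
  flagged <- unique(hf$gene_id)
  expect_setequal(flagged, sv$truth$gene_id[sv$truth$has_hf])

  # no high-frequency plants -> nothing retained
  sv0 <- simulate_variants(co$genes, co$hits, seed = 2, base_hf_rate = 0)
  expect_equal(nrow(filter_high_frequency(sv0$variants)), 0L)
})
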