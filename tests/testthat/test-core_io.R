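test_that("gene table TSV reading assigns ordinals by start position", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("mag_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "M1\tc1\tg1\t100\t300\t+",
               "M1\tc1\tg2\t900\t1100\t-",
               "M1\tc1\tg3\t50\t80\t+"), tsv)
  g <- read_gene_table(tsv)
  expect_equal(g$ordinal[match(c("g1", "g2", "g3"), g$gene_id)],
               c(1L, 2L, 0L))

  empty <- tempfile(fileext = ".tsv")
  writeLines("mag_id\tcontig_id\tgene_id\tstart\tend\tstrand", empty)
  expect_equal(nrow(read_gene_table(empty)), 0L)
})

test_that("gene table validation rejects malformed input", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("mag_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "M1\tc1\tg1\tabc\t300\t+"), bad)
  expect_error(read_gene_table(bad), "malformed.*line 1")

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("mag_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "M1\tc1\tg1\t100\t300\t+",
               "M1\tc1\tg1\t400\t500\t+"), dup)
  expect_error(read_gene_table(dup), "duplicate gene_id")

  rev <- tempfile(fileext = ".tsv")
  writeLines(c("mag_id\tcontig_id\tgene_id\tstart\tend\tstrand",
               "M1\tc1\tg1\t300\t100\t+"), rev)
  expect_error(read_gene_table(rev), "end < start")
})

test_that("GFF3 reading matches a hand-sorted listing per contig", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ctgA\tsrc\tCDS\t500\t900\t.\t+\t0\tID=a2",
    "ctgA\tsrc\tCDS\t10\t400\t.\t+\t0\tID=a1",
    "ctgB\tsrc\tCDS\t100\t200\t.\t-\t0\tID=b1",
    "ctgB\tsrc\tCDS\t300\t450\t.\t+\t0\tID=b2"), gff)
  g <- read_gene_table(gff, mag_id = "magX")
  # independent oracle: sort each contig's rows by start by hand
  expect_equal(g$gene_id[g$contig_id == "ctgA"], c("a1", "a2"))
  expect_equal(g$ordinal[g$contig_id == "ctgA"], c(0L, 1L))
  expect_equal(g$gene_id[g$contig_id == "ctgB"], c("b1", "b2"))
  expect_equal(g$ordinal[g$contig_id == "ctgB"], c(0L, 1L))
  expect_true(all(g$mag_id == "magX"))
})

test_that("ordinals are a 0-based permutation per contig", {
  co <- simulate_cohort(sim_config(seed = 3, n_mags = 3))
  for (ctg in unique(co$genes$contig_id)) {
    o <- sort(co$genes$ordinal[co$genes$contig_id == ctg])
    expect_identical(o, seq_along(o) - 1L)
  }
})

test_that("defense annotation reading normalizes roles and dedupes", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfamily\tgene_name\trole",
               paste0("g", 1:5, "\tRM\tRM_A\tMandatory", collapse = "\n")),
             tsv)
  h <- read_defense_annotations(tsv)
  expect_equal(nrow(h), 5L)
  expect_true(all(h$role == "mandatory"))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfamily\tgene_name\trole",
               "g1\tRM\tRM_A\tmandatory",
               "g1\tCBASS\tCBASS_A\taccessory"), dup)
  expect_warning(h2 <- read_defense_annotations(dup), "1 duplicate")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$family, "RM")

  badrole <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfamily\tgene_name\trole",
               "g1\tRM\tRM_A\tcore"), badrole)
  expect_error(read_defense_annotations(badrole), "unknown role")

  nofam <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfamily\tgene_name\trole",
               "g1\t\tRM_A\tmandatory"), nofam)
  expect_error(read_defense_annotations(nofam), "missing family")
})

test_that("BED reading converts coordinates and drops multi-class overlaps", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("c1\t99\t200\tplasmid",
               "c2\t99\t200\tplasmid",
               "c2\t149\t300\tprophage",
               "c3\t99\t200\tplasmid",
               "c3\t299\t400\tprophage"), bed)
  expect_message(mge <- read_mge_intervals(bed), "2 MGE interval")
  c1 <- mge[mge$contig_id == "c1", ]
  expect_equal(c(c1$start, c1$end), c(100L, 200L))
  expect_equal(nrow(mge[mge$contig_id == "c2", ]), 0L)   # both removed
  expect_equal(nrow(mge[mge$contig_id == "c3", ]), 2L)   # disjoint kept

  badclass <- tempfile(fileext = ".bed")
  writeLines("c1\t0\t100\ttransposon", badclass)
  expect_error(read_mge_intervals(badclass), "allowed")
})

test_that("same-class nested intervals merge; BED round-trip is identity", {
  mge <- data.frame(contig_id = "c1", start = c(100L, 150L),
                    end = c(400L, 300L), mge_class = "prophage")
  merged <- resolve_mge_conflicts(mge)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 400L))

  path <- tempfile(fileext = ".bed")
  write_mge_bed(merged, path)
  back <- read_mge_intervals(path)
  expect_equal(back, merged)
})

test_that("VCF reading expands alternate alleles and computes AO/DP", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "geneA\t150\t.\tA\tG\t60\t.\tDP=40;AO=12",
    "geneA\t300\t.\tC\tT,G\t60\t.\tDP=100;AO=30,10",
    "geneB\t10\t.\tT\tTA\t60\t.\tDP=50;AO=20",
    "geneB\t99\t.\tG\tA\t60\t.\tDP=0;AO=0"), vcf)
  expect_warning(v <- read_variants(vcf), "DP=0")
  expect_equal(nrow(v), 4L)  # 1 + 2 (multi-allelic) + 1 indel
  first <- v[v$gene_id == "geneA" & v$position == 150, ]
  expect_equal(first$allele_frequency, 0.30)
  expect_equal(first$supporting_reads, 12L)
  expect_equal(sum(v$gene_id == "geneA" & v$position == 300), 2L)
  expect_equal(v$var_type[v$gene_id == "geneB"], "indel")
})

test_that("TSV round-trips reproduce records field by field", {
  co <- simulate_cohort(sim_config(seed = 5, n_mags = 2))
  sv <- simulate_variants(co$genes, co$hits, seed = 5)

  gp <- tempfile(fileext = ".tsv")
  write_gene_table(co$genes, gp)
  expect_equal(read_gene_table(gp), co$genes)

  hp <- tempfile(fileext = ".tsv")
  write_defense_annotations(co$hits, hp)
  expect_equal(read_defense_annotations(hp), co$hits)

  vp <- tempfile(fileext = ".tsv")
  write_variants(sv$variants, vp)
  expect_equal(read_variants(vp), sv$variants)

  mp <- tempfile(fileext = ".tsv")
  write_mag_metadata(co$mags, mp)
  expect_equal(read_mag_metadata(mp), co$mags)
})
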