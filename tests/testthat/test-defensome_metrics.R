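test_that("per-kb density matches hand arithmetic", {
  expect_equal(density_per_kb(10, 5e6), 2e-3)
  expect_equal(density_per_kb(0, 5e6), 0)
  expect_equal(density_per_kb(7, 3.5e6), 7 / 3500)
  expect_error(density_per_kb(1, 0), "positive")
})

test_that("family prevalence is the percentage of MAGs with a system", {
  mags <- data.frame(mag_id = paste0("M", 1:4), habitat = "soil",
                     size_bp = 3e6)
  sys <- data.frame(system_id = paste0("S", 1:3), family = "RM",
                    mag_id = paste0("M", 1:3), contig_id = "c",
                    n_genes = 2L, n_mandatory = 2L,
                    completeness = "complete", member_gene_ids = "x")
  asm <- list(systems = sys, gene_status = NULL)
  prev <- family_prevalence(asm, mags)
  expect_equal(prev$prevalence_pct[prev$family == "RM"], 75)

  sys$completeness <- "incomplete"
  prev0 <- family_prevalence(list(systems = sys), mags)
  expect_equal(nrow(prev0), 0L)  # no complete system anywhere

  co <- simulate_cohort(sim_config(seed = 31, n_mags = 8))
  asm2 <- assemble_systems(co$genes, co$hits, co$rules)
  p <- family_prevalence(asm2, co$mags)
  expect_true(all(p$prevalence_pct >= 0 & p$prevalence_pct <= 100))
})

test_that("size correlations recover monotone relationships", {
  prof <- data.frame(size_bp = seq(2e6, 6e6, length.out = 20))
  prof$n_systems <- seq_len(20)            # strictly increasing with size
  prof$density_systems_kb <- 5 / prof$size_bp  # count fixed -> 1/size
  sc <- size_correlation(prof)
  expect_equal(sc$rho[sc$comparison == "count_vs_size"], 1)
  expect_equal(sc$rho[sc$comparison == "density_vs_size"], -1)
})

test_that("Spearman rho equals the brute-force rank formula at n = 6", {
  prof <- data.frame(size_bp = c(2.1e6, 3.3e6, 2.8e6, 5e6, 4.2e6, 3.9e6),
                     n_systems = c(3, 9, 2, 11, 8, 5))
  prof$density_systems_kb <- density_per_kb(prof$n_systems, prof$size_bp)
  sc <- size_correlation(prof)
  # oracle: Pearson correlation of average ranks
  rk <- function(x) rank(x)
  oracle <- cor(rk(prof$size_bp), rk(prof$n_systems))
  expect_equal(sc$rho[sc$comparison == "count_vs_size"], oracle,
               tolerance = 1e-12)
})

test_that("constant vectors are flagged rather than correlated", {
  prof <- data.frame(size_bp = seq(2e6, 4e6, length.out = 10),
                     n_systems = 5, density_systems_kb = 1e-3)
  sc <- size_correlation(prof)
  expect_true(all(sc$constant))
  expect_true(all(is.na(sc$rho)))
})

test_that("density is size-independent when counts scale with size", {
  set.seed(11)
  size <- runif(200, 2e6, 8e6)
  counts <- rpois(200, size * 2e-6)
  prof <- data.frame(size_bp = size, n_systems = counts,
                     density_systems_kb = density_per_kb(counts, size))
  sc <- size_correlation(prof)
  expect_lt(abs(sc$rho[sc$comparison == "density_vs_size"]), 0.1)
})

test_that("phylogenetic depth is the mean root-to-tip path", {
  tw <- ape::read.tree(text = "(A:0.1,B:0.3);")
  expect_equal(phylo_depth(tw), 0.2)
  ultra <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(phylo_depth(ultra), 2)
  unrooted <- ape::unroot(ape::rtree(5))
  expect_error(phylo_depth(unrooted), "unrooted")
})

test_that("path-sum depth equals the VCV-diagonal mean", {
  set.seed(8)
  for (rep in 1:5) {
    tr <- ape::rtree(10)
    oracle <- mean(diag(ape::vcv.phylo(tr)))
    expect_equal(phylo_depth(tr), oracle, tolerance = 1e-9)
  }
})

test_that("stepwise selection finds the planted predictors", {
  set.seed(5)
  n <- 60
  df <- data.frame(size = rnorm(n), depth = rnorm(n))
  df$n_defense_genes <- 2 * df$size + rnorm(n, sd = 1e-8)
  res <- suppressWarnings(stepwise_defensome(df))  # near-perfect fit
  expect_equal(res$selected, "size")

  df$n_defense_genes <- 3 * df$size + 2 * df$depth + rnorm(n, sd = 0.2)
  res2 <- stepwise_defensome(df)
  expect_setequal(res2$selected, c("size", "depth"))
  expect_true(all(res2$partial_r2 > 0))
})

test_that("stepwise selects nothing under the null in most replicates", {
  # BIC entry requires a chi-square(1) exceedance of log(n); at n = 100
  # a spurious predictor enters with probability ~3%, so the intercept
  # model is kept in >= 90% of null replicates. AIC's fixed penalty of 2
  # admits spurious terms ~16% of the time per predictor by construction,
  # so only a majority bound is meaningful there.
  set.seed(17)
  res <- replicate(100, {
    n <- 100
    df <- data.frame(size = rnorm(n), depth = rnorm(n),
                     n_defense_genes = rnorm(n))
    c(bic = length(stepwise_defensome(df, criterion = "BIC")$selected) == 0,
      aic = length(stepwise_defensome(df)$selected) == 0)
  })
  expect_gte(mean(res["bic", ]), 0.9)
  expect_gte(mean(res["aic", ]), 0.5)
})

test_that("habitat comparison behaves under shift and null", {
  set.seed(3)
  a <- rnorm(20)
  res0 <- habitat_compare(c(a, a), rep(c("x", "y"), each = 20))
  expect_gte(res0$tests$p_value, 0.99)

  res1 <- habitat_compare(c(a, a + 5), rep(c("x", "y"), each = 20))
  expect_lt(res1$tests$p_value, 1e-3)

  # U + U' = n1 * n2
  b <- rnorm(15, 1)
  u1 <- habitat_compare(c(a, b), rep(c("x", "y"), c(20, 15)))$tests$U
  u2 <- suppressWarnings(stats::wilcox.test(b, a)$statistic)
  expect_equal(unname(u1 + u2), 20 * 15)

  expect_warning(
    habitat_compare(c(a, b, 1, 2), rep(c("x", "y", "z"), c(20, 15, 2))),
    "excluded")
})
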