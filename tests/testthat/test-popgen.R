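test_that("PCA centers scores and duplicates map to identical rows", {
  set.seed(41)
  d <- matrix(rbinom(50 * 2, 2, 0.5), 50, 2)
  d <- d[apply(d, 1, var) > 0, ]
  gm <- toy_gm(d)
  m <- pca_fit(gm, 1)
  expect_equal(unname(m$scores[1, 1]), -unname(m$scores[2, 1]))  # symmetric about 0
  d4 <- cbind(dA <- rbinom(60, 2, 0.5), rbinom(60, 2, 0.3), dA, rbinom(60, 2, 0.6))
  gm4 <- toy_gm(d4)
  m4 <- pca_fit(gm4, 2)
  expect_equal(m4$scores[1, ], m4$scores[3, ], ignore_attr = TRUE)
  # k beyond rank truncates with warning
  expect_warning(mk <- pca_fit(gm4, 10), "rank")
  expect_lte(mk$k, 4)
})

test_that("PCA separates island-model subpopulations", {
  cfg <- sim_config(seed = 51, n_sites = 2000, n_subpops = 3, n_per_subpop = 20,
                    fst_param = 0.1, missing_rate = 0.02)
  geno <- simulate_genome(cfg)
  pop <- simulate_population(cfg, geno$layout, geno$masks)
  m <- pca_fit(pop$gm, 2)
  km <- kmeans(m$scores, centers = 3, nstart = 25)
  agree <- sum(apply(table(km$cluster, pop$labels), 1, max)) / length(pop$labels)
  expect_gte(agree, 0.95)
})

test_that("projection uses stored standardization and reproduces training scores", {
  cfg <- sim_config(seed = 52, n_sites = 800, n_per_subpop = 10)
  geno <- simulate_genome(cfg)
  pop <- simulate_population(cfg, geno$layout, geno$masks)
  m <- pca_fit(pop$gm, 4)
  proj <- pca_project(m, pop$gm)
  expect_lt(max(abs(proj - m$scores)) / max(abs(m$scores)), 1e-8)
  # genotypes at the model means project to the origin
  i <- match(m$site_key, variant_key(pop$gm$sites))
  mean_gm <- genotype_matrix(pop$gm$sites[i, ],
                             matrix(as.integer(round(m$center)), length(i), 1),
                             "neutral", pop$gm$layout, sort = FALSE)
  z <- pca_project(m, subset_samples(pop$gm, 1))
  ctr <- (round(m$center) - m$center) / m$scale   # rounding residue bound
  expect_lt(max(abs(pca_project(m, mean_gm))), sum(abs(ctr)) + 1e-8)
  # held-out samples land with their own subpopulation
  cfg2 <- sim_config(seed = 53, n_sites = 2000, n_subpops = 3, n_per_subpop = 22)
  g2 <- simulate_genome(cfg2)
  p2 <- simulate_population(cfg2, g2$layout, g2$masks)
  train <- setdiff(p2$gm$samples, paste0("pop2_s", sprintf("%02d", 21:22)))
  m2 <- pca_fit(subset_samples(p2$gm, train), 2)
  news <- pca_project(m2, subset_samples(p2$gm, setdiff(p2$gm$samples, train)))
  own <- m2$scores[startsWith(rownames(m2$scores), "pop2"), ]
  for (r in seq_len(nrow(news))) {
    d_own <- min(sqrt(colSums((t(own) - news[r, ])^2)))
    d_other <- min(sqrt(colSums((t(m2$scores[!startsWith(rownames(m2$scores), "pop2"), ]) - news[r, ])^2)))
    expect_lt(d_own, d_other)
  }
})

test_that("association scan matches lm and is calibrated under the null", {
  set.seed(63)
  gm <- toy_gm(matrix(rbinom(30 * 40, 2, 0.4), 30, 40))
  y <- rnorm(40)
  m <- pca_fit(gm, 2)
  res <- assoc_scan(gm, y, m, 2)
  # oracle: explicit lm fit per site
  for (i in c(1, 7, 23)) {
    g <- gm$dosage[i, ]
    fit <- summary(lm(y ~ g + m$scores[, 1] + m$scores[, 2]))$coefficients
    expect_equal(res$beta[i], fit["g", 1], tolerance = 1e-10)
    expect_equal(res$p[i], fit["g", 4], tolerance = 1e-10)
  }
  expect_error(assoc_scan(gm, rep(1, 40)), "constant")
  # null calibration: KS test on uniform p-values
  gm0 <- toy_gm(matrix(rbinom(1000 * 60, 2, 0.5), 1000, 60))
  p0 <- assoc_scan(gm0, rnorm(60))$p
  expect_gt(ks.test(p0, "punif")$p.value, 0.01)
  # perfect signal attains the scan minimum
  gms <- toy_gm(matrix(rbinom(50 * 30, 2, 0.4), 50, 30))
  ys <- 2.5 * gms$dosage[17, ]
  ps <- assoc_scan(gms, ys)$p
  expect_equal(which.min(ps), 17)
})

test_that("planted causal site is top-ranked in nearly all replicates", {
  hits <- vapply(1:60, function(r) {
    cfg <- sim_config(seed = 7000 + r, n_sites = 400, n_subpops = 2,
                      n_per_subpop = 100, missing_rate = 0)
    layout <- genome_layout(names(cfg$chromosomes), cfg$chromosomes)
    pop <- simulate_population(cfg, layout)
    ci <- which.min(abs(site_summaries(pop$gm)$maf - 0.3))  # well-powered causal site
    y <- implant_trait(pop$gm, list(causal_index = ci, beta = 1.5, sd = 1,
                                    model = "quantitative"), cfg$seed)
    res <- assoc_scan(pop$gm, y, pca_fit(pop$gm, 2), 2)
    which.min(res$p) == ci
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("window diversity matches the unbiased heterozygosity formula", {
  # one site, p = 0.5 from 4 called alleles, 1 Mb window
  gm <- toy_gm(matrix(c(1L, 1L), 1, 2), pos = 500000)
  w <- list(chrom = "A01", start = 0, end = 1e6)
  expect_equal(pi_window(gm, gm$samples, w), (2 * .5 * .5 * 4 / 3) / 1e6)
  # no variants in window -> 0; monomorphic group -> 0
  expect_equal(pi_window(gm, gm$samples, list(chrom = "A02", start = 0, end = 1e5)), 0)
  gm0 <- toy_gm(matrix(2L, 1, 4), pos = 500)
  expect_equal(pi_window(gm0, gm0$samples, w), 0)
  # concatenating two windows length-weights pi
  set.seed(14)
  gm2 <- toy_gm(matrix(rbinom(40 * 8, 2, .4), 40, 8),
                pos = sort(sample(2e5, 40)))
  w1 <- list(chrom = "A01", start = 0, end = 1e5)
  w2 <- list(chrom = "A01", start = 1e5, end = 2e5)
  w12 <- list(chrom = "A01", start = 0, end = 2e5)
  expect_equal(pi_window(gm2, gm2$samples, w12),
               (pi_window(gm2, gm2$samples, w1) * 1e5 +
                  pi_window(gm2, gm2$samples, w2) * 1e5) / 2e5)
  # allele relabeling leaves pi unchanged
  gm_flip <- toy_gm(2L - gm2$dosage, pos = gm2$sites$pos)
  expect_equal(pi_window(gm_flip, gm_flip$samples, w12),
               pi_window(gm2, gm2$samples, w12))
})

test_that("Hudson Fst behaves at the boundaries and recovers F", {
  # fixed difference -> Fst ~ 1
  gm <- toy_gm(matrix(c(rep(2L, 20), rep(0L, 20)), 1, 40), pos = 100)
  gA <- gm$samples[1:20]; gB <- gm$samples[21:40]
  w <- list(chrom = "A01", start = 0, end = 1e3)
  expect_equal(fst_window(gm, gA, gB, w), 1)
  # panmictic -> near 0; relabel invariance
  set.seed(15)
  gmp <- toy_gm(matrix(rbinom(500 * 40, 2, .3), 500, 40),
                pos = sort(sample(9e5, 500)))
  w2 <- list(chrom = "A01", start = 0, end = 1e6)
  f0 <- fst_window(gmp, gmp$samples[1:20], gmp$samples[21:40], w2)
  expect_lt(abs(f0), 0.02)
  gmf <- toy_gm(2L - gmp$dosage, pos = gmp$sites$pos)
  expect_equal(fst_window(gmf, gmf$samples[1:20], gmf$samples[21:40], w2), f0)
  # two-island simulation recovers F = 0.15
  cfg <- sim_config(seed = 16, n_sites = 5000, n_subpops = 2, n_per_subpop = 25,
                    fst_param = 0.15)
  geno <- simulate_genome(cfg)
  pop <- simulate_population(cfg, geno$layout, geno$masks)
  st <- selection_scan(pop$gm, names(pop$labels)[pop$labels == "pop1"],
                       names(pop$labels)[pop$labels == "pop2"])
  expect_lt(abs(mean(st$fst, na.rm = TRUE) - 0.15), 0.02)
  expect_true(all(st$fst <= 1, na.rm = TRUE))
})

test_that("ROD definition and undefined propagation", {
  expect_equal(rod_window(2e-4, 2e-4), 0)
  expect_equal(rod_window(1e-4, 2e-4), 0.5)
  expect_true(is.na(rod_window(1e-4, 0)))
})

test_that("sliding windows tile chromosomes as specified", {
  expect_equal(nrow(sliding_windows(genome_layout("c1", 3e6), 1e6, 1e5)), 21)
  one <- sliding_windows(genome_layout("c1", 1e6), 1e6, 1e5)
  expect_equal(nrow(one), 1)
  short <- sliding_windows(genome_layout("c1", 4e5), 1e6, 1e5)
  expect_equal(as.numeric(c(short$start, short$end)), c(0, 4e5))
})

test_that("top-quantile selection counts, merges and ignores order", {
  st <- data.frame(chrom = "A01", start = seq(0, 99) * 1e5,
                   end = seq(0, 99) * 1e5 + 1e6, fst = 1:100,
                   rod = NA_real_)
  top <- top_quantile_regions(st, "fst", 0.05)
  expect_equal(attr(top, "threshold"), quantile(1:100, 0.95, names = FALSE))
  # 5 overlapping windows merge into one region spanning windows 96..100
  expect_equal(nrow(top), 1)
  expect_equal(c(top$start, top$end), c(95 * 1e5, 99 * 1e5 + 1e6))
  shuf <- st[sample(100), ]
  top2 <- top_quantile_regions(shuf, "fst", 0.05)
  expect_equal(as.data.frame(top2), as.data.frame(top))
  # ties: all equal -> everything selected, one region per chromosome
  st$fst <- 1
  expect_equal(nrow(top_quantile_regions(st, "fst", 0.05)), 1)
  expect_error(top_quantile_regions(st, "rod", 0.05), "undefined")
})

test_that("sweep scan: ROD and Fst top regions hit the planted sweep", {
  sweep <- list(chrom = "A01", start = 2e6, end = 2.6e6,
                target_subpop = "pop1", residual_freq = 0.05)
  hit <- vapply(1:25, function(r) {
    cfg <- sim_config(seed = 9000 + r, n_sites = 3000, n_subpops = 3,
                      n_per_subpop = 15, sweep = sweep)
    geno <- simulate_genome(cfg)
    pop <- simulate_population(cfg, geno$layout, geno$masks)
    gm <- implant_sweep(pop$gm, pop$labels, sweep, cfg$seed)
    tgt <- names(pop$labels)[pop$labels == "pop1"]
    ref <- names(pop$labels)[pop$labels != "pop1"]
    st <- selection_scan(gm, tgt, ref)
    olap <- function(rs) any(rs$chrom == "A01" & rs$start < 2.6e6 & rs$end > 2e6)
    olap(top_quantile_regions(st, "rod", 0.05)) &&
      olap(top_quantile_regions(st, "fst", 0.05))
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})
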