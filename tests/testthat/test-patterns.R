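test_that("profile PCA matches a hand SVD with a fixed sign convention", {
  x <- matrix(c(1, 2, 3,
                4, 6, 8), 2, 3, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("0", "4", "8")))
  res <- pca_profiles(x)
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  # reconstruction reproduces the centred matrix
  expect_equal(res$scores %*% t(res$loadings), xc, tolerance = 1e-9)
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-12)
  expect_equal(unname(abs(res$scores[, 1])), abs(sv$u[, 1] * sv$d[1]),
               tolerance = 1e-9)
  # sign convention: dominant loading of each PC positive
  for (j in seq_len(ncol(res$loadings))) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  expect_error(pca_profiles(matrix(1, 5, 3)), "constant")
})

test_that("PCA reconstruction holds on simulated profiles", {
  sim <- generate_ld_dataset(sim_spec(n_features = 80, seed = 12))
  prof <- mean_profiles(sim$table)
  res <- pca_profiles(prof)
  expect_equal(res$scores %*% t(res$loadings), prof - rowMeans(prof),
               tolerance = 1e-9)
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-12)
})

test_that("well separated planted profile groups cluster perfectly", {
  zts <- c(0, 4, 8, 12, 16, 20)
  withr::with_seed(13, {
    g1 <- t(replicate(50, cos(2 * pi * (zts - 0) / 24) + rnorm(6, 0, 0.05)))
    g2 <- t(replicate(50, cos(2 * pi * (zts - 12) / 24) + rnorm(6, 0, 0.05)))
    prof <- rbind(g1, g2)
    rownames(prof) <- sprintf("f%03d", 1:100)
    colnames(prof) <- as.character(zts)
    cl <- cluster_profiles(prof, cut_height = 100, min_cluster_size = 20)
    expect_equal(length(setdiff(unique(cl$cluster), "unassigned")), 2)
    # adjusted Rand = 1: partition identical to planting up to labels
    expect_equal(length(unique(cl$cluster[1:50])), 1)
    expect_equal(length(unique(cl$cluster[51:100])), 1)
    expect_false(cl$cluster[1] == cl$cluster[51])

    # feature order invariance
    perm <- sample(100)
    cl2 <- cluster_profiles(prof[perm, ], cut_height = 100,
                            min_cluster_size = 20)
    expect_identical(cl2$cluster[match(cl$feature, cl2$feature)], cl$cluster)

    # oversized minimum forces unassignment of at least one group
    cl3 <- cluster_profiles(prof, min_cluster_size = 60)
    expect_true("unassigned" %in% cl3$cluster)
  })
})

test_that("identical profiles give a single cluster and small n warns", {
  prof <- matrix(rep(c(1, 2, 3, 2, 1, 0), each = 40), 40, 6,
                 dimnames = list(sprintf("f%02d", 1:40),
                                 c("0", "4", "8", "12", "16", "20")))
  cl <- cluster_profiles(prof, min_cluster_size = 20)
  expect_equal(unique(cl$cluster), "C1")
  expect_warning(cluster_profiles(prof[1:5, ], min_cluster_size = 20),
                 "unassigned")
})

test_that("peak phase distributions count rhythmic features", {
  res <- data.frame(feature = sprintf("f%02d", 1:10),
                    peak_zt = rep(8, 10), rhythmic = TRUE)
  d <- peak_phase_distribution(res, zts = c(0, 4, 8, 12, 16, 20))
  expect_equal(d$fraction[d$zt == 8], 1)
  expect_equal(sum(d$fraction), 1)
  expect_error(peak_phase_distribution(
    data.frame(feature = "a", peak_zt = 0, rhythmic = FALSE)), "no rhythmic")
})

test_that("uniformly planted phases give a uniform peak distribution", {
  grid_phase <- function(n) sample(c(0, 4, 8, 12, 16, 20), n, replace = TRUE)
  sim <- generate_ld_dataset(sim_spec(n_features = 600, frac_rhythmic = 1,
                                      fold = 4, cv = 0.05, phase = grid_phase,
                                      loading_spread = 0, seed = 14))
  res <- rhythm_analysis(mean_normalize(sim$table))
  d <- peak_phase_distribution(res)
  gof <- chisq.test(d$count, p = rep(1 / 6, 6))
  expect_gt(gof$p.value, 0.01)
})

test_that("protein-motif peak pairing reports the differing fraction", {
  pr <- data.frame(feature = "P1", locus = "X", peak_zt = 4, rhythmic = TRUE)
  mo <- data.frame(feature = c("m1", "m2"), locus = "X",
                   peak_zt = c(4, 0), rhythmic = TRUE)
  pairs <- pair_protein_phospho(pr, mo)
  expect_equal(nrow(pairs), 2)
  expect_equal(attr(pairs, "fraction_differing"), 0.5)

  mo2 <- transform(mo, peak_zt = 4)
  expect_equal(attr(pair_protein_phospho(pr, mo2), "fraction_differing"), 0)
  expect_error(pair_protein_phospho(pr, transform(mo, locus = "Z")),
               "no shared loci")
})

test_that("independent protein and motif phases differ at the 5/6 rate", {
  withr::with_seed(15, {
    zts <- c(0, 4, 8, 12, 16, 20)
    n <- 3000
    pr <- data.frame(feature = sprintf("P%04d", 1:500),
                     locus = sprintf("L%04d", 1:500),
                     peak_zt = sample(zts, 500, TRUE), rhythmic = TRUE)
    mo <- data.frame(feature = sprintf("m%04d", 1:n),
                     locus = sample(pr$locus, n, TRUE),
                     peak_zt = sample(zts, n, TRUE), rhythmic = TRUE)
    frac <- attr(pair_protein_phospho(pr, mo), "fraction_differing")
    expect_lt(abs(frac - 5 / 6), 0.03)
  })
})

test_that("Fisher category enrichment matches hypergeometric enumeration", {
  bg <- sprintf("f%02d", 1:8)
  members <- bg[1:4]
  ann <- data.frame(term = "T1", feature = bg[c(1, 2, 3, 5)])
  res <- category_enrichment(members, bg, ann, mode = "fisher")
  # table [[3,1],[1,3]]
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$p, fisher_oracle(3, 1, 1, 3), tolerance = 1e-12)

  # term covering the whole background is uninformative
  ann2 <- data.frame(term = "ALL", feature = bg)
  expect_equal(category_enrichment(members, bg, ann2)$p, 1)

  # random tables with N <= 50 agree with the enumeration oracle
  withr::with_seed(16, {
    for (i in 1:20) {
      N <- sample(8:50, 1)
      bgN <- sprintf("g%03d", 1:N)
      mem <- sample(bgN, sample(2:(N - 2), 1))
      tf <- sample(bgN, sample(2:(N - 2), 1))
      res <- category_enrichment(mem, bgN,
                                 data.frame(term = "t", feature = tf))
      a <- sum(mem %in% tf); b <- sum(!mem %in% tf)
      c_ <- sum(!tf %in% mem); d <- N - a - b - c_
      expect_equal(res$p, fisher_oracle(a, b, c_, d), tolerance = 1e-9)
    }
  })
})

test_that("KS-on-loadings ranks a planted high-loading term first", {
  withr::with_seed(17, {
    bg <- sprintf("f%03d", 1:200)
    loadings <- setNames(c(runif(40, 0.6, 1), runif(160, 0, 0.3)), bg)
    ann <- data.frame(
      term = rep(c("planted", "random1", "random2"), each = 40),
      feature = c(bg[1:40], sample(bg, 40), sample(bg, 40))
    )
    res <- category_enrichment(character(), bg, ann, mode = "ks_on_loadings",
                               loadings = loadings)
    expect_equal(res$term[1], "planted")
    expect_lt(res$p[1], 1e-6)
  })
})
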