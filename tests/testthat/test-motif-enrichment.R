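test_that("site windows are extracted with terminal padding", {
  seqs <- c(prot = "MKAASTPLKDEFGHIKLSPR")  # length 20
  w8 <- extract_windows(data.frame(locus = "prot", position = 8), seqs)
  expect_equal(nchar(w8$window), 15)
  expect_false(grepl("_", w8$window))
  expect_equal(w8$window, unname(substring(seqs, 1, 15)))

  w3 <- extract_windows(data.frame(locus = "prot", position = 3), seqs)
  expect_equal(substring(w3$window, 1, 5), "_____")
  expect_equal(nchar(w3$window), 15)

  expect_error(extract_windows(data.frame(locus = "prot", position = 25),
                               seqs), "outside sequence")
  expect_error(extract_windows(data.frame(locus = "nope", position = 2),
                               seqs), "missing")
})

test_that("binomial logo heights match the exact tail and the printed line", {
  # foreground: 10 windows, 5 with R at +2; background rate of R at +2 = 0.2
  fg <- c(replicate(5, make_window(list(`2` = "R"))),
          replicate(5, make_window(list(`2` = "G"))))
  bg <- c(replicate(4, make_window(list(`2` = "R"))),
          replicate(16, make_window(list(`2` = "G"))))
  res <- binomial_logo(fg, bg)
  cell <- res$heights[res$heights$position == 2 & res$heights$residue == "R", ]
  expect_equal(cell$k, 5)
  expect_equal(cell$n, 10)
  expect_equal(cell$p_bg, 0.2)
  expect_equal(cell$p_value, 0.0328, tolerance = 1e-3)
  expect_equal(cell$p_value, binom_tail_oracle(5, 10, 0.2), tolerance = 1e-12)
  expect_equal(cell$height, 1.48, tolerance = 0.01)

  # Bonferroni line over 20 residues x 15 positions
  expect_equal(res$threshold, 3.78)
  expect_equal(round(-log10(0.05 / 300), 1), 3.8)

  # under-representation is signed negative
  cellG <- res$heights[res$heights$position == 2 & res$heights$residue == "G", ]
  expect_lt(cellG$height, 0)
  expect_error(binomial_logo(character(), bg), "empty foreground")
})

test_that("logo tails agree with exact enumeration for n <= 30", {
  withr::with_seed(40, {
    for (i in 1:10) {
      n <- sample(5:30, 1)
      k <- sample(0:n, 1)
      p <- runif(1, 0.05, 0.6)
      over <- binom_tail_oracle(k, n, p)
      expect_equal(pbinom(k - 1, n, p, lower.tail = FALSE), over,
                   tolerance = 1e-12)
    }
  })
})

test_that("pads never contribute to counts", {
  fg <- c(make_window(list(`-7` = "_", `1` = "P")),
          make_window(list(`-7` = "_", `1` = "P")))
  bg <- replicate(10, make_window(list(`1` = "P")))
  res <- binomial_logo(fg, bg)
  cell <- res$heights[res$heights$position == -7 & res$heights$residue == "A", ]
  expect_equal(cell$n, 0)
  expect_equal(cell$flag, "no_observations")
  expect_equal(cell$height, 0)
})

test_that("a null foreground stays below the significance line", {
  withr::with_seed(41, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    rand_win <- function() paste(sample(aa, 15, TRUE), collapse = "")
    bg <- replicate(2000, rand_win())
    hits <- vapply(1:20, function(i) {
      fg <- sample(bg, 50)
      res <- binomial_logo(fg, bg)
      max(abs(res$heights$height)) < res$threshold
    }, TRUE)
    expect_gte(sum(hits), 17)
  })
})

test_that("grouped-residue binomials cover the documented cases", {
  # saturated group: event rate 1, p-value 1
  fg <- replicate(5, make_window())
  bg <- replicate(10, make_window())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sat <- grouped_binomial(fg, bg, group = aa, positions = 1:3)
  expect_equal(sat$p_bg, 1)
  expect_equal(sat$p_value, 1)

  # planted acidic +1..+3 at rate 1 vs a low background rate
  fgA <- replicate(60, make_window(list(`1` = "D")))
  bgA <- c(replicate(30, make_window(list(`1` = "D"))),
           replicate(70, make_window()))
  acid <- grouped_binomial(fgA, bgA, group = c("D", "E"), positions = 1:3)
  expect_equal(acid$k, 60)
  expect_equal(acid$p_bg, 0.3)
  expect_lt(acid$p_value, 1e-10)
  expect_equal(acid$p_value, binom_tail_oracle(60, 60, 0.3), tolerance = 1e-9)

  expect_error(grouped_binomial(fg, bg, group = "D", positions = 9),
               "positions")
  expect_error(grouped_binomial(fg, bg, group = character(), positions = 1),
               "empty residue group")
})

test_that("motif classes match their consensus definitions", {
  cls <- motif_classes()
  sp <- make_window(list(`1` = "P"))
  cdk <- make_window(list(`1` = "P", `4` = "K"))
  acid <- make_window(list(`2` = "E"))
  hydro <- make_window(list(`-5` = "L", `4` = "V"), fill = "G")
  none <- make_window(fill = "G")
  expect_true(match_motif_class(sp, cls$proline_directed))
  expect_false(match_motif_class(sp, cls$cdk_like))
  expect_true(match_motif_class(cdk, cls$cdk_like))
  expect_true(match_motif_class(acid, cls$acid_directed))
  expect_true(match_motif_class(hydro, cls$hydrophobic_directed))
  expect_false(any(vapply(cls, function(cl) match_motif_class(none, cl), TRUE)))
})

test_that("phase-specific enrichment pinpoints a planted consensus", {
  withr::with_seed(42, {
    zts <- c(0, 4, 8, 12, 16, 20)
    n <- 300
    feats <- sprintf("m%03d", 1:n)
    peak <- sample(zts, n, TRUE)
    # all ZT16 motifs proline-directed; background rate much lower
    win <- ifelse(peak == 16,
                  replicate(n, make_window(list(`1` = "P"))),
                  replicate(n, make_window(list(`1` = "G"))))
    rhythm <- data.frame(feature = feats, peak_zt = peak, rhythmic = TRUE)
    windows <- data.frame(feature = feats, window = win)
    res <- phase_motif_enrichment(rhythm, windows, win)
    best <- res[which.min(res$p_value), ]
    expect_equal(best$zt, 16)
    expect_equal(best$class, "proline_directed")
    # counts per cell partition the rhythmic motifs with windows
    one_class <- res[res$class == "proline_directed", ]
    expect_equal(sum(one_class$n), n)
  })
})

test_that("equal class frequencies in every bin give no significant cell", {
  withr::with_seed(43, {
    zts <- c(0, 4, 8, 12, 16, 20)
    sigs <- vapply(1:10, function(i) {
      n <- 240
      feats <- sprintf("m%03d", 1:n)
      peak <- sample(zts, n, TRUE)
      win <- replicate(n, make_window(
        if (runif(1) < 0.3) list(`1` = "P") else list(`1` = "G")))
      rhythm <- data.frame(feature = feats, peak_zt = peak, rhythmic = TRUE)
      windows <- data.frame(feature = feats, window = win)
      res <- phase_motif_enrichment(rhythm, windows, win,
                                    classes = motif_classes()["proline_directed"])
      any(res$q < 0.05)
    }, TRUE)
    expect_lte(sum(sigs), 1)
  })
})
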