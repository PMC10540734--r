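make_variants <- function(meta_rows, ab) {
  meta <- do.call(rbind, lapply(meta_rows, as.data.frame))
  rownames(ab) <- meta$variant_id
  phospho_variants(meta, ab)
}

two_col_keys <- format_sample_keys("LD", c(0, 4), c("A", "A"))

test_that("variants sharing a site set sum into one motif", {
  v <- make_variants(list(
    list(variant_id = "v1", locus = "X", sequence = "PEP", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "10",
         ambiguous = FALSE),
    list(variant_id = "v2", locus = "X", sequence = "PEP", charge = 3,
         missed_cleavages = 0, modifications = "", positions = "10",
         ambiguous = FALSE)
  ), matrix(c(100, 50, 40, 60), 2, 2, dimnames = list(NULL, two_col_keys)))
  out <- merge_variants(v)
  expect_equal(out$report$n_motifs, 1)
  expect_equal(unname(out$motifs$abundance["X:10", ]), c(150, 100))
  expect_equal(out$motifs$features$site_key, "10")
})

test_that("a multiply phosphorylated site set is a distinct motif", {
  v <- make_variants(list(
    list(variant_id = "v1", locus = "X", sequence = "PEP", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "10",
         ambiguous = FALSE),
    list(variant_id = "v2", locus = "X", sequence = "PEP", charge = 2,
         missed_cleavages = 1, modifications = "", positions = "10;14",
         ambiguous = FALSE)
  ), matrix(1:4, 2, 2, dimnames = list(NULL, two_col_keys)))
  out <- merge_variants(v)
  expect_equal(out$report$n_motifs, 2)
  expect_setequal(out$motifs$features$site_key, c("10", "10+14"))
})

test_that("merging matches a brute-force group-and-sum on randomized variants", {
  withr::with_seed(11, {
    n <- 500
    keys <- as.vector(outer(c(0, 4, 8, 12, 16, 20), LETTERS[1:5],
                            function(z, r) format_sample_keys("LD", z, r)))
    meta <- data.frame(
      variant_id = sprintf("v%03d", 1:n),
      locus = sample(sprintf("L%02d", 1:30), n, replace = TRUE),
      sequence = "PEP", charge = sample(2:4, n, TRUE),
      missed_cleavages = sample(0:2, n, TRUE),
      modifications = sample(c("", "oxidation"), n, TRUE),
      positions = vapply(1:n, function(i) {
        paste(sample(5:40, sample(1:2, 1)), collapse = ";")
      }, ""),
      ambiguous = FALSE, stringsAsFactors = FALSE
    )
    ab <- matrix(rlnorm(n * 30, 4, 1), n, 30,
                 dimnames = list(meta$variant_id, keys))
    v <- phospho_variants(meta, ab)
    out <- merge_variants(v)
    oracle <- merge_oracle(meta, ab)
    expect_setequal(rownames(out$motifs$abundance), rownames(oracle))
    expect_equal(out$motifs$abundance,
                 oracle[rownames(out$motifs$abundance), ],
                 tolerance = 1e-12)
    # mass conservation to 1e-9 relative
    expect_equal(colSums(out$motifs$abundance), colSums(ab),
                 tolerance = 1e-9)
    # permutation invariance
    perm <- sample(n)
    v2 <- phospho_variants(meta[perm, ], ab[perm, ])
    out2 <- merge_variants(v2)
    expect_identical(rownames(out2$motifs$abundance),
                     rownames(out$motifs$abundance))
    expect_equal(out2$motifs$abundance, out$motifs$abundance,
                 tolerance = 1e-12)
    # idempotence: re-merging the motif output is the identity
    m <- out$motifs
    v3 <- phospho_variants(
      data.frame(variant_id = m$features$feature,
                 locus = m$features$locus, sequence = "PEP",
                 charge = 2, missed_cleavages = 0, modifications = "",
                 positions = gsub("+", ";", m$features$site_key,
                                  fixed = TRUE),
                 ambiguous = FALSE, stringsAsFactors = FALSE),
      m$abundance)
    out3 <- merge_variants(v3)
    expect_equal(out3$motifs$abundance, m$abundance, tolerance = 1e-12)
  })
})

test_that("variants without phospho-sites or with shared loci are discarded", {
  v <- make_variants(list(
    list(variant_id = "v1", locus = "X", sequence = "PEP", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "",
         ambiguous = FALSE),
    list(variant_id = "v2", locus = "X;Y", sequence = "PEP", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "5",
         ambiguous = FALSE),
    list(variant_id = "v3", locus = "X", sequence = "PEP", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "5",
         ambiguous = FALSE)
  ), matrix(1:6, 3, 2, dimnames = list(NULL, two_col_keys)))
  out <- merge_variants(v)
  expect_equal(out$report$n_discarded, 2)
  expect_setequal(out$report$discarded$reason, c("no_sites", "shared"))
  expect_equal(out$report$n_in,
               sum(out$motifs$features$n_members) + out$report$n_discarded)
})

test_that("ambiguous sites are reassigned from matching predictions", {
  v <- make_variants(list(
    list(variant_id = "v1", locus = "X", sequence = "AASPK", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "12",
         ambiguous = TRUE),
    list(variant_id = "v2", locus = "X", sequence = "NOMATCH", charge = 2,
         missed_cleavages = 0, modifications = "", positions = "30",
         ambiguous = TRUE)
  ), matrix(1:4, 2, 2, dimnames = list(NULL, two_col_keys)))
  preds <- data.frame(sequence = "AASPK", charge = 2, n_mods = 1,
                      positions = "14", confidence = 1)
  r <- resolve_ambiguous_sites(v, preds)
  expect_equal(r$meta$positions[1], "14")
  expect_equal(r$meta$site_flag[1], "reassigned")
  expect_equal(r$meta$positions[2], "30")
  expect_equal(r$meta$site_flag[2], "unconfirmed")

  # a prediction with a different modification count is not a match
  preds2 <- data.frame(sequence = "AASPK", charge = 2, n_mods = 2,
                       positions = "14", confidence = 1)
  r2 <- resolve_ambiguous_sites(v, preds2)
  expect_equal(r2$meta$positions[1], "12")
  expect_equal(r2$meta$site_flag[1], "unconfirmed")
})

test_that("merge inverts the synthetic variant generator exactly", {
  sim <- generate_ld_dataset(sim_spec(n_features = 40, seed = 5))
  gen <- generate_phospho_variants(sim$table, seed = 6)
  out <- merge_variants(gen$variants)
  # abundances per (locus, site set) equal the source motif abundances
  key_of <- gen$truth$motif_feature[match(
    vapply(strsplit(out$motifs$features$member_ids, ";"), `[`, "", 1),
    gen$truth$variant_id)]
  expect_equal(unname(out$motifs$abundance),
               unname(sim$table$abundance[key_of, ]), tolerance = 1e-9)

  # planted ambiguous reassignments are fully recovered
  genA <- generate_phospho_variants(sim$table, ambiguous_frac = 0.4, seed = 8)
  expect_gt(sum(genA$variants$meta$ambiguous), 0)
  resolved <- resolve_ambiguous_sites(genA$variants, genA$predictions)
  expect_identical(resolved$meta$positions,
                   genA$truth$true_positions[match(resolved$meta$variant_id,
                                                   genA$truth$variant_id)])
  genN <- generate_phospho_variants(sim$table, ambiguous_frac = 0, seed = 9)
  expect_false(any(genN$variants$meta$ambiguous))
  expect_null(genN$predictions)
})
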