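test_that("window enumeration matches brute force and the published counts", {
  expect_equal(nrow(enumerate_site_windows(30, 1, 60, 1, 1)), 1830)
  expect_equal(nrow(enumerate_site_windows(30, 5, 60, 5, 5)), 78)
  # brute force across assorted parameter combinations
  for (p in list(c(30, 1, 60, 1, 1), c(30, 5, 60, 5, 5),
                 c(5, 1, 10, 1, 1), c(4, 2, 8, 3, 2))) {
    expect_equal(nrow(do.call(enumerate_site_windows, as.list(p))),
                 do.call(bf_window_count, as.list(p)),
                 info = paste(p, collapse = ","))
  }
  w <- enumerate_site_windows(30, 60, 60)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$offset_start, w$offset_end), c(-30, 30))
  # offsets never include 0
  w <- enumerate_site_windows(5, 1, 10)
  expect_false(any(w$offset_start == 0 | w$offset_end == 0))
  expect_error(enumerate_site_windows(5, 1, 20), "invalid parameter")
  expect_error(enumerate_site_windows(5, 6, 2), "invalid parameter")
})

test_that("kmer_frequency counts overlapping occurrences", {
  expect_equal(kmer_frequency("GGAU", "G"), 0.5)
  expect_equal(kmer_frequency("GGG", "GG"), 1)
  expect_equal(kmer_frequency("AUGC", "GG"), 0)
  expect_equal(kmer_frequency("AU", "GGG"), 0)  # window shorter than k
  expect_error(kmer_frequency("AUGC", "GT"), "invalid token")
})

test_that("single-nucleotide frequencies over one window sum to 1", {
  set.seed(8)
  for (i in 1:20) {
    s <- random_rna(sample(1:30, 1))
    expect_equal(sum(vapply(c("A", "C", "G", "U"), kmer_frequency,
                            0, seq_window = s)), 1)
  }
})

test_that("codon and amino-acid frequencies follow the stated conventions", {
  tx <- transcript("g1", "AAAUGGCUUAAGG", 2, 11)  # codons AUG GCU UAA
  expect_equal(codon_aa_frequency(tx, "cds", "AUG"), 1 / 3)
  # aa denominator excludes the stop codon
  expect_equal(codon_aa_frequency(tx, "cds", "M"), 1 / 2)
  # site window in the 5'-UTR: no in-frame codon overlaps
  expect_equal(codon_aa_frequency(tx, c(0, 1), "AUG"), 0)
  # absolute window over the first codon only
  expect_equal(codon_aa_frequency(tx, c(2, 4), "AUG"), 1)
  expect_equal(codon_aa_frequency(tx, c(2, 4), "M"), 1)
  # window spanning codons 2-3: GCU UAA; stop counted as codon, not aa
  expect_equal(codon_aa_frequency(tx, c(5, 10), "GCU"), 1 / 2)
  expect_equal(codon_aa_frequency(tx, c(5, 10), "A"), 1)
  expect_error(codon_aa_frequency(tx, "cds", "XYZ"), "invalid")
})

test_that("fold_mfe reproduces hand values and the enumeration oracle", {
  expect_equal(fold_mfe("AAAA"), 0)
  expect_equal(fold_mfe("GGGAAACCC"), -9)
  expect_error(fold_mfe("GGXA"), "invalid letters")
  set.seed(5)
  for (i in 1:25) {
    s <- random_rna(sample(4:12, 1))
    expect_equal(fold_mfe(s), bf_mfe(s), info = s)
    expect_lte(fold_mfe(s), 0)
  }
})

test_that("fold backend plug-in takes precedence", {
  withr::with_options(list(cleavefeat.fold_backend = function(s) -99), {
    expect_equal(fold_mfe("GGGAAACCC"), -99)
  })
})

test_that("window_ro averages over in-bounds positions", {
  ro <- structure(list(
    sites = data.frame(gene = "g1", position = c(10L, 11L),
                       ro_site = c(0.1, 0.3)),
    genes = data.frame(gene = "g1", ro_gene = 0.4, ro_utr5 = 0,
                       ro_cds = 0.4, ro_utr3 = 0)), class = "cf_ro_table")
  # site at position 10: offsets +1, +2 are positions 10, 11
  expect_equal(window_ro(ro, "g1", 10L, c(1, 2)), 0.2)
  # window past the transcript end: only position 10/11 in bounds
  expect_equal(window_ro(ro, "g1", 10L, c(1, 5), transcript_length = 12),
               0.4 / 2)
  expect_equal(window_ro(ro, "g2", 10L, c(1, 2)), 0)
})

test_that("region features cover k-mers, blocks, structure and RO sums", {
  # explicit 9-codon CDS with a single AUG and a single stop
  tx <- transcript("t1", paste0("GAAAUUUCCC",
                                "AUGGCUGGGUUUAAACCCGGGUUUUAA",
                                "GGCCAAUU"), 10, 37)
  ro <- structure(list(
    sites = data.frame(gene = "t1", position = c(1L, 12L),
                       ro_site = c(0.2, 0.5)),
    genes = data.frame(gene = "t1", ro_gene = 0.7, ro_utr5 = 0.2,
                       ro_cds = 0.5, ro_utr3 = 0)), class = "cf_ro_table")
  cfg <- feature_config(categories = c("nucleotide", "codon",
                                       "amino_acid", "structure",
                                       "occupancy"),
                        k = 1, site_max_offset = 3, site_min_len = 1,
                        site_max_len = 2, struct_max_offset = 3,
                        struct_min_len = 6, struct_max_len = 6,
                        struct_step = 1, occ_max_offset = 3,
                        occ_min_len = 1, occ_max_len = 1,
                        end_block_nt = 12, codon_block = 10)
  rf <- region_features(tx, ro, cfg)
  regions <- transcript_regions(tx)
  expect_equal(rf[["nt|rna|whole|G"]],
               kmer_frequency(regions$whole, "G"))
  expect_equal(rf[["nt|rna|5utr:end5|A"]],
               kmer_frequency(substr(regions$utr5, 1, 12), "A"))
  expect_equal(rf[["mfe|rna|cds|"]], fold_mfe(regions$cds))
  # RO sum of the whole region equals RO_gene
  expect_equal(rf[["ro|rna|whole|"]], 0.7)
  expect_equal(rf[["ro|rna|cds|"]], 0.5)
  # 10-codon start block truncated to the 9 codons present
  expect_equal(rf[["codon|rna|cds:start_codons|AUG"]], 1 / 9)
  # aa frequencies in the full CDS exclude the stop from the denominator
  expect_equal(rf[["aa|rna|cds|M"]], 1 / 8)
})

test_that("build_feature_matrix drops context-less sites and is deterministic", {
  tx <- toy_transcript(n_codons = 40, seed = 3)   # 138 nt
  tx2 <- tx; tx2$id <- "t2"
  transcripts <- list(t1 = tx, t2 = tx2)
  cfg <- feature_config(categories = "nucleotide", k = 1,
                        site_max_offset = 30, site_min_len = 1,
                        site_max_len = 3, whole_rna = FALSE)
  sites <- data.frame(gene = c("t1", "t1", "t1", "t2"),
                      position = c(10L, 60L, 130L, 60L))
  fm <- build_feature_matrix(sites, transcripts, config = cfg)
  # position 10 lacks 30 nt upstream; 130 lacks 30 nt downstream (len 138)
  expect_equal(nrow(fm$sites), 2)
  expect_setequal(fm$sites$position, c(60L, 60L))
  # identical transcripts give identical rows
  expect_equal(fm$X[1, ], fm$X[2, ])
  # pure function: repeated call agrees exactly
  fm2 <- build_feature_matrix(sites, transcripts, config = cfg)
  expect_identical(fm$X, fm2$X)
})

test_that("toy configuration column count matches hand enumeration", {
  cfg <- feature_config(categories = "nucleotide", k = 1,
                        site_max_offset = 3, site_min_len = 1,
                        site_max_len = 6, whole_rna = FALSE)
  tx <- toy_transcript(n_codons = 30, seed = 4)
  fm <- build_feature_matrix(data.frame(gene = "t1", position = 50L),
                             list(t1 = tx), config = cfg)
  # windows of lengths 1..6 in a 6-nt strip: 6+5+4+3+2+1 = 21; 4 tokens
  expect_equal(ncol(fm$X), 21 * 4)
  expect_true(all(fm$X >= 0 & fm$X <= 1))
})

test_that("matrix window values agree with direct kmer computation", {
  tx <- toy_transcript(n_codons = 30, seed = 6)
  cfg <- feature_config(categories = "nucleotide", k = 1:2,
                        site_max_offset = 4, site_min_len = 1,
                        site_max_len = 8, whole_rna = FALSE)
  pos <- c(40L, 41L, 55L)
  fm <- build_feature_matrix(data.frame(gene = "t1", position = pos),
                             list(t1 = tx), config = cfg)
  for (j in sample(ncol(fm$X), 40)) {
    sp <- fm$specs[j, ]
    for (i in seq_along(pos)) {
      a <- cleavefeat:::offset_to_abs(pos[i], sp$offset_start)
      b <- cleavefeat:::offset_to_abs(pos[i], sp$offset_end)
      expect_equal(unname(fm$X[i, j]),
                   kmer_frequency(substr(tx$seq, a + 1, b + 1), sp$token),
                   info = sp$name)
    }
  }
  # single-nucleotide frequencies over the same window sum to 1
  one_nt <- fm$specs$token %in% c("A", "C", "G", "U") &
    nchar(fm$specs$token) == 1
  key <- paste(fm$specs$offset_start, fm$specs$offset_end)[one_nt]
  for (kk in unique(key)) {
    cols <- which(one_nt)[key == kk]
    expect_equal(unname(rowSums(fm$X[, cols])), rep(1, length(pos)))
  }
})

test_that("around-site codon windows restrict to in-frame overlapping codons", {
  tx <- transcript("g1", paste0("AAAAAAAAAA", "AUGGCUGGGUUUUAA", "CCCCC"),
                   10, 25)
  cfg <- feature_config(categories = "codon", site_max_offset = 3,
                        site_min_len = 2, site_max_len = 2,
                        whole_rna = FALSE)
  # site at position 13: offsets +1..+2 are positions 13-14 (codon GCU)
  fm <- build_feature_matrix(data.frame(gene = "g1", position = 13L),
                             list(g1 = tx), config = cfg)
  sp <- fm$specs
  j <- which(sp$offset_start == 1 & sp$offset_end == 2 &
               sp$token == "GCU")
  expect_equal(unname(fm$X[1, j]), 1)
  j2 <- which(sp$offset_start == -3 & sp$offset_end == -2 &
                sp$token == "AUG")  # positions 10-11 -> codon AUG
  expect_equal(unname(fm$X[1, j2]), 1)
})

test_that("occupancy windows are truncated at transcript bounds", {
  tx <- toy_transcript(n_codons = 20, seed = 9)  # 78 nt
  ro <- structure(list(
    sites = data.frame(gene = "t1", position = 70:77,
                       ro_site = rep(0.1, 8)),
    genes = data.frame(gene = "t1", ro_gene = 0.8, ro_utr5 = 0,
                       ro_cds = 0, ro_utr3 = 0.8)), class = "cf_ro_table")
  cfg <- feature_config(categories = "occupancy", occ_max_offset = 20,
                        occ_min_len = 40, occ_max_len = 40,
                        occ_step = 1, whole_rna = FALSE)
  fm <- build_feature_matrix(data.frame(gene = "t1", position = 70L),
                             list(t1 = tx), ro, cfg)
  # window +/-20 around position 70 truncates to positions 50..77 (28 nt),
  # of which 70..77 carry 0.1 each
  j <- which(fm$specs$offset_start == -20 & fm$specs$offset_end == 20)
  expect_equal(unname(fm$X[1, j]), 0.8 / 28)
})
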