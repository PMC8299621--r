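cap_track <- function(gene, total) count_track(gene, "cap", 0L, total)

test_that("abundance retention uses a strict > 50 rule", {
  ab <- compute_abundance(list(cap_track("g1", 51), cap_track("g2", 50)))
  expect_true(ab$retained[ab$gene == "g1"])
  expect_false(ab$retained[ab$gene == "g2"])
  expect_false("g3" %in% ab$gene)
  expect_equal(nrow(compute_abundance(list())), 0)
})

test_that("CS_site is reads over cap abundance and CS_gene is its sum", {
  ab <- compute_abundance(list(cap_track("g1", 51), cap_track("g2", 100)),
                          min_reads = 50)
  deg <- list(count_track("g1", "degradome", c(3L, 9L), c(10, 5)),
              count_track("g3", "degradome", 1L, 4))  # g3 not retained
  cs <- compute_cs_table(deg, ab)
  expect_equal(cs$sites$cs_site[cs$sites$position == 3], 10 / 51)
  expect_equal(cs$genes$cs_gene[cs$genes$gene == "g1"], 15 / 51)
  expect_false("g3" %in% cs$sites$gene)
  # sparse: no rows for zero-read positions
  expect_equal(nrow(cs$sites), 2)
})

test_that("CS_site is invariant to common scaling of degradome and cap counts", {
  k <- 7
  ab1 <- compute_abundance(list(cap_track("g1", 60)))
  ab2 <- compute_abundance(list(cap_track("g1", 60 * k)))
  deg1 <- list(count_track("g1", "degradome", c(1L, 2L), c(6, 12)))
  deg2 <- list(count_track("g1", "degradome", c(1L, 2L), c(6, 12) * k))
  expect_equal(compute_cs_table(deg1, ab1)$sites$cs_site,
               compute_cs_table(deg2, ab2)$sites$cs_site)
})

test_that("RO_site, RO_gene and region sums follow the transcript regions", {
  tx <- list(g1 = transcript("g1", paste0(strrep("A", 10), "AUGGGGUAA",
                                          strrep("C", 5)), 10, 19))
  ab <- compute_abundance(list(cap_track("g1", 100)))
  rpf <- list(count_track("g1", "rpf", c(2L, 11L, 20L), c(5, 8, 2)))
  ro <- compute_ro_table(rpf, ab, tx)
  expect_equal(ro$sites$ro_site[ro$sites$position == 2], 0.05)
  g <- ro$genes[ro$genes$gene == "g1", ]
  expect_equal(g$ro_gene, (5 + 8 + 2) / 100)
  expect_equal(g$ro_utr5, 0.05)
  expect_equal(g$ro_cds, 0.08)   # only position 11 is in [10, 19)
  expect_equal(g$ro_utr3, 0.02)
  expect_error(compute_ro_table(rpf, ab, list()), "missing transcript")
})

make_gene_set <- function(n_sites_per_gene, cs_gene_levels, len = 100) {
  # one track per gene; counts chosen so cs_gene hits the requested level
  genes <- sprintf("g%02d", seq_along(cs_gene_levels))
  cap <- lapply(genes, cap_track, total = 100)
  deg <- mapply(function(g, lvl, ns) {
    count_track(g, "degradome", seq_len(ns) - 1L,
                rep(100 * lvl / ns, ns))
  }, genes, cs_gene_levels, n_sites_per_gene, SIMPLIFY = FALSE)
  tx <- setNames(lapply(genes, function(g) {
    transcript(g, paste0(strrep("A", 10), "AUG",
                         strrep("GCU", (len - 19) %/% 3), "UAA",
                         strrep("C", len - 16 - 3 * ((len - 19) %/% 3))),
               10, 16 + 3 * ((len - 19) %/% 3))
  }), genes)
  list(cs = compute_cs_table(deg, compute_abundance(cap)), tx = tx)
}

test_that("reliability filter applies the 20% rule and the percentile band", {
  # 20 genes: one with too few cleaved sites, the rest 25 sites each with
  # distinct cs_gene so the band edges are unambiguous
  lvls <- seq(0.1, 2, length.out = 20)
  ns <- c(10, rep(25, 19))
  d <- make_gene_set(ns, lvls)
  out <- filter_reliable_sites(d$cs, d$tx)
  kept <- unique(out$sites$gene)
  expect_false("g01" %in% kept)  # 10/100 = 10% cleaved -> dropped
  # band is computed over the 19 surviving genes; extremes fall outside
  surv <- sprintf("g%02d", 2:20)
  q <- quantile(lvls[2:20], c(0.05, 0.95))
  expect_setequal(kept, surv[lvls[2:20] > q[1] & lvls[2:20] < q[2]])
})

test_that("exclusion list drops sites and cs_gene is recomputed", {
  d <- make_gene_set(rep(25, 12), seq(0.5, 1.5, length.out = 12))
  excl <- data.frame(gene = "g05", position = 0)
  out <- filter_reliable_sites(d$cs, d$tx, exclusion = excl)
  expect_false(any(out$sites$gene == "g05" & out$sites$position == 0))
  g5 <- out$sites[out$sites$gene == "g05", ]
  expect_equal(out$genes$cs_gene[out$genes$gene == "g05"],
               sum(g5$cs_site))
})

test_that("split is gene-level, deterministic, and partitions the genes", {
  d <- make_gene_set(rep(25, 40), seq(0.5, 1.5, length.out = 40))
  cs <- split_sites(d$cs, test_fraction = 0.1, seed = 9)
  by_gene <- tapply(cs$sites$split, cs$sites$gene, function(s)
    length(unique(s)))
  expect_true(all(by_gene == 1))  # no gene straddles the split
  tg <- unique(cs$sites$gene[cs$sites$split == "test"])
  ng <- length(unique(cs$sites$gene))
  expect_equal(length(tg), round(ng * 0.1))
  expect_setequal(unique(cs$sites$split), c("train", "test"))

  cs2 <- split_sites(d$cs, test_fraction = 0.1, seed = 9)
  expect_equal(cs$sites$split, cs2$sites$split)
  cs3 <- split_sites(d$cs, test_fraction = 0.1, seed = 10)
  expect_false(identical(cs$sites$split, cs3$sites$split))
})

test_that("split refuses fewer than 10 genes and honours the 9:1 ratio", {
  d <- make_gene_set(rep(25, 8), seq(0.5, 1.5, length.out = 8))
  expect_error(split_sites(d$cs, 0.1, 1), "fewer than 10")

  # 1,000 genes, ratio 0.1 -> 900 train / 100 test (gene-level arithmetic)
  sites <- data.frame(gene = sprintf("g%04d", 1:1000), position = 0L,
                      reads = 1, cs_site = 0.1, split = "none",
                      stringsAsFactors = FALSE)
  cs <- cleavefeat:::cs_table(sites)
  cs <- split_sites(cs, 0.1, 2)
  expect_equal(sum(cs$sites$split == "test"), 100)
  expect_equal(sum(cs$sites$split == "train"), 900)
})
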