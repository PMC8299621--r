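# Independent oracles and fixture builders. Oracles deliberately use
# different algorithms from the implementation (enumeration / closed forms)
# so that agreement is informative.

# Brute-force window enumeration: test every (start, end) pair in the strip
# against the length and placement rules.
bf_window_count <- function(max_offset, min_len, max_len, step, len_step) {
  W <- 2 * max_offset
  lengths <- seq(min_len, max_len, by = len_step)
  n <- 0L
  for (s in seq_len(W)) {
    for (e in s:W) {
      L <- e - s + 1
      if (L %in% lengths && (s - 1) %% step == 0) n <- n + 1L
    }
  }
  n
}

# Exhaustive minimum-energy search over nested structures (first-position
# branching, no memoization): position i is either unpaired or paired with
# some k (pair allowed, loop >= min_loop), splitting the problem into the
# enclosed and following region.
bf_pair_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  if (key %in% names(w)) w[[key]] else NA_real_
}

bf_mfe <- function(seq, min_loop = 3) {
  chars <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      w <- bf_pair_weight(chars[i], chars[k])
      if (!is.na(w)) {
        best <- min(best, w + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    best
  }
  rec(1, length(chars))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# A deterministic toy transcript: 10 nt UTR5, `n_codons` codons, 8 nt UTR3.
toy_transcript <- function(id = "t1", n_codons = 20, seed = 1) {
  set.seed(seed)
  code <- cleavefeat:::rna_genetic_code()
  sense <- setdiff(names(code), names(code)[code == "*"])
  cds <- paste(c("AUG", sample(sense, n_codons - 2, replace = TRUE),
                 "UAA"), collapse = "")
  transcript(id, paste0(random_rna(10), cds, random_rna(8)), 10,
             10 + 3 * n_codons)
}

write_tsv_file <- function(d, path = tempfile(fileext = ".tsv")) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal feature matrix around a plain numeric design.
toy_feature_matrix <- function(X, y, split = rep("train", length(y)),
                               gene = paste0("g", seq_along(y))) {
  specs <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
    cleavefeat:::spec_row("nucleotide", "around_site",
                          ostart = -j, oend = -j, token = "A")
  }))
  specs$name <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  feature_matrix(data.frame(gene = gene, position = seq_along(y), y = y,
                            split = split, stringsAsFactors = FALSE),
                 X, specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared small simulation for pipeline-level tests (kept small for speed).
small_sim_config <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(n_genes = 15, utr5_len = c(30, 40), cds_codons = c(60, 80),
         utr3_len = c(30, 40), seed = seed), list(...))
  do.call(sim_config, args)
}
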