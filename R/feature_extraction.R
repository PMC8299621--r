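# Explanatory-variable construction: exhaustive sliding windows around each
# cleavage site and whole-RNA/region features, over sequence composition,
# secondary-structure stability and ribosome occupancy.
#
# Site-relative coordinates have no position 0: the cleavage point lies
# between offsets -1 and +1, and +1 is the nucleotide whose 5' end is
# detected by the degradome read. For a 0-based site position p, offset o
# maps to absolute position p + o (o < 0) or p + o - 1 (o > 0), so the
# +/-max_offset strip is the contiguous run [p - max_offset, p + max_offset - 1].

# ---- coordinate helpers ------------------------------------------------

offset_to_abs <- function(site, offset) {
  ifelse(offset < 0L, site + offset, site + offset - 1L)
}

strip_to_offset <- function(s, max_offset) {
  ifelse(s <= max_offset, s - max_offset - 1L, s - max_offset)
}

#' Enumerate sliding windows around a cleavage site
#'
#' All contiguous windows of each permitted length, placed every `step`
#' nucleotides inside the +/-`max_offset` region (which holds
#' `2 * max_offset` nucleotides since there is no offset 0). With the
#' defaults of the sequence feature space (+/-30, lengths 1-60, step 1)
#' this yields 1,830 windows; the structure mode (lengths 5-60 in steps of
#' 5, placement step 5) yields 78.
#'
#' @param max_offset Half-width of the region in nucleotides.
#' @param min_len,max_len Smallest and largest window length.
#' @param step Placement step in nucleotides.
#' @param len_step Increment between permitted window lengths.
#' @return data.frame with columns offset_start, offset_end, length,
#'   strip_start, strip_end (1-based indices into the strip).
#' @export
enumerate_site_windows <- function(max_offset = 30, min_len = 1,
                                   max_len = 60, step = 1, len_step = 1) {
  max_offset <- as.integer(max_offset); min_len <- as.integer(min_len)
  max_len <- as.integer(max_len); step <- as.integer(step)
  len_step <- as.integer(len_step)
  if (max_offset < 1 || min_len < 1 || step < 1 || len_step < 1 ||
      min_len > max_len || max_len > 2L * max_offset) {
    stop("enumerate_site_windows: invalid parameter combination")
  }
  W <- 2L * max_offset
  out <- list()
  for (L in seq.int(min_len, max_len, by = len_step)) {
    starts <- seq.int(1L, W - L + 1L, by = step)
    out[[length(out) + 1L]] <- data.frame(
      strip_start = starts, strip_end = starts + L - 1L, length = L)
  }
  d <- do.call(rbind, out)
  d$offset_start <- strip_to_offset(d$strip_start, max_offset)
  d$offset_end <- strip_to_offset(d$strip_end, max_offset)
  d[, c("offset_start", "offset_end", "length", "strip_start", "strip_end")]
}

# ---- elementary feature values -----------------------------------------

#' Overlapping k-mer frequency in a sequence window
#'
#' Occurrences are counted with overlaps and divided by the number of slots
#' (window length - k + 1); a window shorter than k has frequency 0.
#'
#' @param seq_window RNA string.
#' @param token k-mer over \{A,C,G,U\}.
#' @return Frequency in `[0, 1]`.
#' @export
kmer_frequency <- function(seq_window, token) {
  if (nchar(gsub("[ACGU]", "", token)) > 0 || nchar(token) < 1) {
    stop("kmer_frequency: invalid token '", token, "'")
  }
  L <- nchar(seq_window)
  k <- nchar(token)
  if (L < k) return(0)
  starts <- seq_len(L - k + 1L)
  sum(substring(seq_window, starts, starts + k - 1L) == token) / (L - k + 1L)
}

rna_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), chartr("T", "U", names(gc)))
}

cds_codons <- function(tx) {
  cds <- transcript_regions(tx)$cds
  nc <- nchar(cds) %/% 3L
  substring(cds, seq.int(1L, by = 3L, length.out = nc),
            seq.int(3L, by = 3L, length.out = nc))
}

#' Codon or amino-acid frequency over in-frame CDS codons
#'
#' The frequency of `token` among the in-frame CDS codons overlapping a
#' window or region. Codon frequencies use all overlapping codons (stop
#' codons included) as denominator; amino-acid frequencies use only
#' non-stop codons (stops encode no residue). Returns 0 when no in-frame
#' codon overlaps (e.g. a window entirely in a UTR).
#'
#' @param tx A `cf_transcript`.
#' @param window Either a region name (`"cds"`, `"cds_start_codons"`,
#'   `"cds_stop_codons"`) or an integer vector `c(from, to)` of 0-based
#'   inclusive transcript positions.
#' @param token A 3-letter RNA codon or a 1-letter amino-acid code.
#' @param codon_block Number of codons in the start/stop blocks.
#' @return Frequency in `[0, 1]`.
#' @export
codon_aa_frequency <- function(tx, window, token, codon_block = 10) {
  stopifnot(inherits(tx, "cf_transcript"))
  codons <- cds_codons(tx)
  nc <- length(codons)
  if (is.character(window)) {
    idx <- switch(window,
      cds = seq_len(nc),
      cds_start_codons = seq_len(min(codon_block, nc)),
      cds_stop_codons = seq.int(max(1L, nc - codon_block + 1L), nc),
      stop("codon_aa_frequency: unknown region '", window, "'"))
  } else {
    from <- window[1]; to <- window[2]
    i_from <- max(0L, floor((from - tx$cds_start) / 3))
    i_to <- min(nc - 1L, floor((to - tx$cds_start) / 3))
    if (to < tx$cds_start || from >= tx$cds_end || i_from > i_to) {
      return(0)
    }
    idx <- seq.int(i_from + 1L, i_to + 1L)
  }
  sel <- codons[idx]
  code <- rna_genetic_code()
  if (nchar(token) == 3L) {
    if (!token %in% names(code)) stop("invalid codon token '", token, "'")
    sum(sel == token) / length(sel)
  } else {
    if (!token %in% code) stop("invalid amino-acid token '", token, "'")
    aa <- code[sel]
    non_stop <- aa != "*"
    if (!any(non_stop)) return(0)
    sum(aa[non_stop] == token) / sum(non_stop)
  }
}

#' Secondary-structure stability score of an RNA sequence
#'
#' Minimum energy over nested (pseudoknot-free) structures under a
#' simplified weighted base-pair model: GC = -3, AU = -2, GU = -1, minimum
#' hairpin loop of 3 unpaired nucleotides, computed by dynamic programming.
#' An external thermodynamic folding engine can be plugged in by setting
#' `options(cleavefeat.fold_backend = function(seq) ...)`; it then takes
#' precedence.
#'
#' @param seq RNA string over \{A,C,G,U\}.
#' @param min_loop Minimum hairpin loop size (default 3).
#' @return Energy score `<= 0` (arbitrary units; kcal/mol if an external
#'   backend is plugged in).
#' @export
fold_mfe <- function(seq, min_loop = 3) {
  if (nchar(seq) < 1) stop("fold_mfe: empty sequence")
  if (nchar(gsub("[ACGU]", "", seq)) > 0) {
    stop("fold_mfe: invalid letters in sequence")
  }
  backend <- getOption("cleavefeat.fold_backend", NULL)
  if (is.function(backend)) return(backend(seq))
  fold_mfe_dp(seq, as.integer(min_loop))
}

#' Mean ribosome occupancy over a site-relative window
#'
#' Averages RO_site over the window's positions, truncating the window at
#' the transcript bounds; returns 0 when no in-bounds position remains or
#' the gene has no occupancy data.
#'
#' @param occupancy A `cf_ro_table`.
#' @param gene Gene id.
#' @param site 0-based site position.
#' @param window Integer vector `c(offset_start, offset_end)` in
#'   site-relative coordinates (no offset 0).
#' @param transcript_length Length used for truncation (default `Inf`).
#' @return Mean RO over in-bounds window positions.
#' @export
window_ro <- function(occupancy, gene, site, window,
                      transcript_length = Inf) {
  stopifnot(inherits(occupancy, "cf_ro_table"))
  a <- offset_to_abs(site, window[1])
  b <- offset_to_abs(site, window[2])
  a <- max(a, 0)
  b <- min(b, transcript_length - 1)
  if (b < a) return(0)
  s <- occupancy$sites
  sel <- s$gene == gene & s$position >= a & s$position <= b
  sum(s$ro_site[sel]) / (b - a + 1)
}

# ---- feature space configuration ---------------------------------------

kmer_tokens <- function(k) {
  sort(apply(expand.grid(rep(list(RNA_BASES), k),
                         stringsAsFactors = FALSE)[, k:1, drop = FALSE],
             1, paste0, collapse = ""))
}

codon_tokens <- function() kmer_tokens(3)

aa_tokens <- function() sort(setdiff(unique(rna_genetic_code()), "*"))

#' Feature-space configuration
#'
#' Defaults describe the full published feature space: nucleotide (k = 1, 2),
#' codon and amino-acid frequencies in all sliding windows within +/-30 nt of
#' the site (lengths 1-60, step 1); structure scores in windows of lengths
#' 5-60 (step 5, placement step 5); mean ribosome occupancy in windows of
#' lengths 1-60 within +/-200 nt; and whole-RNA features per region (5'-UTR,
#' CDS, 3'-UTR, whole): k-mer frequencies, 50-nt 5'/3' end-block k-mer
#' frequencies, a structure score, the RO sum, and (CDS only) codon and
#' amino-acid frequencies plus 10-codon start/stop blocks. Tests and the
#' simulator use reduced configurations of the same shape.
#'
#' @param categories Feature categories to emit.
#' @param k Nucleotide k-mer sizes.
#' @param site_max_offset,site_min_len,site_max_len,site_step,site_len_step
#'   Sequence window parameters around the site.
#' @param struct_max_offset,struct_min_len,struct_max_len,struct_step,struct_len_step
#'   Structure window parameters.
#' @param occ_max_offset,occ_min_len,occ_max_len,occ_step,occ_len_step
#'   Occupancy window parameters.
#' @param regions Whole-RNA regions to cover.
#' @param end_block_nt Length of the region 5'/3' end blocks.
#' @param codon_block Codons in the CDS start/stop blocks.
#' @param whole_rna Emit whole-RNA features at all.
#' @return A `cf_feature_config` list.
#' @export
feature_config <- function(categories = FEATURE_CATEGORIES,
                           k = 1:2,
                           site_max_offset = 30, site_min_len = 1,
                           site_max_len = 60, site_step = 1,
                           site_len_step = 1,
                           struct_max_offset = 30, struct_min_len = 5,
                           struct_max_len = 60, struct_step = 5,
                           struct_len_step = 5,
                           occ_max_offset = 200, occ_min_len = 1,
                           occ_max_len = 60, occ_step = 1,
                           occ_len_step = 1,
                           regions = c("5utr", "cds", "3utr", "whole"),
                           end_block_nt = 50, codon_block = 10,
                           whole_rna = TRUE) {
  categories <- match.arg(categories, FEATURE_CATEGORIES, several.ok = TRUE)
  structure(as.list(environment()), class = "cf_feature_config")
}

feature_name <- function(category, scope, region, block, ostart, oend,
                         token) {
  code <- c(nucleotide = "nt", codon = "codon", amino_acid = "aa",
            structure = "mfe", occupancy = "ro")[[category]]
  loc <- if (scope == "around_site") {
    sprintf("%+d..%+d", ostart, oend)
  } else if (nzchar(block)) paste0(region, ":", block) else region
  scope_code <- if (scope == "around_site") "site" else "rna"
  paste(code, scope_code, loc, token, sep = "|")
}

spec_row <- function(category, scope, region = "", block = "",
                     ostart = NA_integer_, oend = NA_integer_, token = "") {
  data.frame(
    name = feature_name(category, scope, region, block,
                        ostart, oend, token),
    category = category, scope = scope, region = region, block = block,
    offset_start = ostart, offset_end = oend, token = token,
    stringsAsFactors = FALSE)
}

# Enumerate the full FeatureSpec table for a configuration, in deterministic
# order: category, then scope (around_site first), then window
# (length, start) or region/block, then token (alphabetical).
enumerate_feature_specs <- function(config, has_occupancy = TRUE) {
  stopifnot(inherits(config, "cf_feature_config"))
  cats <- config$categories
  if (!has_occupancy) cats <- setdiff(cats, "occupancy")
  seq_windows <- enumerate_site_windows(config$site_max_offset,
                                        config$site_min_len,
                                        config$site_max_len,
                                        config$site_step,
                                        config$site_len_step)
  out <- list()
  add <- function(d) out[[length(out) + 1L]] <<- d
  blocks <- c("", "end5", "end3")
  for (cat in intersect(FEATURE_CATEGORIES, cats)) {
    if (cat == "nucleotide") {
      for (kk in config$k) {
        for (tok in kmer_tokens(kk)) {
          add(spec_row(cat, "around_site", ostart = seq_windows$offset_start,
                       oend = seq_windows$offset_end, token = tok))
        }
      }
      if (config$whole_rna) {
        for (reg in config$regions) for (bl in blocks) {
          for (kk in config$k) {
            add(spec_row(cat, "whole_rna", region = reg, block = bl,
                         token = kmer_tokens(kk)))
          }
        }
      }
    } else if (cat %in% c("codon", "amino_acid")) {
      toks <- if (cat == "codon") codon_tokens() else aa_tokens()
      for (tok in toks) {
        add(spec_row(cat, "around_site", ostart = seq_windows$offset_start,
                     oend = seq_windows$offset_end, token = tok))
      }
      if (config$whole_rna && "cds" %in% config$regions) {
        for (bl in c("", "start_codons", "stop_codons")) {
          add(spec_row(cat, "whole_rna", region = "cds", block = bl,
                       token = toks))
        }
      }
    } else if (cat == "structure") {
      sw <- enumerate_site_windows(config$struct_max_offset,
                                   config$struct_min_len,
                                   config$struct_max_len,
                                   config$struct_step,
                                   config$struct_len_step)
      add(spec_row(cat, "around_site", ostart = sw$offset_start,
                   oend = sw$offset_end))
      if (config$whole_rna) {
        add(spec_row(cat, "whole_rna", region = config$regions))
      }
    } else if (cat == "occupancy") {
      ow <- enumerate_site_windows(config$occ_max_offset,
                                   config$occ_min_len, config$occ_max_len,
                                   config$occ_step, config$occ_len_step)
      add(spec_row(cat, "around_site", ostart = ow$offset_start,
                   oend = ow$offset_end))
      if (config$whole_rna) {
        add(spec_row(cat, "whole_rna", region = config$regions))
      }
    }
  }
  d <- do.call(rbind, out)
  # canonical order: category, scope, region/block, window (length, start),
  # token
  len_key <- ifelse(is.na(d$offset_start), 0L,
                    d$offset_end - d$offset_start)
  start_key <- ifelse(is.na(d$offset_start), 0L, d$offset_start)
  ord <- order(match(d$category, FEATURE_CATEGORIES),
               match(d$scope, FEATURE_SCOPES),
               match(d$region, c("", "5utr", "cds", "3utr", "whole")),
               match(d$block, c("", "end5", "end3", "start_codons",
                                "stop_codons")),
               len_key, start_key, d$token)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}

# ---- whole-RNA (per-gene) feature values --------------------------------

region_sequence <- function(tx, region, block, end_block_nt) {
  s <- transcript_regions(tx)[[switch(region, "5utr" = "utr5",
                                      "3utr" = "utr3", region)]]
  L <- nchar(s)
  if (block == "end5") s <- substr(s, 1L, min(end_block_nt, L))
  if (block == "end3") s <- substr(s, max(1L, L - end_block_nt + 1L), L)
  s
}

#' Whole-RNA and per-region feature values for one transcript
#'
#' Computes the whole-RNA slice of the feature space for a single
#' transcript: per-region k-mer frequencies (with 50-nt end blocks),
#' structure scores, ribosome-occupancy sums, and CDS codon/amino-acid
#' frequencies (with 10-codon start/stop blocks). Zero-length regions yield
#' 0 for all their features (flagged in the `empty_regions` attribute).
#'
#' @param tx A `cf_transcript`.
#' @param occupancy Optional `cf_ro_table`.
#' @param config A `cf_feature_config`.
#' @return Named numeric vector over the whole-RNA feature specs.
#' @export
region_features <- function(tx, occupancy = NULL,
                            config = feature_config()) {
  specs <- enumerate_feature_specs(config,
                                   has_occupancy = !is.null(occupancy))
  specs <- specs[specs$scope == "whole_rna", , drop = FALSE]
  vals <- whole_rna_values(tx, occupancy, specs, config)
  empties <- Filter(function(r) {
    nchar(region_sequence(tx, r, "", config$end_block_nt)) == 0L
  }, config$regions)
  if (length(empties)) {
    cf_log("region_features(%s): empty region(s): %s", tx$id,
           paste(empties, collapse = ","))
  }
  structure(setNames(vals, specs$name), empty_regions = unlist(empties))
}

whole_rna_values <- function(tx, occupancy, specs, config) {
  ro_row <- NULL
  if (!is.null(occupancy)) {
    i <- match(tx$id, occupancy$genes$gene)
    if (!is.na(i)) ro_row <- occupancy$genes[i, ]
  }
  vapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    if (sp$category == "nucleotide") {
      s <- region_sequence(tx, sp$region, sp$block, config$end_block_nt)
      if (nchar(s) == 0L) 0 else kmer_frequency(s, sp$token)
    } else if (sp$category %in% c("codon", "amino_acid")) {
      reg <- if (nzchar(sp$block)) paste0("cds_", sp$block) else "cds"
      codon_aa_frequency(tx, reg, sp$token, config$codon_block)
    } else if (sp$category == "structure") {
      s <- region_sequence(tx, sp$region, "", config$end_block_nt)
      if (nchar(s) == 0L) 0 else fold_mfe(s)
    } else { # occupancy: per-region RO sum
      if (is.null(ro_row)) 0 else switch(sp$region,
        whole = ro_row$ro_gene, "5utr" = ro_row$ro_utr5,
        cds = ro_row$ro_cds, "3utr" = ro_row$ro_utr3, 0)
    }
  }, 0)
}

# ---- matrix assembly ----------------------------------------------------

#' Build the sites-by-features matrix
#'
#' One row per cleavage site that has the full sequence context (the
#' +/-max_offset strip, including the structure window half-width) inside
#' its transcript; sites lacking context are excluded and logged.
#' Occupancy windows are truncated at transcript bounds rather than
#' dropped. Columns follow the deterministic FeatureSpec order (category,
#' scope, region/window, token).
#'
#' @param sites A `cf_cs_table`, or a data.frame with columns gene,
#'   position (plus optional y, split).
#' @param transcripts Named list of `cf_transcript`.
#' @param occupancy Optional `cf_ro_table`; when absent, occupancy features
#'   are omitted.
#' @param config A `cf_feature_config`.
#' @return A `cf_feature_matrix`.
#' @export
build_feature_matrix <- function(sites, transcripts, occupancy = NULL,
                                 config = feature_config()) {
  if (inherits(sites, "cf_cs_table")) {
    sites <- data.frame(gene = sites$sites$gene,
                        position = sites$sites$position,
                        y = sites$sites$cs_site, split = sites$sites$split,
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(sites), all(c("gene", "position") %in%
                                        names(sites)))
  if (is.null(sites$y)) sites$y <- NA_real_
  if (is.null(sites$split)) sites$split <- "none"
  if ("occupancy" %in% config$categories && is.null(occupancy)) {
    cf_log("build_feature_matrix: no occupancy table; omitting occupancy features")
  }
  specs <- enumerate_feature_specs(config,
                                   has_occupancy = !is.null(occupancy))

  seq_cats <- intersect(config$categories,
                        c("nucleotide", "codon", "amino_acid"))
  ctx <- max(c(if (length(seq_cats)) config$site_max_offset,
               if ("structure" %in% config$categories)
                 config$struct_max_offset, 1L))
  lens <- vapply(sites$gene, function(g) {
    tx <- transcripts[[g]]
    if (is.null(tx)) stop("build_feature_matrix: missing transcript for ", g)
    tx$length
  }, 0L)
  ok <- sites$position >= ctx & sites$position <= lens - ctx
  if (any(!ok)) {
    cf_log("build_feature_matrix: excluded %d site(s) lacking +/-%d context",
           sum(!ok), ctx)
  }
  sites <- sites[ok, , drop = FALSE]
  rownames(sites) <- NULL

  X <- matrix(0, nrow(sites), nrow(specs))
  for (g in unique(sites$gene)) {
    idx <- which(sites$gene == g)
    X[idx, ] <- gene_feature_block(transcripts[[g]], sites$position[idx],
                                   occupancy, specs, config)
  }
  feature_matrix(sites, X, specs)
}

# All feature values for the sites of one gene (rows) across all specs
# (columns). Around-site sequence features are vectorized with cumulative
# counts along the +/-max_offset strip.
gene_feature_block <- function(tx, pos, occupancy, specs, config) {
  n <- length(pos)
  M <- matrix(0, n, nrow(specs))
  chars <- strsplit(tx$seq, "")[[1]]

  # -- whole-RNA: one value per gene, replicated over its sites
  wr <- specs$scope == "whole_rna"
  if (any(wr)) {
    vals <- whole_rna_values(tx, occupancy, specs[wr, , drop = FALSE],
                             config)
    M[, wr] <- matrix(vals, n, sum(wr), byrow = TRUE)
  }

  # -- around-site nucleotide k-mers
  nt <- specs$scope == "around_site" & specs$category == "nucleotide"
  if (any(nt)) {
    mo <- config$site_max_offset
    W <- 2L * mo
    strip_idx <- outer(pos, seq_len(W), `+`) - mo  # 1-based char indices
    charmat <- matrix(chars[strip_idx], n, W)
    eq <- lapply(setNames(RNA_BASES, RNA_BASES),
                 function(b) charmat == b)
    cum_tri <- function(A) {
      # row-wise cumulative sums via multiplication with upper-triangular 1s
      m <- ncol(A)
      A %*% upper.tri(matrix(0, m, m), diag = TRUE)
    }
    cum_cache <- new.env(parent = emptyenv())
    for (j in which(nt)) {
      tok <- specs$token[j]
      k <- nchar(tok)
      cum <- get0(tok, cum_cache)
      if (is.null(cum)) {
        tk <- strsplit(tok, "")[[1]]
        Mk <- eq[[tk[1]]][, seq_len(W - k + 1L), drop = FALSE]
        if (k > 1) for (u in 2:k) {
          Mk <- Mk & eq[[tk[u]]][, seq.int(u, W - k + u), drop = FALSE]
        }
        cum <- cbind(0, cum_tri(Mk))
        assign(tok, cum, cum_cache)
      }
      s <- off_to_strip(specs$offset_start[j], mo)
      e <- off_to_strip(specs$offset_end[j], mo)
      L <- e - s + 1L
      if (L < k) next  # frequency 0 for windows shorter than k
      M[, j] <- (cum[, e - k + 2L] - cum[, s]) / (L - k + 1L)
    }
  }

  # -- around-site codon / amino-acid frequencies (in-frame)
  ca <- specs$scope == "around_site" &
    specs$category %in% c("codon", "amino_acid")
  if (any(ca)) {
    codons <- cds_codons(tx)
    nc <- length(codons)
    aa <- rna_genetic_code()[codons]
    cum_non_stop <- c(0, cumsum(aa != "*"))
    tok_cache <- new.env(parent = emptyenv())
    for (j in which(ca)) {
      a <- offset_to_abs(pos, specs$offset_start[j])
      b <- offset_to_abs(pos, specs$offset_end[j])
      i_from <- pmax(0L, (a - tx$cds_start) %/% 3L)
      i_to <- pmin(nc - 1L, (b - tx$cds_start) %/% 3L)
      valid <- b >= tx$cds_start & a < tx$cds_end & i_from <= i_to
      # clamp so cumulative-sum indexing stays in bounds for invalid rows
      i_from <- pmin(i_from, nc - 1L)
      i_to <- pmax(i_to, 0L)
      if (!any(valid)) next
      tok <- specs$token[j]
      key <- paste0(specs$category[j], ":", tok)
      cum <- get0(key, tok_cache)
      if (is.null(cum)) {
        ind <- if (specs$category[j] == "codon") codons == tok else
          aa == tok & aa != "*"
        cum <- c(0, cumsum(ind))
        assign(key, cum, tok_cache)
      }
      cnt <- cum[i_to + 2L] - cum[i_from + 1L]
      denom <- if (specs$category[j] == "codon") {
        i_to - i_from + 1L
      } else {
        cum_non_stop[i_to + 2L] - cum_non_stop[i_from + 1L]
      }
      v <- ifelse(valid & denom > 0, cnt / pmax(denom, 1L), 0)
      M[, j] <- v
    }
  }

  # -- around-site structure scores
  st <- specs$scope == "around_site" & specs$category == "structure"
  if (any(st)) {
    for (j in which(st)) {
      a <- offset_to_abs(pos, specs$offset_start[j])
      b <- offset_to_abs(pos, specs$offset_end[j])
      M[, j] <- vapply(seq_len(n), function(i) {
        fold_mfe(substr(tx$seq, a[i] + 1L, b[i] + 1L))
      }, 0)
    }
  }

  # -- around-site occupancy (mean RO over the window, truncated)
  oc <- specs$scope == "around_site" & specs$category == "occupancy"
  if (any(oc) && !is.null(occupancy)) {
    s <- occupancy$sites
    sel <- s$gene == tx$id
    ro <- numeric(tx$length)
    if (any(sel)) ro[s$position[sel] + 1L] <- s$ro_site[sel]
    cum <- c(0, cumsum(ro))
    for (j in which(oc)) {
      a <- pmin(pmax(offset_to_abs(pos, specs$offset_start[j]), 0L),
                tx$length)
      b <- pmin(offset_to_abs(pos, specs$offset_end[j]), tx$length - 1L)
      m <- b - a + 1L
      v <- ifelse(m > 0, (cum[b + 2L] - cum[a + 1L]) / pmax(m, 1L), 0)
      M[, j] <- v
    }
  }
  M
}

off_to_strip <- function(o, max_offset) {
  ifelse(o < 0L, o + max_offset + 1L, o + max_offset)
}
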