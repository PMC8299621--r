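# Site-level cleavage scores (CS_site), ribosome occupancy (RO_site),
# reliability filters and the gene-level train/test split.
#
# CS_site = degradome 5'-end reads at a position / the gene's capped-read
# total; CS_gene = sum of CS_site over the gene. RO_site is the analogous
# normalization of ribosome-protected-fragment 5'-end reads.

#' Per-gene capped-read abundance
#'
#' Totals capped (intact 5' end) reads per gene; genes are retained for
#' scoring only when their cap-read total strictly exceeds `min_reads`
#' (default 50).
#'
#' @param cap_tracks Named list of `cf_track` of kind "cap".
#' @param min_reads Retention threshold (strict inequality).
#' @return data.frame (`cf_abundance`) with columns gene, cap_reads,
#'   retained.
#' @export
compute_abundance <- function(cap_tracks, min_reads = 50) {
  stopifnot(all(vapply(cap_tracks, function(t) t$kind, "") == "cap"))
  genes <- vapply(cap_tracks, function(t) t$transcript_id, "")
  totals <- vapply(cap_tracks, function(t) sum(t$count), 0)
  d <- data.frame(gene = unname(genes), cap_reads = unname(totals),
                  stringsAsFactors = FALSE)
  d <- d[order(d$gene), , drop = FALSE]
  rownames(d) <- NULL
  d$retained <- d$cap_reads > min_reads
  class(d) <- c("cf_abundance", "data.frame")
  d
}

#' Site-level cleavage scores
#'
#' For each retained gene, every position with at least one degradome read
#' gets a row with CS_site = reads / cap-read total (the table is sparse:
#' zero-read positions have no row). CS_gene is the per-gene sum of CS_site.
#' Degradome tracks for non-retained genes are excluded (count logged).
#'
#' @param degradome_tracks Named list of `cf_track` of kind "degradome".
#' @param abundance A `cf_abundance` from [compute_abundance()].
#' @return A `cf_cs_table`: list with `sites` (gene, position, reads,
#'   cs_site, split) and `genes` (gene, cs_gene).
#' @export
compute_cs_table <- function(degradome_tracks, abundance) {
  stopifnot(inherits(abundance, "cf_abundance"))
  kept <- abundance[abundance$retained, , drop = FALSE]
  cap <- setNames(kept$cap_reads, kept$gene)
  n_excluded <- 0L
  rows <- list()
  for (tr in degradome_tracks) {
    g <- tr$transcript_id
    if (!g %in% names(cap)) { n_excluded <- n_excluded + 1L; next }
    keep <- tr$count > 0
    if (!any(keep)) next
    rows[[g]] <- data.frame(gene = g, position = tr$pos[keep],
                            reads = tr$count[keep],
                            cs_site = tr$count[keep] / cap[[g]],
                            stringsAsFactors = FALSE)
  }
  if (n_excluded) {
    cf_log("compute_cs_table: excluded %d track(s) for non-retained genes",
           n_excluded)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), position = integer(), reads = numeric(),
               cs_site = numeric())
  sites <- sites[order(sites$gene, sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites$split <- rep("none", nrow(sites))
  cs_table(sites)
}

cs_table <- function(sites) {
  cs_gene <- if (nrow(sites)) {
    agg <- tapply(sites$cs_site, sites$gene, sum)
    data.frame(gene = names(agg), cs_gene = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else data.frame(gene = character(), cs_gene = numeric())
  rownames(cs_gene) <- NULL
  structure(list(sites = sites, genes = cs_gene), class = "cf_cs_table")
}

#' @export
print.cf_cs_table <- function(x, ...) {
  cat(sprintf("<cf_cs_table: %d sites over %d genes>\n", nrow(x$sites),
              nrow(x$genes)))
  invisible(x)
}

#' Site-level ribosome occupancy
#'
#' RO_site = RPF 5'-end reads / cap-read abundance for retained genes;
#' RO_gene is the per-gene sum, and per-region sums (5'-UTR, CDS, 3'-UTR,
#' whole) are computed from the transcript CDS coordinates.
#'
#' @param rpf_tracks Named list of `cf_track` of kind "rpf".
#' @param abundance A `cf_abundance`.
#' @param transcripts Named list of `cf_transcript` (required for region
#'   sums; a scored gene without a transcript is an error).
#' @return A `cf_ro_table`: list with `sites` (gene, position, ro_site) and
#'   `genes` (gene, ro_gene, ro_utr5, ro_cds, ro_utr3).
#' @export
compute_ro_table <- function(rpf_tracks, abundance, transcripts) {
  stopifnot(inherits(abundance, "cf_abundance"))
  kept <- abundance[abundance$retained, , drop = FALSE]
  cap <- setNames(kept$cap_reads, kept$gene)
  rows <- list(); gene_rows <- list()
  for (tr in rpf_tracks) {
    g <- tr$transcript_id
    if (!g %in% names(cap)) next
    tx <- transcripts[[g]]
    if (is.null(tx)) stop("compute_ro_table: missing transcript for ", g)
    keep <- tr$count > 0
    pos <- tr$pos[keep]
    ro <- tr$count[keep] / cap[[g]]
    if (length(pos)) {
      rows[[g]] <- data.frame(gene = g, position = pos, ro_site = ro,
                              stringsAsFactors = FALSE)
    }
    in_cds <- pos >= tx$cds_start & pos < tx$cds_end
    gene_rows[[g]] <- data.frame(
      gene = g, ro_gene = sum(ro),
      ro_utr5 = sum(ro[pos < tx$cds_start]),
      ro_cds = sum(ro[in_cds]),
      ro_utr3 = sum(ro[pos >= tx$cds_end]),
      stringsAsFactors = FALSE)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), position = integer(), ro_site = numeric())
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene = character(), ro_gene = numeric(), ro_utr5 = numeric(),
               ro_cds = numeric(), ro_utr3 = numeric())
  rownames(sites) <- rownames(genes) <- NULL
  structure(list(sites = sites, genes = genes), class = "cf_ro_table")
}

#' Reliability filters for cleavage sites
#'
#' Keeps genes whose fraction of cleaved positions (positions with at least
#' one degradome read) relative to transcript length strictly exceeds
#' `min_cleaved_frac`, and whose CS_gene lies strictly between the lower and
#' upper percentiles (`band`, default 5th/95th, linear-interpolation
#' quantiles) of the CS_gene distribution of the genes surviving the first
#' rule. Any (gene, position) pair present in `exclusion` (e.g. putative
#' miRNA-guided cleavage sites) is then dropped and CS_gene recomputed.
#'
#' @param cs A `cf_cs_table`.
#' @param transcripts Named list of `cf_transcript`.
#' @param exclusion Optional data.frame with columns gene, position.
#' @param min_cleaved_frac Cleaved-fraction threshold (default 0.20).
#' @param band Percentile band as two numbers in (0,100).
#' @return Filtered `cf_cs_table`.
#' @export
filter_reliable_sites <- function(cs, transcripts, exclusion = NULL,
                                  min_cleaved_frac = 0.2, band = c(5, 95)) {
  stopifnot(inherits(cs, "cf_cs_table"), length(band) == 2)
  sites <- cs$sites
  if (!nrow(sites)) return(cs)
  n_sites <- table(sites$gene)
  genes <- names(n_sites)
  lens <- vapply(genes, function(g) {
    tx <- transcripts[[g]]
    if (is.null(tx)) stop("filter_reliable_sites: missing transcript for ", g)
    tx$length
  }, 0L)
  frac_ok <- as.numeric(n_sites) / lens > min_cleaved_frac
  surv <- genes[frac_ok]
  cg <- cs$genes[match(surv, cs$genes$gene), "cs_gene"]
  q <- quantile(cg, band / 100, type = 7, names = FALSE)
  keep_genes <- surv[cg > q[1] & cg < q[2]]
  sites <- sites[sites$gene %in% keep_genes, , drop = FALSE]
  if (!is.null(exclusion) && nrow(exclusion)) {
    key <- paste(sites$gene, sites$position)
    drop <- key %in% paste(exclusion$gene, exclusion$position)
    if (any(drop)) cf_log("filter_reliable_sites: dropped %d excluded site(s)",
                          sum(drop))
    sites <- sites[!drop, , drop = FALSE]
  }
  rownames(sites) <- NULL
  cs_table(sites)
}

#' Gene-level train/test split
#'
#' Genes (not sites) are randomly partitioned so that sites of one gene
#' never straddle the split; every site inherits its gene's label. The
#' partition is deterministic given `seed`.
#'
#' @param cs A filtered `cf_cs_table`.
#' @param test_fraction Fraction of genes assigned to the test set (default
#'   0.1, the 9:1 convention).
#' @param seed Integer seed.
#' @return The `cf_cs_table` with `split` set to "train"/"test".
#' @export
split_sites <- function(cs, test_fraction = 0.1, seed = 1) {
  stopifnot(inherits(cs, "cf_cs_table"))
  genes <- sort(unique(cs$sites$gene))
  n <- length(genes)
  if (n < 10) stop("split_sites: fewer than 10 genes (", n, ")")
  n_test <- max(1L, round(n * test_fraction))
  set.seed(seed)
  test_genes <- sample(genes, n_test)
  cs$sites$split <- ifelse(cs$sites$gene %in% test_genes, "test", "train")
  cs
}
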