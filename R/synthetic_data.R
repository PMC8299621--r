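# Synthetic degradome generator: transcripts plus degradome/cap/RPF count
# tracks drawn from a known log-linear cleavage model, giving planted
# ground truth for end-to-end pipeline tests and parameter recovery.
#
# Generative model, per candidate site i of gene g:
#   log10 CS_i = alpha0 + sum_j beta_j z_ij + eps_i,  eps ~ N(0, sigma_eps^2)
# where z are the planted features computed by the real feature-extraction
# code and z-scored across candidate sites (so beta is in SD units,
# directly comparable to the standardized fitted coefficients), and
#   degradome reads_i ~ Poisson(a_g * 10^{log10 CS_i} * deg_depth)
#   cap reads_g      ~ Poisson(a_g * cap_depth)          (at position 0)
#   RPF reads_{g,p}  ~ Poisson(a_g * rpf_depth * f_g * (1 or utr factor))
# with gene abundances a_g log-normal and f_g a per-gene occupancy factor.

#' Default planted effects for the simulator
#'
#' Ten around-site single-nucleotide frequency features with effects
#' `|beta| in [0.3, 0.5]` (SD units of log10 CS_site) and mixed signs, one
#' per offset in -5..+5. The layout is constrained so every planted
#' effect is identifiable under the pipeline's keep-best-correlated
#' decorrelation rule:
#'
#' * windows are pairwise disjoint single positions, so any wider window
#'   containing a planted position dilutes its signal by `1/sqrt(L)`;
#' * because the four nucleotide indicators at one position anti-correlate
#'   at about -1/3, a two-position proxy window leaks `-beta_nb/3` of the
#'   adjacent planted effect; the planted feature at `p` outranks all its
#'   proxies iff `|beta_p - beta_nb/3|/sqrt(2) < |beta_p|`, i.e.
#'   `beta_nb / beta_p > -1.24` for each neighbour. Signs are therefore
#'   arranged in two contiguous blocks with the largest magnitudes facing
#'   each other at the sign boundary, which satisfies the inequality for
#'   every adjacent pair.
#'
#' @return data.frame with columns offset_start, offset_end, token, beta.
#' @export
default_planted_effects <- function() {
  data.frame(
    offset_start = c(-5L, -4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L, 5L),
    offset_end   = c(-5L, -4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L, 5L),
    token        = c("G", "A", "C", "U", "A", "G", "U", "C", "A", "G"),
    beta         = c(0.5, 0.4, 0.4, 0.35, 0.3, 0.5, -0.5, -0.35, -0.3,
                     -0.3),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe the stated desk-scale world: 50 genes with realistic
#' mRNA architecture (5'-UTR 40-80 nt, CDS 180-220 codons, 3'-UTR 60-120
#' nt), log-normal abundances (median 200 capped reads per depth unit),
#' baseline log10 cleavage score `alpha0 = -1.3`, site noise
#' `sigma_eps = 0.5`, candidate-site density 0.4 over CDS-internal
#' positions (so the cleaved fraction of ~0.29 clears the 20% reliability
#' filter comfortably and ~10,000 analyzed sites result), and depths
#' giving on the order of 50 degradome reads at a median site.
#'
#' @param n_genes Number of genes.
#' @param utr5_len,utr3_len Uniform length ranges (nt).
#' @param cds_codons Uniform range of codons (including start and stop).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters.
#' @param alpha0 Baseline log10 CS_site.
#' @param sigma_eps Site-level noise SD on log10 CS_site.
#' @param planted data.frame of planted effects (see
#'   [default_planted_effects()]).
#' @param feature_config Feature space used both to compute planted
#'   features and downstream (default: single-nucleotide windows within
#'   +/-5 nt, lengths 1-10 — 220 features).
#' @param site_density Fraction of eligible CDS-internal positions made
#'   candidate sites.
#' @param deg_depth,cap_depth,rpf_depth Sequencing depth factors.
#' @param utr_rpf_factor RPF rate in UTRs relative to CDS.
#' @param occupancy_sdlog SD of the per-gene log-normal occupancy factor.
#' @param overdispersion Optional gamma-mixing dispersion for degradome
#'   counts (NULL = pure Poisson).
#' @param seed Integer seed.
#' @return A `cf_sim_config`.
#' @export
sim_config <- function(n_genes = 50, utr5_len = c(40, 80),
                       cds_codons = c(180, 220), utr3_len = c(60, 120),
                       abundance_meanlog = log(200), abundance_sdlog = 0.5,
                       alpha0 = -1.3, sigma_eps = 0.5,
                       planted = default_planted_effects(),
                       feature_config = cleavefeat::feature_config(
                         categories = "nucleotide", k = 1,
                         site_max_offset = 5, site_min_len = 1,
                         site_max_len = 10, whole_rna = FALSE),
                       site_density = 0.4, deg_depth = 5, cap_depth = 5,
                       rpf_depth = 0.05, utr_rpf_factor = 0.05,
                       occupancy_sdlog = 0.5, overdispersion = NULL,
                       seed = 1) {
  stopifnot(n_genes >= 1, deg_depth > 0, cap_depth > 0, rpf_depth > 0,
            site_density > 0, site_density <= 1)
  structure(as.list(environment()), class = "cf_sim_config")
}

sample_codons <- function(n, sense, stops) {
  c("AUG", sample(sense, n - 2L, replace = TRUE), sample(stops, 1L))
}

#' Simulate transcripts
#'
#' Random sequences with an AUG start codon, a stop codon at the CDS end
#' and no internal in-frame stop; UTR composition is uniform over
#' \{A,C,G,U\}. Deterministic given the config seed.
#'
#' @param config A `cf_sim_config`.
#' @return Named list of `cf_transcript`.
#' @export
simulate_transcripts <- function(config) {
  stopifnot(inherits(config, "cf_sim_config"))
  if (min(config$cds_codons) < 2) {
    stop("simulate_transcripts: CDS must have at least 2 codons")
  }
  set.seed(config$seed)
  code <- rna_genetic_code()
  stops <- names(code)[code == "*"]
  sense <- setdiff(names(code), stops)
  out <- list()
  for (i in seq_len(config$n_genes)) {
    id <- sprintf("sim%04d", i)
    u5 <- sample(seq(config$utr5_len[1], config$utr5_len[2]), 1)
    u3 <- sample(seq(config$utr3_len[1], config$utr3_len[2]), 1)
    nc <- sample(seq(config$cds_codons[1], config$cds_codons[2]), 1)
    seq5 <- paste(sample(RNA_BASES, u5, replace = TRUE), collapse = "")
    seq3 <- paste(sample(RNA_BASES, u3, replace = TRUE), collapse = "")
    cds <- paste(sample_codons(nc, sense, stops), collapse = "")
    out[[id]] <- transcript(id, paste0(seq5, cds, seq3), u5, u5 + 3L * nc)
  }
  out
}

candidate_sites <- function(transcripts, config) {
  ctx <- config$feature_config$site_max_offset
  rows <- lapply(transcripts, function(tx) {
    lo <- max(tx$cds_start + 1L, ctx)
    hi <- min(tx$cds_end - 1L, tx$length - ctx)
    if (hi < lo) return(NULL)
    data.frame(gene = tx$id, position = seq.int(lo, hi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate degradome and cap count tracks with ground truth
#'
#' Candidate sites are CDS-internal positions with full sequence context,
#' subsampled at `site_density`; their planted features are computed by
#' [build_feature_matrix()] and z-scored, true log10 cleavage scores are
#' drawn from the log-linear model, and degradome/cap reads are Poisson
#' sampled. A planted effect whose feature is not in the configured
#' feature space, or is constant across sites, is skipped with a log
#' message.
#'
#' @param transcripts Output of [simulate_transcripts()].
#' @param config A `cf_sim_config`.
#' @return List with `degradome` and `cap` track sets and `truth`
#'   (a `cf_sim_truth`: per-gene abundance, per-site true log10 CS and
#'   planted signal, the planted coefficient table, and the realized
#'   standardized planted features).
#' @export
simulate_degradome <- function(transcripts, config) {
  stopifnot(inherits(config, "cf_sim_config"))
  set.seed(config$seed + 1L)
  n_genes <- length(transcripts)
  abundance <- rlnorm(n_genes, config$abundance_meanlog,
                      config$abundance_sdlog)
  names(abundance) <- names(transcripts)

  cand <- candidate_sites(transcripts, config)
  keep <- runif(nrow(cand)) < config$site_density
  sites <- cand[keep, , drop = FALSE]
  rownames(sites) <- NULL

  fm <- build_feature_matrix(sites, transcripts, occupancy = NULL,
                             config = config$feature_config)
  planted <- config$planted
  planted$name <- feature_name("nucleotide", "around_site", "", "",
                               planted$offset_start, planted$offset_end,
                               planted$token)
  idx <- match(planted$name, fm$specs$name)
  skip <- is.na(idx)
  if (!all(skip)) {
    Zp <- fm$X[, idx[!skip], drop = FALSE]
    sds <- apply(Zp, 2, sd)
    const <- sds == 0
    skip[!skip][const] <- TRUE
    Zp <- Zp[, !const, drop = FALSE]
  }
  if (any(skip)) {
    cf_log("simulate_degradome: skipped %d planted effect(s): %s",
           sum(skip), paste(planted$name[skip], collapse = ","))
  }
  planted <- planted[!skip, , drop = FALSE]
  Z <- scale(fm$X[, match(planted$name, fm$specs$name), drop = FALSE])
  signal <- if (nrow(planted)) as.numeric(Z %*% planted$beta) else
    numeric(nrow(fm$sites))
  eps <- rnorm(nrow(fm$sites), 0, config$sigma_eps)
  log10_cs <- config$alpha0 + signal + eps

  a_site <- abundance[fm$sites$gene]
  lam <- a_site * 10^log10_cs * config$deg_depth
  if (!is.null(config$overdispersion) && config$overdispersion > 0) {
    od <- config$overdispersion
    lam <- lam * rgamma(length(lam), shape = 1 / od, scale = od)
  }
  reads <- rpois(length(lam), lam)

  deg <- lapply(split(seq_len(nrow(fm$sites)), fm$sites$gene), function(i) {
    nz <- reads[i] > 0
    count_track(fm$sites$gene[i[1]], "degradome",
                fm$sites$position[i][nz], reads[i][nz])
  })
  cap <- lapply(names(transcripts), function(g) {
    count_track(g, "cap", 0L, rpois(1, abundance[[g]] * config$cap_depth))
  })
  names(cap) <- names(transcripts)

  truth <- structure(list(
    abundance = data.frame(gene = names(abundance),
                           abundance = unname(abundance),
                           stringsAsFactors = FALSE),
    sites = data.frame(gene = fm$sites$gene,
                       position = fm$sites$position,
                       true_log10_cs = log10_cs, signal = signal,
                       reads = reads, stringsAsFactors = FALSE),
    planted = planted[, c("name", "beta")],
    alpha0 = config$alpha0, sigma_eps = config$sigma_eps,
    Z_planted = Z), class = "cf_sim_truth")
  list(degradome = structure(deg, kind = "degradome"),
       cap = structure(cap, kind = "cap"), truth = truth)
}

#' Simulate ribosome-protected-fragment tracks
#'
#' RPF reads concentrate in the CDS (UTR positions receive
#' `utr_rpf_factor` times the CDS rate), scaled by gene abundance and a
#' per-gene log-normal occupancy factor.
#'
#' @param transcripts Output of [simulate_transcripts()].
#' @param config A `cf_sim_config`.
#' @param truth Optional `cf_sim_truth` so abundances match the degradome
#'   simulation; drawn fresh otherwise.
#' @return List with `rpf` (track set) and `occupancy_factor` (named
#'   per-gene vector).
#' @export
simulate_ribosome <- function(transcripts, config, truth = NULL) {
  stopifnot(inherits(config, "cf_sim_config"))
  set.seed(config$seed + 2L)
  abundance <- if (!is.null(truth)) {
    setNames(truth$abundance$abundance, truth$abundance$gene)
  } else {
    setNames(rlnorm(length(transcripts), config$abundance_meanlog,
                    config$abundance_sdlog), names(transcripts))
  }
  f <- setNames(rlnorm(length(transcripts), 0, config$occupancy_sdlog),
                names(transcripts))
  rpf <- lapply(transcripts, function(tx) {
    rate <- rep(config$utr_rpf_factor, tx$length)
    rate[(tx$cds_start + 1L):tx$cds_end] <- 1
    lam <- abundance[[tx$id]] * config$rpf_depth * f[[tx$id]] * rate
    reads <- rpois(tx$length, lam)
    nz <- reads > 0
    count_track(tx$id, "rpf", which(nz) - 1L, reads[nz])
  })
  list(rpf = structure(rpf, kind = "rpf"), occupancy_factor = f)
}

#' Compare a fitted model against the planted truth
#'
#' A planted effect counts as recovered when its feature survived the
#' pipeline, has a nonzero fitted coefficient, and the coefficient sign
#' matches the planted sign. Nonzero fitted features that were not planted
#' are false positives.
#'
#' @param fitted A `cf_model`.
#' @param truth A `cf_sim_truth`.
#' @return A `cf_recovery`: per-feature table plus `n_planted`,
#'   `n_recovered`, `false_positives`.
#' @export
recovery_report <- function(fitted, truth) {
  stopifnot(inherits(fitted, "cf_model"), inherits(truth, "cf_sim_truth"))
  beta_hat <- fitted$beta[match(truth$planted$name, names(fitted$beta))]
  beta_hat[is.na(beta_hat)] <- 0
  recovered <- beta_hat != 0 & sign(beta_hat) == sign(truth$planted$beta)
  per <- data.frame(name = truth$planted$name,
                    beta_true = truth$planted$beta,
                    beta_hat = unname(beta_hat),
                    recovered = unname(recovered),
                    stringsAsFactors = FALSE)
  fp <- setdiff(names(fitted$beta)[fitted$beta != 0], truth$planted$name)
  structure(list(per_feature = per, n_planted = nrow(per),
                 n_recovered = sum(recovered),
                 false_positives = length(fp), false_positive_names = fp),
            class = "cf_recovery")
}

#' @export
print.cf_recovery <- function(x, ...) {
  cat(sprintf("<cf_recovery: %d/%d planted recovered, %d false positives>\n",
              x$n_recovered, x$n_planted, x$false_positives))
  invisible(x)
}

#' Write simulated data and ground truth to a directory
#' @param transcripts,deg,rib Outputs of the simulate functions.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(transcripts, deg, rib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(transcripts, file.path(dir, "transcripts.fa"),
                    file.path(dir, "regions.tsv"))
  write_count_track(deg$degradome, file.path(dir, "degradome.tsv"))
  write_count_track(deg$cap, file.path(dir, "cap.tsv"))
  write_count_track(rib$rpf, file.path(dir, "rpf.tsv"))
  write.table(deg$truth$sites, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(deg$truth$planted, file.path(dir, "truth_planted.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
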