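# Reading and validation of transcripts and per-position 5'-end count tracks.
#
# Coordinate conventions (used everywhere in the package):
#   * transcript positions are 0-based; CDS is the half-open interval
#     [cds_start, cds_end), cds_end pointing one past the stop codon;
#   * count-track positions are 0-based positions of read 5' ends.

#' Construct a transcript record
#'
#' A transcript is a spliced RNA sequence over \{A,C,G,U\} together with CDS
#' coordinates that partition it into 5'-UTR, CDS and 3'-UTR. DNA input (T)
#' is mapped to RNA (U) on construction.
#'
#' @param id Transcript identifier.
#' @param seq Sequence string (DNA or RNA alphabet; T is converted to U).
#' @param cds_start 0-based inclusive index of the first CDS nucleotide.
#' @param cds_end 0-based exclusive index one past the stop codon.
#' @return An object of class `cf_transcript` with fields `id`, `seq`,
#'   `cds_start`, `cds_end`, `length`.
#' @export
transcript <- function(id, seq, cds_start, cds_end) {
  seq <- chartr("T", "U", toupper(as.character(seq)))
  bad <- gsub("[ACGU]", "", seq)
  if (nchar(bad) > 0) {
    stop(sprintf("transcript '%s': invalid symbols in sequence: %s",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = ",")))
  }
  len <- nchar(seq)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!(cds_start >= 0L && cds_start < cds_end && cds_end <= len)) {
    stop(sprintf("transcript '%s': CDS [%d,%d) out of bounds for length %d",
                 id, cds_start, cds_end, len))
  }
  if ((cds_end - cds_start) %% 3L != 0L) {
    stop(sprintf("transcript '%s': CDS length %d not divisible by 3",
                 id, cds_end - cds_start))
  }
  structure(list(id = id, seq = seq, cds_start = cds_start,
                 cds_end = cds_end, length = len),
            class = "cf_transcript")
}

#' @export
print.cf_transcript <- function(x, ...) {
  cat(sprintf("<cf_transcript %s: %d nt, CDS [%d,%d)>\n",
              x$id, x$length, x$cds_start, x$cds_end))
  invisible(x)
}

#' Extract the 5'-UTR, CDS and 3'-UTR sequences of a transcript
#'
#' @param tx A `cf_transcript`.
#' @return Named list of strings `utr5`, `cds`, `utr3`, `whole` (possibly
#'   empty strings for absent UTRs).
#' @export
transcript_regions <- function(tx) {
  stopifnot(inherits(tx, "cf_transcript"))
  list(
    utr5 = substr(tx$seq, 1L, tx$cds_start),
    cds = substr(tx$seq, tx$cds_start + 1L, tx$cds_end),
    utr3 = substr(tx$seq, tx$cds_end + 1L, tx$length),
    whole = tx$seq
  )
}

#' Read transcripts from FASTA plus a CDS region table
#'
#' The region table is a TSV with header columns `id`, `cds_start`, `cds_end`
#' (0-based, half-open). One transcript is returned per id present in both
#' inputs; records failing validation (symbols outside A/C/G/U/T, CDS out of
#' bounds or length not divisible by 3, id missing from the FASTA) are
#' skipped and tallied in the `skipped` attribute.
#'
#' @param fasta_path Path to the transcript FASTA.
#' @param region_table_path Path to the region TSV.
#' @return Named list of `cf_transcript` objects, with attribute `skipped`
#'   (data.frame of id/reason).
#' @export
read_transcripts <- function(fasta_path, region_table_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(region_table_path)) {
    stop("region table not found: ", region_table_path)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reg <- read.delim(region_table_path, stringsAsFactors = FALSE)
  need <- c("id", "cds_start", "cds_end")
  if (!all(need %in% names(reg))) {
    stop("region table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  skipped <- list()
  for (i in seq_len(nrow(reg))) {
    id <- as.character(reg$id[i])
    if (!id %in% names(seqs)) {
      skipped[[length(skipped) + 1L]] <- data.frame(id = id,
                                                    reason = "not in FASTA")
      next
    }
    tx <- tryCatch(
      transcript(id, as.character(seqs[[id]]), reg$cds_start[i],
                 reg$cds_end[i]),
      error = function(e) conditionMessage(e)
    )
    if (is.character(tx)) {
      skipped[[length(skipped) + 1L]] <- data.frame(id = id, reason = tx)
    } else {
      out[[id]] <- tx
    }
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(id = character(), reason = character())
  if (nrow(skipped)) {
    cf_log("read_transcripts: skipped %d record(s)", nrow(skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read a per-position 5'-end count track
#'
#' Input is a bedGraph-like TSV on transcript coordinates with header columns
#' `transcript_id`, `position` (0-based), `count`. Duplicate (id, position)
#' rows are summed. Positions are validated against transcript lengths when
#' `transcripts` is supplied.
#'
#' @param path Path to the TSV (an empty or header-only file yields an empty
#'   set).
#' @param kind One of `"degradome"`, `"cap"`, `"rpf"`.
#' @param transcripts Optional named list of `cf_transcript` for bounds
#'   validation.
#' @return Named list (by transcript id) of `cf_track` objects with fields
#'   `transcript_id`, `kind`, `pos` (sorted integer vector), `count`.
#' @export
read_count_track <- function(path, kind = c("degradome", "cap", "rpf"),
                             transcripts = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("count track not found: ", path)
  if (file.size(path) == 0L) return(structure(list(), kind = kind))
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% names(d))) {
    stop("count track must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d) == 0L) return(structure(list(), kind = kind))
  if (any(d$count < 0)) stop("negative counts in ", path)
  if (any(d$position < 0)) stop("negative positions in ", path)
  tracks <- lapply(split(d, d$transcript_id), function(g) {
    agg <- tapply(g$count, g$position, sum)
    pos <- as.integer(names(agg))
    o <- order(pos)
    count_track(g$transcript_id[1], kind, pos[o], as.numeric(agg)[o])
  })
  if (!is.null(transcripts)) {
    for (tr in tracks) {
      tx <- transcripts[[tr$transcript_id]]
      if (!is.null(tx) && length(tr$pos) && max(tr$pos) >= tx$length) {
        stop(sprintf("track position %d >= length %d for transcript '%s'",
                     max(tr$pos), tx$length, tr$transcript_id))
      }
    }
  }
  structure(tracks, kind = kind)
}

#' Construct a count track in memory
#'
#' @param transcript_id Transcript id.
#' @param kind One of degradome/cap/rpf.
#' @param pos Integer vector of 0-based positions.
#' @param count Non-negative counts, same length as `pos`.
#' @return A `cf_track`.
#' @export
count_track <- function(transcript_id, kind = c("degradome", "cap", "rpf"),
                        pos = integer(), count = numeric()) {
  kind <- match.arg(kind)
  stopifnot(length(pos) == length(count), all(count >= 0), all(pos >= 0))
  o <- order(pos)
  structure(list(transcript_id = transcript_id, kind = kind,
                 pos = as.integer(pos[o]), count = as.numeric(count[o])),
            class = "cf_track")
}

#' Write a set of count tracks to a TSV
#' @param tracks Named list of `cf_track`.
#' @param path Output path.
#' @export
write_count_track <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    if (!length(tr$pos)) return(NULL)
    data.frame(transcript_id = tr$transcript_id, position = tr$pos,
               count = tr$count)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) {
    d <- data.frame(transcript_id = character(), position = integer(),
                    count = numeric())
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transcripts to FASTA and a region TSV
#' @param transcripts Named list of `cf_transcript`.
#' @param fasta_path Output FASTA path.
#' @param region_table_path Output region TSV path.
#' @export
write_transcripts <- function(transcripts, fasta_path, region_table_path) {
  lines <- unlist(lapply(transcripts, function(tx) c(paste0(">", tx$id),
                                                     tx$seq)))
  writeLines(lines, fasta_path)
  reg <- data.frame(id = vapply(transcripts, `[[`, "", "id"),
                    cds_start = vapply(transcripts, `[[`, 0L, "cds_start"),
                    cds_end = vapply(transcripts, `[[`, 0L, "cds_end"))
  write.table(reg, region_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}
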