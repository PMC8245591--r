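## tRNA evidence channel: extract annotated tRNA genes (prediction itself is
## an input, not performed here) and link phages to hosts through shared
## tRNAs at >= 95% identity, keeping only the best hit per phage tRNA.

#' Read tRNA annotations from a GFF3 file
#'
#' @param path GFF3 file.
#' @return data.frame with \code{seqid}, \code{start}, \code{end} (1-based
#'   inclusive), \code{strand}, \code{type}, \code{id}.
#' @export
read_trna_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("trna_", seq_along(gr))
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type), id = id)
}

#' Write tRNA annotations to a GFF3 file
#'
#' @param ann data.frame with \code{seqid}, \code{start}, \code{end}
#'   (1-based inclusive), \code{strand} and an \code{attributes} or
#'   \code{id} column; NULL writes an empty file.
#' @param path output path.
#' @export
write_trna_gff3 <- function(ann, path) {
  if (is.null(ann) || nrow(ann) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  id <- if (!is.null(ann$attributes)) sub("^ID=", "", ann$attributes) else
    if (!is.null(ann$id)) ann$id else paste0("trna_", seq_len(nrow(ann)))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seqid,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand, type = "tRNA", ID = id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract tRNA gene sequences from annotated contigs
#'
#' Coordinates are 1-based inclusive (GFF3); minus-strand genes are
#' reverse-complemented so all returned sequences read 5' to 3'. Records
#' referencing unknown contigs or exceeding contig bounds raise an error
#' naming the record; records whose length falls outside [50, 120] bp are
#' dropped with a warning.
#'
#' @param seqs named character vector of contig sequences.
#' @param annotations data.frame as from [read_trna_gff3()], or a path to a
#'   GFF3 file. Only rows with \code{type == "tRNA"} are used.
#' @return data.frame with \code{id}, \code{owner} (contig id),
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{seq}.
#' @export
extract_trnas <- function(seqs, annotations) {
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_trna_gff3(annotations)
  ann <- annotations[annotations$type == "tRNA", , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(ann))) {
    sid <- ann$seqid[r]
    if (!sid %in% names(seqs))
      stop("tRNA record ", r, ": unknown contig '", sid, "'")
    n <- nchar(seqs[[sid]])
    if (ann$start[r] < 1L || ann$end[r] > n || ann$start[r] > ann$end[r])
      stop("tRNA record ", r, ": coordinates [", ann$start[r], ", ",
           ann$end[r], "] out of bounds for contig '", sid, "' (", n, " bp)")
    len <- ann$end[r] - ann$start[r] + 1L
    if (len < 50L || len > 120L) {
      warning("tRNA record ", r, ": length ", len,
              " bp outside [50, 120], dropped")
      next
    }
    s <- substr(seqs[[sid]], ann$start[r], ann$end[r])
    if (ann$strand[r] == "-") s <- revcomp(s)
    id <- if (!is.null(ann$id)) ann$id[r] else paste0("trna_", r)
    out[[length(out) + 1L]] <- data.frame(
      id = id, owner = sid, start = ann$start[r] - 1L, end = ann$end[r],
      strand = ann$strand[r], seq = s)
  }
  if (!length(out)) {
    return(data.frame(id = character(0), owner = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), seq = character(0)))
  }
  do.call(rbind, out)
}

## End-free (overlap) global alignment of two short sequences; returns
## identity over aligned columns and coverage of the shorter sequence.
trna_align_stats <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
  cols <- Biostrings::nchar(pa)
  if (cols == 0L) return(c(identity = 0, coverage = 0, score = -Inf))
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  covered <- min(Biostrings::end(pat) - Biostrings::start(pat) + 1L,
                 Biostrings::end(sub) - Biostrings::start(sub) + 1L)
  c(identity = Biostrings::nmatch(pa) / cols,
    coverage = covered / min(nchar(a), nchar(b)),
    score = Biostrings::score(pa))
}

#' Link phages to hosts through shared tRNA genes
#'
#' Each phage tRNA is aligned (end-free global alignment, both
#' orientations) to every host tRNA. A pair is a candidate when identity
#' over aligned columns is at least \code{min_identity} and the aligned
#' region covers at least \code{min_coverage} of the shorter sequence. Per
#' phage tRNA only the single best host hit is kept (highest identity, then
#' highest coverage, then host id lexicographic, logged when tied); one
#' evidence link of channel \code{"trna"} is emitted per linked
#' (phage, host) pair.
#'
#' @param phage_trnas,host_trnas data.frames from [extract_trnas()].
#' @param min_identity identity threshold (default 0.95).
#' @param min_coverage coverage threshold over the shorter sequence
#'   (default 0.9).
#' @return list with \code{matches} (per phage-tRNA best hits) and
#'   \code{links}.
#' @export
match_trnas <- function(phage_trnas, host_trnas, min_identity = 0.95,
                        min_coverage = 0.9) {
  empty_links <- data.frame(phage_id = character(0), host_id = character(0),
                            channel = character(0), identity = numeric(0),
                            score = numeric(0))
  empty_matches <- data.frame(phage_trna = character(0),
                              host_trna = character(0),
                              phage_id = character(0), host_id = character(0),
                              identity = numeric(0), coverage = numeric(0))
  if (nrow(phage_trnas) == 0L || nrow(host_trnas) == 0L)
    return(list(matches = empty_matches, links = empty_links))
  best <- list()
  for (i in seq_len(nrow(phage_trnas))) {
    cand <- list()
    for (j in seq_len(nrow(host_trnas))) {
      st_f <- trna_align_stats(phage_trnas$seq[i], host_trnas$seq[j])
      st_r <- trna_align_stats(phage_trnas$seq[i], revcomp(host_trnas$seq[j]))
      ## orientation decided by alignment score: identity alone would favour
      ## tiny perfect end-overlaps in the wrong orientation
      st <- if (st_f["score"] >= st_r["score"]) st_f else st_r
      if (st["identity"] >= min_identity && st["coverage"] >= min_coverage) {
        cand[[length(cand) + 1L]] <- data.frame(
          phage_trna = phage_trnas$id[i], host_trna = host_trnas$id[j],
          phage_id = phage_trnas$owner[i], host_id = host_trnas$owner[j],
          identity = unname(st["identity"]), coverage = unname(st["coverage"]))
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    ord <- order(-cand$identity, -cand$coverage, cand$host_id)
    if (nrow(cand) > 1L &&
        cand$identity[ord[1]] == cand$identity[ord[2]] &&
        cand$coverage[ord[1]] == cand$coverage[ord[2]])
      message("tRNA best-hit tie for ", phage_trnas$id[i],
              ": keeping host id '", cand$host_id[ord[1]], "'")
    best[[length(best) + 1L]] <- cand[ord[1], ]
  }
  if (!length(best)) return(list(matches = empty_matches, links = empty_links))
  matches <- do.call(rbind, best)
  rownames(matches) <- NULL
  ord <- order(matches$phage_id, matches$host_id, -matches$identity)
  m <- matches[ord, ]
  top <- m[!duplicated(m[, c("phage_id", "host_id")]), ]
  links <- data.frame(phage_id = top$phage_id, host_id = top$host_id,
                      channel = "trna", identity = top$identity,
                      score = top$identity, row.names = NULL)
  list(matches = matches, links = links)
}
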