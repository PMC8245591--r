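## Homology evidence channel: find integrated-prophage signatures of phage
## contigs in host genomes by local alignment, then apply the identity and
## length acceptance window (>80% identity, span between 1 kb and 50% of
## the host contig length).

#' Local nucleotide alignment (seed-and-extend with exact DP on windows)
#'
#' Aligns \code{query} against \code{subject} on both strands with
#' Smith-Waterman scoring (match +1, mismatch -1, affine gaps costing
#' \code{gap_open + gap_extend * L}). Small problems are solved by exact
#' dynamic programming over the full matrix; larger ones are seeded with
#' exact 11-mer matches, chained by diagonal into candidate windows, and
#' solved exactly within each window. Reported alignments are greedily
#' non-overlapping on the subject, in descending score order.
#'
#' @param query,subject character DNA sequences.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param min_score minimum alignment score to report (default 50, about a
#'   50 bp exact match).
#' @param seed_k exact seed size for the seed-and-extend path.
#' @param max_dp_cells threshold (query x subject cells) below which the
#'   full exact DP is used directly.
#' @return data.frame with one row per alignment: \code{q_start},
#'   \code{q_end}, \code{s_start}, \code{s_end} (0-based half-open, on the
#'   forward strands), \code{strand}, \code{score}, \code{matches},
#'   \code{cols} (aligned columns) and \code{identity = matches/cols}.
#' @export
local_align <- function(query, subject, match = 1, mismatch = -1,
                        gap_open = 10, gap_extend = 10, min_score = 50,
                        seed_k = 11L, max_dp_cells = 4e6) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  qlen <- nchar(query)
  res <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "-") revcomp(query) else query
    alns <- if (qlen * nchar(subject) <= max_dp_cells) {
      a <- affine_local_cpp(qs, subject, match, mismatch, gap_open, gap_extend)
      if (a$score > 0 && a$score >= min_score) list(a) else list()
    } else {
      align_windows(qs, subject, match, mismatch, gap_open, gap_extend,
                    min_score, seed_k)
    }
    for (a in alns) {
      qa <- c(a$q_start, a$q_end)
      if (strand == "-") qa <- c(qlen - a$q_end, qlen - a$q_start)
      res[[length(res) + 1L]] <- data.frame(
        q_start = qa[1], q_end = qa[2],
        s_start = a$s_start, s_end = a$s_end, strand = strand,
        score = a$score, matches = a$matches, cols = a$cols,
        identity = a$matches / a$cols)
    }
  }
  if (!length(res)) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), score = numeric(0),
                      matches = integer(0), cols = integer(0),
                      identity = numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$score, out$s_start), ]
  ## greedy non-overlap on the subject
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ov <- keep & out$s_start < out$s_end[i] & out$s_start[i] < out$s_end
    keep[i] <- !any(ov[seq_len(i - 1L)])
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Seed, cluster into windows, and align each window exactly.
align_windows <- function(q, s, match, mismatch, gap_open, gap_extend,
                          min_score, seed_k, margin = 200L,
                          diag_band = 64L, chain_gap = 1500L) {
  seeds <- seed_hits_cpp(q, s, seed_k)
  if (nrow(seeds) == 0L) return(list())
  ## cluster seeds by diagonal band, then by subject-position gaps within a
  ## band; a near-ungapped local alignment (gap costs are steep) keeps an
  ## almost constant diagonal, so bands of width diag_band suffice
  diag <- seeds[, 2] - seeds[, 1]
  bin <- diag %/% diag_band
  ord <- order(bin, seeds[, 2])
  seeds <- seeds[ord, , drop = FALSE]
  bin <- bin[ord]
  new_cluster <- c(TRUE, bin[-1] != bin[-length(bin)] |
                     diff(seeds[, 2]) > chain_gap)
  cl <- cumsum(new_cluster)
  ## candidate windows from clusters of >= 2 seeds (a single random 11-mer
  ## is never worth refining)
  win <- list()
  for (g in unique(cl)) {
    sel <- cl == g
    if (sum(sel) < 2L) next
    win[[length(win) + 1L]] <- c(
      max(0L, min(seeds[sel, 1]) - margin),
      min(nchar(q), max(seeds[sel, 1]) + seed_k + margin),
      max(0L, min(seeds[sel, 2]) - margin),
      min(nchar(s), max(seeds[sel, 2]) + seed_k + margin))
  }
  if (!length(win)) return(list())
  ## merge windows overlapping in both coordinates so a homologous region
  ## touched by many seed clusters is aligned once
  win <- do.call(rbind, win)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(win)) {
      j <- i + 1L
      while (j <= nrow(win)) {
        if (win[i, 1] < win[j, 2] && win[j, 1] < win[i, 2] &&
            win[i, 3] < win[j, 4] && win[j, 3] < win[i, 4]) {
          win[i, ] <- c(min(win[i, 1], win[j, 1]), max(win[i, 2], win[j, 2]),
                        min(win[i, 3], win[j, 3]), max(win[i, 4], win[j, 4]))
          win <- win[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  out <- list()
  for (i in seq_len(nrow(win))) {
    q0 <- win[i, 1]; q1 <- win[i, 2]; s0 <- win[i, 3]; s1 <- win[i, 4]
    if ((q1 - q0) * (s1 - s0) > 6e7) next  # window too large to refine
    a <- affine_local_cpp(slice0(q, q0, q1), slice0(s, s0, s1),
                          match, mismatch, gap_open, gap_extend)
    if (a$score < min_score) next
    a$q_start <- a$q_start + q0; a$q_end <- a$q_end + q0
    a$s_start <- a$s_start + s0; a$s_end <- a$s_end + s0
    out[[length(out) + 1L]] <- a
  }
  out
}

#' Align all phages against all hosts and collect prophage candidates
#'
#' @param phages,hosts named character vectors of sequences.
#' @param ... passed to [local_align()].
#' @return data.frame of alignments with \code{phage_id} and
#'   \code{host_contig} columns prepended.
#' @export
align_prophages <- function(phages, hosts, ...) {
  out <- list()
  for (pid in names(phages)) for (hid in names(hosts)) {
    a <- local_align(phages[[pid]], hosts[[hid]], ...)
    if (nrow(a))
      out[[length(out) + 1L]] <- cbind(data.frame(phage_id = pid,
                                                  host_contig = hid), a)
  }
  if (!length(out)) {
    return(cbind(data.frame(phage_id = character(0),
                            host_contig = character(0)),
                 local_align("A", "C")[0, ]))
  }
  do.call(rbind, out)
}

#' Filter prophage alignments to evidence links
#'
#' Applies the acceptance window: identity strictly above
#' \code{min_identity} (default 0.80), aligned span on the host of at least
#' \code{min_span} (default 1000 bp) and at most \code{max_span_frac}
#' (default 0.5) of the host contig length. Host contigs shorter than
#' \code{2 * min_span} have an empty acceptance window and never yield a
#' link (a message notes how many alignments this discards). Per
#' (phage, host) pair only the highest-scoring surviving alignment becomes
#' one evidence link of channel \code{"homology"}.
#'
#' @param alignments data.frame from [align_prophages()].
#' @param hosts named character vector of host sequences, or named integer
#'   vector of host contig lengths.
#' @return list with \code{alignments} (input plus \code{span} and
#'   \code{accepted} columns) and \code{links}.
#' @export
filter_prophage_hits <- function(alignments, hosts,
                                 min_identity = 0.80, min_span = 1000L,
                                 max_span_frac = 0.5) {
  host_len <- if (is.numeric(hosts)) hosts else
    setNames(nchar(hosts), names(hosts))
  unknown <- setdiff(unique(alignments$host_contig), names(host_len))
  if (length(unknown))
    stop("unknown host contig id(s): ", paste(unknown, collapse = ", "))
  a <- alignments
  empty_links <- data.frame(phage_id = character(0), host_id = character(0),
                            channel = character(0), identity = numeric(0),
                            span = integer(0), score = numeric(0))
  if (nrow(a) == 0L)
    return(list(alignments = cbind(a, span = integer(0), accepted = logical(0)),
                links = empty_links))
  a$span <- a$s_end - a$s_start
  hl <- host_len[a$host_contig]
  degenerate <- hl < 2L * min_span
  if (any(degenerate & a$span >= min_span))
    message(sum(degenerate), " alignment(s) on host contigs shorter than ",
            2L * min_span, " bp: acceptance window empty, rejected")
  a$accepted <- a$identity > min_identity & a$span >= min_span &
    a$span <= max_span_frac * hl
  acc <- a[a$accepted, , drop = FALSE]
  if (nrow(acc) == 0L) return(list(alignments = a, links = empty_links))
  ord <- order(acc$phage_id, acc$host_contig, -acc$score)
  acc <- acc[ord, ]
  best <- acc[!duplicated(acc[, c("phage_id", "host_contig")]), ]
  links <- data.frame(phage_id = best$phage_id, host_id = best$host_contig,
                      channel = "homology", identity = best$identity,
                      span = best$span, score = best$score, row.names = NULL)
  list(alignments = a, links = links)
}
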