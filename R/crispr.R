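## CRISPR evidence channel: a simplified repeat-spacer array detector
## (periodic exact k-mer seeds extended to the repeat unit) and full-length
## Hamming spacer matching with a <=1 mismatch acceptance rule.

#' Detect CRISPR repeat-spacer arrays on a host contig
#'
#' Seeds are exact 13-mers occurring at least \code{min_repeats} times with
#' consecutive spacings inside the feasible repeat+spacer period window.
#' Seed runs whose spans overlap are grouped into one candidate array; the
#' repeat unit is the union of the grouped seeds' relative offsets, so on
#' mutation-free arrays the repeat boundaries are recovered exactly.
#' Candidates are validated against repeat-length, spacer-length and
#' repeat-identity constraints and reported greedily leftmost without
#' overlap.
#'
#' @param host character DNA sequence.
#' @param host_id contig identifier carried into results.
#' @param min_repeats minimum repeat copies (>= 3).
#' @param repeat_len_range,spacer_len_range admissible lengths in bp.
#' @param min_repeat_identity minimum mean identity of repeat copies to
#'   their column-majority consensus.
#' @param seed_k exact seed word size.
#' @return list of arrays; each is a list with \code{host_contig_id},
#'   \code{repeat_consensus}, \code{repeats} (data.frame of 0-based
#'   half-open intervals), \code{spacers} (intervals plus sequences),
#'   \code{strand}, and the overall \code{start}/\code{end}.
#' @export
detect_arrays <- function(host, host_id = "host", min_repeats = 3L,
                          repeat_len_range = c(21L, 48L),
                          spacer_len_range = c(17L, 60L),
                          min_repeat_identity = 0.9, seed_k = 13L) {
  n <- nchar(host)
  if (n < 3L * repeat_len_range[1]) return(list())
  period_min <- repeat_len_range[1] + spacer_len_range[1]
  period_max <- repeat_len_range[2] + spacer_len_range[2]

  starts <- seq_len(n - seed_k + 1L)
  kmers <- substring(host, starts, starts + seed_k - 1L)
  pos_by_kmer <- split(starts - 1L, kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= min_repeats]

  runs <- list()
  for (pp in pos_by_kmer) {
    pp <- sort(pp)
    gaps_ok <- diff(pp) >= period_min & diff(pp) <= period_max
    r <- rle(gaps_ok)
    idx <- 1L
    for (q in seq_along(r$lengths)) {
      if (r$values[q] && r$lengths[q] + 1L >= min_repeats)
        runs[[length(runs) + 1L]] <- pp[idx:(idx + r$lengths[q])]
      idx <- idx + r$lengths[q]
    }
  }
  if (!length(runs)) return(list())

  spans <- t(vapply(runs, function(p) c(min(p), max(p) + seed_k), numeric(2)))
  ord <- order(spans[, 1])
  runs <- runs[ord]
  spans <- spans[ord, , drop = FALSE]
  cluster_id <- integer(length(runs))
  cur <- 0L
  cur_end <- -1
  for (i in seq_along(runs)) {
    if (spans[i, 1] > cur_end) {
      cur <- cur + 1L
      cur_end <- spans[i, 2]
    } else cur_end <- max(cur_end, spans[i, 2])
    cluster_id[i] <- cur
  }

  arrays <- list()
  for (cid in unique(cluster_id)) {
    members <- runs[cluster_id == cid]
    sizes <- lengths(members)
    anchor <- members[[order(-sizes, vapply(members, min, numeric(1)))[1]]]
    offs <- 0L
    for (m in members) {
      if (length(m) == length(anchor)) {
        d <- m - anchor
        if (all(d == d[1]) && abs(d[1]) < repeat_len_range[2])
          offs <- c(offs, d[1])
      } else {
        ## a seed missing from some repeat copies: take the most frequent
        ## pairwise shift, preferring the smallest |shift| on ties
        dd <- as.vector(outer(m, anchor, "-"))
        tab <- table(dd)
        cand <- as.integer(names(tab)[tab == max(tab)])
        dmode <- cand[order(abs(cand), cand)][1]
        if (max(tab) >= min_repeats && abs(dmode) < repeat_len_range[2])
          offs <- c(offs, dmode)
      }
    }
    ## drop offsets that would stretch the repeat beyond its maximum
    ## length (spurious shifts), farthest from the anchor first
    offs <- sort(unique(offs))
    while (max(offs) + seed_k - min(offs) > repeat_len_range[2] &&
           length(offs) > 1L) {
      offs <- offs[-which.max(abs(offs))]
    }
    arr <- build_array(host, host_id, anchor, min(offs), max(offs) + seed_k,
                       min_repeats, repeat_len_range, spacer_len_range,
                       min_repeat_identity)
    if (!is.null(arr)) arrays[[length(arrays) + 1L]] <- arr
  }
  if (!length(arrays)) return(list())

  ## greedy leftmost, no overlapping arrays
  ord <- order(vapply(arrays, `[[`, numeric(1), "start"))
  out <- list()
  last_end <- -1
  for (a in arrays[ord]) {
    if (a$start >= last_end) {
      out[[length(out) + 1L]] <- a
      last_end <- a$end
    }
  }
  out
}

## Assemble and validate one candidate array from anchor seed positions and
## the repeat extent [offmin, offmax) relative to those positions.
build_array <- function(host, host_id, anchor, offmin, offmax, min_repeats,
                        repeat_len_range, spacer_len_range,
                        min_repeat_identity) {
  n <- nchar(host)
  rep_len <- offmax - offmin
  if (rep_len < repeat_len_range[1] || rep_len > repeat_len_range[2])
    return(NULL)
  rs <- anchor + offmin
  re <- anchor + offmax
  keep <- rs >= 0 & re <= n
  rs <- rs[keep]; re <- re[keep]
  if (length(rs) < min_repeats) return(NULL)

  ## longest consecutive stretch with valid spacer gaps
  gap <- rs[-1] - re[-length(re)]
  ok <- gap >= spacer_len_range[1] & gap <= spacer_len_range[2]
  r <- rle(ok)
  best <- NULL
  idx <- 1L
  for (q in seq_along(r$lengths)) {
    if (r$values[q] && r$lengths[q] + 1L >= min_repeats &&
        (is.null(best) || r$lengths[q] > best$len))
      best <- list(from = idx, to = idx + r$lengths[q], len = r$lengths[q])
    idx <- idx + r$lengths[q]
  }
  if (is.null(best)) return(NULL)
  rs <- rs[best$from:best$to]
  re <- re[best$from:best$to]

  ## trim boundary columns with imperfect cross-copy agreement: characters
  ## just outside the true repeat can coincide across copies and drag the
  ## extent out by one; on mutation-free arrays this restores exact bounds
  agreement <- function(pos_offsets) {
    vapply(pos_offsets, function(o) {
      col <- substring(host, rs + o + 1L, rs + o + 1L)
      max(table(col)) / length(col)
    }, numeric(1))
  }
  while (re[1] - rs[1] > repeat_len_range[1] && agreement(0L) < 1) rs <- rs + 1L
  while (re[1] - rs[1] > repeat_len_range[1] &&
         agreement(re[1] - rs[1] - 1L) < 1) re <- re - 1L

  copies <- substring(host, rs + 1L, re)
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  consensus <- apply(mat, 2L, function(col) names(which.max(table(col))))
  ident <- mean(vapply(seq_len(nrow(mat)),
                       function(i) mean(mat[i, ] == consensus), numeric(1)))
  if (ident < min_repeat_identity) return(NULL)

  m <- length(rs)
  spacer_start <- re[-m]
  spacer_end <- rs[-1]
  list(host_contig_id = host_id,
       repeat_consensus = paste(consensus, collapse = ""),
       repeats = data.frame(start = rs, end = re),
       spacers = data.frame(start = spacer_start, end = spacer_end,
                            seq = substring(host, spacer_start + 1L,
                                            spacer_end)),
       strand = "+", start = rs[1], end = re[m])
}

#' Match CRISPR spacers against phage contigs
#'
#' Full-length ungapped matching: every position of every phage (both
#' strands) where a spacer aligns with Hamming distance at most
#' \code{max_mismatch} is a hit. Each (phage, host) pair with at least one
#' hit yields one evidence link of channel \code{"crispr"} carrying its best
#' hit (fewest mismatches, then leftmost on the phage, then + strand).
#' Spacers containing ambiguity codes are skipped with a warning.
#'
#' @param arrays list of arrays from [detect_arrays()].
#' @param phages named character vector of phage sequences.
#' @param max_mismatch maximum Hamming distance over the full spacer length.
#' @return list with \code{hits} (one row per spacer hit: phage_id, host_id,
#'   array_id, spacer_idx, phage_start, phage_end, strand, mismatches) and
#'   \code{links} (one row per linked pair with the best hit's fields and
#'   \code{channel = "crispr"}, \code{score = -mismatches}).
#' @export
match_spacers <- function(arrays, phages, max_mismatch = 1L) {
  hits <- list()
  subjects <- lapply(phages, Biostrings::DNAString)
  for (ai in seq_along(arrays)) {
    arr <- arrays[[ai]]
    for (si in seq_len(nrow(arr$spacers))) {
      sp <- arr$spacers$seq[si]
      if (!nzchar(sp)) next
      if (grepl("[^ACGT]", sp)) {
        warning("skipping spacer with ambiguity codes (array ", ai,
                ", spacer ", si, ")")
        next
      }
      for (strand in c("+", "-")) {
        pat <- if (strand == "-") revcomp(sp) else sp
        for (pid in names(subjects)) {
          m <- Biostrings::matchPattern(pat, subjects[[pid]],
                                        max.mismatch = max_mismatch,
                                        with.indels = FALSE)
          if (length(m) == 0L) next
          hit_seq <- as.character(m)
          mm <- vapply(hit_seq, hamming, numeric(1), b = pat, USE.NAMES = FALSE)
          hits[[length(hits) + 1L]] <- data.frame(
            phage_id = pid, host_id = arr$host_contig_id,
            array_id = ai, spacer_idx = si,
            phage_start = Biostrings::start(m) - 1L,
            phage_end = Biostrings::end(m),
            strand = strand, mismatches = as.integer(mm))
        }
      }
    }
  }
  if (!length(hits)) {
    empty <- data.frame(phage_id = character(0), host_id = character(0),
                        array_id = integer(0), spacer_idx = integer(0),
                        phage_start = integer(0), phage_end = integer(0),
                        strand = character(0), mismatches = integer(0))
    return(list(hits = empty,
                links = data.frame(phage_id = character(0),
                                   host_id = character(0),
                                   channel = character(0),
                                   mismatches = integer(0),
                                   score = numeric(0))))
  }
  hits <- do.call(rbind, hits)
  ## best hit per (phage, host): fewest mismatches, leftmost, + strand
  ord <- order(hits$phage_id, hits$host_id, hits$mismatches,
               hits$phage_start, hits$strand)
  h <- hits[ord, ]
  best <- h[!duplicated(h[, c("phage_id", "host_id")]), ]
  links <- data.frame(phage_id = best$phage_id, host_id = best$host_id,
                      channel = "crispr", mismatches = best$mismatches,
                      score = -best$mismatches, row.names = NULL)
  list(hits = hits, links = links)
}
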