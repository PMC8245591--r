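## Phage replication-mode calling: integrase/excisionase-like marker ORFs
## take precedence; phages without marker hits fall back to a transparent
## k-nearest-neighbour classifier on tetranucleotide composition. Ratios of
## temperate to lytic abundance are computed per environment on the
## copy-per-kilobase scale.

#' Find open reading frames in all six frames
#'
#' Maximal start-to-stop ORFs under the standard genetic code: within each
#' stop-delimited segment of a frame, the ORF runs from the first ATG to
#' the terminating stop. Only ORFs whose protein (including the initial
#' Met, excluding the stop) has at least \code{min_orf_aa} residues are
#' returned.
#'
#' @param phage character DNA sequence.
#' @param min_orf_aa minimum protein length in residues (default 60).
#' @param id contig identifier carried into results.
#' @return data.frame with \code{phage_id}, \code{frame} (0-2),
#'   \code{strand}, \code{start}, \code{end} (0-based half-open on the
#'   forward strand, including the stop codon) and \code{protein}. The
#'   interval length always equals \code{3 * (nchar(protein) + 1)}.
#' @export
find_orfs <- function(phage, min_orf_aa = 60L, id = "phage") {
  n <- nchar(phage)
  gc_tab <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "-") revcomp(phage) else phage
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < min_orf_aa + 1L) next
      starts <- frame + (seq_len(ncod) - 1L) * 3L + 1L
      codons <- substring(s, starts, starts + 2L)
      aa <- unname(gc_tab[codons])
      aa[is.na(aa)] <- "X"
      stop_at <- which(aa == "*")
      prev <- 0L
      for (t in stop_at) {
        if (t - prev >= min_orf_aa + 1L) {
          seg <- aa[(prev + 1L):(t - 1L)]
          m_rel <- match("M", seg)
          if (!is.na(m_rel)) {
            m <- prev + m_rel
            if (t - m >= min_orf_aa) {
              a0 <- frame + 3L * (m - 1L)  # 0-based on s
              b0 <- frame + 3L * t
              if (strand == "-") {
                fs <- n - b0; fe <- n - a0
              } else {
                fs <- a0; fe <- b0
              }
              out[[length(out) + 1L]] <- data.frame(
                phage_id = id, frame = frame, strand = strand,
                start = fs, end = fe,
                protein = paste(aa[m:(t - 1L)], collapse = ""))
            }
          }
        }
        prev <- t
      }
    }
  }
  if (!length(out)) {
    return(data.frame(phage_id = character(0), frame = integer(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), protein = character(0)))
  }
  do.call(rbind, out)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Detect lifestyle marker proteins among ORFs
#'
#' Local protein alignment (BLOSUM62, gap open 10 / extend 1) of every ORF
#' against every marker exemplar. A hit requires identity of at least
#' \code{min_identity} over an alignment covering at least
#' \code{min_coverage} of the exemplar length.
#'
#' @param orfs data.frame from [find_orfs()] (possibly several phages).
#' @param marker_db named character vector of amino-acid exemplars, e.g.
#'   [marker_exemplars()].
#' @param min_identity,min_coverage hit thresholds.
#' @return data.frame with \code{phage_id}, \code{orf}, \code{marker_id},
#'   \code{score}, \code{identity}, \code{coverage} (empty if no hits).
#' @export
detect_markers <- function(orfs, marker_db, min_identity = 0.35,
                           min_coverage = 0.5) {
  hits <- list()
  if (nrow(orfs) > 0L) {
    subs <- lapply(marker_db, Biostrings::AAString)
    for (i in seq_len(nrow(orfs))) {
      p <- Biostrings::AAString(gsub("X", "A", orfs$protein[i]))
      for (mid in names(subs)) {
        pa <- Biostrings::pairwiseAlignment(
          p, subs[[mid]], type = "local",
          substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1)
        cols <- Biostrings::nchar(pa)
        if (cols == 0L) next
        ident <- Biostrings::nmatch(pa) / cols
        sub_al <- Biostrings::subject(pa)
        cov <- (Biostrings::end(sub_al) - Biostrings::start(sub_al) + 1L) /
          nchar(marker_db[[mid]])
        if (ident >= min_identity && cov >= min_coverage) {
          hits[[length(hits) + 1L]] <- data.frame(
            phage_id = orfs$phage_id[i], orf = i, marker_id = mid,
            score = Biostrings::score(pa), identity = ident, coverage = cov)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(phage_id = character(0), orf = integer(0),
                      marker_id = character(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0)))
  }
  do.call(rbind, hits)
}

#' Build a tetranucleotide composition k-NN classifier
#'
#' Stores normalized 4-mer frequency vectors of labelled reference
#' sequences. Classification is by majority vote of the k nearest
#' references in Euclidean distance; confidence is the winning vote
#' fraction.
#'
#' @param ref_seqs named character vector of reference DNA sequences.
#' @param labels character vector of lifestyle labels
#'   (\code{"temperate"} / \code{"lytic"}), one per reference.
#' @param k neighbours considered (default 5; capped at the reference
#'   count).
#' @return object of class \code{composition_classifier}.
#' @export
composition_classifier <- function(ref_seqs, labels, k = 5L) {
  stopifnot(length(ref_seqs) == length(labels))
  mat <- if (length(ref_seqs))
    t(vapply(ref_seqs, tetra_freq, numeric(256))) else
    matrix(numeric(0), 0, 256)
  structure(list(freq = mat, labels = as.character(labels), k = as.integer(k)),
            class = "composition_classifier")
}

tetra_freq <- function(seq) {
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 4L)
  as.numeric(f / max(sum(f), 1L))
}

## k-NN vote for one sequence; returns label and vote fraction.
knn_vote <- function(classifier, seq) {
  n_ref <- nrow(classifier$freq)
  if (n_ref == 0L) return(list(label = "unclassified", confidence = 0))
  v <- tetra_freq(seq)
  d <- sqrt(rowSums(sweep(classifier$freq, 2L, v)^2))
  k <- min(classifier$k, n_ref)
  nn <- order(d, seq_len(n_ref))[seq_len(k)]
  votes <- table(classifier$labels[nn])
  win <- sort(names(votes)[votes == max(votes)])[1]  # tie: alphabetical
  list(label = win, confidence = as.numeric(max(votes)) / k)
}

#' Call the replication mode of one phage
#'
#' Marker precedence: any marker hit forces a temperate call. Otherwise the
#' composition classifier votes; its call stands when the vote fraction
#' reaches \code{conf_threshold}, else the phage is unclassified.
#'
#' @param phage_id contig identifier.
#' @param seq DNA sequence (used by the classifier path).
#' @param marker_hits data.frame from [detect_markers()] (all phages; rows
#'   matching \code{phage_id} are used).
#' @param classifier a [composition_classifier()] or NULL.
#' @param conf_threshold minimum vote fraction (default 0.6).
#' @return one-row data.frame: \code{phage_id}, \code{call}, \code{basis},
#'   \code{confidence}, \code{n_marker_hits}.
#' @export
classify_lifestyle <- function(phage_id, seq, marker_hits,
                               classifier = NULL, conf_threshold = 0.6) {
  nh <- if (is.null(marker_hits)) 0L else
    sum(marker_hits$phage_id == phage_id)
  if (nh > 0L) {
    return(data.frame(phage_id = phage_id, call = "temperate",
                      basis = "marker", confidence = 1,
                      n_marker_hits = nh))
  }
  if (is.null(classifier)) {
    return(data.frame(phage_id = phage_id, call = "unclassified",
                      basis = "none", confidence = 0, n_marker_hits = 0L))
  }
  v <- knn_vote(classifier, seq)
  call <- if (v$label != "unclassified" && v$confidence >= conf_threshold)
    v$label else "unclassified"
  data.frame(phage_id = phage_id, call = call, basis = "composition",
             confidence = v$confidence, n_marker_hits = 0L)
}

#' Call replication modes for a set of phages
#'
#' @param phages named character vector of sequences.
#' @param marker_db marker exemplars (see [detect_markers()]).
#' @param classifier optional [composition_classifier()].
#' @param min_orf_aa,conf_threshold,... thresholds passed through.
#' @return data.frame of calls (one row per phage) with the marker hit
#'   table attached as attribute \code{"marker_hits"}.
#' @export
call_lifestyles <- function(phages, marker_db = marker_exemplars(),
                            classifier = NULL, min_orf_aa = 60L,
                            conf_threshold = 0.6, ...) {
  orfs <- do.call(rbind, lapply(names(phages), function(pid)
    find_orfs(phages[[pid]], min_orf_aa = min_orf_aa, id = pid)))
  if (is.null(orfs)) orfs <- find_orfs("AAA", id = "none")[0, ]
  hits <- detect_markers(orfs, marker_db, ...)
  calls <- do.call(rbind, lapply(names(phages), function(pid)
    classify_lifestyle(pid, phages[[pid]], hits, classifier, conf_threshold)))
  attr(calls, "marker_hits") <- hits
  calls
}

#' Temperate:lytic abundance ratios per environment
#'
#' Normalizes counts to copies per kilobase and, per environment, sums Cpk
#' over temperate and over lytic phages across that environment's samples.
#' Unclassified phages are excluded from the ratios. Also reports the
#' contig-count ratio temperate/lytic.
#'
#' @param calls data.frame with \code{phage_id} and \code{call}; every row
#'   of \code{abundance} must have a call.
#' @param abundance count matrix (phages x samples).
#' @param lengths named contig lengths in bp.
#' @param sample_env named sample-to-environment map.
#' @return list with \code{per_env} (data.frame: environment,
#'   temperate_cpk, lytic_cpk, ratio, infinite flag), \code{count_ratio},
#'   \code{n_temperate}, \code{n_lytic}.
#' @export
tl_ratio <- function(calls, abundance, lengths, sample_env) {
  missing_call <- setdiff(rownames(abundance), calls$phage_id)
  if (length(missing_call))
    stop("phages without a lifestyle call: ",
         paste(missing_call, collapse = ", "))
  call_of <- setNames(calls$call, calls$phage_id)[rownames(abundance)]
  x <- cpk(abundance, lengths)
  envs <- unique(unname(sample_env[colnames(x)]))
  per_env <- do.call(rbind, lapply(envs, function(e) {
    cols <- sample_env[colnames(x)] == e
    t_sum <- sum(x[call_of == "temperate", cols, drop = FALSE])
    l_sum <- sum(x[call_of == "lytic", cols, drop = FALSE])
    data.frame(environment = e, temperate_cpk = t_sum, lytic_cpk = l_sum,
               ratio = if (l_sum > 0) t_sum / l_sum else Inf,
               infinite = l_sum == 0)
  }))
  n_t <- sum(call_of == "temperate")
  n_l <- sum(call_of == "lytic")
  list(per_env = per_env,
       count_ratio = if (n_l > 0) n_t / n_l else Inf,
       n_temperate = n_t, n_lytic = n_l)
}
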