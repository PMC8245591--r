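## Infection-network assembly and analysis: ensemble of the three evidence
## channels, enrichment labelling on a copy-per-kilobase scale,
## environmental partitioning of the network, and a label-randomization
## permutation test for stratification.

PHAGE_SOURCES <- c("sponge", "seawater", "mixed", "unknown")
HOST_NICHES <- c("sponge_symbiont", "plankton", "other_environment",
                 "other_animal")

#' Copy-per-kilobase normalization
#'
#' @param counts matrix of read counts (phages x samples).
#' @param lengths named contig lengths in bp (matched by rownames).
#' @return matrix of counts per kilobase of contig.
#' @export
cpk <- function(counts, lengths) {
  len <- lengths[rownames(counts)]
  if (any(is.na(len))) stop("missing contig length for: ",
                            paste(rownames(counts)[is.na(len)], collapse = ", "))
  if (any(len <= 0)) stop("zero or negative contig length")
  counts / (len / 1000)
}

#' Assemble the ensemble infection network
#'
#' Evidence links from any combination of channels are deduplicated by
#' (phage, host) pair with channel evidence unioned; only phages and hosts
#' that carry at least one edge appear as nodes.
#'
#' @param links data.frame with \code{phage_id}, \code{host_id},
#'   \code{channel}, \code{score} columns (rbind of channel outputs).
#' @param phage_meta data.frame with \code{id} and \code{enrichment}.
#' @param host_meta data.frame with \code{id} and \code{niche}.
#' @return object of class \code{infection_network}: list with
#'   \code{phages}, \code{hosts} node tables and an \code{edges} table
#'   (\code{phage_id}, \code{host_id}, \code{channels} comma-collapsed,
#'   \code{n_channels}, per-channel score columns).
#' @export
assemble_network <- function(links, phage_meta, host_meta) {
  if (nrow(links)) {
    bad_p <- setdiff(unique(links$phage_id), phage_meta$id)
    bad_h <- setdiff(unique(links$host_id), host_meta$id)
    if (length(bad_p)) stop("unknown phage id(s): ", paste(bad_p, collapse = ", "))
    if (length(bad_h)) stop("unknown host id(s): ", paste(bad_h, collapse = ", "))
  }
  if (nrow(links) == 0L) {
    edges <- data.frame(phage_id = character(0), host_id = character(0),
                        channels = character(0), n_channels = integer(0))
  } else {
    key <- paste(links$phage_id, links$host_id, sep = "\r")
    agg <- lapply(split(seq_len(nrow(links)), key), function(ix) {
      l <- links[ix, ]
      chans <- sort(unique(l$channel))
      row <- data.frame(phage_id = l$phage_id[1], host_id = l$host_id[1],
                        channels = paste(chans, collapse = ","),
                        n_channels = length(chans))
      for (ch in c("crispr", "homology", "trna")) {
        sc <- l$score[l$channel == ch]
        row[[paste0("score_", ch)]] <- if (length(sc)) max(sc) else NA_real_
      }
      row
    })
    edges <- do.call(rbind, agg)
    rownames(edges) <- NULL
    edges <- edges[order(edges$phage_id, edges$host_id), ]
  }
  phages <- phage_meta[phage_meta$id %in% edges$phage_id,
                       intersect(c("id", "enrichment"), names(phage_meta)),
                       drop = FALSE]
  hosts <- host_meta[host_meta$id %in% edges$host_id,
                     intersect(c("id", "niche"), names(host_meta)),
                     drop = FALSE]
  rownames(phages) <- rownames(hosts) <- NULL
  structure(list(phages = phages, hosts = hosts, edges = edges),
            class = "infection_network")
}

#' @export
print.infection_network <- function(x, ...) {
  cat(sprintf("Infection network: %d phages, %d hosts, %d edges\n",
              nrow(x$phages), nrow(x$hosts), nrow(x$edges)))
  if (nrow(x$edges)) {
    tab <- table(unlist(strsplit(x$edges$channels, ",")))
    cat("  channel evidence:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert an infection network to an igraph bipartite graph
#'
#' @param network an \code{infection_network}.
#' @return an igraph graph with a logical \code{type} vertex attribute
#'   (TRUE for hosts), \code{label} vertex attributes, and edge
#'   \code{channels} attributes.
#' @export
as_igraph <- function(network) {
  verts <- rbind(
    data.frame(name = network$phages$id, type = FALSE,
               label = network$phages$enrichment),
    data.frame(name = network$hosts$id, type = TRUE,
               label = network$hosts$niche))
  igraph::graph_from_data_frame(
    network$edges[, c("phage_id", "host_id", "channels")],
    directed = FALSE, vertices = verts)
}

#' Label phage enrichment from an abundance table
#'
#' Abundance is normalized to copies per kilobase (Cpk). A phage is labelled
#' \code{env_a} ("sponge") when its mean Cpk there is at least \code{fold}
#' times the mean in \code{env_b} ("seawater") and it is detected (Cpk > 0)
#' in at least \code{min_prevalence} of the \code{env_a} samples; the
#' symmetric rule gives \code{env_b}; phages absent everywhere are
#' \code{unknown}; everything else is \code{mixed}.
#'
#' @param abundance count matrix (phages x samples).
#' @param lengths named contig lengths (bp).
#' @param sample_env named character vector mapping sample to environment.
#' @param fold enrichment fold threshold (default 2).
#' @param min_prevalence detection prevalence threshold (default 0.5).
#' @param env_a,env_b the two environments compared.
#' @return named character vector of labels.
#' @export
label_enrichment <- function(abundance, lengths, sample_env, fold = 2.0,
                             min_prevalence = 0.5,
                             env_a = "sponge", env_b = "seawater") {
  stopifnot(all(colnames(abundance) %in% names(sample_env)))
  env <- sample_env[colnames(abundance)]
  if (!any(env == env_a) || !any(env == env_b))
    stop("need at least one sample per environment")
  x <- cpk(abundance, lengths)
  a <- x[, env == env_a, drop = FALSE]
  b <- x[, env == env_b, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  prev_a <- rowMeans(a > 0)
  prev_b <- rowMeans(b > 0)
  lab <- rep("mixed", nrow(x))
  lab[mean_a >= fold * mean_b & mean_a > 0 & prev_a >= min_prevalence] <- env_a
  lab[mean_b >= fold * mean_a & mean_b > 0 & prev_b >= min_prevalence] <- env_b
  lab[mean_a == 0 & mean_b == 0] <- "unknown"
  setNames(lab, rownames(x))
}

#' Environmental partitioning of the infection network
#'
#' For each phage, each distinct host-niche category it links to increments
#' the cell (phage source, niche) by one: a phage can contribute to several
#' niche columns, but at most once per niche. With
#' \code{counting = "per_edge"} every edge increments its cell instead.
#'
#' @param network an \code{infection_network} with labelled nodes.
#' @param counting \code{"per_phage_niche"} (default) or \code{"per_edge"}.
#' @return integer matrix, rows = phage sources, columns = host niches.
#' @export
partition_table <- function(network,
                            counting = c("per_phage_niche", "per_edge")) {
  counting <- match.arg(counting)
  tab <- matrix(0L, nrow = length(PHAGE_SOURCES), ncol = length(HOST_NICHES),
                dimnames = list(PHAGE_SOURCES, HOST_NICHES))
  if (nrow(network$edges) == 0L) return(tab)
  e <- network$edges
  e$src <- network$phages$enrichment[match(e$phage_id, network$phages$id)]
  e$niche <- network$hosts$niche[match(e$host_id, network$hosts$id)]
  if (counting == "per_phage_niche")
    e <- e[!duplicated(e[, c("phage_id", "niche")]), ]
  for (i in seq_len(nrow(e)))
    tab[e$src[i], e$niche[i]] <- tab[e$src[i], e$niche[i]] + 1L
  tab
}

#' Assortment statistic of the infection network
#'
#' Difference of conditional proportions over edges:
#' P(edge reaches a sponge-symbiont host | phage labelled sponge) minus
#' P(edge reaches a sponge-symbiont host | phage labelled seawater).
#' Edges of mixed/unknown phages are excluded. Bounded in [-1, 1]; positive
#' when sponge-enriched phages preferentially infect sponge symbionts.
#'
#' @param network an \code{infection_network}.
#' @param symbiont_niche host niche treated as the focal category.
#' @param label_a,label_b the two phage labels contrasted.
#' @return numeric scalar.
#' @export
assortment_statistic <- function(network, symbiont_niche = "sponge_symbiont",
                                 label_a = "sponge", label_b = "seawater") {
  pre <- network_stat_data(network, symbiont_niche)
  stat_from_labels(pre, pre$labels, label_a, label_b)
}

## Precompute per-phage edge tallies used by the statistic and the
## permutation test.
network_stat_data <- function(network, symbiont_niche = "sponge_symbiont") {
  e <- network$edges
  if (nrow(e) == 0L) stop("degenerate labels: network has no edges")
  niche <- network$hosts$niche[match(e$host_id, network$hosts$id)]
  is_sym <- niche == symbiont_niche
  ids <- network$phages$id
  deg <- as.integer(table(factor(e$phage_id, levels = ids)))
  sym <- as.integer(tapply(as.integer(is_sym),
                           factor(e$phage_id, levels = ids), sum,
                           default = 0L))
  list(ids = ids, deg = deg, sym = sym,
       labels = network$phages$enrichment)
}

stat_from_labels <- function(pre, labels, label_a = "sponge",
                             label_b = "seawater") {
  a <- labels == label_a
  b <- labels == label_b
  da <- sum(pre$deg[a])
  db <- sum(pre$deg[b])
  if (da == 0L || db == 0L) stop("degenerate labels: one class has no edges")
  sum(pre$sym[a]) / da - sum(pre$sym[b]) / db
}

#' Label-randomization permutation test for network stratification
#'
#' Compares the observed assortment statistic against its null distribution
#' under uniform random permutation of the phage enrichment labels (edges
#' and host niches fixed). The p value uses the add-one rule
#' \code{(1 + #extreme) / (1 + n_perm)}, where extreme means
#' \code{|null| >= |observed|} (two-sided), \code{null <= observed}
#' ("less") or \code{null >= observed} ("greater"). Replicates with a
#' degenerate label assignment are resampled, up to \code{10 * n_perm}
#' attempts in total.
#'
#' @param network an \code{infection_network}.
#' @param n_perm number of label randomizations (the source analysis used
#'   10,000).
#' @param seed RNG seed driving all permutations.
#' @param sided "two" (default), "less" or "greater".
#' @param symbiont_niche,label_a,label_b passed to the statistic.
#' @return list of class \code{stratification_result}: \code{observed},
#'   \code{null} (numeric vector), \code{p_value}, \code{n_perm},
#'   \code{seed}, \code{sided}.
#' @export
permutation_test <- function(network, n_perm = 10000L, seed = 1L,
                             sided = c("two", "less", "greater"),
                             symbiont_niche = "sponge_symbiont",
                             label_a = "sponge", label_b = "seawater") {
  sided <- match.arg(sided)
  pre <- network_stat_data(network, symbiont_niche)
  observed <- stat_from_labels(pre, pre$labels, label_a, label_b)
  labels <- pre$labels
  null <- with_seed(seed, {
    out <- numeric(n_perm)
    attempts <- 0L
    i <- 1L
    while (i <= n_perm) {
      if (attempts >= 10L * n_perm)
        stop("too many degenerate label permutations; aborting")
      attempts <- attempts + 1L
      perm <- labels[sample.int(length(labels))]
      s <- tryCatch(stat_from_labels(pre, perm, label_a, label_b),
                    error = function(e) NA_real_)
      if (is.na(s)) next
      out[i] <- s
      i <- i + 1L
    }
    out
  })
  extreme <- switch(sided,
                    two = sum(abs(null) >= abs(observed)),
                    less = sum(null <= observed),
                    greater = sum(null >= observed))
  structure(list(observed = observed, null = null,
                 p_value = (1 + extreme) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, sided = sided),
            class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("Label-randomization test: observed = %.4f, p = %.4g (%s-sided, %d permutations)\n",
              x$observed, x$p_value, x$sided, x$n_perm))
  invisible(x)
}
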