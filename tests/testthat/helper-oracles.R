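# Independent oracles, deliberately naive, against which the package
# implementations are checked.

rand_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Sliding full-length Hamming scan of a spacer over a phage, both strands.
# Returns a data.frame of every position with distance <= max_mismatch.
oracle_hamming_scan <- function(spacer, phage, max_mismatch = 1L) {
  L <- nchar(spacer)
  n <- nchar(phage)
  ph <- utf8ToInt(phage)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "-") holophage::revcomp(spacer) else spacer
    sp <- utf8ToInt(pat)
    if (n >= L) {
      mism <- integer(n - L + 1L)
      for (k in seq_len(L))
        mism <- mism + (ph[seq(k, n - L + k)] != sp[k])
      hit <- which(mism <= max_mismatch)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          start = hit - 1L, strand = strand, mismatches = mism[hit])
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  do.call(rbind, out)
}

# Exhaustive flood oracle for prominence-based maxima. For every plateau
# (connected equal-valued region with no higher neighbour), flood the
# component of {pixels >= value - t} containing it; the plateau is reported
# iff that region holds no strictly higher pixel and no equal-valued
# already-reported plateau (processed in value-descending, index-ascending
# order, so one representative survives per tied group).
oracle_find_maxima <- function(image, t) {
  nr <- nrow(image); nc <- ncol(image)
  lin <- function(r, c) r + (c - 1L) * nr
  neighbours <- function(p) {
    r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        out <- c(out, lin(rr, cc))
    }
    out
  }
  flood <- function(start, keep) {  # BFS over pixels satisfying keep()
    seen <- logical(nr * nc)
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in neighbours(p)) {
        if (!seen[q] && keep(q)) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
    which(seen)
  }
  v <- as.vector(image)
  # plateaus: connected equal-value components with no higher neighbour
  assigned <- logical(nr * nc)
  plateaus <- list()
  for (p in order(-v, seq_along(v))) {
    if (assigned[p]) next
    same <- flood(p, function(q) v[q] == v[p])
    assigned[same] <- TRUE
    if (length(same) == length(v)) next  # constant image: no maxima
    higher <- any(vapply(same, function(q)
      any(v[neighbours(q)] > v[p]), logical(1)))
    if (!higher) plateaus[[length(plateaus) + 1L]] <- list(cells = same,
                                                           value = v[p])
  }
  ord <- order(-vapply(plateaus, `[[`, numeric(1), "value"),
               vapply(plateaus, function(x) min(x$cells), numeric(1)))
  reported_cells <- integer(0)
  reported_vals <- numeric(0)
  res <- list()
  for (pl in plateaus[ord]) {
    region <- flood(pl$cells[1], function(q) v[q] >= pl$value - t)
    if (any(v[region] > pl$value)) next
    eq_rep <- reported_cells[reported_vals == pl$value]
    if (length(eq_rep) && any(eq_rep %in% region)) next
    reported_cells <- c(reported_cells, pl$cells[1])
    reported_vals <- c(reported_vals, pl$value)
    res[[length(res) + 1L]] <- pl$value
  }
  length(res)
}

# Brute-force six-frame ORF enumeration: for every position and strand,
# does an ATG start a maximal ORF (immediately after a stop or a sequence
# start in frame) running to an in-frame stop of protein length >= min_aa?
oracle_orfs <- function(seq, min_aa = 60L) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- nchar(seq)
  count <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "-") holophage::revcomp(seq) else seq
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 1) next
      starts <- frame + (seq_len(ncod) - 1L) * 3L + 1L
      cods <- substring(s, starts, starts + 2L)
      aa <- unname(gc_tab[cods]); aa[is.na(aa)] <- "X"
      i <- 1L
      while (i <= ncod) {
        if (aa[i] == "M") {
          # maximal: no earlier M since the last stop
          j <- i - 1L
          maximal <- TRUE
          while (j >= 1L && aa[j] != "*") {
            if (aa[j] == "M") { maximal <- FALSE; break }
            j <- j - 1L
          }
          if (maximal) {
            k <- i
            while (k <= ncod && aa[k] != "*") k <- k + 1L
            if (k <= ncod && (k - i) >= min_aa) count <- count + 1L
            i <- k
            next
          }
        }
        i <- i + 1L
      }
    }
  }
  count
}

# Brute-force tally for the partition table: loop over phages and niches.
oracle_partition <- function(network) {
  src_levels <- c("sponge", "seawater", "mixed", "unknown")
  niche_levels <- c("sponge_symbiont", "plankton", "other_environment",
                    "other_animal")
  tab <- matrix(0L, length(src_levels), length(niche_levels),
                dimnames = list(src_levels, niche_levels))
  for (i in seq_len(nrow(network$phages))) {
    pid <- network$phages$id[i]
    src <- network$phages$enrichment[i]
    linked_hosts <- network$edges$host_id[network$edges$phage_id == pid]
    niches <- unique(network$hosts$niche[network$hosts$id %in% linked_hosts])
    for (nc in niches) tab[src, nc] <- tab[src, nc] + 1L
  }
  tab
}

# Construct a labelled bipartite network directly from edge and label
# specifications (no sequences), via assemble_network.
make_network <- function(edges, phage_labels, host_niches) {
  links <- data.frame(phage_id = edges$phage_id, host_id = edges$host_id,
                      channel = "crispr", score = 0)
  assemble_network(links,
                   data.frame(id = names(phage_labels),
                              enrichment = unname(phage_labels)),
                   data.frame(id = names(host_niches),
                              niche = unname(host_niches)))
}

# Random null network: edges independent of labels and niches.
random_null_network <- function(n_phages = 24L, n_hosts = 12L,
                                p_edge = 0.2) {
  repeat {
    pid <- sprintf("p%02d", seq_len(n_phages))
    hid <- sprintf("h%02d", seq_len(n_hosts))
    labs <- setNames(sample(c("sponge", "seawater", "mixed"), n_phages,
                            replace = TRUE, prob = c(0.4, 0.4, 0.2)), pid)
    niches <- setNames(sample(c("sponge_symbiont", "plankton"), n_hosts,
                              replace = TRUE), hid)
    em <- which(matrix(runif(n_phages * n_hosts) < p_edge,
                       n_phages, n_hosts), arr.ind = TRUE)
    if (nrow(em) < 4L) next
    net <- make_network(data.frame(phage_id = pid[em[, 1]],
                                   host_id = hid[em[, 2]]), labs, niches)
    ok <- tryCatch({ assortment_statistic(net); TRUE },
                   error = function(e) FALSE)
    if (ok) return(net)
  }
}
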