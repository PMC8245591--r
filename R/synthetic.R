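## Synthetic holobiont community generator. Background sequences are i.i.d.
## uniform nucleotides so matcher false-positive rates stay analytically
## predictable; planted features (CRISPR arrays, prophage segments, shared
## tRNA genes, lifestyle marker ORFs) overwrite background slices, which
## keeps every coordinate stable and recorded in the ground truth.

#' Configuration for a synthetic holobiont community
#'
#' Defines the study conditions under which the full pipeline is exercised:
#' community sizes, per-pair link probabilities for the three evidence
#' channels, feature fidelity (spacer mutations, prophage identity, tRNA
#' identity), environment structure of the abundance table, lifestyle
#' composition, and the RNG seed. All randomness downstream of a fixed
#' config + seed is deterministic.
#'
#' @param n_phages,n_hosts community sizes.
#' @param phage_len_range,host_len_range contig length ranges in bp.
#' @param p_crispr_link,p_prophage_link,p_trna_link per (phage, host) pair
#'   Bernoulli probabilities of planting a link in each channel.
#' @param n_spacers spacers per planted CRISPR array that derive from the
#'   linked phage (arrays are padded with random spacers so that at least
#'   three repeat copies are always present).
#' @param spacer_len,repeat_len spacer and repeat lengths in bp.
#' @param spacer_mutations substitutions planted into each spacer relative
#'   to its protospacer (exact count).
#' @param prophage_length,prophage_identity planted prophage segment length
#'   (bp) and per-base identity to the source phage (substitutions are drawn
#'   i.i.d. at rate \code{1 - prophage_identity}).
#' @param trna_identity identity of the host tRNA copy to the phage copy
#'   (exact substitution count, \code{round((1 - identity) * length)}).
#' @param trna_len_range shared tRNA gene length range in bp.
#' @param environments,samples_per_env abundance table design.
#' @param abundance_fold fold-change of an enriched phage's mean abundance
#'   in its home environment relative to the other environment;
#'   \code{Inf} gives mean zero away from home.
#' @param base_mu mean copy-per-kilobase abundance of a phage in its home
#'   environment.
#' @param dispersion negative-binomial dispersion (\code{size = 1/dispersion});
#'   0 gives Poisson counts.
#' @param p_enrichment named probabilities over phage enrichment classes
#'   (\code{sponge}, \code{seawater}, \code{mixed}).
#' @param p_niche named probabilities over host niche classes
#'   (\code{sponge_symbiont}, \code{plankton}, \code{other_environment},
#'   \code{other_animal}).
#' @param p_temperate probability that a phage is temperate (and receives a
#'   planted integrase-like marker ORF).
#' @param composition_bias GC shift of temperate phage background sequence:
#'   base probabilities become \code{(0.25-d, 0.25+d, 0.25+d, 0.25-d)} for
#'   (A, C, G, T). Drives the composition classifier signal.
#' @param assortative if TRUE, links are only planted between compatible
#'   pairs (sponge-enriched phage with sponge-symbiont host, seawater with
#'   plankton; mixed phages link anywhere), producing a stratified network.
#'   If FALSE (default), link placement is independent of labels (the null).
#' @param seed integer RNG seed.
#' @return a list of class \code{community_config}.
#' @export
community_config <- function(n_phages = 20L, n_hosts = 10L,
                             phage_len_range = c(5000L, 20000L),
                             host_len_range = c(30000L, 60000L),
                             p_crispr_link = 0.15, p_prophage_link = 0.12,
                             p_trna_link = 0.12,
                             n_spacers = 3L, spacer_len = 32L,
                             repeat_len = 30L, spacer_mutations = 0L,
                             prophage_length = 2000L, prophage_identity = 1.0,
                             trna_identity = 1.0, trna_len_range = c(70L, 90L),
                             environments = c("sponge", "seawater"),
                             samples_per_env = 6L,
                             abundance_fold = 8, base_mu = 20,
                             dispersion = 0.2,
                             p_enrichment = c(sponge = 0.4, seawater = 0.3,
                                              mixed = 0.3),
                             p_niche = c(sponge_symbiont = 0.4, plankton = 0.3,
                                         other_environment = 0.2,
                                         other_animal = 0.1),
                             p_temperate = 0.4, composition_bias = 0.05,
                             assortative = FALSE, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_crispr_link, p_prophage_link, p_trna_link, p_temperate,
             p_enrichment, p_niche)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(phage_len_range <= 0) || any(host_len_range <= 0))
    stop("length ranges must be positive")
  if (prophage_length < 1000L)
    stop("prophage_length must be at least 1 kb")
  if (prophage_length > phage_len_range[1])
    stop("prophage_length exceeds the minimum phage length: cannot fit")
  array_len <- (max(n_spacers + 1L, 3L)) * repeat_len +
    (max(n_spacers + 1L, 3L) - 1L) * spacer_len
  if (array_len + prophage_length + max(trna_len_range) > host_len_range[1])
    stop("planted features cannot fit in the smallest host contig")
  if (prophage_identity <= 0 || prophage_identity > 1)
    stop("prophage_identity must lie in (0, 1]")
  class(cfg) <- "community_config"
  cfg
}

## ---- individual planting operations -------------------------------------

#' Plant a CRISPR repeat-spacer array on a host contig
#'
#' Writes a repeat-spacer-...-repeat structure (at least 3 repeat copies)
#' into the host sequence at a free random position. \code{n_spacers}
#' spacers are substrings of the phage (random position and strand), each
#' mutated at exactly \code{mutations_per_spacer} positions; extra random
#' spacers pad the array when needed to reach 3 repeats.
#'
#' @param host,phage character DNA sequences.
#' @param n_spacers phage-derived spacers to plant.
#' @param mutations_per_spacer exact substitution count per spacer.
#' @param spacer_len,repeat_len lengths in bp.
#' @param occupied data.frame of 0-based half-open intervals already used on
#'   the host (rejection sampling avoids them).
#' @return list with the modified \code{seq}, the planted array interval
#'   (\code{start}, \code{end}, 0-based half-open), \code{repeat_unit}, and a
#'   \code{protospacers} data.frame (phage coordinates, strand, spacer
#'   sequence as planted).
#' @export
plant_crispr_array <- function(host, phage, n_spacers = 3L,
                               mutations_per_spacer = 0L,
                               spacer_len = 32L, repeat_len = 30L,
                               occupied = empty_intervals()) {
  stopifnot(n_spacers >= 1L, mutations_per_spacer >= 0L)
  if (nchar(phage) < spacer_len) stop("phage shorter than a spacer")
  n_rep <- max(n_spacers + 1L, 3L)
  n_pad <- n_rep - 1L - n_spacers
  repeat_unit <- random_dna(repeat_len)
  proto <- data.frame(phage_start = integer(0), phage_end = integer(0),
                      strand = character(0), spacer = character(0))
  spacers <- character(0)
  for (i in seq_len(n_spacers)) {
    s <- sample.int(nchar(phage) - spacer_len + 1L, 1L) - 1L
    seqi <- slice0(phage, s, s + spacer_len)
    strand <- sample(c("+", "-"), 1L)
    sp <- if (strand == "-") revcomp(seqi) else seqi
    sp <- mutate_exact(sp, mutations_per_spacer)
    proto <- rbind(proto, data.frame(phage_start = s,
                                     phage_end = s + spacer_len,
                                     strand = strand, spacer = sp))
    spacers <- c(spacers, sp)
  }
  if (n_pad > 0L) spacers <- c(spacers, replicate(n_pad, random_dna(spacer_len)))
  array_seq <- paste0(paste0(repeat_unit, spacers, collapse = ""), repeat_unit)
  start <- sample_free_start(nchar(host), nchar(array_seq), occupied)
  list(seq = overwrite_at(host, start, array_seq),
       start = start, end = start + nchar(array_seq),
       repeat_unit = repeat_unit, n_repeats = n_rep,
       protospacers = proto)
}

#' Plant an integrated prophage segment on a host contig
#'
#' Copies a random slice of the phage into the host at a free position on a
#' random strand, substituting each base independently at rate
#' \code{1 - identity}.
#'
#' @inheritParams plant_crispr_array
#' @param identity target per-base identity in (0, 1].
#' @param length segment length in bp (>= 1 kb, <= phage length).
#' @return list with modified \code{seq}, host interval, phage source
#'   interval, and \code{strand}.
#' @export
plant_prophage <- function(host, phage, identity = 1.0, length = 2000L,
                           occupied = empty_intervals()) {
  stopifnot(identity > 0, identity <= 1)
  if (length < 1000L) stop("prophage segments must be at least 1 kb")
  if (length > nchar(phage)) stop("prophage length exceeds phage length")
  src <- sample.int(nchar(phage) - length + 1L, 1L) - 1L
  seg <- slice0(phage, src, src + length)
  seg <- mutate_iid(seg, 1 - identity)
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") seg <- revcomp(seg)
  start <- sample_free_start(nchar(host), length, occupied)
  list(seq = overwrite_at(host, start, seg),
       start = start, end = start + length,
       phage_start = src, phage_end = src + length, strand = strand)
}

#' Plant a shared tRNA gene on a phage and a host contig
#'
#' Writes a random 70-90 bp gene into the phage (exact) and into the host
#' (mutated at \code{round((1 - identity) * length)} positions), each at a
#' free random position and strand, and returns 1-based GFF3-style records
#' for both copies.
#'
#' @inheritParams plant_prophage
#' @param len_range tRNA gene length range in bp.
#' @param occupied_host,occupied_phage interval data.frames to avoid.
#' @return list with modified \code{phage_seq} and \code{host_seq}, the gene
#'   sequences, coordinates and strands of both copies, and \code{gff} rows.
#' @export
plant_trna <- function(host, phage, identity = 1.0,
                       len_range = c(70L, 90L),
                       occupied_host = empty_intervals(),
                       occupied_phage = empty_intervals()) {
  stopifnot(identity > 0, identity <= 1)
  len <- sample(seq(len_range[1], len_range[2]), 1L)
  gene <- random_dna(len)
  host_gene <- mutate_exact(gene, round((1 - identity) * len))
  p_start <- sample_free_start(nchar(phage), len, occupied_phage)
  h_start <- sample_free_start(nchar(host), len, occupied_host)
  p_strand <- sample(c("+", "-"), 1L)
  h_strand <- sample(c("+", "-"), 1L)
  p_ins <- if (p_strand == "-") revcomp(gene) else gene
  h_ins <- if (h_strand == "-") revcomp(host_gene) else host_gene
  list(phage_seq = overwrite_at(phage, p_start, p_ins),
       host_seq = overwrite_at(host, h_start, h_ins),
       gene = gene, host_gene = host_gene,
       phage_start = p_start, phage_end = p_start + len, phage_strand = p_strand,
       host_start = h_start, host_end = h_start + len, host_strand = h_strand)
}

## Back-translate an amino-acid string with uniformly random synonymous
## codons (standard genetic code, stops excluded).
back_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  tab <- split(names(gc), unname(gc))
  res <- vapply(strsplit(aa, "", fixed = TRUE)[[1]], function(r) {
    cods <- tab[[r]]
    if (is.null(cods)) stop("cannot back-translate residue: ", r)
    sample(cods, 1L)
  }, character(1))
  paste(res, collapse = "")
}

#' Plant a marker ORF (back-translated protein exemplar) on a phage
#'
#' Builds a cassette \code{TAA + ATG + codons + TAA}; the leading in-frame
#' stop guarantees that the maximal ORF starts exactly at the planted ATG.
#' The cassette is written at a free random position on a random strand.
#'
#' @param phage character DNA sequence.
#' @param marker_aa amino-acid string (no stops).
#' @param occupied intervals to avoid.
#' @return list with modified \code{seq}, the ORF interval on the forward
#'   strand (0-based half-open, ATG through stop codon), cassette interval,
#'   and \code{strand}.
#' @export
plant_marker_orf <- function(phage, marker_aa, occupied = empty_intervals()) {
  orf <- paste0("ATG", back_translate(marker_aa), "TAA")
  cassette <- paste0("TAA", orf)
  strand <- sample(c("+", "-"), 1L)
  ins <- if (strand == "-") revcomp(cassette) else cassette
  start <- sample_free_start(nchar(phage), nchar(cassette), occupied)
  L <- nchar(cassette)
  if (strand == "+") {
    orf_start <- start + 3L; orf_end <- start + L
  } else {
    orf_start <- start; orf_end <- start + L - 3L
  }
  list(seq = overwrite_at(phage, start, ins),
       start = start, end = start + L,
       orf_start = orf_start, orf_end = orf_end, strand = strand)
}

empty_intervals <- function() data.frame(start = integer(0), end = integer(0))

add_interval <- function(occ, start, end) rbind(occ, data.frame(start = start, end = end))

## ---- abundance and images -----------------------------------------------

#' Simulate an environment-structured phage abundance table
#'
#' Per-sample read counts are negative binomial around environment-specific
#' means: a phage has mean \code{base_mu * length/1000} copies in its home
#' environment and \code{base_mu/fold * length/1000} elsewhere (mixed phages
#' have the home mean everywhere). \code{fold = Inf} gives mean zero away
#' from home.
#'
#' @param phage_meta data.frame with \code{id}, \code{length},
#'   \code{enrichment} columns.
#' @param environments,samples_per_env sampling design.
#' @param fold,base_mu,dispersion noise model parameters (see
#'   [community_config()]).
#' @param seed optional seed; if NULL the current RNG state is used.
#' @return list with \code{counts} (matrix, phages x samples) and
#'   \code{sample_env} (named character vector).
#' @export
simulate_abundance <- function(phage_meta,
                               environments = c("sponge", "seawater"),
                               samples_per_env = 6L, fold = 8,
                               base_mu = 20, dispersion = 0.2, seed = NULL) {
  run <- function() {
    envs <- rep(environments, each = samples_per_env)
    samples <- paste0(rep(environments, each = samples_per_env), "_s",
                      rep(seq_len(samples_per_env), length(environments)))
    names(envs) <- samples
    n <- nrow(phage_meta)
    counts <- matrix(0L, nrow = n, ncol = length(samples),
                     dimnames = list(phage_meta$id, samples))
    for (i in seq_len(n)) {
      len_kb <- phage_meta$length[i] / 1000
      enr <- phage_meta$enrichment[i]
      for (j in seq_along(samples)) {
        home <- enr == "mixed" || enr == envs[j]
        mu <- if (home) base_mu * len_kb
              else if (is.infinite(fold)) 0 else base_mu / fold * len_kb
        counts[i, j] <- if (mu == 0) 0L
                        else if (dispersion <= 0) stats::rpois(1L, mu)
                        else rnbinom(1L, mu = mu, size = 1 / dispersion)
      }
    }
    list(counts = counts, sample_env = envs)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Synthesize a fluorescence spot image
#'
#' Sum of isotropic Gaussian spots over a constant background with i.i.d.
#' Gaussian noise, clipped to a non-negative integer grid. Coordinates use
#' x = column, y = row.
#'
#' @param spot_centers matrix or data.frame with columns x, y (may be empty).
#' @param dim image dimensions c(rows, cols).
#' @param amplitude peak height of each spot above background.
#' @param psf_sigma Gaussian spot width in pixels.
#' @param noise_sd Gaussian noise standard deviation.
#' @param background constant background level.
#' @param seed optional RNG seed.
#' @return numeric matrix (integer-valued).
#' @export
synth_image <- function(spot_centers, dim = c(64L, 64L), amplitude = 100,
                        psf_sigma = 2, noise_sd = 0, background = 10,
                        seed = NULL) {
  run <- function() {
    img <- matrix(background, nrow = dim[1], ncol = dim[2])
    sc <- as.matrix(spot_centers)
    if (length(sc) > 0) {
      rows <- matrix(seq_len(dim[1]), nrow = dim[1], ncol = dim[2])
      cols <- matrix(seq_len(dim[2]), nrow = dim[1], ncol = dim[2], byrow = TRUE)
      for (i in seq_len(nrow(sc))) {
        d2 <- (rows - sc[i, 2])^2 + (cols - sc[i, 1])^2
        img <- img + amplitude * exp(-d2 / (2 * psf_sigma^2))
      }
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    matrix(pmax(0, round(img)), nrow = dim[1])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- full community -----------------------------------------------------

#' Load the bundled synthetic marker exemplars
#'
#' Returns the packaged integrase-like and excisionase-like amino-acid
#' exemplars. These are synthetic stand-in sequences (fixed random
#' proteins), not real enzyme sequences; planted marker ORFs are
#' back-translations of the first exemplar so detection against this set
#' recovers them at ~100% identity.
#'
#' @return named character vector of amino-acid sequences.
#' @export
marker_exemplars <- function() {
  path <- system.file("extdata", "markers_synthetic.faa", package = "holophage")
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub(" .*", "", names(aa)))
}

#' Generate a synthetic holobiont community with planted ground truth
#'
#' Creates random phage and host contigs; assigns phage enrichment and
#' lifestyle labels and host niche labels; plants marker ORFs on temperate
#' phages; draws per-pair Bernoulli link indicators for the three evidence
#' channels and plants the supporting features (tRNA genes first, so that
#' spacers and prophage segments are sliced from final phage sequences);
#' and simulates the abundance table. Everything is deterministic under the
#' config seed.
#'
#' @param config a [community_config()].
#' @return object of class \code{holobiont_community}: list with
#'   \code{phages}, \code{hosts} (named character vectors), \code{phage_meta},
#'   \code{host_meta}, \code{truth} (links, features, protospacers),
#'   \code{trna_gff} (1-based GFF3-style data.frames for phages and hosts),
#'   \code{abundance}, \code{sample_env}, and the \code{config}.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, generate_community_impl(config))
}

generate_community_impl <- function(cfg) {
  phage_ids <- sprintf("phage_%03d", seq_len(cfg$n_phages))
  host_ids <- sprintf("host_%03d", seq_len(cfg$n_hosts))

  enrich <- sample(names(cfg$p_enrichment), cfg$n_phages, replace = TRUE,
                   prob = cfg$p_enrichment)
  lifestyle <- ifelse(runif(cfg$n_phages) < cfg$p_temperate,
                      "temperate", "lytic")
  niche <- sample(names(cfg$p_niche), cfg$n_hosts, replace = TRUE,
                  prob = cfg$p_niche)

  d <- cfg$composition_bias
  plens <- sample(seq(cfg$phage_len_range[1], cfg$phage_len_range[2]),
                  cfg$n_phages, replace = TRUE)
  hlens <- sample(seq(cfg$host_len_range[1], cfg$host_len_range[2]),
                  cfg$n_hosts, replace = TRUE)
  phages <- vapply(seq_len(cfg$n_phages), function(i) {
    probs <- if (lifestyle[i] == "temperate")
      c(0.25 - d, 0.25 + d, 0.25 + d, 0.25 - d) else rep(0.25, 4)
    random_dna(plens[i], probs)
  }, character(1))
  names(phages) <- phage_ids
  hosts <- vapply(hlens, random_dna, character(1))
  names(hosts) <- host_ids

  occ_p <- setNames(replicate(cfg$n_phages, empty_intervals(), simplify = FALSE),
                    phage_ids)
  occ_h <- setNames(replicate(cfg$n_hosts, empty_intervals(), simplify = FALSE),
                    host_ids)
  features <- list()
  protospacers <- list()
  trna_gff_p <- list()
  trna_gff_h <- list()

  ## Marker ORFs on temperate phages.
  markers <- marker_exemplars()
  for (i in seq_len(cfg$n_phages)) {
    if (lifestyle[i] == "temperate") {
      pl <- plant_marker_orf(phages[i], markers[["integrase_like_synthetic"]],
                             occ_p[[i]])
      phages[i] <- pl$seq
      occ_p[[i]] <- add_interval(occ_p[[i]], pl$start, pl$end)
      features[[length(features) + 1L]] <- data.frame(
        contig = phage_ids[i], type = "marker_orf",
        start = pl$orf_start, end = pl$orf_end, strand = pl$strand,
        partner = NA_character_)
    }
  }

  ## Per-pair link indicators: one fixed-order uniform draw per channel,
  ## under a seed derived from the config seed so the draws can be replayed
  ## independently for verification.
  u <- with_seed(derive_seed(cfg$seed, "links"),
                 array(runif(cfg$n_phages * cfg$n_hosts * 3L),
                       dim = c(cfg$n_phages, cfg$n_hosts, 3L)))
  compatible <- function(i, j) {
    if (!cfg$assortative) return(TRUE)
    (enrich[i] == "sponge" && niche[j] == "sponge_symbiont") ||
      (enrich[i] == "seawater" && niche[j] == "plankton") ||
      enrich[i] == "mixed"
  }
  link_crispr <- link_proph <- link_trna <-
    matrix(FALSE, cfg$n_phages, cfg$n_hosts)
  for (i in seq_len(cfg$n_phages)) for (j in seq_len(cfg$n_hosts)) {
    if (!compatible(i, j)) next
    link_crispr[i, j] <- u[i, j, 1L] < cfg$p_crispr_link
    link_proph[i, j] <- u[i, j, 2L] < cfg$p_prophage_link
    link_trna[i, j] <- u[i, j, 3L] < cfg$p_trna_link
  }

  links <- list()
  push_link <- function(i, j, channel) {
    links[[length(links) + 1L]] <<- data.frame(
      phage_id = phage_ids[i], host_id = host_ids[j], channel = channel)
  }

  ## tRNA links first: they modify phage sequences.
  for (i in seq_len(cfg$n_phages)) for (j in seq_len(cfg$n_hosts)) {
    if (!link_trna[i, j]) next
    pl <- plant_trna(hosts[j], phages[i], identity = cfg$trna_identity,
                     len_range = cfg$trna_len_range,
                     occupied_host = occ_h[[j]], occupied_phage = occ_p[[i]])
    phages[i] <- pl$phage_seq
    hosts[j] <- pl$host_seq
    occ_p[[i]] <- add_interval(occ_p[[i]], pl$phage_start, pl$phage_end)
    occ_h[[j]] <- add_interval(occ_h[[j]], pl$host_start, pl$host_end)
    gid <- sprintf("trna_%s_%s", phage_ids[i], host_ids[j])
    trna_gff_p[[length(trna_gff_p) + 1L]] <- data.frame(
      seqid = phage_ids[i], source = "holophage", type = "tRNA",
      start = pl$phage_start + 1L, end = pl$phage_end, score = ".",
      strand = pl$phage_strand, attributes = paste0("ID=", gid, "_p"))
    trna_gff_h[[length(trna_gff_h) + 1L]] <- data.frame(
      seqid = host_ids[j], source = "holophage", type = "tRNA",
      start = pl$host_start + 1L, end = pl$host_end, score = ".",
      strand = pl$host_strand, attributes = paste0("ID=", gid, "_h"))
    features[[length(features) + 1L]] <- data.frame(
      contig = host_ids[j], type = "trna", start = pl$host_start,
      end = pl$host_end, strand = pl$host_strand, partner = phage_ids[i])
    push_link(i, j, "trna")
  }

  ## CRISPR arrays and prophage segments read the final phage sequences.
  for (i in seq_len(cfg$n_phages)) for (j in seq_len(cfg$n_hosts)) {
    if (link_crispr[i, j]) {
      pl <- plant_crispr_array(hosts[j], phages[i],
                               n_spacers = cfg$n_spacers,
                               mutations_per_spacer = cfg$spacer_mutations,
                               spacer_len = cfg$spacer_len,
                               repeat_len = cfg$repeat_len,
                               occupied = occ_h[[j]])
      hosts[j] <- pl$seq
      occ_h[[j]] <- add_interval(occ_h[[j]], pl$start, pl$end)
      features[[length(features) + 1L]] <- data.frame(
        contig = host_ids[j], type = "crispr_array", start = pl$start,
        end = pl$end, strand = "+", partner = phage_ids[i])
      protospacers[[length(protospacers) + 1L]] <- cbind(
        data.frame(phage_id = phage_ids[i], host_id = host_ids[j]),
        pl$protospacers)
      push_link(i, j, "crispr")
    }
    if (link_proph[i, j]) {
      pl <- plant_prophage(hosts[j], phages[i],
                           identity = cfg$prophage_identity,
                           length = cfg$prophage_length,
                           occupied = occ_h[[j]])
      hosts[j] <- pl$seq
      occ_h[[j]] <- add_interval(occ_h[[j]], pl$start, pl$end)
      features[[length(features) + 1L]] <- data.frame(
        contig = host_ids[j], type = "prophage", start = pl$start,
        end = pl$end, strand = pl$strand, partner = phage_ids[i])
      push_link(i, j, "prophage")
    }
  }

  phage_meta <- data.frame(id = phage_ids, length = nchar(phages),
                           enrichment = enrich, lifestyle = lifestyle,
                           row.names = NULL)
  host_meta <- data.frame(id = host_ids, length = nchar(hosts),
                          niche = niche, row.names = NULL)

  ab <- simulate_abundance(phage_meta, environments = cfg$environments,
                           samples_per_env = cfg$samples_per_env,
                           fold = cfg$abundance_fold, base_mu = cfg$base_mu,
                           dispersion = cfg$dispersion)

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  link_df <- bind(links, data.frame(phage_id = character(0),
                                    host_id = character(0),
                                    channel = character(0)))
  ## truth link channel names match the evidence channel names downstream
  link_df$channel[link_df$channel == "prophage"] <- "homology"

  structure(list(
    phages = phages, hosts = hosts,
    phage_meta = phage_meta, host_meta = host_meta,
    truth = list(
      links = link_df,
      features = bind(features, data.frame(contig = character(0),
                                           type = character(0),
                                           start = integer(0), end = integer(0),
                                           strand = character(0),
                                           partner = character(0))),
      protospacers = bind(protospacers, NULL)),
    trna_gff = list(phage = bind(trna_gff_p, NULL), host = bind(trna_gff_h, NULL)),
    abundance = ab$counts, sample_env = ab$sample_env,
    config = cfg), class = "holobiont_community")
}

#' @export
print.holobiont_community <- function(x, ...) {
  cat("Synthetic holobiont community\n")
  cat(sprintf("  %d phages (%d temperate), %d hosts\n",
              length(x$phages),
              sum(x$phage_meta$lifestyle == "temperate"),
              length(x$hosts)))
  tab <- table(x$truth$links$channel)
  cat("  planted links:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  abundance: %d samples across %s\n",
              ncol(x$abundance),
              paste(unique(x$sample_env), collapse = "/")))
  invisible(x)
}

#' Write a community to disk in standard formats
#'
#' FASTA for phage and host contigs, GFF3 for tRNA annotations, TSV for the
#' abundance table and sample metadata, and JSON for the ground truth.
#'
#' @param community a \code{holobiont_community}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(community$phages),
                              p("phages.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(community$hosts),
                              p("hosts.fasta"))
  write_trna_gff3(community$trna_gff$phage, p("phage_trna.gff3"))
  write_trna_gff3(community$trna_gff$host, p("host_trna.gff3"))
  ab <- data.frame(contig = rownames(community$abundance),
                   community$abundance, check.names = FALSE)
  utils::write.table(ab, p("abundance.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(community$sample_env),
                                environment = unname(community$sample_env)),
                     p("sample_env.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(community$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(vapply(c("phages.fasta", "hosts.fasta", "phage_trna.gff3",
                     "host_trna.gff3", "abundance.tsv", "sample_env.tsv",
                     "truth.json"), p, character(1)))
}
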