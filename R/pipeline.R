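## End-to-end orchestration: simulate -> predict (three channels) ->
## network + stratification test -> lifestyle -> report, with per-stage
## seeds derived deterministically from one global seed.

#' Run the full synthetic-community pipeline
#'
#' Generates (or accepts) a synthetic holobiont community, runs the three
#' host-prediction channels, assembles the infection network, labels phage
#' enrichment from abundance, tabulates environmental partitioning, runs
#' the label-randomization stratification test, calls lifestyles, computes
#' temperate:lytic ratios, and scores each channel against the planted
#' ground truth.
#'
#' @param config a [community_config()]; its seed drives every stage
#'   through stage-specific derived seeds.
#' @param community optionally a pre-built \code{holobiont_community}
#'   (config is then only used for analysis parameters).
#' @param n_perm permutations for the stratification test.
#' @param out_dir optional directory; when given, per-stage artifacts
#'   (FASTA/GFF3/TSV inputs, channel link tables, network edge list,
#'   report JSON) are written there.
#' @param max_mismatch,min_identity_homology,min_span,trna_min_identity
#'   channel acceptance parameters (defaults as documented per channel).
#' @param enrichment_fold fold threshold for [label_enrichment()].
#' @param conf_threshold classifier confidence for [call_lifestyles()].
#' @return a \code{pipeline_report} list; see Details.
#' @details The report contains \code{links} (per-channel counts),
#'   \code{channel_scores} (precision/recall per channel against truth),
#'   \code{enrichment_accuracy}, \code{partition} (the source x niche
#'   table), \code{stratification} (observed statistic and p value),
#'   \code{lifestyle} (call tallies, marker sensitivity),
#'   \code{tl} (per-environment temperate:lytic Cpk ratios and the contig
#'   count ratio), and the \code{seed}.
#' @export
run_pipeline <- function(config = community_config(), community = NULL,
                         n_perm = 1000L, out_dir = NULL,
                         max_mismatch = 1L, min_identity_homology = 0.80,
                         min_span = 1000L, trna_min_identity = 0.95,
                         enrichment_fold = 2.0, conf_threshold = 0.6) {
  if (is.null(community)) community <- generate_community(config)
  cm <- community

  ## --- channel 1: CRISPR
  arrays <- unlist(lapply(names(cm$hosts), function(hid)
    detect_arrays(cm$hosts[[hid]], host_id = hid)), recursive = FALSE)
  crispr <- match_spacers(arrays, cm$phages, max_mismatch = max_mismatch)

  ## --- channel 2: prophage homology
  alns <- align_prophages(cm$phages, cm$hosts)
  homology <- filter_prophage_hits(alns, cm$hosts,
                                   min_identity = min_identity_homology,
                                   min_span = min_span)

  ## --- channel 3: shared tRNAs
  ptr <- extract_trnas(cm$phages, gff_from_df(cm$trna_gff$phage))
  htr <- extract_trnas(cm$hosts, gff_from_df(cm$trna_gff$host))
  trna <- match_trnas(ptr, htr, min_identity = trna_min_identity)

  shared <- c("phage_id", "host_id", "channel", "score")
  links <- rbind(crispr$links[, shared], homology$links[, shared],
                 trna$links[, shared])

  ## --- enrichment labels and network
  labels <- label_enrichment(cm$abundance,
                             setNames(cm$phage_meta$length, cm$phage_meta$id),
                             cm$sample_env, fold = enrichment_fold)
  phage_meta <- cm$phage_meta
  phage_meta$enrichment <- unname(labels[phage_meta$id])
  net <- assemble_network(links, phage_meta, cm$host_meta)
  part <- partition_table(net)

  strat <- tryCatch(
    permutation_test(net, n_perm = n_perm,
                     seed = derive_seed(cm$config$seed, "permutation")),
    error = function(e) list(observed = NA_real_, p_value = NA_real_,
                             n_perm = n_perm, error = conditionMessage(e)))

  ## --- lifestyle: markers + classifier trained on labelled references
  ## built under the planted composition bias
  cls <- with_seed(derive_seed(cm$config$seed, "classifier"),
                   make_reference_classifier(cm$config))
  calls <- call_lifestyles(cm$phages, classifier = cls,
                           conf_threshold = conf_threshold)
  tl <- tl_ratio(calls, cm$abundance,
                 setNames(cm$phage_meta$length, cm$phage_meta$id),
                 cm$sample_env)

  ## --- scoring against truth
  channel_scores <- do.call(rbind, lapply(
    c("crispr", "homology", "trna"), function(ch)
      score_channel(links, cm$truth$links, ch)))
  truth_enr <- setNames(cm$phage_meta$enrichment, cm$phage_meta$id)
  enr_acc <- mean(labels[names(truth_enr)] == truth_enr)
  truth_ls <- setNames(cm$phage_meta$lifestyle, cm$phage_meta$id)
  marker_sens <- {
    temp <- names(truth_ls)[truth_ls == "temperate"]
    called <- setNames(calls$call, calls$phage_id)
    if (length(temp)) mean(called[temp] == "temperate") else NA_real_
  }

  report <- structure(list(
    seed = cm$config$seed,
    links = list(crispr = nrow(crispr$links),
                 homology = nrow(homology$links),
                 trna = nrow(trna$links),
                 total_pairs = nrow(net$edges)),
    channel_scores = channel_scores,
    enrichment_accuracy = enr_acc,
    partition = part,
    stratification = list(observed = strat$observed,
                          p_value = strat$p_value, n_perm = strat$n_perm),
    lifestyle = list(calls = as.list(table(calls$call)),
                     marker_sensitivity = marker_sens),
    tl = list(per_env = tl$per_env, count_ratio = tl$count_ratio,
              n_temperate = tl$n_temperate, n_lytic = tl$n_lytic)),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_community(cm, file.path(out_dir, "community"))
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(crispr$hits, "crispr_hits.tsv")
    wt(homology$alignments, "prophage_alignments.tsv")
    wt(trna$matches, "trna_matches.tsv")
    wt(net$edges, "network_edges.tsv")
    wt(calls, "lifestyle_calls.tsv")
    jsonlite::write_json(unclass_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

## Convert stored GFF3-style rows (already 1-based) into the annotation
## data.frame extract_trnas() expects.
gff_from_df <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      type = character(0), id = character(0)))
  }
  data.frame(seqid = df$seqid, start = df$start, end = df$end,
             strand = df$strand, type = df$type,
             id = sub("^ID=", "", df$attributes))
}

## Precision/recall of one channel's predicted (phage, host) pairs against
## the planted truth links of that channel.
score_channel <- function(pred_links, truth_links, channel) {
  pred <- unique(paste(pred_links$phage_id[pred_links$channel == channel],
                       pred_links$host_id[pred_links$channel == channel]))
  truth <- unique(paste(truth_links$phage_id[truth_links$channel == channel],
                        truth_links$host_id[truth_links$channel == channel]))
  tp <- length(intersect(pred, truth))
  data.frame(channel = channel,
             n_pred = length(pred), n_truth = length(truth), tp = tp,
             precision = if (length(pred)) tp / length(pred) else NA_real_,
             recall = if (length(truth)) tp / length(truth) else NA_real_)
}

## Labelled reference sequences for the composition classifier, generated
## under the same composition-bias model as the community phages.
make_reference_classifier <- function(cfg, n_per_class = 15L, len = 8000L,
                                      k = 5L) {
  d <- cfg$composition_bias
  temp <- replicate(n_per_class,
                    random_dna(len, c(0.25 - d, 0.25 + d, 0.25 + d, 0.25 - d)))
  lyt <- replicate(n_per_class, random_dna(len))
  refs <- c(temp, lyt)
  names(refs) <- c(sprintf("ref_temperate_%02d", seq_len(n_per_class)),
                   sprintf("ref_lytic_%02d", seq_len(n_per_class)))
  composition_classifier(refs,
                         rep(c("temperate", "lytic"), each = n_per_class),
                         k = k)
}

unclass_report <- function(r) {
  r <- unclass(r)
  r$partition <- as.data.frame(as.table(r$partition))
  names(r$partition) <- c("phage_source", "host_niche", "count")
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  links: crispr=%d homology=%d trna=%d (pairs=%d)\n",
              x$links$crispr, x$links$homology, x$links$trna,
              x$links$total_pairs))
  print(x$channel_scores, row.names = FALSE)
  cat(sprintf("  enrichment label accuracy: %.3f\n", x$enrichment_accuracy))
  cat(sprintf("  stratification: observed=%.4f p=%.4g (n_perm=%d)\n",
              x$stratification$observed, x$stratification$p_value,
              x$stratification$n_perm))
  cat(sprintf("  lifestyle: %s; marker sensitivity %.3f\n",
              paste(sprintf("%s=%d", names(x$lifestyle$calls),
                            unlist(x$lifestyle$calls)), collapse = " "),
              x$lifestyle$marker_sensitivity))
  cat(sprintf("  temperate:lytic count ratio: %.3f (%d/%d)\n",
              x$tl$count_ratio, x$tl$n_temperate, x$tl$n_lytic))
  invisible(x)
}
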