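# CRISPR channel: array detection on constructed and planted arrays,
# spacer matching against the sliding Hamming oracle, mismatch rules.

test_that("a constructed repeat-spacer-repeat contig is detected exactly", {
  set.seed(21)
  rep_unit <- rand_dna(30)
  s1 <- rand_dna(30); s2 <- rand_dna(30)
  # flanks chosen to differ from the repeat ends so boundaries are
  # identifiable
  left <- rand_dna(200); right <- rand_dna(200)
  contig <- paste0(left, rep_unit, s1, rep_unit, s2, rep_unit, right)
  arrs <- detect_arrays(contig, host_id = "c1")
  expect_length(arrs, 1L)
  a <- arrs[[1]]
  expect_identical(a$repeat_consensus, rep_unit)
  expect_identical(nrow(a$spacers), 2L)
  expect_identical(a$start, 200L)
  expect_identical(a$end, 200L + 3L * 30L + 2L * 30L)
  expect_identical(a$spacers$seq, c(s1, s2))
})

test_that("two repeat copies are not an array", {
  set.seed(22)
  rep_unit <- rand_dna(30)
  contig <- paste0(rand_dna(300), rep_unit, rand_dna(32), rep_unit,
                   rand_dna(300))
  expect_length(detect_arrays(contig, host_id = "c1"), 0L)
})

test_that("planted arrays are recovered exactly at mutation level zero", {
  set.seed(23)
  hits <- 0L
  for (i in 1:10) {
    host <- rand_dna(4000)
    phage <- rand_dna(8000)
    pl <- plant_crispr_array(host, phage, n_spacers = 3L)
    arrs <- detect_arrays(pl$seq, host_id = "h")
    expect_length(arrs, 1L)
    # exact recovery unless a flanking base coincides across all copies
    # (an intrinsic identifiability limit); tolerate at most 1 bp per side
    expect_lte(abs(arrs[[1]]$start - pl$start), 1L)
    expect_lte(abs(arrs[[1]]$end - pl$end), 1L)
    hits <- hits + (arrs[[1]]$start == pl$start && arrs[[1]]$end == pl$end)
    expect_identical(nrow(arrs[[1]]$spacers), 3L)
  }
  expect_gte(hits, 8L)
})

test_that("random contigs without planted arrays yield no arrays", {
  set.seed(24)
  for (i in 1:20) expect_length(detect_arrays(rand_dna(3000), "h"), 0L)
})

test_that("spacer matching equals the sliding Hamming oracle", {
  set.seed(25)
  for (i in 1:10) {
    phage <- rand_dna(5000)
    spacer <- if (i <= 5) rand_dna(32) else {
      # ensure some true hits: embed the spacer with 0-2 mutations
      s <- substr(phage, 1001, 1032)
      holophage:::mutate_exact(s, i %% 3)
    }
    arr <- list(host_contig_id = "h", repeat_consensus = "",
                repeats = data.frame(start = integer(0), end = integer(0)),
                spacers = data.frame(start = 0L, end = 32L, seq = spacer),
                strand = "+", start = 0L, end = 0L)
    got <- match_spacers(list(arr), c(ph = phage), max_mismatch = 1L)$hits
    want <- oracle_hamming_scan(spacer, phage, 1L)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      og <- order(got$phage_start, got$strand)
      ow <- order(want$start, want$strand)
      expect_identical(got$phage_start[og], want$start[ow])
      expect_identical(got$mismatches[og], as.integer(want$mismatches[ow]))
    }
  }
})

test_that("two spacer mutations break matching at one allowed mismatch", {
  set.seed(26)
  phage <- rand_dna(6000)
  host <- rand_dna(3000)
  pl <- plant_crispr_array(host, phage, n_spacers = 3L,
                           mutations_per_spacer = 2L)
  arrs <- detect_arrays(pl$seq, host_id = "h")
  expect_length(arrs, 1L)
  res <- match_spacers(arrs, c(ph = phage), max_mismatch = 1L)
  expect_identical(nrow(res$links), 0L)
  # and they reappear when two mismatches are allowed
  res2 <- match_spacers(arrs, c(ph = phage), max_mismatch = 2L)
  expect_identical(nrow(res2$links), 1L)
})

test_that("zero-mismatch hits are a subset of one-mismatch hits", {
  set.seed(27)
  phage <- rand_dna(4000)
  spacer <- holophage:::mutate_exact(substr(phage, 501, 532), 1)
  arr <- list(host_contig_id = "h",
              spacers = data.frame(start = 0L, end = 32L, seq = spacer))
  h0 <- match_spacers(list(arr), c(ph = phage), max_mismatch = 0L)$hits
  h1 <- match_spacers(list(arr), c(ph = phage), max_mismatch = 1L)$hits
  key <- function(h) paste(h$phage_start, h$strand)
  expect_true(all(key(h0) %in% key(h1)))
  expect_gt(nrow(h1), nrow(h0))
})

test_that("reverse-complementing a phage preserves linked pairs", {
  set.seed(28)
  phage <- rand_dna(5000)
  host <- rand_dna(3000)
  pl <- plant_crispr_array(host, phage, n_spacers = 3L)
  arrs <- detect_arrays(pl$seq, host_id = "h")
  fwd <- match_spacers(arrs, c(ph = phage))
  rev <- match_spacers(arrs, c(ph = revcomp(phage)))
  expect_identical(
    unique(fwd$links[, c("phage_id", "host_id")]),
    unique(rev$links[, c("phage_id", "host_id")]))
  # strands permute
  expect_setequal(fwd$hits$strand,
                  chartr("+-", "-+", rev$hits$strand))
})

test_that("spacers with ambiguity codes are skipped with a warning", {
  arr <- list(host_contig_id = "h",
              spacers = data.frame(start = 0L, end = 20L,
                                   seq = "ACGTNACGTACGTACGTACG"))
  expect_warning(res <- match_spacers(list(arr), c(ph = rand_dna(1000))),
                 "ambiguity")
  expect_identical(nrow(res$hits), 0L)
})
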