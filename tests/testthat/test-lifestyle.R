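# Lifestyle calling: ORF finding against brute-force enumeration, marker
# detection with shuffle controls, classifier behaviour, T:L arithmetic.

test_that("ORF counts agree with brute-force six-frame enumeration", {
  set.seed(61)
  for (i in 1:6) {
    s <- rand_dna(2000)
    got <- find_orfs(s, min_orf_aa = 20L)
    expect_identical(nrow(got), oracle_orfs(s, 20L))
    # invariant: interval length is 3 * (protein + stop)
    if (nrow(got))
      expect_true(all(got$end - got$start ==
                        3L * (nchar(got$protein) + 1L)))
  }
})

test_that("a sequence without ATG yields no ORFs", {
  s <- paste(rep("C", 600), collapse = "")
  expect_identical(nrow(find_orfs(s)), 0L)
})

test_that("planted marker ORFs are recovered at exact coordinates", {
  set.seed(62)
  markers <- marker_exemplars()
  for (i in 1:5) {
    phage <- rand_dna(6000)
    pl <- plant_marker_orf(phage, markers[["integrase_like_synthetic"]])
    orfs <- find_orfs(pl$seq)
    hit <- orfs[orfs$start == pl$orf_start & orfs$end == pl$orf_end, ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$strand, pl$strand)
    # the ORF translates back to Met + the exemplar
    expect_identical(substring(hit$protein, 2),
                     unname(markers[["integrase_like_synthetic"]]))
  }
})

test_that("marker detection finds back-translations at near-full identity", {
  set.seed(63)
  markers <- marker_exemplars()
  phage <- rand_dna(6000)
  pl <- plant_marker_orf(phage, markers[["integrase_like_synthetic"]])
  orfs <- find_orfs(pl$seq)
  hits <- detect_markers(orfs, markers)
  expect_gte(nrow(hits), 1L)
  expect_gte(max(hits$identity), 0.99)
  expect_gte(max(hits$coverage), 0.99)
  # a phage without a planted marker has no hits
  expect_identical(nrow(detect_markers(find_orfs(rand_dna(6000)), markers)),
                   0L)
})

test_that("marker hits take precedence and flip calls only toward temperate", {
  hits <- data.frame(phage_id = "p1", orf = 1L,
                     marker_id = "integrase_like_synthetic",
                     score = 500, identity = 1, coverage = 1)
  # even with a classifier that would vote lytic
  set.seed(64)
  refs <- setNames(replicate(10, rand_dna(4000)), paste0("r", 1:10))
  cls <- composition_classifier(refs, rep("lytic", 10))
  call <- classify_lifestyle("p1", rand_dna(4000), hits, cls)
  expect_identical(call$call, "temperate")
  expect_identical(call$basis, "marker")
  # without the hit the same classifier votes lytic
  call2 <- classify_lifestyle("p1", rand_dna(4000), hits[0, ], cls)
  expect_identical(call2$call, "lytic")
})

test_that("an empty reference set leaves phages unclassified", {
  cls <- composition_classifier(character(0), character(0))
  call <- classify_lifestyle("p1", rand_dna(3000), NULL, cls)
  expect_identical(call$call, "unclassified")
  call2 <- classify_lifestyle("p1", rand_dna(3000), NULL, NULL)
  expect_identical(call2$call, "unclassified")
})

test_that("low-confidence composition votes are unclassified", {
  set.seed(65)
  refs <- setNames(replicate(10, rand_dna(4000)), paste0("r", 1:10))
  labels <- rep(c("temperate", "lytic"), 5)   # unseparable references
  cls <- composition_classifier(refs, labels, k = 2L)
  # with k=2 a split 1-1 vote has confidence 0.5 < 0.6 somewhere in a batch
  calls <- vapply(1:20, function(i)
    classify_lifestyle(paste0("q", i), rand_dna(4000), NULL, cls)$call,
    character(1))
  expect_true(any(calls == "unclassified"))
})

test_that("temperate:lytic ratios match hand computation", {
  counts <- rbind(t1 = c(10, 20), t2 = c(5, 5), l1 = c(10, 20), u1 = c(9, 9))
  colnames(counts) <- c("sp1", "sw1")
  env <- c(sp1 = "sponge", sw1 = "seawater")
  lens <- c(t1 = 1000, t2 = 2000, l1 = 1000, u1 = 1000)
  calls <- data.frame(phage_id = c("t1", "t2", "l1", "u1"),
                      call = c("temperate", "temperate", "lytic",
                               "unclassified"))
  res <- tl_ratio(calls, counts, lens, env)
  sponge <- res$per_env[res$per_env$environment == "sponge", ]
  # Cpk sums: temperate 10/1 + 5/2 = 12.5; lytic 10/1 = 10
  expect_equal(sponge$temperate_cpk, 12.5)
  expect_equal(sponge$lytic_cpk, 10)
  expect_equal(sponge$ratio, 1.25)
  expect_equal(res$count_ratio, 2 / 1)

  # equal Cpk gives ratio one
  m2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  eq <- tl_ratio(data.frame(phage_id = c("a", "b"),
                            call = c("temperate", "lytic")),
                 m2, c(a = 1000, b = 1000), c(s1 = "sponge"))
  expect_equal(eq$per_env$ratio, 1)

  # zero lytic Cpk is flagged infinite
  inf <- tl_ratio(data.frame(phage_id = c("a", "b"),
                             call = c("temperate", "lytic")),
                  matrix(c(10, 0), 2, 1,
                         dimnames = list(c("a", "b"), "s1")),
                  c(a = 1000, b = 1000), c(s1 = "sponge"))
  expect_true(inf$per_env$infinite)
  expect_identical(inf$per_env$ratio, Inf)

  expect_error(tl_ratio(calls[1:2, ], counts, lens, env), "without")
})

test_that("Cpk ratios are invariant to per-sample scaling of counts", {
  set.seed(66)
  counts <- matrix(rpois(8, 50), 4, 2,
                   dimnames = list(c("t1", "t2", "l1", "l2"), c("s1", "s2")))
  lens <- setNames(c(1500, 2500, 3000, 1200), rownames(counts))
  env <- c(s1 = "sponge", s2 = "sponge")
  calls <- data.frame(phage_id = rownames(counts),
                      call = c("temperate", "temperate", "lytic", "lytic"))
  r1 <- tl_ratio(calls, counts, lens, env)
  r2 <- tl_ratio(calls, counts * 7L, lens, env)
  expect_equal(r1$per_env$ratio, r2$per_env$ratio)
})
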