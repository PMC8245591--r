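# Infection network: assembly and deduplication, enrichment labelling,
# partition table against a brute-force tally, assortment statistic and
# permutation test properties.

test_that("edges deduplicate by pair with channel evidence unioned", {
  links <- data.frame(
    phage_id = c("p1", "p1", "p2"), host_id = c("h1", "h1", "h1"),
    channel = c("crispr", "homology", "trna"), score = c(0, 120, 0.99))
  pm <- data.frame(id = c("p1", "p2", "p3"),
                   enrichment = c("sponge", "seawater", "mixed"))
  hm <- data.frame(id = c("h1", "h2"),
                   niche = c("sponge_symbiont", "plankton"))
  net <- assemble_network(links, pm, hm)
  expect_identical(nrow(net$edges), 2L)
  e1 <- net$edges[net$edges$phage_id == "p1", ]
  expect_identical(e1$channels, "crispr,homology")
  expect_identical(e1$n_channels, 2L)
  # isolated nodes dropped
  expect_false("p3" %in% net$phages$id)
  expect_false("h2" %in% net$hosts$id)

  empty <- assemble_network(links[0, ], pm, hm)
  expect_identical(nrow(empty$edges), 0L)
  expect_error(assemble_network(
    data.frame(phage_id = "px", host_id = "h1", channel = "crispr", score = 0),
    pm, hm), "px")
})

test_that("enrichment labels follow the fold and prevalence rules", {
  counts <- rbind(
    sponge_phage = c(100, 100, 100, 0, 0, 0),
    mixed_phage = c(50, 50, 50, 50, 50, 50),
    absent_phage = c(0, 0, 0, 0, 0, 0),
    sea_phage = c(1, 0, 2, 80, 90, 100))
  colnames(counts) <- paste0("s", 1:6)
  env <- setNames(rep(c("sponge", "seawater"), each = 3), colnames(counts))
  lens <- setNames(rep(1000L, 4), rownames(counts))
  lab <- label_enrichment(counts, lens, env)
  expect_identical(unname(lab["sponge_phage"]), "sponge")
  expect_identical(unname(lab["mixed_phage"]), "mixed")
  expect_identical(unname(lab["absent_phage"]), "unknown")
  expect_identical(unname(lab["sea_phage"]), "seawater")
  expect_error(label_enrichment(counts, setNames(c(0, 1, 1, 1) * 1000,
                                                 rownames(counts)), env),
               "length")
})

test_that("planted enrichment labels are recovered from simulated counts", {
  set.seed(51)
  correct <- 0L; total <- 0L
  for (i in 1:25) {
    meta <- data.frame(id = sprintf("p%02d", 1:12),
                       length = sample(5000:20000, 12),
                       enrichment = sample(c("sponge", "seawater", "mixed"),
                                           12, replace = TRUE))
    ab <- simulate_abundance(meta, fold = 8, samples_per_env = 6L)
    lab <- label_enrichment(ab$counts, setNames(meta$length, meta$id),
                            ab$sample_env)
    correct <- correct + sum(lab[meta$id] == meta$enrichment)
    total <- total + 12L
  }
  expect_gte(correct / total, 0.95)
})

test_that("partition table equals the brute-force tally", {
  set.seed(52)
  for (i in 1:20) {
    net <- random_null_network(n_phages = 15L, n_hosts = 8L, p_edge = 0.25)
    expect_identical(partition_table(net), oracle_partition(net))
  }
})

test_that("partition counting rules match their definitions", {
  net <- make_network(
    data.frame(phage_id = c("p1", "p1", "p2", "p2"),
               host_id = c("h1", "h2", "h1", "h3")),
    c(p1 = "sponge", p2 = "mixed"),
    c(h1 = "sponge_symbiont", h2 = "sponge_symbiont", h3 = "plankton"))
  tab <- partition_table(net)
  # p1 links two symbiont hosts but counts once in that niche
  expect_identical(tab["sponge", "sponge_symbiont"], 1L)
  # p2 contributes once to each of two niches
  expect_identical(tab["mixed", "sponge_symbiont"], 1L)
  expect_identical(tab["mixed", "plankton"], 1L)
  expect_identical(sum(tab), 3L)
  per_edge <- partition_table(net, counting = "per_edge")
  expect_identical(per_edge["sponge", "sponge_symbiont"], 2L)
  expect_identical(sum(per_edge), 4L)
})

test_that("assortment statistic is 1 for perfect stratification and flips sign", {
  net <- make_network(
    data.frame(phage_id = c("p1", "p2", "p3", "p4"),
               host_id = c("h1", "h1", "h2", "h2")),
    c(p1 = "sponge", p2 = "sponge", p3 = "seawater", p4 = "seawater"),
    c(h1 = "sponge_symbiont", h2 = "plankton"))
  expect_identical(assortment_statistic(net), 1)
  swapped <- make_network(
    data.frame(phage_id = c("p1", "p2", "p3", "p4"),
               host_id = c("h1", "h1", "h2", "h2")),
    c(p1 = "seawater", p2 = "seawater", p3 = "sponge", p4 = "sponge"),
    c(h1 = "sponge_symbiont", h2 = "plankton"))
  expect_identical(assortment_statistic(swapped), -1)
  # single edge per side
  tiny <- make_network(
    data.frame(phage_id = c("p1", "p2"), host_id = c("h1", "h2")),
    c(p1 = "sponge", p2 = "seawater"),
    c(h1 = "sponge_symbiont", h2 = "plankton"))
  expect_identical(assortment_statistic(tiny), 1)
  # degenerate: no seawater-labelled phage
  degen <- make_network(
    data.frame(phage_id = c("p1", "p2"), host_id = c("h1", "h2")),
    c(p1 = "sponge", p2 = "mixed"),
    c(h1 = "sponge_symbiont", h2 = "plankton"))
  expect_error(assortment_statistic(degen), "degenerate")
})

test_that("statistic is near zero on average when labels are independent", {
  set.seed(53)
  stats <- replicate(60, assortment_statistic(random_null_network()))
  se <- sd(stats) / sqrt(length(stats))
  expect_lt(abs(mean(stats)), 2 * se + 1e-9)
  expect_true(all(stats >= -1 & stats <= 1))
})

test_that("permutation p-values respect the add-one rule and bounds", {
  set.seed(54)
  net <- random_null_network()
  res <- permutation_test(net, n_perm = 99L, seed = 5L)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_identical(length(res$null), 99L)
  expect_identical(res$p_value,
                   (1 + sum(abs(res$null) >= abs(res$observed))) / 100)
  # determinism under the seed
  res2 <- permutation_test(net, n_perm = 99L, seed = 5L)
  expect_identical(res$null, res2$null)
  expect_true(all(res$null >= -1 & res$null <= 1))
})

test_that("a perfectly stratified network is declared significant", {
  edges <- data.frame(phage_id = sprintf("p%02d", 1:12),
                      host_id = rep(c("h1", "h2"), each = 6))
  labs <- setNames(rep(c("sponge", "seawater"), each = 6),
                   sprintf("p%02d", 1:12))
  niches <- c(h1 = "sponge_symbiont", h2 = "plankton")
  net <- make_network(edges, labs, niches)
  res <- permutation_test(net, n_perm = 1000L, seed = 6L)
  expect_identical(res$observed, 1)
  expect_lte(res$p_value, 0.05)
})

test_that("a label-symmetric network has p near one", {
  # sponge and seawater phages link symbiont and plankton hosts identically
  edges <- data.frame(phage_id = rep(sprintf("p%02d", 1:8), each = 2),
                      host_id = rep(c("h1", "h2"), times = 8))
  labs <- setNames(rep(c("sponge", "seawater"), each = 4),
                   sprintf("p%02d", 1:8))
  net <- make_network(edges, labs, c(h1 = "sponge_symbiont", h2 = "plankton"))
  res <- permutation_test(net, n_perm = 200L, seed = 7L)
  expect_identical(res$observed, 0)
  expect_gte(res$p_value, 0.99)
})
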