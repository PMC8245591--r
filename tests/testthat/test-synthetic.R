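# Synthetic holobiont generator: config validation, determinism, planted
# feature construction, abundance model.

test_that("config validation rejects impossible or invalid settings", {
  expect_error(community_config(p_crispr_link = 1.2), "probabilities")
  expect_error(community_config(prophage_length = 500), "1 kb")
  expect_error(community_config(prophage_length = 6000,
                                phage_len_range = c(5000, 8000)),
               "cannot fit|exceeds")
  expect_error(community_config(host_len_range = c(-1, 10)), "positive")
})

test_that("a probability-one link config plants exactly one link per channel", {
  cfg <- community_config(n_phages = 1L, n_hosts = 1L,
                          p_crispr_link = 1, p_prophage_link = 0,
                          p_trna_link = 0, seed = 5L)
  cm <- generate_community(cfg)
  expect_identical(nrow(cm$truth$links), 1L)
  expect_identical(cm$truth$links$channel, "crispr")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- community_config(n_phages = 4L, n_hosts = 3L, seed = 42L)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$phages, b$phages)
  expect_identical(a$hosts, b$hosts)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(tempdir(), "cmA"); d2 <- file.path(tempdir(), "cmB")
  write_community(a, d1)
  write_community(b, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "phages.fasta"))),
                   unname(tools::md5sum(file.path(d2, "phages.fasta"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "hosts.fasta"))),
                   unname(tools::md5sum(file.path(d2, "hosts.fasta"))))
})

test_that("planted truth link count replays the generator's Bernoulli draws", {
  cfg <- community_config(n_phages = 20L, n_hosts = 10L, seed = 7L)
  cm <- generate_community(cfg)
  u <- holophage:::with_seed(holophage:::derive_seed(7L, "links"),
                             array(runif(20 * 10 * 3), dim = c(20, 10, 3)))
  expected <- sum(u[, , 1] < cfg$p_crispr_link) +
    sum(u[, , 2] < cfg$p_prophage_link) +
    sum(u[, , 3] < cfg$p_trna_link)
  expect_identical(nrow(cm$truth$links), as.integer(expected))
})

test_that("planted spacers have the exact requested Hamming distance", {
  set.seed(11)
  host <- rand_dna(3000)
  phage <- rand_dna(6000)
  pl0 <- plant_crispr_array(host, phage, n_spacers = 1L,
                            mutations_per_spacer = 0L)
  proto <- substr(phage, pl0$protospacers$phage_start + 1L,
                  pl0$protospacers$phage_end)
  sp <- pl0$protospacers$spacer
  expect_true(sp == proto || sp == revcomp(proto))
  # at least 3 repeat copies even with one spacer
  expect_gte(pl0$n_repeats, 3L)

  pl2 <- plant_crispr_array(host, phage, n_spacers = 2L,
                            mutations_per_spacer = 2L)
  for (i in 1:2) {
    proto <- substr(phage, pl2$protospacers$phage_start[i] + 1L,
                    pl2$protospacers$phage_end[i])
    if (pl2$protospacers$strand[i] == "-") proto <- revcomp(proto)
    expect_identical(holophage:::hamming(pl2$protospacers$spacer[i], proto), 2L)
  }
})

test_that("planted prophages match the requested identity", {
  set.seed(13)
  host <- rand_dna(20000)
  phage <- rand_dna(8000)
  pl <- plant_prophage(host, phage, identity = 1.0, length = 2000L)
  ins <- substr(pl$seq, pl$start + 1L, pl$end)
  src <- substr(phage, pl$phage_start + 1L, pl$phage_end)
  if (pl$strand == "-") ins <- revcomp(ins)
  expect_identical(ins, src)

  # i.i.d. mutations: mismatch count ~ Binomial(2000, 0.15)
  mm <- replicate(20, {
    pl <- plant_prophage(host, phage, identity = 0.85, length = 2000L)
    ins <- substr(pl$seq, pl$start + 1L, pl$end)
    if (pl$strand == "-") ins <- revcomp(ins)
    src <- substr(phage, pl$phage_start + 1L, pl$phage_end)
    holophage:::hamming(ins, src)
  })
  expect_true(all(mm >= qbinom(1e-5, 2000, 0.15) &
                    mm <= qbinom(1e-5, 2000, 0.15, lower.tail = FALSE)))
  expect_lt(abs(mean(mm) - 300), 5 * sqrt(2000 * 0.15 * 0.85 / 20))

  expect_error(plant_prophage(host, phage, length = 500L), "1 kb")
  expect_error(plant_prophage(host, phage, length = 9000L), "exceeds")
})

test_that("planted shared tRNAs hit the requested host-copy identity", {
  set.seed(17)
  host <- rand_dna(5000)
  phage <- rand_dna(5000)
  pl <- plant_trna(host, phage, identity = 1.0)
  expect_identical(pl$gene, pl$host_gene)
  pl2 <- plant_trna(host, phage, identity = 0.96)
  len <- nchar(pl2$gene)
  expect_identical(holophage:::hamming(pl2$gene, pl2$host_gene),
                   as.integer(round(0.04 * len)))
  # extraction round-trip from the emitted coordinates
  ext <- substr(pl2$phage_seq, pl2$phage_start + 1L, pl2$phage_end)
  if (pl2$phage_strand == "-") ext <- revcomp(ext)
  expect_identical(ext, pl2$gene)
})

test_that("abundance model: infinite fold means zero counts away from home", {
  meta <- data.frame(id = c("a", "b"), length = c(10000L, 10000L),
                     enrichment = c("sponge", "seawater"))
  ab <- simulate_abundance(meta, fold = Inf, samples_per_env = 4L, seed = 3L)
  sw <- ab$sample_env == "seawater"
  expect_true(all(ab$counts["a", sw] == 0))
  expect_true(all(ab$counts["b", !sw] == 0))
  ab2 <- simulate_abundance(meta, fold = Inf, samples_per_env = 4L, seed = 3L)
  expect_identical(ab$counts, ab2$counts)
})

test_that("synthetic images: no spots and no noise give a constant image", {
  img <- synth_image(matrix(numeric(0), 0, 2), dim = c(16L, 16L),
                     noise_sd = 0, background = 7)
  expect_true(all(img == 7))
  img2 <- synth_image(cbind(x = c(10, 30), y = c(10, 10)), dim = c(20L, 40L),
                      amplitude = 100, psf_sigma = 2, noise_sd = 0,
                      background = 10)
  expect_identical(find_maxima(img2, 50)$count, 2L)
})

test_that("planted features never overlap within a contig", {
  cfg <- community_config(n_phages = 10L, n_hosts = 4L, p_crispr_link = 0.5,
                          p_prophage_link = 0.5, p_trna_link = 0.5,
                          seed = 19L)
  cm <- generate_community(cfg)
  f <- cm$truth$features
  for (ct in unique(f$contig)) {
    fi <- f[f$contig == ct, ]
    fi <- fi[order(fi$start), ]
    if (nrow(fi) > 1L)
      expect_true(all(fi$start[-1] >= fi$end[-nrow(fi)]))
  }
})
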