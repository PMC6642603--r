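test_that("union-mode fragment counting resolves gene assignment", {
  models <- dplyr::bind_rows(
    toy_models("s1", c(101L, 501L), c(300L, 700L), gene_id = "gA",
               transcript_id = "gA.t1"),
    # gB overlaps gA's second exon
    toy_models("s1", c(650L, 901L), c(800L, 1000L), gene_id = "gB",
               transcript_id = "gB.t1")
  )
  sq <- tibble::tibble(name = "s1", length = 5000L)
  aln <- dplyr::bind_rows(
    # pair fully inside gA exon 1
    make_aln("f1", 99L, "s1", 110L, "50M", sq = sq),
    make_aln("f1", 147L, "s1", 200L, "50M", sq = sq),
    # pair overlapping exons of both gA and gB -> ambiguous, uncounted
    make_aln("f2", 99L, "s1", 660L, "50M", sq = sq),
    make_aln("f2", 147L, "s1", 690L, "50M", sq = sq),
    # intron-only fragment -> uncounted
    make_aln("f3", 99L, "s1", 350L, "50M", sq = sq),
    make_aln("f3", 147L, "s1", 400L, "50M", sq = sq),
    # pair in gB only
    make_aln("f4", 99L, "s1", 920L, "50M", sq = sq),
    make_aln("f4", 147L, "s1", 940L, "50M", sq = sq)
  )
  attr(aln, "sq") <- sq
  cm <- count_fragments(aln, models, "s")
  expect_equal(cm$count[cm$gene_id == "gA"], 1L)
  expect_equal(cm$count[cm$gene_id == "gB"], 1L)
  expect_equal(attr(cm, "library_sizes")[["s"]], 4L)
})

test_that("counts are proportional to simulated transcript abundance", {
  hg <- make_host_genome(1, 150000, 5, seed = 89)
  models <- hg$models
  txs <- unique(models$transcript_id)
  ab <- stats::setNames(c(4, 1, 1, 2, 1), txs)
  sim <- simulate_rnaseq(hg$genome, models, ab,
                         read_sim_config(insert_mean = 300, insert_sd = 30,
                                         depth = 40, seed = 7))
  cm <- count_fragments(sim$genome_aln, models)
  truth_counts <- table(factor(
    sub("_f[0-9]+$", "", sim$fragments$qname),
    levels = txs))
  g2t <- models[!duplicated(models$transcript_id),
                c("gene_id", "transcript_id")]
  for (i in seq_len(nrow(g2t))) {
    got <- cm$count[cm$gene_id == g2t$gene_id[i]]
    expect_lt(abs(got - truth_counts[[g2t$transcript_id[i]]]),
              0.12 * truth_counts[[g2t$transcript_id[i]]] + 10)
  }
})

test_that("target-region masking removes only overlapping fragments", {
  models <- toy_models("s1")
  sq <- tibble::tibble(name = "s1", length = 5000L)
  aln <- dplyr::bind_rows(
    make_aln("f1", 99L, "s1", 110L, "50M", sq = sq),
    make_aln("f1", 147L, "s1", 200L, "50M", sq = sq),
    make_aln("f2", 99L, "s1", 510L, "50M", sq = sq),
    make_aln("f2", 147L, "s1", 600L, "50M", sq = sq)
  )
  attr(aln, "sq") <- sq
  targets <- interval_tbl("s1", 100, 320)
  masked <- mask_target_regions(aln, targets)
  expect_setequal(masked$qname, "f2")
  # a gene entirely inside the target loses all its counts
  cm <- count_fragments(masked, models)
  expect_equal(cm$count[cm$gene_id == "gA"], 1L)
  # no overlap -> unchanged
  far <- mask_target_regions(aln, interval_tbl("s1", 4000, 4500))
  expect_equal(nrow(far), nrow(aln))
  # warning when a declared target lies outside its gene's exons
  t2 <- interval_tbl("s1", 350, 400)
  t2$gene_id <- "gA"
  expect_warning(mask_target_regions(aln, t2, models), "not fully inside")
})

test_that("normalization factors match a step-by-step reference", {
  counts <- tidyr::crossing(gene_id = paste0("g", 1:50),
                            sample = c("a", "b", "c"))
  set.seed(97)
  counts$count <- rpois(nrow(counts), 50)
  same <- counts
  same$count <- rep(counts$count[counts$sample == "a"], each = 3)
  n_same <- normalize_counts(same, "depth",
                             library_sizes = c(a = 100, b = 100, c = 100))
  expect_true(all(n_same$size_factors$size_factor == 1))

  # doubling one sample doubles its median-of-ratios factor
  dbl <- counts
  dbl$count[dbl$sample == "b"] <- dbl$count[dbl$sample == "a"] * 2L
  dbl$count[dbl$sample == "c"] <- dbl$count[dbl$sample == "a"]
  dbl$count[dbl$sample == "a"] <- dbl$count[dbl$sample == "c"]
  n_dbl <- normalize_counts(dbl, "median_of_ratios")
  sf <- n_dbl$size_factors
  expect_equal(sf$size_factor[sf$sample == "b"] /
                 sf$size_factor[sf$sample == "a"], 2)

  # reference computation, step by step on the wide matrix
  n_mor <- normalize_counts(counts, "median_of_ratios")
  wide <- tidyr::pivot_wider(counts, names_from = "sample",
                             values_from = "count")
  mat <- as.matrix(wide[, -1])
  keep <- apply(mat > 0, 1, all)
  geo <- exp(rowMeans(log(mat[keep, ])))
  ref_sf <- apply(mat[keep, ] / geo, 2, stats::median)
  expect_equal(n_mor$size_factors$size_factor, unname(ref_sf),
               tolerance = 1e-9)
  expect_error(
    normalize_counts(dplyr::mutate(counts, count = 0L), "median_of_ratios"),
    "nonzero")
})

test_that("TPM sums to one million and the threshold follows the formula", {
  set.seed(101)
  counts <- tidyr::crossing(gene_id = paste0("g", 1:200),
                            sample = c("s1", "s2"))
  counts$count <- rpois(nrow(counts), 30)
  lens <- tibble::tibble(gene_id = paste0("g", 1:200),
                         exonic_length_nt = sample(300:3000, 200))
  libs <- c(s1 = 5e5, s2 = 8e5)
  ft <- fpkm_tpm(counts, lens, libs)
  sums <- ft$abundance %>%
    dplyr::group_by(sample) %>%
    dplyr::summarise(s = sum(tpm))
  expect_equal(sums$s, rep(1e6, 2), tolerance = 1e-6)
  fsum <- ft$abundance %>%
    dplyr::group_by(sample) %>%
    dplyr::summarise(s = sum(fpkm))
  expect_equal(ft$thresholds$tpm_threshold, 1e6 / fsum$s)

  # a sample whose FPKMs sum to 1e6 has threshold exactly 1
  one <- tibble::tibble(gene_id = "g1", sample = "x", count = 1e6L)
  ft1 <- fpkm_tpm(one, tibble::tibble(gene_id = "g1",
                                      exonic_length_nt = 1000),
                  c(x = 1e6))
  expect_equal(ft1$thresholds$tpm_threshold, 1)

  # counts tuned so that sum(FPKM) = 293,255.13 give threshold 3.41
  lens2 <- tibble::tibble(gene_id = "g1", exonic_length_nt = 1000)
  target <- 293255.13
  cnt <- tibble::tibble(gene_id = "g1", sample = "x",
                        count = target * 1e6 * 1000 / 1e9)
  ft2 <- fpkm_tpm(cnt, lens2, c(x = 1e6))
  expect_equal(round(ft2$thresholds$tpm_threshold, 2), 3.41)

  expect_error(fpkm_tpm(one, lens2, c(x = 0)), "library size")
})

test_that("exonic lengths merge overlapping exon copies", {
  models <- dplyr::bind_rows(
    toy_models("s1"),
    toy_models("s1", c(150L, 501L), c(350L, 700L),
               transcript_id = "gA.t2"))
  gl <- gene_exonic_lengths(models)
  # union of 101-300, 150-350, 501-700 = 250 + 200
  expect_equal(gl$exonic_length_nt[gl$gene_id == "gA"], 450L)
})

test_that("DEG gates apply mean, TPM and LFC thresholds", {
  samples <- tibble::tibble(sample = c("w1", "w2", "t1", "t2"),
                            condition = c("WT", "WT", "TG", "TG"))
  norm <- tidyr::crossing(gene_id = c("low", "flat", "up"),
                          sample = samples$sample)
  norm$norm_count <- c(9, 9, 9, 9,      # low: mean below 10
                       100, 100, 100, 100,  # flat
                       50, 50, 200, 200)[order(rep(1:3, each = 4))] * NA
  norm$norm_count <- dplyr::case_when(
    norm$gene_id == "low" ~ 9,
    norm$gene_id == "flat" ~ 100,
    norm$gene_id == "up" & norm$sample %in% c("w1", "w2") ~ 50,
    TRUE ~ 200
  )
  degs <- call_degs(norm, samples, ref_condition = "WT")
  res <- tidy(degs)
  expect_false(res$passed_mean_filter[res$gene_id == "low"])
  expect_false(res$called_deg[res$gene_id == "low"])
  expect_equal(res$lfc[res$gene_id == "flat"], 0)
  expect_false(res$called_deg[res$gene_id == "flat"])
  expect_true(res$called_deg[res$gene_id == "up"])
  expect_equal(res$lfc[res$gene_id == "up"], log2(201 / 51))
  g <- glance(degs)
  expect_equal(g$n_degs, 1L)
  expect_error(call_degs(norm, dplyr::mutate(samples, condition = "WT"),
                         "WT"), "two conditions")

  # monotone: raising the LFC threshold never adds DEGs
  for (th in c(0.5, 1, 1.5, 2.5)) {
    expect_lte(sum(tidy(call_degs(norm, samples, "WT",
                                  lfc_threshold = th))$called_deg),
               sum(tidy(call_degs(norm, samples, "WT",
                                  lfc_threshold = th - 0.4))$called_deg))
  }

  # TPM gate: a gene under threshold in both conditions is not a DEG
  ab <- tidyr::crossing(gene_id = c("low", "flat", "up"),
                        sample = samples$sample)
  ab$fpkm <- 1; ab$tpm <- ifelse(ab$gene_id == "up", 0.5, 10)
  th <- tibble::tibble(sample = samples$sample, tpm_threshold = 3.41)
  gated <- tidy(call_degs(norm, samples, "WT", abundance = ab,
                          thresholds = th))
  expect_false(gated$called_deg[gated$gene_id == "up"])
  expect_false(gated$passed_tpm_filter[gated$gene_id == "up"])
  expect_true(gated$passed_tpm_filter[gated$gene_id == "flat"])
})

test_that("planted fold changes are recovered from noisy counts", {
  set.seed(103)
  n_gene <- 2000; n_plant <- 20
  mu <- rexp(n_gene, 1 / 200) + 30
  fold <- rep(1, n_gene); fold[seq_len(n_plant)] <- 4
  # tight dispersion: the characterized replicates correlate at r >= 0.99
  nb <- function(m) rnbinom(length(m), mu = m, size = 50)
  counts <- tibble::tibble(
    gene_id = rep(sprintf("g%04d", 1:n_gene), 4),
    sample = rep(c("w1", "w2", "t1", "t2"), each = n_gene),
    count = c(nb(mu), nb(mu), nb(mu * fold), nb(mu * fold))
  )
  norm <- normalize_counts(counts, "depth",
                           library_sizes = c(w1 = 1, w2 = 1, t1 = 1,
                                             t2 = 1))$normalized
  samples <- tibble::tibble(sample = c("w1", "w2", "t1", "t2"),
                            condition = c("WT", "WT", "TG", "TG"))
  res <- tidy(call_degs(norm, samples, "WT", lfc_threshold = 1.4))
  planted <- res$gene_id %in% sprintf("g%04d", 1:n_plant)
  expect_gte(sum(res$called_deg[planted]), 18)
  expect_equal(sum(res$called_deg[!planted]), 0)
})
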