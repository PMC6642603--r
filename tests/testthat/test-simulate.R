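test_that("synthetic genomes are deterministic with valid gene structure", {
  a <- make_host_genome(2, c(20000, 15000), n_genes = 4, seed = 21)
  b <- make_host_genome(2, c(20000, 15000), n_genes = 4, seed = 21)
  expect_identical(a, b)
  c2 <- make_host_genome(2, c(20000, 15000), n_genes = 4, seed = 22)
  expect_false(identical(a$genome$seq, c2$genome$seq))

  m <- a$models
  expect_equal(dplyr::n_distinct(m$gene_id), 4)
  # every CDS part inside an exon
  for (tx in unique(m$transcript_id)) {
    cds <- m[m$transcript_id == tx & m$type == "cds", ]
    ex <- m[m$transcript_id == tx & m$type == "exon", ]
    expect_equal(interval_overlap_length(cds, ex), cds$end - cds$start + 1L)
  }
  # spliced CDS translates: ATG start, single trailing stop, GT..AG introns
  for (tx in unique(m$transcript_id)) {
    cds_seq <- transcript_seq(a$genome, m, tx)
    expect_equal(nchar(cds_seq) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    ex <- m[m$transcript_id == tx & m$type == "exon", ]
    ex <- ex[order(ex$start), ]
    g <- a$genome$seq[match(ex$chrom[1], a$genome$id)]
    if (nrow(ex) > 1) {
      for (k in seq_len(nrow(ex) - 1)) {
        intron <- substr(g, ex$end[k] + 1, ex$start[k + 1] - 1)
        if (ex$strand[1] == "-") intron <- tgscan:::revcomp(intron)
        expect_equal(substr(intron, 1, 2), "GT")
        expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
      }
    }
  }
})

test_that("background GC content matches the request within binomial noise", {
  g <- make_host_genome(1, 1000000, n_genes = 0, gc = 0.5,
                        repeat_fraction = 0, seed = 31)
  bases <- table(strsplit(g$genome$seq, "")[[1]])
  gc <- sum(bases[c("G", "C")]) / sum(bases)
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1000000))
})

test_that("construct geometry tiles the published insert lengths", {
  fuct <- transgene_spec("FucT")
  xylt <- transgene_spec("XylT")
  expect_equal(nchar(fuct$seq), 4768L)
  expect_equal(nchar(xylt$seq), 4536L)
  for (cs in list(fuct, xylt)) {
    seg <- cs$segments
    expect_equal(seg$segment, c("LB", "P", "C", "T", "RB"))
    expect_equal(seg$start[1], 1L)
    expect_equal(seg$end[nrow(seg)], nchar(cs$seq))
    expect_equal(seg$start[-1], seg$end[-nrow(seg)] + 1L)
  }
  expect_equal(
    fuct$segments$end[3] - fuct$segments$start[3] + 1L, 1072L)
  expect_equal(
    xylt$segments$end[3] - xylt$segments$start[3] + 1L, 840L)
})

test_that("insertion arithmetic conserves sequence and junction layout", {
  hg <- make_host_genome(1, 30000, 1, seed = 13)
  tg <- transgene_spec("FucT")
  L <- nchar(hg$genome$seq[1])

  clean <- apply_insertion(hg$genome, tg, "scaf1", 10000, deleted = 0)
  expect_equal(nchar(clean$haplotypes[[1]]$seq), L + nchar(tg$seq))

  del <- apply_insertion(hg$genome, tg, "scaf1", 27872, deleted = 28)
  expect_equal(del$truth$right_resume, 27901L)
  expect_equal(nchar(del$haplotypes[[1]]$seq), L - 28L + nchar(tg$seq))
  # flank sequences preserved around the construct
  mod <- del$haplotypes[[1]]$seq
  expect_equal(substr(mod, 27872 - 49, 27872),
               substr(hg$genome$seq[1], 27872 - 49, 27872))
  expect_equal(substr(mod, 27873, 27872 + nchar(tg$seq)), tg$seq)
  expect_equal(substr(mod, 27873 + nchar(tg$seq),
                      27872 + nchar(tg$seq) + 50),
               substr(hg$genome$seq[1], 27901, 27950))

  hom <- apply_insertion(hg$genome, tg, "scaf1", 10000, zygosity = "hom")
  expect_equal(hom$haplotypes[[1]]$seq, hom$haplotypes[[2]]$seq)
  het <- apply_insertion(hg$genome, tg, "scaf1", 10000, zygosity = "het")
  expect_equal(het$haplotypes[[2]]$seq, hg$genome$seq[1])
  expect_error(apply_insertion(hg$genome, tg, "scaf1", 29999, deleted = 10),
               "exceeds")
})

test_that("error-free simulated reads match the reference at M positions", {
  hg <- make_host_genome(1, 30000, 1, seed = 17)
  tg <- transgene_spec("XylT")
  ins <- apply_insertion(hg$genome, tg, "scaf1", 15000, deleted = 5)
  sq <- reference_dict(hg$genome, list(tg))
  sim <- simulate_genomic_pairs(ins$haplotypes, sq,
                                read_sim_config(depth = 5, seed = 2))
  refs <- c(stats::setNames(hg$genome$seq, hg$genome$id),
            stats::setNames(tg$seq, tg$name))
  aln <- sim$alignments
  set.seed(1)
  for (i in sample(nrow(aln), 200)) {
    cl <- cigar_clips(aln$cigar[i])
    span <- cigar_ref_span(aln$cigar[i])
    aligned <- substr(aln$seq[i], cl$left + 1, cl$left + span)
    expect_equal(aligned,
                 substr(refs[[aln$rname[i]]], aln$pos[i],
                        aln$pos[i] + span - 1))
  }
  # determinism
  sim2 <- simulate_genomic_pairs(ins$haplotypes, sq,
                                 read_sim_config(depth = 5, seed = 2))
  expect_identical(sim$alignments, sim2$alignments)
  expect_error(
    simulate_genomic_pairs(ins$haplotypes, sq,
                           read_sim_config(depth = -1, seed = 1)))
})

test_that("injected base errors appear at the configured rate", {
  hg <- make_host_genome(1, 50000, 0, seed = 19)
  sq <- reference_dict(hg$genome)
  sim <- simulate_genomic_pairs(list(as_haplotype(hg$genome[1, ])), sq,
                                read_sim_config(depth = 5,
                                                error_rate = 0.01, seed = 4))
  n_bases <- sum(nchar(sim$alignments$seq))
  n_err <- sum(sim$alignments$nm)
  expect_lt(abs(n_err / n_bases - 0.01), 3 * sqrt(0.01 / n_bases))
})

test_that("truth alignments convert back to sequencing reads", {
  hg <- make_host_genome(1, 20000, 0, seed = 151)
  sim <- simulate_genomic_pairs(list(as_haplotype(hg$genome[1, ])),
                                reference_dict(hg$genome),
                                read_sim_config(depth = 3, seed = 1))
  r1 <- alignments_to_reads(sim$alignments, 1)
  r2 <- alignments_to_reads(sim$alignments, 2)
  expect_equal(nrow(r1), nrow(sim$fragments))
  expect_equal(nrow(r2), nrow(sim$fragments))
  # mate 1 is the fragment prefix on the haplotype
  i <- match(paste0(sim$fragments$qname, "/1"), r1$id)
  expect_equal(r1$seq[i[1:20]],
               substring(hg$genome$seq[1], sim$fragments$start[1:20],
                         sim$fragments$start[1:20] + 124L))
  tf <- withr::local_tempfile(fileext = ".fq")
  write_fastq(r1, tf)
  expect_equal(read_fastq(tf), r1)
})

test_that("planted variant counts and Ti/Tv follow the requested rates", {
  g <- make_host_genome(1, 500000, 0, seed = 23)$genome
  none <- plant_variants(g, rate_per_mbp = 0, seed = 1)
  expect_equal(nrow(none$truth), 0)
  expect_equal(none$genome$seq, g$seq)

  pv <- plant_variants(g, rate_per_mbp = 8152, titv_ratio = 2.0, seed = 2)
  expect_lt(abs(nrow(pv$truth) - 8152 * 0.5), 3 * sqrt(8152 * 0.5))
  # mutated genome differs exactly at planted positions
  orig <- strsplit(g$seq, "")[[1]]
  mut <- strsplit(pv$genome$seq, "")[[1]]
  diff_pos <- which(orig != mut)
  expect_setequal(diff_pos, pv$truth$pos)

  big <- plant_variants(g, rate_per_mbp = 20000, titv_ratio = 2.0, seed = 3)
  expect_gt(nrow(big$truth), 9000)
  expect_lt(abs(titv_ratio(big$truth %>%
                             dplyr::mutate(vtype = "SNV")) - 2.0), 0.1)

  expect_error(plant_variants(g, 10,
                              region_track = interval_tbl(character(),
                                                          integer(),
                                                          integer())),
               "empty region")

  # region restriction
  tr <- interval_tbl("scaf1", 1000, 2000)
  reg <- plant_variants(g, rate_per_mbp = 5e5, region_track = tr, seed = 4)
  expect_true(all(reg$truth$pos >= 1000 & reg$truth$pos <= 2000))
})

test_that("planted indels use the anchored-base representation", {
  g <- make_host_genome(1, 100000, 0, seed = 29)$genome
  pv <- plant_variants(g, rate_per_mbp = 0, indel_rate_per_mbp = 100,
                       seed = 5)
  ind <- pv$truth[pv$truth$vtype != "SNV", ]
  expect_gt(nrow(ind), 0)
  expect_true(all(substr(ind$ref, 1, 1) == substr(ind$alt, 1, 1)))
  orig <- strsplit(g$seq, "")[[1]]
  expect_true(all(ind$ref != ind$alt))
  expect_true(all(vapply(seq_len(nrow(ind)), function(i) {
    substr(g$seq, ind$pos[i], ind$pos[i] + nchar(ind$ref[i]) - 1L) ==
      ind$ref[i]
  }, logical(1))))
})

test_that("RNA simulation respects abundances, splicing and fusions", {
  hg <- make_host_genome(1, 100000, 3, seed = 37)
  models <- hg$models
  txs <- unique(models$transcript_id)
  ab <- stats::setNames(c(0, 1, 1), txs)
  cfg <- read_sim_config(insert_mean = 300, insert_sd = 30, depth = 20,
                         seed = 6)
  sim <- simulate_rnaseq(hg$genome, models, ab, cfg)
  expect_false(txs[1] %in% sim$fragments$transcript)
  # spliced truth alignments reproduce the reference at M blocks
  aln <- sim$genome_aln
  blocks <- alignment_blocks(aln)
  g <- hg$genome$seq[1]
  set.seed(2)
  for (i in sample(nrow(aln), 50)) {
    b <- blocks[blocks$row_id == i, ]
    cl <- cigar_clips(aln$cigar[i])
    offset <- cl$left
    for (j in seq_len(nrow(b))) {
      w <- b$end[j] - b$start[j] + 1L
      expect_equal(substr(aln$seq[i], offset + 1, offset + w),
                   substr(g, b$start[j], b$end[j]))
      offset <- offset + w
    }
  }
  # uniform sampling: per-exon means within sampling noise of each other
  cov <- per_exon_coverage(sim$genome_aln, models, txs[2])
  expect_true(all(abs(cov$mean_depth - mean(cov$mean_depth)) <
                    4 * sqrt(mean(cov$mean_depth))))
  expect_error(
    simulate_rnaseq(hg$genome, models, ab, cfg,
                    fusion = list(construct = transgene_spec("FucT"),
                                  transcript_id = txs[2], from_exon = 99,
                                  abundance = 1)),
    "unknown exon")
})
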