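test_that("ambiguous and duplicate alignments are removed", {
  sq <- tibble::tibble(name = "c1", length = 100000L)
  aln <- dplyr::bind_rows(
    # primary with an equally good secondary (NM tie) -> dropped
    make_aln("amb", 0L, "c1", 100L, "50M", nm = 0L),
    make_aln("amb", 256L, "c1", 900L, "50M", nm = 0L),
    # primary clearly better than its secondary -> kept
    make_aln("good", 0L, "c1", 200L, "50M", nm = 0L),
    make_aln("good", 256L, "c1", 950L, "50M", nm = 3L),
    # no secondary -> kept
    make_aln("solo", 0L, "c1", 300L, "50M")
  )
  attr(aln, "sq") <- sq
  out <- dedup_primary_unique(aln)
  expect_setequal(out$qname, c("good", "solo"))
  expect_equal(attr(out, "dedup_counts")[["n_ambiguous"]], 1L)

  # 100 duplicates of one fragment collapse to the best-quality record
  dup <- make_aln(paste0("d", 1:100), 0L, "c1", 500L, "50M",
                  qual = c(strrep("J", 50), rep(strrep("I", 50), 99)),
                  sq = sq)
  kept <- dedup_primary_unique(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$qual, strrep("J", 50))
  expect_equal(attr(kept, "dedup_counts")[["n_duplicates"]], 99L)

  # clip-adjusted starts: clipped record duplicates an unclipped one
  cl <- dplyr::bind_rows(
    make_aln("u1", 0L, "c1", 500L, "50M", pnext = 900L),
    make_aln("u2", 0L, "c1", 505L, "5S45M", pnext = 900L)
  )
  attr(cl, "sq") <- sq
  expect_equal(nrow(dedup_primary_unique(cl)), 1)
})

test_that("pileup genotyping recovers planted SNVs with allele balance", {
  g <- make_host_genome(1, 50000, 0, seed = 67)$genome
  expect_error(pileup_genotype(make_aln("x", 0L, "nope", 1L, "10M"), g),
               "missing from genome")
  # all reads match the reference -> empty call set
  sim0 <- simulate_genomic_pairs(list(as_haplotype(g[1, ])),
                                 reference_dict(g),
                                 read_sim_config(depth = 10, seed = 1))
  expect_equal(nrow(pileup_genotype(sim0$alignments, g)), 0)

  pv <- plant_variants(g, rate_per_mbp = 400, titv_ratio = 1.4, seed = 3)
  hom <- list(name = "scaf1", seq = pv$genome$seq[1],
              blocks = as_haplotype(g[1, ])$blocks)
  sim <- simulate_genomic_pairs(list(hom), reference_dict(g),
                                read_sim_config(depth = 30, seed = 2))
  calls <- pileup_genotype(sim$alignments, g)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  found <- key(pv$truth) %in% key(calls)
  expect_gte(mean(found), 0.95)
  expect_true(all(calls$alt_count / calls$depth == 1))

  # het: one mutated and one reference haplotype
  simh <- simulate_genomic_pairs(list(hom, as_haplotype(g[1, ])),
                                 reference_dict(g),
                                 read_sim_config(depth = 30, seed = 4))
  ch <- pileup_genotype(simh$alignments, g)
  ch <- ch[key(ch) %in% key(pv$truth), ]
  af <- ch$alt_count / ch$depth
  expect_gt(mean(af), 0.4)
  expect_lt(mean(af), 0.6)
  expect_true(all(ch$alt_count <= ch$depth))
})

test_that("pileup emits anchored-base indel candidates from CIGARs", {
  g <- tibble::tibble(id = "c1",
                      seq = strrep("ACGTTGCA", 100), description = "")
  ins <- make_aln(paste0("i", 1:5), 0L, "c1", 11L, "10M2I10M",
                  seq = paste0(substr(g$seq, 11, 20), "TT",
                               substr(g$seq, 21, 30)),
                  sq = tibble::tibble(name = "c1", length = 800L))
  calls <- pileup_genotype(ins, g, min_alt = 2)
  ind <- calls[calls$vtype == "INS", ]
  expect_equal(nrow(ind), 1)
  expect_equal(ind$pos, 20L)
  expect_equal(nchar(ind$alt), 3L)
  expect_equal(substr(ind$alt, 1, 1), ind$ref)

  del <- make_aln(paste0("d", 1:5), 0L, "c1", 11L, "10M3D10M",
                  seq = paste0(substr(g$seq, 11, 20), substr(g$seq, 24, 33)),
                  sq = tibble::tibble(name = "c1", length = 800L))
  dcalls <- pileup_genotype(del, g, min_alt = 2)
  dd <- dcalls[dcalls$vtype == "DEL", ]
  expect_equal(dd$pos, 20L)
  expect_equal(nchar(dd$ref), 4L)
  expect_equal(dd$alt, substr(dd$ref, 1, 1))
})

test_that("per-variant filter rules reject annotated failures", {
  prof <- filter_profile("genomic", max_cov = 30)
  v <- dplyr::bind_rows(
    toy_variant(pos = 100L),                                  # clean
    toy_variant(pos = 200L, qual = 10),                       # low qual
    toy_variant(pos = 300L, mq_mean = 15),                    # low MQ
    toy_variant(pos = 400L, depth = 3L, alt_count = 3L),      # low cov
    toy_variant(pos = 500L, depth = 40L),                     # high cov
    toy_variant(pos = 600L, mq0f = 0.2),                      # MQ0F
    toy_variant(pos = 700L, alt_fwd = 3L, alt_rev = 0L)       # one strand
  )
  out <- filter_callset(v, prof)
  expect_equal(out$pos, 100L)
  audit <- attr(out, "audit")
  expect_equal(audit$removed_by[match(c(200L, 300L, 400L, 500L, 600L, 700L),
                                      audit$pos)],
               c("min_qual", "min_avg_mq", "min_cov", "max_cov", "mq0f",
                 "min_reads_per_strand"))
  expect_error(filter_callset(v, list(name = "genomic")), "unknown")
  # annotations the caller left NA never reject
  v2 <- toy_variant(pos = 800L, qual = NA_real_)
  expect_equal(nrow(filter_callset(v2, prof)), 1)
})

test_that("transcriptomic positional exclusions match their examples", {
  prof <- filter_profile("transcriptomic")
  # clusters of 3 SNVs within 10 nt: 100/104/108 all removed
  cl <- toy_variant(pos = c(100L, 104L, 108L), alt_count = 19L,
                    depth = 20L, ref_count = 1L)
  out <- filter_callset(cl, prof)
  expect_equal(nrow(out), 0)
  expect_true(all(attr(out, "audit")$removed_by == "snv_cluster"))
  # SNV within 10 nt of an indel is removed, the indel itself kept
  mix <- dplyr::bind_rows(
    toy_variant(pos = 105L, alt_count = 19L, depth = 20L, ref_count = 1L),
    toy_variant(pos = 100L, ref = "A", alt = "AT", vtype = "INS",
                alt_count = 19L, depth = 20L, ref_count = 1L)
  )
  out2 <- filter_callset(mix, prof)
  expect_equal(out2$vtype, "INS")
  expect_equal(attr(out2, "audit")$removed_by[
    attr(out2, "audit")$vtype == "SNV"], "snv_near_indel")
  # indel pairs within 100 nt: both removed
  ip <- toy_variant(pos = c(100L, 180L), ref = "A", alt = "AT",
                    vtype = "INS", alt_count = 19L, depth = 20L,
                    ref_count = 1L)
  expect_equal(nrow(filter_callset(ip, prof)), 0)
  # alt-fraction rule
  lowaf <- toy_variant(pos = 900L, alt_count = 10L, ref_count = 10L,
                       depth = 20L)
  expect_equal(nrow(filter_callset(lowaf, prof)), 0)
  # literal MQ0F minimum mode flips the rule
  m <- toy_variant(pos = 950L, mq0f = 0.5, alt_count = 19L, depth = 20L,
                   ref_count = 1L)
  expect_equal(nrow(filter_callset(m, prof)), 0)
  lit <- filter_profile("transcriptomic", mq0f_literal_min = TRUE)
  expect_equal(nrow(filter_callset(m, lit)), 1)
})

test_that("the filter cascade is idempotent", {
  set.seed(73)
  v <- toy_variant(
    pos = sort(sample.int(2000L, 60)),
    vtype = sample(c("SNV", "INS"), 60, TRUE, prob = c(0.8, 0.2)),
    alt_count = 19L, depth = 20L, ref_count = 1L)
  v$ref <- ifelse(v$vtype == "INS", "A", "A")
  v$alt <- ifelse(v$vtype == "INS", "AT", "G")
  prof <- filter_profile("transcriptomic")
  once <- filter_callset(v, prof)
  twice <- filter_callset(once, prof)
  strip <- function(x) as.data.frame(`attr<-`(x, "audit", NULL))
  expect_equal(strip(twice), strip(once))
  # and nothing is rejected on the second pass
  expect_true(all(is.na(attr(twice, "audit")$removed_by)))
})

test_that("self-map subtraction is position-level and allele-agnostic", {
  v <- toy_variant(pos = c(100L, 200L, 300L))
  expect_equal(subtract_selfmap(v, v[0, ]), v)
  selfmap <- toy_variant(pos = c(200L, 400L), alt = "T")
  out <- subtract_selfmap(v, selfmap)
  expect_equal(out$pos, c(100L, 300L))
  # planted consensus errors removed, true variants untouched
  truth <- toy_variant(pos = c(10L, 20L, 30L))
  consensus <- toy_variant(pos = c(50L, 60L))
  mixed <- dplyr::bind_rows(truth, consensus)
  clean <- subtract_selfmap(mixed, consensus)
  expect_equal(clean$pos, truth$pos)
})

test_that("set partition matches brute force and conserves counts", {
  a <- toy_variant(pos = c(1L, 2L, 3L))
  p <- set_partition(a, a)
  expect_equal(nrow(p$unique_a), 0)
  expect_equal(nrow(p$unique_b), 0)

  set.seed(79)
  pa <- sample.int(5000L, 800)
  pb <- sample.int(5000L, 800)
  va <- toy_variant(pos = sort(pa))
  vb <- toy_variant(pos = sort(pb))
  pp <- set_partition(va, vb)
  expect_equal(sort(pp$shared$pos), sort(intersect(pa, pb)))
  expect_equal(sort(pp$unique_a$pos), sort(setdiff(pa, pb)))
  expect_equal(nrow(pp$shared) + nrow(pp$unique_a), nrow(va))
  expect_equal(nrow(pp$shared) + nrow(pp$unique_b), nrow(vb))
})

test_that("Ti/Tv handles transitions, transversions and edge cases", {
  v <- toy_variant(pos = 1:3, ref = c("A", "C", "A"),
                   alt = c("G", "T", "C"))
  expect_equal(titv_ratio(v), 2.0)
  expect_equal(titv_ratio(toy_variant(ref = "A", alt = "C")), 0)
  expect_true(is.na(titv_ratio(toy_variant(ref = "A", alt = "G"))))
  expect_true(is.na(titv_ratio(v[0, ])))
})

test_that("SNV density uses covered CDS positions as denominator", {
  expect_equal(
    divergence_snv_per_mbp(toy_variant()[0, ],
                           covered_positions = 1000000)$snv_per_mbp, 0)
  expect_error(divergence_snv_per_mbp(toy_variant(), covered_positions = 0),
               "no covered")
  # depth/CDS plumbing: only CDS positions with depth >= 4 count
  depth <- tibble::tibble(chrom = "c1", pos = 1:1000,
                          depth = rep(c(10L, 2L), each = 500))
  cds <- interval_tbl("c1", 101, 700)
  v <- toy_variant(pos = c(150L, 650L, 800L))  # 650 uncovered, 800 off-CDS
  d <- divergence_snv_per_mbp(v, depth, cds)
  expect_equal(d$covered_positions, 400L)
  expect_equal(d$snv_count, 1L)
  expect_equal(d$snv_per_mbp_raw, 1 / (400 / 1e6))
})

test_that("coding-impact calls agree with a translate-and-compare oracle", {
  hg <- make_host_genome(1, 60000, 4, seed = 83)
  models <- hg$models
  g <- hg$genome
  cds_all <- models[models$type == "cds", ]
  set.seed(3)
  checked <- 0
  for (rep in 1:200) {
    row <- cds_all[sample(nrow(cds_all), 1), ]
    pos <- sample(row$start:row$end, 1)
    refb <- substr(g$seq[1], pos, pos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    v <- toy_variant(chrom = "scaf1", pos = pos, ref = refb, alt = altb)
    ann <- classify_impact(v, models, g)
    ann <- ann[ann$transcript_id == row$transcript_id, ]
    # oracle: mutate the genome, retranslate the whole CDS, compare proteins
    mut <- g
    substr(mut$seq[1], pos, pos) <- altb
    p0 <- as.character(Biostrings::translate(
      Biostrings::DNAString(transcript_seq(g, models, row$transcript_id))))
    p1 <- as.character(Biostrings::translate(
      Biostrings::DNAString(transcript_seq(mut, models,
                                           row$transcript_id))))
    expected <- if (p0 == p1) {
      "synonymous"
    } else {
      i <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
      a0 <- substr(p0, i, i); a1 <- substr(p1, i, i)
      if (i == 1 && a1 != "M") "start_lost"
      else if (a0 != "*" && a1 == "*") "stop_gained"
      else if (a0 == "*" && a1 != "*") "stop_lost"
      else "missense"
    }
    expect_equal(ann$consequence, expected)
    checked <- checked + 1
  }
  expect_equal(checked, 200)
})

test_that("indel and splice-site impacts follow the classification rules", {
  models <- toy_models()  # exons 101-300, 501-700 on + strand
  g <- tibble::tibble(
    id = "s1",
    seq = withr::with_seed(5, tgscan:::random_dna(1000)),
    description = "")
  del1 <- toy_variant(chrom = "s1", pos = 150L, ref = "AG", alt = "A",
                      vtype = "DEL")
  a <- classify_impact(del1, models, g)
  expect_equal(a$consequence, "frameshift")
  expect_equal(a$impact, "HIGH")
  ins3 <- toy_variant(chrom = "s1", pos = 150L, ref = "A", alt = "ACCC",
                      vtype = "INS")
  expect_equal(classify_impact(ins3, models, g)$consequence,
               "inframe_indel")
  # the two intronic bases at the donor site
  don <- toy_variant(chrom = "s1", pos = 301L)
  expect_equal(classify_impact(don, models, g)$consequence, "splice_site")
  acc <- toy_variant(chrom = "s1", pos = 499L)
  expect_equal(classify_impact(acc, models, g)$consequence, "splice_site")
  deep <- toy_variant(chrom = "s1", pos = 400L)
  expect_equal(classify_impact(deep, models, g)$consequence, "non_coding")
  expect_equal(classify_impact(deep, models, g)$impact, "MODIFIER")
})
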