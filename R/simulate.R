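#' Synthetic host genomes with gene models and repeats
#'
#' Generates random scaffolds with embedded multi-exon protein-coding genes
#' (ATG start, stop codon, GT..AG introns, CDS == exons) and labeled repeat
#' intervals. Deterministic for a fixed seed. The generated set stands in for
#' a draft plant assembly at desk scale.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param lengths Integer vector of scaffold lengths (recycled), each >= 10 kb.
#' @param n_genes Total genes, distributed proportionally to length.
#' @param gc GC content of the random background.
#' @param repeat_fraction Approximate fraction of each scaffold covered by
#'   labeled repeat intervals.
#' @param seed Integer seed.
#' @return A list with `genome` (FASTA tibble), `models` (gene-model tibble),
#'   `repeats` (interval tibble).
#' @export
make_host_genome <- function(n_scaffolds = 1, lengths = 100000L,
                             n_genes = 5L, gc = 0.4,
                             repeat_fraction = 0.05, seed = 1L) {
  lengths <- as.integer(rep_len(lengths, n_scaffolds))
  stopifnot(all(lengths >= 10000L))
  withr::with_seed(seed, {
    scafs <- paste0("scaf", seq_len(n_scaffolds))
    seqs <- vapply(lengths, random_dna, character(1), gc = gc)
    gene_alloc <- table(factor(
      sample(scafs, n_genes, replace = TRUE, prob = lengths), levels = scafs
    ))
    models <- list()
    gi <- 0L
    for (s in seq_len(n_scaffolds)) {
      ng <- as.integer(gene_alloc[[s]])
      if (!ng) next
      # carve non-overlapping gene loci with margins
      slots <- floor(lengths[s] / ng)
      for (k in seq_len(ng)) {
        gi <- gi + 1L
        gene <- random_gene(paste0("g", gi), paste0("g", gi, ".t1"))
        lo <- (k - 1L) * slots + 1L
        hi <- k * slots - nchar(gene$seq) - 200L
        if (hi <= lo + 100L) {
          stop("requested gene does not fit in scaffold slot", call. = FALSE)
        }
        at <- sample(seq.int(lo + 100L, hi), 1L)
        substr(seqs[s], at, at + nchar(gene$seq) - 1L) <- gene$seq
        m <- gene$models
        m$chrom <- scafs[s]
        m$start <- m$start + at - 1L
        m$end <- m$end + at - 1L
        models[[gi]] <- m
      }
    }
    models <- dplyr::bind_rows(models)
    models$valid <- TRUE
    reps <- list()
    for (s in seq_len(n_scaffolds)) {
      n_rep <- max(0L, round(lengths[s] * repeat_fraction / 800))
      if (!n_rep) next
      w <- sample(200:1500, n_rep, replace = TRUE)
      st <- sample.int(lengths[s] - max(w), n_rep, replace = TRUE)
      reps[[s]] <- tibble(chrom = scafs[s], start = st, end = st + w - 1L,
                          strand = ".")
    }
    list(
      genome = tibble(id = scafs, seq = seqs, description = ""),
      models = models,
      repeats = if (length(reps)) dplyr::bind_rows(reps) else
        interval_tbl(character(), integer(), integer())
    )
  })
}

random_dna <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

# one gene in local coordinates (start = 1), CDS == exons, GT..AG introns
random_gene <- function(gene_id, transcript_id) {
  n_ex <- sample(2:6, 1)
  aa <- sample(100:400, 1)
  cds <- random_cds(aa)
  cuts <- sort(sample(seq(30L, nchar(cds) - 30L), n_ex - 1L))
  ex_len <- diff(c(0L, cuts, nchar(cds)))
  in_len <- sample(80:400, n_ex - 1L, replace = TRUE)
  introns <- vapply(in_len, function(w) {
    paste0("GT", random_dna(w - 4L), "AG")
  }, character(1))
  strand <- sample(c("+", "-"), 1)
  pieces <- character(2 * n_ex - 1)
  pieces[seq(1, 2 * n_ex - 1, by = 2)] <-
    substring(cds, cumsum(c(1L, ex_len[-n_ex])),
              cumsum(ex_len))
  pieces[seq(2, 2 * n_ex - 1, by = 2)] <- introns
  gseq <- paste(pieces, collapse = "")
  st <- cumsum(c(1L, utils::head(ex_len, -1) + in_len))
  en <- st + ex_len - 1L
  if (strand == "-") {
    gseq <- revcomp(gseq)
    L <- nchar(gseq)
    new_st <- L - en + 1L
    en <- L - st + 1L
    st <- new_st
    o <- order(st); st <- st[o]; en <- en[o]
  }
  models <- dplyr::bind_rows(
    tibble(chrom = NA_character_, type = "exon", start = st, end = en),
    tibble(chrom = NA_character_, type = "cds", start = st, end = en)
  )
  models$strand <- strand
  models$gene_id <- gene_id
  models$transcript_id <- transcript_id
  list(seq = gseq, models = models)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Transgene construct specifications
#'
#' Builds a construct record: left/right border repeats flanking a promoter,
#' an RNAi cassette and a terminator. Default geometry mirrors the
#' characterized binary vectors: 25-nt borders, 2,774-nt promoter, 872-nt
#' terminator, and cassettes of 1,072 nt (FucT) or 840 nt (XylT), giving
#' total insert lengths of 4,768 and 4,536 nt.
#'
#' @param name Construct name (`"FucT"`, `"XylT"`, or any label).
#' @param promoter_len,cassette_len,terminator_len,border_len Segment
#'   lengths in nt; `cassette_len` defaults by `name`.
#' @param seed Seed for the random construct sequence.
#' @return A list with `name`, `seq`, and `segments` (tibble `segment`
#'   in `LB`/`P`/`C`/`T`/`RB` with 1-based `start`, `end` on the construct).
#' @export
transgene_spec <- function(name = "FucT", promoter_len = 2774L,
                           cassette_len = NULL, terminator_len = 872L,
                           border_len = 25L, seed = NULL) {
  if (is.null(cassette_len)) {
    cassette_len <- switch(name, FucT = 1072L, XylT = 840L, 1000L)
  }
  if (is.null(seed)) {
    seed <- sum(utf8ToInt(name)) + 7L
  }
  lens <- c(LB = border_len, P = promoter_len, C = cassette_len,
            T = terminator_len, RB = border_len)
  seq <- withr::with_seed(seed, random_dna(sum(lens), gc = 0.45))
  en <- cumsum(lens)
  st <- en - lens + 1L
  list(name = name, seq = seq,
       segments = tibble(segment = names(lens), start = unname(st),
                         end = unname(en)))
}

#' Insert a transgene into a host scaffold
#'
#' The modified haplotype is `host[1..left_junction] + construct +
#' host[left_junction + deleted + 1 ..]`: `left_junction` is the last
#' retained host base of the 5' flank and the right flank resumes
#' `deleted` bases later. `zygosity = "het"` keeps an unmodified second
#' haplotype.
#'
#' @param genome FASTA tibble of host scaffolds.
#' @param transgene A [transgene_spec()].
#' @param scaffold Scaffold id receiving the insertion.
#' @param left_junction 1-based last retained host base of the 5' flank.
#' @param deleted Host bases deleted at the integration site.
#' @param orientation `"forward"` or `"reverse"` construct orientation.
#' @param zygosity `"hom"` or `"het"`.
#' @param models Optional gene-model tibble; used to flag whether the lesion
#'   falls inside an annotated gene (and which intron).
#' @return A list with `haplotypes` (each `name`, `seq`, `blocks`) and
#'   `truth` (one-row tibble describing the event).
#' @export
apply_insertion <- function(genome, transgene, scaffold, left_junction,
                            deleted = 0L, orientation = "forward",
                            zygosity = "hom", models = NULL) {
  i <- match(scaffold, genome$id)
  stopifnot(!is.na(i), deleted >= 0)
  host <- genome$seq[i]
  L <- nchar(host)
  if (left_junction + deleted >= L) {
    stop("insertion (junction + deletion) exceeds scaffold length",
         call. = FALSE)
  }
  cons <- if (orientation == "forward") transgene$seq else
    revcomp(transgene$seq)
  K <- nchar(cons)
  right_from <- left_junction + deleted + 1L
  mod_seq <- paste0(substr(host, 1L, left_junction), cons,
                    substr(host, right_from, L))
  blocks <- tibble(
    ref = c(scaffold, transgene$name, scaffold),
    ref_start = c(1L, 1L, right_from),
    ref_end = c(left_junction, K, L),
    strand = c("+", if (orientation == "forward") "+" else "-", "+"),
    hap_start = c(1L, left_junction + 1L, left_junction + K + 1L),
    hap_end = c(left_junction, left_junction + K,
                left_junction + K + (L - right_from) + 1L)
  )
  hap_mod <- list(name = paste0(scaffold, "_tg"), seq = mod_seq,
                  blocks = blocks)
  haplotypes <- if (zygosity == "het") {
    list(hap_mod, as_haplotype(genome[i, ]))
  } else {
    list(hap_mod, hap_mod)
  }
  in_gene <- NA_character_
  intron_index <- NA_integer_
  if (!is.null(models)) {
    ex <- models[models$type == "exon" & models$chrom == scaffold, ]
    hit <- ex %>%
      dplyr::group_by(.data$gene_id, .data$transcript_id) %>%
      dplyr::summarise(gs = min(.data$start), ge = max(.data$end),
                       .groups = "drop") %>%
      dplyr::filter(.data$gs <= left_junction + 1L, .data$ge > left_junction)
    if (nrow(hit)) {
      in_gene <- hit$gene_id[1]
      tx_ex <- ex[ex$transcript_id == hit$transcript_id[1], ]
      tx_ex <- tx_ex[order(tx_ex$start), ]
      k <- sum(tx_ex$end <= left_junction)
      if (k >= 1 && k < nrow(tx_ex) && tx_ex$start[k + 1] > left_junction) {
        # intron index in transcript orientation
        intron_index <- if (tx_ex$strand[1] == "-") nrow(tx_ex) - k else k
      }
    }
  }
  truth <- tibble(
    scaffold = scaffold, construct = transgene$name,
    left_junction = as.integer(left_junction), deleted = as.integer(deleted),
    right_resume = as.integer(right_from), orientation = orientation,
    zygosity = zygosity, disrupted_gene = in_gene,
    intron_index = intron_index
  )
  list(haplotypes = haplotypes, truth = truth)
}

#' @rdname apply_insertion
#' @param record One-row FASTA tibble.
#' @export
as_haplotype <- function(record) {
  L <- nchar(record$seq[1])
  list(name = record$id[1], seq = record$seq[1],
       blocks = tibble(ref = record$id[1], ref_start = 1L, ref_end = L,
                       strand = "+", hap_start = 1L, hap_end = L))
}

#' Read-simulation configuration
#'
#' Defaults follow the characterized libraries: 2 x 125 nt reads from
#' fragments with a 700-bp peak length; the fragment-length spread is not
#' published, so the default SD of 50 is a package choice (normal draw
#' truncated at `2 * read_length`).
#'
#' @param read_length Read length in nt.
#' @param insert_mean,insert_sd Fragment-length distribution parameters (bp).
#' @param depth Mean sequenced depth over the haplotypes.
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param seed Integer seed.
#' @export
read_sim_config <- function(read_length = 125L, insert_mean = 700,
                            insert_sd = 50, depth = 30, error_rate = 0,
                            seed = 1L) {
  stopifnot(read_length >= 1, read_length <= insert_mean,
            error_rate >= 0, error_rate < 1, depth > 0)
  list(read_length = as.integer(read_length), insert_mean = insert_mean,
       insert_sd = insert_sd, depth = depth, error_rate = error_rate,
       seed = as.integer(seed))
}

#' Simulate paired-end reads with exact truth alignments
#'
#' Fragments are drawn uniformly along the supplied haplotypes; each yields
#' an FR read pair. Truth alignments are emitted directly from simulation
#' coordinates against the references named in the haplotype block maps:
#' pairs straddling an integration junction become bridging pairs, reads
#' overlapping a junction become chimeric primary + supplementary records
#' with soft clips encoding the split (supplementary flag on the shorter
#' segment). Base errors are substitutions at `error_rate`.
#'
#' @param haplotypes List of haplotypes (`name`, `seq`, `blocks`), e.g. from
#'   [apply_insertion()] / [as_haplotype()].
#' @param sq Reference dictionary tibble (`name`, `length`) for the truth SAM.
#' @param config A [read_sim_config()].
#' @param qname_prefix Prefix for read names.
#' @return A list with `alignments` (truth SAM tibble, `"sq"` attribute set)
#'   and `fragments` (per-fragment truth tibble).
#' @export
simulate_genomic_pairs <- function(haplotypes, sq, config = read_sim_config(),
                                   qname_prefix = "frag") {
  rl <- config$read_length
  withr::with_seed(config$seed, {
    hlen <- vapply(haplotypes, function(h) nchar(h$seq), integer(1))
    # depth is reference coverage: haplotypes of one individual share it
    n_frag <- max(1L, round(config$depth * mean(hlen) / (2 * rl)))
    hap_i <- sample.int(length(haplotypes), n_frag, replace = TRUE,
                        prob = hlen)
    flen <- pmax(round(stats::rnorm(n_frag, config$insert_mean,
                                    config$insert_sd)), 2L * rl)
    flen <- pmin(flen, hlen[hap_i])
    fstart <- floor(stats::runif(n_frag) * (hlen[hap_i] - flen + 1)) + 1L
    qname <- paste0(qname_prefix, seq_len(n_frag))
    frags <- tibble(qname = qname, hap = hap_i, start = as.integer(fstart),
                    len = as.integer(flen))
    recs <- vector("list", 2L * length(haplotypes))
    k <- 0L
    for (h in seq_along(haplotypes)) {
      sel <- frags[frags$hap == h, ]
      if (!nrow(sel)) next
      hp <- haplotypes[[h]]
      e <- sel$start + sel$len - 1L
      r1 <- extract_reads(hp, sel$start, sel$start + rl - 1L, FALSE,
                          sel$qname, config$error_rate)
      r2 <- extract_reads(hp, e - rl + 1L, e, TRUE, sel$qname,
                          config$error_rate)
      k <- k + 1L; recs[[k]] <- pair_up(r1, r2, TRUE, sel)
      k <- k + 1L; recs[[k]] <- pair_up(r2, r1, FALSE, sel)
    }
    aln <- dplyr::bind_rows(recs[seq_len(k)])
    aln <- finalize_alignments(aln, sq)
    list(alignments = aln, fragments = frags)
  })
}

# map haplotype-interval reads to truth records (possibly split)
extract_reads <- function(hap, starts, ends, reverse, qname, error_rate) {
  seqs <- substring(hap$seq, starts, ends)
  rl <- ends - starts + 1L
  if (error_rate > 0) {
    n_err <- stats::rbinom(length(seqs), rl, error_rate)
    for (i in which(n_err > 0)) {
      at <- sample.int(rl[i], n_err[i])
      s <- strsplit(seqs[i], "")[[1]]
      s[at] <- vapply(s[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      seqs[i] <- paste(s, collapse = "")
    }
  } else {
    n_err <- integer(length(seqs))
  }
  bl <- hap$blocks
  bi_s <- findInterval(starts, bl$hap_start)
  bi_e <- findInterval(ends, bl$hap_start)
  simple <- bi_s == bi_e
  out <- vector("list", 2)
  # single-block reads (vectorized)
  if (any(simple)) {
    i <- which(simple)
    b <- bi_s[i]
    plus <- bl$strand[b] == "+"
    off_s <- starts[i] - bl$hap_start[b]
    off_e <- ends[i] - bl$hap_start[b]
    pos <- ifelse(plus, bl$ref_start[b] + off_s, bl$ref_end[b] - off_e)
    qn <- qname[i]
    out[[1]] <- tibble(
      qname = qn, rname = bl$ref[b], pos = as.integer(pos),
      cigar = paste0(rl[i], "M"),
      seq = ifelse(plus, seqs[i], revcomp_chr(seqs[i])),
      reverse = xor(rep(reverse, length(i)), !plus),
      supplementary = FALSE, nm = n_err[i], primary_of = qn
    )
  }
  # junction-spanning (chimeric) reads
  if (any(!simple)) {
    out[[2]] <- dplyr::bind_rows(lapply(which(!simple), function(i) {
      segs <- split_read_segments(bl, starts[i], ends[i])
      segs$qname <- qname[i]
      longest <- which.max(segs$mlen)
      segs$supplementary <- seq_len(nrow(segs)) != longest
      segs$seq_fwd <- seqs[i]
      segs$seq <- ifelse(segs$plus, seqs[i], revcomp_chr(seqs[i]))
      segs$cigar <- ifelse(
        segs$plus,
        paste0(clip_str(segs$qs - 1L), segs$mlen, "M",
               clip_str(rl[i] - segs$qe)),
        paste0(clip_str(rl[i] - segs$qe), segs$mlen, "M",
               clip_str(segs$qs - 1L))
      )
      segs$reverse <- xor(reverse, !segs$plus)
      segs$nm <- 0L
      segs$primary_of <- qname[i]
      segs[, c("qname", "rname", "pos", "cigar", "seq", "reverse",
               "supplementary", "nm", "primary_of")]
    }))
  }
  dplyr::bind_rows(out)
}

clip_str <- function(n) ifelse(n > 0, paste0(n, "S"), "")

revcomp_chr <- function(x) {
  if (!length(x)) return(character())
  revcomp(x)
}

split_read_segments <- function(bl, a, b) {
  js <- which(bl$hap_end >= a & bl$hap_start <= b)
  dplyr::bind_rows(lapply(js, function(j) {
    x <- max(a, bl$hap_start[j]); y <- min(b, bl$hap_end[j])
    plus <- bl$strand[j] == "+"
    pos <- if (plus) bl$ref_start[j] + (x - bl$hap_start[j]) else
      bl$ref_end[j] - (y - bl$hap_start[j])
    tibble(rname = bl$ref[j], pos = as.integer(pos), plus = plus,
           qs = x - a + 1L, qe = y - a + 1L, mlen = y - x + 1L)
  }))
}

pair_up <- function(self, mate, first, frags) {
  mate_primary <- mate[!mate$supplementary, ]
  m <- match(self$primary_of, mate_primary$qname)
  fl <- frags$len[match(self$primary_of, frags$qname)]
  # proper iff both reads map as single full-length records on one reference
  self_simple <- !grepl("S", self$cigar)
  mate_simple <- !grepl("S", mate_primary$cigar[m])
  proper <- self_simple & mate_simple & self$rname == mate_primary$rname[m]
  flag <- 1L +
    ifelse(proper & !self$supplementary, 2L, 0L) +
    ifelse(self$reverse, 16L, 0L) +
    ifelse(mate_primary$reverse[m], 32L, 0L) +
    (if (first) 64L else 128L) +
    ifelse(self$supplementary, 2048L, 0L)
  tlen <- ifelse(proper & !self$supplementary,
                 ifelse(self$pos <= mate_primary$pos[m], fl, -fl), 0L)
  tibble(
    qname = self$qname, flag = flag, rname = self$rname, pos = self$pos,
    mapq = 60L, cigar = self$cigar, rnext = mate_primary$rname[m],
    pnext = mate_primary$pos[m], tlen = as.integer(tlen), seq = self$seq,
    qual = strrep("I", nchar(self$seq)), nm = as.integer(self$nm),
    score = NA_integer_, tags = NA_character_
  )
}

finalize_alignments <- function(aln, sq) {
  aln <- decode_sam_flags(aln)
  known <- unique(aln$rname)
  missing <- setdiff(known, sq$name)
  if (length(missing)) {
    stop("simulated reference not in sq dictionary: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(aln, "sq") <- sq
  aln
}

#' Turn truth alignments back into sequencing reads
#'
#' Extracts the read set (5'->3' as sequenced, phred+33 qualities) from the
#' primary records of a truth alignment tibble, e.g. to write FASTQ for an
#' external aligner.
#'
#' @param aln Alignment tibble from the simulators.
#' @param mate 1 or 2: which mate to extract.
#' @return Tibble `id`, `seq`, `qual`.
#' @export
alignments_to_reads <- function(aln, mate = 1L) {
  sel <- aln[!aln$is_secondary & !aln$is_supplementary &
               aln$is_first == (mate == 1L), ]
  seq <- ifelse(sel$is_reverse, revcomp_chr(sel$seq), sel$seq)
  tibble(id = paste0(sel$qname, "/", mate), seq = seq,
         qual = ifelse(sel$is_reverse,
                       vapply(sel$qual, function(q) {
                         paste(rev(strsplit(q, "")[[1]]), collapse = "")
                       }, character(1), USE.NAMES = FALSE),
                       sel$qual))
}

#' Reference dictionary for a genome plus constructs
#'
#' @param genome FASTA tibble.
#' @param constructs List of [transgene_spec()] objects.
#' @return Tibble `name`, `length` usable as a SAM `@SQ` dictionary.
#' @export
reference_dict <- function(genome, constructs = list()) {
  dplyr::bind_rows(
    tibble(name = genome$id, length = nchar(genome$seq)),
    dplyr::bind_rows(lapply(constructs, function(cs) {
      tibble(name = cs$name, length = nchar(cs$seq))
    }))
  )
}
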