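# Shared in-memory fixtures and independent oracles.

rand_chrom <- function(len, seed = NULL) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# The canonical toy transcriptome: one coding gene on "+" with exons
# [100,200) + [300,400) and CDS [150,200) + [300,350); one non-coding
# single-exon gene; one minus-strand single-exon coding gene [600,700)
# with CDS [620,680).
toy_index <- function(genome_seq = NULL, config = annotation_config()) {
  exon_tab <- data.frame(
    transcript_id = c("TX1", "TX1", "NC1", "TXM"),
    gene_id = c("G1", "G1", "G2", "G3"),
    gene_name = c("GENE1", "GENE1", "GENE2", "GENE3"),
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "protein_coding"),
    chrom = "chr1", strand = c("+", "+", "+", "-"),
    start = c(100L, 300L, 450L, 600L),
    end = c(200L, 400L, 520L, 700L))
  cds_tab <- data.frame(transcript_id = c("TX1", "TX1", "TXM"),
                        start = c(150L, 300L, 620L),
                        end = c(200L, 350L, 680L))
  if (is.null(genome_seq)) {
    set.seed(7)
    genome_seq <- rand_chrom(1500)
  }
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_seq))
  modannot:::build_annotation_index(exon_tab, cds_tab, genome, config)
}

# Random annotation with forced overlaps between genes: gene starts are drawn
# from a small window so CDS/intron/UTR/promoter features of different genes
# collide; both strands, coding and non-coding.
rand_index <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:6, 1)
  exon_rows <- list(); cds_rows <- list()
  for (g in seq_len(n_genes)) {
    strand <- sample(c("+", "-"), 1)
    coding <- stats::runif(1) < 0.7
    n_ex <- sample(1:3, 1)
    widths <- sample(40:150, n_ex, replace = TRUE)
    introns <- if (n_ex > 1) sample(30:100, n_ex - 1, replace = TRUE) else
      integer(0)
    gstart <- sample(0:1500, 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- gstart
    for (i in seq_len(n_ex)) {
      starts[i] <- pos; ends[i] <- pos + widths[i]
      pos <- ends[i] + if (i < n_ex) introns[i] else 0L
    }
    tid <- sprintf("RT%02d", g)
    exon_rows[[g]] <- data.frame(
      transcript_id = tid, gene_id = sprintf("RG%02d", g),
      gene_name = sprintf("RGENE%02d", g),
      biotype = if (coding) "protein_coding" else "lincRNA",
      chrom = "chrR", strand = strand, start = starts, end = ends)
    if (coding) {
      L <- sum(widths)
      u5 <- sample(5:max(5, L %/% 4), 1)
      clen <- max(6L, ((sample(6:max(6, L %/% 2), 1)) %/% 3L) * 3L)
      clen <- min(clen, L - u5 - 5L)
      if (clen >= 3) {
        m <- modannot:::new_transcript_model(
          tid, "tmp", "tmp", "protein_coding", "chrR", strand,
          data.frame(start = starts, end = ends))
        cg <- modannot:::tx_range_to_genomic(m, u5, u5 + clen)
        cds_rows[[length(cds_rows) + 1L]] <-
          data.frame(transcript_id = tid, start = cg$start, end = cg$end)
      }
    }
  }
  exon_tab <- do.call(rbind, exon_rows)
  cds_tab <- if (length(cds_rows)) do.call(rbind, cds_rows) else
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0))
  chrom_len <- max(exon_tab$end) + 1200L
  genome <- Biostrings::DNAStringSet(
    stats::setNames(rand_chrom(chrom_len), "chrR"))
  modannot:::build_annotation_index(exon_tab, cds_tab, genome,
                                    annotation_config())
}

rand_sites <- function(index, n, seed) {
  set.seed(seed)
  len <- unname(index$seqlens[1])
  start <- sample(0:(len - 160L), n, replace = TRUE)
  site_set(data.frame(
    chrom = names(index$seqlens)[1],
    start = start,
    end = start + sample(1:150, n, replace = TRUE),
    name = sprintf("r%03d", seq_len(n)),
    score = 0,
    strand = sample(c("+", "-", "."), n, replace = TRUE)), dedup = FALSE)
}

# Independent brute-force assignment oracle: enumerates every (site, feature)
# overlap pair by direct interval arithmetic and ranks candidates with
# explicit loops over the priority order, feature-midpoint distance and
# gene id. Shares no code with assign_features().
oracle_assign <- function(sites, index) {
  feats <- as.data.frame(index$features)
  prio <- c("CDS", "UTR3", "UTR5", "intron", "exon_nc", "promoter",
            "downstream")
  out <- character(nrow(sites)); gene <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s0 <- sites$start[i]; e0 <- sites$end[i]; st <- sites$strand[i]
    best <- NULL
    for (j in seq_len(nrow(feats))) {
      f_s0 <- feats$start[j] - 1L; f_e0 <- feats$end[j]
      if (as.character(feats$seqnames[j]) != sites$chrom[i]) next
      if (max(s0, f_s0) >= min(e0, f_e0)) next
      if (st != "." && st != as.character(feats$strand[j])) next
      cand <- list(
        prio = which(prio == feats$category[j]),
        dist = abs((f_s0 + f_e0) %/% 2L - (s0 + e0) %/% 2L),
        gene = feats$gene_id[j], tx = feats$transcript_id[j],
        cat = feats$category[j])
      if (is.null(best) ||
          cand$prio < best$prio ||
          (cand$prio == best$prio && cand$dist < best$dist) ||
          (cand$prio == best$prio && cand$dist == best$dist &&
             cand$gene < best$gene)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      out[i] <- "intergenic"
    } else {
      out[i] <- best$cat
      gene[i] <- best$gene
    }
  }
  data.frame(category = out, gene_id = gene)
}

# Exhaustive hypergeometric upper tail by direct combinatorial enumeration.
hyper_tail_oracle <- function(x, K, N, n) {
  if (x <= 0) return(1)
  tot <- choose(N, n)
  sum(vapply(x:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / tot
}

# One shared 20-gene end-to-end fixture, built lazily and reused by tests.
.fixture_cache <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- run_fixtures(
      file.path(tempdir(), "modannot_shared_fix"),
      spec = fixture_spec(n_genes = 20, seed = 42),
      n_sites = 400,
      placement = placement_region_rates(c(utr5 = 1, cds = 1, utr3 = 2)),
      site_seed = 43)
  }
  .fixture_cache$fx
}

# A 4-gene all-coding annotation with identical structure (single exon,
# utr5 150 / cds 300 / utr3 150) at known positions, used for hand-checkable
# profile arithmetic.
four_tx_index <- function(seqlen = 20000L) {
  starts <- c(1200L, 5000L, 9000L, 13000L)
  exon_tab <- data.frame(
    transcript_id = sprintf("P%d", 1:4), gene_id = sprintf("GP%d", 1:4),
    gene_name = sprintf("GP%d", 1:4), biotype = "protein_coding",
    chrom = "chrP", strand = "+", start = starts, end = starts + 600L)
  cds_tab <- data.frame(transcript_id = sprintf("P%d", 1:4),
                        start = starts + 150L, end = starts + 450L)
  genome <- Biostrings::DNAStringSet(
    stats::setNames(rand_chrom(seqlen), "chrP"))
  modannot:::build_annotation_index(exon_tab, cds_tab, genome)
}
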