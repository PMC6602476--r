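## Deterministic synthetic-data generator: toy genome FASTA, GTF, site BEDs
## with ground truth, gene lists and GMT collections. The generator is
## first-class, tested code; every downstream surface is validated against the
## ground truth it emits.

#' Specification of a synthetic toy transcriptome
#'
#' Defaults describe the standard desk-scale validation genome: one ~250 kb
#' chromosome, 50 genes on both strands, a biotype mix dominated by
#' protein-coding genes, multi-exon structures with valid start/stop codons at
#' the CDS termini, and mRNA regions long enough (>= 100 nt) for default
#' 100-bin metagene profiles. The same seed yields byte-identical outputs.
#'
#' @param n_genes Number of genes (default 50).
#' @param seed Random seed (default 1).
#' @param strand_mix Fraction of minus-strand genes (default 0.5).
#' @param biotype_mix Named fractions over `protein_coding`, `lincRNA`,
#'   `miRNA`; must sum to 1.
#' @param utr5_len,cds_len,utr3_len Length ranges (nt) for the mRNA regions;
#'   CDS lengths are rounded to multiples of 3.
#' @param lincrna_len,mirna_len Length ranges for non-coding transcripts.
#' @param n_exons Candidate exon counts for multi-exon genes.
#' @param intron_len Intron length range (nt).
#' @param gene_gap Intergenic gap range (nt).
#' @param overlap_inject Fraction of genes deliberately placed overlapping
#'   their upstream neighbour (default 0: non-overlapping).
#' @param chrom Chromosome name.
#' @return A list of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_genes = 50L, seed = 1L, strand_mix = 0.5,
                         biotype_mix = c(protein_coding = 0.8,
                                         lincRNA = 0.15, miRNA = 0.05),
                         utr5_len = c(150L, 300L), cds_len = c(300L, 900L),
                         utr3_len = c(150L, 400L),
                         lincrna_len = c(300L, 800L),
                         mirna_len = c(70L, 90L),
                         n_exons = 1:4, intron_len = c(100L, 400L),
                         gene_gap = c(2200L, 3000L), overlap_inject = 0,
                         chrom = "chrS1") {
  stopifnot(abs(sum(biotype_mix) - 1) < 1e-9, n_genes >= 1,
            all(c(utr5_len, cds_len, utr3_len, intron_len) >= 1))
  structure(as.list(environment()), class = "FixtureSpec")
}

.rint <- function(rng) sample(seq.int(rng[1], rng[2]), 1L)

.rand_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.revcomp_chars <- function(x) {
  rev(chartr("ACGT", "TGCA", x))
}

# cut [0, L) into k exon pieces with every piece >= min_w
.cut_points <- function(L, k, min_w = 20L) {
  if (k == 1) return(integer(0))
  for (try in 1:200) {
    cp <- sort(sample(seq.int(min_w, L - min_w), k - 1L))
    if (all(diff(c(0L, cp, L)) >= min_w)) return(cp)
  }
  stop("cannot cut length ", L, " into ", k, " exons of >= ", min_w, " nt")
}

#' Generate a synthetic transcriptome (FASTA + GTF)
#'
#' Lays out multi-exon coding and non-coding genes on both strands of one
#' synthetic chromosome, plants ATG/TAA codons at the CDS termini, and writes
#' a genome FASTA and a GTF (gene/transcript/exon/CDS records with
#' `gene_biotype` attributes; CDS records include the stop codon). The GTF
#' round-trips through [load_annotation()] without warnings.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `fasta`, `gtf` (paths), `genes` (layout table) and
#'   `chrom_len`.
#' @export
make_transcriptome <- function(spec = fixture_spec(), dir = tempfile("fix")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(spec$seed, {
    genes <- list()
    cur <- 1500L
    last_end <- 0L
    for (g in seq_len(spec$n_genes)) {
      biotype <- sample(names(spec$biotype_mix), 1, prob = spec$biotype_mix)
      strand <- if (stats::runif(1) < spec$strand_mix) "-" else "+"
      if (biotype == "protein_coding") {
        u5 <- .rint(spec$utr5_len); u3 <- .rint(spec$utr3_len)
        cds <- (.rint(spec$cds_len) %/% 3L) * 3L
        L <- u5 + cds + u3
      } else if (biotype == "lincRNA") {
        u5 <- u3 <- cds <- NA_integer_
        L <- .rint(spec$lincrna_len)
      } else {
        u5 <- u3 <- cds <- NA_integer_
        L <- .rint(spec$mirna_len)
      }
      k <- if (biotype == "miRNA") 1L else sample(spec$n_exons, 1L)
      cp <- .cut_points(L, k)
      exon_tx <- cbind(start = c(0L, cp), end = c(cp, L))
      introns <- if (k > 1) vapply(seq_len(k - 1L), function(i)
        .rint(spec$intron_len), integer(1)) else integer(0)

      txseq <- .rand_dna(L)
      if (biotype == "protein_coding") {
        txseq[(u5 + 1):(u5 + 3)] <- c("A", "T", "G")
        txseq[(u5 + cds - 2):(u5 + cds)] <- c("T", "A", "A")
      }

      if (spec$overlap_inject > 0 && g > 1 &&
          stats::runif(1) < spec$overlap_inject) {
        # pull the start back inside the previous gene's span
        cur <- max(0L, last_end - sample(100:800, 1L))
      }
      # genomic exon intervals, ascending; on "-" the genomic order is the
      # reverse of the transcript order
      widths <- exon_tx[, "end"] - exon_tx[, "start"]
      g_order <- if (strand == "+") seq_len(k) else rev(seq_len(k))
      starts <- integer(k); ends <- integer(k)
      pos <- cur
      for (j in seq_len(k)) {
        tx_i <- g_order[j]
        starts[tx_i] <- pos
        ends[tx_i] <- pos + widths[tx_i]
        pos <- ends[tx_i] + if (j < k) introns[min(j, length(introns))] else 0L
      }
      gene_end <- pos
      genes[[g]] <- list(
        gene_id = sprintf("G%03d", g), transcript_id = sprintf("T%03d", g),
        gene_name = sprintf("GENE%03d", g), biotype = biotype,
        strand = strand, L = L, u5 = u5, cds = cds, u3 = u3,
        exon_tx = exon_tx, exon_start = starts, exon_end = ends,
        txseq = txseq, span = c(cur, gene_end))
      last_end <- gene_end
      cur <- gene_end + .rint(spec$gene_gap)
    }
    chrom_len <- cur + 1500L
    chrom <- .rand_dna(chrom_len)
    for (gg in genes) {
      for (i in seq_len(nrow(gg$exon_tx))) {
        seg <- gg$txseq[(gg$exon_tx[i, 1] + 1):gg$exon_tx[i, 2]]
        if (gg$strand == "-") seg <- .revcomp_chars(seg)
        chrom[(gg$exon_start[i] + 1):gg$exon_end[i]] <- seg
      }
    }

    fasta <- file.path(dir, "genome.fa")
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chrom, collapse = ""), spec$chrom))
    Biostrings::writeXStringSet(genome, fasta)

    gtf <- file.path(dir, "annotation.gtf")
    lines <- character(0)
    emit <- function(type, s0, e0, gg, extra = "") {
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";%s',
        gg$gene_id, gg$transcript_id, gg$gene_name, gg$biotype, extra)
      sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
              spec$chrom, type, s0 + 1L, e0, gg$strand, attrs)
    }
    for (gg in genes) {
      lines <- c(lines, emit("gene", gg$span[1], gg$span[2], gg),
                 emit("transcript", gg$span[1], gg$span[2], gg))
      for (i in seq_len(nrow(gg$exon_tx))) {
        lines <- c(lines,
                   emit("exon", gg$exon_start[i], gg$exon_end[i], gg,
                        sprintf(' exon_number "%d";', i)))
      }
      if (gg$biotype == "protein_coding") {
        # a throwaway model (no CDS yet) supplies the tx->genome mapping
        m <- new_transcript_model(
          gg$transcript_id, gg$gene_id, gg$gene_name, gg$biotype,
          spec$chrom, gg$strand,
          data.frame(start = gg$exon_start, end = gg$exon_end))
        cdsg <- tx_range_to_genomic(m, gg$u5, gg$u5 + gg$cds)
        for (i in seq_len(nrow(cdsg))) {
          lines <- c(lines, emit("CDS", cdsg$start[i], cdsg$end[i], gg))
        }
      }
    }
    writeLines(lines, gtf)

    gene_tab <- data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      transcript_id = vapply(genes, `[[`, character(1), "transcript_id"),
      biotype = vapply(genes, `[[`, character(1), "biotype"),
      strand = vapply(genes, `[[`, character(1), "strand"),
      tx_length = vapply(genes, `[[`, integer(1), "L"),
      start = vapply(genes, function(x) x$span[1], integer(1)),
      end = vapply(genes, function(x) x$span[2], integer(1)))
    list(fasta = fasta, gtf = gtf, genes = gene_tab, chrom_len = chrom_len)
  })
}

#' Anchor-relative site placement model
#'
#' Sites are drawn per transcript around a transcript-space anchor with a
#' Gaussian offset (rounded to integers, clipped to the transcript).
#'
#' @param anchor One of `"start_codon"`, `"stop_codon"`, `"TSS"`, `"TES"`.
#' @param sd Standard deviation of the offset in nucleotides.
#' @export
placement_anchor <- function(anchor = "stop_codon", sd = 30) {
  list(type = "anchor", anchor = anchor, sd = sd)
}

#' Per-region rate site placement model
#'
#' Sites are distributed over (transcript, region) pairs with probability
#' proportional to `rate x region length`; positions are uniform within the
#' chosen region.
#'
#' @param rates Named rates per kb for a subset of `utr5`, `cds`, `utr3`.
#' @export
placement_region_rates <- function(rates = c(cds = 1, utr3 = 2)) {
  list(type = "region_rates", rates = rates)
}

.truth_category <- function(model, tx) {
  if (!is_coding(model)) return("exon_nc")
  if (tx < model$cds_range[1]) "UTR5"
  else if (tx < model$cds_range[2]) "CDS"
  else "UTR3"
}

#' Generate synthetic modification sites with ground truth
#'
#' Draws sites in transcript space per the placement model on the
#' representative coding transcripts, projects them to the genome via
#' [tx_to_genome()], and emits a ground-truth table (host gene/transcript,
#' true category, realized anchor offset). With `planted_motif`, the genome
#' sequence under every site is rewritten so that a concrete instance of the
#' IUPAC motif sits with its modified base exactly at the site (strand-aware);
#' the edited genome is returned and must be used downstream.
#'
#' @param index An `AnnotationIndex` over the fixture transcriptome.
#' @param n Number of sites (default 2000).
#' @param placement A [placement_anchor()] or [placement_region_rates()].
#' @param width Site width in nt (default 1; wider values emulate peaks,
#'   centred genomically on the drawn base).
#' @param seed Random seed.
#' @param planted_motif Optional IUPAC motif to plant under every site.
#' @return List with `sites` (a `SiteSet`), `truth` (data frame), and
#'   `genome` (the index genome, edited when a motif was planted).
#' @export
make_sites <- function(index, n = 2000L,
                       placement = placement_anchor("stop_codon", sd = 30),
                       width = 1L, seed = 1L, planted_motif = NULL) {
  .with_seed(seed, {
    coding <- Filter(is_coding, index$rep_models)
    if (!length(coding)) stop("fixture transcriptome has no coding genes")
    draws <- list()
    if (placement$type == "anchor") {
      anchors <- vapply(coding, function(m) switch(placement$anchor,
        start_codon = m$start_codon_pos, stop_codon = m$stop_codon_pos,
        TSS = 0L, TES = m$tx_length - 1L), integer(1))
      pick <- sample.int(length(coding), n, replace = TRUE)
      off <- as.integer(round(stats::rnorm(n, 0, placement$sd)))
      for (i in seq_len(n)) {
        m <- coding[[pick[i]]]
        tx <- min(max(anchors[pick[i]] + off[i], 0L), m$tx_length - 1L)
        draws[[i]] <- list(m = m, tx = tx, off = tx - anchors[pick[i]])
      }
    } else {
      cells <- list()
      for (m in coding) {
        rngs <- list(utr5 = m$utr5_range, cds = m$cds_range,
                     utr3 = m$utr3_range)
        for (r in names(placement$rates)) {
          len <- diff(rngs[[r]])
          if (len > 0) cells[[length(cells) + 1L]] <-
              list(m = m, rng = rngs[[r]],
                   w = placement$rates[[r]] * len / 1000)
        }
      }
      wts <- vapply(cells, `[[`, numeric(1), "w")
      pick <- sample.int(length(cells), n, replace = TRUE, prob = wts)
      for (i in seq_len(n)) {
        cell <- cells[[pick[i]]]
        tx <- cell$rng[1] + sample.int(diff(cell$rng), 1L) - 1L
        draws[[i]] <- list(m = cell$m, tx = tx, off = NA_integer_)
      }
    }

    genome <- index$genome
    if (!is.null(planted_motif)) {
      motif <- toupper(gsub("U", "T", planted_motif))
      moff <- .default_motif_offset(motif)
      code <- Biostrings::IUPAC_CODE_MAP
      chrom_chars <- lapply(as.character(genome), function(s)
        strsplit(s, "", fixed = TRUE)[[1]])
    }
    nS <- length(draws)
    tid <- vapply(draws, function(d) d$m$transcript_id, character(1))
    tx <- vapply(draws, function(d) d$tx, integer(1))
    off <- vapply(draws, function(d) d$off, integer(1))
    if (!is.null(planted_motif)) {
      planted_at <- list()  # per-transcript positions already carrying a motif
      for (i in seq_len(nS)) {
        m <- draws[[i]]$m
        # keep the whole motif inside the transcript
        tx[i] <- min(max(tx[i], moff), m$tx_length - (nchar(motif) - moff))
        # avoid overlapping plantings (a later instance would overwrite an
        # earlier one): nudge to a free position at least motif-length away
        used <- planted_at[[m$transcript_id]]
        anchor_i <- if (is.na(off[i])) NA_integer_ else tx[i] - off[i]
        tries <- 0L
        while (length(used) && any(abs(used - tx[i]) < nchar(motif)) &&
               tries < 100L) {
          tx[i] <- moff + sample.int(m$tx_length - nchar(motif) + 1L, 1L) - 1L
          tries <- tries + 1L
        }
        if (!is.na(anchor_i)) off[i] <- tx[i] - anchor_i
        planted_at[[m$transcript_id]] <- c(used, tx[i])
        inst <- vapply(strsplit(motif, "")[[1]], function(ch) {
          opts <- strsplit(code[[ch]], "")[[1]]
          opts[sample.int(length(opts), 1L)]
        }, character(1))
        tpos <- (tx[i] - moff) + seq_len(nchar(motif)) - 1L
        gpos <- tx_to_genome(m, tpos)
        bases <- if (m$strand == "-") chartr("ACGT", "TGCA", inst) else inst
        chrom_chars[[m$chrom]][gpos + 1L] <- bases
      }
      genome <- Biostrings::DNAStringSet(stats::setNames(
        vapply(chrom_chars, paste, character(1), collapse = ""),
        names(genome)))
    }
    g <- integer(nS); chroms <- character(nS); strands <- character(nS)
    genes <- character(nS); cats <- character(nS)
    for (t in unique(tid)) {
      m <- index$transcripts[[t]]
      sel <- which(tid == t)
      g[sel] <- tx_to_genome(m, tx[sel])
      chroms[sel] <- m$chrom; strands[sel] <- m$strand
      genes[sel] <- m$gene_id
      cats[sel] <- vapply(tx[sel], function(p) .truth_category(m, p),
                          character(1))
    }
    s0 <- pmax(0L, g - width %/% 2L)
    e0 <- pmin(unname(index$seqlens[chroms]), s0 + width)
    nm <- sprintf("site%05d", seq_len(nS))
    sites <- site_set(
      data.frame(chrom = chroms, start = s0, end = e0, name = nm,
                 score = 1, strand = strands),
      source_label = "fixture_sites", dedup = FALSE)
    truth <- data.frame(name = nm, chrom = chroms, start = s0, end = e0,
                        gene_id = genes, transcript_id = tid, tx_pos = tx,
                        category = cats, anchor_offset = off)
    list(sites = sites, truth = truth, genome = genome)
  })
}

#' Write a synthetic GMT collection over a gene universe
#'
#' The first set (`SET_ENRICHED`) is drawn mostly from `enriched_genes`, the
#' remaining sets are uniform draws from the universe.
#'
#' @param universe Character vector of gene ids.
#' @param enriched_genes Genes favoured by the first set.
#' @param path Output GMT path.
#' @param n_sets Total number of sets (default 8).
#' @param set_size Range of set sizes.
#' @param seed Random seed.
#' @return `path`, invisibly.
#' @export
make_gene_sets <- function(universe, enriched_genes, path, n_sets = 8L,
                           set_size = c(5L, 20L), seed = 1L) {
  .with_seed(seed, {
    lines <- character(0)
    sz <- min(max(set_size[1], length(enriched_genes)), set_size[2])
    first <- unique(c(
      sample(enriched_genes, min(length(enriched_genes), sz)),
      sample(universe, max(0, sz - length(enriched_genes)))))
    lines <- c(lines, paste(c("SET_ENRICHED", "planted enriched set", first),
                            collapse = "\t"))
    for (i in seq_len(n_sets - 1L)) {
      sz <- .rint(set_size)
      genes <- sample(universe, min(sz, length(universe)))
      lines <- c(lines, paste(c(sprintf("SET_RAND%02d", i),
                                "random set", genes), collapse = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
  })
}
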