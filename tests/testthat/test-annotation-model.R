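test_that("toy transcript model derives the expected region partition", {
  idx <- toy_index()
  m <- idx$transcripts[["TX1"]]
  expect_equal(m$tx_length, 200L)
  expect_equal(m$utr5_range, c(0L, 50L))
  expect_equal(m$cds_range, c(50L, 150L))
  expect_equal(m$utr3_range, c(150L, 200L))
  expect_equal(diff(m$utr5_range) + diff(m$cds_range) + diff(m$utr3_range),
               m$tx_length)
  # derived catalog
  expect_equal(nrow(m$introns), nrow(m$exons) - 1L)
  expect_equal(m$introns$start, 200L)
  expect_equal(m$introns$end, 300L)
  expect_equal(m$splice5_pos, 99L)
  expect_equal(m$splice3_pos, 100L)
  expect_equal(m$start_codon_pos, 50L)
  expect_equal(m$stop_codon_pos, 149L)
})

test_that("non-coding and single-exon transcripts have absent ranges", {
  idx <- toy_index()
  nc <- idx$transcripts[["NC1"]]
  expect_null(nc$cds)
  expect_null(nc$utr5_range)
  expect_equal(nrow(nc$introns), 0L)
  expect_length(nc$splice5_pos, 0)
  expect_true(is.na(nc$start_codon_pos))
})

test_that("genome/transcript coordinate mapping matches hand-computed cases", {
  idx <- toy_index()
  m <- idx$transcripts[["TX1"]]
  expect_equal(genome_to_tx(m, 150L), 50L)
  expect_equal(genome_to_tx(m, 100L), 0L)
  expect_equal(genome_to_tx(m, 250L), NA_integer_)   # intronic
  expect_equal(genome_to_tx(m, 399L), 199L)
  # minus strand single exon [600, 700): first transcript base is gpos 699
  mm <- idx$transcripts[["TXM"]]
  expect_equal(genome_to_tx(mm, 699L), 0L)
  expect_equal(genome_to_tx(mm, 600L), 99L)
})

test_that("mapping equals a brute-force exon-walk oracle and round-trips", {
  for (seed in c(11, 12, 13)) {
    idx <- rand_index(seed)
    for (m in idx$transcripts) {
      # oracle: walk exons in transcript orientation, emitting genomic
      # positions in transcript order
      ord <- if (m$strand == "+") seq_len(nrow(m$exons)) else
        rev(seq_len(nrow(m$exons)))
      gpos_in_tx_order <- unlist(lapply(ord, function(i) {
        p <- seq.int(m$exons$start[i], m$exons$end[i] - 1L)
        if (m$strand == "-") rev(p) else p
      }))
      expect_equal(genome_to_tx(m, gpos_in_tx_order),
                   seq_along(gpos_in_tx_order) - 1L)
      expect_equal(tx_to_genome(m, seq_along(gpos_in_tx_order) - 1L),
                   gpos_in_tx_order)
      # round trip over every exonic genomic position
      expect_equal(tx_to_genome(m, genome_to_tx(m, gpos_in_tx_order)),
                   gpos_in_tx_order)
      # minus-strand mapping is strictly decreasing in genomic coordinate
      if (m$strand == "-") {
        g_sorted <- sort(gpos_in_tx_order)
        expect_true(all(diff(genome_to_tx(m, g_sorted)) < 0))
      }
    }
  }
})

test_that("representative transcript selection is deterministic", {
  mk <- function(id, len, coding, strand = "+") {
    modannot:::new_transcript_model(
      id, "G", "G", if (coding) "protein_coding" else "lincRNA", "c", strand,
      data.frame(start = 0L, end = len),
      cds = if (coding) data.frame(start = 3L, end = len - 3L) else NULL)
  }
  # coding beats longer non-coding
  expect_equal(select_representative(
    list(mk("A", 500L, TRUE), mk("B", 900L, FALSE)))$transcript_id, "A")
  # equal length ties break lexicographically
  expect_equal(select_representative(
    list(mk("TX2", 500L, TRUE), mk("TX1", 500L, TRUE)))$transcript_id, "TX1")
  # singleton
  expect_equal(select_representative(list(mk("Z", 90L, FALSE)))$transcript_id,
               "Z")
})

test_that("region sequences are spliced, strand-corrected and partitioned", {
  # genome with a planted ATG at the CDS start of TX1 (gpos 150..152) and
  # "AAAC" inside the minus-strand exon
  g <- strsplit(rand_chrom(1500), "")[[1]]
  g[151:153] <- c("A", "T", "G")
  g[601:604] <- c("A", "A", "A", "C")
  idx <- toy_index(paste(g, collapse = ""))
  cds <- extract_region_sequences(idx, "cds")
  expect_equal(unname(Biostrings::width(cds)["TX1" == names(cds)]), 100L)
  expect_equal(substr(as.character(cds[["TX1"]]), 1, 3), "ATG")
  # utr5/cds/utr3 concatenate to the whole transcript
  tx <- extract_region_sequences(idx, "tx")
  u5 <- extract_region_sequences(idx, "utr5")
  u3 <- extract_region_sequences(idx, "utr3")
  expect_equal(paste0(as.character(u5[["TX1"]]), as.character(cds[["TX1"]]),
                      as.character(u3[["TX1"]])),
               as.character(tx[["TX1"]]))
  # non-coding transcripts are omitted from mRNA sub-regions
  expect_false("NC1" %in% names(u5))
  # minus-strand: genomic AAAC at gpos 600..603 = transcript positions
  # 96..99 read as reverse complement GTTT
  txm <- as.character(tx[["TXM"]])
  expect_equal(substr(txm, 97, 100), "GTTT")
})

test_that("promoter and downstream flanks respect strand and clipping", {
  idx <- toy_index()
  m <- idx$transcripts[["TX1"]]
  # promoter upstream of TSS at 100, clipped at chromosome start
  expect_equal(c(m$promoter$start, m$promoter$end), c(0L, 100L))
  expect_true(m$promoter$clipped)
  expect_equal(c(m$downstream$start, m$downstream$end), c(400L, 1400L))
  expect_false(m$downstream$clipped)
  # minus strand: promoter at higher genomic coordinates than the TSS
  mm <- idx$transcripts[["TXM"]]
  expect_equal(c(mm$promoter$start, mm$promoter$end), c(700L, 1500L))
  expect_true(mm$promoter$start >= mm$exons$end[1] - 1L)
})

test_that("annotation loading validates inputs with clear errors", {
  dir <- tempfile("ann"); dir.create(dir)
  gtf <- file.path(dir, "a.gtf"); fa <- file.path(dir, "g.fa")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1"; gene_biotype "protein_coding";',
    "broken line without tabs"), gtf)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chr1 = rand_chrom(500))), fa)
  expect_error(load_annotation(gtf, fa), "line 2")

  writeLines(
    'chr2\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    gtf)
  expect_error(load_annotation(gtf, fa), "chr2")

  # CDS outside exons: transcript skipped with warning and counted
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\tCDS\t301\t340\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chr1\tsrc\texon\t401\t460\t.\t+\t.\tgene_id "G2"; transcript_id "T2";'),
    gtf)
  expect_warning(idx <- load_annotation(gtf, fa), "skipping transcript T1")
  expect_equal(idx$skipped_transcripts, "T1")
  expect_equal(names(idx$transcripts), "T2")
  # biotype fell back to "unknown" without gene_biotype/gene_type
  expect_equal(idx$genes$biotype, "unknown")
})
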