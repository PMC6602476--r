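test_that("metagene bins midpoints by floor(offset/len*bins) per region", {
  idx <- four_tx_index()
  # one site at cds offset 150 of P1 (gpos 1200+150+150), plus boundary
  # sites at region offset 0 and region_len-1 of the 3'UTR of P2
  s <- site_set(data.frame(
    chrom = "chrP",
    start = c(1500L, 5450L, 5599L),
    end = c(1501L, 5451L, 5600L), strand = "+"))
  a <- assign_features(s, idx)
  mg <- metagene(a, idx, bins = 100L)
  expect_equal(mg$n_transcripts_used, 4L)
  expect_equal(mg$n_placed, 3L)
  d <- mg$profile
  # cds bin 50 -> global bin 100 + 50
  expect_equal(d$density[d$bin == 150], 1 / 4)
  # utr3 offset 0 -> first utr3 bin (200); offset 149 -> bin floor(149/150*100)=99
  expect_equal(d$density[d$bin == 200], 1 / 4)
  expect_equal(d$density[d$bin == 200 + 99], 1 / 4)
  expect_equal(sum(d$density) * mg$n_transcripts_used, mg$n_placed)
})

test_that("transcripts with any region shorter than the bin count are excluded", {
  # P-like index plus one gene with a 40 nt 5'UTR
  starts <- c(1200L, 5000L)
  exon_tab <- data.frame(
    transcript_id = c("A1", "A2"), gene_id = c("GA1", "GA2"),
    gene_name = c("GA1", "GA2"), biotype = "protein_coding",
    chrom = "chrP", strand = "+",
    start = starts, end = starts + c(600L, 490L))
  cds_tab <- data.frame(transcript_id = c("A1", "A2"),
                        start = starts + c(150L, 40L),
                        end = starts + c(450L, 340L))
  genome <- Biostrings::DNAStringSet(stats::setNames(rand_chrom(9000), "chrP"))
  idx <- modannot:::build_annotation_index(exon_tab, cds_tab, genome)
  a <- assign_features(site_set(data.frame(chrom = "chrP", start = 1500L,
                                           end = 1501L, strand = "+")), idx)
  mg <- metagene(a, idx, bins = 100L)
  expect_equal(mg$n_transcripts_used, 1L)
  expect_equal(mg$n_excluded_short, 1L)
  expect_error(metagene(a, idx, bins = 1000L), "bin-length filter")
})

test_that("boundary coverage CI equals mean +/- 1.96 SEM, recomputed by hand", {
  idx <- four_tx_index()
  # single-nucleotide site at stop_codon offset +10 in P1 and P2 only;
  # stop codon tx pos 449 -> gpos start+459
  s <- site_set(data.frame(chrom = "chrP",
                           start = c(1200L, 5000L) + 459L,
                           end = c(1200L, 5000L) + 460L, strand = "+"))
  bp <- boundary_coverage(s, idx, "stop_codon", flank = 100L)
  expect_equal(bp$n_units, 4L)
  prof <- bp$profile
  expect_equal(prof$mean_cov[prof$offset == 10], 0.5)
  expect_equal(sum(prof$mean_cov), 0.5)  # single covered offset
  sem <- stats::sd(c(1, 1, 0, 0)) / sqrt(4)
  expect_equal(sem, 0.2886751, tolerance = 1e-6)
  expect_equal(prof$ci_high[prof$offset == 10], 0.5 + 1.96 * sem)
  expect_equal(prof$ci_low[prof$offset == 10], 0)  # clipped at zero
  expect_true(all(prof$ci_low <= prof$mean_cov + 1e-12 &
                    prof$mean_cov <= prof$ci_high + 1e-12))
})

test_that("empty input and n=1 degenerate cases are well defined", {
  idx <- four_tx_index()
  none <- site_set(data.frame(chrom = character(0), start = integer(0),
                              end = integer(0)))
  bp0 <- boundary_coverage(none, idx, "stop_codon", flank = 50L)
  expect_true(all(bp0$profile$mean_cov == 0))
  expect_true(all(bp0$profile$ci_low == 0 & bp0$profile$ci_high == 0))
  # delta site exactly at the stop codon, n_units == 1 via covered_only:
  # SEM is defined as 0 so the CI collapses onto the mean
  s <- site_set(data.frame(chrom = "chrP", start = 1649L, end = 1650L,
                           strand = "+"))
  bp1 <- boundary_coverage(s, idx, "stop_codon", flank = 100L,
                           covered_only = TRUE)
  expect_equal(bp1$n_units, 1L)
  p <- bp1$profile
  expect_equal(p$mean_cov[p$offset == 0], 1)
  expect_equal(p$ci_high, p$mean_cov)
  expect_equal(p$ci_low, p$mean_cov)
  expect_error(boundary_coverage(s, idx, "stop_codon", flank = 0L), "flank")
})

test_that("splice-site anchors live on junctions and respect wide intervals", {
  idx <- toy_index()
  # interval spanning the TX1 junction (tx 99|100, genomic 199|300):
  # coverage uses the full interval, so both splice flanks are covered
  s <- site_set(data.frame(chrom = "chr1", start = 190L, end = 310L,
                           strand = "+"))
  b5 <- boundary_coverage(s, idx, "splice5", flank = 5L)
  expect_equal(b5$n_units, 1L)  # only TX1 is multi-exon
  expect_true(all(b5$profile$mean_cov == 1))
  # single-exon transcriptome: empty profile with a warning
  idx1 <- four_tx_index()
  expect_warning(b <- boundary_coverage(s, idx1, "splice5", flank = 5L),
                 "anchors")
  expect_equal(b$n_units, 0L)
})

test_that("heatmap rows sort by occupancy and column means equal the profile", {
  idx <- four_tx_index()
  set.seed(5)
  starts <- c(1200L, 5000L, 9000L, 13000L)
  # distinct per-transcript occupancy: 3, 2, 1, 0 covered nucleotides
  pos <- c(starts[1] + 459L + c(-3L, 0L, 3L), starts[2] + 459L + c(0L, 5L),
           starts[3] + 459L)
  s <- site_set(data.frame(chrom = "chrP", start = pos, end = pos + 1L,
                           strand = "+"))
  hm <- boundary_heatmap(s, idx, "stop_codon", flank = 20L)
  expect_equal(dim(hm), c(4L, 41L))
  expect_equal(rownames(hm), c("P1", "P2", "P3", "P4"))
  expect_true(all(diff(rowSums(hm)) <= 0))
  bp <- boundary_coverage(s, idx, "stop_codon", flank = 20L)
  expect_equal(unname(colMeans(hm)), bp$profile$mean_cov)
  # single-instance heatmap equals its coverage vector
  idx2 <- toy_index()
  s2 <- site_set(data.frame(chrom = "chr1", start = 199L, end = 200L,
                            strand = "+"))
  hm2 <- boundary_heatmap(s2, idx2, "splice5", flank = 3L)
  expect_equal(nrow(hm2), 1L)
  expect_equal(unname(hm2[1, ]),
               boundary_coverage(s2, idx2, "splice5",
                                 flank = 3L)$profile$mean_cov)
})

test_that("feature coverage densities are counts per kilobase of feature", {
  idx <- four_tx_index()
  # 6 CDS sites; total CDS length = 4 x 300 = 1200 nt -> 5 sites/kb
  pos <- c(1400L, 1410L, 1420L, 5400L, 9400L, 13400L)
  s <- site_set(data.frame(chrom = "chrP", start = pos, end = pos + 1L,
                           strand = "+"))
  a <- assign_features(s, idx)
  fc <- feature_coverage_summary(a, idx)
  expect_equal(fc$total_length_nt[fc$category == "CDS"], 1200)
  expect_equal(fc$density_per_kb[fc$category == "CDS"], 5)
  expect_equal(fc$count[fc$category == "UTR5"], 0L)
  expect_equal(fc$density_per_kb[fc$category == "UTR5"], 0)
  expect_true(all(fc$density_per_kb >= 0))
})

test_that("profiles are invariant under a constant genomic shift", {
  shift <- 750L
  mk <- function(off) {
    starts <- c(1200L, 5000L, 9000L, 13000L) + off
    exon_tab <- data.frame(
      transcript_id = sprintf("P%d", 1:4), gene_id = sprintf("GP%d", 1:4),
      gene_name = sprintf("GP%d", 1:4), biotype = "protein_coding",
      chrom = "chrP", strand = "+", start = starts, end = starts + 600L)
    cds_tab <- data.frame(transcript_id = sprintf("P%d", 1:4),
                          start = starts + 150L, end = starts + 450L)
    genome <- Biostrings::DNAStringSet(
      stats::setNames(rand_chrom(21000), "chrP"))
    modannot:::build_annotation_index(exon_tab, cds_tab, genome)
  }
  idx0 <- mk(0L); idx1 <- mk(shift)
  set.seed(8)
  pos <- sample(0:599, 25) + rep(c(1200L, 5000L, 9000L, 13000L), length = 25)
  mk_sites <- function(off) site_set(data.frame(
    chrom = "chrP", start = pos + off, end = pos + off + 1L, strand = "+"),
    dedup = FALSE)
  a0 <- assign_features(mk_sites(0L), idx0)
  a1 <- assign_features(mk_sites(shift), idx1)
  expect_equal(a0$category, a1$category)
  expect_equal(metagene(a0, idx0)$profile, metagene(a1, idx1)$profile)
  expect_equal(boundary_coverage(mk_sites(0L), idx0, "stop_codon", 50)$profile,
               boundary_coverage(mk_sites(shift), idx1, "stop_codon",
                                 50)$profile)
})
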