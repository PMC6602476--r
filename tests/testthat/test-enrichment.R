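test_that("flank windows are centered, strand-corrected and reproducible", {
  idx <- toy_index()
  s <- site_set(data.frame(chrom = "chr1", start = c(160L, 650L),
                           end = c(161L, 651L), strand = c("+", "-")))
  fl <- extract_flank_sequences(s, idx, window = 21L, bg_seed = 3)
  expect_equal(unname(Biostrings::width(fl$fg)), c(21L, 21L))
  expect_equal(length(fl$bg), 2L)
  # plus-strand window equals the raw genomic slice
  g <- as.character(idx$genome[["chr1"]])
  expect_equal(as.character(fl$fg[[1]]), substr(g, 151, 171))
  # minus-strand host transcript: reverse complement of the genomic slice
  expect_equal(as.character(fl$fg[[2]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(g, 641, 661)))))
  # same seed -> identical background; different seed -> differs
  fl2 <- extract_flank_sequences(s, idx, window = 21L, bg_seed = 3)
  expect_identical(as.character(fl$bg), as.character(fl2$bg))
  # clipping near the chromosome start is counted
  s2 <- site_set(data.frame(chrom = "chr1", start = 2L, end = 3L,
                            strand = "+"))
  fl3 <- extract_flank_sequences(s2, idx, window = 41L)
  expect_equal(fl3$n_clipped, 1L)
  expect_lt(Biostrings::width(fl3$fg)[1], 41L)
})

test_that("k-mer p-values match the exhaustive hypergeometric oracle", {
  # planted motif: GGACT in 20/20 foreground, 1/20 background
  set.seed(4)
  pad <- function(w) paste(sample(c("A", "C"), w, TRUE), collapse = "")
  fg <- vapply(1:20, function(i) paste0(pad(8), "GGACT", pad(8)),
               character(1))
  bg <- vapply(1:20, function(i) pad(21), character(1))
  bg[1] <- paste0(pad(8), "GGACT", pad(8))
  km <- kmer_enrichment(fg, bg, k_values = 5L)
  top <- km[1, ]
  expect_equal(top$kmer, "GGACT")
  expect_equal(top$fg_count, 20L)
  expect_equal(top$bg_count, 1L)
  # one-sided Fisher on [[20,0],[1,19]], by independent enumeration
  expect_equal(top$p, hyper_tail_oracle(20, 21, 40, 20), tolerance = 1e-12)
  expect_equal(top$p,
               stats::fisher.test(matrix(c(20, 0, 1, 19), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
  # random 2x2 presence tables with N <= 100: 1e-12 relative agreement
  set.seed(5)
  for (rep in 1:200) {
    nf <- sample(1:50, 1); nb <- sample(1:50, 1)
    fc <- sample(0:nf, 1); bc <- sample(0:nb, 1)
    p_pkg <- stats::phyper(fc - 1, fc + bc, nf + nb - fc - bc, nf,
                           lower.tail = FALSE)
    p_orc <- hyper_tail_oracle(fc, fc + bc, nf + nb, nf)
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
})

test_that("k-mer edge rules: null case, short sequences, BH within k", {
  fg <- c("ACGTACGTAC", "TACGGACTGG")
  km0 <- kmer_enrichment(fg, fg, k_values = 6L)
  expect_true(all(km0$log2_enrichment == 0))
  # identical presence counts: upper-tail p is never small
  expect_true(all(km0$p > 0.5))
  # sequences shorter than k are skipped and totals adjusted
  km1 <- kmer_enrichment(c(fg, "ACG"), c(fg, "ACG"), k_values = 6L)
  expect_equal(unique(km1$fg_total), 2L)
  expect_error(kmer_enrichment(character(0), fg), "empty")
  expect_error(kmer_enrichment("ACG", "ACG", k_values = 6L), "long enough")
  # q-values monotone in ranked-p order within each k
  set.seed(6)
  idxx <- rand_index(61)
  s <- rand_sites(idxx, 25, 7)
  fl <- extract_flank_sequences(s, idxx, window = 31L)
  km <- kmer_enrichment(fl$fg, fl$bg, k_values = c(6L, 7L))
  for (k in unique(km$k)) {
    sub <- km[km$k == k, ]
    expect_true(all(diff(sub$q) >= -1e-12))
    expect_true(all(sub$q >= sub$p - 1e-12))
  }
  expect_lte(nrow(top_kmers(km, 5)), 10L)
})

test_that("planted RRACH is recovered in the top five k-mers", {
  fx <- run_fixtures(tempfile("motif"),
                     spec = fixture_spec(n_genes = 15, seed = 77),
                     n_sites = 150,
                     placement = placement_region_rates(c(cds = 1, utr3 = 1)),
                     site_seed = 78, planted_motif = "RRACH")
  fl <- extract_flank_sequences(fx$sites, fx$index, window = 21L, bg_seed = 1)
  # every foreground window carries the motif instance at its center
  centers <- substr(as.character(fl$fg), 9, 13)
  expect_true(all(grepl("^[AG][AG]AC[ACT]$", centers)))
  km <- kmer_enrichment(fl$fg, fl$bg, k_values = c(5L, 6L))
  for (k in c(5L, 6L)) {
    top5 <- utils::head(km[km$k == k, ], 5)
    hit <- vapply(top5$kmer, function(x)
      grepl("[AG][AG]AC[ACT]", x), logical(1))
    expect_true(any(hit), label = paste("k =", k))
  }
})

test_that("peak refinement emits width-1 sites at every motif match", {
  # transcript whose CDS carries GGACTGGACT; the two RRACH matches put the
  # modified A at local offsets 2 and 7
  g <- strsplit(rand_chrom(1500), "")[[1]]
  g[161:170] <- strsplit("GGACTGGACT", "")[[1]]  # gpos 160..169, CDS of TX1
  g[171:180] <- rep("C", 10)                     # no spurious match downstream
  g[151:160] <- rep("C", 10)
  idx <- toy_index(paste(g, collapse = ""))
  peak <- site_set(data.frame(chrom = "chr1", start = 155L, end = 185L,
                              strand = "+", name = "pk1", score = 7))
  ref <- refine_peaks_to_sites(peak, idx, "RRACH")
  expect_equal(nrow(ref), 2L)
  expect_equal(ref$end - ref$start, c(1L, 1L))
  expect_equal(ref$start, c(162L, 167L))  # the A of each GGACT
  expect_true(all(ref$start >= peak$start & ref$end <= peak$end))
  # no-match peak contributes nothing
  peak2 <- site_set(data.frame(chrom = "chr1", start = 171L, end = 180L,
                               strand = "+"))
  expect_equal(nrow(refine_peaks_to_sites(peak2, idx, "RRACH")), 0L)
  expect_error(refine_peaks_to_sites(peak, idx, "RRAXH"), "IUPAC")
})

test_that("refinement offsets: GAAGAAG uses position 3, and matches map back through splicing", {
  # plant GAAGAAG across the TX1 exon junction (tx 96..102; genomic
  # 196..199 + 300..302) so the modified base tx 99 = genomic 199
  g <- strsplit(rand_chrom(1500), "")[[1]]
  tx_target <- 96:102
  m0 <- toy_index()$transcripts[["TX1"]]
  gpos <- tx_to_genome(m0, tx_target)
  g[gpos + 1L] <- strsplit("GAAGAAG", "")[[1]]
  idx <- toy_index(paste(g, collapse = ""))
  peak <- site_set(data.frame(chrom = "chr1", start = 150L, end = 350L,
                              strand = "+"))
  ref <- refine_peaks_to_sites(peak, idx, "GAAGAAG")
  expect_true(199L %in% ref$start)  # tx 96 + offset 3 = tx 99 -> gpos 199
  expect_true(all(ref$end - ref$start == 1L))
})

test_that("gene-set enrichment matches the combinatorial example", {
  gmt <- list(S1 = list(id = "S1", name = "example set",
                        genes = sprintf("u%02d", 1:5)))
  universe <- sprintf("u%02d", 1:20)
  query <- c(sprintf("u%02d", 1:4), "u10")  # overlap 4 of 5
  res <- geneset_enrichment(query, gmt, universe)
  # P[X >= 4], X ~ Hypergeom(N=20, K=5, n=5) = 76/15504
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p, hyper_tail_oracle(4, 5, 20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 4L)
  # certain event: query == set == universe
  res2 <- geneset_enrichment(universe[1:5], gmt, universe[1:5])
  expect_equal(res2$p, 1)
  # zero overlap reports p = 1 under the upper-tail convention
  res3 <- geneset_enrichment("u20", gmt, universe)
  expect_equal(res3$p, 1)
  expect_error(geneset_enrichment(query, gmt, character(0)), "universe")
  expect_error(geneset_enrichment(query, list(), universe), "empty")
  # ids outside the universe are dropped and counted
  res4 <- geneset_enrichment(c(query, "nope"), gmt, universe)
  expect_equal(attr(res4, "n_query_dropped"), 1L)
})

test_that("GMT round trip and BH monotonicity across sets", {
  f <- tempfile(fileext = ".gmt")
  make_gene_sets(sprintf("u%02d", 1:30), sprintf("u%02d", 1:6), f, seed = 2)
  gmt <- read_gmt(f)
  expect_gte(length(gmt), 2L)
  expect_equal(gmt[["SET_ENRICHED"]]$name, "planted enriched set")
  res <- geneset_enrichment(sprintf("u%02d", 1:6), gmt, sprintf("u%02d", 1:30))
  expect_true(all(diff(res$q) >= -1e-12))  # ranked by p
  expect_true(all(res$overlap <= pmin(res$set_size, res$query_size)))
  # the planted set is the most significant
  expect_equal(res$set_id[1], "SET_ENRICHED")
  # malformed GMT line errors with its number
  writeLines("onlyone\tfield", f)
  expect_error(read_gmt(f), "line 1")
})
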