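## Motif and gene-set enrichment: flank sequence extraction with a
## category-matched seeded background, presence/absence k-mer enrichment
## (hypergeometric upper tail), motif-guided refinement of peaks to exact
## single-nucleotide sites, and hypergeometric gene-set enrichment over
## user-supplied GMT collections.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Vectorized window extraction: windows centered on `center` (0-based), on the
# given strands, clipped at chromosome ends. Works on cached character
# chromosomes; minus-strand windows are reverse-complemented in one batch.
.chrom_windows <- function(index, chrom, center, window, strand) {
  cache <- as.character(index$genome)
  lo <- pmax(0L, center - window %/% 2L)
  hi <- pmin(unname(index$seqlens[chrom]), center - window %/% 2L + window)
  out <- toupper(substring(cache[chrom], lo + 1L, hi))
  neg <- strand == "-"
  if (any(neg)) {
    out[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[neg])))
  }
  out
}

#' Extract sequences around site midpoints, with a matched background
#'
#' Foreground: `window` nucleotides centered on each site midpoint, on the
#' strand of the host transcript (the site's own strand for unassigned sites,
#' `"."` treated as `"+"`). Background: an equal number of length-matched
#' windows sampled uniformly from feature intervals with the same category
#' composition as the foreground (seeded and reproducible); intergenic
#' foreground windows draw uniform genomic backgrounds. Windows clipped at
#' chromosome ends are kept (shorter) and counted; [kmer_enrichment()] skips
#' sequences shorter than `k`.
#'
#' @param sites A `SiteSet`.
#' @param index An `AnnotationIndex`.
#' @param window Window length in nucleotides (default 41).
#' @param assignments Optional precomputed [assign_features()] output.
#' @param bg_seed Seed for background sampling (default 1).
#' @return List with `fg` and `bg` (`DNAStringSet`) and `n_clipped`.
#' @export
extract_flank_sequences <- function(sites, index, window = 41L,
                                    assignments = NULL, bg_seed = 1L) {
  if (!nrow(sites)) stop("empty site set")
  if (is.null(assignments)) assignments <- assign_features(sites, index)
  mids <- site_midpoints(sites)
  tx_strand <- vapply(index$transcripts, function(m) m$strand, character(1))
  strands <- ifelse(!is.na(assignments$transcript_id),
                    tx_strand[assignments$transcript_id],
                    ifelse(sites$strand %in% c("+", "-"), sites$strand, "+"))
  fg <- .chrom_windows(index, sites$chrom, mids, window, strands)
  n_clipped <- sum(nchar(fg) < window)

  feats <- index$features
  fcat <- S4Vectors::mcols(feats)$category
  ftx <- S4Vectors::mcols(feats)$transcript_id
  fchrom <- as.character(GenomicRanges::seqnames(feats))
  fstart <- GenomicRanges::start(feats) - 1L
  fw <- GenomicRanges::width(feats)
  bg <- .with_seed(bg_seed, {
    n <- nrow(sites)
    b_chrom <- character(n); b_pos <- integer(n); b_strand <- character(n)
    for (i in seq_len(n)) {
      cat <- assignments$category[i]
      pool <- which(fcat == cat)
      if (cat == "intergenic" || !length(pool)) {
        b_chrom[i] <- sample(names(index$seqlens), 1,
                             prob = as.numeric(index$seqlens))
        b_pos[i] <- sample.int(index$seqlens[[b_chrom[i]]], 1) - 1L
        b_strand[i] <- "+"
      } else {
        j <- pool[sample.int(length(pool), 1, prob = fw[pool])]
        b_chrom[i] <- fchrom[j]
        b_pos[i] <- fstart[j] + sample.int(fw[j], 1) - 1L
        b_strand[i] <- tx_strand[[ftx[j]]]
      }
    }
    .chrom_windows(index, b_chrom, b_pos, window, b_strand)
  })
  nm <- make.unique(ifelse(sites$name == ".",
                           paste0("site", seq_len(nrow(sites))), sites$name))
  list(fg = Biostrings::DNAStringSet(stats::setNames(fg, nm)),
       bg = Biostrings::DNAStringSet(
         stats::setNames(bg, paste0("bg", seq_along(bg)))),
       n_clipped = n_clipped)
}

.kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Presence/absence k-mer enrichment of foreground vs background sequences
#'
#' For each k-mer, `fg_count` is the number of foreground sequences containing
#' it at least once (likewise `bg_count`); the p-value is the hypergeometric
#' upper tail of drawing `fg_count` containing-sequences among the foreground
#' (equivalent to a one-sided Fisher test on the 2x2 presence table).
#' Sequences shorter than `k` are skipped with totals adjusted. q-values are
#' BH-adjusted within each k; rows are ranked by p, then by decreasing log2
#' enrichment (computed with 0.5 pseudocounts).
#'
#' @param fg,bg Character vectors or `DNAStringSet`s (U is read as T).
#' @param k_values Motif lengths to scan (default 6, 7, 8).
#' @return Data frame with `kmer`, `k`, `fg_count`, `fg_total`, `bg_count`,
#'   `bg_total`, `log2_enrichment`, `p`, `q`.
#' @export
kmer_enrichment <- function(fg, bg, k_values = c(6L, 7L, 8L)) {
  fg <- toupper(gsub("U", "T", as.character(fg)))
  bg <- toupper(gsub("U", "T", as.character(bg)))
  if (!length(fg)) stop("empty foreground sequence set")
  out <- list()
  for (k in k_values) {
    fg_k <- fg[nchar(fg) >= k]; bg_k <- bg[nchar(bg) >= k]
    if (!length(fg_k)) next
    fg_tab <- table(unlist(lapply(fg_k, .kmers_of, k = k)))
    bg_tab <- table(unlist(lapply(bg_k, .kmers_of, k = k)))
    kmers <- union(names(fg_tab), names(bg_tab))
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    if (!length(kmers)) next
    fc <- as.integer(fg_tab[kmers]); fc[is.na(fc)] <- 0L
    bc <- as.integer(bg_tab[kmers]); bc[is.na(bc)] <- 0L
    nf <- length(fg_k); nb <- length(bg_k)
    p <- stats::phyper(fc - 1L, fc + bc, nf + nb - fc - bc, nf,
                       lower.tail = FALSE)
    l2 <- log2(((fc + 0.5) / (nf + 1)) / ((bc + 0.5) / (nb + 1)))
    tab <- data.frame(kmer = kmers, k = as.integer(k),
                      fg_count = fc, fg_total = nf,
                      bg_count = bc, bg_total = nb,
                      log2_enrichment = l2, p = p,
                      q = stats::p.adjust(p, method = "BH"))
    out[[as.character(k)]] <- tab[order(tab$p, -tab$log2_enrichment,
                                        tab$kmer), , drop = FALSE]
  }
  if (!length(out)) stop("no sequence long enough for any requested k")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top enriched k-mers per motif length
#'
#' @param table Output of [kmer_enrichment()].
#' @param n Number of rows per k (default 5).
#' @return Subset of `table` with the `n` best-ranked k-mers for each k.
#' @export
top_kmers <- function(table, n = 5L) {
  do.call(rbind, lapply(split(table, table$k), utils::head, n = n))
}

.default_motif_offset <- function(motif) {
  if (toupper(motif) == "RRACH") return(2L)
  if (toupper(motif) == "GAAGAAG") return(3L)
  as.integer(nchar(motif) %/% 2L)
}

#' Refine peaks to exact modified positions by consensus-motif scanning
#'
#' Each peak is projected onto the spliced sequence of its host representative
#' transcript; every match of the IUPAC consensus within the projected
#' sequence yields one single-nucleotide site at the modified base of the
#' motif (offset 2 for RRACH, i.e. the central A; offset 3 for GAAGAAG;
#' the central position for other motifs unless overridden), mapped back to
#' genomic coordinates. Peaks without a host transcript or without a match
#' contribute no sites.
#'
#' @param peaks A `SiteSet` of (typically wide) peaks.
#' @param index An `AnnotationIndex`.
#' @param motif IUPAC consensus string (U allowed, read as T).
#' @param modified_offset 0-based offset of the modified base within the
#'   motif; `NULL` for the defaults above.
#' @return A `SiteSet` of width-1 sites, genomically contained in their peaks.
#' @export
refine_peaks_to_sites <- function(peaks, index, motif,
                                  modified_offset = NULL) {
  motif <- toupper(gsub("U", "T", motif))
  if (grepl(paste0("[^", paste(names(Biostrings::IUPAC_CODE_MAP),
                               collapse = ""), "]"), motif))
    stop("invalid IUPAC character in motif '", motif, "'")
  if (is.null(modified_offset)) modified_offset <- .default_motif_offset(motif)
  stopifnot(modified_offset >= 0, modified_offset < nchar(motif))
  assignments <- assign_features(peaks, index)
  txseq_cache <- list()
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    tid <- assignments$transcript_id[i]
    if (is.na(tid)) next
    m <- index$transcripts[[tid]]
    pieces <- genomic_range_to_tx(m, peaks$start[i], peaks$end[i])
    if (!nrow(pieces)) next
    if (is.null(txseq_cache[[tid]]))
      txseq_cache[[tid]] <- as.character(transcript_sequence(index, m))
    txseq <- txseq_cache[[tid]]
    tpos <- unlist(lapply(seq_len(nrow(pieces)), function(j)
      seq.int(pieces$tx_start[j], pieces$tx_end[j] - 1L)))
    pseq <- paste(substring(txseq, tpos + 1L, tpos + 1L), collapse = "")
    hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(pseq),
                                     fixed = FALSE)
    if (!length(hits)) next
    loc <- Biostrings::start(hits) + modified_offset  # 1-based local index
    loc <- loc[loc <= length(tpos)]
    if (!length(loc)) next
    gpos <- tx_to_genome(m, tpos[loc])
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = m$chrom, start = gpos, end = gpos + 1L,
      name = paste0(ifelse(peaks$name[i] == ".",
                           paste0("peak", i), peaks$name[i]),
                    "_", motif, "_", seq_along(gpos)),
      score = peaks$score[i], strand = m$strand)
  }
  if (!length(rows)) {
    return(site_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)),
                    source_label = "refined_sites"))
  }
  site_set(do.call(rbind, rows), source_label = "refined_sites", dedup = TRUE)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set id, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of sets, each `list(id, name, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file '", path, "'")
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, ": fewer than 3 fields")
    list(id = f[1], name = f[2], genes = unique(f[-(1:2)]))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "id"))
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the seen overlap between the query and the set, both intersected with
#' the universe first; query genes outside the universe are dropped and
#' counted. q-values are BH-adjusted across all tested sets.
#'
#' @param query Character vector of gene ids.
#' @param gmt Output of [read_gmt()] (or an equivalently shaped list).
#' @param universe Character vector of background gene ids.
#' @param drop_zero Drop sets with zero overlap instead of reporting them
#'   with p = 1 (default FALSE).
#' @return Data frame ranked by p with `set_id`, `set_name`, `overlap`,
#'   `set_size`, `universe`, `query_size`, `p`, `q`; attribute
#'   `n_query_dropped` counts query ids outside the universe.
#' @export
geneset_enrichment <- function(query, gmt, universe, drop_zero = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!length(gmt)) stop("empty gene-set collection")
  query0 <- unique(query)
  query <- intersect(query0, universe)
  n_dropped <- length(query0) - length(query)
  N <- length(universe); n <- length(query)
  rows <- lapply(gmt, function(s) {
    genes <- intersect(s$genes, universe)
    K <- length(genes)
    x <- length(intersect(query, genes))
    p <- if (K == 0) 1 else
      stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = s$id, set_name = s$name, overlap = x,
               set_size = K, universe = N, query_size = n, p = p)
  })
  out <- do.call(rbind, rows)
  if (drop_zero) out <- out[out$overlap > 0, , drop = FALSE]
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- n_dropped
  out
}
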