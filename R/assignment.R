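#' Feature categories in priority order
#'
#' A site overlapping several annotations is resolved to the single
#' highest-priority category: CDS > 3'UTR > 5'UTR > intron > non-coding exon >
#' promoter > downstream; a site overlapping nothing is intergenic.
#' @export
FEATURE_PRIORITY <- c("CDS", "UTR3", "UTR5", "intron", "exon_nc",
                      "promoter", "downstream")

#' Feature category vocabulary (priority order plus intergenic)
#' @export
FEATURE_CATEGORIES <- c(FEATURE_PRIORITY, "intergenic")

#' Resolve each site to one gene-feature category and host gene
#'
#' Every site receives exactly one category: the highest-priority category
#' among all features its interval overlaps (see [FEATURE_PRIORITY]). Ties
#' within a category are broken by the feature whose midpoint is nearest the
#' site midpoint, then by smallest gene id. Sites with known strand are only
#' matched against same-strand features; strandless sites match both strands
#' and carry a `both_strand_hit` flag when candidate features exist on both.
#' Sites on chromosomes absent from the annotation are intergenic and counted
#' in the `diagnostics` attribute.
#'
#' @param sites A `SiteSet`.
#' @param index An `AnnotationIndex`.
#' @return A data frame with one row per site: the site columns plus
#'   `category`, `biotype`, `gene_id`, `transcript_id`, `tx_pos` (transcript
#'   coordinate of the site midpoint, `NA` unless the midpoint is exonic on
#'   the host transcript) and `both_strand_hit`.
#' @export
assign_features <- function(sites, index) {
  n <- nrow(sites)
  out <- data.frame(as.data.frame(sites),
                    category = rep("intergenic", n),
                    biotype = rep(NA_character_, n),
                    gene_id = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    tx_pos = rep(NA_integer_, n),
                    both_strand_hit = rep(FALSE, n))
  if (!n) {
    attr(out, "diagnostics") <- list(n_unknown_chrom = 0L)
    return(out)
  }
  gr <- sites_as_granges(sites)
  feats <- index$features
  unknown <- !(sites$chrom %in% names(index$seqlens))

  hits <- GenomicRanges::findOverlaps(gr, feats, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  site_strand <- sites$strand[qh]
  feat_strand <- as.character(GenomicRanges::strand(feats))[sh]
  keep <- site_strand == "." | site_strand == feat_strand
  qh <- qh[keep]; sh <- sh[keep]

  if (length(qh)) {
    fmid <- (GenomicRanges::start(feats)[sh] - 1L +
             GenomicRanges::end(feats)[sh]) %/% 2L
    smid <- site_midpoints(sites)[qh]
    cand <- data.frame(
      site = qh,
      prio = match(S4Vectors::mcols(feats)$category[sh], FEATURE_PRIORITY),
      dist = abs(fmid - smid),
      gene_id = S4Vectors::mcols(feats)$gene_id[sh],
      transcript_id = S4Vectors::mcols(feats)$transcript_id[sh],
      strand = feat_strand[seq_along(sh)])
    cand <- cand[order(cand$site, cand$prio, cand$dist, cand$gene_id), ,
                 drop = FALSE]
    both <- tapply(cand$strand, cand$site,
                   function(s) length(unique(s)) > 1)
    best <- cand[!duplicated(cand$site), , drop = FALSE]
    i <- best$site
    out$category[i] <- FEATURE_PRIORITY[best$prio]
    out$gene_id[i] <- best$gene_id
    out$transcript_id[i] <- best$transcript_id
    gmap <- stats::setNames(index$genes$biotype, index$genes$gene_id)
    out$biotype[i] <- unname(gmap[best$gene_id])
    out$both_strand_hit[i] <- sites$strand[i] == "." &
      unname(both[as.character(i)])
    exonic <- i[out$category[i] %in% c("CDS", "UTR5", "UTR3", "exon_nc")]
    for (j in exonic) {
      m <- index$transcripts[[out$transcript_id[j]]]
      out$tx_pos[j] <- genome_to_tx(m, site_midpoints(sites)[j])
    }
  }
  attr(out, "diagnostics") <- list(n_unknown_chrom = sum(unknown))
  out
}

#' Site counts and fractions per gene biotype
#'
#' Host-gene biotypes of the assigned sites; intergenic sites are tallied as
#' their own row. Fractions sum to one over all input sites.
#'
#' @param assignments Output of [assign_features()].
#' @return Data frame with `biotype`, `count`, `fraction`, sorted by
#'   decreasing count.
#' @export
biotype_distribution <- function(assignments) {
  if (!nrow(assignments)) {
    return(data.frame(biotype = character(0), count = integer(0),
                      fraction = numeric(0)))
  }
  bt <- ifelse(assignments$category == "intergenic", "intergenic",
               assignments$biotype)
  tab <- sort(table(bt), decreasing = TRUE)
  data.frame(biotype = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / nrow(assignments),
             row.names = NULL)
}

#' Summary counts per feature category
#'
#' @param assignments Output of [assign_features()].
#' @return Data frame with `category`, `count`, `fraction` over all categories
#'   in priority order (plus intergenic).
#' @export
category_distribution <- function(assignments) {
  counts <- vapply(FEATURE_CATEGORIES,
                   function(cat) sum(assignments$category == cat), integer(1))
  data.frame(category = FEATURE_CATEGORIES, count = counts,
             fraction = if (nrow(assignments)) counts / nrow(assignments)
                        else rep(0, length(counts)),
             row.names = NULL)
}

#' Table of modified genes
#'
#' Unique genes hosting at least one non-intergenic site, with total and
#' per-category site counts.
#'
#' @param assignments Output of [assign_features()].
#' @return Data frame with one row per modified gene.
#' @export
modified_gene_list <- function(assignments) {
  a <- assignments[assignments$category != "intergenic" &
                     !is.na(assignments$gene_id), , drop = FALSE]
  genes <- sort(unique(a$gene_id))
  out <- data.frame(gene_id = genes)
  if (nrow(a)) {
    meta <- a[!duplicated(a$gene_id), c("gene_id", "biotype")]
    out$biotype <- meta$biotype[match(genes, meta$gene_id)]
    out$n_sites <- as.integer(table(a$gene_id)[genes])
    for (cat in FEATURE_PRIORITY) {
      out[[paste0("n_", cat)]] <-
        vapply(genes, function(g) sum(a$gene_id == g & a$category == cat),
               integer(1))
    }
  }
  rownames(out) <- NULL
  out
}
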