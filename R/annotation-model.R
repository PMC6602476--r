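#' Configuration for annotation loading and derived features
#'
#' Collects the flank parameters used to derive promoter/downstream regions and
#' the default windows of the boundary-coverage profiles. All lengths are in
#' nucleotides.
#'
#' @param flank_tss Flank around transcription start/end sites (default 1000).
#' @param flank_codon Flank around translation start/stop codons (default 100).
#' @param flank_splice Flank around splice junctions (default 100).
#' @param promoter_len Length of the promoter interval upstream of the TSS and
#'   of the downstream interval past the TES (default 1000).
#' @param representative Either "auto" (one representative transcript per gene:
#'   coding preferred, then longest, then lexicographically smallest id) or
#'   "all" (every transcript kept as its own unit).
#' @return A list of class `AnnotationConfig`.
#' @export
annotation_config <- function(flank_tss = 1000L, flank_codon = 100L,
                              flank_splice = 100L, promoter_len = 1000L,
                              representative = c("auto", "all")) {
  representative <- match.arg(representative)
  stopifnot(flank_tss >= 1, flank_codon >= 1, flank_splice >= 1,
            promoter_len >= 1)
  structure(list(flank_tss = as.integer(flank_tss),
                 flank_codon = as.integer(flank_codon),
                 flank_splice = as.integer(flank_splice),
                 promoter_len = as.integer(promoter_len),
                 representative = representative),
            class = "AnnotationConfig")
}

## ---- coordinate arithmetic -------------------------------------------------
## Exons are stored 0-based half-open, in ascending genomic order. Transcript
## coordinates are 0-based, 5'->3' in transcript orientation (so on "-" the
## first transcript base is the highest genomic coordinate).

.exon_order_tx <- function(model) {
  n <- nrow(model$exons)
  if (model$strand == "+") seq_len(n) else rev(seq_len(n))
}

# cumulative transcript offset at the 5' end of each exon (genomic order index)
.exon_tx_offsets <- function(model) {
  w <- model$exons$end - model$exons$start
  ord <- .exon_order_tx(model)
  off <- integer(length(w))
  off[ord] <- cumsum(c(0L, w[ord]))[seq_along(w)]
  off
}

#' Map genomic positions to transcript coordinates
#'
#' @param model A `TranscriptModel`.
#' @param gpos Integer vector of 0-based genomic positions on the model's
#'   chromosome.
#' @return Integer vector of 0-based transcript offsets; `NA` where a position
#'   is not exonic.
#' @export
genome_to_tx <- function(model, gpos) {
  ex <- model$exons
  off <- .exon_tx_offsets(model)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex$start[i] & gpos < ex$end[i]
    if (!any(hit)) next
    out[hit] <- if (model$strand == "+") {
      off[i] + (gpos[hit] - ex$start[i])
    } else {
      off[i] + (ex$end[i] - 1L - gpos[hit])
    }
  }
  as.integer(out)
}

#' Map transcript coordinates back to genomic positions
#'
#' Inverse of [genome_to_tx()]: for every exonic genomic position `p`,
#' `tx_to_genome(model, genome_to_tx(model, p)) == p`.
#'
#' @param model A `TranscriptModel`.
#' @param tpos Integer vector of 0-based transcript offsets.
#' @return Integer vector of 0-based genomic positions; `NA` outside
#'   `[0, tx_length)`.
#' @export
tx_to_genome <- function(model, tpos) {
  ex <- model$exons
  off <- .exon_tx_offsets(model)
  w <- ex$end - ex$start
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(tpos) & tpos >= off[i] & tpos < off[i] + w[i]
    if (!any(hit)) next
    out[hit] <- if (model$strand == "+") {
      ex$start[i] + (tpos[hit] - off[i])
    } else {
      ex$end[i] - 1L - (tpos[hit] - off[i])
    }
  }
  as.integer(out)
}

# Map a transcript-coordinate interval [a, b) (0-based half-open) to its
# genomic intervals (0-based half-open, ascending genomic order).
tx_range_to_genomic <- function(model, a, b) {
  stopifnot(a >= 0, b <= model$tx_length, a < b)
  ex <- model$exons
  off <- .exon_tx_offsets(model)
  w <- ex$end - ex$start
  out <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    lo <- max(a, off[i]); hi <- min(b, off[i] + w[i])
    if (lo >= hi) next
    out[[i]] <- if (model$strand == "+") {
      c(ex$start[i] + (lo - off[i]), ex$start[i] + (hi - off[i]))
    } else {
      c(ex$end[i] - (hi - off[i]), ex$end[i] - (lo - off[i]))
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- data.frame(start = out[, 1], end = out[, 2])
  res[order(res$start), , drop = FALSE]
}

# Project a genomic interval [s, e) onto transcript coordinates; returns a
# data.frame of disjoint [tx_start, tx_end) pieces (one per exon touched).
genomic_range_to_tx <- function(model, s, e) {
  ex <- model$exons
  pieces <- list()
  for (i in seq_len(nrow(ex))) {
    lo <- max(s, ex$start[i]); hi <- min(e, ex$end[i])
    if (lo >= hi) next
    t1 <- genome_to_tx(model, lo)
    t2 <- genome_to_tx(model, hi - 1L)
    pieces[[length(pieces) + 1L]] <- c(min(t1, t2), max(t1, t2) + 1L)
  }
  if (!length(pieces)) {
    return(data.frame(tx_start = integer(0), tx_end = integer(0)))
  }
  m <- do.call(rbind, pieces)
  res <- data.frame(tx_start = m[, 1], tx_end = m[, 2])
  res[order(res$tx_start), , drop = FALSE]
}

## ---- model construction ----------------------------------------------------

# Build a TranscriptModel from 0-based half-open exon/CDS intervals.
# `seqlen` (chromosome length) is needed to clip promoter/downstream flanks.
new_transcript_model <- function(transcript_id, gene_id, gene_name, biotype,
                                 chrom, strand, exons, cds = NULL,
                                 seqlen = NA_integer_,
                                 config = annotation_config()) {
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end[-nrow(exons)] > exons$start[-1])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  tx_length <- sum(exons$end - exons$start)
  model <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    biotype = biotype, chrom = chrom, strand = strand,
    exons = exons, cds = NULL, tx_length = as.integer(tx_length),
    utr5_range = NULL, cds_range = NULL, utr3_range = NULL
  ), class = "TranscriptModel")

  if (!is.null(cds) && nrow(cds)) {
    cds <- cds[order(cds$start), , drop = FALSE]
    ok <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(ok)) stop("CDS outside exons in transcript ", transcript_id)
    model$cds <- cds
    tp <- sort(genome_to_tx(model, c(cds$start, cds$end - 1L)))
    cs <- tp[1]; ce <- tp[length(tp)] + 1L
    model$cds_range <- c(cs, ce)
    model$utr5_range <- c(0L, cs)
    model$utr3_range <- c(ce, model$tx_length)
  }

  # derived feature catalog
  n <- nrow(exons)
  model$introns <- if (n > 1) {
    data.frame(start = exons$end[-n], end = exons$start[-1])
  } else data.frame(start = integer(0), end = integer(0))

  cumw <- cumsum((exons$end - exons$start)[.exon_order_tx(model)])
  if (n > 1) {
    model$splice5_pos <- as.integer(cumw[-n] - 1L)  # last nt of each exon
    model$splice3_pos <- as.integer(cumw[-n])       # first nt of next exon
  } else {
    model$splice5_pos <- integer(0)
    model$splice3_pos <- integer(0)
  }
  if (!is.null(model$cds_range)) {
    model$start_codon_pos <- model$cds_range[1]
    model$stop_codon_pos <- model$cds_range[2] - 1L  # last nt of the CDS
  } else {
    model$start_codon_pos <- NA_integer_
    model$stop_codon_pos <- NA_integer_
  }

  gstart <- exons$start[1]; gend <- exons$end[n]
  plen <- config$promoter_len
  if (strand == "+") {
    prom <- c(max(0L, gstart - plen), gstart)
    down <- c(gend, if (is.na(seqlen)) gend + plen else min(seqlen, gend + plen))
  } else {
    prom <- c(gend, if (is.na(seqlen)) gend + plen else min(seqlen, gend + plen))
    down <- c(max(0L, gstart - plen), gstart)
  }
  model$promoter <- list(start = prom[1], end = prom[2],
                         clipped = (prom[2] - prom[1]) < plen)
  model$downstream <- list(start = down[1], end = down[2],
                           clipped = (down[2] - down[1]) < plen)
  model
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (%s, %s) %s:%s [%d exon(s), %d nt%s]\n",
              x$transcript_id, x$gene_id, x$biotype, x$chrom, x$strand,
              nrow(x$exons), x$tx_length,
              if (is.null(x$cds)) ", non-coding" else ""))
  invisible(x)
}

is_coding <- function(model) !is.null(model$cds)

#' Select the representative transcript of a gene
#'
#' Deterministic choice used for all transcript-coordinate computations:
#' protein-coding transcripts are preferred, then the longest transcript,
#' ties broken by lexicographically smallest transcript id.
#'
#' @param models List of `TranscriptModel` objects belonging to one gene.
#' @return The chosen `TranscriptModel`.
#' @export
select_representative <- function(models) {
  stopifnot(length(models) >= 1)
  coding <- vapply(models, is_coding, logical(1))
  len <- vapply(models, function(m) m$tx_length, integer(1))
  ids <- vapply(models, function(m) m$transcript_id, character(1))
  ord <- order(!coding, -len, ids)
  models[[ord[1]]]
}

## ---- index construction ----------------------------------------------------

# Core constructor used by both load_annotation() and the in-memory fixture
# generators. `exon_tab` has one row per exon (0-based half-open) with columns
# transcript_id, gene_id, gene_name, biotype, chrom, strand, start, end;
# `cds_tab` has transcript_id, start, end.
build_annotation_index <- function(exon_tab, cds_tab, genome,
                                   config = annotation_config()) {
  stopifnot(is(genome, "DNAStringSet"))
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  miss <- setdiff(unique(exon_tab$chrom), names(seqlens))
  if (length(miss)) {
    stop("chromosomes in annotation but missing from FASTA: ",
         paste(miss, collapse = ", "))
  }
  skipped <- character(0)
  models <- list()
  for (tid in unique(exon_tab$transcript_id)) {
    rows <- exon_tab[exon_tab$transcript_id == tid, , drop = FALSE]
    cds <- cds_tab[cds_tab$transcript_id == tid, c("start", "end"),
                   drop = FALSE]
    if (!nrow(cds)) cds <- NULL
    m <- tryCatch(
      new_transcript_model(tid, rows$gene_id[1], rows$gene_name[1],
                           rows$biotype[1], rows$chrom[1], rows$strand[1],
                           rows[, c("start", "end")], cds,
                           seqlen = seqlens[[rows$chrom[1]]], config = config),
      error = function(e) {
        warning("skipping transcript ", tid, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(m)) skipped <- c(skipped, tid) else models[[tid]] <- m
  }
  if (!length(models)) stop("no usable transcripts in annotation")

  gene_ids <- vapply(models, function(m) m$gene_id, character(1))
  rep_tx <- character(0)
  for (g in unique(gene_ids)) {
    cand <- models[names(models)[gene_ids == g]]
    rep_tx[g] <- if (config$representative == "all") NA_character_ else
      select_representative(cand)$transcript_id
  }
  if (config$representative == "all") {
    rep_models <- models
  } else {
    rep_models <- models[unname(rep_tx)]
  }

  genes <- data.frame(
    gene_id = vapply(rep_models, function(m) m$gene_id, character(1)),
    gene_name = vapply(rep_models, function(m) m$gene_name, character(1)),
    biotype = vapply(rep_models, function(m) m$biotype, character(1)),
    representative_tx = vapply(rep_models, function(m) m$transcript_id,
                               character(1)),
    row.names = NULL)

  idx <- structure(list(
    transcripts = models,
    rep_models = rep_models,
    genes = genes,
    features = .build_feature_index(rep_models, seqlens),
    genome = genome,
    seqlens = seqlens,
    config = config,
    skipped_transcripts = skipped
  ), class = "AnnotationIndex")
  idx
}

# Genomic GRanges of every derived feature of the representative transcripts.
.build_feature_index <- function(models, seqlens) {
  rows <- list()
  add <- function(m, category, df) {
    if (is.null(df) || !nrow(df)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = m$chrom, start = df$start, end = df$end, strand = m$strand,
      category = category, gene_id = m$gene_id,
      transcript_id = m$transcript_id)
  }
  for (m in models) {
    if (is_coding(m)) {
      add(m, "CDS", m$cds)
      if (diff(m$utr5_range) > 0)
        add(m, "UTR5", tx_range_to_genomic(m, m$utr5_range[1], m$utr5_range[2]))
      if (diff(m$utr3_range) > 0)
        add(m, "UTR3", tx_range_to_genomic(m, m$utr3_range[1], m$utr3_range[2]))
    } else {
      add(m, "exon_nc", m$exons)
    }
    add(m, "intron", m$introns)
    add(m, "promoter", data.frame(start = m$promoter$start,
                                  end = m$promoter$end))
    add(m, "downstream", data.frame(start = m$downstream$start,
                                    end = m$downstream$end))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[tab$end > tab$start, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    strand = tab$strand)
  S4Vectors::mcols(gr)$category <- tab$category
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$transcript_id
  gr
}

#' @export
print.AnnotationIndex <- function(x, ...) {
  cat(sprintf(
    "AnnotationIndex: %d transcripts, %d genes, %d feature intervals, %d chromosome(s)\n",
    length(x$transcripts), nrow(x$genes), length(x$features),
    length(x$genome)))
  if (length(x$skipped_transcripts))
    cat("  skipped transcripts (CDS outside exons):",
        length(x$skipped_transcripts), "\n")
  invisible(x)
}

## ---- GTF/FASTA loading -----------------------------------------------------

# Cheap structural validation so malformed lines are reported with their line
# number before rtracklayer parses the file.
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop("malformed GTF line ", i, ": bad coordinates '", f[4], "'..'",
           f[5], "'")
  }
  invisible(length(lines))
}

.first_non_na <- function(...) {
  for (v in list(...)) if (!is.null(v) && !all(is.na(v))) return(v)
  NULL
}

#' Load a transcript annotation index from GTF and genome FASTA
#'
#' Parses exon and CDS records into per-transcript models (coordinates
#' converted from the GTF's 1-based closed convention to 0-based half-open),
#' selects one representative transcript per gene, derives promoters,
#' downstream regions, introns, splice-junction and codon positions, and builds
#' a genomic interval index over all derived features for overlap queries.
#'
#' `gene_biotype` attributes are used where present, falling back to
#' `gene_type` (GENCODE) and then to `"unknown"`. Transcripts whose CDS falls
#' outside their exons are skipped with a warning and counted.
#'
#' @param gtf_path Path to a GTF file with exon (and optionally CDS) records
#'   carrying `gene_id` and `transcript_id` attributes.
#' @param fasta_path Path to the genome FASTA; every chromosome used in the
#'   GTF must be present (hard error listing mismatches otherwise).
#' @param config An [annotation_config()].
#' @return An `AnnotationIndex`.
#' @export
load_annotation <- function(gtf_path, fasta_path,
                            config = annotation_config()) {
  .validate_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  keep <- as.character(mc$type) %in% c("exon", "CDS")
  gr <- gr[keep]; mc <- S4Vectors::mcols(gr)
  if (!length(gr)) stop("GTF contains no exon records")
  if (is.null(mc$gene_id) || is.null(mc$transcript_id))
    stop("GTF records lack gene_id/transcript_id attributes")

  biotype <- .first_non_na(mc$gene_biotype, mc$gene_type)
  if (is.null(biotype)) biotype <- rep("unknown", length(gr))
  biotype[is.na(biotype)] <- "unknown"
  gname <- .first_non_na(mc$gene_name)
  if (is.null(gname)) gname <- mc$gene_id
  gname[is.na(gname)] <- mc$gene_id[is.na(gname)]

  tab <- data.frame(
    type = as.character(mc$type),
    transcript_id = mc$transcript_id,
    gene_id = mc$gene_id,
    gene_name = gname,
    biotype = biotype,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr))

  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  exon_tab <- tab[tab$type == "exon", , drop = FALSE]
  cds_tab <- tab[tab$type == "CDS", c("transcript_id", "start", "end"),
                 drop = FALSE]
  build_annotation_index(exon_tab, cds_tab, genome, config)
}

## ---- sequence extraction ---------------------------------------------------

# Spliced, strand-corrected sequence of one transcript.
transcript_sequence <- function(index, model) {
  chrom <- index$genome[[model$chrom]]
  parts <- Biostrings::DNAStringSet(lapply(seq_len(nrow(model$exons)),
    function(i) chrom[(model$exons$start[i] + 1L):model$exons$end[i]]))
  seq <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (model$strand == "-") seq <- Biostrings::reverseComplement(seq)
  seq
}

#' Extract spliced region sequences of the representative transcripts
#'
#' @param index An `AnnotationIndex`.
#' @param region One of `"utr5"`, `"cds"`, `"utr3"`, `"tx"`. Non-coding
#'   transcripts are omitted for the three mRNA sub-regions.
#' @return A named `DNAStringSet` (names are transcript ids); sequences are
#'   strand-corrected (reverse-complemented for minus-strand transcripts).
#' @export
extract_region_sequences <- function(index,
                                     region = c("tx", "utr5", "cds", "utr3")) {
  region <- match.arg(region)
  out <- list()
  for (m in index$rep_models) {
    rng <- switch(region,
      tx = c(0L, m$tx_length),
      utr5 = m$utr5_range, cds = m$cds_range, utr3 = m$utr3_range)
    if (is.null(rng) || diff(rng) <= 0) next
    seq <- transcript_sequence(index, m)
    out[[m$transcript_id]] <- as.character(seq[(rng[1] + 1L):rng[2]])
  }
  if (!length(out)) return(Biostrings::DNAStringSet())
  Biostrings::DNAStringSet(unlist(out))
}
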