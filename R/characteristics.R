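#' Per-region gene characteristics of the representative transcripts
#'
#' Sequence length and GC content per region; an optional secondary-structure
#' score (e.g. minimum free energy from an external folding tool) is filled
#' only when a backend is supplied, otherwise left absent (`NA`).
#'
#' @param index An `AnnotationIndex`.
#' @param regions Subset of `c("utr5","cds","utr3","tx")`.
#' @param structure_backend Either `NULL` (no structure score), a function
#'   mapping a character vector of sequences to a numeric vector of scores, or
#'   a command template string containing `%s` which is replaced by a FASTA
#'   file of the sequences and must print one numeric score per sequence.
#' @return Data frame with `gene_id`, `transcript_id`, `region`, `length`,
#'   `gc`, `structure_score`.
#' @export
compute_characteristics <- function(index,
                                    regions = c("utr5", "cds", "utr3", "tx"),
                                    structure_backend = NULL) {
  regions <- match.arg(regions, c("utr5", "cds", "utr3", "tx"),
                       several.ok = TRUE)
  backend <- structure_backend
  if (is.character(backend)) backend <- structure_backend_command(backend)
  out <- list()
  for (r in regions) {
    seqs <- extract_region_sequences(index, r)
    if (!length(seqs)) next
    gc <- Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE)[, 1]
    tid <- names(seqs)
    gid <- vapply(tid, function(t) index$transcripts[[t]]$gene_id,
                  character(1))
    score <- if (is.null(backend)) rep(NA_real_, length(seqs)) else
      backend(as.character(seqs))
    out[[r]] <- data.frame(gene_id = unname(gid), transcript_id = tid,
                           region = r,
                           length = Biostrings::width(seqs),
                           gc = unname(gc), structure_score = score,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a structure-score backend from a shell command template
#'
#' The template must contain `%s`, replaced by the path of a temporary FASTA
#' file holding the query sequences; the command must print one numeric score
#' per sequence (whitespace-separated), e.g. a wrapper around an RNA folding
#' tool emitting minimum free energies.
#'
#' @param template Command template string.
#' @return A function `character -> numeric` usable as `structure_backend`.
#' @export
structure_backend_command <- function(template) {
  stopifnot(grepl("%s", template, fixed = TRUE))
  function(seqs) {
    fa <- tempfile(fileext = ".fa")
    on.exit(unlink(fa))
    writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fa)
    out <- system(sprintf(template, fa), intern = TRUE)
    vals <- as.numeric(unlist(strsplit(paste(out, collapse = " "), "\\s+")))
    vals <- vals[!is.na(vals)]
    if (length(vals) != length(seqs))
      stop("structure backend returned ", length(vals), " score(s) for ",
           length(seqs), " sequence(s)")
    vals
  }
}

#' Compare gene characteristics between a foreground set and background
#'
#' For every region and characteristic present in `table`, compares the
#' foreground genes against the background (default: all other genes) with a
#' two-sided Mann-Whitney U test (exact p for groups of at most 8, normal
#' approximation with tie correction otherwise). Effect direction is the sign
#' of the foreground-vs-background median difference. q-values are BH-adjusted
#' across all comparisons in the report.
#'
#' @param foreground Character vector of foreground gene ids.
#' @param table Output of [compute_characteristics()].
#' @param background Character vector of background gene ids, or `NULL` for
#'   all non-foreground genes in `table`.
#' @return Data frame with `region`, `characteristic`, `n_fg`, `n_bg`,
#'   `median_fg`, `median_bg`, `direction`, `p`, `q`.
#' @export
compare_characteristics <- function(foreground, table, background = NULL) {
  universe <- unique(table$gene_id)
  foreground <- intersect(foreground, universe)
  if (!length(foreground)) stop("foreground is empty after id matching")
  if (is.null(background)) background <- setdiff(universe, foreground)
  background <- setdiff(intersect(background, universe), foreground)
  if (!length(background))
    stop("background is empty: foreground equals the gene universe")
  chars <- intersect(c("length", "gc", "structure_score"), names(table))
  rows <- list()
  for (r in unique(table$region)) {
    sub <- table[table$region == r, , drop = FALSE]
    for (ch in chars) {
      x <- sub[[ch]][sub$gene_id %in% foreground]
      y <- sub[[ch]][sub$gene_id %in% background]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) next
      exact <- length(x) <= 8 && length(y) <= 8
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value),
        error = function(e) NA_real_)
      if (is.na(p)) p <- 1
      md <- stats::median(x) - stats::median(y)
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, characteristic = ch,
        n_fg = length(x), n_bg = length(y),
        median_fg = stats::median(x), median_bg = stats::median(y),
        direction = if (md > 0) "greater" else if (md < 0) "less" else "none",
        p = p)
    }
  }
  if (!length(rows)) stop("no comparable characteristics")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
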