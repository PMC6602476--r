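#' Construct a SiteSet from a data frame of modification intervals
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open genomic) and optionally `name`, `score`, `strand`.
#' @param source_label Label carried through reports.
#' @param dedup Drop duplicate `(chrom, start, end, strand)` records
#'   (default TRUE, with a warning when any are dropped).
#' @return A `SiteSet`: a data frame sorted by `(chrom, start)` with
#'   attributes `source_label`, `n_skipped` and `is_single_nucleotide`.
#' @export
site_set <- function(df, source_label = "sites", dedup = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$name)) df$name <- rep(".", nrow(df))
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  df <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (nrow(df) && any(df$start >= df$end))
    stop("site intervals must satisfy start < end")
  if (nrow(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (dedup && nrow(df)) {
    key <- paste(df$chrom, df$start, df$end, df$strand)
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)), " duplicate site(s) dropped")
      df <- df[!duplicated(key), , drop = FALSE]
    }
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("SiteSet", "data.frame"),
            source_label = source_label,
            n_skipped = attr(df, "n_skipped") %||% 0L,
            is_single_nucleotide = nrow(df) > 0 && all(df$end - df$start == 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.SiteSet <- function(x, ...) {
  cat(sprintf("SiteSet '%s': %d site(s)%s, %d malformed line(s) skipped\n",
              attr(x, "source_label"), nrow(x),
              if (isTRUE(attr(x, "is_single_nucleotide")))
                " (single-nucleotide)" else "",
              attr(x, "n_skipped") %||% 0L))
  NextMethod()
}

.open_text <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gz") return(readLines(gzfile(path), warn = FALSE))
  if (ext == "zip") {
    members <- utils::unzip(path, list = TRUE)$Name
    if (length(members) != 1)
      stop("zip archive must contain exactly one member, found ",
           length(members))
    con <- unz(path, members[1])
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  readLines(path, warn = FALSE)
}

#' Read modification sites from a BED file
#'
#' Accepts BED3 to BED6, plain text or gzip/zip-compressed (one member).
#' Missing name/score/strand columns are filled with `"."`, `0`, `"."`.
#' `track`, `browser` and `#` comment lines are skipped. Data lines with
#' non-numeric coordinates or `start >= end` are rejected and counted in the
#' `n_skipped` attribute; a data line with fewer than three columns is a hard
#' error reported with its line number.
#'
#' @param path Path to the BED file.
#' @param source_label Label for reports; defaults to the file name.
#' @param dedup Drop duplicate records (default TRUE).
#' @return A `SiteSet` (BED coordinates are kept 0-based half-open).
#' @export
read_bed <- function(path, source_label = basename(path), dedup = TRUE) {
  lines <- .open_text(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  if (!any(keep)) stop("no data lines in BED file '", path, "'")
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop("BED line ", idx[which(ncol < 3)[1]],
         ": fewer than 3 columns")
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default,
           character(1))
  }
  df <- data.frame(
    chrom = get(1, "."),
    start = suppressWarnings(as.integer(get(2, NA))),
    end = suppressWarnings(as.integer(get(3, NA))),
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = get(6, "."))
  df$score[is.na(df$score)] <- 0
  df$strand[!df$strand %in% c("+", "-", ".")] <- "."
  bad <- is.na(df$start) | is.na(df$end) | df$start >= df$end |
    !nzchar(df$chrom)
  n_skipped <- sum(bad)
  if (n_skipped)
    message(n_skipped, " malformed BED line(s) skipped")
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df)) stop("no valid records in BED file '", path, "'")
  ss <- site_set(df, source_label = source_label, dedup = dedup)
  attr(ss, "n_skipped") <- n_skipped
  ss
}

#' Write a SiteSet as BED
#'
#' Emits BED6; with `feature_col = TRUE` a seventh column holds the resolved
#' feature category (a documented extension beyond strict BED6).
#'
#' @param sites A `SiteSet` (optionally carrying a `category` column from
#'   [assign_features()] when `feature_col = TRUE`).
#' @param path Output path.
#' @param feature_col Append the category column (default FALSE).
#' @export
write_bed <- function(sites, path, feature_col = FALSE) {
  df <- as.data.frame(sites)[, c("chrom", "start", "end", "name", "score",
                                 "strand")]
  if (feature_col) df$category <- as.data.frame(sites)$category %||% "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Midpoints of site intervals
#'
#' `floor((start + end) / 2)`; a single-nucleotide site returns its own
#' position.
#'
#' @param sites A `SiteSet` or data frame with `start`/`end`.
#' @return Integer vector of 0-based genomic positions.
#' @export
site_midpoints <- function(sites) {
  as.integer((sites$start + sites$end) %/% 2L)
}

# SiteSet -> GRanges (1-based); "." strand becomes "*".
sites_as_granges <- function(sites) {
  st <- sites$strand
  st[st == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    strand = st)
  S4Vectors::mcols(gr)$name <- sites$name
  S4Vectors::mcols(gr)$score <- sites$score
  S4Vectors::mcols(gr)$row <- seq_len(nrow(sites))
  gr
}

#' Intersection or union of two site sets
#'
#' Intersection keeps the sites of `a` that overlap (by at least one
#' nucleotide) any site of `b`; the symmetric list (sites of `b` overlapping
#' `a`) is attached as attribute `other`. Union merges the two interval sets.
#' Overlap respects strand only when both strands are known (`"."` matches
#' both).
#'
#' @param a,b `SiteSet` objects on the same genome.
#' @param op `"intersection"` or `"union"`.
#' @param strand_aware Respect strand where known (default TRUE).
#' @return A `SiteSet`.
#' @export
set_algebra <- function(a, b, op = c("intersection", "union"),
                        strand_aware = TRUE) {
  op <- match.arg(op)
  ga <- sites_as_granges(a); gb <- sites_as_granges(b)
  if (op == "intersection") {
    hit_a <- IRanges::overlapsAny(ga, gb,
                                        ignore.strand = !strand_aware)
    hit_b <- IRanges::overlapsAny(gb, ga,
                                        ignore.strand = !strand_aware)
    res <- site_set(as.data.frame(a)[hit_a, , drop = FALSE],
                    source_label = "intersection", dedup = FALSE)
    attr(res, "other") <- site_set(as.data.frame(b)[hit_b, , drop = FALSE],
                                   source_label = "intersection_other",
                                   dedup = FALSE)
    return(res)
  }
  merged <- GenomicRanges::reduce(c(ga, gb), ignore.strand = !strand_aware)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    name = ".", score = 0,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(merged))))
  site_set(df, source_label = "union", dedup = FALSE)
}
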