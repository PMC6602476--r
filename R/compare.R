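#' Compare modification distributions between two or more groups
#'
#' Runs the single-case annotation layer per group, computes the pairwise
#' site-overlap matrix (diagonal: per-group site counts; off-diagonal:
#' overlapping interval pairs), side-by-side category fractions, per-group
#' metagene profiles, and a combined site set (intersection or union across
#' groups) that feeds the shared annotations.
#'
#' @param site_sets Named list of at least two `SiteSet` objects.
#' @param index An `AnnotationIndex`.
#' @param mode How the combined set is formed: `"union"` or `"intersection"`.
#' @param bins Metagene bins per region.
#' @param strand_aware Respect strand in overlaps where known.
#' @return A `GroupComparison`: list with `labels`, `per_group` (each holding
#'   `assignments`, `categories`, `biotypes`, `metagene`), `overlap_matrix`,
#'   `category_contrast`, `combined_mode`, `combined` (a `SiteSet`) and
#'   `combined_assignments` (`NULL` when the combined set is empty).
#' @export
group_compare <- function(site_sets, index,
                          mode = c("union", "intersection"),
                          bins = 100L, strand_aware = TRUE) {
  mode <- match.arg(mode)
  if (length(site_sets) < 2) stop("group comparison needs >= 2 groups")
  labels <- names(site_sets)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- paste0("group", seq_along(site_sets))
  names(site_sets) <- labels

  per_group <- lapply(site_sets, function(ss) {
    a <- assign_features(ss, index)
    list(assignments = a,
         categories = category_distribution(a),
         biotypes = biotype_distribution(a),
         metagene = tryCatch(metagene(a, index, bins = bins),
                             error = function(e) NULL))
  })

  k <- length(site_sets)
  ov <- matrix(0L, k, k, dimnames = list(labels, labels))
  grs <- lapply(site_sets, sites_as_granges)
  for (i in seq_len(k)) {
    ov[i, i] <- nrow(site_sets[[i]])
    for (j in seq_len(k)) {
      if (j <= i) next
      n <- length(GenomicRanges::findOverlaps(
        grs[[i]], grs[[j]], ignore.strand = !strand_aware))
      ov[i, j] <- ov[j, i] <- n
    }
  }

  contrast <- do.call(rbind, lapply(labels, function(l) {
    d <- per_group[[l]]$categories
    d$group <- l
    d
  }))

  combined <- Reduce(function(a, b)
    set_algebra(a, b, op = mode, strand_aware = strand_aware), site_sets)
  combined_assignments <- if (nrow(combined)) {
    assign_features(site_set(as.data.frame(combined), dedup = FALSE), index)
  } else {
    message("combined ", mode, " set is empty; shared annotations skipped")
    NULL
  }

  structure(list(labels = labels, per_group = per_group,
                 overlap_matrix = ov, category_contrast = contrast,
                 combined_mode = mode, combined = combined,
                 combined_assignments = combined_assignments),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison: %d groups (%s), combined %s set of %d site(s)\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              x$combined_mode, nrow(x$combined)))
  invisible(x)
}

#' Contrast a user gene list against background genes
#'
#' Splits the assignments into sites hosted by the listed genes versus all
#' other genes and mirrors the group-case outputs: contrasted category
#' distributions, in-list and background metagene profiles, and a gene
#' characteristics comparison. Gene ids are matched exactly against
#' `gene_id`, with fallback to `gene_name` (case-sensitive); unmatched ids
#' are reported.
#'
#' @param assignments Output of [assign_features()].
#' @param gene_list Character vector of gene ids or names.
#' @param index An `AnnotationIndex`.
#' @param bins Metagene bins per region.
#' @param structure_backend Passed to [compute_characteristics()].
#' @return A `GeneCaseReport`: list with `matched_genes`, `unmatched_ids`,
#'   `category_contrast`, `metagene_in`, `metagene_bg`,
#'   `characteristics_comparison` (NULL when background is empty).
#' @export
gene_case <- function(assignments, gene_list, index, bins = 100L,
                      structure_backend = NULL) {
  gene_list <- unique(gene_list[nzchar(gene_list)])
  if (!length(gene_list)) stop("empty gene list")
  by_id <- gene_list[gene_list %in% index$genes$gene_id]
  by_name <- gene_list[!gene_list %in% by_id &
                         gene_list %in% index$genes$gene_name]
  matched <- unique(c(
    by_id,
    index$genes$gene_id[match(by_name, index$genes$gene_name)]))
  unmatched <- setdiff(gene_list, c(by_id, by_name))
  if (!length(matched))
    stop("no gene ids matched the annotation; accepted namespaces are ",
         "gene_id (e.g. '", index$genes$gene_id[1], "') and gene_name (e.g. '",
         index$genes$gene_name[1], "')")

  in_list <- assignments[!is.na(assignments$gene_id) &
                           assignments$gene_id %in% matched, , drop = FALSE]
  bg <- assignments[!(!is.na(assignments$gene_id) &
                        assignments$gene_id %in% matched), , drop = FALSE]
  contrast <- rbind(
    cbind(category_distribution(in_list), group = "in_list"),
    cbind(category_distribution(bg), group = "background"))

  mg_in <- tryCatch(metagene(in_list, index, bins = bins),
                    error = function(e) NULL)
  mg_bg <- if (nrow(bg)) tryCatch(metagene(bg, index, bins = bins),
                                  error = function(e) NULL) else NULL

  chars <- compute_characteristics(index,
                                   structure_backend = structure_backend)
  cc <- tryCatch(compare_characteristics(matched, chars),
                 error = function(e) {
                   message("characteristics comparison degenerate: ",
                           conditionMessage(e))
                   NULL
                 })
  structure(list(matched_genes = matched, unmatched_ids = unmatched,
                 category_contrast = contrast,
                 metagene_in = mg_in, metagene_bg = mg_bg,
                 characteristics = chars,
                 characteristics_comparison = cc),
            class = "GeneCaseReport")
}

#' @export
print.GeneCaseReport <- function(x, ...) {
  cat(sprintf("GeneCaseReport: %d matched gene(s), %d unmatched id(s)\n",
              length(x$matched_genes), length(x$unmatched_ids)))
  invisible(x)
}
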