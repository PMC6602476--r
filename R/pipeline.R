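## End-to-end runners behind the command-line interface: each writes the full
## annotation suite of one analysis case into an output directory as TSV/JSON
## (and BED) files. All tables state 0-based half-open coordinates.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a complete fixture bundle (genome, annotation, sites, gene sets)
#'
#' Convenience wrapper over [make_transcriptome()], [load_annotation()],
#' [make_sites()] and [make_gene_sets()]: writes `genome.fa`,
#' `annotation.gtf`, `sites.bed`, `sites_truth.tsv`, `gene_list.txt` and
#' `genesets.gmt` into `dir`. When a motif is planted the genome FASTA is
#' rewritten with the edited sequence.
#'
#' @param dir Output directory.
#' @param spec A [fixture_spec()].
#' @param n_sites Number of sites.
#' @param placement Site placement model.
#' @param width Site width (nt).
#' @param site_seed Seed for site generation.
#' @param planted_motif Optional IUPAC motif planted under every site.
#' @return List of paths plus the loaded `index`, `sites` and `truth`.
#' @export
run_fixtures <- function(dir, spec = fixture_spec(), n_sites = 2000L,
                         placement = placement_anchor("stop_codon", sd = 30),
                         width = 1L, site_seed = spec$seed + 1L,
                         planted_motif = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- make_transcriptome(spec, dir)
  index <- load_annotation(tr$gtf, tr$fasta)
  made <- make_sites(index, n = n_sites, placement = placement,
                     width = width, seed = site_seed,
                     planted_motif = planted_motif)
  if (!is.null(planted_motif)) {
    Biostrings::writeXStringSet(made$genome, tr$fasta)
    index <- load_annotation(tr$gtf, tr$fasta)
  }
  bed <- file.path(dir, "sites.bed")
  write_bed(made$sites, bed)
  truth_path <- file.path(dir, "sites_truth.tsv")
  write_tsv(made$truth, truth_path)

  modified <- unique(made$truth$gene_id)
  gene_list <- file.path(dir, "gene_list.txt")
  writeLines(utils::head(sort(modified), 10L), gene_list)
  gmt <- file.path(dir, "genesets.gmt")
  make_gene_sets(index$genes$gene_id, utils::head(sort(modified), 10L),
                 gmt, seed = spec$seed)
  list(dir = dir, fasta = tr$fasta, gtf = tr$gtf, bed = bed,
       truth_path = truth_path, gene_list = gene_list, gmt = gmt,
       index = index, sites = made$sites, truth = made$truth)
}

.as_siteset <- function(x) {
  if (inherits(x, "SiteSet")) x else read_bed(x)
}

.as_index <- function(index, gtf, fasta, config) {
  if (!is.null(index)) return(index)
  if (is.null(gtf) || is.null(fasta))
    stop("either an AnnotationIndex or gtf + fasta paths are required")
  load_annotation(gtf, fasta, config)
}

#' Annotate one modification site set (single case)
#'
#' Runs the full annotation suite on one BED input and writes every output
#' class as a file: per-site assignments and modified-gene lists, feature and
#' biotype distributions, feature-coverage densities, boundary coverage with
#' 95% CI and occupancy heatmaps around TSS/TES, start/stop codons and splice
#' junctions, the whole-mRNA metagene, top enriched k-mers, gene
#' characteristics with a modified-vs-background comparison, and (when GMT
#' collections are given) hypergeometric gene-set enrichment.
#'
#' @param bed Path to a BED file (plain/.gz/.zip) or a `SiteSet`.
#' @param outdir Output directory.
#' @param gtf,fasta Annotation paths (ignored when `index` is given).
#' @param index Optional prebuilt `AnnotationIndex`.
#' @param config An [annotation_config()].
#' @param gmts Named character vector of GMT paths (e.g.
#'   `c(GO = "go.gmt", pathways = "kegg.gmt")`); one enrichment table is
#'   written per collection.
#' @param bins Metagene bins per region (default 100).
#' @param k_values Motif lengths for k-mer enrichment (default 6, 7, 8).
#' @param motif_window Flank-sequence window for motif analysis (default 41).
#' @param seed Seed for the motif background sampling.
#' @return Invisibly, a list with all computed objects.
#' @export
run_single_case <- function(bed, outdir, gtf = NULL, fasta = NULL,
                            index = NULL, config = annotation_config(),
                            gmts = NULL, bins = 100L,
                            k_values = c(6L, 7L, 8L), motif_window = 41L,
                            seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  index <- .as_index(index, gtf, fasta, config)
  sites <- .as_siteset(bed)

  assignments <- assign_features(sites, index)
  write_tsv(assignments, file.path(outdir, "site_annotations.tsv"))
  write_tsv(category_distribution(assignments),
            file.path(outdir, "feature_categories.tsv"))
  write_tsv(biotype_distribution(assignments),
            file.path(outdir, "biotype_distribution.tsv"))
  genes_tab <- modified_gene_list(assignments)
  write_tsv(genes_tab, file.path(outdir, "modified_genes.tsv"))
  write_tsv(feature_coverage_summary(assignments, index),
            file.path(outdir, "feature_coverage_summary.tsv"))

  boundaries <- list(TSS = config$flank_tss, TES = config$flank_tss,
                     start_codon = config$flank_codon,
                     stop_codon = config$flank_codon,
                     splice5 = config$flank_splice,
                     splice3 = config$flank_splice)
  profiles <- list()
  for (anchor in names(boundaries)) {
    bp <- boundary_coverage(sites, index, anchor, boundaries[[anchor]])
    profiles[[anchor]] <- bp
    write_tsv(cbind(bp$profile, n_units = bp$n_units),
              file.path(outdir, paste0(anchor, "_coverage.tsv")))
    if (anchor %in% c("TSS", "TES", "start_codon", "stop_codon")) {
      hm <- boundary_heatmap(sites, index, anchor, boundaries[[anchor]])
      utils::write.table(hm,
                         file.path(outdir, paste0(anchor, "_heatmap.tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }

  mg <- tryCatch(metagene(assignments, index, bins = bins),
                 error = function(e) NULL)
  if (!is.null(mg)) write_tsv(mg$profile, file.path(outdir, "metagene.tsv"))

  motifs <- tryCatch({
    fl <- extract_flank_sequences(sites, index, window = motif_window,
                                  assignments = assignments, bg_seed = seed)
    km <- kmer_enrichment(fl$fg, fl$bg, k_values = k_values)
    write_tsv(km, file.path(outdir, "motif_enrichment.tsv"))
    write_tsv(top_kmers(km), file.path(outdir, "top_motifs.tsv"))
    km
  }, error = function(e) {
    message("motif enrichment skipped: ", conditionMessage(e))
    NULL
  })

  chars <- compute_characteristics(index)
  write_tsv(chars, file.path(outdir, "gene_characteristics.tsv"))
  char_cmp <- tryCatch(
    compare_characteristics(genes_tab$gene_id, chars),
    error = function(e) NULL)
  if (!is.null(char_cmp))
    write_tsv(char_cmp, file.path(outdir, "characteristics_comparison.tsv"))

  enrich <- list()
  for (nm in names(gmts)) {
    res <- geneset_enrichment(genes_tab$gene_id, read_gmt(gmts[[nm]]),
                              universe = index$genes$gene_id)
    enrich[[nm]] <- res
    write_tsv(res, file.path(outdir,
                             paste0("geneset_enrichment_", nm, ".tsv")))
  }

  summary <- list(
    n_sites = nrow(sites),
    n_skipped_bed_lines = attr(sites, "n_skipped") %||% 0L,
    n_modified_genes = nrow(genes_tab),
    n_unknown_chrom = attr(assignments, "diagnostics")$n_unknown_chrom,
    categories = stats::setNames(
      as.list(category_distribution(assignments)$count), FEATURE_CATEGORIES),
    coordinate_convention = "0-based half-open")
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(index = index, sites = sites, assignments = assignments,
                 genes = genes_tab, boundary = profiles, metagene = mg,
                 motifs = motifs, characteristics = chars,
                 characteristics_comparison = char_cmp, enrichment = enrich))
}

#' Annotate and compare several site sets (group case)
#'
#' @param beds Named list/vector of BED paths or `SiteSet` objects (>= 2).
#' @param outdir Output directory.
#' @inheritParams run_single_case
#' @param mode Combined-set mode: `"union"` or `"intersection"`.
#' @return Invisibly, the `GroupComparison`.
#' @export
run_group_case <- function(beds, outdir, gtf = NULL, fasta = NULL,
                           index = NULL, config = annotation_config(),
                           mode = c("union", "intersection"), bins = 100L) {
  mode <- match.arg(mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  index <- .as_index(index, gtf, fasta, config)
  site_sets <- lapply(beds, .as_siteset)
  if (is.null(names(site_sets)))
    names(site_sets) <- paste0("group", seq_along(site_sets))
  gc <- group_compare(site_sets, index, mode = mode, bins = bins)
  utils::write.table(gc$overlap_matrix,
                     file.path(outdir, "overlap_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_tsv(gc$category_contrast,
            file.path(outdir, "category_contrast.tsv"))
  for (l in gc$labels) {
    write_tsv(gc$per_group[[l]]$categories,
              file.path(outdir, paste0("categories_", l, ".tsv")))
    if (!is.null(gc$per_group[[l]]$metagene))
      write_tsv(gc$per_group[[l]]$metagene$profile,
                file.path(outdir, paste0("metagene_", l, ".tsv")))
  }
  write_bed(gc$combined, file.path(outdir, paste0("combined_", mode, ".bed")))
  if (!is.null(gc$combined_assignments))
    write_tsv(gc$combined_assignments,
              file.path(outdir, "combined_site_annotations.tsv"))
  invisible(gc)
}

#' Contrast a gene list against background (gene case)
#'
#' @param run_dir Directory of a prior single-case run (its
#'   `site_annotations.tsv` supplies the assignments), or `NULL` when
#'   `assignments` is given.
#' @param gene_list Path to a one-id-per-line text file, or a character
#'   vector of gene ids/names.
#' @param outdir Output directory.
#' @param assignments Optional precomputed [assign_features()] output.
#' @inheritParams run_single_case
#' @return Invisibly, the `GeneCaseReport`.
#' @export
run_gene_case <- function(run_dir = NULL, gene_list, outdir, gtf = NULL,
                          fasta = NULL, index = NULL,
                          config = annotation_config(), assignments = NULL,
                          bins = 100L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  index <- .as_index(index, gtf, fasta, config)
  if (is.null(assignments)) {
    if (is.null(run_dir)) stop("need a prior run directory or assignments")
    assignments <- utils::read.delim(
      file.path(run_dir, "site_annotations.tsv"),
      colClasses = c(chrom = "character", strand = "character",
                     category = "character"))
  }
  if (length(gene_list) == 1 && file.exists(gene_list))
    gene_list <- readLines(gene_list, warn = FALSE)
  rep <- gene_case(assignments, gene_list, index, bins = bins)
  write_tsv(rep$category_contrast,
            file.path(outdir, "gene_case_category_contrast.tsv"))
  if (!is.null(rep$metagene_in))
    write_tsv(rep$metagene_in$profile,
              file.path(outdir, "gene_case_metagene_in_list.tsv"))
  if (!is.null(rep$metagene_bg))
    write_tsv(rep$metagene_bg$profile,
              file.path(outdir, "gene_case_metagene_background.tsv"))
  if (!is.null(rep$characteristics_comparison))
    write_tsv(rep$characteristics_comparison,
              file.path(outdir, "gene_case_characteristics_comparison.tsv"))
  writeLines(rep$unmatched_ids,
             file.path(outdir, "gene_case_unmatched_ids.txt"))
  invisible(rep)
}
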