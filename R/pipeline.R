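#' Validate a pipeline configuration
#'
#' A configuration names the inputs and thresholds of a full profiling run.
#' All referenced paths must exist at validation time; the significance
#' level must lie in (0, 1). Can be loaded from YAML.
#'
#' @param atlas path to the expression matrix (CSV/TSV).
#' @param gene_lists named character vector/list of disease gene-list paths.
#' @param out_dir output directory (created if missing).
#' @param annotations optional GMT annotation path.
#' @param interactome optional interactome TSV path.
#' @param staining optional staining-table TSV path.
#' @param housekeeping optional housekeeping gene-list path.
#' @param max_age retained developmental ages (default "23y").
#' @param regions regions to retain (default canonical 11, intersected with
#'   the atlas).
#' @param known_regions region vocabulary accepted by the reader.
#' @param exclude_6mo drop the 6mo time point (off by default; the
#'   systematically low 6mo column is kept, since only maxima matter).
#' @param scheme a [tier_scheme()].
#' @param alpha enrichment significance level.
#' @param correction \code{"BH"} or \code{"none"}.
#' @param max_module_size module size cap for network construction.
#' @return validated config list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(atlas, gene_lists, out_dir,
                            annotations = NULL, interactome = NULL,
                            staining = NULL, housekeeping = NULL,
                            max_age = "23y", regions = canonical_regions(),
                            known_regions = canonical_regions(),
                            exclude_6mo = FALSE,
                            scheme = tier_scheme(), alpha = 0.01,
                            correction = "BH", max_module_size = 35) {
  paths <- c(atlas = atlas, unlist(gene_lists), annotations = annotations,
             interactome = interactome, staining = staining,
             housekeeping = housekeeping)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop_bt("input path(s) do not exist: %s", paste(missing, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop_bt("alpha must lie in (0, 1)")
  if (is.null(names(gene_lists)) || any(!nzchar(names(gene_lists))))
    stop_bt("gene_lists must be named")
  structure(list(atlas = atlas, gene_lists = as.list(gene_lists),
                 out_dir = out_dir, annotations = annotations,
                 interactome = interactome, staining = staining,
                 housekeeping = housekeeping, max_age = max_age,
                 regions = regions, known_regions = known_regions,
                 exclude_6mo = exclude_6mo, scheme = scheme, alpha = alpha,
                 correction = correction,
                 max_module_size = max_module_size),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Relative paths in the YAML are resolved against the YAML file's
#' directory.
#'
#' @param path YAML config path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  scheme_args <- cfg$scheme %||% list()
  pipeline_config(
    atlas = fix(cfg$atlas),
    gene_lists = lapply(cfg$gene_lists, fix),
    out_dir = if (is.null(cfg$out_dir)) file.path(base, "results")
              else if (grepl("^(/|[A-Za-z]:)", cfg$out_dir)) cfg$out_dir
              else file.path(base, cfg$out_dir),
    annotations = fix(cfg$annotations),
    interactome = fix(cfg$interactome),
    staining = fix(cfg$staining),
    housekeeping = fix(cfg$housekeeping),
    max_age = cfg$max_age %||% "23y",
    regions = cfg$regions %||% canonical_regions(),
    known_regions = cfg$known_regions %||% canonical_regions(),
    exclude_6mo = cfg$exclude_6mo %||% FALSE,
    scheme = do.call(tier_scheme, scheme_args),
    alpha = cfg$alpha %||% 0.01,
    correction = cfg$correction %||% "BH",
    max_module_size = cfg$max_module_size %||% 35)
}

#' Run the full profiling pipeline
#'
#' Reads and filters the atlas, assigns per-region tiers, writes tier
#' heatmaps and a per-region summary for every disease list, Venn counts,
#' highly-expressed GMT subsets, optional housekeeping calibration, term
#' enrichment (all genes vs highly expressed, compared), interactome
#' module overlay, and staining specificity calls. Outputs are
#' deterministic TSV/GMT/JSON files plus a run manifest recording row
#' counts at every stage.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of in-memory results; files under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_bt("config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(config$out_dir, ...)
  manifest <- list(alpha = config$alpha, correction = config$correction,
                   max_age = config$max_age,
                   boundaries = config$scheme$boundaries)

  atlas <- read_expression_matrix(config$atlas,
                                  known_regions = config$known_regions)
  atlas <- filter_ages(atlas, config$max_age)
  keep_regions <- intersect(config$regions, atlas_regions(atlas))
  if (length(keep_regions) == 0) stop_bt("no requested region present in atlas")
  atlas <- subset_regions(atlas, keep_regions)
  if (config$exclude_6mo && "6mo" %in% atlas$samples$age) {
    keep <- atlas$samples$age != "6mo"
    atlas <- expression_atlas(atlas$values[, keep, drop = FALSE],
                              atlas$samples$region[keep],
                              atlas$samples$age[keep])
  }
  manifest$n_genes <- length(atlas$genes)
  manifest$n_samples <- nrow(atlas$samples)
  manifest$regions <- atlas_regions(atlas)

  assignments <- assign_region_tiers(atlas, config$scheme)

  sets <- list(); excluded <- list()
  for (nm in names(config$gene_lists)) {
    parsed <- parse_gene_list(config$gene_lists[[nm]], atlas, name = nm)
    sets[[nm]] <- parsed$set
    excluded[[nm]] <- parsed$excluded
    manifest[[paste0("excluded_", nm)]] <- length(parsed$excluded)
  }

  results <- list(atlas = atlas, assignments = assignments, sets = sets,
                  excluded = excluded)

  if (!is.null(config$housekeeping)) {
    hk <- parse_gene_list(config$housekeeping, atlas, name = "housekeeping")$set
    results$calibration <- housekeeping_calibration(atlas, hk, config$scheme)
    manifest$housekeeping_within_limit <- results$calibration$n_within_limit
    manifest$housekeeping_offending <- results$calibration$offending
  }

  high_sets <- list()
  for (nm in names(sets)) {
    sub <- assignments[assignments$gene %in% sets[[nm]]$members, , drop = FALSE]
    export_heatmap(sub, outp(sprintf("heatmap_%s.tsv", nm)))
    summ <- summarize_region(sets[[nm]], assignments)
    utils::write.table(summ, outp(sprintf("summary_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hs <- highly_expressed_subset(sets[[nm]], assignments, allow_empty = TRUE)
    if (!inherits(hs, "gene_set")) hs <- NULL
    high_sets[[nm]] <- hs
    manifest[[paste0("n_high_", nm)]] <-
      if (is.null(hs)) 0L else length(hs$members)
  }
  results$summaries <- lapply(sets, summarize_region, assignments = assignments)
  results$high_sets <- high_sets
  write_gmt(Filter(Negate(is.null), high_sets), outp("highly_expressed.gmt"))

  if (length(sets) >= 2) {
    results$venn <- venn_counts(sets[seq_len(min(3, length(sets)))])
    jsonlite::write_json(results$venn$regions, outp("venn_members.json"))
    vdf <- data.frame(region = names(results$venn$regions),
                      n = vapply(results$venn$regions, length, 0L))
    utils::write.table(vdf, outp("venn_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$annotations)) {
    ann <- read_annotation_gmt(config$annotations)
    results$enrichment <- list()
    for (nm in names(sets)) {
      if (is.null(high_sets[[nm]])) next
      universe <- gene_set("universe", atlas$genes)
      res_full <- fisher_enrich(sets[[nm]], universe, ann,
                                alpha = config$alpha,
                                correction = config$correction)
      res_high <- fisher_enrich(high_sets[[nm]], universe, ann,
                                alpha = config$alpha,
                                correction = config$correction)
      write_enrichment(res_full, outp(sprintf("enrichment_%s_all.tsv", nm)))
      write_enrichment(res_high, outp(sprintf("enrichment_%s_high.tsv", nm)))
      results$enrichment[[nm]] <-
        list(all = res_full, high = res_high,
             comparison = compare_enrichments(res_full, res_high))
    }
  }

  if (!is.null(config$interactome) && length(high_sets) > 0) {
    net <- read_interactome(config$interactome)
    first <- names(sets)[1]
    mods_all <- build_focus_modules(sets[[first]], net,
                                    max_size = config$max_module_size,
                                    source = "all_genes")
    mods <- mods_all
    if (!is.null(high_sets[[first]])) {
      mods_high <- build_focus_modules(high_sets[[first]], net,
                                       max_size = config$max_module_size,
                                       source = "high_genes")
      for (i in seq_along(mods_high))
        mods_high[[i]]$id <- sprintf("H%02d", i)
      mods <- c(mods_high, mods_all)
    }
    if (length(mods) >= 2) {
      results$meta <- overlay_meta_graph(mods, net)
      write_meta_graph(results$meta, outp("meta_graph.tsv"))
      results$central <- central_modules(results$meta)
      manifest$n_modules <- length(mods)
      manifest$n_orphans <- length(results$meta$orphans)
    }
  }

  if (!is.null(config$staining)) {
    st <- read_staining_table(config$staining)
    first_high <- high_sets[[names(sets)[1]]]
    results$specificity <- specificity_call(
      st, genes = if (!is.null(first_high)) first_high$members else NULL)
    utils::write.table(results$specificity, outp("specificity_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$specificity_counts <-
      summarize_specificity(results$specificity)$counts
  }

  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE)
  results$manifest <- manifest
  invisible(results)
}
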