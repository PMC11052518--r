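#' Assemble and validate a pipeline configuration
#'
#' A configuration either points at input files (`table`, `taxonomy`,
#' `metadata` TSV paths) or carries a [community_design()] for synthetic
#' input. It fixes the rarefaction depth, dissimilarity metrics, grouping
#' factors for the comparison stage, permutation counts, the grouping
#' factor for per-group networks, RMT scan settings and the master seed.
#' The configuration is serialised verbatim into the output directory so
#' a run can be reproduced exactly.
#'
#' @param input named list with file paths `table`, `metadata` and
#'   optionally `taxonomy`, or `NULL` to simulate.
#' @param design a [community_design()] used when `input` is `NULL`.
#' @param depth rarefaction depth.
#' @param metrics dissimilarity metrics for the beta stage.
#' @param grouping metadata factors tested in the comparison stage.
#' @param n_perm permutations for PERMANOVA/MRPP.
#' @param nmds_starts random starts for the ordination stage.
#' @param network_group metadata factor defining one network per level.
#' @param rmt named list overriding [rmt_threshold()] settings
#'   (`thresholds`, `alpha`, `stability`, `unfold_df`, `min_spacings`).
#' @param compose_ranks taxonomic ranks summarised by the composition
#'   stage (requires a taxonomy).
#' @param seed master seed; stage seeds are derived from it.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, design = NULL, depth = 17248L,
                            metrics = c("bray_curtis", "jaccard"),
                            grouping = c("species", "season", "gut_part"),
                            n_perm = 999L, nmds_starts = 10L,
                            network_group = "species", rmt = list(),
                            compose_ranks = c("phylum", "genus"),
                            seed = 1L) {
  if (is.null(input) && is.null(design))
    stop("provide either `input` paths or a synthetic `design`")
  if (!is.null(input)) {
    if (!all(c("table", "metadata") %in% names(input)))
      stop("`input` needs at least `table` and `metadata` paths")
  }
  if (!is.null(design) && !inherits(design, "community_design"))
    stop("`design` must be a community_design")
  metrics <- match.arg(metrics, c("bray_curtis", "jaccard",
                                  "jaccard_quant"), several.ok = TRUE)
  grouping <- match.arg(grouping, c("species", "season", "gut_part"),
                        several.ok = TRUE)
  network_group <- match.arg(network_group,
                             c("species", "season", "gut_part"))
  compose_ranks <- match.arg(compose_ranks, taxonomy_ranks,
                             several.ok = TRUE)
  stopifnot(depth >= 1, n_perm >= 1, nmds_starts >= 1)
  cfg <- list(input = input, design = design, depth = as.integer(depth),
              metrics = metrics, grouping = grouping,
              n_perm = as.integer(n_perm),
              nmds_starts = as.integer(nmds_starts),
              network_group = network_group, rmt = rmt,
              compose_ranks = compose_ranks, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the same keys as [pipeline_config()]; a `design` mapping is
#' passed to [community_design()].
#'
#' @param path YAML file path.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) y$design <- do.call(community_design, y$design)
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path, rownames_to = NULL) {
  if (!is.null(rownames_to)) {
    df <- data.frame(stats::setNames(list(rownames(df)), rownames_to),
                     as.data.frame(df), check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Mean relative abundance per design cell at a taxonomic rank
#'
#' Aggregates the table to `rank` as relative abundances and averages the
#' sample columns within each species x season x gut-part cell.
#'
#' @param table an [asv_table()].
#' @param tax a [taxonomy_table()].
#' @param metadata a [sample_metadata()].
#' @param rank taxonomic rank.
#' @return matrix taxa x cells; cell names are
#'   `species|season|gut_part`.
#' @export
compose_summary <- function(table, tax, metadata, rank = "phylum") {
  rel <- aggregate_by_taxon(table, tax, rank)
  md <- metadata[match(colnames(rel), metadata$sample_id), ]
  cell <- paste(md$species, md$season, md$gut_part, sep = "|")
  cells <- unique(cell)
  out <- vapply(cells, function(cl)
    rowMeans(rel[, cell == cl, drop = FALSE]), numeric(nrow(rel)))
  matrix(out, nrow = nrow(rel), dimnames = list(rownames(rel), cells))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (read or simulate), rarefaction, alpha
#' diversity with group comparisons, beta diversity (distance matrices,
#' NMDS ordination, PERMANOVA + MRPP per grouping factor and metric),
#' composition summaries (when a taxonomy is available) and per-group
#' co-occurrence networks. Every artifact is written to `out_dir` as
#' TSV/JSON/GraphML together with a `manifest.json` recording inputs,
#' seeds, conventions, package version, completed stages and every
#' dropped sample or failed network with its reason. Identical
#' configuration and seed reproduce all outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly; the manifest is also returned as the
#'   `"manifest"` attribute.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ecomena",
                   version = as.character(utils::packageVersion("ecomena")),
                   seed = config$seed, stages = character(0),
                   conventions = list(
                     rarefaction = "without replacement; shallow samples dropped",
                     jaccard = "binary presence/absence",
                     avgCC = "degree<2 nodes contribute 0",
                     GD = "mean shortest path within components",
                     permutation_p = "add-one smoothing"))
  yaml::write_yaml(list(depth = config$depth, metrics = config$metrics,
                        grouping = config$grouping,
                        n_perm = config$n_perm,
                        nmds_starts = config$nmds_starts,
                        network_group = config$network_group,
                        compose_ranks = config$compose_ranks,
                        seed = config$seed,
                        input = config$input,
                        design = if (!is.null(config$design))
                          unclass(config$design)),
                   file.path(out_dir, "config.yaml"))

  # -- input ---------------------------------------------------------
  tax <- NULL
  stage_wrap("input", {
    if (!is.null(config$input)) {
      table <- read_asv_table(config$input$table)
      metadata <- read_metadata(config$input$metadata)
      if (!is.null(config$input$taxonomy))
        tax <- read_taxonomy(config$input$taxonomy)
      manifest$input <- config$input
    } else {
      sim <- simulate_community(config$design)
      table <- sim$table
      metadata <- sim$metadata
      tax <- simulate_taxonomy(rownames(table),
                               seed = derive_seed(config$seed, 99))
      write_asv_table(table, file.path(out_dir, "asv_table.tsv"))
      write_metadata(metadata, file.path(out_dir, "metadata.tsv"))
      write_taxonomy(tax, file.path(out_dir, "taxonomy.tsv"))
      jsonlite::write_json(
        list(seed = sim$truth$seed,
             species_affected = sim$truth$species_affected,
             season_affected = sim$truth$season_affected,
             gutpart_affected = sim$truth$gutpart_affected),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      manifest$input <- "synthetic"
    }
    metadata <- metadata[metadata$sample_id %in% colnames(table), ]
  })
  manifest$stages <- c(manifest$stages, "input")

  # -- rarefy --------------------------------------------------------
  stage_wrap("rarefy", {
    table <- rarefy(table, depth = config$depth,
                    seed = derive_seed(config$seed, 1))
    manifest$dropped_samples <- as.list(attr(table, "dropped_samples"))
    metadata <- metadata[metadata$sample_id %in% colnames(table), ]
    write_asv_table(table, file.path(out_dir, "rarefied_table.tsv"))
  })
  manifest$stages <- c(manifest$stages, "rarefy")

  # -- alpha ---------------------------------------------------------
  stage_wrap("alpha", {
    alpha <- alpha_diversity(table)
    write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
    comp <- do.call(rbind, lapply(config$grouping, function(f) {
      if (length(unique(metadata[[f]])) < 2) return(NULL)
      cbind(factor_name = f, alpha_compare(alpha, metadata, f))
    }))
    if (!is.null(comp))
      write_tsv(comp, file.path(out_dir, "alpha_comparisons.tsv"))
  })
  manifest$stages <- c(manifest$stages, "alpha")

  # -- beta / ordinate / compare ------------------------------------
  stage_wrap("beta", {
    dmats <- lapply(config$metrics, function(m) distance_matrix(table, m))
    names(dmats) <- config$metrics
    for (m in config$metrics)
      write_tsv(as.data.frame(dmats[[m]]),
                file.path(out_dir, paste0("distance_", m, ".tsv")),
                rownames_to = "sample_id")
    ord <- nmds(dmats[[1L]], k = 2, n_starts = config$nmds_starts,
                seed = derive_seed(config$seed, 2))
    coords <- data.frame(sample_id = rownames(ord$points), ord$points,
                         stringsAsFactors = FALSE)
    write_tsv(coords, file.path(out_dir, "nmds_coordinates.tsv"))
    manifest$nmds_stress <- ord$stress
    rows <- list()
    for (f in config$grouping) {
      if (length(unique(metadata[[f]])) < 2) next
      groups <- metadata[[f]][match(colnames(table),
                                    metadata$sample_id)]
      for (m in config$metrics) {
        pa <- permanova(dmats[[m]], groups, n_perm = config$n_perm,
                        seed = derive_seed(config$seed, 3))
        mr <- mrpp(dmats[[m]], groups, n_perm = config$n_perm,
                   seed = derive_seed(config$seed, 4))
        rows[[length(rows) + 1L]] <- data.frame(
          factor_name = f, metric = m,
          pseudo_F = pa$pseudo_F, R2 = pa$R2, p_permanova = pa$p_perm,
          delta = mr$delta_observed, A = mr$A, p_mrpp = mr$p_perm,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows))
      write_tsv(do.call(rbind, rows),
                file.path(out_dir, "group_comparisons.tsv"))
  })
  manifest$stages <- c(manifest$stages, "beta")

  # -- compose -------------------------------------------------------
  if (!is.null(tax)) {
    stage_wrap("compose", {
      for (rk in config$compose_ranks) {
        cs <- compose_summary(table, tax, metadata, rk)
        write_tsv(as.data.frame(cs),
                  file.path(out_dir, paste0("composition_", rk, ".tsv")),
                  rownames_to = "taxon")
      }
    })
    manifest$stages <- c(manifest$stages, "compose")
  }

  # -- network -------------------------------------------------------
  stage_wrap("network", {
    fac <- config$network_group
    levels_ <- sort(unique(metadata[[fac]]))
    rows <- list()
    failures <- list()
    for (lv in levels_) {
      ids <- metadata$sample_id[metadata[[fac]] == lv]
      sub <- unclass_table(table)[, colnames(table) %in% ids,
                                  drop = FALSE]
      res <- tryCatch({
        net <- do.call(conet, c(list(table = asv_table(sub)), config$rmt))
        tag <- gsub("[^A-Za-z0-9]+", "_", lv)
        write_tsv(net$edges,
                  file.path(out_dir, paste0("network_edges_", tag,
                                            ".tsv")))
        nodes <- net$topology
        if (!is.null(tax)) {
          nodes$genus <- tax$genus[match(nodes$node, tax$asv_id)]
        }
        write_tsv(nodes,
                  file.path(out_dir, paste0("network_nodes_", tag,
                                            ".tsv")))
        write_tsv(net$rmt$scan,
                  file.path(out_dir, paste0("network_rmtscan_", tag,
                                            ".tsv")))
        write_graphml(net, file.path(out_dir, paste0("network_", tag,
                                                     ".graphml")))
        data.frame(group = lv, n_nodes = net$stats$n_nodes,
                   n_links = net$stats$n_links,
                   avgCC = net$stats$avgCC, GD = net$stats$GD,
                   M = net$stats$M, threshold = net$threshold,
                   n_modules = net$n_modules,
                   n_keystone = sum(net$topology$keystone),
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        failures[[lv]] <<- conditionMessage(e)
        data.frame(group = lv, n_nodes = NA_integer_,
                   n_links = NA_integer_, avgCC = NA_real_,
                   GD = NA_real_, M = NA_real_, threshold = NA_real_,
                   n_modules = NA_integer_, n_keystone = NA_integer_,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
    write_tsv(do.call(rbind, rows),
              file.path(out_dir, "network_stats.tsv"))
    manifest$network_failures <- failures
  })
  manifest$stages <- c(manifest$stages, "network")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(structure(out_dir, manifest = manifest))
}
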