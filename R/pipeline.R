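#' Assemble and validate a pipeline configuration
#'
#' Inputs may be paths to the package's text formats or already-constructed
#' objects (handy for simulation studies). The configuration is validated
#' before any stage runs and is serialised verbatim into the report for
#' provenance.
#'
#' @param otu OTU table: path or [otu_table()].
#' @param meta sample metadata: path or data.frame.
#' @param env optional environment table: path or [env_table()]; when
#'   absent, variation partitioning is skipped with a warning.
#' @param lattice optional habitat lattice: path or [habitat_lattice()];
#'   built from the metadata grid by default.
#' @param out_dir optional output directory; when given, every stage writes
#'   its table there before the next stage begins, plus `report.json`.
#' @param min_rel_abund rare-OTU filter threshold (pooled relative
#'   abundance).
#' @param core_thresh,dominant_thresh species-group thresholds.
#' @param alpha torus-test per-tail significance level.
#' @param harms use the 0.025 per-tail convention.
#' @param forest_type_map optional named map habitat -> forest type for the
#'   pooled preference summary.
#' @param weight bipartite edge-weight scheme (see [build_network()]).
#' @param n_restarts restarts for the module search and NMDS.
#' @param n_perm permutations for PERMANOVA.
#' @param transform community transform for variation partitioning.
#' @param kingdom label recorded on association rows (e.g. `"bacteria"`).
#' @param seed master RNG seed; stage seeds are derived from it, so an
#'   identical configuration yields an identical report.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(otu, meta, env = NULL, lattice = NULL,
                            out_dir = NULL, min_rel_abund = 1e-4,
                            core_thresh = 0.10, dominant_thresh = 0.005,
                            alpha = 0.05, harms = FALSE,
                            forest_type_map = NULL,
                            weight = "relative", n_restarts = 20,
                            n_perm = 999, transform = "hellinger",
                            kingdom = "all", seed = 1) {
  cfg <- list(otu = otu, meta = meta, env = env, lattice = lattice,
              out_dir = out_dir, min_rel_abund = min_rel_abund,
              core_thresh = core_thresh, dominant_thresh = dominant_thresh,
              alpha = alpha, harms = harms,
              forest_type_map = forest_type_map, weight = weight,
              n_restarts = n_restarts, n_perm = n_perm,
              transform = transform, kingdom = kingdom,
              seed = as.integer(seed))
  stopifnot(cfg$min_rel_abund >= 0, cfg$min_rel_abund < 1,
            cfg$alpha > 0, cfg$alpha <= 0.5, cfg$n_restarts >= 1,
            cfg$n_perm >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the
#'   file's directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("otu", "meta", "env", "lattice"))
    if (!is.null(y[[key]]) && is.character(y[[key]]) &&
        !file.exists(y[[key]]))
      y[[key]] <- file.path(base, y[[key]])
  if (!is.null(y$forest_type_map)) y$forest_type_map <- unlist(y$forest_type_map)
  do.call(pipeline_config, y)
}

.load_input <- function(value, reader) {
  if (is.character(value)) reader(value) else value
}

#' Run the full habitat-specialization pipeline
#'
#' Stages, in order: read and validate inputs; rare-OTU filter; species
#' groups; torus-translation association test and summary; bipartite network
#' and module search; variation partitioning (skipped with a warning when no
#' environment table is supplied); ordination statistics (Bray-Curtis, NMDS,
#' habitat-centroid fit, PERMANOVA, accumulation curve). Every stage's table
#' is written to `out_dir` (when set) before the next stage begins, and the
#' whole report is serialised to `report.json`. Identical configuration and
#' seed give an identical report; any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return list of class `habspec_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[habspec] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  x <- stage("read", {
    x <- .load_input(config$otu, read_otu_table)
    stopifnot(inherits(x, "otu_table"))
    x
  })
  meta <- stage("read", sample_metadata(.load_input(config$meta,
                                                    read_sample_metadata)))
  lattice <- stage("read", {
    if (is.null(config$lattice)) build_lattice(meta)
    else .load_input(config$lattice, read_lattice)
  })
  env <- if (is.null(config$env)) NULL
         else stage("read", .load_input(config$env, read_env_table))

  n_pre <- nrow(x$counts)
  xf <- stage("filter", filter_rare(x, config$min_rel_abund))
  if (!is.null(out)) write_otu_table(xf, file.path(out, "filtered_otu.tsv"))

  groups <- stage("groups", species_groups(xf, config$core_thresh,
                                           config$dominant_thresh))

  assoc <- stage("torus", {
    a <- torus_test(xf, meta, lattice, alpha = config$alpha,
                    harms = config$harms)
    a$kingdom <- config$kingdom
    a
  })
  if (!is.null(out))
    utils::write.table(assoc, file.path(out, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- stage("torus",
                   summarize_associations(assoc, groups,
                                          config$forest_type_map))

  net <- stage("network", build_network(xf, meta, config$weight))
  modules <- stage("network",
                   optimize_modules(net, n_restarts = config$n_restarts,
                                    seed = config$seed + 1L))
  if (!is.null(out)) {
    write_edge_list(net, file.path(out, "network_edges.tsv"))
    utils::write.table(
      data.frame(node = c(names(modules$row_module),
                          names(modules$col_module)),
                 type = rep(c("otu", "habitat"),
                            c(length(modules$row_module),
                              length(modules$col_module))),
                 module = c(modules$row_module, modules$col_module)),
      file.path(out, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  vp <- NULL
  if (is.null(env)) {
    warning("no environment table supplied; variation partitioning skipped")
  } else {
    vp <- stage("varpart", varpart_env(xf, env, transform = config$transform))
  }

  ord <- stage("ordination", {
    d <- bray_curtis(xf)
    hab <- habitat_of(meta, colnames(xf$counts))
    nm <- nmds(d, k = 2, n_restarts = config$n_restarts,
               seed = config$seed + 2L)
    fit <- envfit_centroids(nm$coords, hab, n_perm = config$n_perm,
                            seed = config$seed + 3L)
    pm <- permanova(d, hab, permutations = config$n_perm,
                    seed = config$seed + 4L)
    acc <- accumulation_curve(xf)
    if (!is.null(out)) {
      utils::write.table(as.matrix(d), file.path(out, "distances.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(data.frame(sample_id = rownames(nm$coords),
                                    nm$coords),
                         file.path(out, "coords.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(acc, file.path(out, "accumulation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(distances = d, nmds = nm, centroid_fit = fit, permanova = pm,
         accumulation = acc)
  })

  report <- structure(list(
    config = config[setdiff(names(config), c("otu", "meta", "env",
                                             "lattice"))],
    n_otus_prefilter = n_pre,
    n_otus_tested = nrow(xf$counts),
    group_sizes = vapply(groups, function(g) length(g$member_otu_ids),
                         integer(1)),
    associations = assoc,
    association_summary = summary,
    modularity = list(Q = modules$Q, n_modules = modules$n_modules,
                      partition = modules),
    varpart = vp,
    ordination = list(nmds_stress = ord$nmds$stress,
                      centroid_fit = ord$centroid_fit[c("r2", "p")],
                      permanova = ord$permanova[c("pseudo_F", "R2", "p")],
                      accumulation = ord$accumulation)),
    class = "habspec_report")
  if (!is.null(out))
    writeLines(report_json(report), file.path(out, "report.json"))
  report
}

#' Serialise a pipeline report to JSON
#'
#' @param report a `habspec_report`.
#' @return a JSON string.
#' @export
report_json <- function(report) {
  r <- unclass(report)
  r$associations <- NULL          # bulky; written as TSV by the pipeline
  r$modularity$partition <- list(
    row_module = as.list(r$modularity$partition$row_module),
    col_module = as.list(r$modularity$partition$col_module))
  r$association_summary <- unclass(r$association_summary)
  if (!is.null(r$varpart))
    r$varpart <- list(fractions = as.list(r$varpart$fractions),
                      totals = as.list(r$varpart$totals),
                      adj_r2 = as.list(r$varpart$adj_r2))
  jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE, force = TRUE)
}

#' @export
print.habspec_report <- function(x, ...) {
  cat(sprintf("habspec_report: %d/%d OTUs tested after filtering\n",
              x$n_otus_tested, x$n_otus_prefilter))
  print(x$association_summary)
  cat(sprintf("\nModularity Q = %.4f (%d modules)\n", x$modularity$Q,
              x$modularity$n_modules))
  if (!is.null(x$varpart)) print(x$varpart)
  cat(sprintf("\nNMDS stress = %.4f; PERMANOVA p = %.4g\n",
              x$ordination$nmds_stress, x$ordination$permanova$p))
  invisible(x)
}

#' Recovery of planted specialists
#'
#' Joins torus-test classifications to a synthetic truth table and reports
#' detection sensitivity (planted specialists flagged positive), specificity
#' (neutral OTUs not flagged), sensitivity for the true habitat, and habitat
#' assignment accuracy among detected specialists (assigned habitat =
#' smallest `p_pos`; see [specialists()]). Only OTUs present in the results
#' (i.e. surviving the filter) are scored.
#'
#' @param results an `association_result` (or a `habspec_report`).
#' @param truth truth table from [generate_community()].
#' @return list with `n_scored`, `n_specialists`, `sensitivity`,
#'   `specificity`, `true_habitat_sensitivity`, `habitat_accuracy`.
#' @export
recovery_metrics <- function(results, truth) {
  if (inherits(results, "habspec_report")) results <- results$associations
  sp <- specialists(results)
  idx <- match(sp$otu_id, truth$otu_id)
  if (anyNA(idx))
    stop("OTU id(s) absent from the truth table: ",
         paste(sp$otu_id[is.na(idx)][1], "..."))
  tr <- truth[idx, ]
  is_true <- tr$specialist
  detected <- sp$specialist
  pos_for_true <- mapply(function(habs, pref)
    !is.na(pref) && pref %in% strsplit(habs, ",", fixed = TRUE)[[1]],
    sp$positive_habitats, tr$preferred_habitat)
  det_true <- detected & is_true
  list(n_scored = nrow(sp),
       n_specialists = sum(is_true),
       sensitivity = if (any(is_true)) mean(detected[is_true]) else NA_real_,
       specificity = if (any(!is_true)) mean(!detected[!is_true])
                     else NA_real_,
       true_habitat_sensitivity = if (any(is_true))
         mean(pos_for_true[is_true]) else NA_real_,
       habitat_accuracy = if (any(det_true))
         mean(sp$best_habitat[det_true] == tr$preferred_habitat[det_true])
         else NA_real_)
}
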