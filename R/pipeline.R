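# End-to-end orchestration: read (or simulate) the four tables, run
# total-sum scaling -> prevalence partition -> Pareto scaling -> CCA ->
# S-plot selection -> cladogram/overview/correlation reporting, write every
# artifact plus a provenance manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @return A named list of configuration values understood by
#'   [run_pipeline()]: either `inputs` (paths `otu`, `taxonomy`, `metadata`,
#'   `markers`) or `synthetic` (arguments for [synthetic_scenario()]),
#'   plus `min_samples`, `n_components`, `tol`, `max_iter`,
#'   `splot_against`, `splot_center`, `overview_threshold`, `out_dir`,
#'   `log_file`.
#' @export
default_pipeline_config <- function(out_dir = "ccadigest_out") {
  list(inputs = NULL,
       synthetic = NULL,
       min_samples = 2L,
       n_components = 2L,
       tol = 1e-10,
       max_iter = 500L,
       splot_against = "working",
       splot_center = "zero",
       overview_threshold = 0.01,
       out_dir = out_dir,
       log_file = NULL)
}

read_pipeline_config <- function(config) {
  cfg <- default_pipeline_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(config)] <- config
  if (is.null(cfg$inputs) && is.null(cfg$synthetic)) {
    stop("config needs either 'inputs' paths or a 'synthetic' scenario",
         call. = FALSE)
  }
  if (cfg$min_samples < 1L) stop("min_samples must be >= 1", call. = FALSE)
  if (cfg$n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (cfg$tol <= 0 || cfg$max_iter < 1L) {
    stop("tol must be positive and max_iter >= 1", call. = FALSE)
  }
  if (cfg$overview_threshold < 0 || cfg$overview_threshold >= 1) {
    stop("overview_threshold must lie in [0, 1)", call. = FALSE)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every step in order on real input files or on a synthetic
#' scenario, writing all artifacts into `config$out_dir`: the four input
#' tables (when simulated), `partition.tsv`, `richness.tsv`, the model
#' tables from [write_results()], per-component cladogram files, the
#' domain overview tables, `correlations.tsv` and a `manifest.yaml` with
#' the config echo, package version, input checksums and per-step
#' dimensions. A failing stage aborts with an error naming the stage.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file of the same shape.
#' @return Invisibly, a list with every intermediate object (`data`,
#'   `abundance`, `partition`, `richness`, `scaled`, `model`, `selection`,
#'   `clades`, `overview`, `correlations`, `manifest`, `files`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cfg$out_dir)) {
    stop("cannot create output directory: ", cfg$out_dir, call. = FALSE)
  }
  log_file <- cfg$log_file
  log_msg <- function(...) {
    line <- paste0(...)
    message("[ccadigest] ", line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE,
                                sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  files <- character()
  checksums <- character()

  data <- stage("load", {
    if (!is.null(cfg$synthetic)) {
      scn <- do.call(synthetic_scenario, cfg$synthetic)
      d <- generate_synthetic(scn)
      files["counts"] <- write_otu_table(d$otu,
                                         file.path(cfg$out_dir, "counts.tsv"))
      files["taxonomy"] <- write_taxonomy(d$taxonomy,
                                          file.path(cfg$out_dir,
                                                    "taxonomy.tsv"))
      files["metadata"] <- write_metadata(d$metadata,
                                          file.path(cfg$out_dir,
                                                    "metadata.tsv"))
      files["markers"] <- write_markers(d$markers,
                                        file.path(cfg$out_dir, "markers.tsv"))
      d
    } else {
      inp <- cfg$inputs
      req <- c("otu", "taxonomy", "metadata", "markers")
      miss <- setdiff(req, names(inp))
      if (length(miss)) stop("inputs missing path(s): ",
                             paste(miss, collapse = ", "))
      checksums <<- vapply(unlist(inp[req]), function(p)
        unname(tools::md5sum(p)), character(1L))
      ot <- read_otu_table(inp$otu,
                           dialect = if (grepl("\\.biom$", inp$otu))
                             "biom" else "tsv")
      list(otu = ot,
           taxonomy = read_taxonomy(inp$taxonomy),
           metadata = read_metadata(inp$metadata, table = ot),
           markers = read_markers(inp$markers),
           truth = NULL)
    }
  })
  log_msg("loaded ", length(data$otu$otu_ids), " OTUs x ",
          length(data$otu$sample_ids), " samples")

  abund <- stage("total_sum_scale", total_sum_scale(data$otu))
  part <- stage("prevalence_partition",
                prevalence_partition(abund, cfg$min_samples))
  log_msg("prevalence filter (>= ", cfg$min_samples, " samples): ",
          length(part$ubiquitous), " ubiquitous, ", length(part$scarce),
          " scarce OTUs discarded")
  rich <- stage("richness", richness(abund, restrict_to = part$ubiquitous))
  scaled <- stage("pareto_scale", pareto_scale(abund, keep = part$ubiquitous))
  dropped <- attr(scaled, "dropped")
  if (length(dropped)) log_msg(length(dropped),
                               " zero-variance OTU(s) dropped before CCA")
  model <- stage("fit_cca",
                 fit_cca(scaled, n_components = cfg$n_components,
                         tol = cfg$tol, max_iter = cfg$max_iter))
  log_msg("CCA: ", paste(sprintf("CC%d %.1f%%",
                                 seq_along(model$explained),
                                 100 * model$explained), collapse = ", "),
          " of total variation")
  selection <- stage("select_otus",
                     select_all_components(model,
                                           against = cfg$splot_against,
                                           center = cfg$splot_center))
  sel_counts <- table(factor(selection$component,
                             levels = seq_len(cfg$n_components)))
  log_msg("S-plot selection: ",
          paste(sprintf("CC%s: %d", names(sel_counts), as.integer(sel_counts)),
                collapse = ", "))

  res_files <- stage("write_results", write_results(model, selection,
                                                    cfg$out_dir))
  files[names(res_files)] <- res_files

  clades <- stage("clade_summary",
                  clade_summary(selection, model, data$taxonomy))
  if (nrow(clades$nodes)) {
    clade_files <- stage("export_cladogram",
                         export_cladogram(clades, cfg$out_dir))
    files["cladogram"] <- clade_files$newick
    files[paste0("annotation_", colnames(model$scores))] <-
      clade_files$annotations
  }

  overview <- stage("traditional_overview",
                    traditional_overview(abund, data$taxonomy,
                                         threshold = cfg$overview_threshold))
  for (dom in intersect(c("Archaea", "Bacteria", "unclassified"),
                        names(overview))) {
    m <- overview[[dom]]
    if (is.null(m)) next
    p <- file.path(cfg$out_dir, paste0("overview_", tolower(dom), ".tsv"))
    write_numeric_tsv(data.frame(group = rownames(m), m, check.names = FALSE),
                      p)
    files[paste0("overview_", tolower(dom))] <- p
  }

  correlations <- stage("correlation_report",
                        correlation_report(model, abund, data$taxonomy,
                                           data$metadata, data$markers))
  files["correlations"] <- file.path(cfg$out_dir, "correlations.tsv")
  write_numeric_tsv(as.data.frame(correlations), files[["correlations"]])

  files["partition"] <- file.path(cfg$out_dir, "partition.tsv")
  utils::write.table(
    data.frame(otu_id = c(part$ubiquitous, part$scarce),
               status = rep(c("ubiquitous", "scarce"),
                            c(length(part$ubiquitous), length(part$scarce)))),
    files[["partition"]], sep = "\t", quote = FALSE, row.names = FALSE)
  files["richness"] <- file.path(cfg$out_dir, "richness.tsv")
  utils::write.table(data.frame(sample_id = names(rich), richness = rich),
                     files[["richness"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    package = "ccadigest",
    version = as.character(utils::packageVersion("ccadigest")),
    config = cfg[setdiff(names(cfg), "log_file")],
    input_checksums = as.list(checksums),
    dimensions = list(
      n_otus_input = length(data$otu$otu_ids),
      n_samples = length(data$otu$sample_ids),
      n_ubiquitous = length(part$ubiquitous),
      n_scarce = length(part$scarce),
      n_zero_variance_dropped = length(dropped),
      n_vars_fitted = nrow(model$loadings),
      n_selected = as.list(stats::setNames(as.integer(sel_counts),
                                           paste0("CC", names(sel_counts))))))
  files["manifest"] <- file.path(cfg$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, files[["manifest"]])
  log_msg("wrote ", length(files), " artifact(s) to ", cfg$out_dir)

  invisible(list(data = data, abundance = abund, partition = part,
                 richness = rich, scaled = scaled, model = model,
                 selection = selection, clades = clades,
                 overview = overview, correlations = correlations,
                 manifest = manifest, files = files))
}

#' Read model artifacts written by [write_results()]
#'
#' Reconstructs a lightweight model object (scores, loadings, saliences)
#' from a results directory, sufficient for [clade_summary()] and
#' [correlation_report()]; the working matrices needed by [splot()] are not
#' part of the on-disk representation.
#'
#' @param dir Directory containing `scores.tsv`, `loadings.tsv`,
#'   `saliences.tsv`.
#' @return A `cca_model` with only the tabular fields.
#' @export
read_model <- function(dir) {
  read_mat <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("missing model artifact: ", p, call. = FALSE)
    df <- utils::read.delim(p, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    m
  }
  structure(list(scores = read_mat("scores.tsv"),
                 loadings = read_mat("loadings.tsv"),
                 saliences = read_mat("saliences.tsv")),
            class = "cca_model")
}

#' Read a selection table written by [write_results()]
#' @param dir Directory containing `selection.tsv`.
#' @return A `selection_result` data frame.
#' @export
read_selection <- function(dir) {
  p <- file.path(dir, "selection.tsv")
  if (!file.exists(p)) stop("missing selection artifact: ", p, call. = FALSE)
  df <- utils::read.delim(p, check.names = FALSE,
                          colClasses = c(otu_id = "character"))
  structure(df, class = c("selection_result", "data.frame"))
}
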