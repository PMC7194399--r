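# Interpretation layer: per-sample richness, the classical 1%-abundance
# overview split by domain, and Pearson correlation of component scores and
# community aggregates against metadata gradients and performance markers.

#' Per-sample OTU richness
#'
#' Number of OTUs (optionally restricted to a subset, typically the
#' ubiquitous set) with strictly positive abundance in each sample.
#'
#' @param abund An `abundance_matrix` (samples x OTUs).
#' @param restrict_to OTU ids to count over; defaults to all.
#' @return Named integer vector, one count per sample.
#' @export
richness <- function(abund, restrict_to = colnames(abund)) {
  stopifnot(is.matrix(abund))
  bad <- setdiff(restrict_to, colnames(abund))
  if (length(bad)) stop("unknown OTU id(s) in restrict_to: ",
                        paste(utils::head(bad, 5L), collapse = ", "),
                        call. = FALSE)
  counts <- rowSums(abund[, restrict_to, drop = FALSE] > 0)
  storage.mode(counts) <- "integer"
  counts
}

#' Classical abundance overview, split by domain
#'
#' The "traditional" view of a 16S dataset: Archaea and Bacteria are studied
#' separately, and within each domain the OTUs that never exceed an
#' abundance threshold (default 1% of the sample total) in any sample are
#' combined into a single "Other" row. Rows are labelled by the domain's
#' display rank (genus for Archaea, order for Bacteria, overridable) with
#' the OTU id kept for uniqueness.
#'
#' @param abund An `abundance_matrix` (samples x OTUs).
#' @param taxonomy A [taxonomy_table()] covering all OTUs of `abund`.
#' @param threshold Keep an OTU individually when its abundance exceeds this
#'   fraction in at least one sample; default 0.01.
#' @param display_ranks Named character vector mapping domain to the rank
#'   used for row labels.
#' @return A list of class `overview_tables` with one matrix (rows = kept
#'   OTUs + "Other <domain>", columns = samples) per domain, and
#'   `unclassified` (a one-row matrix, or NULL) for OTUs whose domain is
#'   neither Archaea nor Bacteria.
#' @export
traditional_overview <- function(abund, taxonomy, threshold = 0.01,
                                 display_ranks = c(Archaea = "genus",
                                                   Bacteria = "order")) {
  stopifnot(is.matrix(abund), inherits(taxonomy, "taxonomy_table"))
  ids <- colnames(abund)
  missing_tax <- setdiff(ids, rownames(taxonomy))
  if (length(missing_tax)) {
    stop("taxonomy missing for OTU(s): ",
         paste(utils::head(missing_tax, 5L), collapse = ", "), call. = FALSE)
  }
  tax <- unclass(taxonomy)[ids, , drop = FALSE]
  domains <- tax[, "domain"]
  known <- c("Archaea", "Bacteria")
  out <- list()
  for (dom in known) {
    in_dom <- ids[domains == dom]
    if (!length(in_dom)) next
    sub <- abund[, in_dom, drop = FALSE]
    keep <- in_dom[apply(sub, 2L, max) > threshold]
    other <- setdiff(in_dom, keep)
    rank <- display_ranks[[dom]]
    rows <- if (length(keep)) {
      kept <- t(sub[, keep, drop = FALSE])
      rownames(kept) <- paste0(tax[keep, rank], " (", keep, ")")
      kept
    } else NULL
    if (length(other)) {
      other_row <- matrix(rowSums(sub[, other, drop = FALSE]), nrow = 1L,
                          dimnames = list(paste("Other", dom),
                                          rownames(abund)))
      rows <- rbind(rows, other_row)
    }
    out[[dom]] <- rows
  }
  unknown_ids <- ids[!domains %in% known]
  out$unclassified <- NULL
  if (length(unknown_ids)) {
    warning(length(unknown_ids),
            " OTU(s) with unclassified domain routed to a flagged row",
            call. = FALSE)
    out$unclassified <- matrix(
      rowSums(abund[, unknown_ids, drop = FALSE]), nrow = 1L,
      dimnames = list("unclassified domain", rownames(abund)))
  }
  structure(out, threshold = threshold, display_ranks = display_ranks,
            class = "overview_tables")
}

#' Pearson correlation over pairwise-complete observations
#'
#' @param series_a,series_b Numeric vectors of equal length; `NA`s allowed.
#' @return A list with elements `r` (Pearson correlation, `NA` on error),
#'   `n` (number of complete pairs used) and `error` (`NA`, or
#'   `"insufficient_n"` / `"zero_variance"`).
#' @export
correlate <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("series must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(series_a, series_b)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, n = n, error = "insufficient_n"))
  a <- series_a[ok]
  b <- series_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, n = n, error = "zero_variance"))
  }
  list(r = stats::cor(a, b), n = n, error = NA_character_)
}

#' Correlation report: components, community aggregates, markers
#'
#' Assembles Pearson correlations linking the ordination to digester
#' behaviour: every component score column against every performance
#' marker; the domain-aggregate Archaea fraction of the community against
#' the co-substrate percentage; and ubiquitous richness against the
#' co-substrate percentage. Cells that cannot be computed (fewer than 3
#' complete pairs, or zero variance) carry the error label instead of r.
#'
#' @param model A [fit_cca()] model fitted on these samples.
#' @param abund The `abundance_matrix` the model derives from.
#' @param taxonomy A [taxonomy_table()] covering the abundance OTUs.
#' @param metadata A [sample_metadata()] for the same samples.
#' @param markers A [marker_table()]; samples matched by `sample_id`.
#' @return A data frame of class `correlation_report` with columns `series`,
#'   `target`, `r`, `n`, `error`.
#' @export
correlation_report <- function(model, abund, taxonomy, metadata, markers) {
  stopifnot(inherits(model, "cca_model"),
            inherits(metadata, "sample_metadata"),
            inherits(markers, "marker_table"))
  samples <- rownames(model$scores)
  if (!all(samples %in% metadata$sample_id)) {
    stop("metadata does not cover all model samples", call. = FALSE)
  }
  meta <- metadata[match(samples, metadata$sample_id), ]
  mk <- as.data.frame(markers)[match(samples, markers$sample_id), ,
                               drop = FALSE]
  marker_names <- setdiff(names(mk), "sample_id")
  rows <- list()
  add <- function(series, target, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, target = target, r = res$r, n = res$n,
      error = res$error, stringsAsFactors = FALSE)
  }
  for (k in seq_len(ncol(model$scores))) {
    for (m in marker_names) {
      add(colnames(model$scores)[k], m,
          correlate(model$scores[, k], mk[[m]]))
    }
  }
  # domain aggregate: Archaea fraction of the whole community per sample
  tax <- unclass(taxonomy)[colnames(abund), , drop = FALSE]
  arch <- colnames(abund)[tax[, "domain"] == "Archaea"]
  if (length(arch)) {
    frac <- rowSums(abund[samples, arch, drop = FALSE])
    add("archaea_fraction", "percent_cosubstrate",
        correlate(frac, meta$percent_cosubstrate))
  }
  rich <- richness(abund[samples, , drop = FALSE],
                   restrict_to = rownames(model$loadings))
  add("ubiquitous_richness", "percent_cosubstrate",
      correlate(as.numeric(rich), meta$percent_cosubstrate))
  out <- do.call(rbind, rows)
  structure(out, class = c("correlation_report", "data.frame"))
}
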