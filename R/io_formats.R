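# Readers/writers and validated containers for the four input tables and the
# model result artifacts. External orientation is always OTUs-as-rows,
# samples-as-columns (the FROGS export convention); in-memory abundance and
# scaled matrices are samples x variables.

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
UNKNOWN_RANK <- "unknown"

#' Construct and validate an OTU count table
#'
#' @param counts Matrix of non-negative integer counts, OTUs as rows and
#'   samples as columns.
#' @param otu_ids,sample_ids Character vectors of unique identifiers; taken
#'   from `dimnames(counts)` when omitted.
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (integer matrix with dimnames), `otu_ids` and `sample_ids`.
#' @examples
#' ot <- otu_table(matrix(c(2, 3, 5, 0, 1, 9), nrow = 3,
#'                        dimnames = list(paste0("otu_", 1:3), c("s1", "s2"))))
#' colSums(ot$counts)
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids) || is.null(sample_ids)) {
    stop("counts must carry OTU and sample identifiers", call. = FALSE)
  }
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(counts) != length(otu_ids) || ncol(counts) != length(sample_ids)) {
    stop("count matrix dimensions do not match identifier lists", call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric with no missing values", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  totals <- colSums(counts)
  if (any(totals == 0L)) {
    stop("sample(s) with zero total count: ",
         paste(sample_ids[totals == 0L], collapse = ", "), call. = FALSE)
  }
  dimnames(counts) <- list(otu_ids, sample_ids)
  structure(list(counts = counts, otu_ids = otu_ids, sample_ids = sample_ids),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples, %.1f%% zero cells\n",
              length(x$otu_ids), length(x$sample_ids),
              100 * mean(x$counts == 0L)))
  invisible(x)
}

#' Read an OTU count table
#'
#' Reads a tab-separated table (first column OTU identifiers, remaining
#' columns one per sample) or a BIOM 2.x file into a validated [otu_table()].
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default, FROGS-style export) or `"biom"`.
#' @return An `otu_table`, with OTU and sample order as in the file.
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("the biom dialect requires the 'biomformat' package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("OTU table needs an id column plus >= 1 sample",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count value in ", path, call. = FALSE)
  rownames(m) <- ids
  otu_table(m, otu_ids = ids, sample_ids = colnames(df)[-1L])
}

#' Write an OTU count table as TSV
#'
#' @param table An `otu_table`.
#' @param path Output path; OTUs as rows, samples as columns, first column
#'   `otu_id`.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = table$otu_ids, table$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a taxonomy table
#'
#' @param lineages Character matrix or data.frame, one row per OTU and one
#'   column per rank (domain, phylum, class, order, family, genus). Short
#'   lineages are padded with `"unknown"`.
#' @param otu_ids Character vector of OTU identifiers.
#' @return Object of class `taxonomy_table`: a character matrix with rows
#'   named by OTU id and the six canonical rank columns.
#' @export
taxonomy_table <- function(lineages, otu_ids = rownames(lineages)) {
  m <- as.matrix(lineages)
  if (is.null(otu_ids)) stop("otu_ids required", call. = FALSE)
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids in taxonomy",
                                   call. = FALSE)
  if (ncol(m) > length(TAXONOMY_RANKS)) {
    m <- m[, seq_along(TAXONOMY_RANKS), drop = FALSE]
  }
  if (ncol(m) < length(TAXONOMY_RANKS)) {
    pad <- matrix(UNKNOWN_RANK, nrow = nrow(m),
                  ncol = length(TAXONOMY_RANKS) - ncol(m))
    m <- cbind(m, pad)
  }
  m[is.na(m) | !nzchar(trimws(m))] <- UNKNOWN_RANK
  m <- trimws(m)
  dimnames(m) <- list(otu_ids, TAXONOMY_RANKS)
  structure(m, class = c("taxonomy_table", class(matrix())))
}

#' Read a taxonomy table
#'
#' Expects a two-column tab-separated file with header: OTU id and a
#' semicolon-separated lineage (domain;phylum;class;order;family;genus).
#' Missing trailing ranks are padded with `"unknown"`; a warning reports how
#' many lineages were incomplete.
#'
#' @param path Path to the file.
#' @return A `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file needs id and lineage columns",
                          call. = FALSE)
  parts <- strsplit(as.character(df[[2L]]), ";", fixed = TRUE)
  n_short <- sum(vapply(parts, length, 1L) < length(TAXONOMY_RANKS))
  if (n_short > 0L) {
    warning(n_short, " lineage(s) shorter than ", length(TAXONOMY_RANKS),
            " ranks; padded with '", UNKNOWN_RANK, "'", call. = FALSE)
  }
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[!nzchar(p)] <- UNKNOWN_RANK
    length(p) <- length(TAXONOMY_RANKS)
    p[is.na(p)] <- UNKNOWN_RANK
    p
  }, character(length(TAXONOMY_RANKS))))
  taxonomy_table(m, otu_ids = as.character(df[[1L]]))
}

#' Write a taxonomy table as TSV (semicolon-joined lineages)
#' @param taxonomy A `taxonomy_table`.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  stopifnot(inherits(taxonomy, "taxonomy_table"))
  df <- data.frame(otu_id = rownames(taxonomy),
                   lineage = apply(unclass(taxonomy), 1L, paste,
                                   collapse = ";"),
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' @param df Data frame with columns `sample_id`, `cosubstrate` (one of
#'   `"FW"`, `"GG"`, `"none"`), `percent_cosubstrate` (0-100), `day`
#'   (positive integer) and optionally `dataset`.
#' @param table Optional `otu_table`; every `sample_id` must then appear in
#'   it.
#' @return Object of class `sample_metadata` (a validated data frame).
#' @export
sample_metadata <- function(df, table = NULL) {
  req <- c("sample_id", "cosubstrate", "percent_cosubstrate", "day")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata",
                                        call. = FALSE)
  if (!all(df$cosubstrate %in% c("FW", "GG", "none"))) {
    stop("cosubstrate must be one of FW, GG, none", call. = FALSE)
  }
  p <- df$percent_cosubstrate
  if (anyNA(p) || any(p < 0 | p > 100)) {
    stop("percent_cosubstrate must lie in [0, 100]", call. = FALSE)
  }
  if (any((p == 0) != (df$cosubstrate == "none"))) {
    stop("percent_cosubstrate must be 0 exactly for pure-sludge samples ",
         "(cosubstrate 'none') and positive otherwise", call. = FALSE)
  }
  if (any(df$day <= 0 | df$day != round(df$day))) {
    stop("day must be a positive integer", call. = FALSE)
  }
  if (!is.null(table)) {
    absent <- setdiff(df$sample_id, table$sample_ids)
    if (length(absent)) {
      stop("metadata sample(s) absent from OTU table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  structure(as.data.frame(df), class = c("sample_metadata", "data.frame"))
}

#' Read sample metadata
#' @param path Tab-separated file with the [sample_metadata()] columns.
#' @param table Optional `otu_table` to validate sample ids against.
#' @return A `sample_metadata`.
#' @export
read_metadata <- function(path, table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_metadata(df, table = table)
}

#' Write sample metadata as TSV
#' @param metadata A `sample_metadata`.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a performance-marker table
#'
#' Markers are real-valued per-sample measurements (e.g. apparent
#' methanogenic-pathway indicator, ammonium, dissolved inorganic carbon,
#' acetate, biogas, CO2). Missing values are permitted at read time; a marker
#' needs at least 3 non-missing values to enter a correlation.
#'
#' @param df Data frame with a `sample_id` column and one numeric column per
#'   marker; `"NA"` encodes missing.
#' @param units Optional named character vector of free-text units per marker.
#' @return Object of class `marker_table` (data frame with a `units`
#'   attribute).
#' @export
marker_table <- function(df, units = NULL) {
  if (!"sample_id" %in% names(df)) stop("markers need a sample_id column",
                                        call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in markers",
                                        call. = FALSE)
  for (nm in setdiff(names(df), "sample_id")) {
    df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  }
  structure(as.data.frame(df), units = units,
            class = c("marker_table", "data.frame"))
}

#' Read a performance-marker table
#' @param path Tab-separated file, samples as rows, markers as columns, with
#'   a `sample_id` column; missing values written as `NA`.
#' @return A `marker_table`.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  marker_table(df)
}

#' Write a performance-marker table as TSV
#' @param markers A `marker_table`.
#' @param path Output path.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Numeric data frame -> TSV at 10 significant digits.
write_numeric_tsv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.10g", out[[nm]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fitted-model artifacts
#'
#' Writes `scores.tsv` (samples x components), `loadings.tsv`,
#' `saliences.tsv` (variables x components) and `selection.tsv`
#' (`otu_id`, `component`, `covariance`, `correlation`, `sign`) into
#' `out_dir`, numbers at 10 significant digits.
#'
#' @param model A fitted [fit_cca()] model.
#' @param selection A selection table as returned by [select_otus()] /
#'   assembled by [run_pipeline()]; may have zero rows.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_results <- function(model, selection, out_dir) {
  stopifnot(inherits(model, "cca_model"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- c(scores = file.path(out_dir, "scores.tsv"),
             loadings = file.path(out_dir, "loadings.tsv"),
             saliences = file.path(out_dir, "saliences.tsv"),
             selection = file.path(out_dir, "selection.tsv"))
  write_numeric_tsv(data.frame(sample_id = rownames(model$scores),
                               model$scores, check.names = FALSE),
                    paths[["scores"]])
  write_numeric_tsv(data.frame(otu_id = rownames(model$loadings),
                               model$loadings, check.names = FALSE),
                    paths[["loadings"]])
  write_numeric_tsv(data.frame(otu_id = rownames(model$saliences),
                               model$saliences, check.names = FALSE),
                    paths[["saliences"]])
  sel <- if (is.null(selection) || nrow(selection) == 0L) {
    data.frame(otu_id = character(), component = integer(),
               covariance = numeric(), correlation = numeric(),
               sign = integer())
  } else {
    selection[, c("otu_id", "component", "covariance", "correlation", "sign")]
  }
  write_numeric_tsv(sel, paths[["selection"]])
  invisible(paths)
}
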