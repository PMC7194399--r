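# Steps 1a-2a of the pipeline: total-sum scaling, prevalence partition into
# ubiquitous/scarce OTUs, Pareto scaling of the retained block.

#' Total-sum scaling of an OTU count table
#'
#' Divides each sample's counts by its library size, giving relative
#' abundances. The result is oriented samples x OTUs, each row summing to 1;
#' zero counts remain exactly zero.
#'
#' @param table An [otu_table()].
#' @return A numeric matrix of class `abundance_matrix` (samples x OTUs).
#' @examples
#' ot <- otu_table(matrix(c(2, 3, 5), ncol = 1,
#'                        dimnames = list(paste0("otu_", 1:3), "s1")))
#' total_sum_scale(ot)
#' @export
total_sum_scale <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(table$sample_ids[totals == 0], collapse = ", "), call. = FALSE)
  }
  a <- t(table$counts) / totals
  structure(a, class = c("abundance_matrix", class(matrix())))
}

#' Re-normalize rows of an abundance matrix (idempotent on valid input)
#' @param abund An `abundance_matrix` or numeric samples x OTUs matrix with
#'   positive row sums.
#' @return An `abundance_matrix` whose rows sum to 1.
#' @export
renormalize <- function(abund) {
  rs <- rowSums(abund)
  if (any(rs <= 0)) stop("row(s) with non-positive total", call. = FALSE)
  structure(abund / rs, class = c("abundance_matrix", class(matrix())))
}

#' Partition OTUs into ubiquitous and scarce by prevalence
#'
#' An OTU is "ubiquitous" when it is present (abundance strictly positive)
#' in at least `min_samples` samples, and "scarce" otherwise. Scarce OTUs
#' are discarded before ordination: presence in fewer samples than the
#' threshold carries no information about substrate preference.
#'
#' @param abund An `abundance_matrix` (samples x OTUs), from
#'   [total_sum_scale()].
#' @param min_samples Prevalence threshold; default 2.
#' @return A list of class `prevalence_partition` with elements `ubiquitous`
#'   and `scarce` (OTU ids, input order preserved) and `min_samples`.
#' @export
prevalence_partition <- function(abund, min_samples = 2L) {
  stopifnot(is.matrix(abund), min_samples >= 1L)
  prev <- colSums(abund > 0)
  ids <- colnames(abund)
  structure(list(ubiquitous = ids[prev >= min_samples],
                 scarce = ids[prev < min_samples],
                 min_samples = as.integer(min_samples)),
            class = "prevalence_partition")
}

#' @export
print.prevalence_partition <- function(x, ...) {
  cat(sprintf(
    "<prevalence_partition> %d ubiquitous / %d scarce (threshold: present in >= %d samples)\n",
    length(x$ubiquitous), length(x$scarce), x$min_samples))
  invisible(x)
}

#' Pareto scaling
#'
#' Column-centers each kept OTU and divides by the square root of its
#' standard deviation (n-1 denominator). Pareto scaling damps the dominance
#' of abundant OTUs while, unlike unit-variance scaling, not inflating
#' near-noise variables: the scaled column variance equals the original
#' standard deviation. Columns with zero variance are dropped with a
#' warning.
#'
#' @param abund An `abundance_matrix` (samples x OTUs).
#' @param keep OTU ids to retain (typically the ubiquitous set); defaults to
#'   all.
#' @return A numeric matrix of class `scaled_matrix` (samples x kept OTUs)
#'   with attributes `center` (means), `scale` (sqrt of SDs) and `dropped`
#'   (zero-variance OTU ids).
#' @export
pareto_scale <- function(abund, keep = colnames(abund)) {
  stopifnot(is.matrix(abund))
  bad <- setdiff(keep, colnames(abund))
  if (length(bad)) stop("keep contains unknown OTU id(s): ",
                        paste(utils::head(bad, 5L), collapse = ", "),
                        call. = FALSE)
  x <- abund[, keep, drop = FALSE]
  mu <- colMeans(x)
  sdev <- apply(x, 2L, stats::sd)
  zero <- sdev == 0
  if (all(zero)) stop("all columns have zero variance", call. = FALSE)
  if (any(zero)) {
    warning(sum(zero), " zero-variance OTU column(s) dropped: ",
            paste(utils::head(colnames(x)[zero], 5L), collapse = ", "),
            call. = FALSE)
  }
  x <- x[, !zero, drop = FALSE]
  mu <- mu[!zero]
  divisor <- sqrt(sdev[!zero])
  y <- sweep(sweep(x, 2L, mu), 2L, divisor, "/")
  structure(y, center = mu, scale = divisor,
            dropped = names(sdev)[zero],
            class = c("scaled_matrix", class(matrix())))
}
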