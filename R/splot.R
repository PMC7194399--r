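# S-plot computation (per-variable covariance and correlation with the
# component scores) and the one-standard-deviation covariance selection
# rule used to pick the OTUs most characteristic of a component.

#' S-plot data for a fitted component
#'
#' For every variable j, computes its covariance and Pearson correlation
#' with the component's score vector: `cov_j = sum_i x_ij t_i / (n - 1)` and
#' `corr_j = cov_j / (sd_j * sd_t)`. By default x is taken from the working
#' matrix as it stood when the component was extracted (the input deflated
#' by earlier components), so covariances are not contaminated by variation
#' already attributed to earlier components; `against = "original"` uses the
#' undeflated input instead.
#'
#' @param model A [fit_cca()] model.
#' @param component Component index (default 1).
#' @param against `"working"` (default) or `"original"`.
#' @return Object of class `splot_data`: a data frame with columns `otu_id`,
#'   `covariance`, `correlation`, `zero_variance` (flag for variables whose
#'   correlation is undefined and reported as 0), plus attributes
#'   `component` and `against`.
#' @export
splot <- function(model, component = 1L, against = c("working", "original")) {
  stopifnot(inherits(model, "cca_model"))
  against <- match.arg(against)
  K <- ncol(model$scores)
  if (component < 1L || component > K) stop("component out of range",
                                            call. = FALSE)
  X <- if (against == "working") working_matrix(model, component) else model$X
  tvec <- model$scores[, component]
  n <- length(tvec)
  sd_t <- stats::sd(tvec)
  if (!is.finite(sd_t) || sd_t == 0) {
    stop("component ", component, " scores have zero variance", call. = FALSE)
  }
  covv <- as.vector(crossprod(X, tvec)) / (n - 1)
  sd_x <- apply(X, 2L, stats::sd)
  zero <- sd_x == 0
  corr <- numeric(ncol(X))
  corr[!zero] <- covv[!zero] / (sd_x[!zero] * sd_t)
  out <- data.frame(otu_id = colnames(X), covariance = covv,
                    correlation = corr, zero_variance = zero,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, component = as.integer(component), against = against,
            class = c("splot_data", "data.frame"))
}

#' Select characteristic OTUs from an S-plot
#'
#' Selects the variables whose absolute covariance with the component scores
#' exceeds one standard deviation of the covariance vector (n-1 denominator,
#' taken across all variables of the component). The band is centered at
#' zero by default — "greater than plus or minus one standard deviation" —
#' with a mean-centered band available via `center = "mean"`. When the
#' covariance spread is zero the selection is empty.
#'
#' @param sp An [splot()] result.
#' @param center `"zero"` (default) or `"mean"`.
#' @return Object of class `selection_result`: a data frame with columns
#'   `otu_id`, `component`, `covariance`, `correlation` and `sign`
#'   (+1/-1), plus a `threshold` attribute (the covariance SD used).
#' @export
select_otus <- function(sp, center = c("zero", "mean")) {
  stopifnot(inherits(sp, "splot_data"))
  center <- match.arg(center)
  if (nrow(sp) < 2L) stop("need at least 2 variables to select from",
                          call. = FALSE)
  covv <- sp$covariance
  thr <- stats::sd(covv)
  dev <- if (center == "mean") covv - mean(covv) else covv
  sel <- if (thr > 0) abs(dev) > thr else rep(FALSE, length(covv))
  out <- data.frame(otu_id = sp$otu_id[sel],
                    component = rep(attr(sp, "component"), sum(sel)),
                    covariance = covv[sel],
                    correlation = sp$correlation[sel],
                    sign = ifelse(dev[sel] > 0, 1L, -1L),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, threshold = thr, center = center,
            class = c("selection_result", "data.frame"))
}

#' S-plot selection across all components of a model
#'
#' Runs [splot()] and [select_otus()] for every component and binds the
#' per-component selections into one table.
#'
#' @inheritParams splot
#' @inheritParams select_otus
#' @return A `selection_result` data frame covering all components; the
#'   `threshold` attribute is the per-component vector of covariance SDs.
#' @export
select_all_components <- function(model, against = c("working", "original"),
                                  center = c("zero", "mean")) {
  against <- match.arg(against)
  center <- match.arg(center)
  K <- ncol(model$scores)
  pieces <- vector("list", K)
  thr <- numeric(K)
  empty <- data.frame(otu_id = character(), component = integer(),
                      covariance = numeric(), correlation = numeric(),
                      sign = integer(), stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    if (stats::sd(model$scores[, k]) == 0) {
      # exhausted component (e.g. input of lower rank): nothing to select
      pieces[[k]] <- empty
      next
    }
    sel <- select_otus(splot(model, k, against = against), center = center)
    thr[k] <- attr(sel, "threshold")
    pieces[[k]] <- as.data.frame(sel)
  }
  structure(do.call(rbind, pieces), threshold = thr, center = center,
            class = c("selection_result", "data.frame"))
}
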