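# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Random OTU count table with guaranteed positive sample totals.
random_otu_table <- function(n_otus = 100L, n_samples = 10L, seed = 42L,
                             sparsity = 0.6, lambda = 50) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_otus * n_samples, lambda), n_otus, n_samples)
  m[stats::runif(length(m)) < sparsity] <- 0L
  m[1L, ] <- m[1L, ] + 1L  # no zero-total sample
  dimnames(m) <- list(sprintf("otu_%03d", seq_len(n_otus)),
                      sprintf("s%02d", seq_len(n_samples)))
  otu_table(m)
}

# Random column-centered matrix (samples x variables).
random_centered_matrix <- function(n = 10L, p = 30L, seed = 1L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- sweep(X, 2L, colMeans(X))
  dimnames(X) <- list(sprintf("s%02d", seq_len(n)),
                      sprintf("v%03d", seq_len(p)))
  X
}

# Column-centered rank-1 matrix u v' with unit-norm, zero-sum u.
rank1_matrix <- function(n = 8L, p = 20L, seed = 3L) {
  set.seed(seed)
  u <- stats::rnorm(n)
  u <- u - mean(u)
  u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(p)
  X <- tcrossprod(u, v)
  dimnames(X) <- list(sprintf("s%02d", seq_len(n)),
                      sprintf("v%03d", seq_len(p)))
  list(X = X, u = u, v = v)
}

# Minimal splot_data object from a covariance vector.
fake_splot <- function(covariance, component = 1L) {
  structure(data.frame(otu_id = sprintf("otu_%02d", seq_along(covariance)),
                       covariance = covariance,
                       correlation = sign(covariance) * 0.5,
                       zero_variance = FALSE, stringsAsFactors = FALSE),
            component = component, against = "working",
            class = c("splot_data", "data.frame"))
}

# Small taxonomy over the given ids, alternating Archaea/Bacteria.
small_taxonomy <- function(otu_ids) {
  n <- length(otu_ids)
  arch <- c("Archaea", "Euryarchaeota", "Methanomicrobia",
            "Methanosarcinales", "Methanosarcinaceae", "Methanosarcina")
  bact <- c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
            "Clostridiaceae", "Clostridium")
  m <- t(vapply(seq_len(n), function(i) if (i %% 2L) bact else arch,
                character(6L)))
  taxonomy_table(m, otu_ids = otu_ids)
}

# Run the preprocessing + CCA + selection chain on a generated dataset.
fit_synthetic <- function(d, n_components = 2L, min_samples = 2L) {
  abund <- total_sum_scale(d$otu)
  part <- prevalence_partition(abund, min_samples)
  scaled <- suppressWarnings(pareto_scale(abund, keep = part$ubiquitous))
  model <- suppressWarnings(fit_cca(scaled, n_components = n_components))
  selection <- select_all_components(model)
  list(abund = abund, part = part, scaled = scaled, model = model,
       selection = selection)
}
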