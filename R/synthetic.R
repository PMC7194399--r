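# Synthetic co-digestion communities: OTU counts with a planted substrate
# gradient, taxonomy, metadata and performance markers, plus the ground
# truth needed for parameter-recovery studies.

#' Define a synthetic co-digestion scenario
#'
#' The default scenario emulates one co-digestion dataset: 5 substrate
#' mixture levels (0/25/50/75/100% co-substrate) observed at 2 time points
#' (10 samples), 600 OTUs with high sparsity and a dominant-vs-subdominant
#' abundance hierarchy. OTU groups respond to the mixture gradient `g`
#' (linearly, positive or negative) or to the mixture-preference latent `m`
#' (quadratic in the percentage, peaked at 50%); "inactive" OTUs have tiny
#' baselines so that most appear in fewer than 2 samples and are removed by
#' the prevalence filter. Expected relative abundances are a softmax of
#' per-OTU linear predictors (the data are compositional, as after
#' total-sum scaling); counts are negative binomial around
#' `depth * abundance`. Performance markers are linear in a latent plus
#' Gaussian noise.
#'
#' @param n_levels Number of mixture levels spanning 0-100% (default 5).
#' @param n_timepoints Time points per level (default 2).
#' @param n_otus Total number of OTUs (default 600).
#' @param groups Named integer vector of group sizes `gradient_pos`,
#'   `gradient_neg`, `mixture_pref`, `inactive`; must sum to `n_otus`.
#' @param archaea_fraction Fraction of OTUs labelled Archaea (default 0.12).
#' @param depth Mean library size (default 50000).
#' @param dispersion Negative-binomial size parameter (default 4; smaller is
#'   more over-dispersed).
#' @param effect_size Log-scale span of the gradient response (default 2,
#'   i.e. about a 7-fold change in expected relative abundance across the
#'   full mixture gradient); per-OTU slopes are `effect_size` times a
#'   Uniform(0.75, 1.25) draw, so each planted group responds coherently.
#' @param baseline_sd SD of the log-scale baselines of active OTUs
#'   (default 0.6), creating the dominant/subdominant hierarchy.
#' @param inactive_shift Log-scale baseline offset of inactive OTUs
#'   (default -10).
#' @param inactive_sd SD of the log-scale baselines of inactive OTUs
#'   (default 3): most are then far below detection and end up scarce,
#'   while the upper tail forms a ubiquitous background of
#'   non-responding OTUs, as observed in real digester communities where
#'   only a minority of ubiquitous OTUs respond to the substrate.
#' @param cosubstrate Co-substrate label for the mixture samples
#'   (default "FW").
#' @param marker_couplings List of marker definitions: each a list with
#'   `name`, `latent` (`"gradient"` or `"mixture"`), `slope`, `intercept`
#'   and `noise_sd`.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_levels = 5L, n_timepoints = 2L,
                               n_otus = 600L,
                               groups = c(gradient_pos = 45L,
                                          gradient_neg = 45L,
                                          mixture_pref = 30L,
                                          inactive = 480L),
                               archaea_fraction = 0.12,
                               depth = 50000,
                               dispersion = 4,
                               effect_size = 2,
                               baseline_sd = 0.6,
                               inactive_shift = -10,
                               inactive_sd = 3,
                               cosubstrate = c("FW", "GG"),
                               marker_couplings = default_marker_couplings(),
                               seed = 1L) {
  cosubstrate <- match.arg(cosubstrate)
  groups <- unlist(groups)  # accept a named list (e.g. from a YAML config)
  req <- c("gradient_pos", "gradient_neg", "mixture_pref", "inactive")
  if (!all(req %in% names(groups))) {
    stop("groups must name ", paste(req, collapse = ", "), call. = FALSE)
  }
  groups <- groups[req]
  if (any(groups < 0) || sum(groups) != n_otus) {
    stop("group sizes must be non-negative and sum to n_otus", call. = FALSE)
  }
  if (depth <= 0 || dispersion <= 0) {
    stop("depth and dispersion must be positive", call. = FALSE)
  }
  if (n_levels < 2L || n_timepoints < 1L) {
    stop("need at least 2 mixture levels and 1 time point", call. = FALSE)
  }
  structure(list(n_levels = as.integer(n_levels),
                 n_timepoints = as.integer(n_timepoints),
                 n_otus = as.integer(n_otus), groups = groups,
                 archaea_fraction = archaea_fraction, depth = depth,
                 dispersion = dispersion, effect_size = effect_size,
                 baseline_sd = baseline_sd, inactive_shift = inactive_shift,
                 inactive_sd = inactive_sd,
                 cosubstrate = cosubstrate,
                 marker_couplings = marker_couplings,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Default marker couplings
#'
#' Three markers mirroring the sign structure seen in co-digestion
#' performance data: one coupled positively to the substrate gradient
#' (`alpha_app`, the acetoclastic/hydrogenotrophic balance indicator), one
#' negatively (`NH4`), and one to the mixture-preference latent
#' (`acetate`).
#' @return A list of marker coupling definitions for
#'   [synthetic_scenario()].
#' @export
default_marker_couplings <- function() {
  list(list(name = "alpha_app", latent = "gradient", slope = 0.3,
            intercept = 0.5, noise_sd = 0.03),
       list(name = "NH4", latent = "gradient", slope = -1.2,
            intercept = 2.5, noise_sd = 0.12),
       list(name = "acetate", latent = "mixture", slope = 1.5,
            intercept = 0.8, noise_sd = 0.15))
}

# Small pools of plausible anaerobic-digester lineages.
archaea_lineages <- function() {
  rbind(
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanosarcinales",
      "Methanosarcinaceae", "Methanosarcina"),
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanomicrobiales",
      "Methanomicrobiaceae", "Methanoculleus"),
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanomicrobiales",
      "Methanomicrobiaceae", "Methanofollis"),
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanomicrobiales",
      "Methanocorpusculaceae", "Methanocorpusculum"),
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanomicrobiales",
      "Methanospirillaceae", "Methanospirillum"),
    c("Archaea", "Euryarchaeota", "Methanobacteria", "Methanobacteriales",
      "Methanobacteriaceae", "Methanobacterium"))
}

bacteria_lineages <- function() {
  rbind(
    c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
      "Clostridiaceae", "Clostridium"),
    c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
      "Ruminococcaceae", "Ruminococcus"),
    c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
      "Christensenellaceae", "unknown"),
    c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
      "Lactobacillaceae", "Lactobacillus"),
    c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales",
      "Porphyromonadaceae", "unknown"),
    c("Bacteria", "Chloroflexi", "Anaerolineae", "Anaerolineales",
      "Anaerolineaceae", "unknown"),
    c("Bacteria", "Cloacimonetes", "Cloacimonadia", "Cloacimonadales",
      "Cloacimonadaceae", "unknown"),
    c("Bacteria", "Synergistetes", "Synergistia", "Synergistales",
      "Synergistaceae", "unknown"),
    c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
      "Betaproteobacteriales", "Rhodocyclaceae", "unknown"),
    c("Bacteria", "Proteobacteria", "Deltaproteobacteria",
      "Syntrophobacterales", "Syntrophobacteraceae", "Syntrophobacter"))
}

#' Generate a synthetic co-digestion dataset
#'
#' @param scn A [synthetic_scenario()].
#' @return A list with elements `otu` ([otu_table()]), `taxonomy`
#'   ([taxonomy_table()]), `metadata` ([sample_metadata()]), `markers`
#'   ([marker_table()]) and `truth` — a list of class `synthetic_truth`
#'   with per-OTU `group` labels, per-sample latents `g` (centered mixture
#'   gradient, monotone in percent co-substrate) and `m`
#'   (mixture preference, maximal at 50%), and the marker generative
#'   parameters.
#' @export
generate_synthetic <- function(scn = synthetic_scenario()) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(scn$seed)
  percents <- seq(0, 100, length.out = scn$n_levels)
  grid <- expand.grid(timepoint = seq_len(scn$n_timepoints),
                      percent = percents)
  n <- nrow(grid)
  day <- 14L + 7L * grid$timepoint
  sample_ids <- sprintf("S%02d_p%03.0f_d%02d", seq_len(n), grid$percent, day)
  g <- (grid$percent - 50) / 50           # in [-1, 1], monotone in percent
  m <- 1 - ((grid$percent - 50) / 50)^2   # in [0, 1], peaks at 50%

  sizes <- scn$groups
  group <- factor(rep(names(sizes), sizes), levels = names(sizes))
  otu_ids <- sprintf("otu_%04d", seq_len(scn$n_otus))
  active <- group != "inactive"
  baseline <- numeric(scn$n_otus)
  baseline[active] <- stats::rnorm(sum(active), 0, scn$baseline_sd)
  baseline[!active] <- scn$inactive_shift +
    stats::rnorm(sum(!active), 0, scn$inactive_sd)
  beta <- numeric(scn$n_otus)
  beta[group == "gradient_pos"] <- scn$effect_size *
    stats::runif(sizes[["gradient_pos"]], 0.75, 1.25)
  beta[group == "gradient_neg"] <- -scn$effect_size *
    stats::runif(sizes[["gradient_neg"]], 0.75, 1.25)
  gamma <- numeric(scn$n_otus)
  gamma[group == "mixture_pref"] <- scn$effect_size *
    stats::runif(sizes[["mixture_pref"]], 0.75, 1.25)

  counts <- matrix(0L, scn$n_otus, n, dimnames = list(otu_ids, sample_ids))
  for (i in seq_len(n)) {
    eta <- baseline + beta * g[i] + gamma * (m[i] - 0.5)
    prob <- exp(eta - max(eta))
    prob <- prob / sum(prob)
    counts[, i] <- stats::rnbinom(scn$n_otus, mu = scn$depth * prob,
                                  size = scn$dispersion)
  }
  zero_total <- colSums(counts) == 0L
  if (any(zero_total)) {
    stop("generated sample(s) with zero total count (depth too small): ",
         paste(sample_ids[zero_total], collapse = ", "), call. = FALSE)
  }
  table <- otu_table(counts)

  n_arch <- round(scn$archaea_fraction * scn$n_otus)
  is_arch <- seq_len(scn$n_otus) %in% sample.int(scn$n_otus, n_arch)
  arch_pool <- archaea_lineages()
  bact_pool <- bacteria_lineages()
  lin <- matrix("", scn$n_otus, length(TAXONOMY_RANKS))
  lin[is_arch, ] <- arch_pool[sample.int(nrow(arch_pool), sum(is_arch),
                                         replace = TRUE), ]
  lin[!is_arch, ] <- bact_pool[sample.int(nrow(bact_pool), sum(!is_arch),
                                          replace = TRUE), ]
  # some OTUs remain unclassified below a random rank, as in real data
  frayed <- stats::runif(scn$n_otus) < 0.15
  cut_at <- sample(3:6, scn$n_otus, replace = TRUE)
  for (j in which(frayed)) lin[j, cut_at[j]:6] <- UNKNOWN_RANK
  taxonomy <- taxonomy_table(lin, otu_ids = otu_ids)

  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids,
    cosubstrate = ifelse(grid$percent == 0, "none", scn$cosubstrate),
    percent_cosubstrate = grid$percent,
    day = day,
    dataset = scn$cosubstrate,
    stringsAsFactors = FALSE), table = table)

  mk <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (cp in scn$marker_couplings) {
    latent <- if (cp$latent == "gradient") g else m
    mk[[cp$name]] <- cp$intercept + cp$slope * latent +
      stats::rnorm(n, 0, cp$noise_sd)
  }
  markers <- marker_table(mk)

  truth <- structure(list(group = stats::setNames(group, otu_ids),
                          g = stats::setNames(g, sample_ids),
                          m = stats::setNames(m, sample_ids),
                          marker_params = scn$marker_couplings),
                     class = "synthetic_truth")
  list(otu = table, taxonomy = taxonomy, metadata = metadata,
       markers = markers, truth = truth)
}

#' Parameter-recovery metrics against the planted truth
#'
#' Measures how well a fitted model recovers the planted structure:
#' `score_gradient_r` is the absolute Pearson correlation between the first
#' component's scores and the planted gradient latent, and
#' precision/recall/F1 compare the OTUs selected on the first component
#' against the union of the planted gradient-responsive groups. An empty
#' selection scores precision 0 and recall 0.
#'
#' @param truth A `synthetic_truth` (from [generate_synthetic()]).
#' @param model The [fit_cca()] model fitted on the generated data.
#' @param selection A `selection_result` covering component 1.
#' @return A list with `score_gradient_r`, `selection_precision`,
#'   `selection_recall` and `F1`.
#' @export
recovery_metrics <- function(truth, model, selection) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(model, "cca_model"))
  g <- truth$g[rownames(model$scores)]
  score_r <- abs(stats::cor(model$scores[, 1L], g))
  positives <- names(truth$group)[truth$group %in%
                                    c("gradient_pos", "gradient_neg")]
  picked <- unique(selection$otu_id[selection$component == 1L])
  tp <- length(intersect(picked, positives))
  precision <- if (length(picked)) tp / length(picked) else 0
  recall <- if (length(positives)) tp / length(positives) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(score_gradient_r = score_r, selection_precision = precision,
       selection_recall = recall, F1 = f1)
}
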