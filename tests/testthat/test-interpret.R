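test_that("richness counts strictly positive OTUs per sample", {
  m <- matrix(c(0.5, 0.5, 0,
                0.2, 0.3, 0.5), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_identical(unname(richness(m)), c(2L, 3L))
  expect_identical(unname(richness(m, restrict_to = c("a", "c"))), c(1L, 2L))
  # brute force on a sparse random matrix
  set.seed(2)
  r <- matrix(rbinom(80, 1, 0.3) * runif(80), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("o", 1:10)))
  expect_identical(unname(richness(r)),
                   unname(apply(r, 1, function(x) sum(x > 0))))
})

test_that("the 1%-abundance overview keeps, merges and conserves correctly", {
  ids <- c("big_arch", "small_arch", "big_bact", "tiny_bact1", "tiny_bact2")
  m <- rbind(s1 = c(0.20, 0.009, 0.70, 0.006, 0.085),
             s2 = c(0.30, 0.009, 0.60, 0.011, 0.080))
  colnames(m) <- ids
  tax <- taxonomy_table(rbind(
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanosarcinales",
      "Methanosarcinaceae", "Methanosarcina"),
    c("Archaea", "Euryarchaeota", "Methanomicrobia", "Methanomicrobiales",
      "Methanospirillaceae", "Methanospirillum"),
    c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
      "Clostridiaceae", "Clostridium"),
    c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
      "Ruminococcaceae", "unknown"),
    c("Bacteria", "Chloroflexi", "Anaerolineae", "Anaerolineales",
      "Anaerolineaceae", "unknown")), otu_ids = ids)
  ov <- traditional_overview(m, tax)

  # small_arch never exceeds 1% -> merged into Other Archaea
  expect_true("Other Archaea" %in% rownames(ov$Archaea))
  expect_false(any(grepl("small_arch", rownames(ov$Archaea))))
  expect_equal(unname(ov$Archaea["Other Archaea", ]), c(0.009, 0.009))
  # tiny_bact1 exceeds 1% in one sample -> kept individually
  expect_true(any(grepl("tiny_bact1", rownames(ov$Bacteria))))
  # labels use genus for Archaea, order for Bacteria
  expect_true(any(grepl("^Methanosarcina", rownames(ov$Archaea))))
  expect_true(any(grepl("^Clostridiales", rownames(ov$Bacteria))))
  # conservation: per-domain row sums equal the domain totals per sample
  arch_tot <- rowSums(m[, c("big_arch", "small_arch")])
  expect_lt(max(abs(colSums(ov$Archaea) - arch_tot)), 1e-12)
  bact_tot <- rowSums(m[, c("big_bact", "tiny_bact1", "tiny_bact2")])
  expect_lt(max(abs(colSums(ov$Bacteria) - bact_tot)), 1e-12)
})

test_that("unknown domains are routed to a flagged row with a warning", {
  ids <- c("x", "y")
  m <- rbind(s1 = c(0.6, 0.4), s2 = c(0.5, 0.5))
  colnames(m) <- ids
  tax <- taxonomy_table(rbind(
    c("Bacteria", rep("unknown", 5)),
    c("unknown", rep("unknown", 5))), otu_ids = ids)
  expect_warning(ov <- traditional_overview(m, tax), "unclassified domain")
  expect_equal(unname(ov$unclassified[1, ]), c(0.4, 0.5))
})

test_that("correlate implements pairwise-complete Pearson r with error cells", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  y <- c(1, -1, 0, 0, 0)
  xc <- x - mean(x)
  y_orth <- y - sum(y * xc) / sum(xc^2) * xc
  expect_lt(abs(correlate(x, y_orth)$r), 1e-12)

  # two-pass textbook oracle on random vectors with missings
  set.seed(6)
  a <- rnorm(20); b <- rnorm(20)
  a[c(3, 11)] <- NA; b[c(11, 17)] <- NA
  ok <- !is.na(a) & !is.na(b)
  am <- a[ok] - mean(a[ok]); bm <- b[ok] - mean(b[ok])
  r_oracle <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  res <- correlate(a, b)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_identical(res$n, sum(ok))

  expect_identical(correlate(c(1, 2), c(3, 4))$error, "insufficient_n")
  expect_identical(correlate(rep(1, 5), rnorm(5))$error, "zero_variance")
})

test_that("the correlation report finds exact couplings and flags degenerate markers", {
  set.seed(10)
  d <- generate_synthetic(synthetic_scenario(n_otus = 120L,
                                             groups = c(gradient_pos = 25L,
                                                        gradient_neg = 25L,
                                                        mixture_pref = 10L,
                                                        inactive = 60L),
                                             seed = 10L))
  fit <- fit_synthetic(d)
  mk <- d$markers
  mk$exact <- 2 * fit$model$scores[match(mk$sample_id,
                                         rownames(fit$model$scores)), 1]
  mk$flat <- rep(1, nrow(mk))
  rep_tab <- correlation_report(fit$model, fit$abund, d$taxonomy,
                                d$metadata, marker_table(as.data.frame(mk)))
  cell <- rep_tab[rep_tab$series == "CC1" & rep_tab$target == "exact", ]
  expect_equal(abs(cell$r), 1, tolerance = 1e-10)
  flat_cells <- rep_tab[rep_tab$target == "flat", ]
  expect_true(all(flat_cells$error == "zero_variance"))
  expect_true(all(rep_tab$r[!is.na(rep_tab$r)] >= -1 &
                    rep_tab$r[!is.na(rep_tab$r)] <= 1))
  expect_true(all(rep_tab$n[is.na(rep_tab$error)] >= 3))
  # expected aggregate rows are present
  expect_true("archaea_fraction" %in% rep_tab$series)
  expect_true("ubiquitous_richness" %in% rep_tab$series)
})

test_that("planted marker coupling signs are recovered across seeds", {
  signs_ok <- logical(10)
  for (s in 1:10) {
    d <- generate_synthetic(synthetic_scenario(seed = s))
    fit <- fit_synthetic(d)
    rep_tab <- correlation_report(fit$model, fit$abund, d$taxonomy,
                                  d$metadata, d$markers)
    r_alpha <- rep_tab$r[rep_tab$series == "CC1" &
                           rep_tab$target == "alpha_app"]
    r_nh4 <- rep_tab$r[rep_tab$series == "CC1" & rep_tab$target == "NH4"]
    # both markers are coupled to the same gradient with opposite slopes,
    # so whatever CC1's sign, the two correlations must be opposite and strong
    signs_ok[s] <- sign(r_alpha) == -sign(r_nh4) &&
      abs(r_alpha) > 0.5 && abs(r_nh4) > 0.5
  }
  expect_true(all(signs_ok))
})
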