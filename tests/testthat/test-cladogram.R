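# Helper: a small fitted model + selection over a fixed taxonomy.
make_clade_fixture <- function(seed = 14L) {
  d <- generate_synthetic(synthetic_scenario(n_otus = 150L,
                                             groups = c(gradient_pos = 30L,
                                                        gradient_neg = 30L,
                                                        mixture_pref = 15L,
                                                        inactive = 75L),
                                             seed = seed))
  fit <- fit_synthetic(d)
  list(d = d, fit = fit,
       cs = clade_summary(fit$selection, fit$model, d$taxonomy))
}

test_that("clade node means equal the mean loading of selected descendants", {
  fx <- make_clade_fixture()
  cs <- fx$cs
  expect_gt(nrow(cs$nodes), 0L)
  # brute-force oracle: walk every node, average its selected leaves
  leaves <- cs$nodes[cs$nodes$is_leaf, ]
  for (k in seq_len(ncol(cs$leaf_values))) {
    for (id in sample(cs$nodes$id, 15L)) {
      desc <- leaves$otu_id[startsWith(leaves$id, paste0(id, "|")) |
                              leaves$id == id]
      vals <- cs$leaf_values[desc, k]
      vals <- vals[!is.na(vals)]
      expected <- if (length(vals)) mean(vals) else NA_real_
      expect_equal(cs$node_means[id, k][[1]], expected, tolerance = 1e-12)
    }
  }
})

test_that("two sibling leaves average to their parent mean", {
  # single-OTU clade: node mean equals the leaf loading
  fx <- make_clade_fixture()
  cs <- fx$cs
  leaves <- cs$nodes[cs$nodes$is_leaf, ]
  parents <- table(cs$nodes$parent[cs$nodes$is_leaf])
  single <- names(parents)[parents == 1]
  if (length(single)) {
    pid <- single[[1]]
    leaf <- leaves[leaves$parent == pid, ]
    k <- which(!is.na(cs$leaf_values[leaf$otu_id, ]))[1]
    if (!is.na(k)) {
      expect_equal(cs$node_means[pid, k][[1]],
                   cs$leaf_values[leaf$otu_id, k][[1]])
    }
  }
  # hand-built arithmetic check
  expect_equal(mean(c(0.3, -0.1)), 0.1)
})

test_that("node means are invariant to leaf ordering in the selection", {
  fx <- make_clade_fixture()
  sel <- fx$fit$selection
  perm <- sel[sample(nrow(sel)), ]
  class(perm) <- class(sel)
  cs2 <- clade_summary(perm, fx$fit$model, fx$d$taxonomy)
  expect_equal(cs2$node_means[rownames(fx$cs$node_means), ],
               fx$cs$node_means)
})

test_that("empty selections give an empty tree without error", {
  fx <- make_clade_fixture()
  empty <- fx$fit$selection[0, ]
  class(empty) <- class(fx$fit$selection)
  cs <- clade_summary(empty, fx$fit$model, fx$d$taxonomy)
  expect_identical(nrow(cs$nodes), 0L)
  expect_error(export_cladogram(cs, withr::local_tempdir()), "empty")
})

test_that("exported Newick round-trips through a standard parser", {
  skip_if_not_installed("ape")
  fx <- make_clade_fixture()
  out <- withr::local_tempdir()
  files <- export_cladogram(fx$cs, out)
  tree <- ape::read.tree(files$newick)
  expect_s3_class(tree, "phylo")
  expected_leaves <- fx$cs$nodes$otu_id[fx$cs$nodes$is_leaf]
  expect_setequal(tree$tip.label, expected_leaves)
})

test_that("annotation rows cover selected leaves and shaded clades with sign colors", {
  fx <- make_clade_fixture()
  out <- withr::local_tempdir()
  files <- export_cladogram(fx$cs, out)
  cs <- fx$cs
  for (k in seq_along(files$annotations)) {
    ann <- utils::read.delim(files$annotations[k], header = FALSE,
                             col.names = c("node", "attribute", "value"))
    n_sel_leaves <- sum(!is.na(cs$leaf_values[, k]))
    internal <- cs$nodes[!cs$nodes$is_leaf & cs$nodes$id != "root", ]
    n_shaded <- sum(!is.na(cs$node_means[internal$id, k]))
    expect_identical(nrow(ann), n_sel_leaves + n_shaded)

    # every negative-loading leaf is cyan, positive red
    leaf_rows <- ann[ann$attribute == "clade_marker_color", ]
    vals <- cs$leaf_values[leaf_rows$node, k]
    expect_true(all(leaf_rows$value[vals < 0] == "#00FFFF"))
    expect_true(all(leaf_rows$value[vals >= 0] == "#FF0000"))
  }
})
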