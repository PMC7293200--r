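# Hand-built mapped reactions for entry extraction.
amide_rxn <- function(acid = "CCC", amine = "CC", label =
                        "C-N Bond Formation (Acylation) (Amide coupling)") {
  tmpl <- reaction_templates()$amide_coupling
  r <- rvdesign:::instantiate_template(tmpl, acid, amine)
  r$label <- parse_label(label)
  r
}

test_that("entry extraction deduplicates on (structure, class)", {
  r1 <- amide_rxn("CCCC", "C")
  r2 <- amide_rxn("CCCC", "CC")      # same starting material (the acid)
  ent <- build_labeled_entries(list(r1, r2), level = 3)
  expect_length(ent, 1)
  expect_equal(attr(ent, "n_duplicates"), 1)
  # same structure under two classes at level 3 stays two entries, merges
  # into one at level 2
  suz <- amide_rxn("CCCC", "C", "C-C Bond Formation (Coupling) (Suzuki)")
  hek <- amide_rxn("CCCC", "C", "C-C Bond Formation (Coupling) (Heck)")
  expect_length(build_labeled_entries(list(suz, hek), level = 3), 2)
  expect_length(build_labeled_entries(list(suz, hek), level = 2), 1)
  # ambiguous mapped-atom ties are discarded and counted
  tie <- parse_reaction("[CH3:1][CH3:2].[CH3:3][CH3:4]>>[CH3:1][CH2:2][CH2:3][CH3:4]")
  tie$label <- parse_label("Synthesis")
  ent2 <- build_labeled_entries(list(tie), level = 3)
  expect_length(ent2, 0)
  expect_equal(attr(ent2, "n_discarded"), 1)
})

test_that("pivoting merges identical fingerprints and unions labels", {
  # two structurally different amines with identical functional-group
  # fingerprints, carrying different classes
  e <- list(
    list(structure = mol_from_smiles("NCCCC"), canonical_id = mol_id("NCCCC"),
         label = parse_label("Functional Conversion")),
    list(structure = mol_from_smiles("NCCCCC"), canonical_id = mol_id("NCCCCC"),
         label = parse_label("Protection")))
  ds <- pivot_merge(e, "fg")
  expect_equal(nrow(ds$X), 1)
  expect_equal(sum(ds$Y), 2)
  expect_equal(ds$member_count, 2L)
  # distinct fingerprints stay distinct
  e2 <- c(e[1], list(list(structure = mol_from_smiles("OC(=O)C"),
                          canonical_id = mol_id("OC(=O)C"),
                          label = parse_label("Protection"))))
  ds2 <- pivot_merge(e2, "fg")
  expect_equal(nrow(ds2$X), 2)
})

test_that("pivot conserves (fingerprint, label) pairs and row positivity", {
  entries <- build_labeled_entries(fx_reactions()[1:400], level = 3)
  ds <- pivot_merge(entries, "keys166")
  fpkey <- vapply(entries, function(e)
    paste(binary_fingerprint(e$structure, "keys166")$bits, collapse = ","), "")
  labkey <- vapply(entries, function(e) label_text(e$label), "")
  expect_equal(sum(ds$Y), length(unique(paste(fpkey, labkey, sep = "|"))))
  expect_true(all(rowSums(ds$Y) >= 1))
  expect_false(any(duplicated(apply(ds$X, 1, paste, collapse = ""))))
  expect_lte(nrow(ds$X), length(unique(vapply(entries, `[[`, "", "canonical_id"))))
})

test_that("coarser schemes merge at least as much as finer ones", {
  entries <- build_labeled_entries(fx_reactions()[1:400], level = 3)
  n_fg <- nrow(pivot_merge(entries, "fg")$X)
  n_keys <- nrow(pivot_merge(entries, "keys166")$X)
  n_hash <- nrow(pivot_merge(entries, "hashed1024")$X)
  expect_lte(n_fg, n_keys)
  expect_lte(n_keys, n_hash)
})

test_that("stratified split respects per-stratum fractions and the seed", {
  Y1 <- matrix(0L, 60, 3); Y1[, 1] <- 1L
  Y1[1:10, 2] <- 1L                      # 10 two-label entries
  ds <- structure(list(X = matrix(rbinom(60 * 5, 1, 0.5), 60, 5,
                                  dimnames = list(NULL, paste0("b", 1:5))),
                       Y = Y1, vocabulary = NULL, scheme = "keys166",
                       level = 3, member_count = rep(1L, 60),
                       entry_ids = as.list(seq_len(60))), class = "rxv_mlds")
  sp <- stratified_split(ds, 0.8, seed = 4)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), 60)
  counts <- rowSums(ds$Y)
  tr <- unlist(sp$train$entry_ids)         # original row indices
  expect_equal(sum(counts[tr] == 1), 40)   # 50 one-label entries -> 40/10
  expect_equal(sum(counts[tr] == 2), 8)    # 10 two-label entries -> 8/2
  sp2 <- stratified_split(ds, 0.8, seed = 4)
  expect_identical(sp$train$X, sp2$train$X)
  sp3 <- stratified_split(ds, 0.8, seed = 5)
  expect_false(identical(sp$train$X, sp3$train$X))
})
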