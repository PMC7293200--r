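test_that("balancing keeps, splits or rejects reactions on carbon count", {
  ok <- balance_reaction(parse_reaction("OC(=O)C.NCC>>CC(=O)NCC.O"))
  expect_length(ok, 1)
  # isomeric alternatives: one entry per product
  iso <- balance_reaction(parse_reaction("BrCCC.N>>NCCC.NC(C)C"))
  expect_length(iso, 2)
  expect_length(iso[[1]]$products, 1)
  expect_setequal(vapply(iso, function(r) mol_id(r$products[[1]]), ""),
                  c(mol_id("NCCC"), mol_id("NC(C)C")))
  # unrecoverable carbon imbalance: rejected with a reason, not an error
  bad <- balance_reaction(parse_reaction("CCCCCC>>CCCC"))
  expect_length(bad, 0)
  expect_equal(attr(bad, "rejections"), "carbon_imbalance")
  expect_error(parse_reaction("CC>>"), "at least one")
  # heavy-atom completion with a known leaving group
  lg <- balance_reaction(parse_reaction("CCBr.N>>CCN"))
  expect_length(lg[[1]]$products, 2)
  expect_equal(mol_id(lg[[1]]$products[[2]]), mol_id("Br"))
})

test_that("starting-material selection follows the mapped-atom rule", {
  single <- parse_reaction("CCO>>CC=O")
  expect_identical(mol_id(select_starting_material(single)), mol_id("CCO"))
  r <- parse_reaction("[CH3:1][C:2](=O)[OH:3].[NH2:4][CH3:5]>>[CH3:1][C:2](=O)[NH:4][CH3:5].[OH2:3]")
  expect_identical(mol_id(select_starting_material(r)), mol_id("CC(=O)O"))
  tie <- parse_reaction("[CH3:1][CH3:2].[CH3:3][CH3:4]>>[CH3:1][CH2:2][CH2:3][CH3:4]")
  expect_null(select_starting_material(tie))
  nomap <- parse_reaction("CC.CC>>CCCC")
  expect_error(select_starting_material(nomap), "atom map")
})

test_that("reaction vectors equal the brute-force descriptor difference", {
  ident <- compute_reaction_vector(parse_reaction("CCO>>CCO"))
  expect_length(ident$negative, 0)
  expect_length(ident$positive, 0)
  r <- parse_reaction("CBr.N>>CN.Br")
  rv <- compute_reaction_vector(r)
  dr <- oracle_diff(oracle_descriptor(mol_from_smiles("CN.Br")),
                    oracle_descriptor(mol_from_smiles("CBr.N")))
  expect_ms_equal(rv$positive, dr[dr > 0])
  expect_ms_equal(rv$negative, -dr[dr < 0])
  expect_equal(names(rv$negative), "2:Br.1.0,1,C.1.0")
  expect_equal(names(rv$positive), "2:C.1.0,1,N.1.0")
  # esterification gains the C-O-C ester path among its AP3 features
  est <- compute_reaction_vector(
    parse_reaction("OC(=O)C.OCC>>CCOC(C)=O.O"))
  expect_true(any(grepl("^3:C\\..*,1,O\\.2\\.0,1,C\\.", names(est$positive))))
  expect_error(compute_reaction_vector(parse_reaction("CCCCCC>>CC")),
               "carbon-balanced")
})

test_that("conservation identity holds exactly on generated reactions", {
  for (r in fx_reactions()[1:40]) {
    rv <- compute_reaction_vector(r)
    dr <- Reduce(ms_add, lapply(r$reactants, molecule_descriptor), ms())
    dp <- Reduce(ms_add, lapply(r$products, molecule_descriptor), ms())
    expect_ms_equal(ms_subtract(dp, dr), ms_subtract(rv$positive, rv$negative))
  }
})

test_that("applicability is count-aware multiset containment", {
  rv <- compute_reaction_vector(parse_reaction("CCBr.N>>CCN.Br"))
  expect_true(is_applicable(rv, mol_from_smiles("CCBr")))
  expect_false(is_applicable(rv, mol_from_smiles("CCO")))
  # a vector needing the feature twice requires two occurrences
  double <- structure(list(
    negative = ms("2:Br.1.0,1,C.2.0", 2), positive = ms(),
    label = NULL, id = "d"), class = "rxv_rvec")
  mono <- mol_from_smiles("CCBr")
  expect_false(is_applicable(double, mono))
  expect_true(is_applicable(double, mono, mol_from_smiles("CCCBr")))
  bis <- mol_from_smiles("BrCCCCBr")
  bd <- molecule_descriptor(bis)
  expect_true(ms_contains(bd, structure(2, names = "2:Br.1.0,1,C.2.0")))
  expect_true(is_applicable(double, bis))
})

test_that("adding a reagent never removes applicability", {
  rvs <- reaction_vectors(fx_reactions()[1:60])
  sms <- c("CCBr", "OC(=O)CC", "NCCCC", "OB(O)c1ccccc1", "O=N(=O)c1ccccc1")
  reag <- mol_from_smiles("Oc1ccc(C)cc1")
  n_applicable <- 0L
  for (rv in rvs) for (s in sms) {
    sm <- mol_from_smiles(s)
    if (is_applicable(rv, sm)) {
      n_applicable <- n_applicable + 1L
      expect_true(is_applicable(rv, sm, reag))
    }
  }
  expect_gt(n_applicable, 0)
})

test_that("vector application regenerates known products", {
  rv <- compute_reaction_vector(parse_reaction("CCBr.N>>CCN.Br"))
  ps <- apply_reaction_vector(rv, mol_from_smiles("CCBr"), mol_from_smiles("N"))
  expect_true(mol_id("CCN") %in% vapply(ps, mol_id, character(1)))
  # empty vector is the identity
  idv <- compute_reaction_vector(parse_reaction("CC>>CC"))
  out <- apply_reaction_vector(idv, mol_from_smiles("CCO"))
  expect_length(out, 1)
  expect_identical(mol_id(out[[1]]), mol_id("CCO"))
  # applying an inapplicable vector violates the precondition
  expect_error(apply_reaction_vector(rv, mol_from_smiles("CCO")),
               "not applicable")
})

test_that("every returned product satisfies the descriptor identity", {
  for (r in fx_reactions()[seq(1, 120, by = 6)]) {
    rv <- compute_reaction_vector(r)
    sm <- r$reactants[[1]]
    reagent <- if (length(r$reactants) > 1) r$reactants[[2]] else NULL
    G <- if (is.null(reagent)) sm else mol_combine(sm, reagent)
    d0 <- molecule_descriptor(G)
    target <- ms_subtract(rv$positive, rv$negative)
    for (p in apply_reaction_vector(rv, sm, reagent)) {
      # product plus reconstructed by-products vs the combined input
      whole <- Reduce(ms_add, lapply(attr(p, "byproducts"), function(s)
        molecule_descriptor(mol_from_smiles(s))), molecule_descriptor(p))
      expect_ms_equal(ms_subtract(whole, d0), target)
    }
  }
})

test_that("vectors serialize to JSON and back", {
  rvs <- reaction_vectors(fx_reactions()[1:10])
  tf <- tempfile(fileext = ".json")
  rv_to_json(rvs, tf)
  back <- rv_from_json(tf)
  expect_length(back, length(rvs))
  for (i in seq_along(rvs)) {
    expect_identical(back[[i]]$id, rvs[[i]]$id)
    expect_ms_equal(back[[i]]$negative, rvs[[i]]$negative)
    expect_ms_equal(back[[i]]$positive, rvs[[i]]$positive)
    expect_identical(label_text(back[[i]]$label), label_text(rvs[[i]]$label))
  }
})
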