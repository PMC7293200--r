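test_that("atom typing follows the element/degree/pi convention", {
  expect_equal(atom_type(mol_from_smiles("C"), 1)[1:3],
               list(element = "C", heavy_degree = 0L, pi_count = 0L))
  expect_equal(atom_type(mol_from_smiles("CC(C)=O"), 2)[1:3],
               list(element = "C", heavy_degree = 3L, pi_count = 1L))
  expect_equal(atom_type(mol_from_smiles("c1ccccc1"), 1)[1:3],
               list(element = "C", heavy_degree = 2L, pi_count = 1L))
  expect_equal(atom_type(mol_from_smiles("C#N"), 1)$pi_count, 2L)
  expect_error(atom_type(mol_from_smiles("CC"), 5), "1..2")
})

test_that("path multisets match hand counts on small molecules", {
  ap2 <- path_descriptor_multiset(mol_from_smiles("CC"), 2)
  expect_equal(unname(ap2), 1)
  expect_equal(names(ap2), "2:C.1.0,1,C.1.0")
  benz <- path_descriptor_multiset(mol_from_smiles("c1ccccc1"), 2)
  expect_length(benz, 1)
  expect_equal(unname(benz), 6)
  ap3 <- path_descriptor_multiset(mol_from_smiles("CCO"), 3)
  expect_length(ap3, 1)
  expect_equal(unname(ap3), 1)
  expect_match(names(ap3), "^3:")
  expect_error(path_descriptor_multiset(mol_from_smiles("CC"), 4), "2 or 3")
})

test_that("whole-molecule descriptors match the brute-force path oracle", {
  smis <- c("CCO", "CC(C)=O", "c1ccccc1", "O=N(=O)c1ccc(C)cc1",
            "OB(O)c1ccccc1", "CC(C)(C)OC(=O)NCC", "BrCCc1ccccc1", "C#N",
            "NCCCCOc1ccc(C)cc1")
  for (s in smis) {
    m <- mol_from_smiles(s)
    expect_ms_equal(molecule_descriptor(m), oracle_descriptor(m))
  }
})

test_that("AP2 counts equal bonds and AP3 counts equal angles", {
  smis <- c("CCO", "c1ccc2ccccc2c1", "CC(C)(C)OC(=O)OC(C)(C)C", "O=C(O)CC")
  for (s in smis) {
    m <- mol_from_smiles(s)
    d <- molecule_descriptor(m)
    deg <- tabulate(c(m$bonds$a1, m$bonds$a2), nbins = nrow(m$atoms))
    expect_equal(sum(d[startsWith(names(d), "2:")]), nrow(m$bonds))
    expect_equal(sum(d[startsWith(names(d), "3:")]), sum(choose(deg, 2)))
  }
})

test_that("descriptors are additive over components and order-invariant", {
  expect_length(molecule_descriptor(structure(
    list(atoms = mol_from_smiles("C")$atoms[0, ],
         bonds = mol_from_smiles("C")$bonds[0, ]), class = "rxv_mol")), 0)
  expect_equal(names(molecule_descriptor(mol_from_smiles("CN"))),
               "2:C.1.0,1,N.1.0")
  both <- molecule_descriptor(mol_from_smiles("CBr.N"))
  apart <- ms_add(molecule_descriptor(mol_from_smiles("CBr")),
                  molecule_descriptor(mol_from_smiles("N")))
  expect_ms_equal(both, apart)
  # atom reordering through alternative SMILES spellings
  pairs <- list(c("OC(=O)c1ccccc1", "c1ccccc1C(O)=O"),
                c("NCCCCBr", "BrCCCCN"),
                c("CC(C)(C)OC(=O)NCC", "CCNC(=O)OC(C)(C)C"))
  for (p in pairs)
    expect_ms_equal(molecule_descriptor(mol_from_smiles(p[1])),
                    molecule_descriptor(mol_from_smiles(p[2])))
})

test_that("path feature keys are canonically oriented (idempotent)", {
  d <- molecule_descriptor(mol_from_smiles("O=C(c1ccccc1)NCCCCOc1ccc(C)cc1"))
  for (k in names(d)) {
    body <- sub("^[23]:", "", k)
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    rev_key <- paste0(substr(k, 1, 2), paste(rev(parts), collapse = ","))
    expect_true(k <= rev_key)
  }
})

test_that("descriptor multisets survive a JSON round trip", {
  d <- molecule_descriptor(mol_from_smiles("CC(=O)Nc1ccccc1"))
  tf <- tempfile(fileext = ".json")
  descriptor_to_json(d, tf)
  expect_ms_equal(descriptor_from_json(tf), d)
})
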