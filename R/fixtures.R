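## Synthetic classified-reaction generator.
##
## Templates are transformation rules applied by the package's own graph
## editor, so generated reactions are born atom-mapped and carbon-balanced:
## reactants are assembled from substituent slot fragments, the template's
## bond edits are applied, and the resulting fragments become the products
## (main product first, by-products after it).  Reaction classes are
## determined by functional groups, the class-frequency skew is strongly
## non-uniform (C-N bond formation, functional conversions and deprotections
## dominate), and competing-functionality cases are built in: molecules
## carrying both an N-H and an O-H occur only in protection/deprotection
## classes, never in coupling or condensation classes.

# Substituent slot pools.  Fragments attach through their first atom.
.slots <- list(
  acids = c("C", "CC", "CCC", "CC(C)C", "CCCC", "CCCCC", "CCCCCC",
            "C(C)CC", "CC(C)CC", "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1",
            "Cc1ccc(C)cc1", "c1ccc(C)cc1", "COC", "CCOC", "COCC"),
  amines_plain = c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)C",
                   "C(C)CC", "CC(C)CC", "CCc1ccccc1", "c1ccccc1",
                   "Cc1ccccc1", "Cc1ccc(C)cc1", "CCCc1ccccc1",
                   "c1ccc(C)cc1", "c1ccc(OC)cc1"),
  alcohols = c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)C",
               "C(C)CC", "Cc1ccccc1", "CCc1ccccc1", "c1ccccc1",
               "c1ccc(C)cc1", "c1ccc(CC)cc1", "c1ccc(OC)cc1"),
  bromides = c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)C",
               "C(C)CC", "CC(C)CC", "Cc1ccccc1", "CCc1ccccc1",
               "CCCc1ccccc1", "Cc1ccc(C)cc1", "Cc1ccc(OC)cc1"),
  nitro_subs = c("c1ccccc1", "c1ccc(C)cc1", "c1ccc(CC)cc1", "c1ccc(CCC)cc1",
                 "c1ccc(OC)cc1", "c1ccc(OCC)cc1", "c1ccc2ccccc2c1",
                 "CC", "CCC", "CCCC", "CC(C)C", "Cc1ccccc1"),
  aryls = c("c1ccccc1", "c1ccc(C)cc1", "c1ccc(CC)cc1", "c1ccc(CCC)cc1",
            "c1ccc(OC)cc1", "c1ccc(OCC)cc1", "c1ccc(C(C)C)cc1",
            "c1ccc2ccccc2c1"),
  # amino alcohols: large enough that the amine (not the reagent) is the
  # mapped-atom-rich starting material; these are the NH+OH cases
  boc_amines = c("CCCCCCCO", "CCCCCCCCO", "CCCCC(C)CCO", "CCCCCCC(C)O",
                 "CCCC(C)CCCO", "CCCCCCCCCO", "CC(C)CCCCCO",
                 "CC", "CCC", "CCCC", "Cc1ccccc1", "CCc1ccccc1"),
  deprot_chains = c("CCCC", "CCCCC", "CCCCCC", "CC(C)CCC", "CCc1ccccc1",
                    "Cc1ccccc1", "CCCc1ccccc1", "CCCCO", "CCCCCO",
                    "CCCCCCO", "CC(C)CCCO")
)

#' Bundled reaction templates
#'
#' Eight functional-group-determined transformation templates: amide
#' coupling, N-alkylation, ester formation, nitro-to-amino reduction,
#' Suzuki-type biaryl coupling, Boc protection, Boc deprotection and
#' Williamson ether formation.  Each template lists its class label (3 or 4
#' hierarchy levels), reactant builders (constant prefix + substituent
#' slot), and the bond edits of the transformation.
#'
#' @return named list of template definitions
#' @export
reaction_templates <- function() {
  list(
    amide_coupling = list(
      label = "C-N Bond Formation (Acylation) (Amide coupling)",
      r1 = "OC(=O)", slots1 = .slots$acids,
      r2 = "N", slots2 = .slots$amines_plain,
      breaks = list(c(1L, 1L, 2L)),           # acid C-OH
      forms = list(c(1L, 2L, 2L, 1L, 1))),    # acid C - amine N
    n_alkylation = list(
      label = "C-N Bond Formation (Alkylation) (N-alkylation) (Bromo)",
      r1 = "Br", slots1 = .slots$bromides,
      r2 = "N", slots2 = .slots$amines_plain,
      breaks = list(c(1L, 1L, 2L)),           # C-Br
      forms = list(c(1L, 2L, 2L, 1L, 1))),    # C - N
    ester_formation = list(
      label = "Functional Conversion (Esterification) (Acid + alcohol)",
      r1 = "OC(=O)", slots1 = .slots$acids,
      r2 = "O", slots2 = .slots$alcohols,
      breaks = list(c(1L, 1L, 2L)),
      forms = list(c(1L, 2L, 2L, 1L, 1))),
    nitro_reduction = list(
      label = "Functional Conversion (Reduction) (Nitro to amino)",
      r1 = "O=N(=O)", slots1 = .slots$nitro_subs,
      r2 = NULL, slots2 = NULL,
      breaks = list(c(1L, 1L, 2L), c(1L, 2L, 3L)),   # both N=O
      forms = list()),
    suzuki_coupling = list(
      label = "C-C Bond Formation (Coupling) (Suzuki) (Bromo)",
      r1 = "OB(O)", slots1 = .slots$aryls,
      r2 = "Br", slots2 = .slots$aryls,
      breaks = list(c(1L, 2L, 4L), c(2L, 1L, 2L)),   # C-B and C-Br
      forms = list(c(1L, 4L, 2L, 2L, 1))),           # aryl-aryl bond
    boc_protection = list(
      label = "Protection (Boc) (Amine)",
      r1 = "O=C(Cl)OC(C)(C)C", slots1 = "",
      r2 = "N", slots2 = .slots$boc_amines,
      breaks = list(c(1L, 2L, 3L)),           # C(=O)-Cl
      forms = list(c(1L, 2L, 2L, 1L, 1))),    # C(=O) - N
    boc_deprotection = list(
      label = "Deprotection (Boc) (Amine)",
      r1 = "O=C(OC(C)(C)C)N", slots1 = .slots$deprot_chains,
      r2 = NULL, slots2 = NULL,
      breaks = list(c(1L, 2L, 8L), c(1L, 3L, 4L)),   # C(=O)-N and O-tBu
      forms = list()),
    williamson_ether = list(
      label = "C-O Bond Formation (Alkylation) (Williamson) (Bromo)",
      r1 = "Br", slots1 = .slots$bromides,
      r2 = "O", slots2 = .slots$alcohols,
      breaks = list(c(1L, 1L, 2L)),
      forms = list(c(1L, 2L, 2L, 1L, 1)))
  )
}

# Default class skew: C-N bond formation dominates, followed by functional
# conversions and deprotections, mirroring the strongly unbalanced class
# composition of patent-derived reaction sets.
.default_class_weights <- c(
  amide_coupling = 0.20, n_alkylation = 0.15, nitro_reduction = 0.12,
  ester_formation = 0.08, boc_deprotection = 0.13, boc_protection = 0.07,
  suzuki_coupling = 0.12, williamson_ether = 0.13)

#' Specification for the fixtures generator
#'
#' @param n_reactions number of classified reactions to generate
#' @param class_weights named positive weights over template names; the
#'   default skew mirrors patent-data class composition
#' @param seed RNG seed
#' @return a list of class `rxv_fixture_spec`
#' @export
fixture_spec <- function(n_reactions = 2000, class_weights = NULL, seed = 1) {
  w <- class_weights %||% .default_class_weights
  stopifnot(n_reactions >= 1, all(w > 0), !is.null(names(w)))
  unknown <- setdiff(names(w), names(reaction_templates()))
  if (length(unknown))
    stop("class_weights name unregistered templates: ",
         paste(unknown, collapse = ", "))
  structure(list(n_reactions = as.integer(n_reactions),
                 class_weights = w / sum(w), seed = as.integer(seed)),
            class = "rxv_fixture_spec")
}

# Assign atom-map numbers start..start+n-1 in atom order.
assign_maps <- function(mol, start) {
  mol$atoms$map <- seq(start, length.out = nrow(mol$atoms))
  mol
}

# Build one mapped, balanced reaction from a template and slot fragments.
instantiate_template <- function(tmpl, f1, f2 = NULL) {
  r1 <- assign_maps(mol_from_smiles(paste0(tmpl$r1, f1)), 1L)
  r2 <- NULL
  offsets <- c(0L, nrow(r1$atoms))
  if (!is.null(tmpl$r2))
    r2 <- assign_maps(mol_from_smiles(paste0(tmpl$r2, f2)), nrow(r1$atoms) + 1L)
  G <- if (is.null(r2)) r1 else mol_combine(r1, r2)
  # resolve template atom references (molecule index, atom index) -> combined
  res <- function(mi, ai) offsets[mi] + ai
  break_rows <- vapply(tmpl$breaks, function(b) {
    i <- res(b[1], b[2]); j <- res(b[1], b[3])
    w <- which((G$bonds$a1 == i & G$bonds$a2 == j) |
               (G$bonds$a1 == j & G$bonds$a2 == i))
    if (length(w) != 1L) stop("template break does not match a bond")
    w
  }, integer(1))
  forms <- lapply(tmpl$forms, function(f)
    c(res(f[1], f[2]), res(f[3], f[4]), f[5]))
  edited <- apply_edits(G, break_rows, forms)
  if (is.null(edited)) stop("template edit produced an invalid valence")
  comp <- component_ids(edited)
  frags <- lapply(seq_len(max(comp)), function(k)
    mol_subset(edited, which(comp == k)))
  sizes <- vapply(frags, n_heavy_atoms, integer(1))
  hetero <- vapply(frags, function(m) sum(m$atoms$element != "C"), integer(1))
  ids <- vapply(frags, mol_id, character(1))
  frags <- frags[order(-sizes, -hetero, ids)]
  new_reaction(Filter(Negate(is.null), list(r1, r2)), frags, tmpl$label)
}

#' Generate a set of classified reactions
#'
#' Samples templates according to the spec's class weights and substituent
#' fragments uniformly per slot, under the spec's seed.  Every generated
#' reaction is atom-mapped, carbon-balanced, and regenerable by applying its
#' own reaction vector to its starting material.
#'
#' @param spec an [fixture_spec()]
#' @return list of classified `rxv_rxn`
#' @export
generate_classified_reactions <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "rxv_fixture_spec"))
  templates <- reaction_templates()
  w <- spec$class_weights
  with_seed(spec$seed, {
    picks <- sample(names(w), spec$n_reactions, replace = TRUE, prob = w)
    lapply(picks, function(nm) {
      tmpl <- templates[[nm]]
      f1 <- sample(tmpl$slots1, 1L)
      f2 <- if (is.null(tmpl$r2)) NULL else sample(tmpl$slots2, 1L)
      instantiate_template(tmpl, f1, f2)
    })
  })
}

#' Generate the retrosynthetic rediscovery case
#'
#' Builds a three-fragment target (an aryl amide with an aryl-ether tail),
#' a reagent pool containing the building blocks needed to reassemble it
#' plus at least 50 decoys, and a reaction-vector set that covers the two
#' joins (amide coupling and Williamson etherification), derived from a
#' generated reaction set extended with join-precedent reactions.  A
#' retrosynthetic run on this case rediscovers the target.
#'
#' @param seed RNG seed
#' @return list with `target` (SMILES), `pool` (list of `rxv_mol`), `rvs`
#'   (list of `rxv_rvec`) and `reactions` (the classified reactions the
#'   vectors and any recommender should be derived from)
#' @export
generate_renate_case <- function(seed = 1) {
  target <- "O=C(c1ccccc1)NCCCCOc1ccc(C)cc1"
  tmpl <- reaction_templates()
  joins <- list(
    instantiate_template(tmpl$amide_coupling, "c1ccccc1", "CCCCBr"),
    instantiate_template(tmpl$amide_coupling, "C", "CCCCBr"),
    instantiate_template(tmpl$williamson_ether, "CCCCNC(=O)c1ccccc1",
                         "c1ccc(C)cc1"),
    instantiate_template(tmpl$williamson_ether, "CCCCN", "c1ccc(C)cc1")
  )
  background <- generate_classified_reactions(
    fixture_spec(n_reactions = 200, seed = seed))
  reactions <- c(background, joins)
  rvs <- reaction_vectors(reactions)
  needed <- c("OC(=O)c1ccccc1", "NCCCCBr", "Oc1ccc(C)cc1")
  decoys <- unique(c(
    paste0("N", .slots$amines_plain), paste0("OC(=O)", .slots$acids),
    paste0("O", .slots$alcohols), paste0("Br", .slots$bromides),
    paste0("O=N(=O)", .slots$nitro_subs), paste0("OB(O)", .slots$aryls),
    paste0("N", .slots$boc_amines)))
  pool_smiles <- unique(c(needed, decoys))
  pool <- lapply(pool_smiles, mol_from_smiles)
  ids <- vapply(pool, mol_id, character(1))
  pool <- pool[!duplicated(ids)]
  list(target = target, pool = pool, rvs = rvs, reactions = reactions)
}
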