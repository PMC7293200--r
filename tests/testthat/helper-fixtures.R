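# Shared fixtures, built once per test run and cached.

.fx_env <- new.env()

fx_reactions <- function() {
  if (is.null(.fx_env$rxns))
    .fx_env$rxns <- generate_classified_reactions(
      fixture_spec(n_reactions = 2000, seed = 7))
  .fx_env$rxns
}

fx_dataset <- function() {
  if (is.null(.fx_env$ds))
    .fx_env$ds <- pivot_merge(build_labeled_entries(fx_reactions(), level = 3),
                              "keys166")
  .fx_env$ds
}

fx_split <- function() {
  if (is.null(.fx_env$sp))
    .fx_env$sp <- stratified_split(fx_dataset(), 0.8, seed = 11)
  .fx_env$sp
}

fx_model <- function() {
  if (is.null(.fx_env$model))
    .fx_env$model <- reaction_recommender(fx_split()$train, strategy = "cc",
                                          base = "linear", seed = 11)
  .fx_env$model
}

fx_renate <- function() {
  if (is.null(.fx_env$renate))
    .fx_env$renate <- generate_renate_case(seed = 3)
  .fx_env$renate
}

# Molecules that carry both an N-H and an O-H in the fixture chemistry
# (amino alcohols fed to the protection template).
fx_nh_oh_smiles <- function() {
  paste0("N", c("CCCCCCCO", "CCCCCCCCO", "CCCCC(C)CCO", "CCCCCCC(C)O",
                "CCCC(C)CCCO"))
}

# Level-1 prefixes of coupling/condensation classes in the fixture taxonomy.
fx_coupling_prefixes <- function() {
  c("C-C Bond Formation", "C-N Bond Formation", "C-O Bond Formation",
    "Functional Conversion (Esterification)")
}
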