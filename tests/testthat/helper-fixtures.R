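# Shared small fixtures, generated in code.

# strip class and similarity attributes, keep dims only
bare <- function(m) {
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  m
}

# tiny three-node chain ontology: d -> p -> g
chain_ontology <- function() {
  data.frame(child = c("d", "p"), parent = c("p", "g"))
}

# diamond: d has two parents p1, p2 sharing grandparent g
diamond_ontology <- function() {
  data.frame(child = c("d", "d", "p1", "p2"),
             parent = c("p1", "p2", "g", "g"))
}

# small planted dataset + ontology for model-level tests
small_dataset <- function(seed = 1, nl = 15, nd = 12) {
  spec <- synthetic_spec(nl = nl, nd = nd, n_blocks = 2,
                         density_in = 0.5, density_out = 0.05, seed = seed)
  syn <- generate_association_matrix(spec)
  list(spec = spec, assoc = syn$assoc, ontology = generate_dag_forest(spec),
       lncrna_blocks = syn$lncrna_blocks, disease_blocks = syn$disease_blocks)
}

# light training configuration for fast unit tests
small_config <- function(...) {
  default_config(n_heads = 2, neurons = 4, epochs = 40, rank = 4, seed = 1, ...)
}
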