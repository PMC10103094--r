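# small in-code fixtures shared across the suite

# a desk-scale confounded population: 60-code ontology, 800 persons,
# 4 drugs, generated fresh from a seed
tiny_study <- function(seed = 1, n = 800, codes = 60, n_drugs = 4, ...) {
  g <- generate_ontology(codes, branching = 3, seed = seed)
  cfg <- sim_config(n_persons = n, n_codes = codes, n_drugs = n_drugs,
                    seed = seed, ...)
  list(graph = g, config = cfg, data = generate_population(g, cfg))
}

# a hand-built path graph a-b-c-d-e in concept_graph form
path_graph <- function(k = 5) {
  nodes <- letters[seq_len(k)]
  ed <- data.frame(from = nodes[-k], to = nodes[-1],
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  structure(list(nodes = igraph::V(g)$name, edges = ed,
                 n_tree_edges = nrow(ed), roots = nodes[2],
                 graph = g),
            class = "concept_graph")
}

# 12-person toy input tables exercising every eligibility / outcome /
# cohort decision branch; expectations in the tests are hand-derived
toy_tables <- function() {
  persons <- data.frame(
    person_id = 1:12,
    age = c(13, 14, 40, 40, 40, 40, 40, 40, 40, 40, 40, 70),
    gender = rep(c("F", "M"), 6),
    race = "white",
    ethnicity = "not_hispanic",
    zip3 = c("021", "021", "021", "021", NA, "", "021", "021", "021",
             "021", "021", "021"),
    history_days = c(400, 400, 364, 365, 400, 400, 400, 400, 400, 400,
                     400, 400),
    stringsAsFactors = FALSE
  )
  exposures <- data.frame(
    person_id = c(2, 4, 7, 8, 8, 9, 12),
    drug = c("drugA", "drugA", "drugA", "drugA", "drugB", "drugB",
             "drugC"),
    stringsAsFactors = FALSE
  )
  severities <- data.frame(
    person_id = 1:12,
    level = c(1L, 2L, 3L, 3L, 4L, 5L, NA, 1L, 2L, NA, 3L, 1L)
  )
  code_events <- data.frame(
    person_id = c(2, 4, 7, 8, 9, 10, 11, 12),
    code = c("X", "X", "Y", "X", "Y", "X", "Y", "X"),
    days_before_index = 10L,
    stringsAsFactors = FALSE
  )
  list(persons = persons, exposures = exposures,
       severities = severities, code_events = code_events)
}

# small random embedding table with named rows
random_embedding <- function(codes, dim = 4, seed = 1) {
  set.seed(seed)
  emb <- matrix(rnorm(length(codes) * dim), length(codes), dim)
  rownames(emb) <- codes
  class(emb) <- c("embedding_table", class(emb))
  emb
}
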