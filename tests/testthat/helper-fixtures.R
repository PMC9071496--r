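# Small fixture builders shared across test files.

toy_proteome <- function(n = 5, length = 200, is_rbp = rep(FALSE, n),
                         sequence = NA_character_, family_tags = NA_character_) {
  data.frame(accession = sprintf("P%d", seq_len(n)),
             gene_name = sprintf("G%d", seq_len(n)),
             length = rep_len(length, n),
             sequence = rep_len(sequence, n),
             is_rbp = rep_len(is_rbp, n),
             family_tags = rep_len(family_tags, n),
             stringsAsFactors = FALSE)
}

toy_sites <- function(accession, position, ptm_type,
                      residue = NA_character_, source = "src",
                      pmid = NA_character_) {
  n <- max(length(accession), length(position), length(ptm_type))
  data.frame(accession = rep_len(accession, n),
             position = as.integer(rep_len(position, n)),
             residue = rep_len(residue, n),
             ptm_type = rep_len(ptm_type, n),
             source = rep_len(source, n),
             pmid = rep_len(pmid, n),
             cell_line = NA_character_, sample_type = NA_character_,
             body_site = NA_character_, disease_state = NA_character_,
             stringsAsFactors = FALSE)
}

toy_edges <- function(a, b, source = "db1") {
  data.frame(accession_a = a, accession_b = b,
             source = rep_len(source, length(a)), stringsAsFactors = FALSE)
}

toy_enzymes <- function(accession, ptm_type, role = "writer") {
  data.frame(accession = accession,
             ptm_type = rep_len(ptm_type, length(accession)),
             role = rep_len(role, length(accession)),
             stringsAsFactors = FALSE)
}

toy_mutations <- function(accession, position, cancer_type = "BRCA",
                          case_count = 1L) {
  n <- max(length(accession), length(position))
  data.frame(accession = rep_len(accession, n),
             position = as.integer(rep_len(position, n)),
             ref_aa = "K", alt_aa = "E", consequence = "missense_variant",
             cancer_type = rep_len(cancer_type, n),
             case_count = as.integer(rep_len(case_count, n)),
             mutation_id = seq_len(n),
             stringsAsFactors = FALSE)
}

# A small random PPI network with sites and enzyme annotations.
random_network <- function(seed, n_prot = 60, n_enz = 8,
                           types = c("phosphorylation", "acetylation")) {
  set.seed(seed)
  prot <- toy_proteome(n_prot, length = 300)
  sites <- toy_sites(sample(prot$accession, 3 * n_prot, TRUE),
                     sample(1:300, 3 * n_prot, TRUE),
                     sample(types, 3 * n_prot, TRUE))
  enz <- toy_enzymes(sprintf("E%d", seq_len(n_enz)),
                     sample(types, n_enz, TRUE),
                     sample(c("writer", "eraser"), n_enz, TRUE))
  all_nodes <- c(prot$accession, enz$accession)
  m <- 4 * n_prot
  edges <- toy_edges(sample(all_nodes, m, TRUE), sample(all_nodes, m, TRUE),
                     sample(c("db1", "db2"), m, TRUE))
  edges <- edges[edges$accession_a != edges$accession_b, ]
  list(prot = prot, sites = sites, enz = enz, edges = edges)
}

# Write a generic-dialect catalog file and return its path.
write_catalog_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}
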