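# The synthetic-data generator: determinism, marginal statistics, planted
# effects, and bundle integrity.

test_that("generation is deterministic per (spec, seed)", {
  spec <- simulation_spec(n_proteins = 200L, seed = 301L)
  expect_identical(generate_proteome(spec), generate_proteome(spec))
  prot <- generate_proteome(spec)
  expect_identical(generate_ptm_catalog(prot, spec),
                   generate_ptm_catalog(prot, spec))
  expect_identical(generate_conservation(prot,
                                         generate_ptm_catalog(prot, spec),
                                         spec),
                   generate_conservation(prot,
                                         generate_ptm_catalog(prot, spec),
                                         spec))
  other <- simulation_spec(n_proteins = 200L, seed = 302L)
  expect_false(identical(generate_proteome(spec), generate_proteome(other)))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(simulation_spec(rbp_fraction = 1.2), "rbp_fraction")
  expect_error(simulation_spec(p_planted = 0.1, p_background = 0.5),
               "p_planted")
  expect_error(simulation_spec(interface_decay = 0), "interface_decay")
  expect_error(simulation_spec(banana = 1), "unknown")
})

test_that("proteome marginals match the spec", {
  expect_false(any(generate_proteome(
    simulation_spec(n_proteins = 300L, rbp_fraction = 0, seed = 1L))$is_rbp))
  spec <- simulation_spec(n_proteins = 10000L, rbp_fraction = 0.12,
                          seed = 311L)
  prot <- generate_proteome(spec)
  n_rbp <- sum(prot$is_rbp)
  # binomial 99% interval around 1200
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.12)
  expect_gte(n_rbp, bounds[1])
  expect_lte(n_rbp, bounds[2])
  expect_true(all(prot$length >= spec$min_length))
  expect_true(all(prot$family_tags[!is.na(prot$family_tags)] == "hnRNP"))
})

test_that("catalog rates respect zero rates and compatibility", {
  spec <- simulation_spec(n_proteins = 150L,
                          ptm_base_rates = c(phosphorylation = 0.004,
                                             acetylation = 0),
                          seed = 321L)
  prot <- generate_proteome(spec)
  sites <- generate_ptm_catalog(prot, spec)
  expect_false(any(sites$ptm_type == "acetylation"))
  expect_true(all(sites$residue[sites$ptm_type == "phosphorylation"] %in%
                    c("S", "T", "Y")))
  expect_true(all(sites$position >= 1 &
                    sites$position <= prot$length[match(sites$accession,
                                                        prot$accession)]))
  # positions unique within (protein, type)
  expect_equal(anyDuplicated(sites[c("accession", "position", "ptm_type")]), 0L)
})

test_that("null catalogs show no RBP density enrichment (replicated)", {
  spec <- simulation_spec(n_proteins = 300L, rbp_fraction = 0.5, seed = 331L)
  prot <- generate_proteome(spec)
  pvals <- sapply(1:40, function(r) {
    sites <- generate_ptm_catalog(prot, spec, enrichment_factor = 1,
                                  seed_key = paste0("null", r))
    density_group_comparison(modification_density(sites, prot))$p_value
  })
  expect_lte(mean(pvals < 0.05), 0.2)  # nominal under the null
})

test_that("degenerate edge probabilities force pure M or pure ME labelings", {
  base <- list(n_proteins = 150L, n_background_edges = 0L, seed = 341L,
               ptm_base_rates = c(phosphorylation = 0.003,
                                  acetylation = 0.0012))
  spec0 <- do.call(simulation_spec,
                   c(base, list(p_planted = 0, p_background = 0)))
  prot <- generate_proteome(spec0)
  sites <- generate_ptm_catalog(prot, spec0)
  net0 <- generate_interactions(prot, sites, spec0)
  expect_equal(nrow(net0$edges), 0L)
  rbpome <- prot$accession[prot$is_rbp]
  m0 <- suppressMessages(me_matrix(rbpome, sites, net0$edges, net0$enzymes))
  expect_true(all(m0 %in% c("M", "none")))
  spec1 <- do.call(simulation_spec,
                   c(base, list(p_planted = 1, p_background = 0)))
  net1 <- generate_interactions(prot, sites, spec1)
  m1 <- suppressMessages(me_matrix(rbpome, sites, net1$edges, net1$enzymes))
  expect_false(any(m1 == "E"))
  expect_false(any(m1 == "M"))  # every modified RBP is ME
  # closed-form ME share under planted edges only:
  # P(>=1 of k enzymes) = 1 - (1 - p1)^k
  spec2 <- do.call(simulation_spec,
                   c(base, list(p_planted = 0.3, p_background = 0)))
  net2 <- generate_interactions(prot, sites, spec2)
  m2 <- suppressMessages(me_matrix(rbpome, sites, net2$edges, net2$enzymes))
  n_mod <- sum(m2[, "phosphorylation"] %in% c("ME", "M"))
  n_me <- sum(m2[, "phosphorylation"] == "ME")
  p_me <- 1 - (1 - 0.3)^spec2$n_enzymes_per_type
  bounds <- qbinom(c(0.005, 0.995), n_mod, p_me)
  expect_gte(n_me, bounds[1])
  expect_lte(n_me, bounds[2])
})

test_that("mutation hotspots concentrate mutations near PTM sites", {
  spec <- simulation_spec(n_proteins = 150L, hotspot_rate = 0.02,
                          background_mutation_rate = 0.002, seed = 351L)
  prot <- generate_proteome(spec)
  sites <- generate_ptm_catalog(prot, spec)
  muts <- generate_mutations(prot, sites, spec)
  near <- mutations_near_sites(muts, sites, k = spec$proximity_k)
  n_near <- attr(near, "n_unique_mutations")
  n_far <- nrow(muts) - n_near
  # residue opportunity split, computed independently
  pos_split <- split(sites$position, sites$accession)
  hot_res <- 0; tot_res <- 0
  for (i in seq_len(nrow(prot))) {
    L <- prot$length[i]
    sp <- pos_split[[prot$accession[i]]]
    hot <- logical(L)
    for (p in unique(sp))
      hot[max(1, p - spec$proximity_k):min(L, p + spec$proximity_k)] <- TRUE
    hot_res <- hot_res + sum(hot); tot_res <- tot_res + L
  }
  rate_near <- n_near / hot_res
  rate_far <- n_far / (tot_res - hot_res)
  ratio <- rate_near / rate_far
  expect_gt(ratio, 10 * 0.75)  # planted 10x recovered within 25%
  expect_lt(ratio, 10 * 1.25)
  # background 0 -> every mutation is a near-site hit
  spec0 <- simulation_spec(n_proteins = 100L, background_mutation_rate = 0,
                           seed = 352L)
  prot0 <- generate_proteome(spec0)
  sites0 <- generate_ptm_catalog(prot0, spec0)
  muts0 <- generate_mutations(prot0, sites0, spec0)
  near0 <- mutations_near_sites(muts0, sites0, k = spec0$proximity_k)
  expect_equal(attr(near0, "n_unique_mutations"), nrow(muts0))
})

test_that("degenerate interface decay places every decayed site at a center", {
  spec <- simulation_spec(n_proteins = 100L, interface_decay = 1,
                          interface_uniform_share = 0,
                          n_interface_sites = 500L, seed = 361L)
  prot <- generate_proteome(spec)
  study <- generate_crosslink_study(prot, spec)
  windows <- standardize_windows(study$crosslinks, prot)
  nd <- nearest_center_distances(study$sites, windows)
  expect_true(all(nd$nearest_distance == 0))
})

test_that("bundles are checksum-stable, loadable, and overwrite-guarded", {
  spec <- simulation_spec(n_proteins = 120L, n_interface_sites = 400L,
                          n_genes = 20L, peaks_per_rbp = 30L, seed = 371L)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_bundle(spec, d1)
  m2 <- make_bundle(spec, d2)
  expect_identical(m1$files, m2$files)
  expect_error(make_bundle(spec, d1), "not empty")
  # every reader consumes its file without error
  prot <- read_proteome(file.path(d1, "proteome.tsv"))
  expect_gt(nrow(prot), 0)
  for (f in c("catalog_a.tsv", "catalog_b.tsv", "catalog_interface.tsv"))
    expect_gt(nrow(load_ptm_catalog(file.path(d1, f), "generic")), 0)
  expect_gt(length(read_rbp_list(file.path(d1, "rbp_list_1.txt"))), 0)
  expect_gt(nrow(read_ppi_edges(file.path(d1, "ppi_edges.tsv"))), 0)
  expect_gt(nrow(read_enzyme_annotations(
    file.path(d1, "enzyme_annotations.tsv"))), 0)
  expect_gt(nrow(read_mutations(file.path(d1, "mutations.tsv"))), 0)
  expect_gt(nrow(read_crosslinks(file.path(d1, "crosslinks.tsv"))), 0)
  expect_gt(nrow(read_conservation(file.path(d1, "conservation.tsv"))), 0)
  expect_gt(nrow(read_gene_models(file.path(d1, "genes.bed"))), 0)
  expect_gt(nrow(read_narrowpeak(file.path(d1, "eclip_rep1.narrowPeak"))), 0)
  # every RBP appears in at least one list
  lists <- lapply(1:3, function(i)
    read_rbp_list(file.path(d1, sprintf("rbp_list_%d.txt", i))))
  expect_setequal(Reduce(union, lists), prot$accession[prot$is_rbp])
})
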