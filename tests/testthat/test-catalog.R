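# Catalog loading, harmonization, RBP-ome construction, atlas export.

test_that("load_ptm_catalog drops predicted rows and keeps experimental ones", {
  rows <- toy_sites("P1", c(10, 20), "phosphorylation")
  rows$evidence <- c("experimental", "predicted")
  path <- write_catalog_file(rows)
  got <- load_ptm_catalog(path, "generic")
  expect_equal(nrow(got), 1L)
  expect_equal(got$position, 10L)
  expect_equal(unname(attr(got, "dropped")["predicted"]), 1L)
})

test_that("load_ptm_catalog on an empty file returns an empty site list", {
  rows <- toy_sites("P1", 1, "phosphorylation")[0, ]
  rows$evidence <- character(0)
  path <- write_catalog_file(rows)
  got <- load_ptm_catalog(path, "generic")
  expect_equal(nrow(got), 0L)
})

test_that("load_ptm_catalog counts every dropped row on a 500-row fixture", {
  set.seed(11)
  n <- 500
  rows <- toy_sites(sample(sprintf("P%d", 1:40), n, replace = TRUE),
                    sample(1:300, n, replace = TRUE),
                    sample(c("phosphorylation", "acetylation"), n, TRUE))
  rows$evidence <- "experimental"
  bad <- sample(n, 37)
  pred <- bad[1:20]
  unmapped <- bad[21:37]
  rows$evidence[pred] <- "predicted"
  rows$ptm_type[unmapped] <- "mystery_mark"
  path <- write_catalog_file(rows)
  # independent line-by-line scan of the fixture
  expected_kept <- sum(rows$evidence != "predicted" &
                         rows$ptm_type != "mystery_mark")
  expect_equal(expected_kept, 463L)
  expect_warning(got <- load_ptm_catalog(path, "generic"), "unmappable")
  expect_equal(nrow(got), 463L)
  expect_equal(sum(attr(got, "dropped")), 37L)
})

test_that("load_ptm_catalog errors name the offending row and dialect", {
  rows <- toy_sites("P1", c(10, -5), "phosphorylation")
  rows$evidence <- "experimental"
  path <- write_catalog_file(rows)
  expect_error(load_ptm_catalog(path, "generic"), "row\\(s\\).*2")
  expect_error(load_ptm_catalog(path, "nope"), "unknown PTM catalog dialect")
})

test_that("alternative dialects map their column names", {
  rows <- data.frame(ACC_ID = "P1", MOD_RSD_POS = 42, MOD_AA = "S",
                     MOD_TYPE = "phospho", PUBMED = "123",
                     EVIDENCE = "experimental", CELL_LINE = "HeLa")
  path <- write_catalog_file(rows)
  got <- load_ptm_catalog(path, "sitelist")
  expect_equal(got$ptm_type, "phosphorylation")  # synonym normalized
  expect_equal(got$position, 42L)
  expect_equal(got$cell_line, "HeLa")
})

test_that("unify_catalogs merges duplicate sites and their provenance", {
  prot <- toy_proteome(2, length = 100)
  a <- toy_sites("P1", 10, "phosphorylation", source = "catA", pmid = "1")
  b <- toy_sites("P1", 10, "phosphorylation", source = "catB", pmid = "2")
  cat <- unify_catalogs(list(a, b), prot)
  expect_equal(nrow(cat$sites), 1L)
  expect_equal(cat$sites$sources, "catA;catB")
  expect_equal(cat$sites$pmids, "1;2")
  expect_equal(nrow(cat$provenance), 2L)
})

test_that("unification is idempotent and order-independent", {
  set.seed(21)
  prot <- toy_proteome(30, length = 400)
  mk <- function(src) toy_sites(sample(prot$accession, 300, TRUE),
                                sample(1:400, 300, TRUE),
                                sample(c("phosphorylation", "acetylation",
                                         "methylation"), 300, TRUE),
                                source = src,
                                pmid = as.character(sample(99, 300, TRUE)))
  cats <- list(mk("a"), mk("b"), mk("c"))
  u1 <- unify_catalogs(cats, prot)
  u2 <- unify_catalogs(cats[c(3, 1, 2)], prot)
  expect_identical(u1$sites, u2$sites)
  expect_identical(u1$provenance, u2$provenance)
  again <- unify_catalogs(list(u1$provenance), prot)
  expect_identical(again$sites, u1$sites)
})

test_that("unified site count equals the brute-force distinct-key count", {
  set.seed(31)
  prot <- toy_proteome(50, length = 500)
  n <- 2000
  rows <- toy_sites(sample(prot$accession, n, TRUE),
                    sample(1:500, n, TRUE),
                    sample(c("phosphorylation", "acetylation"), n, TRUE))
  dup <- rows[sample(n, 200), ]  # planted 10% duplication
  dup$source <- "src2"
  cat <- unify_catalogs(list(rows, dup), prot)
  key <- unique(paste(c(rows$accession, dup$accession),
                      c(rows$position, dup$position),
                      c(rows$ptm_type, dup$ptm_type)))
  expect_equal(nrow(cat$sites), length(key))
  expect_true(all(cat$sites$position >= 1))
  expect_true(all(cat$sites$position <=
                    prot$length[match(cat$sites$accession, prot$accession)]))
})

test_that("sites off the proteome or beyond protein length are dropped", {
  prot <- toy_proteome(1, length = 50)
  rows <- toy_sites(c("P1", "P1", "PX"), c(10, 99, 5), "acetylation")
  expect_message(cat <- unify_catalogs(rows, prot), "dropped 1 site")
  expect_equal(nrow(cat$sites), 1L)
  expect_equal(cat$sites$position, 10L)
})

test_that("residue conflicts with the sequence are dropped (or kept on request)", {
  prot <- toy_proteome(1, length = 6, sequence = "MKSTYA")
  rows <- toy_sites("P1", c(2, 3), "phosphorylation", residue = c("K", "K"))
  expect_message(dropped <- unify_catalogs(rows, prot), "1 residue conflicts")
  expect_equal(dropped$sites$position, 2L)  # position 3 is S, stated K
  kept <- suppressMessages(
    unify_catalogs(rows, prot, residue_conflict = "keep"))
  expect_equal(nrow(kept$sites), 2L)
})

test_that("build_rbpome takes set unions and flags unknown accessions", {
  expect_setequal(build_rbpome(list(c("A", "B"), c("B", "C"))), c("A", "B", "C"))
  expect_setequal(build_rbpome(list(c("A", "B"))), c("A", "B"))
  set.seed(41)
  lists <- replicate(3, sample(sprintf("P%d", 1:100), 60), simplify = FALSE)
  expect_setequal(build_rbpome(lists), Reduce(union, lists))
  prot <- toy_proteome(3)
  expect_warning(got <- build_rbpome(list(c("P1", "ZZ")), prot),
                 "not in proteome")
  expect_true("ZZ" %in% got)
  expect_equal(attr(got, "missing"), "ZZ")
  expect_equal(annotate_rbpome(prot, c("P1", "P3"))$is_rbp,
               c(TRUE, FALSE, TRUE))
})

test_that("atlas export writes one row per provenance record and round-trips", {
  set.seed(51)
  prot <- toy_proteome(20, length = 300)
  n <- 300
  rows <- toy_sites(sample(prot$accession, n, TRUE),
                    sample(1:300, n, TRUE),
                    sample(c("phosphorylation", "ubiquitination"), n, TRUE),
                    residue = sample(c("S", "K"), n, TRUE),
                    source = sample(c("a", "b", "c"), n, TRUE),
                    pmid = as.character(sample(999, n, TRUE)))
  cat <- unify_catalogs(rows, prot)
  path <- tempfile(fileext = ".tsv")
  n_written <- export_atlas(cat, prot, path)
  expect_equal(n_written, nrow(cat$provenance))
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header, c("uniprot_id", "gene_name", "position", "pmid",
                         "source", "amino_acid", "modification_type",
                         "cell_line", "sample_type", "body_site",
                         "disease_state"))
  back <- import_atlas(path)
  expect_identical(back$sites, cat$sites)
  expect_identical(back$provenance, cat$provenance)
})

test_that("single-site atlas rows carry explicit nulls and strict header works", {
  prot <- toy_proteome(1, length = 100)
  cat <- unify_catalogs(toy_sites("P1", 7, "acetylation", residue = "K",
                                  source = "src", pmid = "99"), prot)
  path <- tempfile(fileext = ".tsv")
  expect_equal(export_atlas(cat, prot, path), 1L)
  row <- strsplit(readLines(path)[2], "\t")[[1]]
  expect_equal(sum(row != "NA"), 7L)  # 11 fields, 4 context nulls
  export_atlas(cat, prot, path, strict_header = TRUE)
  expect_true(grepl("\tSsource\t", readLines(path, n = 1)))
  # per-site export mode: one row per unified site
  expect_equal(export_atlas(cat, prot, path, mode = "site"), nrow(cat$sites))
})
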