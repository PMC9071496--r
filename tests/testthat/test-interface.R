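# Crosslink window standardization, PTM-distance assignment,
# distance-frequency statistics, group contrasts, and eCLIP intersection.

test_that("window standardization follows the center/clip rules exactly", {
  prot <- toy_proteome(2, length = c(200L, 100L))
  ranges <- data.frame(accession = c("P1", "P1", "P2"),
                       start = c(40L, 10L, 1L), end = c(60L, 60L, 5L),
                       study = "s1", stringsAsFactors = FALSE)
  w <- standardize_windows(ranges, prot, w = 21)
  # exact 21-residue range stays as-is
  expect_equal(unlist(w[1, c("center", "start", "end")], use.names = FALSE),
               c(50L, 40L, 60L))
  # longer range: centered truncation with floor-center
  expect_equal(unlist(w[2, c("center", "start", "end")], use.names = FALSE),
               c(35L, 25L, 45L))
  # short range near the boundary: clipped without re-centering
  expect_equal(unlist(w[3, c("center", "start", "end")], use.names = FALSE),
               c(3L, 1L, 13L))
  expect_error(standardize_windows(
    data.frame(accession = "P2", start = 90L, end = 120L, study = "s"),
    prot), "outside the protein")
  expect_error(standardize_windows(ranges, prot, w = 20), "odd")
})

test_that("standardized windows satisfy the window invariants (1000 fixtures)", {
  set.seed(251)
  n <- 1000
  L <- sample(30:600, n, replace = TRUE)
  start <- pmax(1L, as.integer(runif(n) * (L - 1)))
  end <- pmin(L, start + sample(0:80, n, replace = TRUE))
  prot <- data.frame(accession = sprintf("Q%04d", 1:n),
                     gene_name = "g", length = L,
                     sequence = NA, is_rbp = FALSE, family_tags = NA)
  ranges <- data.frame(accession = prot$accession, start = start, end = end,
                       study = "s")
  w <- standardize_windows(ranges, prot, w = 21)
  for (i in seq_len(n)) {
    ref <- oracle_window(start[i], end[i], L[i])
    expect_equal(w$center[i], unname(ref["center"]))
    expect_equal(w$start[i], unname(ref["start"]))
    expect_equal(w$end[i], unname(ref["end"]))
  }
  expect_true(all(w$start <= w$center & w$center <= w$end))
  expect_true(all(w$end - w$start + 1 <= 21))
  long <- end - start + 1 >= 21
  expect_true(all(w$start[long] >= start[long] & w$end[long] <= end[long]))
  # window length is min(w, what the protein boundary allows)
  feasible <- pmin(w$center + 10, L) - pmax(w$center - 10, 1) + 1
  expect_equal(w$end - w$start + 1, feasible)
})

test_that("PTM-distance assignment respects the (w-1)/2 bound", {
  prot <- toy_proteome(1, length = 500)
  ranges <- data.frame(accession = "P1", start = 90L, end = 110L, study = "s")
  w <- standardize_windows(ranges, prot)
  sites <- toy_sites("P1", c(100, 110, 111, 90, 89), "phosphorylation")
  got <- assign_ptm_distances(sites, w)
  expect_equal(nrow(got), 3L)  # 100, 110, 90 inside; 111 and 89 out
  expect_equal(sort(got$distance), c(0L, 10L, 10L))
})

test_that("distance assignments equal the brute-force per-window scan", {
  set.seed(261)
  accs <- sprintf("P%d", 1:100)
  prot <- data.frame(accession = accs, gene_name = "g", length = 400L,
                     sequence = NA, is_rbp = FALSE, family_tags = NA)
  ranges <- data.frame(accession = sample(accs, 300, TRUE),
                       start = sample(1:350, 300, TRUE), study = "s")
  ranges$end <- pmin(400L, ranges$start + sample(0:60, 300, TRUE))
  windows <- standardize_windows(ranges, prot)
  sites <- toy_sites(sample(accs, 2000, TRUE), sample(1:400, 2000, TRUE),
                     sample(c("phosphorylation", "acetylation"), 2000, TRUE))
  got <- assign_ptm_distances(sites, windows)
  ref <- oracle_assignments(sites, windows)
  cols <- c("accession", "position", "ptm_type", "center", "distance")
  expect_equal(multiset_key(got, cols), multiset_key(ref, cols))
  expect_true(all(got$distance <= 10))
  # the distance-0 bin is exactly the count of PTMs at centers
  stats0 <- distance_frequency_stats(got, windows)
  expect_equal(stats0$bins$count[1], sum(ref$distance == 0))
})

test_that("distance-frequency correlation handles forced patterns", {
  # strictly decreasing raw counts across bins 0..10 -> rho = -1
  assn <- data.frame(accession = "P1", position = 1, ptm_type = "x",
                     center = 1, window_start = 1, window_end = 21,
                     study = "s",
                     distance = rep(0:10, times = 22 - 2 * (0:10)))
  res <- distance_frequency_stats(assn, windows = NULL)
  expect_equal(res$rho, -1)
  expect_lt(res$p_value, 0.01)
  # equal counts in every bin -> all-ties convention: rho 0, flagged
  flat <- assn[rep(which(!duplicated(assn$distance)), each = 3), ]
  res_flat <- distance_frequency_stats(flat, windows = NULL)
  expect_equal(res_flat$rho, 0)
  expect_equal(res_flat$flag, "all_ties")
  # a single observed distance is insufficient
  one <- assn[assn$distance == 4, ]
  expect_equal(distance_frequency_stats(one, windows = NULL)$flag,
               "insufficient")
})

test_that("opportunity normalization counts clipped slots correctly", {
  prot <- toy_proteome(1, length = 100)
  # window clipped at the left edge: center 3, window 1..13
  w <- standardize_windows(
    data.frame(accession = "P1", start = 1L, end = 5L, study = "s"), prot)
  opp <- distance_opportunities(w)
  expect_equal(opp$opportunity[opp$distance == 0], 1L)
  expect_equal(opp$opportunity[opp$distance == 2], 2L)   # both flanks in
  expect_equal(opp$opportunity[opp$distance == 5], 1L)   # left flank clipped
  expect_equal(opp$opportunity[opp$distance == 10], 1L)
})

test_that("nearest-center distances and the family contrast behave", {
  prot <- toy_proteome(3, length = 500,
                       family_tags = c("hnRNP", NA, NA))
  ranges <- data.frame(accession = c("P1", "P2"), start = c(90L, 190L),
                       end = c(110L, 210L), study = "s")
  windows <- standardize_windows(ranges, prot)
  sites <- toy_sites(c("P1", "P1", "P2", "P3"), c(130, 95, 240, 10),
                     "phosphorylation")
  nd <- nearest_center_distances(sites, windows)
  # P3 has no windows and is excluded; P1 at 130 is 30 from center 100
  expect_equal(nrow(nd), 3L)
  expect_equal(nd$nearest_distance[nd$position == 130], 30L)
  expect_equal(nd$nearest_distance[nd$position == 95], 5L)
  # identical distance lists in both groups -> t = 0
  bal <- data.frame(accession = c("P1", "P1", "P1", "P2", "P2", "P2"),
                    position = 1:6, ptm_type = "x",
                    nearest_distance = c(1L, 5L, 9L, 1L, 5L, 9L))
  gc <- interface_group_contrast(bal, prot, tag = "hnRNP")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$mean_a, gc$mean_b)
  expect_error(interface_group_contrast(bal[1:3, ], prot, tag = "hnRNP"),
               "at least 2 sites")
})

test_that("tagged proteins with near-center PTMs show shorter mean distances", {
  set.seed(271)
  n <- 40
  prot <- toy_proteome(n, length = 600,
                       family_tags = c(rep("hnRNP", 10), rep(NA, n - 10)))
  ranges <- data.frame(accession = prot$accession, start = 290L, end = 310L,
                       study = "s")
  windows <- standardize_windows(ranges, prot)
  near <- toy_sites(prot$accession[1:10],
                    300 + sample(-5:5, 50, TRUE), "phosphorylation")
  near$accession <- rep(prot$accession[1:10], each = 5)
  far <- toy_sites(rep(prot$accession[11:n], each = 5),
                   sample(c(1:200, 400:600), 5 * (n - 10), TRUE),
                   "phosphorylation")
  nd <- nearest_center_distances(rbind(near, far), windows)
  gc <- interface_group_contrast(nd, prot, tag = "hnRNP")
  expect_lt(gc$mean_a, gc$mean_b)
  expect_lt(gc$p_value, 0.01)
})

test_that("eCLIP hits require overlap fraction and strand in both replicates", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "+")
  peak <- function(start, end, strand = "+", rbp = "RBP1") {
    data.frame(chrom = "chr1", start = start, end = end, name = "p",
               score = 0L, strand = strand, signal_value = 1, p_value = 1,
               q_value = 1, peak = 1L, rbp = rbp)
  }
  inside <- peak(1200L, 1400L)
  expect_equal(nrow(eclip_gene_hits(inside, inside, genes)), 1L)
  # 40% overlap misses the 50% default threshold
  part <- peak(920L, 1120L)  # 120 of 200 inside? no: 1000..1120 = 120 -> 60%
  part40 <- peak(880L, 1080L)  # 80 of 200 inside = 40%
  expect_equal(nrow(eclip_gene_hits(part40, part40, genes)), 0L)
  expect_equal(nrow(eclip_gene_hits(part, part, genes)), 1L)
  # full overlap on the opposite strand is not a hit
  minus <- peak(1200L, 1400L, strand = "-")
  expect_equal(nrow(eclip_gene_hits(minus, minus, genes)), 0L)
  # a hit needs a qualifying peak in EACH replicate
  expect_equal(nrow(eclip_gene_hits(inside, part40, genes)), 0L)
  # replicate order symmetry
  expect_equal(eclip_gene_hits(inside, part, genes),
               eclip_gene_hits(part, inside, genes))
})

test_that("eCLIP hits equal the brute-force all-pairs interval check", {
  set.seed(281)
  mk_peaks <- function(n) {
    start <- sample(1:49000, n, TRUE)
    data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
               start = start, end = start + sample(50:400, n, TRUE),
               name = "p", score = 0L,
               strand = sample(c("+", "-"), n, TRUE),
               signal_value = 1, p_value = 1, q_value = 1, peak = 1L,
               rbp = sample(c("A", "B", "C"), n, TRUE),
               stringsAsFactors = FALSE)
  }
  gstart <- sample(1:45000, 50, TRUE)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:50),
                      chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = gstart, end = gstart + sample(500:5000, 50, TRUE),
                      strand = sample(c("+", "-"), 50, TRUE),
                      stringsAsFactors = FALSE)
  rep1 <- mk_peaks(250); rep2 <- mk_peaks(250)
  got <- eclip_gene_hits(rep1, rep2, genes, f = 0.5)
  ref <- oracle_eclip_hits(rep1, rep2, genes, 0.5)
  expect_equal(paste(got$rbp, got$gene_id, sep = "\r"), ref)
  # invariant to peak input order
  got2 <- eclip_gene_hits(rep1[sample(nrow(rep1)), ],
                          rep2[sample(nrow(rep2)), ], genes, f = 0.5)
  expect_equal(got, got2)
})

test_that("narrowPeak reading validates structure with line numbers", {
  f <- tempfile()
  writeLines(c("chr1\t10\t100\tRBP1_p1\t0\t+\t1\t1\t1\t5",
               "chr1\t10\t100\tbad_line\t0\t+\t1\t1"), f)
  expect_error(read_narrowpeak(f), "line\\(s\\) 2")
  writeLines("chr1\t10\t100\tRBP1_p1\t0\t+\t1\t1\t1\t5", f)
  pk <- read_narrowpeak(f)
  expect_equal(pk$rbp, "RBP1")
  expect_equal(read_narrowpeak(f, rbp = "X")$rbp, "X")
})
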