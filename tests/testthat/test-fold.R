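# Ensemble folding engine: enumeration oracle, partition function, ligand
# bonus, x ratio, annotation, arcplot.

test_that("enumeration lists exactly the valid structures", {
  # no complementary pairs at all
  en <- enumerate_structures("AAAA")
  expect_equal(nrow(en), 1)
  expect_equal(en$structure, "....")
  # complementary but inside the hairpin gap
  expect_equal(enumerate_structures("GC")$structure, "..")
  # count matches an independent first-position recursion
  for (s in c("GGGAAACCC", "GCGCAAAAGCGC", "AUGCAUGCAUGC")) {
    expect_equal(nrow(enumerate_structures(s)),
                 count_structures_oracle(s))
  }
  expect_error(enumerate_structures(strrep("A", 30)), "cap")
})

test_that("dot-bracket round-trips pair lists", {
  pr <- rbind(c(1L, 9L), c(2L, 8L))
  db <- pairs_to_dotbracket(pr, 10)
  expect_equal(db, "((.....)).")
  back <- dotbracket_to_pairs(db)
  expect_equal(back[order(back[, 1]), , drop = FALSE], pr)
  expect_error(dotbracket_to_pairs("(()"), "unbalanced")
})

test_that("partition function matches enumeration on random short sequences", {
  set.seed(11)
  for (rep in 1:40) {
    s <- random_rna(sample(8:14, 1))
    b <- brute_pair_probs(s)
    pf <- partition_function(s)
    expect_equal(pf$Z, b$Z, tolerance = 1e-12)
    expect_lt(max(abs(pf$p - b$p)), 1e-9)
  }
})

test_that("prohibitive pair energies leave only the unfolded chain", {
  m <- energy_model(gc = 1e6, au = 1e6, gu = 1e6)
  pf <- partition_function("GGGGAAAACCCC", m)
  expect_equal(pf$Z, 1)
  expect_equal(max(pf$p), 0)
})

test_that("the ligand bonus reweights exactly the motif-closing structures", {
  s <- "GGCAAAAGCC"
  mot <- aptamer_motif(list(c(0, 2), c(7, 10)),
                       closing_pairs = list(c(1, 8)), kd_intrinsic = 2)
  # L = 0 reproduces the ligand-free matrix bit for bit
  pp0 <- partition_function(s, ligand = list(motif = mot, conc = 0))
  expect_identical(pp0$p, partition_function(s)$p)
  # enumeration oracle with the (1 + L/Kd) factor on structures containing
  # the closing pair (1-based 2:9)
  for (L in c(0.5, 2, 20, 200)) {
    b <- brute_pair_probs(s, bonus_pair = c(2, 9), bonus = L / 2)
    pf <- partition_function(s, ligand = list(motif = mot, conc = L))
    expect_equal(pf$Z, b$Z, tolerance = 1e-12)
    expect_lt(max(abs(pf$p - b$p)), 1e-9)
  }
  # motif-formation probability is non-decreasing in L
  pm <- vapply(c(0, 1, 5, 25, 125, 625), function(L)
    partition_function(s, ligand = list(motif = mot, conc = L))$p_motif_formed,
    numeric(1))
  expect_true(all(diff(pm) >= -1e-12))
})

test_that("pair-probability rows never sum above one", {
  set.seed(12)
  for (rep in 1:10) {
    s <- random_rna(sample(15:40, 1))
    pf <- partition_function(s)
    full <- pf$p + t(pf$p)
    expect_lt(max(rowSums(full)), 1 + 1e-9)
  }
})

test_that("x ratio is 1 without ligand and matches enumeration on a small
           design", {
  d <- tiny_design()
  expect_equal(x_ratio(d, ligand_conc = 0)$score, 1)
  xr <- x_ratio(d, ligand_conc = 50)
  expect_true(xr$scoreable)
  expect_gte(xr$score, 1)
  # oracle: closing pair (1-based 2:9) probability in both ensembles
  b0 <- brute_pair_probs(d$sequence, bonus_pair = c(2, 9), bonus = 0)
  bL <- brute_pair_probs(d$sequence, bonus_pair = c(2, 9), bonus = 50 / 2)
  expect_equal(xr$raw, b0$p[2, 9] / bL$p[2, 9], tolerance = 1e-9)
  # x ratio is monotone non-increasing (raw) in L for this single-motif design
  raws <- vapply(c(0, 5, 50, 500), function(L)
    x_ratio(d, ligand_conc = L)$raw, numeric(1))
  expect_true(all(diff(raws) <= 1e-12))
})

test_that("x ratio of a design whose input motif cannot pair is 1", {
  # closing "pair" between two A's can never form
  input <- aptamer_motif(list(c(0, 3)), closing_pairs = list(c(0, 8)),
                         kd_intrinsic = 2)
  output <- aptamer_motif(list(c(9, 13)), closing_pairs = list(c(9, 12)))
  d <- switch_design("X", "AAAAAAAAAAAAAA", input, output, "on")
  xr <- x_ratio(d, ligand_conc = 100)
  expect_equal(xr$score, 1)
})

test_that("element annotation labels motifs, complements and spacers", {
  # [GGGG input] AAAA [CCCC pairs only the input] AAAA; no U, so A's are inert
  seqc <- "GGGGAAAACCCCAAAA"
  input <- aptamer_motif(list(c(0, 4)), closing_pairs = list(c(0, 11)),
                         kd_intrinsic = 2)
  output <- aptamer_motif(list(c(12, 16)), closing_pairs = list(c(12, 15)))
  d <- switch_design("A1", seqc, input, output, "on")
  ann <- annotate_elements(d, ligand_conc = 100)
  expect_equal(nrow(ann), nchar(seqc))
  expect_true(all(ann$label[1:4] == "input"))
  expect_true(all(ann$label[13:16] == "output"))  # motif label by definition
  expect_true(all(ann$label[9:12] == "input_comp"))
  expect_true(all(ann$label[5:8] == "unpaired"))
})

test_that("an isolated stable hairpin outside both motifs is static", {
  # [UUUU input] AAAA [AAAA input-comp] [GGGG-AAAA-CCCC static GC hairpin]
  seqc <- "UUUUAAAAAAAAGGGGAAAACCCC"
  input <- aptamer_motif(list(c(0, 4)), closing_pairs = list(c(0, 11)),
                         kd_intrinsic = 2)
  output <- aptamer_motif(list(c(4, 8)), closing_pairs = list(c(4, 7)))
  d <- switch_design("A2", seqc, input, output, "on")
  ann <- annotate_elements(d, ligand_conc = 100)
  expect_true(all(ann$label[c(13:16, 21:24)] == "static"))
  # the A's locked against the U motif by the ligand-stabilised register;
  # the remaining A's dilute their pairing below the 0.5 threshold
  expect_true(all(ann$label[11:12] == "input_comp"))
})

test_that("arcplot export is consistent with the partition function", {
  d <- tiny_design()
  arc <- arcplot_export(d, ligand_conc = 50, threshold = 0.01)
  expect_true(all(diff(arc$i * 1000 + arc$j) > 0))  # ordered by (i, j)
  pp0 <- partition_function(d$sequence,
                            ligand = list(motif = d$input_motif, conc = 0))
  ppL <- partition_function(d$sequence,
                            ligand = list(motif = d$input_motif, conc = 50))
  for (r in seq_len(nrow(arc))) {
    expect_equal(arc$p_absent[r], pp0$p[arc$i[r] + 1, arc$j[r] + 1])
    expect_equal(arc$p_present[r], ppL$p[arc$i[r] + 1, arc$j[r] + 1])
  }
  # L = 0: both columns identical
  arc0 <- arcplot_export(d, ligand_conc = 0)
  expect_equal(arc0$p_absent, arc0$p_present)
  # all-A sequence: empty table
  input <- aptamer_motif(list(c(0, 3)), closing_pairs = list(c(0, 8)),
                         kd_intrinsic = 2)
  output <- aptamer_motif(list(c(9, 13)), closing_pairs = list(c(9, 12)))
  dA <- switch_design("X", "AAAAAAAAAAAAAA", input, output, "on")
  expect_equal(nrow(arcplot_export(dA, ligand_conc = 10)), 0)
})

test_that("the minimum-energy representative structure is the enumeration
           minimum", {
  set.seed(13)
  for (rep in 1:10) {
    s <- random_rna(sample(8:14, 1))
    en <- enumerate_structures(s)
    mfe <- mfe_structure(s)
    expect_equal(mfe$energy, min(en$energy))
  }
})
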