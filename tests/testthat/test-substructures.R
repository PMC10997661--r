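test_that("fragmentation respects the size window and never breaks rings", {
  # cyclopropane: the whole ring is the only candidate
  cp <- fragment_molecule("C1CC1")
  expect_equal(nrow(cp), 1)
  expect_equal(cp$atoms[[1]], 1:3)
  # ethane: below the 3-atom minimum
  expect_equal(nrow(fragment_molecule("CC")), 0)
  # aspirin: every fragment within 3-20 atoms, rings intact
  info <- parse_molecules("CC(=O)OC1=CC=CC=C1C(=O)O")[[1]]
  fr <- fragment_molecule(info)
  expect_gt(nrow(fr), 3)
  sizes <- vapply(fr$atoms, length, integer(1))
  expect_true(all(sizes >= 3 & sizes <= 20))
  for (a in fr$atoms) {
    for (ring in info$rings) {
      overlap <- length(intersect(a, ring))
      expect_true(overlap == 0 || overlap == length(ring))
    }
  }
})

test_that("fragmenter subsets behave and union over techniques", {
  g_only <- fragment_molecule("CCCCC(=O)NC",
                              extraction_config(fragmenters = "GRINDER"))
  all_three <- fragment_molecule("CCCCC(=O)NC")
  expect_true(all(g_only$smiles %in% all_three$smiles))
})

test_that("importance detection applies the strict percentile rule", {
  att <- c(1, 1, 1, rep(0, 7))
  frags <- list(1:3, 4:6)
  flags <- detect_important_fragments(att, frags, p_f = 75)
  expect_equal(flags, c(TRUE, FALSE))
  # uniform attention: nothing strictly exceeds the percentile
  expect_false(any(detect_important_fragments(rep(0.4, 8),
                                              list(1:3, 2:5), 75)))
  # brute-force recomputation matches
  set.seed(12)
  att2 <- runif(12)
  frs <- list(1:4, c(2, 7, 9), 5:12, c(1, 12))
  thr <- quantile(att2, 0.75, type = 7, names = FALSE)
  manual <- vapply(frs, function(a) median(att2[a]) > thr, logical(1))
  expect_equal(detect_important_fragments(att2, frs, 75), manual)
})

test_that("the fragment score is the mean fragment-vs-molecule excess", {
  occ <- data.frame(m_frag = c(0.8, 0.6), m_mol = c(0.5, 0.5))
  expect_equal(score_fragment(occ), 0.2)
  expect_equal(score_fragment(data.frame(m_frag = 0.9, m_mol = 0.4)), 0.5)
  expect_equal(score_fragment(data.frame(m_frag = c(0.3, 0.7),
                                         m_mol = c(0.3, 0.7))), 0)
  expect_error(score_fragment(data.frame(m_frag = numeric(0),
                                         m_mol = numeric(0))),
               "occurrences")
})

make_attention_set <- function(n = 8, seed = 3) {
  pool <- generated_pool(n)
  att <- list()
  smi <- character(0)
  set.seed(seed)
  for (i in seq_len(n)) {
    info <- parse_molecules(pool$smiles[i])[[1]]
    att[[pool$id[i]]] <- runif(info$n_atoms)
    smi[pool$id[i]] <- info$smiles
  }
  list(attention = att, smiles = smi)
}

test_that("fragment statistics aggregate occurrences consistently", {
  as <- make_attention_set()
  fs <- fragment_statistics(as$attention, as$smiles)
  st <- fs$stats
  expect_true(all(st$important_pct ==
                    100 * st$n_important / st$n_compounds))
  expect_true(all(st$n_important <= st$n_compounds))
  # recompute one fragment's score from its occurrences
  f <- st$fragment[which.max(st$n_occurrences)]
  occ <- fs$occurrences[fs$occurrences$fragment == f, ]
  expect_equal(st$score[st$fragment == f], mean(occ$m_frag - occ$m_mol))
  # processing order does not matter
  fs2 <- fragment_statistics(rev(as$attention), as$smiles)
  expect_equal(fs2$stats[order(fs2$stats$fragment), ],
               st[order(st$fragment), ], ignore_attr = TRUE)
})

test_that("selection enforces all three conditions and is monotone", {
  as <- make_attention_set()
  fs <- fragment_statistics(as$attention, as$smiles)
  sel <- suppressWarnings(select_potential_substructures(fs))
  if (nrow(sel) > 0) {
    support_cut <- quantile(fs$stats$n_important, 0.7, type = 7,
                            names = FALSE)
    expect_true(all(sel$important_pct >= 50))
    expect_true(all(sel$n_important >= support_cut))
    expect_true(all(sel$score > 0))
  }
  # raising the support percentile never enlarges the selection
  stricter <- suppressWarnings(select_potential_substructures(
    fs, extraction_config(p_s = 90)))
  expect_true(all(stricter$fragment %in% sel$fragment))
  # raising the importance percentile never enlarges it either
  fs_hi <- fragment_statistics(as$attention, as$smiles,
                               extraction_config(p_f = 95))
  expect_true(all(fs_hi$stats$n_important <= fs$stats$n_important))
})

test_that("redundant subgraph fragments are dropped in favour of larger ones", {
  occ <- data.frame(
    fragment = c("CCC", "CCCC", "CCO"),
    molecule = c("m1", "m1", "m2"),
    m_frag = c(0.8, 0.9, 0.7),
    m_mol = c(0.4, 0.4, 0.3),
    important = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  occ$atoms <- list(1:3, 1:4, 5:7)
  st <- data.frame(
    fragment = c("CCC", "CCCC", "CCO"),
    n_compounds = c(1L, 1L, 1L), n_important = c(1L, 1L, 1L),
    important_pct = c(100, 100, 100),
    score = c(0.4, 0.5, 0.4), n_occurrences = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
  fs <- structure(list(stats = st, occurrences = occ,
                       config = extraction_config(p_s = 10)),
                  class = "fragment_statistics")
  sel <- select_potential_substructures(fs)
  # CCC sits inside CCCC with a lower score: dropped; CCO unrelated: kept
  expect_setequal(sel$fragment, c("CCCC", "CCO"))
})
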