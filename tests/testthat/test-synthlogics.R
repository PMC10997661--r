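test_that("the five built-in logics carry their defining SMARTS", {
  logics <- builtin_logics()
  expect_length(logics, 5)
  expect_setequal(names(logics),
                  c("Logic6", "Logic7", "Logic9", "Logic14", "3MR"))
  expect_setequal(logics$Logic6$leaves, c("[FX1]", "[CX3]=O"))
  expect_true("[R0;D2,D1][R0;D2][R0;D2,D1]" %in% logics$Logic7$leaves)
  expect_true("[cX3]1[cX3H][cX3H][cX3H][cX3H][cX3H]1" %in%
                logics$Logic9$leaves)
  expect_setequal(logics$Logic14$positive_patterns,
                  c("[OD2](C)C", "[CX3]=O"))
  expect_equal(logics$`3MR`$leaves, "*1**1")
})

test_that("logic evaluation matches hand-derived labels on a panel", {
  logics <- builtin_logics()
  panel <- list(
    # fluorine AND carbonyl
    list("Logic6", "CC(=O)F", 1), list("Logic6", "CCF", 0),
    list("Logic6", "CC=O", 0), list("Logic6", "FCCCC(=O)C", 1),
    # unbranched acyclic triple AND carbonyl
    list("Logic7", "CCCC(=O)C", 1), list("Logic7", "C1CC1C(=O)C1CC1", 0),
    # amine AND ether AND mono-substituted benzene
    list("Logic9", "NCCOCc1ccccc1", 1), list("Logic9", "NCCOc1ccccc1", 0),
    list("Logic9", "CCOCc1ccccc1", 0),
    # (ether OR no hydroxyl) AND carbonyl AND no alkyne
    list("Logic14", "CC(=O)C", 1), list("Logic14", "C#CC(C)=O", 0),
    list("Logic14", "OCCC(=O)C", 0), list("Logic14", "COCC(=O)CO", 1),
    # any three-membered ring
    list("3MR", "C1CC1", 1), list("3MR", "c1ccccc1", 0),
    list("3MR", "C1OC1CC", 1)
  )
  for (case in panel) {
    ev <- evaluate_logic(logics[[case[[1]]]], case[[2]])
    expect_equal(ev$labels, case[[3]],
                 label = paste(case[[1]], case[[2]]))
  }
})

test_that("ground-truth masks collect matched atoms of positive leaves", {
  logics <- builtin_logics()
  ev <- evaluate_logic(logics$`3MR`, "C1CC1")
  expect_equal(ev$masks[[1]], list(1:3))
  expect_equal(evaluate_logic(logics$`3MR`, "c1ccccc1")$masks[[1]], list())
  # two carbonyls: at least two alternative ground truths
  ev7 <- evaluate_logic(logics$Logic7, "CCCCC(=O)CC(=O)C")
  expect_equal(ev7$labels, 1)
  expect_gte(length(ev7$masks[[1]]), 2)
  # NOT leaves contribute no ground-truth atoms: a positive via the
  # "no hydroxyl" branch still gets its mask from the carbonyl only
  ev14 <- evaluate_logic(logics$Logic14, "CCC(=O)CC")
  expect_equal(ev14$labels, 1)
  carbonyl_atoms <- match_smarts("CCC(=O)CC", "[CX3]=O")[[1]][[1]][[1]]
  expect_true(all(vapply(ev14$masks[[1]], function(m)
    all(m %in% carbonyl_atoms), logical(1))))
})

test_that("generated datasets are deterministic, balanced, self-consistent", {
  g1 <- generate_dataset("Logic6", 200, seed = 5)
  g2 <- generate_dataset("Logic6", 200, seed = 5)
  expect_identical(g1$records, g2$records)
  g3 <- generate_dataset("Logic6", 200, seed = 6)
  expect_false(identical(g1$records$smiles, g3$records$smiles))
  bal <- mean(g1$records$target)
  expect_gte(bal, 0.45)
  expect_lte(bal, 0.55)
  # labels re-derive from the logic itself
  re <- evaluate_logic(builtin_logics()$Logic6, g1$records$smiles)
  expect_equal(re$labels, g1$records$target)
  # unknown logic names list the alternatives
  expect_error(generate_dataset("Logic99", 200), "built-ins")
})

test_that("attention AUROC follows pairwise concordance with max over masks", {
  expect_equal(attention_auroc(c(1, 1, 0, 0, 1), list(c(1, 2, 5))), 1)
  expect_equal(attention_auroc(rep(0.3, 6), list(1:2)), 0.5)
  expect_equal(attention_auroc(c(0.9, 0.8, 0.1, 0.7, 0.2),
                               list(c(1, 2, 4))), 1)
  # degenerate masks are skipped
  expect_true(is.na(attention_auroc(c(0.1, 0.9), list(1:2))))
  set.seed(77)
  for (i in 1:60) {
    n <- sample(4:15, 1)
    att <- round(runif(n), 1)
    mask <- sample(n, sample(n - 1, 1))
    y <- as.integer(seq_len(n) %in% mask)
    expect_equal(attention_auroc(att, list(mask)), bf_auroc(att, y),
                 tolerance = 1e-12)
  }
})

test_that("attention accuracy thresholds at 0.5 and maximizes over masks", {
  expect_equal(attention_acc(c(0.9, 0.1, 0.2, 0.8), list(c(1, 4))), 1)
  expect_equal(attention_acc(rep(0.6, 4), list(1)), 0.25)
  expect_equal(attention_acc(c(0.9, 0.9, 0.1), list(1, c(1, 2))), 1)
  set.seed(78)
  for (i in 1:60) {
    n <- sample(4:15, 1)
    att <- runif(n)
    masks <- lapply(1:3, function(j) sample(n, sample(n, 1)))
    manual <- max(vapply(masks, function(m) bf_attacc(att, m), numeric(1)))
    expect_equal(attention_acc(att, masks), manual, tolerance = 1e-12)
  }
})

test_that("oracle attention scores perfectly through the fold evaluator", {
  # indicator attention on the mask is a perfect scorer
  mask <- c(2, 3, 5)
  att <- as.numeric(seq_len(7) %in% mask)
  expect_equal(attention_auroc(att, list(mask)), 1)
  expect_equal(attention_acc(att, list(mask)), 1)
  # random attention hovers at chance over many draws
  set.seed(123)
  vals <- replicate(400, {
    att <- runif(10)
    attention_auroc(att, list(sample(10, 4)))
  })
  expect_equal(mean(vals), 0.5, tolerance = 0.03)
})
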