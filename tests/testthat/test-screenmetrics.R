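# Hit-list construction, enrichment factors, ROC/AUC

fake_records <- function(parents, scores, labels, status = NULL) {
  data.frame(state_id = paste0(parents, "_s", seq_along(parents)),
             parent_id = parents, variant = "QMDS1", qmds = scores,
             is_ligand = labels,
             status = status %||% rep("converged", length(parents)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hit lists collapse states to the lowest score and drop failures", {
  rec <- fake_records(c("M1", "M1", "M2", "M3"),
                      c(-5, -7, -1, NA),
                      c(TRUE, TRUE, FALSE, FALSE),
                      status = c("converged", "converged", "converged", "failed"))
  hl <- build_hitlist(rec)
  expect_equal(hl$n_total, 2L)
  expect_equal(hl$table$score[hl$table$parent_id == "M1"], -7)
  expect_equal(hl$excluded, "M3")
  expect_equal(hl$hits_total, 1L)

  # equal scores: deterministic lexicographic order
  tie <- fake_records(c("B", "A", "C"), c(1, 1, 0), c(TRUE, FALSE, TRUE))
  expect_equal(build_hitlist(tie)$table$parent_id, c("C", "A", "B"))

  all_failed <- fake_records("M1", NA, TRUE, status = "failed")
  expect_error(build_hitlist(all_failed), "failed")
})

test_that("enrichment factors reproduce hand-computed values", {
  # perfect ranking: 10 ligands of 1000 all in the top 10
  hl <- build_hitlist(fake_records(sprintf("M%04d", 1:1000), 1:1000,
                                   c(rep(TRUE, 10), rep(FALSE, 990))))
  expect_equal(enrichment_factor(hl, 1), 100)
  expect_equal(enrichment_factor(hl, 100), 1)

  # 8 hits in the top 20 of 200 with 20 ligands total: EF(10) = 4
  lab <- rep(FALSE, 200)
  lab[c(1:8, 151:162)] <- TRUE
  hl2 <- build_hitlist(fake_records(sprintf("M%03d", 1:200), 1:200, lab))
  expect_equal(enrichment_factor(hl2, 10), (8 / 20) / (20 / 200))

  no_hits <- build_hitlist(fake_records(c("A", "B"), c(1, 2), c(FALSE, FALSE)))
  expect_error(enrichment_factor(no_hits, 1), "no ligands")
})

test_that("EF matches the brute-force counting oracle on random lists", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(20:400, 1)
    scores <- rnorm(n)
    labels <- runif(n) < 0.15
    if (!any(labels)) labels[1] <- TRUE
    hl <- build_hitlist(fake_records(sprintf("M%04d", 1:n), scores, labels))
    for (x in c(1, 2, 5, 10, 25, 100)) {
      expect_equal(enrichment_factor(hl, x), brute_ef(scores, labels, x))
    }
    expect_equal(enrichment_factor(hl, 100), 1)
    # EF is bounded by both saturation limits
    expect_lte(enrichment_factor(hl, 5),
               min(100 / 5 + 1e-9, n / sum(labels)))
  }
})

test_that("AUC equals Mann-Whitney pair counting, including ties", {
  hl <- build_hitlist(fake_records(c("L1", "L2", "D1", "D2"),
                                   c(1, 3, 2, 4),
                                   c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(roc_auc(hl)$auc, 0.75)

  set.seed(44)
  for (rep in 1:200) {
    n <- sample(10:300, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- runif(n) < 0.2
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    hl <- build_hitlist(fake_records(sprintf("M%04d", 1:n), scores, labels))
    expect_equal(roc_auc(hl)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  scores <- rnorm(300)
  labels <- runif(300) < 0.25
  labels[1] <- TRUE; labels[2] <- FALSE
  hl <- build_hitlist(fake_records(sprintf("M%04d", 1:300), scores, labels))
  ref <- pROC::auc(pROC::roc(response = labels, predictor = scores,
                             direction = ">", quiet = TRUE))
  expect_equal(roc_auc(hl)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("perfect and degenerate rankings hit the ROC extremes", {
  perfect <- build_hitlist(fake_records(sprintf("M%02d", 1:40), 1:40,
                                        c(rep(TRUE, 6), rep(FALSE, 34))))
  expect_equal(roc_auc(perfect)$auc, 1.0)
  worst <- build_hitlist(fake_records(sprintf("M%02d", 1:40), 1:40,
                                      c(rep(FALSE, 34), rep(TRUE, 6))))
  expect_equal(roc_auc(worst)$auc, 0.0)
  single <- build_hitlist(fake_records(c("A", "B"), c(1, 2), c(TRUE, TRUE)))
  expect_error(roc_auc(single), "both")
})

test_that("shuffled labels give AUC near one half", {
  set.seed(66)
  aucs <- vapply(1:20, function(rep) {
    scores <- rnorm(500)
    labels <- sample(c(rep(TRUE, 50), rep(FALSE, 450)))
    hl <- build_hitlist(fake_records(sprintf("M%04d", 1:500), scores, labels))
    roc_auc(hl)$auc
  }, 0)
  expect_lt(max(abs(aucs - 0.5)), 0.15)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the enrichment curve is a monotone step from (0,0) to (100,100)", {
  set.seed(77)
  hl <- build_hitlist(fake_records(sprintf("M%03d", 1:120), rnorm(120),
                                   runif(120) < 0.2 | c(TRUE, rep(FALSE, 119))))
  curve <- enrichment_plot_data(hl)
  expect_equal(curve$pct_screened[1], 0)
  expect_equal(curve$pct_ligands_found[1], 0)
  expect_equal(tail(curve$pct_screened, 1), 100)
  expect_equal(tail(curve$pct_ligands_found, 1), 100)
  expect_true(all(diff(curve$pct_ligands_found) >= 0))

  # perfect ranking recovers every ligand once hits/N of the list is screened
  perfect <- build_hitlist(fake_records(sprintf("M%02d", 1:50), 1:50,
                                        c(rep(TRUE, 10), rep(FALSE, 40))))
  pc <- enrichment_plot_data(perfect)
  expect_equal(min(pc$pct_screened[pc$pct_ligands_found == 100]), 20)
})

test_that("a decoy ranked below all ligands affects EF only via the totals", {
  # dropping the worst-ranked decoy leaves every top set's content intact;
  # EF then rescales exactly by (N-1)/N through the ligand-fraction
  # normalization whenever the ceiling top-set size is unchanged, and the
  # top-set ligand count never decreases at any size
  set.seed(88)
  scores <- c(rnorm(30, -2), rnorm(70, 2))
  labels <- c(rep(TRUE, 30), rep(FALSE, 70))
  hl_full <- build_hitlist(fake_records(sprintf("M%03d", 1:100), scores, labels))
  drop <- which(!labels & scores == max(scores[!labels]))[1]
  hl_drop <- build_hitlist(fake_records(sprintf("M%03d", seq_len(99)),
                                        scores[-drop], labels[-drop]))
  n_full <- hl_full$n_total; n_drop <- hl_drop$n_total
  for (x in c(1, 5, 10, 50)) {
    if (ceiling(x * n_full / 100) == ceiling(x * n_drop / 100)) {
      expect_equal(enrichment_factor(hl_drop, x),
                   enrichment_factor(hl_full, x) * n_drop / n_full,
                   tolerance = 1e-12)
    }
  }
  cum_full <- cumsum(hl_full$table$is_ligand)
  cum_drop <- cumsum(hl_drop$table$is_ligand)
  expect_true(all(cum_drop >= cum_full[seq_along(cum_drop)]))
})
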