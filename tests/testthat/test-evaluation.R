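test_that("compute_metrics reproduces the printed formulas", {
  perfect <- compute_metrics(confusion_counts(5, 5, 0, 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 1))
  # hand-evaluated fixture: tp=3, fn=1, tn=2, fp=2
  m <- compute_metrics(confusion_counts(tp = 3, tn = 2, fp = 2, fn = 1))
  expect_equal(unname(m["Sn"]), 0.75)
  expect_equal(unname(m["Sp"]), 0.5)
  expect_equal(unname(m["Ac"]), 0.625)
  expect_equal(unname(m["Pre"]), 0.6)
  expect_equal(unname(m["MCC"]), (3 * 2 - 2 * 1) / sqrt(4 * 5 * 3 * 4))
  expect_equal(unname(m["MCC"]), 0.2582, tolerance = 1e-4)
  # zero denominators are undefined (NA), not zero
  z <- compute_metrics(confusion_counts(tp = 0, tn = 4, fp = 0, fn = 2))
  expect_true(is.na(z["Pre"]))
  expect_true(is.na(z["MCC"]))
  expect_false(anyNA(z[c("Sn", "Sp", "Ac")]))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("MCC is antisymmetric under label flip and Sn/Sp swap", {
  set.seed(41)
  for (r in 1:20) {
    cnt <- sample(1:30, 4)
    a <- compute_metrics(confusion_counts(cnt[1], cnt[2], cnt[3], cnt[4]))
    # renaming the positive class (truth and predictions both flip):
    # tp<->tn, fp<->fn -- MCC invariant, Sn and Sp swap
    b <- compute_metrics(confusion_counts(cnt[2], cnt[1], cnt[4], cnt[3]))
    expect_equal(unname(b["MCC"]), unname(a["MCC"]))
    expect_equal(unname(b["Sn"]), unname(a["Sp"]))
    expect_equal(unname(b["Sp"]), unname(a["Sn"]))
    # inverting the classifier's predictions only: tp<->fn, tn<->fp --
    # MCC negated
    d <- compute_metrics(confusion_counts(cnt[4], cnt[3], cnt[2], cnt[1]))
    expect_equal(unname(d["MCC"]), -unname(a["MCC"]))
    expect_equal(unname(d["Sn"]), 1 - unname(a["Sn"]))
  }
})

test_that("Ac equals (Sn + Sp) / 2 on balanced counts", {
  set.seed(43)
  for (r in 1:10) {
    tp <- sample(0:20, 1); fn <- 20 - tp
    tn <- sample(0:20, 1); fp <- 20 - tn
    m <- compute_metrics(confusion_counts(tp, tn, fp, fn))
    expect_equal(unname(m["Ac"]), (m[["Sn"]] + m[["Sp"]]) / 2)
  }
})

test_that("roc_curve sweeps monotonically from (0,0) to (1,1)", {
  set.seed(47)
  scores <- rnorm(40)
  labels <- rep(c(1, -1), 20)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(rc$fpr >= 0 & rc$fpr <= 1 & rc$tpr >= 0 & rc$tpr <= 1))
})

test_that("auc_roc: perfect ranking, chance level, oracle equality", {
  expect_equal(auc_roc(c(3, 4, 5, 1, 2), c(1, 1, 1, -1, -1)), 1)
  expect_equal(auc_roc(c(1, 2), c(-1, 1)), 1)
  # chance level at large n
  set.seed(53)
  s <- rnorm(1000)
  y <- sample(rep(c(1, -1), 500))
  expect_equal(auc_roc(s, y), 0.5, tolerance = 0.05)
  # trapezoid equals the all-pairs Mann-Whitney oracle, ties counted 1/2
  for (r in 1:50) {
    n <- sample(4:12, 1)
    sc <- sample(1:6, n, replace = TRUE)  # heavy ties
    yy <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
    expect_equal(auc_roc(sc, yy), oracle_auc(sc, yy), tolerance = 1e-9)
  }
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auc_roc is invariant under strictly increasing transforms", {
  set.seed(59)
  s <- rnorm(60)
  y <- sample(rep(c(1, -1), 30))
  a <- auc_roc(s, y)
  expect_equal(auc_roc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(auc_roc(2 * s + 17, y), a, tolerance = 1e-12)
})

test_that("kfold_split partitions with near-equal, stratified sizes", {
  f <- kfold_split(100, 10, seed = 61)
  expect_equal(sort(lengths(f)), rep(10L, 10))
  f2 <- kfold_split(103, 10, seed = 61)
  expect_equal(sort(lengths(f2)), c(rep(10L, 7), rep(11L, 3)))
  expect_equal(sort(unlist(f2)), 1:103)  # disjoint cover
  # stratification keeps the class ratio within one instance per fold
  y <- rep(c(1, -1), each = 50)
  f3 <- kfold_split(100, 10, seed = 67, stratified = TRUE, labels = y)
  for (fold in f3) {
    expect_lte(abs(sum(y[fold] == 1) - sum(y[fold] == -1)), 1L)
  }
  expect_equal(sort(unlist(f3)), 1:100)
  expect_error(kfold_split(5, 6), "more folds")
})

test_that("balanced_sample_sets draws 50/50 sets, differing across sets", {
  g <- class_generator(rep(0.05, 20), len_range = c(30L, 50L))
  pos <- generate_dataset(g, g, 12, 1, seed = 71)[1:12, ]
  neg0 <- generate_dataset(g, g, 1, 200, seed = 73)
  neg <- neg0[neg0$label == -1, ]
  sets <- balanced_sample_sets(pos, neg, n_sets = 10, seed = 79)
  expect_length(sets, 10L)
  for (s in sets) {
    expect_equal(nrow(s), 24L)
    expect_equal(sum(s$label == 1), 12L)
    expect_equal(sum(s$label == -1), 12L)
    expect_equal(anyDuplicated(s$id), 0L)  # without replacement within a set
  }
  draws <- vapply(sets, function(s) paste(sort(s$id[s$label == -1]),
                                          collapse = ","), character(1))
  expect_gt(length(unique(draws)), 1L)  # sets differ
  # determinism
  sets2 <- balanced_sample_sets(pos, neg, n_sets = 10, seed = 79)
  expect_identical(sets, sets2)
  expect_error(balanced_sample_sets(neg, pos, 2), "fewer negatives")
  # no sampling freedom when classes are equal in size
  one <- balanced_sample_sets(pos, neg[1:12, ], 1, seed = 3)[[1]]
  expect_setequal(one$id, c(pos$id, neg$id[1:12]))
})

test_that("run_cv: separable data scores perfectly and never leaks", {
  # two residue-disjoint composition blocks: separable by construction
  set.seed(83)
  mk <- function(core, other) vapply(1:10, function(i) {
    paste(sample(c(rep(core, 40), sample(other, 10, replace = TRUE))),
          collapse = "")
  }, character(1))
  ds <- labeled_dataset(
    protein_set(sprintf("s%02d", 1:20),
                c(mk("L", c("A", "K", "E")), mk("D", c("G", "S", "T")))),
    rep(c(1L, -1L), each = 10))
  res <- suppressMessages(run_cv(ds, "AAC", k = 5, seed = 89,
                                 kernel = kernel_spec("linear")))
  expect_equal(nrow(res$folds), 5L)
  expect_true(all(res$folds$Ac == 1))
  # partition property via ID tracking: test folds reassemble the dataset
  expect_setequal(res$predictions$id, ds$id)
  expect_equal(anyDuplicated(res$predictions$id), 0L)
  # fold-level counts sum to the dataset size
  expect_equal(sum(res$folds$tp + res$folds$tn + res$folds$fp + res$folds$fn),
               nrow(ds))
})

test_that("run_loocv predicts each instance exactly once", {
  ds <- labeled_dataset(
    protein_set(sprintf("t%d", 1:6),
                c("LLLLLLLLLL", "LLLLLLLLLK", "LLLLLLLLKK",
                  "DDDDDDDDDD", "DDDDDDDDDE", "DDDDDDDDEE")),
    c(1L, 1L, 1L, -1L, -1L, -1L))
  res <- suppressMessages(run_loocv(ds, "AAC", kernel = kernel_spec("linear")))
  expect_equal(nrow(res$predictions), 6L)
  expect_setequal(res$predictions$id, ds$id)
  with(res$counts, expect_equal(tp + tn + fp + fn, 6))
  expect_equal(unname(res$metrics["Ac"]), 1)
  expect_error(run_loocv(ds[1:3, ], "AAC"), "both classes|3 instances")
  # a singleton class would leave degenerate training sets
  expect_error(run_loocv(ds[c(1, 2, 4), ], "AAC"), "single member")
})

test_that("run_loocv on 15-vs-15 yields 30 per-instance predictions", {
  pre <- leucine_enriched_preset(c(40L, 60L))
  ds <- generate_dataset(pre$pos, pre$neg, 15, 15, seed = 97)
  res <- suppressMessages(run_loocv(ds, "AAC"))
  expect_equal(nrow(res$predictions), 30L)
})

test_that("aggregate_report computes mean/sd and tracks undefined cells", {
  mk <- function(ac) data.frame(fold = 1:2, tp = 1, tn = 1, fp = 0, fn = 0,
                                Sn = 1, Sp = 1, Ac = ac, Pre = 1, MCC = 1,
                                AUC = 1)
  rep1 <- aggregate_report(list(mk(c(0.8, 0.8)), mk(c(0.8, 0.8))),
                           protocol = list(k = 2L, n_sets = 2L))
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "Ac"], 0.8)
  expect_equal(s$sd[s$metric == "Ac"], 0)
  expect_equal(nrow(rep1$cells), 4L)  # k x n_sets bookkeeping
  # two values {0.8, 1.0}: mean 0.9, sample sd 0.1414
  rep2 <- aggregate_report(list(mk(c(0.8, 1.0))))
  expect_equal(rep2$summary$mean[3], 0.9)
  expect_equal(rep2$summary$sd[3], sqrt(0.02))  # sample sd of {0.8, 1.0}
  expect_equal(rep2$summary$sd[3], 0.1414, tolerance = 1e-3)
  # undefined cells are excluded and counted
  tab <- mk(c(0.8, 1.0))
  tab$Pre <- c(NA, 0.5)
  rep3 <- aggregate_report(list(tab))
  expect_equal(rep3$summary$n_undefined[rep3$summary$metric == "Pre"], 1L)
  expect_equal(rep3$summary$mean[rep3$summary$metric == "Pre"], 0.5)
  tab$Pre <- NA_real_
  expect_error(aggregate_report(list(tab)), "undefined in every cell")
})

test_that("evaluate_balanced wires sets, folds and report together", {
  pre <- leucine_enriched_preset(c(150L, 250L))
  ds <- generate_dataset(pre$pos, pre$neg, 10, 40, seed = 101)
  pos <- ds[ds$label == 1, ]
  neg <- ds[ds$label == -1, ]
  rep <- suppressMessages(
    evaluate_balanced(pos, neg, n_sets = 2, scheme = "AAC", k = 4, seed = 5))
  expect_s3_class(rep, "evaluation_report")
  expect_equal(nrow(rep$cells), 8L)  # 2 sets x 4 folds
  expect_setequal(rep$summary$metric, c("Sn", "Sp", "Ac", "Pre", "MCC", "AUC"))
  out <- withr::local_tempfile()
  paths <- write_report(rep, out)
  expect_true(all(file.exists(paste0(out, c("_cells.csv", "_summary.csv")))))
  # LOOCV flavour
  rep2 <- suppressMessages(
    evaluate_balanced(pos, neg, n_sets = 2, scheme = "AAC", loocv = TRUE,
                      seed = 5))
  expect_equal(nrow(rep2$cells), 2L)  # one pooled row per sample set
})
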