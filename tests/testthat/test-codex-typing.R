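codex_fixture <- function(seed = 4L, n_cells = 3000L) {
  generate_codex(cfg_default(), seed = seed, n_cells = n_cells)
}

default_gates <- function() {
  list(
    Epithelial = list(list(feature = "mem_PanCytoK", op = ">=", value = 30)),
    EpithelialCDH = list(list(feature = "mem_CDH12", op = ">=", value = 30)),
    Stromal = list(list(feature = "mem_aSMA", op = ">=", value = 30)),
    CD8T = list(list(feature = "mem_CD8", op = ">=", value = 30)),
    Macrophage = list(list(feature = "mem_CD68", op = ">=", value = 30)))
}

test_that("gating labels pure planted classes and drops ambiguous cells", {
  cx <- codex_fixture()
  tr <- gate_training_set(cx$cells, default_gates())
  expect_gt(nrow(tr), 1000L)
  expect_gte(mean(tr$gated_class == tr$broad), 0.99)
  # contradictory gate yields an empty class with a warning
  bad <- c(default_gates(),
           list(Impossible = list(
             list(feature = "mem_CD8", op = ">=", value = 30),
             list(feature = "mem_CD8", op = "<=", value = 10))))
  expect_warning(tr2 <- gate_training_set(cx$cells, bad), "Impossible")
  expect_false("Impossible" %in% tr2$gated_class)
  # a cell passing two class gates is excluded as ambiguous
  two <- cx$cells[1, ]
  two$mem_CD8 <- 50; two$mem_aSMA <- 50
  both <- gate_training_set(dplyr::bind_rows(two, cx$cells[2:50, ]),
                            default_gates())
  expect_false(two$cell_id %in% both$cell_id)
})

test_that("class balancing caps at 2,500 and keeps small classes whole", {
  cells <- tibble::tibble(cell_id = seq_len(4200),
                          gated_class = rep(c("big", "small"),
                                            times = c(3000, 1200)))
  bal <- balance_classes(cells, cap = 2500, seed = 3)
  expect_equal(sum(bal$gated_class == "big"), 2500L)
  expect_equal(sum(bal$gated_class == "small"), 1200L)
  expect_identical(balance_classes(cells, cap = 2500, seed = 3),
                   balance_classes(cells, cap = 2500, seed = 3))
  expect_false(identical(balance_classes(cells, cap = 2500, seed = 4)$cell_id,
                         bal$cell_id))
})

test_that("kNN typing is accurate and matches a brute-force neighbor scan", {
  cx <- codex_fixture()
  feats <- grep("^mem_", names(cx$cells), value = TRUE)
  tr <- gate_training_set(cx$cells, default_gates())
  bal <- balance_classes(tr, cap = 400, seed = 1)
  query <- cx$cells[cx$cells$broad %in% names(default_gates()), ][1:800, ]
  pred <- knn_classify(bal, query, feats, k = 50)
  expect_gte(mean(pred == query$broad), 0.95)
  # brute-force oracle on a <= 500-cell instance
  small_tr <- bal[bal$gated_class %in% c("CD8T", "Stromal"), ][1:200, ]
  small_q <- query[1:60, ]
  got <- knn_classify(small_tr, small_q, feats, k = 15)
  trm <- as.matrix(small_tr[, feats])
  med <- apply(trm, 2, median); iqr <- apply(trm, 2, IQR); iqr[iqr == 0] <- 1
  sc <- function(m) sweep(sweep(m, 2, med, "-"), 2, iqr, "/")
  trs <- sc(trm); qus <- sc(as.matrix(small_q[, feats]))
  labs <- sort(unique(small_tr$gated_class))
  for (i in seq_len(nrow(qus))) {
    d <- sqrt(rowSums((trs - matrix(qus[i, ], nrow(trs), ncol(trs),
                                    byrow = TRUE))^2))
    nb <- order(d)[1:15]
    votes <- table(factor(small_tr$gated_class[nb], levels = labs))
    expect_equal(got[i], labs[which.max(votes)])
  }
})

test_that("k = 1 on a training point returns its own label", {
  cx <- codex_fixture(n_cells = 500L)
  feats <- grep("^mem_", names(cx$cells), value = TRUE)
  tr <- cx$cells
  tr$gated_class <- tr$broad
  pred <- knn_classify(tr, tr[17, ], feats, k = 1)
  expect_equal(pred, tr$broad[17])
})

test_that("rescue voting is majoritarian, reproducible and rejects immune labels", {
  cx <- codex_fixture()
  feats <- grep("^mem_", names(cx$cells), value = TRUE)
  pool <- cx$cells
  pool$gated_class <- pool$broad
  # cells surrounded (in feature space) by one subtype win all rounds
  q_epi <- cx$cells[cx$cells$broad == "Epithelial", ][1:20, ]
  res <- rescue_classify(q_epi, pool, feats, rounds = 10, per_class = 300,
                         k = 20, seed = 5)
  expect_true(all(res$label == "Epithelial"))
  expect_true(all(vapply(res$votes, function(v) all(v == "Epithelial"),
                         logical(1))))
  # immune rescues are rejected, not relabeled
  q_cd8 <- cx$cells[cx$cells$broad == "CD8T", ][1:20, ]
  rej <- rescue_classify(q_cd8, pool, feats, rounds = 10, per_class = 300,
                         k = 20, seed = 5,
                         reject_classes = c("CD8T", "CD4T", "Macrophage",
                                            "Bcell"))
  expect_true(all(rej$removed))
  expect_true(all(is.na(rej$label)))
  # per-round ballots match recomputing each round through the public API
  res2 <- rescue_classify(q_epi, pool, feats, rounds = 3, per_class = 300,
                          k = 20, seed = 9)
  for (r in 1:3) {
    train <- balance_classes(pool, class_col = "gated_class", cap = 300,
                             seed = nichemap:::derive_seed(9, r))
    expect_equal(vapply(res2$votes, `[[`, character(1), r),
                 knn_classify(train, q_epi, feats, k = 20))
  }
})
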