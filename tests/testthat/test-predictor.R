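test_that("the architecture obeys its dimensional contract", {
  fc <- feature_config(hotspot_length = 9L)
  cfg <- test_model_config()
  m <- build_model(cfg, fc)
  # one conv weight block per kernel size, sized kernel*dim x filters
  for (k in cfg$kernel_sizes)
    expect_equal(dim(m$params[[paste0("Wconv", k)]]),
                 c(k * 20L, cfg$filters_per_kernel))
  # concatenation width = filters * kernels + scalar branch
  concat <- cfg$filters_per_kernel * length(cfg$kernel_sizes) + cfg$scalar_units
  expect_equal(dim(m$params$Wdense1), c(concat, cfg$dense_units[1L]))
  expect_equal(dim(m$params$Wout), c(cfg$dense_units[2L], 1L))
  # kernels wider than the hotspot are rejected
  expect_error(build_model(cfg, feature_config(hotspot_length = 5L)),
               "kernel")
  # published defaults are preserved
  d <- presentation_model_config()
  expect_equal(d$kernel_sizes, c(1L, 3L, 5L, 7L))
  expect_equal(d$dense_units, c(2000L, 256L))
  expect_equal(d$learning_rate, 1e-5)
  expect_equal(d$weight_decay, 1e-6)
  expect_equal(d$dropout, 0.1)
  expect_equal(d$batch_size, 50L)
  expect_equal(d$folds, 10L)
})

test_that("an all-zero network scores exactly one half", {
  fc <- feature_config(hotspot_length = 9L)
  m <- build_model(test_model_config(), fc)
  m$params <- lapply(m$params, function(p) p * 0)
  d <- data.frame(peptide = c("SIINFEKL", "AAYNFPTMA"),
                  rank_percent = c(0.5, 80), stringsAsFactors = FALSE)
  expect_equal(predict_presentation(m, d)$score, c(0.5, 0.5))
})

test_that("ROC-AUC equals pairwise concordance, ties included", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(100:1000, 1L)
    y <- rbinom(n, 1L, 0.3)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
    s <- rnorm(n) + y
    if (i > 2) s <- round(s, 1)  # force ties
    expect_equal(roc_auc(y, s), auc_concordance_oracle(y, s),
                 tolerance = 1e-9)
  }
  expect_error(roc_auc(rep(1, 5), 1:5), "both classes")
})

test_that("ROC and PR AUC agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rbinom(400, 1L, 0.25)
  s <- rnorm(400) + 1.2 * y
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(y, s, quiet = TRUE, direction = "<")),
               tolerance = 1e-9)
  # perfect and inverted separations hit the endpoints
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(4, 3, 2, 1)), 0)
  expect_equal(pr_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
})

test_that("decoy generation is ratio-exact, disjoint and reproducible", {
  set.seed(6)
  positives <- vapply(sample(8:11, 60, replace = TRUE), random_peptide,
                      character(1L))
  proteome <- setNames(vapply(rep(3000L, 4L), random_peptide, character(1L)),
                       paste0("r", 1:4))
  d1 <- generate_decoys(positives, proteome, 10L, seed = 101)
  expect_length(d1, 600L)
  expect_equal(sort(nchar(d1)), sort(rep(nchar(positives), 10L)))
  expect_false(any(d1 %in% positives))
  # every decoy is a substring of the proteome
  hay <- paste(proteome, collapse = "\x01")
  expect_true(all(vapply(d1[1:50], grepl, logical(1L), x = hay, fixed = TRUE)))
  d2 <- generate_decoys(positives, proteome, 10L, seed = 101)
  expect_identical(d1, d2)
  expect_identical(generate_decoys(positives, proteome, 0L, seed = 1),
                   character(0L))
  # positives embedded verbatim in the source still yield disjoint decoys
  emb <- c(proteome, emb = paste(positives, collapse = ""))
  d3 <- generate_decoys(positives, emb, 2L, seed = 5)
  expect_false(any(d3 %in% positives))
})

test_that("cross-validation recovers a planted motif and respects folds", {
  fc <- feature_config(hotspot_length = 11L)
  ms <- motif_spec(anchors = c("2" = "Y", "5" = "L"), lengths = 8:11,
                   n_positive = 120L, decoy_ratio = 5L)
  ds <- make_presentation_dataset(ms, proteome_size = 20000L, seed = 42)
  cfg <- test_model_config(seed = 1L, folds = 5L)
  cv <- train_cv(ds$data, cfg, fc)
  expect_gte(cv$report$pooled_roc_auc, 0.95)
  # folds partition the data and are stratified
  expect_equal(sort(unique(cv$report$fold_assignments)), 1:5)
  expect_length(cv$report$fold_assignments, nrow(ds$data))
  per_fold_pos <- tapply(ds$data$label, cv$report$fold_assignments, sum)
  expect_true(all(abs(per_fold_pos - mean(per_fold_pos)) <= 1))
  expect_error(train_cv(ds$data[ds$data$label == 1L, ], cfg, fc),
               "both labels")
})

test_that("training and scoring are deterministic under a fixed seed", {
  fc <- feature_config(hotspot_length = 11L)
  ms <- motif_spec(n_positive = 40L, decoy_ratio = 2L)
  ds <- make_presentation_dataset(ms, proteome_size = 8000L, seed = 9)
  cfg <- test_model_config(seed = 33L, epochs = 4L)
  m1 <- fit_presentation_model(ds$data, cfg, fc)
  m2 <- fit_presentation_model(ds$data, cfg, fc)
  p1 <- predict_presentation(m1, ds$data)
  p2 <- predict_presentation(m2, ds$data)
  expect_identical(p1$score, p2$score)
  # duplicate rows get identical scores; order is preserved
  dup <- ds$data[c(1L, 1L, 2L, 2L), ]
  pd <- predict_presentation(m1, dup)
  expect_equal(pd$score[1L], pd$score[2L])
  expect_equal(pd$score[3L], pd$score[4L])
  expect_identical(pd$peptide, dup$peptide)
  # empty input yields empty output
  expect_equal(nrow(predict_presentation(m1, ds$data[0L, ])), 0L)
  # over-long peptides are rejected without a core policy
  long <- data.frame(peptide = random_peptide(15L), rank_percent = 1)
  expect_error(predict_presentation(m1, long), "core-extraction")
})

test_that("binder calling is monotone in both thresholds", {
  set.seed(44)
  scored <- data.frame(
    peptide = vapply(rep(9L, 50L), random_peptide, character(1L)),
    mhc_class = sample(c("I", "II"), 50L, replace = TRUE),
    rank_percent = c(runif(40, 0.1, 30), rep(NA, 10)),
    score = runif(50), stringsAsFactors = FALSE)
  all_kept <- call_binders(scored, 0, 100)
  expect_equal(nrow(all_kept$candidates), 50L)
  expect_equal(sum(all_kept$counts), 50L)
  none <- call_binders(scored, 1 + 1e-9, 100)
  expect_equal(nrow(none$candidates), 0L)
  # missing rank passes the rank filter
  na_only <- call_binders(scored, 0, 1e-6)
  expect_true(all(is.na(na_only$candidates$rank_percent)))
  prev <- Inf
  for (thr in c(0, 0.25, 0.5, 0.75, 1)) {
    n <- nrow(call_binders(scored, thr, 100)$candidates)
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (rt in c(100, 30, 10, 1)) {
    n <- nrow(call_binders(scored, 0, rt)$candidates)
    expect_lte(n, prev)
    prev <- n
  }
})
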