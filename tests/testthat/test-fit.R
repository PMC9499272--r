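# shared tiny training fixture: two well-separated motif classes
fit_fixture <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- generate_peptides(synth_spec(c(ABP = 30, ACP = 30), seed = 61,
                                          length_range = c(8, 16)))
    }
    ds
  }
})

test_that("training reduces the loss and records the class weights it used", {
  ds <- fit_fixture()
  cfg <- tiny_config(n_labels = 2, L = 16)
  fit <- mfpnet(ds$records, ds$vocab, cfg, epochs = 15, lr = 3e-3, seed = 2)
  expect_lt(fit$loss[15], fit$loss[1])
  enc <- encode_peptides(ds$records, ds$vocab, L = 16)
  counts <- colSums(enc$labels)
  expect_equal(as.numeric(fit$class_weights),
               as.numeric(cw_weights(counts, nrow(enc$labels))))
  expect_equal(unname(fit$counts), unname(counts))
})

test_that("fits are bitwise identical under the same seed", {
  ds <- fit_fixture()
  cfg <- tiny_config(n_labels = 2, L = 16, dropout = 0.3)
  f1 <- mfpnet(ds$records, ds$vocab, cfg, epochs = 4, seed = 11)
  f2 <- mfpnet(ds$records, ds$vocab, cfg, epochs = 4, seed = 11)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss, f2$loss)
  f3 <- mfpnet(ds$records, ds$vocab, cfg, epochs = 4, seed = 12)
  expect_false(identical(f3$params, f1$params))
})

test_that("predict returns labelled probabilities and thresholded calls", {
  ds <- fit_fixture()
  cfg <- tiny_config(n_labels = 2, L = 16)
  fit <- mfpnet(ds$records, ds$vocab, cfg, epochs = 2, seed = 1)
  pr <- predict(fit, ds$records[1:5, ])
  expect_equal(dim(pr), c(5L, 2L))
  expect_equal(colnames(pr), unclass(ds$vocab))
  expect_true(all(pr > 0 & pr < 1))
  lb <- predict(fit, ds$records[1:5, ], type = "label", threshold = 0.5)
  expect_equal(lb, (pr >= 0.5) + 0L)
})

test_that("S3 surface (print, summary, coef, plot) works on a fit", {
  ds <- fit_fixture()
  fit <- mfpnet(ds$records, ds$vocab, tiny_config(n_labels = 2, L = 16),
                epochs = 2, seed = 1)
  expect_output(print(fit), "mfpnet")
  expect_output(summary(fit), "weight")
  expect_type(coef(fit), "list")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("an ensemble of identical members equals one member; averaging is exact", {
  ds <- fit_fixture()
  cfg <- tiny_config(n_labels = 2, L = 16)
  ens <- train_ensemble(ds$records, ds$vocab, cfg, n_models = 3,
                        seeds = c(7, 7, 7), epochs = 2)
  single <- mfpnet(ds$records, ds$vocab, cfg, epochs = 2, seed = 7)
  expect_equal(predict(ens, ds$records[1:4, ]),
               predict(single, ds$records[1:4, ]), tolerance = 1e-12)
  ens2 <- train_ensemble(ds$records, ds$vocab, cfg, n_models = 2,
                         seeds = c(3, 9), epochs = 2)
  p1 <- predict(ens2$fits[[1]], ds$records[1:4, ])
  p2 <- predict(ens2$fits[[2]], ds$records[1:4, ])
  expect_equal(predict(ens2, ds$records[1:4, ]), (p1 + p2) / 2,
               tolerance = 1e-12)
  # averaging commutes with sample permutation
  perm <- c(3, 1, 4, 2)
  expect_equal(predict(ens2, ds$records[perm, ]),
               predict(ens2, ds$records[1:4, ])[perm, ],
               tolerance = 1e-12)
  # mismatched member vocabularies are rejected
  broken <- ens2
  broken$fits[[2]]$vocab <- label_vocab(c("QSP", "SBP"))
  expect_error(predict(broken, ds$records[1:2, ]), "mismatched")
})

test_that("grid search returns per-fold reports and prefers the trained model", {
  ds <- generate_peptides(synth_spec(c(ABP = 40, ACP = 40), seed = 91,
                                     length_range = c(8, 16)))
  gs <- grid_search_cv(ds$records, ds$vocab,
                       grid = list(list(epochs = 0),
                                   list(epochs = 30, lr = 3e-3)),
                       folds = 3, seed = 5, batch_size = 16,
                       embed_dim = 5, kernel_sizes = c(2, 3), filters = 4,
                       hidden = 4, heads = 2, d_k = 3, dropout = 0, L = 16)
  expect_equal(nrow(gs$table), 2L)
  expect_length(gs$fold_reports[[1]], 3L)
  expect_equal(gs$best_index, 2L)
  expect_gt(gs$table$accuracy[2], gs$table$accuracy[1])
})

test_that("a single grid point is returned as best with full fold reports", {
  ds <- fit_fixture()
  gs <- grid_search_cv(ds$records, ds$vocab,
                       grid = list(list(epochs = 1)), folds = 2, seed = 2,
                       embed_dim = 5, kernel_sizes = c(2, 3), filters = 4,
                       hidden = 4, heads = 2, d_k = 3, dropout = 0, L = 16)
  expect_equal(gs$best_index, 1L)
  expect_length(gs$fold_reports[[1]], 2L)
})

test_that("ablations share seeds, disable one stage each, and report t-tests", {
  ds <- generate_peptides(synth_spec(c(ABP = 40, ACP = 30), seed = 111,
                                     length_range = c(8, 16)))
  sp <- split_train_test(ds$records, ratio = 0.75, seed = 1)
  ab <- run_ablation(sp$train, sp$test, ds$vocab,
                     variants = c("no_mhsa", "no_cw"),
                     config = tiny_config(n_labels = 2, L = 16),
                     seed = 3, epochs = 3, reps = 3)
  expect_equal(ab$table$model, c("full", "no_mhsa", "no_cw"))
  expect_equal(as.numeric(ab$fits$no_cw$class_weights), c(1, 1))
  expect_equal(ab$fits$full$weight_scheme, "cw")
  expect_false(ab$fits$no_mhsa$config$use_mhsa)
  expect_true(all(c("p_accuracy", "stars") %in% names(ab$table)))
  # empty variant list -> table with the full model only
  ab0 <- run_ablation(sp$train, sp$test, ds$vocab, variants = character(),
                      config = tiny_config(n_labels = 2, L = 16),
                      seed = 3, epochs = 1, reps = 2)
  expect_equal(ab0$table$model, "full")
  expect_error(run_ablation(sp$train, sp$test, ds$vocab,
                            variants = "no_dropout",
                            config = tiny_config(n_labels = 2, L = 16)),
               "unknown variant")
})

test_that("class weights are computed from the training split only", {
  ds <- generate_peptides(synth_spec(c(ABP = 40, ACP = 20), seed = 121,
                                     length_range = c(8, 16)))
  sp <- split_train_test(ds$records, ratio = 0.8, seed = 9)
  cfg <- tiny_config(n_labels = 2, L = 16)
  fit <- mfpnet(sp$train, ds$vocab, cfg, epochs = 1, seed = 1)
  enc_tr <- encode_peptides(sp$train, ds$vocab, L = 16)
  expect_equal(as.numeric(fit$class_weights),
               as.numeric(cw_weights(colSums(enc_tr$labels),
                                     nrow(enc_tr$labels))))
  expect_equal(fit$n_train, nrow(sp$train))
})

test_that("loss stays finite even when predictions saturate", {
  # clipping keeps the weighted BCE finite at probabilities of exactly 0/1,
  # so aggressive learning rates degrade gracefully instead of overflowing
  ds <- fit_fixture()
  cfg <- tiny_config(n_labels = 2, L = 16)
  fit <- mfpnet(ds$records, ds$vocab, cfg, epochs = 2, lr = 50, seed = 1)
  expect_true(all(is.finite(fit$loss)))
})

test_that("a class absent from training gets zero weight with a warning", {
  recs <- peptide_set(c("a", "b"), c("AAAAAAA", "CCCCCCC"),
                      list("ABP", "ABP"))
  vocab <- label_vocab(c("ABP", "ACP"))
  cfg <- tiny_config(n_labels = 2, L = 8)
  w <- capture_warnings(fit <- mfpnet(recs, vocab, cfg, epochs = 1, seed = 1))
  expect_true(any(grepl("no training instances", w)))
  expect_equal(unname(fit$class_weights[["ACP"]]), 0)
})
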