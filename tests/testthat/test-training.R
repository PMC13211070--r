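# Two-phase training protocol: loss identities, scheduler contract, teacher
# freezing, descent on a small separable task, and ablation-variant wiring.

test_that("cross-entropy identities: one-hot zero, uniform ln K, monotone sweep", {
  expect_equal(cross_entropy(c(0, 1, 0), 2L), 0, tolerance = 1e-12)
  expect_equal(cross_entropy(rep(1 / 9, 9L), 5L), log(9), tolerance = 1e-12)
  p_seq <- seq(0.05, 0.95, by = 0.05)
  ces <- vapply(p_seq, function(p) cross_entropy(c(p, 1 - p), 1L), 1)
  expect_true(all(diff(ces) < 0))
  expect_error(cross_entropy(c(0.5, 0.5), 3L), "out of range")
  # batch averaging
  p <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy(p, c(1L, 2L)),
               mean(-log(c(0.9, 0.8))), tolerance = 1e-12)
})

test_that("the total loss is the weighted sum of its parts", {
  expect_equal(total_loss(0.5, 2.0, alpha = 1), 2.5)
  expect_equal(total_loss(0.5, 2.0, alpha = 2), 4.5)
  expect_equal(total_loss(0.7, 3.0, alpha = 0), 0.7)
  expect_error(total_loss(1, 1, alpha = -1), "non-negative")
})

test_that("the plateau schedule halves after exactly 5 flat epochs and floors at lr_min", {
  cfg <- train_config()
  hist <- c(1.0, 0.9, 0.95, 0.96, 0.97, 0.98, 0.99)
  # 4 non-improving epochs: unchanged; 5th: halved
  expect_equal(plateau_scheduler(hist[1:6], 1e-4, cfg), 1e-4)
  expect_equal(plateau_scheduler(hist, 1e-4, cfg), 5e-5)
  expect_equal(plateau_scheduler(seq(1, 0.1, length.out = 8), 1e-4, cfg), 1e-4)
  expect_equal(plateau_scheduler(rep(1, 30), 1e-7, cfg), 1e-7)
  expect_equal(plateau_scheduler(rep(1, 6), 1.5e-7, cfg), 1e-7)
})

test_that("teacher pretraining descends on a separable two-class task and freezes", {
  data <- tiny_dataset(seed = 2L)
  cfg <- train_config(epochs = 3L, batch_size = 4L, lr_init = 1e-3, seed = 1L)
  teacher <- pretrain_teacher(data$train, data$val, cfg, spec = tiny_spec(12L))
  expect_s3_class(teacher, "ecg_teacher")
  expect_true(teacher$frozen)
  expect_lt(utils::tail(teacher$log$ce, 1L), teacher$log$ce[1L])
  expect_match(teacher$hash, "^[0-9a-f]{32}$")
  # hash reflects the weights actually stored
  expect_identical(weights_hash(teacher[c("extractor", "classifier")]),
                   teacher$hash)
  # deterministic re-run reproduces the weights bit for bit
  teacher2 <- pretrain_teacher(data$train, data$val, cfg, spec = tiny_spec(12L))
  expect_identical(teacher2$hash, teacher$hash)
  expect_error(pretrain_teacher(data$train, data$val, cfg,
                                spec = tiny_spec(1L)), "12-lead")
})

test_that("phase 2 trains the full variant, logs consistent losses and never touches the teacher", {
  data <- tiny_dataset(seed = 3L)
  tcfg <- train_config(epochs = 2L, batch_size = 4L, lr_init = 1e-3, seed = 1L)
  teacher <- pretrain_teacher(data$train, data$val, tcfg, spec = tiny_spec(12L))
  hash_before <- teacher$hash

  cfg <- train_config(epochs = 3L, batch_size = 4L, lr_init = 1e-3, seed = 2L,
                      variant = "full", alpha = 1.0)
  fit <- train_slfr(data$train, data$val, teacher, cfg, lead = 1L,
                    student_spec = tiny_spec(1L))
  expect_s3_class(fit, "slfr_model")
  # bookkeeping identity every epoch
  expect_lt(max(abs(fit$log$l_total - (fit$log$l1 + cfg$alpha * fit$log$ce))),
            1e-6)
  # teacher untouched by the whole phase
  expect_identical(weights_hash(teacher[c("extractor", "classifier")]),
                   hash_before)
  # validation alignment loss decreases from the first epoch
  expect_lt(utils::tail(fit$log$val_l1, 1L), fit$log$val_l1[1L])
  # prediction surface
  probs <- predict(fit, data$test)
  expect_equal(dim(probs), c(length(data$test), 2L))
  expect_equal(rowSums(probs), rep(1, length(data$test)), tolerance = 1e-6)
  cls <- predict(fit, data$test, type = "class")
  expect_true(all(cls %in% 1:2))
})

test_that("alpha = 0 silences the cross-entropy path: classifier gradients vanish", {
  data <- tiny_dataset(seed = 4L, n_patients = 4L)
  ag <- asNamespace("slecg")
  set.seed(9)
  mod <- ag$student_modules("full", 16L, 2L, tiny_spec(1L),
                            recon_spec(16L, n_heads = 2L, ffn_mult = 2L,
                                       dropout = 0),
                            fusion_spec(16L, n_heads = 2L, ffn_mult = 2L,
                                        dropout = 0))
  r <- data$train[[1L]]
  f_full <- matrix(stats::rnorm(prod(dim(extract(r$signal[1, , drop = FALSE],
                                                 mod$student)))),
                   ncol = 16L)
  ag$ag_reset()
  fwd <- ag$student_forward(ag$as_node(t(r$signal[1L, , drop = FALSE])),
                            r$label, f_full, mod, "full", "L1",
                            alpha = 0, training = TRUE)
  ag$ag_backward(fwd$total)
  clf_grads <- lapply(ag$collect_params(mod$classifier), function(p) p$grad)
  expect_true(all(vapply(clf_grads, function(g) is.null(g) || all(g == 0),
                         TRUE)))
  # the reconstruction module still learns
  rec_grads <- ag$collect_params(mod$recon)
  expect_gt(max(vapply(rec_grads, function(p)
    if (is.null(p$grad)) 0 else max(abs(p$grad)), 1)), 0)
})

test_that("variant wiring: baseline has no teacher modules, supervise_only no reconstruction", {
  data <- tiny_dataset(seed = 5L, n_patients = 6L)
  cfg <- train_config(epochs = 1L, batch_size = 4L, lr_init = 1e-3, seed = 1L,
                      variant = "baseline_single")
  base <- train_slfr(data$train, data$val, teacher = NULL, cfg, lead = 1L,
                     student_spec = tiny_spec(1L))
  expect_null(base$recon)
  expect_null(base$fusion)
  expect_true(is.na(base$teacher_hash))
  expect_true(all(base$log$l1 == 0))

  tcfg <- train_config(epochs = 1L, batch_size = 4L, lr_init = 1e-3, seed = 1L)
  teacher <- pretrain_teacher(data$train, data$val, tcfg, spec = tiny_spec(12L))
  cfg$variant <- "supervise_only"
  sup <- train_slfr(data$train, data$val, teacher, cfg, lead = 1L,
                    student_spec = tiny_spec(1L))
  expect_null(sup$recon)
  expect_null(sup$fusion)
  expect_gt(utils::tail(sup$log$l1, 1L), 0)

  cfg$variant <- "no_fusion"
  nf <- train_slfr(data$train, data$val, teacher, cfg, lead = 1L,
                   student_spec = tiny_spec(1L))
  expect_null(nf$fusion)
  expect_false(is.null(nf$recon))

  # guard rails
  cfg$variant <- "full"
  expect_error(train_slfr(data$train, data$val, teacher = NULL, cfg),
               "requires a pretrained teacher")
  unfrozen <- teacher
  unfrozen$frozen <- FALSE
  expect_error(train_slfr(data$train, data$val, unfrozen, cfg),
               "frozen")
  expect_error(train_slfr(data$train, data$val, teacher, cfg, lead = 13L),
               "lead index out of range")
})

test_that("model methods print, summarize, plot and expose classifier coefficients", {
  data <- tiny_dataset(seed = 6L, n_patients = 6L)
  cfg <- train_config(epochs = 1L, batch_size = 4L, lr_init = 1e-3, seed = 1L,
                      variant = "baseline_single")
  fit <- train_slfr(data$train, data$val, NULL, cfg, lead = 1L,
                    student_spec = tiny_spec(1L))
  expect_output(print(fit), "baseline_single")
  expect_output(summary(fit), "parameters")
  co <- coef(fit)
  expect_equal(dim(co$w_pred), c(32L, 2L))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
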