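# Two-phase training: Phase 1 pretrains the 12-lead teacher and freezes it;
# Phase 2 trains the single-lead network (extractor + reconstruction +
# fusion + classifier) under L_total = L_align + alpha * L_CE, with the
# frozen teacher's feature maps as the alignment target.

#' Training configuration
#'
#' @param epochs Training epochs (the full-scale default is 120; desk runs
#'   use far fewer).
#' @param batch_size Records per optimization step (full-scale default 128).
#' @param lr_init,lr_min Initial and floor learning rates (1e-4, 1e-7).
#' @param plateau_patience Consecutive non-improving epochs before the
#'   learning rate is halved (5).
#' @param lr_factor Multiplier applied on plateau (0.5).
#' @param alpha Weight of the cross-entropy term in the total loss. The
#'   originating method leaves this weight unreported; 1.0 is this package's
#'   default and it is deliberately exposed here.
#' @param stop_after_halvings Convergence-based early stopping: training
#'   ends once the plateau schedule has reduced the learning rate this many
#'   times (the monitored loss has then repeatedly stopped improving), or at
#'   `epochs`, whichever comes first. `Inf` disables early stopping. This is
#'   the desk-scale analogue of training every variant to convergence under
#'   a long epoch budget; slower-converging variants automatically receive
#'   more epochs, up to the cap.
#' @param seed Integer seed; fixes initialization, sampling, dropout.
#' @param variant One of `"full"` (reconstruction + fusion),
#'   `"supervise_only"` (align the single-lead features themselves to the
#'   teacher, no reconstruction module, no fusion), `"no_fusion"`
#'   (reconstruction, classify the reconstructed map directly),
#'   `"baseline_single"` (cross-entropy only, no teacher), or
#'   `"teacher_12lead"` (the 12-lead model itself).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 120L, batch_size = 128L, lr_init = 1e-4,
                         lr_min = 1e-7, plateau_patience = 5L, lr_factor = 0.5,
                         alpha = 1.0, stop_after_halvings = Inf, seed = 1L,
                         variant = c("full", "supervise_only", "no_fusion",
                                     "baseline_single", "teacher_12lead")) {
  variant <- match.arg(variant)
  if (lr_min > lr_init) stop("lr_min must not exceed lr_init")
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must be in (0, 1)")
  if (alpha < 0) stop("alpha must be non-negative")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_min = lr_min,
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor, alpha = alpha,
                 stop_after_halvings = stop_after_halvings,
                 seed = as.integer(seed), variant = variant),
            class = "train_config")
}

# has the schedule halved often enough to call the run converged?
converged_by_schedule <- function(lr, config) {
  is.finite(config$stop_after_halvings) &&
    lr <= config$lr_init * config$lr_factor^config$stop_after_halvings + 1e-15
}

#' Multi-class cross-entropy
#'
#' `-log p[label]`, averaged over the batch. Labels are 1-based class
#' indices.
#'
#' @param p_pred Probability vector (one sample) or `n x K` matrix.
#' @param label Integer label(s) in `1..K`.
#' @return Mean negative log-likelihood.
#' @examples
#' cross_entropy(rep(1 / 9, 9), 3)  # log(9)
#' @export
cross_entropy <- function(p_pred, label) {
  if (!is.matrix(p_pred)) p_pred <- matrix(p_pred, nrow = 1L)
  k <- ncol(p_pred)
  if (any(label < 1L | label > k)) stop("label out of range 1..", k)
  -mean(log(p_pred[cbind(seq_len(nrow(p_pred)), label)]))
}

#' Total training loss
#'
#' The weighted sum `L_align + alpha * L_CE` of the feature-alignment loss
#' and the classification cross-entropy.
#'
#' @param l1_value Alignment-loss value.
#' @param ce_value Cross-entropy value.
#' @param alpha Non-negative weight of the cross-entropy term.
#' @return `l1_value + alpha * ce_value`.
#' @export
total_loss <- function(l1_value, ce_value, alpha = 1.0) {
  if (alpha < 0) stop("alpha must be non-negative")
  l1_value + alpha * ce_value
}

#' Plateau learning-rate schedule
#'
#' Halves the learning rate (multiplies by `lr_factor`) whenever the
#' monitored loss has not improved on its running best for
#' `plateau_patience` consecutive epochs (the counter resets on every
#' strict improvement), and never lets it drop below `lr_min`.
#'
#' @param loss_history Numeric vector of the monitored loss, one entry per
#'   completed epoch (latest last).
#' @param lr Current learning rate.
#' @param config A [train_config()].
#' @return The learning rate to use next epoch.
#' @export
plateau_scheduler <- function(loss_history, lr, config = train_config()) {
  n <- length(loss_history)
  if (n >= 2L) {
    best <- cummin(loss_history)
    improved <- c(TRUE, diff(best) < 0)
    streak <- n - max(which(improved))
    if (streak > 0L && streak %% config$plateau_patience == 0L) {
      lr <- lr * config$lr_factor
    }
  }
  max(lr, config$lr_min)
}

#' Content hash of a model's weights
#'
#' MD5 over the serialized parameter values and batch-norm running
#' statistics. Used to certify that the frozen teacher never changes during
#' Phase 2.
#'
#' @param x Any parameter tree (teacher, student, module).
#' @return A 32-character hex string.
#' @export
weights_hash <- function(x) {
  vals <- list(p = params_snapshot(collect_params(x)),
               bn = lapply(collect_bn_states(x), function(s)
                 list(s$running_mean, s$running_var)))
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(vals, f, compress = FALSE)
  unname(tools::md5sum(f))
}

# ---- internal helpers ----

records_signal_check <- function(records, leads) {
  if (length(records) == 0L) {
    stop("empty record set: with very few patients the 7:1:2 patient-level ",
         "split can leave a partition empty; use more patients")
  }
  for (r in records) {
    if (nrow(r$signal) != leads) {
      stop("records must carry ", leads, " lead(s); found ", nrow(r$signal))
    }
    if (ncol(r$signal) %% 64L != 0L) {
      stop("record length must be divisible by 64; run preprocess_records()")
    }
  }
  invisible(NULL)
}

labels_of <- function(records) vapply(records, function(r) r$label, 1L)

# evaluation-mode class probabilities for a generic forward closure
eval_probs <- function(records, fwd_one) {
  do.call(rbind, lapply(records, function(r) fwd_one(r)))
}

# ---- Phase 1: teacher ----

#' Pretrain the 12-lead teacher
#'
#' Trains the 12-lead feature extractor plus classifier head with
#' cross-entropy under class-balanced sampling and the plateau learning-rate
#' schedule; keeps the epoch checkpoint with the best validation macro-F1,
#' then freezes the model and records its weight hash.
#'
#' @param train_records,val_records Preprocessed 12-lead `ecg_record` lists
#'   (see [preprocess_records()]).
#' @param config A [train_config()].
#' @param spec An [extractor_spec()] with `in_leads = 12`.
#' @return An object of class `ecg_teacher`: frozen extractor + classifier,
#'   its architecture spec, the weight `hash`, the class count and the
#'   epoch log.
#' @export
pretrain_teacher <- function(train_records, val_records,
                             config = train_config(),
                             spec = extractor_spec(in_leads = 12L,
                                                   small_profile = TRUE)) {
  if (spec$in_leads != 12L) stop("the teacher is a 12-lead model")
  records_signal_check(train_records, 12L)
  records_signal_check(val_records, 12L)
  y_train <- labels_of(train_records)
  y_val <- labels_of(val_records)
  k <- max(c(y_train, y_val))
  if (k < 2L) stop("need at least 2 classes")

  log_rows <- list()
  withr::with_seed(config$seed, {
    extractor <- extractor_init(spec)
    classifier <- classifier_init(spec$d_model, k)
    params <- c(collect_params(extractor), collect_params(classifier))
    opt <- new.env(); opt$t <- 0L
    sampler <- balanced_sampler(y_train, seed = config$seed + 1000003L)
    lr <- config$lr_init
    best <- list(f1 = -Inf, snap = NULL, epoch = 0L)
    val_hist <- numeric(0)
    steps <- max(1L, nrow_steps(length(train_records), config$batch_size))

    for (epoch in seq_len(config$epochs)) {
      ce_sum <- 0
      for (s in seq_len(steps)) {
        idx <- sampler(config$batch_size)
        for (i in idx) {
          r <- train_records[[i]]
          ag_reset()
          f <- fwd_extract(as_node(t(r$signal)), extractor, training = TRUE)
          p <- fwd_classify(f, classifier)
          ce <- ag_scale(ag_log(ag_cols(p, r$label)), -1)
          ag_backward(ce)
          ce_sum <- ce_sum + ce$value[1L]
        }
        adam_step(params, lr, opt, grad_scale = 1 / length(idx))
        zero_grads(params)
      }
      ag_reset()
      probs <- eval_probs(val_records, function(r)
        ag_no_grad(fwd_classify(fwd_extract(as_node(t(r$signal)), extractor,
                                            training = FALSE),
                                classifier))$value)
      m <- compute_metrics(y_val, probs)
      val_ce <- cross_entropy(probs, y_val)
      train_ce <- ce_sum / (steps * config$batch_size)
      log_rows[[epoch]] <- data.frame(epoch = epoch, ce = train_ce,
                                      lr = lr, val_ce = val_ce,
                                      val_acc = m$accuracy,
                                      val_macro_f1 = m$macro_f1)
      if (m$macro_f1 > best$f1) {
        best <- list(f1 = m$macro_f1,
                     snap = list(ext = model_snapshot(extractor),
                                 clf = model_snapshot(classifier)),
                     epoch = epoch)
      }
      val_hist <- c(val_hist, val_ce)
      lr <- plateau_scheduler(val_hist, lr, config)
      if (converged_by_schedule(lr, config)) break
    }
    if (!is.null(best$snap)) {
      model_restore(extractor, best$snap$ext)
      model_restore(classifier, best$snap$clf)
    }
  })
  teacher <- structure(list(extractor = extractor, classifier = classifier,
                            spec = spec, n_classes = k, frozen = TRUE,
                            hash = NA_character_,
                            log = do.call(rbind, log_rows),
                            best_epoch = best$epoch, config = config),
                       class = "ecg_teacher")
  teacher$hash <- weights_hash(teacher[c("extractor", "classifier")])
  teacher
}

nrow_steps <- function(n, batch) max(1L, as.integer(floor(n / batch)))

#' @export
print.ecg_teacher <- function(x, ...) {
  cat("Frozen 12-lead teacher |", x$n_classes, "classes | d_model",
      x$spec$d_model, "| best epoch", x$best_epoch,
      sprintf("(val macro-F1 %.3f)", max(x$log$val_macro_f1)), "\n")
  cat("weight hash:", x$hash, "\n")
  invisible(x)
}

#' Predict class probabilities with the frozen teacher
#' @param object An `ecg_teacher`.
#' @param records Preprocessed 12-lead records.
#' @param ... Unused.
#' @return An `n x K` probability matrix.
#' @export
predict.ecg_teacher <- function(object, records, ...) {
  records_signal_check(records, 12L)
  eval_probs(records, function(r)
    ag_no_grad(fwd_classify(fwd_extract(as_node(t(r$signal)), object$extractor,
                                        training = FALSE),
                            object$classifier))$value)
}

# ---- Phase 2: single-lead network ----

student_modules <- function(variant, d_model, k, student_spec, rspec, fspec) {
  list(student = extractor_init(student_spec),
       recon = if (variant %in% c("full", "no_fusion")) recon_init(rspec),
       fusion = if (variant == "full") fusion_init(fspec),
       classifier = classifier_init(d_model, k))
}

# one training-mode forward; returns nodes (total, ce) and the alignment value
student_forward <- function(x_node, label, f_full, mod, variant, loss_kind,
                            alpha, training = TRUE) {
  f_single <- fwd_extract(x_node, mod$student, training = training)
  align <- NULL
  feat <- switch(variant,
    full = {
      f_rec <- fwd_reconstruct(f_single, mod$recon, training = training)
      align <- fwd_recon_loss(f_rec, f_full, loss_kind)
      fwd_fuse(f_rec, f_single, mod$fusion, training = training)
    },
    supervise_only = {
      align <- fwd_recon_loss(f_single, f_full, loss_kind)
      f_single
    },
    no_fusion = {
      f_rec <- fwd_reconstruct(f_single, mod$recon, training = training)
      align <- fwd_recon_loss(f_rec, f_full, loss_kind)
      f_rec
    },
    baseline_single = f_single)
  p <- fwd_classify(feat, mod$classifier)
  ce <- ag_scale(ag_log(ag_cols(p, label)), -1)
  total <- if (is.null(align)) {
    ag_scale(ce, alpha)
  } else {
    ag_add(align, ag_scale(ce, alpha))
  }
  list(total = total, ce = ce$value[1L],
       align = if (is.null(align)) 0 else align$value[1L],
       p = p$value)
}

#' Train the single-lead feature-reconstruction network
#'
#' Phase 2 of the protocol. Per record: the frozen teacher's 12-lead feature
#' map `F_full` is the alignment target (computed once and cached — the
#' padding realization is shared with the student by construction); the
#' student extracts `F_single` from the selected lead(s); the reconstruction
#' module maps it to `F_rec`; cross-attention fusion yields the enhanced map
#' that the classifier scores. Optimizes
#' `recon_loss(F_rec, F_full) + alpha * CE` with Adam, class-balanced
#' sampling and the plateau schedule; keeps the best-validation-macro-F1
#' checkpoint. Ablation variants rewire this graph, see [train_config()].
#'
#' @param train_records,val_records Preprocessed 12-lead `ecg_record` lists;
#'   the student consumes the rows selected by `lead`.
#' @param teacher A frozen [pretrain_teacher()] result (required for all
#'   variants except `baseline_single`).
#' @param config A [train_config()].
#' @param lead Integer index (or vector, e.g. 3 leads) of the input lead(s).
#' @param student_spec [extractor_spec()] for the student; defaults to the
#'   teacher's architecture with `in_leads = length(lead)`.
#' @param rspec,fspec Reconstruction and fusion specs; defaults match the
#'   student's `d_model`.
#' @param loss_kind Alignment loss, see [recon_loss()].
#' @return An object of class `slfr_model`.
#' @export
train_slfr <- function(train_records, val_records, teacher = NULL,
                       config = train_config(), lead = 1L,
                       student_spec = NULL, rspec = NULL, fspec = NULL,
                       loss_kind = NULL) {
  variant <- config$variant
  if (variant == "teacher_12lead") {
    stop("use pretrain_teacher() for the 12-lead variant")
  }
  use_teacher <- variant != "baseline_single"
  if (use_teacher) {
    if (is.null(teacher) || !inherits(teacher, "ecg_teacher")) {
      stop("this variant requires a pretrained teacher")
    }
    if (!isTRUE(teacher$frozen)) stop("teacher must be frozen before Phase 2")
  }
  records_signal_check(train_records, 12L)
  records_signal_check(val_records, 12L)
  nlead <- 12L
  if (any(lead < 1L | lead > nlead)) stop("lead index out of range 1..", nlead)
  y_train <- labels_of(train_records)
  y_val <- labels_of(val_records)
  k <- if (use_teacher) teacher$n_classes else max(c(y_train, y_val))

  if (is.null(student_spec)) {
    base <- if (use_teacher) teacher$spec else extractor_spec(in_leads = 12L,
                                                              small_profile = TRUE)
    student_spec <- extractor_spec(
      in_leads = length(lead), oscnn_kernels = base$oscnn_kernels,
      oscnn_out_channels = base$oscnn_out_channels,
      block_channels = base$block_channels, block_expansion = base$block_expansion,
      d_model = base$d_model, n_transformer_layers = base$n_transformer_layers,
      n_heads = base$n_heads, se_reduction = base$se_reduction,
      ffn_mult = base$ffn_mult, dropout = base$dropout)
  }
  d <- student_spec$d_model
  if (use_teacher && d != teacher$spec$d_model) {
    stop("student d_model must match the teacher's for feature alignment")
  }
  if (is.null(rspec)) rspec <- recon_spec(d, n_heads = student_spec$n_heads)
  if (is.null(fspec)) fspec <- fusion_spec(d, n_heads = student_spec$n_heads)
  if (is.null(loss_kind)) loss_kind <- rspec$loss_kind

  hash0 <- if (use_teacher) weights_hash(teacher[c("extractor", "classifier")])
  if (use_teacher && !identical(hash0, teacher$hash)) {
    stop("teacher weights changed since freezing")
  }
  # cache frozen teacher feature maps (the padding realization is per-record
  # and fixed at preprocessing, so one forward per record suffices)
  fcache_train <- if (use_teacher) {
    lapply(train_records, function(r)
      ag_no_grad(fwd_extract(as_node(t(r$signal)), teacher$extractor,
                             training = FALSE))$value)
  }
  fcache_val <- if (use_teacher) {
    lapply(val_records, function(r)
      ag_no_grad(fwd_extract(as_node(t(r$signal)), teacher$extractor,
                             training = FALSE))$value)
  }

  log_rows <- list()
  best <- list(f1 = -Inf, snap = NULL, epoch = 0L)
  withr::with_seed(config$seed, {
    mod <- student_modules(variant, d, k, student_spec, rspec, fspec)
    params <- collect_params(mod)
    opt <- new.env(); opt$t <- 0L
    sampler <- balanced_sampler(y_train, seed = config$seed + 1000003L)
    lr <- config$lr_init
    val_hist <- numeric(0)
    steps <- nrow_steps(length(train_records), config$batch_size)

    for (epoch in seq_len(config$epochs)) {
      s_align <- s_ce <- 0
      for (s in seq_len(steps)) {
        idx <- sampler(config$batch_size)
        for (i in idx) {
          r <- train_records[[i]]
          ag_reset()
          fwd <- student_forward(as_node(t(r$signal[lead, , drop = FALSE])),
                                 r$label,
                                 if (use_teacher) fcache_train[[i]],
                                 mod, variant, loss_kind, config$alpha,
                                 training = TRUE)
          ag_backward(fwd$total)
          s_align <- s_align + fwd$align
          s_ce <- s_ce + fwd$ce
        }
        adam_step(params, lr, opt, grad_scale = 1 / length(idx))
        zero_grads(params)
      }
      ag_reset()
      n_seen <- steps * config$batch_size
      ep_align <- s_align / n_seen
      ep_ce <- s_ce / n_seen
      # validation pass (eval mode, no gradients)
      val <- lapply(seq_along(val_records), function(j) {
        r <- val_records[[j]]
        ag_no_grad(student_forward(as_node(t(r$signal[lead, , drop = FALSE])),
                                   r$label,
                                   if (use_teacher) fcache_val[[j]],
                                   mod, variant, loss_kind, config$alpha,
                                   training = FALSE))
      })
      probs <- do.call(rbind, lapply(val, `[[`, "p"))
      m <- compute_metrics(y_val, probs)
      val_align <- mean(vapply(val, `[[`, 1, "align"))
      val_ce <- mean(vapply(val, `[[`, 1, "ce"))
      val_total <- total_loss(val_align, val_ce, config$alpha)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, l1 = ep_align, ce = ep_ce,
        l_total = total_loss(ep_align, ep_ce, config$alpha), lr = lr,
        val_l1 = val_align, val_ce = val_ce, val_total = val_total,
        val_acc = m$accuracy, val_macro_f1 = m$macro_f1)
      if (m$macro_f1 > best$f1) {
        best <- list(f1 = m$macro_f1, snap = lapply(mod, function(mm)
          if (!is.null(mm)) model_snapshot(mm)), epoch = epoch)
      }
      val_hist <- c(val_hist, val_total)
      lr <- plateau_scheduler(val_hist, lr, config)
      if (use_teacher &&
          !identical(weights_hash(teacher[c("extractor", "classifier")]), hash0)) {
        stop("teacher immutability violated at epoch ", epoch)
      }
      if (converged_by_schedule(lr, config)) break
    }
    if (!is.null(best$snap)) {
      for (nm in names(mod)) {
        if (!is.null(mod[[nm]])) model_restore(mod[[nm]], best$snap[[nm]])
      }
    }
  })
  structure(list(student = mod$student, recon = mod$recon, fusion = mod$fusion,
                 classifier = mod$classifier, variant = variant, lead = lead,
                 loss_kind = loss_kind, n_classes = k,
                 teacher_hash = if (use_teacher) hash0 else NA_character_,
                 log = do.call(rbind, log_rows), best_epoch = best$epoch,
                 config = config, student_spec = student_spec),
            class = "slfr_model")
}

# ---- slfr_model methods ----

#' @export
print.slfr_model <- function(x, ...) {
  cat("Single-lead network | variant:", x$variant, "| lead(s):",
      paste(x$lead, collapse = ","), "| classes:", x$n_classes, "\n")
  cat(sprintf("best epoch %d, val macro-F1 %.3f\n", x$best_epoch,
              max(x$log$val_macro_f1)))
  invisible(x)
}

#' @export
summary.slfr_model <- function(object, ...) {
  np <- sum(vapply(collect_params(object[c("student", "recon", "fusion",
                                           "classifier")]),
                   function(p) length(p$value), 1))
  cat("Single-lead feature-reconstruction network\n")
  cat("  variant      :", object$variant, "\n")
  cat("  input lead(s):", paste(object$lead, collapse = ","), "\n")
  cat("  parameters   :", format(np, big.mark = ","), "\n")
  cat("  align loss   :", object$loss_kind, ", alpha =", object$config$alpha, "\n")
  cat("  epochs       :", nrow(object$log), "(best", object$best_epoch, ")\n")
  tail_log <- utils::tail(object$log, 3L)
  print(tail_log, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Predict with a trained single-lead network
#'
#' Runs the variant's evaluation graph (extractor, and where present the
#' reconstruction and fusion modules) on each record's configured lead(s).
#'
#' @param object An `slfr_model`.
#' @param records Preprocessed records (12-lead, from which the model's
#'   lead(s) are taken, or already restricted to the model's leads).
#' @param type `"prob"` for the probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @return An `n x K` matrix or an integer vector.
#' @export
predict.slfr_model <- function(object, records, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- eval_probs(records, function(r) {
    x <- if (nrow(r$signal) > length(object$lead)) {
      r$signal[object$lead, , drop = FALSE]
    } else r$signal
    ag_no_grad({
      f_single <- fwd_extract(as_node(t(x)), object$student, training = FALSE)
      feat <- switch(object$variant,
        full = {
          f_rec <- fwd_reconstruct(f_single, object$recon, training = FALSE)
          fwd_fuse(f_rec, f_single, object$fusion, training = FALSE)
        },
        no_fusion = fwd_reconstruct(f_single, object$recon, training = FALSE),
        f_single)
      fwd_classify(feat, object$classifier)
    })$value
  })
  if (type == "prob") probs else max.col(probs, ties.method = "first")
}

#' @export
coef.slfr_model <- function(object, ...) {
  list(w_pred = object$classifier$w$value, b_pred = as.vector(object$classifier$b$value))
}

#' Plot training curves of a single-lead network
#'
#' Left axis: training alignment (L1) and cross-entropy losses per epoch;
#' right panel: validation macro-F1.
#'
#' @param x An `slfr_model`.
#' @param ... Passed to `matplot`.
#' @return Invisibly, `x`.
#' @export
plot.slfr_model <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(lg$epoch, cbind(lg$l1, lg$ce, lg$l_total), type = "l",
                    lty = 1, col = c("steelblue", "firebrick", "black"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("align", "CE", "total"), lty = 1,
                   col = c("steelblue", "firebrick", "black"), bty = "n")
  graphics::plot(lg$epoch, lg$val_macro_f1, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation macro-F1")
  invisible(x)
}
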