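# Desk-scale study machinery: fixed "desk" conditions shared by the test
# suite, the examples and the acceptance script, plus the ablation runner
# that compares training variants across replicate seeds.

#' Desk-scale study conditions
#'
#' A fixed, documented configuration small enough to train on one CPU in
#' minutes while preserving every architectural contract of the full model
#' (stride product 64, token arithmetic, teacher/student symmetry):
#'
#' * data: 100 patients x 2 records at 500 Hz, 6-8 s, 6 classes, 20 dB SNR,
#'   the engineered wearable-lead deficit, patient-level 7:1:2 split;
#' * preprocessing: 0.05-48 Hz band-pass, 250 Hz, 4 s window (1024 samples,
#'   16 tokens);
#' * architecture: OS-CNN kernels 1/5/9/13 at 4 channels each, blocks
#'   16-20-24-28-32, d_model 32, expansion 2, 2 transformer layers, 2 heads;
#' * training: Adam (batch 4, initial rate 6e-3) under the plateau
#'   schedule, with convergence-based early stopping after 3 rate halvings;
#'   epoch caps 24 (teacher) and 32 (students) so slower-converging
#'   variants receive the epochs they need within a bounded budget.
#'
#' @param seed Base seed for the dataset draw.
#' @return A list with `sim` ([sim_spec()]), `preproc`
#'   ([preprocess_config()]), `teacher_spec`, `student_spec`
#'   ([extractor_spec()]), `teacher_train` and `train` ([train_config()]).
#' @export
desk_conditions <- function(seed = 1L) {
  list(
    sim = sim_spec(n_patients = 100L, records_per_patient = 2L, fs = 500,
                   duration_s = c(6, 8), n_classes = 6L, snr_db = 20,
                   seed = seed),
    preproc = preprocess_config(target_fs = 250, target_len_s = 4),
    teacher_spec = desk_extractor_spec(12L),
    student_spec = desk_extractor_spec(1L),
    teacher_train = train_config(epochs = 24L, batch_size = 4L,
                                 lr_init = 6e-3, stop_after_halvings = 3,
                                 seed = seed),
    train = train_config(epochs = 32L, batch_size = 4L, lr_init = 6e-3,
                         stop_after_halvings = 3, seed = seed))
}

desk_extractor_spec <- function(in_leads) {
  extractor_spec(in_leads = in_leads, oscnn_kernels = c(1L, 5L, 9L, 13L),
                 oscnn_out_channels = 16L,
                 block_channels = c(16L, 20L, 24L, 28L, 32L),
                 block_expansion = 2L, d_model = 32L, n_transformer_layers = 2L,
                 n_heads = 2L, se_reduction = 4L, ffn_mult = 2L, dropout = 0.05)
}

#' Simulate, preprocess and split a dataset in one call
#'
#' @param sim A [sim_spec()].
#' @param preproc A [preprocess_config()].
#' @param seed Seed for the patient split and pad realizations.
#' @return A list with `train`, `val`, `test` record lists and the `split`
#'   data frame.
#' @export
prepare_dataset <- function(sim, preproc = preprocess_config(), seed = 1L) {
  ds <- simulate_dataset(sim)
  split <- split_patients(ds, seed = seed)
  pp <- preprocess_records(ds, preproc, split = split, seed = seed + 17L)
  by_split <- split(pp$records, vapply(pp$records, function(r) r$split, ""))
  list(train = by_split$train, val = by_split$val, test = by_split$test,
       split = split, excluded = pp$excluded)
}

#' Ablation study: training variants against one frozen teacher
#'
#' Simulates one dataset under the given conditions, pretrains and freezes
#' one 12-lead teacher, then trains each requested single-lead variant once
#' per replicate seed against that same frozen teacher (replicates differ in
#' student initialization, sampling and dropout — the teacher is shared, as
#' in the component-ablation design this miniature mirrors). Every model,
#' including the teacher, is scored on the held-out test patients.
#'
#' @param seeds Integer vector of replicate (student-training) seeds.
#' @param variants Character vector of variants to train (see
#'   [train_config()]); `"teacher_12lead"` scores the frozen teacher itself.
#' @param conditions A [desk_conditions()]-shaped list.
#' @param lead Input lead(s) for the single-lead variants.
#' @return A list with `results` (data frame: seed, variant, test macro-F1,
#'   accuracy), `models` (the trained fits, plus `teacher`), and `data`.
#' @export
ablation_study <- function(seeds = 1:3,
                           variants = c("baseline_single", "supervise_only",
                                        "full"),
                           conditions = desk_conditions(), lead = 1L) {
  data <- prepare_dataset(conditions$sim, conditions$preproc,
                          seed = conditions$sim$seed)
  y_test <- labels_of(data$test)
  teacher <- pretrain_teacher(data$train, data$val, conditions$teacher_train,
                              spec = conditions$teacher_spec)
  rows <- list()
  models <- list(teacher = teacher)
  if ("teacher_12lead" %in% variants) {
    m <- compute_metrics(y_test, predict(teacher, data$test))
    rows[[length(rows) + 1L]] <- data.frame(seed = NA_integer_,
                                            variant = "teacher_12lead",
                                            macro_f1 = m$macro_f1,
                                            accuracy = m$accuracy)
  }
  for (sd in seeds) {
    for (v in setdiff(variants, "teacher_12lead")) {
      cfg <- conditions$train
      cfg$variant <- v
      cfg$seed <- as.integer(sd)
      fit <- train_slfr(data$train, data$val,
                        teacher = if (v != "baseline_single") teacher,
                        config = cfg, lead = lead,
                        student_spec = conditions$student_spec)
      m <- compute_metrics(y_test, predict(fit, data$test))
      rows[[length(rows) + 1L]] <- data.frame(seed = sd, variant = v,
                                              macro_f1 = m$macro_f1,
                                              accuracy = m$accuracy)
      models[[paste0(v, "_seed", sd)]] <- fit
    }
  }
  list(results = do.call(rbind, rows), models = models, data = data)
}

#' Run the package's reference desk-scale study
#'
#' The study the test suite and the acceptance script both report: under
#' [desk_conditions()], one synthetic dataset and one frozen 12-lead
#' teacher, with the `baseline_single`, `supervise_only` and `full`
#' single-lead variants each trained under three replicate seeds and scored
#' on held-out test patients alongside the teacher.
#'
#' @param seed Base integer seed (dataset, teacher and replicate seeds all
#'   derive from it).
#' @return See [ablation_study()].
#' @export
run_acceptance_study <- function(seed = 1L) {
  conditions <- desk_conditions(seed * 1000L + 7L)
  conditions$teacher_train$seed <- as.integer(seed)
  ablation_study(seeds = seed * 10L + 0:2,
                 variants = c("baseline_single", "supervise_only", "full",
                              "teacher_12lead"),
                 conditions = conditions)
}
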