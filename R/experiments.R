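#' Experimental arm configuration
#'
#' The four arms of the benchmark design: the original set (OS), the
#' rotation-augmented set (DA), the cheat-sheet set (CS) and both combined
#' (DACS). The flag matrix is fixed per arm name; sizes default to the MIAS
#' campaign (100 test, 222 train before augmentation, 25% validation,
#' 15 runs).
#'
#' @param name One of `"OS"`, `"DA"`, `"CS"`, `"DACS"`.
#' @param n_train,n_test Split sizes (train counted before augmentation).
#' @param val_fraction Validation fraction within training.
#' @param n_runs Number of seeded repetitions.
#' @return An object of class `arm_config`.
#' @export
arm_config <- function(name = c("OS", "DA", "CS", "DACS"), n_train = 222L,
                       n_test = 100L, val_fraction = 0.25, n_runs = 15L) {
  name <- match.arg(name)
  flags <- list(OS = c(FALSE, FALSE), DA = c(FALSE, TRUE),
                CS = c(TRUE, FALSE), DACS = c(TRUE, TRUE))[[name]]
  structure(list(name = name, use_cheatsheet = flags[1],
                 use_augmentation = flags[2], n_train = as.integer(n_train),
                 n_test = as.integer(n_test), val_fraction = val_fraction,
                 n_runs = as.integer(n_runs)), class = "arm_config")
}

#' All four arms
#'
#' @inheritParams arm_config
#' @return A named list of four [arm_config()]s.
#' @export
default_arms <- function(n_train = 222L, n_test = 100L, val_fraction = 0.25,
                         n_runs = 15L) {
  arms <- lapply(c("OS", "DA", "CS", "DACS"), arm_config, n_train = n_train,
                 n_test = n_test, val_fraction = val_fraction,
                 n_runs = n_runs)
  names(arms) <- c("OS", "DA", "CS", "DACS")
  arms
}

#' Seeded train/test split
#'
#' Draws disjoint train and test id sets of the configured sizes from the
#' original records only (augmented copies are created downstream, after the
#' split, so none can cross it).
#'
#' @param ids Character vector of record ids.
#' @param n_train,n_test Split sizes.
#' @param seed Integer seed.
#' @return A list with `train` and `test` id vectors.
#' @export
make_split <- function(ids, n_train, n_test, seed) {
  if (length(ids) < n_train + n_test)
    stopf("cohort of %d records cannot supply %d train + %d test",
          length(ids), n_train, n_test)
  withr::with_seed(seed, {
    test <- sample(ids, n_test)
    train <- sample(setdiff(ids, test), n_train)
  })
  list(train = train, test = test)
}

default_chromosome <- function() chromosome(0.75, 0.75, 170)

encode_record <- function(pixels, chrom, biopsy_seed, enumerate = FALSE) {
  ex <- extract_roi(pixels, chrom)
  bio <- electronic_biopsy(ex$crop, seed = biopsy_seed,
                           enumerate = enumerate)
  encode_frames(ex$crop, bio, max(1, ex$roi$radius))$pixels
}

#' Build one arm's train/validation-ready tensors
#'
#' Follows the pipeline order: cheat-sheet arms first pass every image (train
#' and test alike) through ROI extraction, electronic biopsy and frame
#' encoding; the cohort is then split; augmentation arms triple the training
#' set only; finally everything is resized to the CNN input size.
#'
#' @param cohort A `phantom_cohort`, or any list with `records` (each record
#'   a list with `id`, `pixels`, `class_raw`) and `metadata`.
#' @param arm An [arm_config()].
#' @param run_seed Integer seed for the split, biopsy draws and downstream
#'   training.
#' @param chrom ROI-refinement [chromosome()] used by cheat-sheet arms.
#' @param input_size CNN input size, `c(height, width)`.
#' @return A list with `train` and `test`, each holding `images` (list of
#'   resized matrices), `labels` and `meta` (id, source_id, transform,
#'   label).
#' @export
build_arm <- function(cohort, arm, run_seed, chrom = default_chromosome(),
                      input_size = c(100L, 100L)) {
  stopifnot(inherits(arm, "arm_config"))
  meta <- assign_labels(cohort$metadata)
  ids <- meta$id
  labels <- meta$label
  n <- length(ids)
  images <- lapply(cohort$records, `[[`, "pixels")
  if (arm$use_cheatsheet) {
    seeds <- withr::with_seed(run_seed,
                              sample.int(.Machine$integer.max - 1L, n))
    images <- lapply(seq_len(n), function(i)
      encode_record(images[[i]], chrom, seeds[i]))
  }
  names(images) <- ids
  split <- make_split(ids, arm$n_train, arm$n_test, seed = run_seed)
  tr_i <- match(split$train, ids)
  te_i <- match(split$test, ids)
  if (arm$use_augmentation) {
    aug <- augment_training_set(images[tr_i], labels[tr_i], ids[tr_i])
    train_images <- aug$images
    train_meta <- aug$meta
  } else {
    train_images <- images[tr_i]
    train_meta <- data.frame(id = ids[tr_i], source_id = ids[tr_i],
                             transform = "orig", label = labels[tr_i])
  }
  stopifnot(!any(train_meta$source_id %in% split$test))   # no leakage
  resize_all <- function(l) lapply(l, resize_image, width = input_size[2],
                                   height = input_size[1])
  list(
    train = list(images = resize_all(train_images),
                 labels = train_meta$label, meta = train_meta),
    test = list(images = resize_all(images[te_i]), labels = labels[te_i],
                meta = data.frame(id = ids[te_i], source_id = ids[te_i],
                                  transform = "orig", label = labels[te_i]))
  )
}

#' Run the multi-arm experiment
#'
#' For every arm and every run: build the arm's data with a per-run seed
#' (`base_seed + run - 1`, shared across arms so each run index sees the same
#' split), train the CNN with 25% validation, score the test images, and
#' record AC/SE/SP/AUOC. The 4-arm, 15-run campaign yields 60 rows.
#'
#' @param cohort A cohort (see [build_arm()]).
#' @param arms List of [arm_config()]s.
#' @param base_seed Integer; run `r` uses seed `base_seed + r - 1`.
#' @param model_config A [cnn_config()]; its seed is replaced per run.
#' @param epochs Optional override of the configured epochs.
#' @param chrom ROI chromosome for cheat-sheet arms.
#' @param verbose Print one line per run?
#' @return A `results_table` data frame with columns `arm`, `run`, `AC`,
#'   `SE`, `SP`, `AUOC` (percent scales).
#' @export
run_experiment <- function(cohort, arms = default_arms(), base_seed = 1L,
                           model_config = cnn_config(), epochs = NULL,
                           chrom = default_chromosome(), verbose = FALSE) {
  rows <- list()
  for (arm in arms) {
    for (run in seq_len(arm$n_runs)) {
      run_seed <- base_seed + run - 1L
      data <- build_arm(cohort, arm, run_seed, chrom = chrom,
                        input_size = model_config$input_size)
      cfg <- model_config
      cfg$seed <- run_seed
      model <- cnn_build(cfg)
      model <- cnn_train(model, data$train$images, data$train$labels,
                         val_fraction = arm$val_fraction, seed = run_seed,
                         epochs = epochs)
      scores <- predict_proba(model, data$test$images)
      m <- run_metrics(data$test$labels, scores)
      rows[[length(rows) + 1L]] <-
        data.frame(arm = arm$name, run = run, AC = m[["AC"]], SE = m[["SE"]],
                   SP = m[["SP"]], AUOC = m[["AUOC"]])
      if (verbose)
        message(sprintf("%s run %d: AC=%.1f SE=%.1f SP=%.1f AUOC=%.1f",
                        arm$name, run, m[["AC"]], m[["SE"]], m[["SP"]],
                        m[["AUOC"]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("results_table", "data.frame")
  out
}

#' Write / read a results table
#'
#' Tab-delimited text with columns `arm`, `run`, `AC`, `SE`, `SP`, `AUOC`;
#' full precision is preserved so the table round-trips losslessly.
#'
#' @param results A results data frame.
#' @param path File path.
#' @return `read_results` returns the table; `write_results` returns `path`
#'   invisibly.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("results_table", "data.frame")
  out
}
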