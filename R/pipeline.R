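# Training/evaluation pipeline: fold construction, the slice-wise training
# loop (pooled shuffled slices, Adam, per-iteration loss log), volume
# prediction by slice restacking, and per-case/cohort evaluation.

#' Build a k-fold cross-validation split
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ by
#' at most one; 188 cases with `k = 4` gives test folds of 47 and training
#' sets of 141.
#'
#' @param case_ids character vector of unique case identifiers.
#' @param k fold count (`>= 2`, `<= length(case_ids)`).
#' @param seed shuffle seed.
#' @return A `FoldSplit`: list with `k` and named integer `assignments`.
#' @export
make_folds <- function(case_ids, k = 4, seed = 1L) {
  if (anyDuplicated(case_ids)) stopf("case ids must be unique")
  if (!is_count(k, 2)) stopf("k must be a count >= 2")
  if (length(case_ids) < k) stopf("need at least k cases")
  ord <- with_seed(seed, sample(length(case_ids)))
  assignments <- integer(length(case_ids))
  assignments[ord] <- rep_len(seq_len(k), length(case_ids))
  names(assignments) <- case_ids
  structure(list(k = as.integer(k), assignments = assignments),
            class = "FoldSplit")
}

#' Training configuration
#'
#' @param loss a [loss_config()].
#' @param batch_size slices per iteration (protocol value 5).
#' @param learning_rate Adam learning rate.
#' @param max_iterations total optimisation steps.
#' @param seed seed controlling shuffling, augmentation and any weight init
#'   done inside [train()].
#' @param augment list with `mode` (`"none"`, `"elastic"`, `"rigid"`,
#'   `"both"`) and optional `sigma`, `alpha`.
#' @param checkpoint_every write a checkpoint every this many iterations
#'   (`Inf` = only at the end when `checkpoint_dir` is set).
#' @param checkpoint_dir directory for `.rds` checkpoints, or `NULL`.
#' @return A `TrainConfig` object.
#' @export
train_config <- function(loss = loss_config("cross_entropy"), batch_size = 5,
                         learning_rate = 1e-4, max_iterations = 100,
                         seed = 1L, augment = list(mode = "none"),
                         checkpoint_every = Inf, checkpoint_dir = NULL) {
  stopifnot(inherits(loss, "LossConfig"))
  if (!is_count(batch_size)) stopf("batch_size must be >= 1")
  if (!is_count(max_iterations)) stopf("max_iterations must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (is.null(augment$mode)) augment$mode <- "none"
  if (!augment$mode %in% c("none", "elastic", "rigid", "both"))
    stopf("augment$mode must be none/elastic/rigid/both")
  structure(list(loss = loss, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), augment = augment,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "TrainConfig")
}

one_hot_slices <- function(label_mat, n_classes) {
  t <- array(0, c(dim(label_mat), n_classes, 1))
  for (ch in seq_len(n_classes)) t[, , ch, 1] <- label_mat == (ch - 1L)
  t
}

# Pool normalized slices (and one-hot targets) from a cohort of
# (volume, labels) pairs.
slice_pool <- function(cohort, input_size) {
  pool <- list()
  for (cs in cohort) {
    d <- dim(cs$volume$voxels)
    if (d[2] != input_size || d[3] != input_size)
      stopf("case '%s' is %dx%d in-plane; preprocess to the network input size %d",
            cs$volume$case_id, d[2], d[3], input_size)
    for (k in seq_len(d[1]))
      pool[[length(pool) + 1L]] <- list(image = normalize_slice(cs$volume$voxels[k, , ]),
                                        mask = cs$labels$labels[k, , ])
  }
  pool
}

#' Train a network on a cohort of cases
#'
#' Pools all axial slices across the training cases, shuffles them every
#' epoch under the config seed (re-drawing augmentation variants each epoch
#' when enabled), and optimises the configured loss with Adam in batches of
#' `batch_size`. Per-iteration losses are logged; a non-finite loss aborts
#' with a training-divergence error (the last checkpoint, if any, is left on
#' disk).
#'
#' @param net a `dunet_network`.
#' @param cohort list of `list(volume, labels)` pairs, already preprocessed to
#'   the network input size.
#' @param cfg a [train_config()].
#' @return `list(net, log)` with `log` a data frame of
#'   `(iteration, epoch, loss)`.
#' @export
train <- function(net, cohort, cfg) {
  stopifnot(inherits(net, "dunet_network"), inherits(cfg, "TrainConfig"))
  if (length(cohort) == 0) stopf("training cohort is empty")
  base_pool <- slice_pool(cohort, net$spec$input_size)
  n_classes <- net$spec$n_classes
  state <- adam_init(net)
  log_it <- integer(0); log_ep <- integer(0); log_loss <- numeric(0)
  ckpt <- function(iter, net) {
    if (!is.null(cfg$checkpoint_dir) &&
        (iter %% cfg$checkpoint_every == 0 || iter == cfg$max_iterations)) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(net = net, iteration = iter),
              file.path(cfg$checkpoint_dir, sprintf("checkpoint_%06d.rds", iter)))
    }
  }
  with_seed(cfg$seed, {
    iter <- 0L
    epoch <- 0L
    queue <- integer(0)
    pool <- base_pool
    while (iter < cfg$max_iterations) {
      if (length(queue) < cfg$batch_size) {
        epoch <- epoch + 1L
        if (cfg$augment$mode != "none") {
          pool <- augment_batch(base_pool, cfg$augment$mode,
                                seed = cfg$seed + epoch,
                                sigma = cfg$augment$sigma %||% 512,
                                alpha = cfg$augment$alpha %||% 21)
        }
        queue <- sample(length(pool))
      }
      take <- queue[seq_len(cfg$batch_size)]
      queue <- queue[-seq_len(cfg$batch_size)]
      sz <- net$spec$input_size
      nb <- length(take)
      x <- array(0, c(sz, sz, 1, nb))
      tt <- array(0, c(sz, sz, n_classes, nb))
      for (b in seq_len(nb)) {
        x[, , 1, b] <- pool[[take[b]]]$image
        tt[, , , b] <- one_hot_slices(pool[[take[b]]]$mask, n_classes)
      }
      fw <- nn_forward(net, x)
      loss <- combined_loss(fw$out, tt, cfg$loss)
      if (!is.finite(loss))
        stopf("training diverged at iteration %d (non-finite loss)", iter + 1L)
      dout <- combined_loss_grad(fw$out, tt, cfg$loss)
      pg <- nn_backward(net, fw, dout)
      upd <- adam_step(net, pg, state, lr = cfg$learning_rate)
      net <- upd$net
      state <- upd$state
      iter <- iter + 1L
      log_it[iter] <- iter; log_ep[iter] <- epoch; log_loss[iter] <- loss
      ckpt(iter, net)
    }
  })
  list(net = net,
       log = data.frame(iteration = log_it, epoch = log_ep, loss = log_loss))
}

#' Predict a label volume slice-by-slice
#'
#' Normalizes each axial slice, runs the network, takes the per-pixel argmax
#' and restacks the slices into a [LabelVolume()] carrying the input's
#' spacing. The whole-prostate mask is the union of labels 1 and 2.
#'
#' @param net a `dunet_network`.
#' @param v a [Volume()] preprocessed to the network input size.
#' @return A [LabelVolume()].
#' @export
predict_volume <- function(net, v) {
  stopifnot(inherits(net, "dunet_network"), inherits(v, "Volume"))
  d <- dim(v$voxels)
  sz <- net$spec$input_size
  if (d[2] != sz || d[3] != sz)
    stopf("volume is %dx%d in-plane; network expects %dx%d", d[2], d[3], sz, sz)
  out <- array(0L, d)
  for (k in seq_len(d[1])) {
    p <- predict_slice(net, normalize_slice(v$voxels[k, , ]))
    out[k, , ] <- apply(p, c(1, 2), which.max) - 1L
  }
  LabelVolume(out, v$spacing, v$case_id)
}

structure_mask <- function(labels, structure) {
  switch(structure,
    prostate = labels > 0L,
    cz = labels == 1L,
    pz = labels == 2L,
    stopf("unknown structure '%s'", structure))
}

#' Evaluate predictions against ground truth
#'
#' Computes per-case metrics for the whole prostate, central zone and
#' peripheral zone (Dice, signed RAVD, directed Hausdorff
#' prediction-to-truth in mm, mean surface distance, sensitivity,
#' specificity), regional apex/mid/base Dice per case, and cohort summaries
#' per structure. Cases where a structure is absent from ground truth or
#' prediction get `NA` for the undefined distance/volume metrics.
#'
#' @param preds list of predicted [LabelVolume()]s.
#' @param gts list of ground-truth [LabelVolume()]s with matching case ids.
#' @return An `EvalReport`: list with `case_metrics`, `regional` and
#'   `summary` data frames.
#' @export
evaluate <- function(preds, gts) {
  ids_p <- vapply(preds, function(x) x$case_id, character(1))
  ids_g <- vapply(gts, function(x) x$case_id, character(1))
  if (!setequal(ids_p, ids_g) || length(ids_p) != length(ids_g))
    stopf("prediction and ground-truth case ids do not match")
  gts <- gts[match(ids_p, ids_g)]
  rows <- list()
  reg_rows <- list()
  for (i in seq_along(preds)) {
    pv <- preds[[i]]; gv <- gts[[i]]
    if (!identical(dim(pv$labels), dim(gv$labels)))
      stopf("case '%s': prediction and ground-truth shapes differ", pv$case_id)
    for (s in c("prostate", "cz", "pz")) {
      pm <- structure_mask(pv$labels, s)
      gm <- structure_mask(gv$labels, s)
      has_g <- any(gm); has_p <- any(pm)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = pv$case_id, structure = s,
        dice = dice_score(gm, pm),
        ravd = if (has_g) ravd(gm, pm) else NA_real_,
        hausdorff = if (has_g && has_p)
          hausdorff(pm, gm, pv$spacing, mode = "directed") else NA_real_,
        msd = if (has_g && has_p)
          mean_surface_distance(pm, gm, pv$spacing) else NA_real_,
        sensitivity = if (has_g) unname(sensitivity_specificity(gm, pm)[1]) else NA_real_,
        specificity = unname(sensitivity_specificity_safe(gm, pm)),
        stringsAsFactors = FALSE)
    }
    reg <- tryCatch(regional_dice(gv, pv), error = function(e) c(apex = NA_real_,
                                                                 mid = NA_real_,
                                                                 base = NA_real_))
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      case_id = pv$case_id, apex = reg[["apex"]], mid = reg[["mid"]],
      base = reg[["base"]], stringsAsFactors = FALSE)
  }
  case_metrics <- do.call(rbind, rows)
  regional <- do.call(rbind, reg_rows)
  summary <- if (length(preds) >= 2) summarize_cohort(case_metrics) else NULL
  structure(list(case_metrics = case_metrics, regional = regional,
                 summary = summary), class = "EvalReport")
}

sensitivity_specificity_safe <- function(gm, pm) {
  tn <- sum(!gm & !pm); fp <- sum(!gm & pm)
  if (tn + fp == 0) return(NA_real_)
  tn / (tn + fp)
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d cases x 3 structures\n",
              nrow(x$case_metrics) / 3))
  if (!is.null(x$summary)) {
    cat("Cohort summary:\n")
    print(x$summary, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
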