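# Experiment orchestration: k-fold cross-validation of one or more network
# variants on a phantom cohort (or a manifest of volumes on disk), with
# per-fold metric tables, pooled cohort summaries and pairwise paired t-tests
# between variants.

spec_from_config <- function(nc) {
  network_spec(
    stage_widths = as.integer(nc$stage_widths %||% 2^(4:10)),
    dense_blocks = as.integer(nc$dense_blocks %||% 2L),
    growth = if (is.null(nc$growth)) "auto" else nc$growth,
    convs_per_block = as.integer(nc$convs_per_block %||% 4L),
    kernel = as.integer(nc$kernel %||% 3L),
    n_classes = as.integer(nc$n_classes %||% 3L),
    input_size = as.integer(nc$input_size %||% 256L))
}

build_network <- function(spec) {
  if (spec$dense_blocks == 0) build_classical_unet(spec) else build_dense_unet(spec)
}

config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("networks")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stopf("experiment config is missing keys: %s", paste(missing, collapse = ", "))
  if (is.null(cfg$phantom) && is.null(cfg$manifest))
    stopf("experiment config needs either a 'phantom' block or a 'manifest' path")
  cfg
}

experiment_cohort <- function(cfg) {
  if (!is.null(cfg$manifest)) return(load_cohort(cfg$manifest))
  ph <- cfg$phantom
  n_cases <- ph$n_cases %||% 20L
  ph$n_cases <- NULL
  if (!is.null(ph$n_slices)) ph$n_slices <- as.integer(unlist(ph$n_slices))
  if (!is.null(ph$intensity)) ph$intensity <- unlist(ph$intensity)
  p <- do.call(phantom_params, ph)
  generate_cohort(p, n_cases, seed = cfg$seed %||% p$seed)
}

train_config_from <- function(tc, seed) {
  lc <- loss_config(kind = tc$loss %||% "cross_entropy",
                    focal_alpha = tc$focal_alpha %||% 1,
                    focal_gamma = tc$focal_gamma %||% 2)
  train_config(loss = lc,
               batch_size = tc$batch_size %||% 5L,
               learning_rate = tc$learning_rate %||% 1e-4,
               max_iterations = tc$max_iterations %||% 100L,
               seed = seed,
               augment = tc$augment %||% list(mode = "none"))
}

#' Run a cross-validated training/evaluation experiment
#'
#' For every fold and every configured network variant: train on the training
#' cases, predict the test fold, evaluate against ground truth. Writes
#' per-variant, per-fold case-metric CSVs, pooled per-variant cohort summary
#' CSVs (one row per structure, the layout of the results tables), and a
#' pairwise comparison CSV with a paired t-test p-value per structure per
#' variant pair (per fold and pooled). Fully reproducible from the config and
#' seed.
#'
#' @param config path to a YAML config, or an equivalent named list. Keys:
#'   `seed`, `folds`, `phantom` (phantom_params fields + `n_cases`) or
#'   `manifest`, `networks` (list of NetworkSpec fields + `name`), `train`
#'   (train_config fields).
#' @param outdir report directory (created; defaults to `config$output` or a
#'   tempdir subdirectory).
#' @return Invisibly, a list with the report directory, per-variant pooled
#'   `EvalReport`s and the comparison table.
#' @export
run_experiment <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) config_from_yaml(config) else config
  if (is.null(cfg$networks)) stopf("experiment config is missing 'networks'")
  if (is.null(cfg$phantom) && is.null(cfg$manifest))
    stopf("experiment config needs either a 'phantom' block or a 'manifest' path")
  seed <- as.integer(cfg$seed %||% 1L)
  k <- as.integer(cfg$folds %||% 4L)
  outdir <- outdir %||% cfg$output %||% file.path(tempdir(), "denseunet_experiment")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cohort <- experiment_cohort(cfg)
  ids <- vapply(cohort, function(cs) cs$volume$case_id, character(1))
  folds <- make_folds(ids, k, seed)

  variants <- lapply(cfg$networks, function(nc) {
    list(name = nc$name %||% if ((nc$dense_blocks %||% 2) == 0) "classical"
         else sprintf("dense%d", nc$dense_blocks %||% 2),
         spec = spec_from_config(nc))
  })
  vnames <- vapply(variants, `[[`, character(1), "name")
  if (anyDuplicated(vnames)) stopf("network variant names must be unique")

  preds <- list()   # preds[[variant]][[case_id]]
  fold_of <- folds$assignments
  for (f in seq_len(k)) {
    train_set <- cohort[fold_of[ids] != f]
    test_set <- cohort[fold_of[ids] == f]
    for (v in variants) {
      net <- with_seed(seed + 1000L * f, build_network(v$spec))
      tc <- train_config_from(cfg$train %||% list(), seed = seed + f)
      fit <- train(net, train_set, tc)
      write.csv(fit$log,
                file.path(outdir, sprintf("%s_fold%d_trainlog.csv", v$name, f)),
                row.names = FALSE)
      fold_preds <- lapply(test_set, function(cs) predict_volume(fit$net, cs$volume))
      rep_f <- evaluate(fold_preds, lapply(test_set, `[[`, "labels"))
      write.csv(rep_f$case_metrics,
                file.path(outdir, sprintf("%s_fold%d_case_metrics.csv", v$name, f)),
                row.names = FALSE)
      for (pv in fold_preds) preds[[v$name]][[pv$case_id]] <- pv
    }
  }

  gts <- lapply(cohort, `[[`, "labels")
  names(gts) <- ids
  reports <- list()
  for (v in variants) {
    rep_v <- evaluate(unname(preds[[v$name]][ids]), unname(gts[ids]))
    reports[[v$name]] <- rep_v
    write.csv(rep_v$case_metrics,
              file.path(outdir, sprintf("%s_case_metrics.csv", v$name)),
              row.names = FALSE)
    write.csv(rep_v$summary,
              file.path(outdir, sprintf("%s_summary.csv", v$name)),
              row.names = FALSE)
    write.csv(rep_v$regional,
              file.path(outdir, sprintf("%s_regional.csv", v$name)),
              row.names = FALSE)
  }

  comparison <- NULL
  if (length(variants) >= 2) {
    cmp_rows <- list()
    pairs <- utils::combn(vnames, 2, simplify = FALSE)
    for (pr in pairs) {
      a <- reports[[pr[1]]]$case_metrics
      b <- reports[[pr[2]]]$case_metrics
      for (s in c("prostate", "cz", "pz")) {
        da <- a$dice[a$structure == s][match(ids, a$case_id[a$structure == s])]
        db <- b$dice[b$structure == s][match(ids, b$case_id[b$structure == s])]
        scopes <- c(stats::setNames(seq_len(k), sprintf("fold%d", seq_len(k))),
                    all = 0L)
        for (scope in names(scopes)) {
          sel <- if (scopes[scope] == 0L) rep(TRUE, length(ids))
          else fold_of[ids] == scopes[scope]
          if (sum(sel) < 2) next
          cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
            variant_a = pr[1], variant_b = pr[2], structure = s, scope = scope,
            mds_a = 100 * mean(da[sel]), mds_b = 100 * mean(db[sel]),
            p_value = paired_ttest(da[sel], db[sel]), stringsAsFactors = FALSE)
        }
      }
    }
    comparison <- do.call(rbind, cmp_rows)
    write.csv(comparison, file.path(outdir, "comparison_ttests.csv"),
              row.names = FALSE)
  }
  invisible(list(outdir = outdir, reports = reports, comparison = comparison,
                 folds = folds))
}
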