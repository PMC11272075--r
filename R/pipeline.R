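#' Study configuration
#'
#' `read_study_config()` loads a YAML or JSON configuration;
#' `default_study_config()` returns a fully-populated configuration for a
#' synthetic two-modality study, which is also the schema reference: any
#' field omitted from a user file falls back to these defaults. The
#' prediction-stage defaults follow the study design: elastic-net mixing
#' 0.2 for single-modality models, 0.8 for the combined model, 5-fold CV
#' for the regularization strength, and median absolute error as the
#' reported error summary.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  .merge_config(default_study_config(), cfg)
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' @rdname read_study_config
#' @export
default_study_config <- function() {
  list(
    seed = 1L,
    output_dir = file.path(tempdir(), "voxelnmf_study"),
    simulate = list(
      n = 60L, grid_dim = 16L, rank_true = 3L, blobs = 3L,
      fwhm_voxels = 4, noise_sd = 0.05,
      modalities = c("MRI", "FDG"),
      outcomes = list(
        list(name = "symptom_present", family = "binary",
             intercept = 0, age_coef = 0, load_coefs = c(6, -6, 0)),
        list(name = "severity_score", family = "continuous",
             intercept = 10, age_coef = 0.05, load_coefs = c(20, -10, 0),
             sigma = 1))),
    split = list(test_n = 12L),
    rank_scan = list(ranks = 2:5, k = 5L, repeats = 2L),
    nmf = list(vol_weight = 0.01, logdet_ridge = 1, max_iter = 200L,
               rel_tol = 1e-5, init = "nndsvd"),
    predict = list(alpha_single = 0.2, alpha_combined = 0.8,
                   cv_folds = 5L, error_summary = "median",
                   min_cases = 10L),
    evaluate = list(n_perm = 2000L, fdr_alpha = 0.05)
  )
}

#' Seeded train/test split requiring full modality coverage
#'
#' Draws `test_n` subjects uniformly at random among those with all
#' modalities available (the held-out set must support every model);
#' everyone else trains.
#'
#' @param ids_by_modality named list of subject-ID vectors, one per
#'   modality.
#' @param test_n held-out set size.
#' @param seed integer seed.
#' @return list with `train` and `test` ID vectors.
#' @export
train_test_split <- function(ids_by_modality, test_n, seed = 1L) {
  all_ids <- unique(unlist(ids_by_modality))
  complete <- Reduce(intersect, ids_by_modality)
  if (length(complete) < test_n)
    stop("only ", length(complete), " subjects have all modalities; cannot ",
         "hold out ", test_n)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  test <- sort(sample(complete, test_n))
  list(train = setdiff(all_ids, test), test = test)
}

.stage_order <- c("simulate", "rank-scan", "fit", "project", "predict",
                  "maps", "evaluate")

.log_line <- function(dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = file.path(dir, "study.log"), append = TRUE)
}

#' Run the study pipeline
#'
#' Executes the requested stages in their fixed order
#' (`simulate`, `rank-scan`, `fit`, `project`, `predict`, `maps`,
#' `evaluate`), writing each stage's artifacts under
#' `config$output_dir` and reading prerequisites from there, so stages can
#' be run in separate invocations. Re-running with the same configuration
#' reproduces the same artifacts. A missing prerequisite raises an error
#' naming the missing file.
#'
#' @param config a configuration list (see [default_study_config()]) or a
#'   path to a YAML/JSON file.
#' @param stages character subset of the stage names; default all.
#' @return (invisibly) the output directory path.
#' @export
run_study <- function(config = default_study_config(), stages = .stage_order) {
  if (is.character(config) && length(config) == 1L)
    config <- read_study_config(config)
  config <- .merge_config(default_study_config(), config)
  bad <- setdiff(stages, .stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- .stage_order[.stage_order %in% stages]
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out, "config_used.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (st in stages) {
    t0 <- Sys.time()
    .log_line(out, "stage ", st, " started (seed ", config$seed, ")")
    switch(st,
           "simulate"  = .stage_simulate(config),
           "rank-scan" = .stage_rank_scan(config),
           "fit"       = .stage_fit(config),
           "project"   = .stage_project(config),
           "predict"   = .stage_predict(config),
           "maps"      = .stage_maps(config),
           "evaluate"  = .stage_evaluate(config))
    .log_line(out, "stage ", st, " done in ",
              round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
              " s")
  }
  invisible(out)
}

.need <- function(path, stage, needed_by) {
  if (!file.exists(path))
    stop("stage '", needed_by, "' requires ", path,
         "; run stage '", stage, "' first")
  path
}

.mod_seed <- function(seed, modality, salt = 0L) {
  (seed * 131L + salt * 17L +
     sum(utf8ToInt(modality)) * 7L) %% 2147483647L
}

.stage_simulate <- function(config) {
  out <- config$output_dir
  sc <- config$simulate
  grid <- default_phantom_grid(sc$grid_dim)
  write_nifti(array(as.double(grid$mask), dim = grid$shape),
              file.path(out, "mask.nii.gz"))
  links <- lapply(sc$outcomes, function(o)
    outcome_link(o$name, o$family, o$intercept %||% 0, o$age_coef %||% 0,
                 unlist(o$load_coefs), o$sigma %||% 1))
  clin <- NULL
  for (mod in sc$modalities) {
    D <- generate_components(grid, sc$rank_true, blobs = sc$blobs,
                             fwhm_voxels = sc$fwhm_voxels,
                             seed = .mod_seed(config$seed, mod, 1L))
    # one shared cohort: loads/outcomes come from the first modality's seed
    coh <- generate_cohort(D, n = sc$n, noise_sd = sc$noise_sd, grid = grid,
                           outcome_links = links,
                           seed = .mod_seed(config$seed, sc$modalities[1], 2L))
    mdir <- file.path(out, "images", mod)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    X <- coh$X$values
    for (i in seq_len(nrow(X)))
      write_nifti(devectorize_volume(X[i, ], grid, 0),
                  file.path(mdir, paste0(rownames(X)[i], ".nii.gz")),
                  datatype = "float64")
    utils::write.csv(
      data.frame(subject_id = rownames(coh$truth$L), coh$truth$L,
                 check.names = FALSE),
      file.path(out, paste0("truth_loads_", mod, ".csv")), row.names = FALSE)
    if (is.null(clin)) clin <- coh$clinical
  }
  utils::write.csv(clin, file.path(out, "clinical.csv"), row.names = FALSE)
  split <- train_test_split(
    stats::setNames(rep(list(clin$subject_id), length(sc$modalities)),
                    sc$modalities),
    test_n = config$split$test_n, seed = config$seed)
  jsonlite::write_json(split, file.path(out, "split.json"), pretty = TRUE)
  invisible(out)
}

.load_modality <- function(config, mod, subjects = NULL) {
  out <- config$output_dir
  mask <- read_nifti(.need(file.path(out, "mask.nii.gz"),
                           "simulate", "load"))
  grid <- masked_grid(mask$data, mask$affine)
  mdir <- file.path(out, "images", mod)
  if (!dir.exists(mdir))
    stop("no images for modality ", mod, " under ", mdir,
         "; run stage 'simulate' first (or point paths at real data)")
  paths <- sort(list.files(mdir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  if (!is.null(subjects)) {
    keep <- ids %in% subjects
    paths <- paths[keep]; ids <- ids[keep]
  }
  modality <- if (mod %in% c("MRI", "FDG")) mod else "other"
  load_image_set(paths, grid, modality = modality, subject_ids = ids)
}

.read_split <- function(config) {
  jsonlite::read_json(.need(file.path(config$output_dir, "split.json"),
                            "simulate", "split"), simplifyVector = TRUE)
}

.nmf_cfg <- function(config, rank, seed) {
  nc <- config$nmf
  nmf_config(rank = rank, vol_weight = nc$vol_weight,
             logdet_ridge = nc$logdet_ridge, max_iter = nc$max_iter,
             rel_tol = nc$rel_tol, seed = seed, init = nc$init)
}

.stage_rank_scan <- function(config) {
  out <- config$output_dir
  split <- .read_split(config)
  for (mod in config$simulate$modalities) {
    X <- .load_modality(config, mod, split$train)
    rs <- config$rank_scan
    scan <- cv_rank_scan(X, ranks = unlist(rs$ranks), k = rs$k,
                         repeats = rs$repeats,
                         config = .nmf_cfg(config, 2L, config$seed),
                         seed = .mod_seed(config$seed, mod, 3L))
    utils::write.csv(scan$errors,
                     file.path(out, paste0("rank_scan_", mod, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(modality = mod, chosen_rank = scan$chosen_rank, rule = scan$rule,
           seed = config$seed),
      file.path(out, paste0("chosen_rank_", mod, ".json")),
      auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}

.chosen_rank <- function(config, mod) {
  path <- file.path(config$output_dir, paste0("chosen_rank_", mod, ".json"))
  if (file.exists(path))
    return(jsonlite::read_json(path)$chosen_rank)
  config$simulate$rank_true          # fall back to the planted rank
}

.stage_fit <- function(config) {
  out <- config$output_dir
  split <- .read_split(config)
  for (mod in config$simulate$modalities) {
    X <- .load_modality(config, mod, split$train)
    r <- .chosen_rank(config, mod)
    fit <- fit_minvol_nmf(X, .nmf_cfg(config, r,
                                      .mod_seed(config$seed, mod, 4L)))
    write_map_nifti(fit$model,
                    file.path(out, paste0("dictionary_", mod, ".nii.gz")))
    utils::write.csv(
      data.frame(subject_id = rownames(fit$model$loads), fit$model$loads,
                 check.names = FALSE),
      file.path(out, paste0("loads_train_", mod, ".csv")), row.names = FALSE)
    saveRDS_free <- list(rank = r, lambda = fit$model$lambda,
                         converged = fit$model$converged,
                         iterations = fit$summary$iterations_run,
                         reconstruction_mae = fit$summary$reconstruction_mae,
                         objective_trace = fit$model$objective_trace)
    jsonlite::write_json(saveRDS_free,
                         file.path(out, paste0("nmf_fit_", mod, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

.read_dictionary <- function(config, mod) {
  out <- config$output_dir
  img <- read_nifti(.need(file.path(out, paste0("dictionary_", mod, ".nii.gz")),
                          "fit", "project/predict"))
  mask <- read_nifti(file.path(out, "mask.nii.gz"))
  grid <- masked_grid(mask$data, mask$affine)
  r <- dim(img$data)[4]
  D <- t(vapply(seq_len(r),
                function(j) vectorize_volume(img$data[, , , j], grid),
                numeric(n_voxels(grid))))
  rownames(D) <- sprintf("comp_%02d", seq_len(r))
  list(D = D, grid = grid)
}

.read_loads <- function(path, stage, needed_by) {
  df <- utils::read.csv(.need(path, stage, needed_by), check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.stage_project <- function(config) {
  out <- config$output_dir
  split <- .read_split(config)
  for (mod in config$simulate$modalities) {
    dict <- .read_dictionary(config, mod)
    X_test <- .load_modality(config, mod, split$test)
    L <- project_loads(X_test, dict$D)
    utils::write.csv(data.frame(subject_id = rownames(L), L,
                                check.names = FALSE),
                     file.path(out, paste0("loads_test_", mod, ".csv")),
                     row.names = FALSE)
  }
  invisible(out)
}

.model_sets <- function(config) {
  mods <- config$simulate$modalities
  sets <- as.list(mods)
  if (length(mods) >= 2L) sets <- c(sets, list(mods))
  sets
}

.set_label <- function(set) paste(set, collapse = "+")

.stage_predict <- function(config) {
  out <- config$output_dir
  pc <- config$predict
  clinical <- read_clinical_table(.need(file.path(out, "clinical.csv"),
                                        "simulate", "predict"))
  loads_train <- lapply(stats::setNames(config$simulate$modalities,
                                        config$simulate$modalities),
                        function(m) .read_loads(
                          file.path(out, paste0("loads_train_", m, ".csv")),
                          "fit", "predict"))
  models <- list()
  for (o in config$simulate$outcomes) {
    spec <- outcome_spec(o$name, o$family)
    for (set in .model_sets(config)) {
      lbl <- .set_label(set)
      alpha <- if (length(set) > 1L) pc$alpha_combined else pc$alpha_single
      des <- assemble_design(loads_train[set], clinical, spec,
                             min_cases = pc$min_cases)
      fam <- if (o$family == "binary") "binary" else "continuous"
      model <- fit_elastic_net(des$design, des$response, family = fam,
                               alpha = alpha, cv_folds = pc$cv_folds,
                               seed = .mod_seed(config$seed, lbl, 5L),
                               outcome_name = o$name)
      key <- paste(o$name, lbl, sep = "|")
      models[[key]] <- list(
        outcome = o$name, family = fam, modalities = set, alpha = alpha,
        lambda = model$lambda, intercept = model$intercept,
        coefficients = as.list(model$coefficients),
        coefficients_std = as.list(model$coefficients_std),
        center = as.list(model$center), scale = as.list(model$scale),
        predictors = model$predictors, cv_folds = model$cv_folds,
        seed = model$seed)
    }
  }
  jsonlite::write_json(models, file.path(out, "prediction_models.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

.rehydrate_model <- function(m) {
  structure(list(
    outcome = m$outcome, family = m$family, alpha = m$alpha,
    lambda = m$lambda, intercept = m$intercept,
    coefficients = unlist(m$coefficients),
    coefficients_std = unlist(m$coefficients_std),
    center = unlist(m$center), scale = unlist(m$scale),
    predictors = unlist(m$predictors), cv_folds = m$cv_folds,
    seed = m$seed), class = "prediction_model")
}

.read_models <- function(config) {
  path <- .need(file.path(config$output_dir, "prediction_models.json"),
                "predict", "maps/evaluate")
  lapply(jsonlite::read_json(path, simplifyVector = FALSE), .rehydrate_model)
}

.stage_maps <- function(config) {
  out <- config$output_dir
  models <- .read_models(config)
  for (key in names(models)) {
    model <- models[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    set <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
    for (mod in set) {
      dict <- .read_dictionary(config, mod)
      comp_names <- paste(mod, rownames(dict$D), sep = "_")
      map <- build_coefficient_map(model, dict$D, dict$grid,
                                   components = comp_names)
      write_map_nifti(map, file.path(
        out, paste0("coefmap_", parts[1], "_", gsub("\\+", "_", parts[2]),
                    "_", mod, ".nii.gz")))
    }
  }
  invisible(out)
}

.stage_evaluate <- function(config) {
  out <- config$output_dir
  pc <- config$predict
  models <- .read_models(config)
  clinical <- read_clinical_table(.need(file.path(out, "clinical.csv"),
                                        "simulate", "evaluate"))
  split <- .read_split(config)
  mods <- config$simulate$modalities
  loads <- list(
    train = lapply(stats::setNames(mods, mods), function(m)
      .read_loads(file.path(out, paste0("loads_train_", m, ".csv")),
                  "fit", "evaluate")),
    test = lapply(stats::setNames(mods, mods), function(m)
      .read_loads(file.path(out, paste0("loads_test_", m, ".csv")),
                  "project", "evaluate")))

  rows <- list(); err_store <- list()
  for (key in names(models)) {
    model <- models[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    set <- strsplit(parts[2], "+", fixed = TRUE)[[1]]
    spec <- outcome_spec(model$outcome,
                         if (model$family == "binary") "binary"
                         else "continuous")
    for (split_name in c("train", "test")) {
      des <- tryCatch(
        assemble_design(loads[[split_name]][set], clinical, spec,
                        min_cases = max(3L, if (split_name == "test") 3L
                                        else pc$min_cases)),
        error = function(e) NULL)
      if (is.null(des)) next
      pred <- predict_outcome(model, des$design)
      if (model$family == "binary") {
        cc <- confusion_counts(des$response, pred$label)
        err <- as.numeric(des$response != pred$label)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = model$outcome, family = model$family,
          modality = parts[2], split = split_name, n = length(err),
          n_positive = sum(des$response == 1),
          mcc = mcc(cc$tp, cc$fp, cc$tn, cc$fn),
          accuracy = accuracy(cc$tp, cc$fp, cc$tn, cc$fn),
          error = mean(err), r2 = NA_real_, mae = NA_real_)
      } else {
        err <- abs(des$response - pred)
        mae <- if (identical(pc$error_summary, "mean"))
          mean_abs_error(des$response, pred)
        else median_abs_error(des$response, pred)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = model$outcome, family = model$family,
          modality = parts[2], split = split_name, n = length(err),
          n_positive = NA_integer_, mcc = NA_real_, accuracy = NA_real_,
          error = mean(err), r2 = r_squared(des$response, pred), mae = mae)
      }
      err_store[[paste(model$outcome, parts[2], split_name, sep = "|")]] <-
        stats::setNames(err, des$subjects)
    }
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(out, "evaluation.csv"),
                   row.names = FALSE)

  # paired modality comparisons on shared test subjects, FDR-adjusted
  if (length(mods) >= 2L) {
    comp <- list()
    for (o in config$simulate$outcomes) {
      a <- err_store[[paste(o$name, mods[1], "test", sep = "|")]]
      b <- err_store[[paste(o$name, mods[2], "test", sep = "|")]]
      if (is.null(a) || is.null(b)) next
      shared <- intersect(names(a), names(b))
      if (length(shared) < 5L) next
      p <- compare_paired_errors(a[shared], b[shared],
                                 n_perm = config$evaluate$n_perm,
                                 seed = .mod_seed(config$seed, o$name, 6L))
      comp[[length(comp) + 1L]] <- data.frame(
        outcome = o$name, modality_a = mods[1], modality_b = mods[2],
        n = length(shared), mean_error_a = mean(a[shared]),
        mean_error_b = mean(b[shared]), p_value = p)
    }
    if (length(comp)) {
      cmp <- do.call(rbind, comp)
      cmp$q_value <- fdr_adjust(cmp$p_value)
      utils::write.csv(cmp, file.path(out, "modality_comparisons.csv"),
                       row.names = FALSE)
    }
  }
  invisible(out)
}
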