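# Pipeline orchestration: generate -> solve -> decompose -> embed ->
# train -> evaluate, with seeded stage reproducibility and on-disk
# artifacts. The full default configuration mirrors the study design the
# package is built around: 7 reference vessels x 200 perturbations + 7
# originals = 1407 meshes, 10 retained POD modes per field, an 80/20
# train/validation split, and a 70-tree depth-20 regressor chain.

#' Pipeline run configuration
#'
#' Collects every stage's settings with the pipeline defaults. All
#' randomness is derived from the single `seed` (see
#' [derive_stage_seeds()]), so a run is fully reproducible.
#'
#' @param n_refs Number of reference vessels.
#' @param n_perturb Random phantoms per reference.
#' @param length_mm,radius_mm Reference vessel length and mean radius.
#' @param n_ax,n_circ,n_rad Mesh resolution (axial stations,
#'   circumferential points, interior radial rings).
#' @param bounds Perturbation bounds ([perturbation_bounds()]).
#' @param solver A [solver_config()].
#' @param solver_backend Registered solver backend name.
#' @param rheology A [blood_rheology()].
#' @param n_modes Retained POD modes per field (ignored if
#'   `energy_threshold` is set).
#' @param energy_threshold Optional singular-value energy threshold in
#'   (0, 1] used instead of a fixed mode count.
#' @param perplexity,tsne_iter,k_nn Embedding settings.
#' @param chain A [chain_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param split Training fraction in (0, 1).
#' @param seed Master seed.
#' @param outdir Output directory for artifacts, or `NULL` to keep the
#'   run in memory only.
#' @return A `run_config` object.
#' @export
run_config <- function(n_refs = 7L, n_perturb = 200L,
                       length_mm = 30, radius_mm = 1.5,
                       n_ax = 101L, n_circ = 32L, n_rad = 4L,
                       bounds = perturbation_bounds(),
                       solver = solver_config(), solver_backend = "quasi1d",
                       rheology = blood_rheology(),
                       n_modes = 10L, energy_threshold = NULL,
                       perplexity = 30, tsne_iter = 500L, k_nn = 5L,
                       chain = chain_config(),
                       split = 0.8, seed = 1L, outdir = NULL) {
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  if (n_modes < 1L) stop("n_modes must be at least 1")
  if (!is.null(energy_threshold) &&
      (energy_threshold <= 0 || energy_threshold > 1))
    stop("energy_threshold must lie in (0, 1]")
  structure(
    list(n_refs = as.integer(n_refs), n_perturb = as.integer(n_perturb),
         length_mm = length_mm, radius_mm = radius_mm,
         n_ax = as.integer(n_ax), n_circ = as.integer(n_circ),
         n_rad = as.integer(n_rad),
         bounds = bounds, solver = solver, solver_backend = solver_backend,
         rheology = rheology, n_modes = as.integer(n_modes),
         energy_threshold = energy_threshold,
         perplexity = perplexity, tsne_iter = as.integer(tsne_iter),
         k_nn = as.integer(k_nn), chain = chain,
         split = split, seed = as.integer(seed), outdir = outdir),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the nested
#' blocks `bounds`, `solver`, `rheology` and `chain` mirror the
#' arguments of their constructors. Missing keys keep the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("bounds", "solver", "rheology", "chain"))]
  if (!is.null(y$bounds)) args$bounds <- do.call(perturbation_bounds, y$bounds)
  if (!is.null(y$solver)) args$solver <- do.call(solver_config, y$solver)
  if (!is.null(y$rheology)) args$rheology <- do.call(blood_rheology, y$rheology)
  if (!is.null(y$chain)) args$chain <- do.call(chain_config, y$chain)
  do.call(run_config, args)
}

#' Serialise a run configuration to YAML text
#' @param cfg A `run_config`.
#' @return YAML string.
#' @export
format_run_config <- function(cfg) {
  flat <- lapply(unclass(cfg), function(x)
    if (is.list(x) || inherits(x, "chain_config")) unclass(x) else x)
  flat$chain$order <- NULL
  yaml::as.yaml(flat)
}

#' Derive per-stage seeds from the master seed
#'
#' Each stage gets its own deterministic seed,
#' `(master * 8191 + offset) mod (2^31 - 1)`, with offsets geometry = 1,
#' embed = 2, chain = 3, split = 4, so stages can be rerun in isolation
#' with the seed the full run would have used.
#'
#' @param seed Master seed (integer).
#' @return Named list of integer stage seeds.
#' @export
derive_stage_seeds <- function(seed) {
  base <- (as.double(seed) %% 2147483647) * 8191
  mk <- function(off) as.integer((base + off) %% 2147483647)
  list(geometry = mk(1), embed = mk(2), chain = mk(3), split = mk(4))
}

.stage_time <- function(log, stage, t0) {
  rbind(log, data.frame(stage = stage,
                        seconds = as.numeric(Sys.time()) - t0))
}

#' Run the full reconstruction pipeline
#'
#' Executes every stage: phantom-dataset generation, surrogate flow
#' solves, cPOD of the pressure and WSS solution matrices, 2-D t-SNE
#' shape embedding, train/test split, regressor-chain fitting, and
#' held-out evaluation with range-normalised NMAE/NRMSE (the range taken
#' over the full dataset per field). Also scores the pure 10-mode
#' truncation (reconstruction from each mesh's own coefficients) over
#' all meshes, the upper bound on what the regression can achieve.
#'
#' @param cfg A [run_config()].
#' @param progress Print per-stage progress messages.
#' @return A `pipeline_run`: list with `cfg`, `seeds`, `dataset`,
#'   `solutions`, per-field `bases` (truncated `pod_basis`), `sigma`
#'   (full spectra), `norm_ranges`, `embedding`, `split` (train/test
#'   index vectors), `chains`, `reports` (`$ml` held-out and `$trunc`
#'   all-mesh, per field), `coef_rmse` (data frame), `timings`.
#'   Artifacts are written under `cfg$outdir` if set (see
#'   [write_run_artifacts()]).
#' @export
run_pipeline <- function(cfg = run_config(), progress = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- derive_stage_seeds(cfg$seed)
  timings <- data.frame(stage = character(), seconds = numeric())
  say <- function(...) if (progress) message(sprintf(...))

  t0 <- as.numeric(Sys.time())
  refs <- reference_vessels(cfg$n_refs, cfg$length_mm, cfg$radius_mm,
                            cfg$n_ax, cfg$n_circ, cfg$n_rad)
  dataset <- generate_dataset(refs, cfg$n_perturb, seed = seeds$geometry,
                              bounds = cfg$bounds, nodes = TRUE)
  timings <- .stage_time(timings, "generate", t0)
  say("generate: %d geometries", length(dataset))

  t0 <- as.numeric(Sys.time())
  solver <- get_solver(cfg$solver_backend)
  solutions <- lapply(dataset, solver, cfg = cfg$solver, rheo = cfg$rheology)
  timings <- .stage_time(timings, "solve", t0)
  say("solve: %d flow solutions", length(solutions))

  t0 <- as.numeric(Sys.time())
  fields <- c("pressure", "wss")
  matrices <- bases <- sigma <- norm_ranges <- list()
  for (f in fields) {
    A <- assemble_solution_matrix(solutions, f)
    full <- pod_decompose(A)
    bases[[f]] <- if (!is.null(cfg$energy_threshold))
      pod_truncate(full, energy = cfg$energy_threshold)
    else pod_truncate(full, k = min(cfg$n_modes, full$k))
    sigma[[f]] <- full$sigma
    norm_ranges[[f]] <- max(A) - min(A)
    matrices[[f]] <- A
  }
  timings <- .stage_time(timings, "decompose", t0)
  say("decompose: k = %d (pressure), %d (wss)",
      bases$pressure$k, bases$wss$k)

  t0 <- as.numeric(Sys.time())
  shapes <- shape_matrix(dataset)
  parents <- vapply(dataset, `[[`, "", "parent_id")
  embedding <- embed_dataset(shapes, perplexity = cfg$perplexity,
                             seed = seeds$embed, k_nn = cfg$k_nn,
                             max_iter = cfg$tsne_iter, parent_ids = parents)
  timings <- .stage_time(timings, "embed", t0)
  say("embed: %d points", nrow(embedding$coords))

  t0 <- as.numeric(Sys.time())
  M <- length(dataset)
  set.seed(seeds$split)
  perm <- sample.int(M)
  n_train <- max(1L, round(cfg$split * M))
  split <- list(train = sort(perm[seq_len(n_train)]),
                test = sort(perm[-seq_len(n_train)]))
  chains <- reports <- list()
  coef_rmse <- list()
  for (f in fields) {
    ccfg <- cfg$chain
    ccfg$seed <- seeds$chain
    chain <- fit_coefficient_chain(embedding$coords[split$train, , drop = FALSE],
                                   bases[[f]]$coefficients[split$train, , drop = FALSE],
                                   ccfg)
    chains[[f]] <- chain
    pred <- predict_chain(chain, embedding$coords[split$test, , drop = FALSE])
    truth <- bases[[f]]$coefficients[split$test, , drop = FALSE]
    coef_rmse[[f]] <- data.frame(
      field = f, mode = seq_len(chain$k),
      rmse_percent = vapply(seq_len(chain$k), function(j)
        coefficient_rmse_percent(pred, truth, j,
                                 norm_range = chain$train_ranges[j]), 0))
    recon_ml <- pod_reconstruct(pred, bases[[f]])
    ids <- attr(matrices[[f]], "mesh_ids")
    reports[[f]] <- list(
      ml = evaluate_test_set(matrices[[f]][split$test, , drop = FALSE],
                             recon_ml, field = f,
                             norm_range = norm_ranges[[f]],
                             mesh_ids = ids[split$test]),
      trunc = evaluate_test_set(matrices[[f]],
                                pod_reconstruct(bases[[f]]$coefficients,
                                                bases[[f]]),
                                field = f, norm_range = norm_ranges[[f]],
                                mesh_ids = ids))
  }
  timings <- .stage_time(timings, "train+evaluate", t0)
  for (f in fields)
    say("%s: held-out NMAE %.2f%%, NRMSE %.2f%% (truncation NRMSE %.3f%%)",
        f, reports[[f]]$ml$mean_nmae, reports[[f]]$ml$mean_nrmse,
        reports[[f]]$trunc$mean_nrmse)

  run <- structure(
    list(cfg = cfg, seeds = seeds, dataset = dataset, solutions = solutions,
         bases = bases, sigma = sigma, norm_ranges = norm_ranges,
         embedding = embedding, split = split, chains = chains,
         reports = reports, coef_rmse = do.call(rbind, coef_rmse),
         timings = timings),
    class = "pipeline_run")
  if (!is.null(cfg$outdir)) write_run_artifacts(run, cfg$outdir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d meshes, k = %d/%d modes (pressure/wss), seed %d\n",
              length(x$dataset), x$bases$pressure$k, x$bases$wss$k, x$cfg$seed))
  for (f in names(x$reports)) print(x$reports[[f]]$ml)
  invisible(x)
}

#' Persist the artifacts of a pipeline run
#'
#' Writes, under `dir`: `manifest.yaml` (config, derived seeds, stage
#' wall-times), `params.csv` (perturbation log), per-field
#' `sigma_<field>.csv` and `coefficients` CSVs (via [write_pod_csv()]),
#' `embedding.csv`, `metrics_<field>.csv` (held-out NMAE/NRMSE per mesh
#' plus summary), `metrics_trunc_<field>.csv` (all-mesh truncation
#' errors), `coef_rmse.csv`, and RDS snapshots of the dataset, solutions,
#' bases, embedding and chains for stage-wise reuse.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c(format_run_config(run$cfg), "",
               yaml::as.yaml(list(stage_seeds = run$seeds,
                                  timings = stats::setNames(
                                    as.list(round(run$timings$seconds, 3)),
                                    run$timings$stage)))),
             file.path(dir, "manifest.yaml"))
  utils::write.csv(dataset_params(run$dataset), file.path(dir, "params.csv"),
                   row.names = FALSE)
  for (f in names(run$bases)) {
    b <- run$bases[[f]]
    b$sigma <- run$sigma[[f]]
    write_pod_csv(b, file.path(dir, paste0("pod_", f)))
    write_error_report_csv(run$reports[[f]]$ml,
                           file.path(dir, sprintf("metrics_%s.csv", f)))
    write_error_report_csv(run$reports[[f]]$trunc,
                           file.path(dir, sprintf("metrics_trunc_%s.csv", f)))
  }
  write_embedding_csv(run$embedding, file.path(dir, "embedding.csv"))
  utils::write.csv(run$coef_rmse, file.path(dir, "coef_rmse.csv"),
                   row.names = FALSE)
  saveRDS(run$dataset, file.path(dir, "dataset.rds"))
  saveRDS(run$solutions, file.path(dir, "solutions.rds"))
  saveRDS(run$bases, file.path(dir, "bases.rds"))
  saveRDS(run$embedding, file.path(dir, "embedding.rds"))
  saveRDS(run$chains, file.path(dir, "chains.rds"))
  saveRDS(list(cfg = run$cfg, seeds = run$seeds,
               norm_ranges = run$norm_ranges, split = run$split),
          file.path(dir, "run_meta.rds"))
  invisible(dir)
}

#' Load a persisted pipeline run
#'
#' Restores the RDS artifacts written by [write_run_artifacts()] into a
#' structure sufficient for [predict_unseen()].
#'
#' @param dir Run directory.
#' @return A `pipeline_run`-like list (without the metric reports).
#' @export
load_run <- function(dir) {
  meta <- readRDS(file.path(dir, "run_meta.rds"))
  structure(
    list(cfg = meta$cfg, seeds = meta$seeds,
         norm_ranges = meta$norm_ranges, split = meta$split,
         dataset = readRDS(file.path(dir, "dataset.rds")),
         solutions = readRDS(file.path(dir, "solutions.rds")),
         bases = readRDS(file.path(dir, "bases.rds")),
         embedding = readRDS(file.path(dir, "embedding.rds")),
         chains = readRDS(file.path(dir, "chains.rds"))),
    class = "pipeline_run")
}

#' Reconstruct the fields of an unseen geometry
#'
#' The fast path the pipeline exists for: place the new mesh in the
#' t-SNE space by out-of-sample interpolation, predict its POD
#' coefficients with the regressor chains, and recombine with the stored
#' modes — no flow solve involved. For validation the function also runs
#' the surrogate solver on the same geometry and reports NMAE/NRMSE of
#' the prediction against that fresh ground truth, normalised by the
#' training run's dataset-wide field ranges (when available).
#'
#' @param run A `pipeline_run` (from [run_pipeline()] or [load_run()]).
#' @param geom A `vessel_geometry` at the run's resolution, built with
#'   coordinates.
#' @param solve_reference Also solve the surrogate for error reporting.
#' @return List with `coords`, per-field `pressure`/`wss` predicted
#'   fields, `reference` (the fresh `flow_solution`, if requested) and
#'   `errors` (data frame field, nmae_pct, nrmse_pct).
#' @export
predict_unseen <- function(run, geom, solve_reference = TRUE) {
  stopifnot(inherits(run, "pipeline_run"), inherits(geom, "vessel_geometry"))
  ref_geom <- run$dataset[[1L]]
  if (geom$n_surface != ref_geom$n_surface || geom$n_volume != ref_geom$n_volume)
    stop("geometry resolution does not match the run")
  y <- out_of_sample_embed(run$embedding, geom)
  fields <- list()
  for (f in names(run$chains)) {
    chat <- predict_chain(run$chains[[f]], y)
    fields[[f]] <- pod_reconstruct(chat, run$bases[[f]])
  }
  out <- list(coords = y, pressure = fields$pressure, wss = fields$wss)
  if (solve_reference) {
    cfg <- run$cfg
    solver <- if (!is.null(cfg)) get_solver(cfg$solver_backend) else get_solver()
    gt <- if (!is.null(cfg)) solver(geom, cfg = cfg$solver, rheo = cfg$rheology)
          else solver(geom)
    ranges <- run$norm_ranges
    err <- do.call(rbind, lapply(names(fields), function(f) {
      rng <- if (!is.null(ranges[[f]])) ranges[[f]] else
        max(gt[[f]]) - min(gt[[f]])
      data.frame(field = f,
                 nmae_pct = nmae(fields[[f]], gt[[f]], rng),
                 nrmse_pct = nrmse(fields[[f]], gt[[f]], rng))
    }))
    out$reference <- gt
    out$errors <- err
  }
  out
}

#' Averaged metrics over repeated train/test splits
#'
#' Repeats the shuffle-split / chain-fit / held-out-evaluation cycle `n`
#' times with distinct seeded splits and averages the dominant-mode
#' coefficient RMSE and the field NMAE/NRMSE across repeats, smoothing
#' out the split-to-split variability of a single shuffle.
#'
#' @param run A completed `pipeline_run`.
#' @param n Number of split repeats.
#' @return Data frame (field, repeat, dominant_rmse_percent, nmae_pct,
#'   nrmse_pct) with a `summary` attribute holding the per-field means.
#' @export
split_repeat_metrics <- function(run, n = 10L) {
  stopifnot(inherits(run, "pipeline_run"))
  M <- nrow(run$embedding$coords)
  out <- list()
  for (rep_i in seq_len(n)) {
    set.seed((run$seeds$split + rep_i) %% 2147483647)
    perm <- sample.int(M)
    n_train <- max(1L, round(run$cfg$split * M))
    tr <- sort(perm[seq_len(n_train)]); te <- sort(perm[-seq_len(n_train)])
    for (f in names(run$bases)) {
      b <- run$bases[[f]]
      ccfg <- run$cfg$chain
      ccfg$seed <- run$seeds$chain + rep_i
      ch <- fit_coefficient_chain(run$embedding$coords[tr, , drop = FALSE],
                                  b$coefficients[tr, , drop = FALSE], ccfg)
      pred <- predict_chain(ch, run$embedding$coords[te, , drop = FALSE])
      A_te <- t(vapply(run$solutions[te], `[[`,
                       numeric(b$n_nodes), f))
      R <- pod_reconstruct(pred, b)
      rng <- run$norm_ranges[[f]]
      er <- evaluate_test_set(A_te, R, field = f, norm_range = rng)
      out[[length(out) + 1L]] <- data.frame(
        field = f, split_repeat = rep_i,
        dominant_rmse_percent = coefficient_rmse_percent(
          pred, b$coefficients[te, , drop = FALSE], 1L,
          norm_range = ch$train_ranges[1L]),
        nmae_pct = er$mean_nmae, nrmse_pct = er$mean_nrmse)
    }
  }
  df <- do.call(rbind, out)
  attr(df, "summary") <- stats::aggregate(
    df[c("dominant_rmse_percent", "nmae_pct", "nrmse_pct")],
    by = df["field"], FUN = mean)
  df
}

#' Chain-order sensitivity check
#'
#' Refits the regressor chains with the reversed mode order and returns
#' the per-mode coefficient RMSE for both orders — a diagnostic, not an
#' asserted property.
#'
#' @param run A completed `pipeline_run`.
#' @param field Field to check.
#' @return Data frame (order, mode, rmse_percent).
#' @export
chain_order_check <- function(run, field = "pressure") {
  stopifnot(inherits(run, "pipeline_run"))
  b <- run$bases[[field]]
  tr <- run$split$train; te <- run$split$test
  out <- list()
  for (ord_name in c("default", "reversed")) {
    ccfg <- run$cfg$chain
    ccfg$seed <- run$seeds$chain
    ccfg$order <- if (ord_name == "reversed") rev(seq_len(b$k)) else NULL
    ch <- fit_coefficient_chain(run$embedding$coords[tr, , drop = FALSE],
                                b$coefficients[tr, , drop = FALSE], ccfg)
    pred <- predict_chain(ch, run$embedding$coords[te, , drop = FALSE])
    out[[ord_name]] <- data.frame(
      order = ord_name, mode = seq_len(b$k),
      rmse_percent = vapply(seq_len(b$k), function(j)
        coefficient_rmse_percent(pred, b$coefficients[te, , drop = FALSE], j,
                                 norm_range = ch$train_ranges[j]), 0))
  }
  do.call(rbind, out)
}
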