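# Ensemble replication, analytic reports, presets and file output.

.config_keys <- c("model", "M", "nu", "p_m", "p_h", "omega", "arrival_mode",
                  "n_steps", "record_every", "replicates", "base_seed",
                  "init", "label")

#' Build an ensemble configuration
#'
#' A flat list of run settings for [run_ensemble()]. Unknown keys raise a
#' named configuration error.
#'
#' @param model One of `"neutral"`, `"sweep"`, `"full"`.
#' @param M,nu,p_m,p_h,omega,arrival_mode,n_steps,record_every As in
#'   [model_params()]. For `model = "sweep"`, `nu` sets the neutral
#'   equilibrium generating the initial diversity; `n_steps` caps the
#'   run (default 50 fixation times).
#' @param replicates Number of independent realizations (>= 1).
#' @param base_seed Replicate `r` runs with seed `base_seed + r`.
#' @param init Initial condition: `"equilibrium"` (Chinese-restaurant
#'   draw at `nu`) or `"monomorphic"`.
#' @param label Free-text tag carried into output headers.
#' @return A list of class `"msweep_config"`.
#' @export
ensemble_config <- function(model = c("neutral", "sweep", "full"),
                            M, nu = 0, p_m = 0, p_h = 0, omega = 0,
                            arrival_mode = "none", n_steps = NULL,
                            record_every = M, replicates = 100,
                            base_seed = 1,
                            init = c("equilibrium", "monomorphic"),
                            label = "") {
  model <- match.arg(model)
  init <- match.arg(init)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1)
    stop("`replicates` must be >= 1", call. = FALSE)
  if (is.null(n_steps)) {
    n_steps <- switch(model,
      neutral = ceiling(3 * tau_eq(M, nu)),
      sweep = ceiling(50 * tau_fix(M, p_m, p_h)),
      full = ceiling(tau_fix(M, p_m, p_h) +
                       if (nu > 0) 3 * tau_eq(M, nu) else 0))
  }
  cfg <- list(model = model, M = as.integer(M), nu = nu, p_m = p_m, p_h = p_h,
              omega = omega, arrival_mode = arrival_mode,
              n_steps = floor(n_steps), record_every = floor(record_every),
              replicates = replicates, base_seed = as.integer(base_seed),
              init = init, label = label)
  validate_config(cfg)
}

#' Validate an ensemble configuration list
#'
#' @param cfg A named list; keys must be a subset of the known
#'   configuration keys.
#' @return The validated config with class `"msweep_config"`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$replicates) || cfg$replicates < 1)
    stop("`replicates` must be >= 1", call. = FALSE)
  # parameter invariants are checked by model_params
  model_params(M = cfg$M, nu = cfg$nu, p_m = cfg$p_m, p_h = cfg$p_h,
               omega = cfg$omega, arrival_mode = cfg$arrival_mode,
               n_steps = cfg$n_steps, record_every = cfg$record_every)
  structure(cfg, class = "msweep_config")
}

#' Experiment presets
#'
#' Named parameter sets for the three headline experiments: the neutral
#' equilibration run (`"fig2"`: M = 10000, nu = 0.01), the single-gene
#' sweep without restoration (`"fig3"`: nu = 0.02, p_h = 0.2,
#' p_m = 0.8), and the competing-time-scales model (`"fig4-single"`,
#' `"fig4-periodic"`, `"fig4-poisson"`: nu = 0.01, p_h = 0.1,
#' p_m = 0.9). `scale = "paper"` uses M = 10000; `scale = "desk"`
#' substitutes M = 1000 with all rates unchanged and 100 replicates, for
#' quick desk-scale runs.
#'
#' @param name Preset name.
#' @param scale `"desk"` (default) or `"paper"`.
#' @return An `"msweep_config"`.
#' @examples
#' preset("fig3", "desk")
#' @export
preset <- function(name = c("fig2", "fig3", "fig4-single", "fig4-periodic",
                            "fig4-poisson"),
                   scale = c("desk", "paper")) {
  if (!is.character(name) || !(name[1] %in% c("fig2", "fig3", "fig4-single",
                                              "fig4-periodic", "fig4-poisson")))
    stop("unknown preset; valid names: fig2, fig3, fig4-single, ",
         "fig4-periodic, fig4-poisson", call. = FALSE)
  name <- match.arg(name)
  scale <- match.arg(scale)
  M <- if (scale == "paper") 10000L else 1000L
  if (name == "fig2") {
    return(ensemble_config("neutral", M = M, nu = 0.01,
                           n_steps = ceiling(3 * tau_eq(M, 0.01)),
                           record_every = M, replicates = 100,
                           init = "monomorphic", label = name))
  }
  if (name == "fig3") {
    return(ensemble_config("sweep", M = M, nu = 0.02, p_h = 0.2, p_m = 0.8,
                           record_every = M, replicates = 100,
                           label = name))
  }
  nu <- 0.01; p_h <- 0.1; p_m <- 0.9
  w0 <- omega0(M, nu, p_m, p_h)
  mode <- sub("fig4-", "", name)
  omega <- if (mode == "single") 0 else 2 * w0
  n_steps <- if (mode == "single") {
    ceiling(tau_fix(M, p_m, p_h) + 3 * tau_eq(M, nu))
  } else {
    ceiling(6 / omega)
  }
  ensemble_config("full", M = M, nu = nu, p_m = p_m, p_h = p_h,
                  omega = omega, arrival_mode = mode, n_steps = n_steps,
                  record_every = M, replicates = 100, label = name)
}

#' Run an ensemble of independent replicates
#'
#' Replicate `r` runs with seed `base_seed + r`, so the whole ensemble is
#' reproducible from the configuration alone. Per-replicate summary
#' statistics depend on the model: the neutral model reports the plateau
#' diversity `S0` (mean over the final third of the run); the sweep model
#' reports initial and final diversity `S_i`, `S_f` and the empirical
#' fixation time; the full model reports first-episode drop/recovery
#' statistics. Aggregates (mean, sd, median, interquartile range, min,
#' max) are computed per statistic.
#'
#' @param cfg An `"msweep_config"` (see [ensemble_config()], [preset()]).
#' @param out_dir Optional directory: writes `summary.tsv` and one
#'   trajectory TSV per replicate.
#' @param keep_trajectories Keep per-replicate trajectories in the return
#'   value (default FALSE to bound memory).
#' @return A list of class `"ensemble_summary"`: `config`, `replicates`
#'   (tibble of per-replicate rows), `aggregate` (tibble of summary
#'   statistics), and optionally `trajectories`.
#' @examples
#' cfg <- ensemble_config("neutral", M = 100, nu = 0.05, n_steps = 6000,
#'                        replicates = 5, base_seed = 1)
#' run_ensemble(cfg)$aggregate
#' @export
run_ensemble <- function(cfg, out_dir = NULL, keep_trajectories = FALSE) {
  cfg <- validate_config(unclass(cfg))
  rows <- vector("list", cfg$replicates)
  trajs <- if (keep_trajectories || !is.null(out_dir)) vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    seed <- cfg$base_seed + r
    set.seed(seed)
    if (cfg$model == "neutral") {
      p <- model_params(cfg$M, nu = cfg$nu, n_steps = cfg$n_steps,
                        record_every = cfg$record_every)
      init <- if (cfg$init == "equilibrium")
        sample_equilibrium_state(cfg$M, cfg$nu) else NULL
      run <- run_neutral(p, init_state = init)
      tr <- run$trajectory
      late <- tr[tr$step >= 2 / 3 * cfg$n_steps, ]
      rows[[r]] <- tibble::tibble(
        replicate = r, seed = seed,
        S0 = mean(late$S), S_min = min(tr$S), S_max = max(tr$S),
        S_mean = mean(tr$S))
      if (!is.null(trajs)) trajs[[r]] <- tr
    } else if (cfg$model == "sweep") {
      st <- if (cfg$init == "monomorphic") new_monomorphic_state(cfg$M)
            else sample_equilibrium_state(cfg$M, cfg$nu)
      st <- introduce_gene(st)
      run <- run_until_fixation(st, cfg$p_m, cfg$p_h,
                                record_every = cfg$record_every,
                                max_steps = cfg$n_steps)
      s <- run$summary
      rows[[r]] <- tibble::tibble(
        replicate = r, seed = seed,
        S_i = s$S_i, S_f = s$S_f, S_ratio = s$S_f / s$S_i,
        fixation_steps = s$fixation_step, truncated = s$truncated)
      if (!is.null(trajs)) trajs[[r]] <- run$trajectory
    } else {
      p <- model_params(cfg$M, nu = cfg$nu, p_m = cfg$p_m, p_h = cfg$p_h,
                        omega = cfg$omega, arrival_mode = cfg$arrival_mode,
                        n_steps = cfg$n_steps, record_every = cfg$record_every)
      init <- if (cfg$init == "monomorphic") new_monomorphic_state(cfg$M) else NULL
      run <- run_full(p, init_state = init)
      ep <- run$episodes[1, ]
      rows[[r]] <- tibble::tibble(
        replicate = r, seed = seed,
        S0 = ep$S_start, S_min = ep$S_min, S_max = max(run$episodes$S_max),
        S_mean = mean(run$trajectory$S), S_end = run$episodes$S_end[nrow(run$episodes)],
        fixation_steps = ep$fixation_step - ep$start_step,
        episodes = nrow(run$episodes))
      if (!is.null(trajs)) trajs[[r]] <- run$trajectory
    }
  }
  per_rep <- do.call(rbind, rows)
  out <- structure(
    list(config = cfg, replicates = per_rep,
         aggregate = aggregate_ensemble(per_rep)),
    class = "ensemble_summary")
  if (keep_trajectories) out$trajectories <- trajs
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ensemble_tsv(out, file.path(out_dir, "summary.tsv"))
    for (r in seq_along(trajs)) {
      write_trajectory_tsv(trajs[[r]], file.path(out_dir, sprintf("traj_%03d.tsv", r)),
                           header = c(sprintf("replicate: %d", r),
                                      sprintf("seed: %d", cfg$base_seed + r)))
    }
  }
  out
}

#' Aggregate per-replicate statistics
#'
#' Mean, standard deviation, median, interquartile range, min and max per
#' numeric statistic; exactly recomputable from the per-replicate table.
#'
#' @param per_rep Tibble of per-replicate rows.
#' @return Tibble with one row per statistic.
#' @export
aggregate_ensemble <- function(per_rep) {
  stats_cols <- setdiff(names(per_rep), c("replicate", "seed", "truncated"))
  stats_cols <- stats_cols[vapply(per_rep[stats_cols], is.numeric, logical(1))]
  do.call(rbind, lapply(stats_cols, function(cn) {
    x <- per_rep[[cn]]
    tibble::tibble(
      statistic = cn,
      mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
      median = median(x, na.rm = TRUE),
      q25 = unname(quantile(x, 0.25, na.rm = TRUE)),
      q75 = unname(quantile(x, 0.75, na.rm = TRUE)),
      min = suppressWarnings(min(x, na.rm = TRUE)),
      max = suppressWarnings(max(x, na.rm = TRUE)))
  }))
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary: %s model, %d replicates (base seed %d)>\n",
              x$config$model, x$config$replicates, x$config$base_seed))
  print(x$aggregate)
  invisible(x)
}

#' Closed-form predictions for a parameter set
#'
#' Collects every analytic quantity for one parameter set: the
#' concentration parameter `theta`, exact and approximate equilibrium
#' diversity, equilibration and fixation times (steps and
#' meta-generations), the sweep parameter `Q0`, the critical arrival
#' frequency `omega0` and the dynamical-regime classification.
#'
#' @param params A [model_params()] object.
#' @return A named list of class `"analytic_prediction"` (all numeric
#'   except the regime label), serializable to JSON and back without
#'   loss.
#' @examples
#' analytic_report(model_params(M = 10000, nu = 0.01, p_m = 0.9, p_h = 0.1,
#'                              n_steps = 1))
#' @export
analytic_report <- function(params) {
  stopifnot(inherits(params, "model_params"))
  M <- params$M; nu <- params$nu; p_m <- params$p_m; p_h <- params$p_h
  has_nu <- nu > 0
  has_sweep <- p_m + p_h > 0
  tfix <- if (has_sweep) tau_fix(M, p_m, p_h) else Inf
  teq <- if (has_nu) tau_eq(M, nu) else Inf
  regime <- if (has_nu && has_sweep)
    classify_regime(params$omega, tfix, teq) else NULL
  structure(list(
    M = M, nu = nu, p_m = p_m, p_h = p_h, omega = params$omega,
    theta = ewens_theta(M, nu),
    S0_exact = if (has_nu) expected_diversity_exact(M, nu) else 1,
    S0_approx = if (has_nu) expected_diversity_approx(M, nu) else 0,
    tau_eq_steps = teq, tau_eq_gen = teq / M,
    tau_fix_steps = tfix, tau_fix_gen = tfix / M,
    Q0 = if (has_nu && p_m > 0) sweep_parameter_Q0(nu, p_m, p_h)
         else if (has_nu) 1 else NA_real_,
    omega0 = if (has_nu && has_sweep) omega0(M, nu, p_m, p_h) else NA_real_,
    x1 = if (!is.null(regime)) regime$x1 else NA_real_,
    x2 = if (!is.null(regime)) regime$x2 else NA_real_,
    regime = if (!is.null(regime)) regime$label else NA_character_),
    class = "analytic_prediction")
}

#' @export
print.analytic_prediction <- function(x, ...) {
  cat("<analytic_prediction>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write an analytic prediction as JSON
#'
#' @param report An `"analytic_prediction"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_analytic_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an analytic prediction from JSON
#'
#' @param path JSON file written by [write_analytic_json()].
#' @return An `"analytic_prediction"` list.
#' @export
read_analytic_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x[vapply(x, is.null, logical(1))] <- NA_real_
  structure(x, class = "analytic_prediction")
}

#' Write a trajectory as TSV
#'
#' Columns `step`, `generation`, `S`, `B`, `arrivals_seen`, preceded by
#' `#`-prefixed header lines with the resolved parameters.
#'
#' @param trajectory Tibble as in `msweep_run$trajectory`.
#' @param path Output file.
#' @param header Extra character lines for the header block.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# metasweep trajectory (package version %s)",
                       as.character(utils::packageVersion("metasweep"))),
               paste0("# ", header)[seq_along(header)]), con)
  write.table(trajectory, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ensemble summary as TSV
#'
#' Per-replicate table followed by a `#aggregate` block, both
#' tab-separated; the header records the full resolved configuration so
#' the file is reproducible from its own metadata.
#'
#' @param ens An `"ensemble_summary"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(ens, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cfg <- ens$config
  hdr <- vapply(names(cfg), function(k) sprintf("# %s: %s", k, cfg[[k]]), "")
  writeLines(c(sprintf("# metasweep ensemble (package version %s)",
                       as.character(utils::packageVersion("metasweep"))), hdr), con)
  write.table(ens$replicates, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("#aggregate", con)
  write.table(ens$aggregate, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
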