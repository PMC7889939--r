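# Pipeline orchestration: the end-to-end synthetic benchmark, per-stage
# artifact handling with manifests, and a thin command-line entry point
# (inst/cli/fesfold).  All artifacts are CSV/JSON; every stage writes a
# manifest recording its configuration, seeds, package version and input
# hashes, so a run can be reproduced from its manifests alone.

#' Default pipeline configuration
#'
#' Desk-scale defaults for the synthetic 6-D two-basin benchmark: biased
#' exploration along (d13, d24), 2000 K-means centers, reference mean
#' forces with 5 percent Gaussian noise, force-matching training with a 20
#' percent held-out split, d13 marginal validation against the exact
#' surface, umbrella sampling + WHAM along d13, and a multi-start string
#' study between the two basins.
#'
#' @return Nested named list of per-stage settings.
#' @export
default_config <- function() {
  list(
    fixture = list(name = "sym6d_wells", overrides = list()),
    explore = list(cv_dims = c(2L, 5L), n_replicas = 20L, n_steps = 1e5,
                   dt = 0.02, kappa_ext = 2, T = 300, Tbar = 3000,
                   hill_height = 0.3, hill_width = 1.5,
                   deposit_stride = 250L, save_stride = 20L),
    centers = list(n_centers = 2000L, max_samples = 5e4),
    meanforce = list(mode = "reference", noise_frac = 0.05,
                     k = 50, n_steps = 5e4, T = 300),
    train = list(layers = c(64L, 64L), features = "symmetric",
                 split_fraction = 0.2, epochs = 8000L, lr = 3e-3,
                 weight_decay = 1e-5, patience = 150L),
    profile = list(dim = 2L, n_grid = 61L, n_mc = 2e4, T = 300,
                   trim = 0.005, exact_n_mc = 4e5),
    wham = list(cv_dim = 2L, from = 4, to = 34, by = 1, spring = 2,
                n_steps = 4e4, n_seeds = 3L, T = 300, n_bins = 80L),
    string = list(n_starts = 8L, M = 24L, n_cell_samples = 300L,
                  dt = 0.005, T = 300, max_iter = 60L, tol = 0.02,
                  distance_threshold = 3)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

.write_manifest <- function(out_dir, stage, config, seed, inputs = character(0)) {
  man <- list(stage = stage, seed = seed,
              package = as.character(utils::packageVersion("fesfold")),
              config = config,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

.log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.need_artifact <- function(path, stage) {
  if (!file.exists(path))
    .stopf("%s: missing upstream artifact %s (run the producing stage first)",
           stage, path)
  path
}

#' Run the synthetic force-matching benchmark pipeline in memory
#'
#' Fixture surface -> biased exploration -> K-means centers -> reference
#' mean forces (analytic gradient + noise) -> force-matching network.
#' This is the common core of the `report` pipeline stage, the acceptance
#' benchmark and the test suite.
#'
#' @param seed base seed for every stochastic stage.
#' @param config configuration list as from [default_config()] (partial
#'   overrides allowed).
#' @param verbose log stage progress to stderr.
#' @return List with `surface`, `exploration`, `centers` (`center_set`),
#'   `records` and the trained `model`.
#' @export
benchmark_pipeline <- function(seed = 1, config = list(), verbose = FALSE) {
  cfg <- .merge_config(default_config(), config)
  surface <- make_surface(cfg$fixture$name, cfg$fixture$overrides)
  if (verbose) .log("explore", "biased sampling: %d replicas x %g steps along CVs (%s)",
                    cfg$explore$n_replicas, cfg$explore$n_steps,
                    paste(cfg$explore$cv_dims, collapse = ","))
  ex <- explore_replicas(surface, cfg$explore$cv_dims,
                         n_replicas = cfg$explore$n_replicas,
                         params = cfg$explore[setdiff(names(cfg$explore),
                                                      c("cv_dims", "n_replicas"))],
                         seed = seed)
  smp <- ex$samples
  if (nrow(smp) > cfg$centers$max_samples) {
    set.seed(seed + 7L)
    smp <- smp[sample.int(nrow(smp), cfg$centers$max_samples), , drop = FALSE]
  }
  if (verbose) .log("centers", "K-means, k = %d from %d samples",
                    cfg$centers$n_centers, nrow(smp))
  cs <- select_centers(smp, cfg$centers$n_centers, seed = seed + 1L)
  if (verbose) .log("meanforce", "mode %s", cfg$meanforce$mode)
  records <- if (identical(cfg$meanforce$mode, "reference")) {
    noisy_reference_forces(surface, cs, noise_frac = cfg$meanforce$noise_frac,
                           T = cfg$meanforce$T, seed = seed + 2L)
  } else {
    batch_mean_forces(surface, cs, k = cfg$meanforce$k,
                      T = cfg$meanforce$T, n_steps = cfg$meanforce$n_steps,
                      seed = seed + 2L)
  }
  if (verbose) .log("train", "force matching: %d records, %d max epochs",
                    nrow(records), cfg$train$epochs)
  model <- fesnet(records, layers = cfg$train$layers,
                  features = cfg$train$features,
                  split_fraction = cfg$train$split_fraction,
                  epochs = cfg$train$epochs, lr = cfg$train$lr,
                  weight_decay = cfg$train$weight_decay,
                  patience = cfg$train$patience, seed = seed + 3L)
  if (verbose) .log("train", "held-out force correlation %.4f",
                    model$report$cor_pooled)
  list(surface = surface, exploration = ex, centers = cs, records = records,
       model = model, config = cfg, seed = seed)
}

#' Marginal-validation step of the benchmark
#'
#' Computes the model's 1-D marginal over the trusted domain along the
#' configured dimension (grid spanning the central quantiles of the
#' training centers), the exact marginal of the fixture surface at the same
#' grid, and their offset-aligned comparison.
#'
#' @param bench result of [benchmark_pipeline()].
#' @param seed seed for the Monte-Carlo integrations.
#' @return List with `profile_model`, `profile_exact` (both `fe_profile`)
#'   and `comparison` (from [compare_profiles()]).
#' @export
benchmark_marginal <- function(bench, seed = 1) {
  cfg <- bench$config$profile
  dmarg <- cfg$dim
  cvals <- bench$model$centers[, dmarg]
  lo <- max(quantile(cvals, cfg$trim), bench$surface$lower[dmarg])
  hi <- min(quantile(cvals, 1 - cfg$trim), bench$surface$upper[dmarg])
  grid <- seq(lo, hi, length.out = cfg$n_grid)
  pm <- marginal_profile(bench$model, dims = dmarg, grid = grid, T = cfg$T,
                         n_mc = cfg$n_mc, seed = seed + 10L)
  pe <- marginal_1d_exact(bench$surface, dim = dmarg, grid = grid, T = cfg$T,
                          n_mc = cfg$exact_n_mc, seed = seed + 11L)
  list(profile_model = pm, profile_exact = pe,
       comparison = compare_profiles(pm, pe))
}

# ---- disk-based stage runner -----------------------------------------------

#' Run one pipeline stage against an output directory
#'
#' Commands: `make-fixture`, `explore`, `centers`, `meanforce`, `train`,
#' `profile`, `wham`, `string`, `report`.  Each stage reads its upstream
#' CSV/JSON artifacts from `out_dir`, writes its own artifacts and a
#' manifest there, and fails with a named cause if an upstream artifact is
#' missing.  `report` runs the full chain and writes `summary.json`.
#'
#' @param command stage name (see above).
#' @param out_dir artifact directory (created if needed).
#' @param config configuration overrides (see [default_config()]).
#' @param seed base seed.
#' @return Invisibly, the stage's main result object.
#' @export
run_stage <- function(command, out_dir, config = list(), seed = 1) {
  cfg <- .merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  surface <- function() {
    fx <- jsonlite::read_json(.need_artifact(pth("fixture.json"), command),
                              simplifyVector = TRUE)
    make_surface(fx$name, as.list(fx$overrides))
  }
  res <- switch(command,
    "make-fixture" = {
      jsonlite::write_json(list(name = cfg$fixture$name,
                                overrides = cfg$fixture$overrides),
                           pth("fixture.json"), auto_unbox = TRUE, digits = NA)
      .write_manifest(out_dir, "make-fixture", cfg$fixture, seed)
      .log("make-fixture", "wrote fixture.json (%s)", cfg$fixture$name)
      invisible(cfg$fixture)
    },
    "explore" = {
      surf <- surface()
      ex <- explore_replicas(surf, cfg$explore$cv_dims,
                             n_replicas = cfg$explore$n_replicas,
                             params = cfg$explore[setdiff(names(cfg$explore),
                                                          c("cv_dims", "n_replicas"))],
                             seed = seed)
      smp <- as.data.frame(ex$samples)
      names(smp) <- paste0("d.", seq_len(ncol(smp)))
      write.csv(smp, pth("samples.csv"), row.names = FALSE)
      write_hills(ex$replicas[[1L]]$hills, pth("hills.csv"))
      .write_manifest(out_dir, "explore", cfg$explore, seed, pth("fixture.json"))
      .log("explore", "%d pooled samples from %d replicas", nrow(smp),
           cfg$explore$n_replicas)
      invisible(ex)
    },
    "centers" = {
      smp <- as.matrix(read.csv(.need_artifact(pth("samples.csv"), command)))
      if (nrow(smp) > cfg$centers$max_samples) {
        set.seed(seed + 7L)
        smp <- smp[sample.int(nrow(smp), cfg$centers$max_samples), , drop = FALSE]
      }
      cs <- select_centers(smp, cfg$centers$n_centers, seed = seed + 1L)
      ctr <- as.data.frame(cs$centers)
      names(ctr) <- paste0("d.", seq_len(ncol(ctr)))
      write.csv(ctr, pth("centers.csv"), row.names = FALSE)
      .write_manifest(out_dir, "centers", cfg$centers, seed, pth("samples.csv"))
      .log("centers", "%d centers", nrow(ctr))
      invisible(cs)
    },
    "meanforce" = {
      surf <- surface()
      ctr <- as.matrix(read.csv(.need_artifact(pth("centers.csv"), command)))
      rec <- if (identical(cfg$meanforce$mode, "reference"))
        noisy_reference_forces(surf, ctr, noise_frac = cfg$meanforce$noise_frac,
                               T = cfg$meanforce$T, seed = seed + 2L)
      else
        batch_mean_forces(surf, ctr, k = cfg$meanforce$k, T = cfg$meanforce$T,
                          n_steps = cfg$meanforce$n_steps, seed = seed + 2L)
      write_mean_forces(rec, pth("mean_forces.csv"))
      .write_manifest(out_dir, "meanforce", cfg$meanforce, seed,
                      c(pth("fixture.json"), pth("centers.csv")))
      .log("meanforce", "%d records (%s)", nrow(rec), cfg$meanforce$mode)
      invisible(rec)
    },
    "train" = {
      rec <- read_mean_forces(.need_artifact(pth("mean_forces.csv"), command))
      model <- fesnet(rec, layers = cfg$train$layers,
                      features = cfg$train$features,
                      split_fraction = cfg$train$split_fraction,
                      epochs = cfg$train$epochs, lr = cfg$train$lr,
                      weight_decay = cfg$train$weight_decay,
                      patience = cfg$train$patience, seed = seed + 3L)
      save_fesnet(model, pth("model.json"))
      .write_manifest(out_dir, "train", cfg$train, seed, pth("mean_forces.csv"))
      .log("train", "held-out force correlation %.4f", model$report$cor_pooled)
      invisible(model)
    },
    "profile" = {
      surf <- surface()
      model <- load_fesnet(.need_artifact(pth("model.json"), command))
      bench <- list(surface = surf, model = model, config = cfg)
      mg <- benchmark_marginal(bench, seed = seed)
      write.csv(mg$profile_model, pth("profile_model.csv"), row.names = FALSE)
      write.csv(mg$profile_exact, pth("profile_exact.csv"), row.names = FALSE)
      .write_manifest(out_dir, "profile", cfg$profile, seed,
                      c(pth("fixture.json"), pth("model.json")))
      .log("profile", "max |dev| vs exact marginal: %.3f kcal/mol",
           mg$comparison$max_abs_dev)
      invisible(mg)
    },
    "wham" = {
      surf <- surface()
      wc <- seq(cfg$wham$from, cfg$wham$to, by = cfg$wham$by)
      win <- run_umbrella(surf, cfg$wham$cv_dim, wc, spring = cfg$wham$spring,
                          T = cfg$wham$T, n_steps = cfg$wham$n_steps,
                          n_seeds = cfg$wham$n_seeds, seed = seed + 4L)
      wr <- wham_solve(win, n_bins = cfg$wham$n_bins, T = cfg$wham$T)
      write.csv(wham_profile(wr), pth("wham_profile.csv"), row.names = FALSE)
      .write_manifest(out_dir, "wham", cfg$wham, seed, pth("fixture.json"))
      .log("wham", "%d windows, converged: %s", length(win), wr$converged)
      invisible(wr)
    },
    "string" = {
      surf <- surface()
      ctr <- surf$params$centers
      if (is.null(ctr)) .stopf("string: fixture surface has no basin centers")
      ms <- string_multistart(surf, ctr["open", ], ctr["folded", ],
                              n_starts = cfg$string$n_starts, M = cfg$string$M,
                              n_cell_samples = cfg$string$n_cell_samples,
                              dt = cfg$string$dt, T = cfg$string$T,
                              max_iter = cfg$string$max_iter,
                              tol = cfg$string$tol,
                              distance_threshold = cfg$string$distance_threshold,
                              seed = seed + 5L)
      for (i in seq_along(ms$paths))
        write_string_path(ms$paths[[i]], pth(sprintf("string_%02d.csv", i)))
      jsonlite::write_json(list(groups = ms$groups,
                                n_channels = length(ms$groups)),
                           pth("string_groups.json"), digits = NA)
      .write_manifest(out_dir, "string", cfg$string, seed, pth("fixture.json"))
      .log("string", "%d starts -> %d channels", cfg$string$n_starts,
           length(ms$groups))
      invisible(ms)
    },
    "report" = {
      for (cmd in c("make-fixture", "explore", "centers", "meanforce",
                    "train", "profile", "wham", "string"))
        run_stage(cmd, out_dir, config, seed)
      model <- load_fesnet(pth("model.json"))
      saved <- jsonlite::read_json(pth("model.json"), simplifyVector = TRUE)
      pm <- read.csv(pth("profile_model.csv"))
      pe <- read.csv(pth("profile_exact.csv"))
      cmpx <- compare_profiles(structure(pm, class = c("fe_profile", "data.frame")),
                               structure(pe, class = c("fe_profile", "data.frame")))
      pw <- read.csv(pth("wham_profile.csv"))
      # compare WHAM to the model marginal on the WHAM grid
      pmw <- marginal_profile(model, dims = cfg$profile$dim, grid = pw$x,
                              T = cfg$wham$T, n_mc = cfg$profile$n_mc,
                              seed = seed + 12L)
      cmpw <- compare_profiles(pmw,
                               structure(pw, class = c("fe_profile", "data.frame")))
      groups <- jsonlite::read_json(pth("string_groups.json"),
                                    simplifyVector = TRUE)
      summary <- list(force_correlation = saved$cor_pooled,
                      marginal_max_abs_dev = cmpx$max_abs_dev,
                      wham_vs_marginal_max_abs_dev = cmpw$max_abs_dev,
                      string_channels = groups$n_channels)
      jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                           digits = NA)
      .log("report", "force r = %.3f; marginal dev = %.3f; wham dev = %.3f; channels = %d",
           summary$force_correlation, summary$marginal_max_abs_dev,
           summary$wham_vs_marginal_max_abs_dev, summary$string_channels)
      invisible(summary)
    },
    .stopf("run_stage: unknown command '%s'", command)
  )
  res
}

#' Command-line entry point
#'
#' Thin wrapper used by the `inst/cli/fesfold` script:
#' `fesfold <command> [--config file.yaml] [--seed N] [--out-dir DIR]
#' [section.key=value ...]`.  Dotted key-value arguments override single
#' configuration entries.
#'
#' @param argv character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
fes_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1L) {
    message("usage: fesfold <command> [--config FILE] [--seed N] [--out-dir DIR] [key=value ...]")
    return(invisible(1L))
  }
  command <- argv[1L]
  argv <- argv[-1L]
  opt <- list(config = NULL, seed = 1L, out_dir = "fesfold_out")
  overrides <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--config") { opt$config <- argv[i + 1L]; i <- i + 2L }
    else if (a == "--seed") { opt$seed <- as.integer(argv[i + 1L]); i <- i + 2L }
    else if (a == "--out-dir") { opt$out_dir <- argv[i + 1L]; i <- i + 2L }
    else if (a == "--threads") { i <- i + 2L }   # accepted; single-threaded
    else if (grepl("^[A-Za-z_.]+=", a)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
      keys <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
      val <- utils::type.convert(kv[2L], as.is = TRUE)
      node <- val
      for (k in rev(keys)) { node <- stats::setNames(list(node), k) }
      overrides <- .merge_config(overrides, node)
      i <- i + 1L
    } else .stopf("fes_cli: unknown argument '%s'", a)
  }
  cfg <- overrides
  if (!is.null(opt$config)) cfg <- .merge_config(yaml::read_yaml(opt$config), cfg)
  run_stage(command, opt$out_dir, cfg, seed = opt$seed)
  invisible(0L)
}
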