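# End-to-end orchestration: configuration, scene/frame simulation, training
# of the comparison solvers, and the desk-scale head-to-head evaluation of
#   one-step GN | PDIPM | RBF-as-inverse-solver | GN + RBF post-processing
# on held-out noisy test scenes with GREIT metrics.

#' Experiment configuration
#'
#' Desk-scale defaults: a single-ring 16-electrode section (circular "tank
#' section" for phantom scenes, thorax contour for lung scenes), coarse
#' inverse mesh of a few hundred elements, n = 200 training scenes, H = 200
#' hidden units, carrier noise spanning 50 dB (near) to 10 dB (far). The
#' full-scale values of the reference experiment (4 x 8-electrode 3D tank,
#' n = 2000, H = 1000) are reachable through these same fields.
#'
#' @param geometry `"tank_section"` (2D disk), `"tank3d"` (4 x 8 cylinder)
#'   or `"thorax"` (Fourier contour)
#' @param n_electrodes electrodes (per ring for `tank3d`)
#' @param n_rings electrode rings (`tank3d` only)
#' @param radius,height tank dimensions, metres
#' @param scene_kind `"phantom"` or `"lung"`
#' @param n_train training scenes; `n_test` held-out test scenes
#' @param hidden RBF hidden units
#' @param snr_max_db,snr_min_db test/training noise profile bounds
#' @param lambda GN hyperparameter (`NULL` = heuristic), `noser_p` exponent
#' @param pdipm include the PDIPM row (slower)
#' @param heights cross-section heights as fractions of model height (3D)
#' @param grid raster resolution G
#' @param seed master seed
#' @return an `eit_experiment_config`
#' @export
experiment_config <- function(geometry = c("tank_section", "tank3d", "thorax"),
                              n_electrodes = 16L, n_rings = 4L,
                              radius = 0.15, height = 0.3,
                              scene_kind = NULL,
                              n_train = 200L, n_test = 20L, hidden = 200L,
                              snr_max_db = 50, snr_min_db = 10,
                              lambda = NULL, noser_p = 0.5,
                              pdipm = TRUE, heights = c(0.25, 0.5, 0.75),
                              grid = 64L, seed = 1L) {
  geometry <- match.arg(geometry)
  scene_kind <- scene_kind %||% if (geometry == "thorax") "lung" else "phantom"
  structure(list(geometry = geometry, n_electrodes = as.integer(n_electrodes),
                 n_rings = as.integer(n_rings), radius = radius, height = height,
                 scene_kind = scene_kind, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), hidden = as.integer(hidden),
                 snr_max_db = snr_max_db, snr_min_db = snr_min_db,
                 lambda = lambda, noser_p = noser_p, pdipm = pdipm,
                 heights = heights, grid = as.integer(grid),
                 seed = as.integer(seed)),
            class = "eit_experiment_config")
}

#' @rdname experiment_config
#' @param path JSON file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname experiment_config
#' @param config an `eit_experiment_config` (for `write_config`)
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(x), names(formals(experiment_config)))
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(experiment_config, x)
}

# Build the forward (fine) and inverse (coarse) models plus protocol for a
# configuration.
experiment_models <- function(config) {
  g <- config$geometry
  if (g == "tank3d") {
    fwd <- build_tank_model(config$radius, config$height, config$n_rings,
                            config$n_electrodes, "fine")
    inv <- build_tank_model(config$radius, config$height, config$n_rings,
                            config$n_electrodes, "coarse")
    protocol <- adjacent_protocol(config$n_rings, config$n_electrodes)
  } else {
    co <- if (g == "thorax") thorax_coefficients() else {
      list(a = c(config$radius, rep(0, 8)), b = rep(0, 8))
    }
    fwd <- build_contour_model(co, config$n_electrodes, "fine")
    inv <- build_contour_model(co, config$n_electrodes, "coarse")
    protocol <- adjacent_protocol(1L, config$n_electrodes)
  }
  list(fwd = fwd, inv = inv, protocol = protocol)
}

nominal_background <- function(config) {
  if (config$scene_kind == "phantom") 1.0 else resistivity_to_conductivity(700)
}

sample_scene <- function(config, model, seed) {
  if (config$scene_kind == "phantom") {
    sample_phantom_scene(model, nominal_background(config), seed = seed)
  } else {
    sample_lung_scene(model, seed = seed)
  }
}

#' Simulate scenes and frames to disk
#'
#' Writes, per scene: the scene (`scene_<i>.json`), the homogeneous and
#' inhomogeneous clean frames and their noise-corrupted counterparts
#' (`frame_<i>_{hom,inh}[_noisy].csv`), plus a `manifest.json` recording
#' every derived seed. Running twice with the same configuration reproduces
#' identical files.
#'
#' @param config an [experiment_config()]
#' @param out_dir output directory
#' @param n number of scenes (defaults to `config$n_test`)
#' @return the manifest, invisibly
#' @export
cmd_simulate <- function(config, out_dir, n = NULL) {
  n <- n %||% config$n_test
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mod <- experiment_models(config)
  cfg <- carrier_config()
  profile <- snr_profile(config$snr_max_db, config$snr_min_db)
  manifest <- list(config = unclass(config), n = n, scenes = list())
  for (i in seq_len(n)) {
    si <- child_seed(child_seed(config$seed, 1000L), i)
    scene <- sample_scene(config, mod$fwd, child_seed(si, 1))
    write_scene(scene, file.path(out_dir, sprintf("scene_%03d.json", i)))
    f_hom <- solve_forward(mod$fwd, rep(scene$background, nrow(mod$fwd$elements)),
                           mod$protocol)$frame
    f_inh <- solve_forward(mod$fwd, paint_scene(mod$fwd, scene), mod$protocol)$frame
    write_frame_csv(f_hom, mod$protocol, file.path(out_dir, sprintf("frame_%03d_hom.csv", i)))
    write_frame_csv(f_inh, mod$protocol, file.path(out_dir, sprintf("frame_%03d_inh.csv", i)))
    s_h <- child_seed(si, 2); s_i <- child_seed(si, 3)
    write_frame_csv(corrupt_frame(f_hom, profile, cfg, mod$protocol, s_h),
                    mod$protocol, file.path(out_dir, sprintf("frame_%03d_hom_noisy.csv", i)))
    write_frame_csv(corrupt_frame(f_inh, profile, cfg, mod$protocol, s_i),
                    mod$protocol, file.path(out_dir, sprintf("frame_%03d_inh_noisy.csv", i)))
    manifest$scenes[[i]] <- list(index = i, seed = si, seed_scene = child_seed(si, 1),
                                 seed_noise_hom = s_h, seed_noise_inh = s_i)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Run the solver comparison on held-out noisy scenes
#'
#' The full head-to-head: train the RBF networks on clean simulated data
#' (and, optionally, on noise-corrupted data), then reconstruct `n_test`
#' held-out scenes whose frames carry carrier noise, and score every method
#' with the GREIT figures of merit against the painted truth. Rows mirror
#' the reference comparison: one-step GN, PDIPM, the network as a direct
#' inverse solver, and the network as GN post-processor, the latter two
#' each with noise-free and noisy training.
#'
#' @param config an [experiment_config()]
#' @param train_noisy also train and evaluate the noisy-training variants
#' @param noise_test apply carrier noise to test frames (default TRUE)
#' @param progress print per-stage timing
#' @return an `eit_comparison`: `table` (one row per method: mean PE per
#'   target, mean |dRES|, mean SD over scenes), `per_scene` details, the
#'   trained networks and the models used
#' @export
run_comparison <- function(config = experiment_config(), train_noisy = TRUE,
                           noise_test = TRUE, progress = interactive()) {
  say <- function(...) if (progress) message(sprintf(...))
  mod <- experiment_models(config)
  protocol <- mod$protocol
  cfg <- carrier_config()
  profile <- snr_profile(config$snr_max_db, config$snr_min_db)
  bg <- nominal_background(config)
  J <- jacobian(mod$inv, rep(bg, nrow(mod$inv$elements)), protocol)
  lambda <- config$lambda %||% choose_lambda(J, config$noser_p)
  M <- build_gn_matrix(J, lambda, config$noser_p)

  say("training sets (n = %d) ...", config$n_train)
  mk_ts <- function(mode, noise, stream) {
    build_training_set(config$n_train, mod$fwd, mod$inv, protocol,
                       mode = mode, scene_kind = config$scene_kind,
                       noise = noise, gn = M,
                       contour_perturbation = if (config$geometry == "thorax") 0.10 else 0,
                       nominal_background = bg,
                       seed = child_seed(config$seed, stream))
  }
  noise_spec <- list(profile = profile, cfg = cfg,
                     nongaussian = config$scene_kind == "lung")
  nets <- list()
  ts_inv <- mk_ts("inverse_solver", NULL, 1L)
  ts_post <- mk_ts("post_processor", NULL, 2L)
  say("training networks (H = %d) ...", config$hidden)
  nets$ann_clean <- train_rbf(ts_inv$inputs, ts_inv$targets, config$hidden,
                              seed = child_seed(config$seed, 11L))
  nets$post_clean <- train_rbf(ts_post$inputs, ts_post$targets, config$hidden,
                               seed = child_seed(config$seed, 12L))
  if (train_noisy) {
    ts_inv_n <- mk_ts("inverse_solver", noise_spec, 3L)
    ts_post_n <- mk_ts("post_processor", noise_spec, 4L)
    nets$ann_noisy <- train_rbf(ts_inv_n$inputs, ts_inv_n$targets, config$hidden,
                                seed = child_seed(config$seed, 13L))
    nets$post_noisy <- train_rbf(ts_post_n$inputs, ts_post_n$targets, config$hidden,
                                 seed = child_seed(config$seed, 14L))
  }

  say("evaluating %d test scenes ...", config$n_test)
  heights <- if (mod$inv$dim == 3L) config$heights * config$height else 0
  methods <- c("gn", if (config$pdipm) "pdipm",
               "ann_clean", "post_clean",
               if (train_noisy) c("ann_noisy", "post_noisy"))
  per_scene <- list()
  for (i in seq_len(config$n_test)) {
    si <- child_seed(child_seed(config$seed, 2000L), i)
    scene <- sample_scene(config, mod$fwd, child_seed(si, 1))
    f_hom <- solve_forward(mod$fwd, rep(scene$background, nrow(mod$fwd$elements)),
                           protocol)$frame
    f_inh <- solve_forward(mod$fwd, paint_scene(mod$fwd, scene), protocol)$frame
    if (noise_test) {
      corrupt <- if (config$scene_kind == "lung") corrupt_frame_nongaussian else corrupt_frame
      f_hom <- corrupt(f_hom, profile, cfg, protocol, seed = child_seed(si, 2))
      f_inh <- corrupt(f_inh, profile, cfg, protocol, seed = child_seed(si, 3))
    }
    dv <- difference_frame(f_inh, f_hom)
    truth_node <- element_to_node(scene_on_model(mod$inv, scene), mod$inv)
    recs <- list()
    gn_img <- reconstruct_gn(M, dv, mod$inv)
    recs$gn <- element_to_node(gn_img, mod$inv)
    if (config$pdipm) {
      # weight commensurate with the L1 data term: lambda^2 / typical |dv|
      pd_cfg <- pdipm_config(lambda = lambda^2 / max(median(abs(dv$values)), 1e-300),
                             max_iterations = 50L, convergence_tol = 1e-5)
      recs$pdipm <- element_to_node(
        suppressWarnings(reconstruct_pdipm(J, dv, pd_cfg, prior = list(p = config$noser_p),
                                           model = mod$inv)),
        mod$inv)
    }
    gn_node <- element_to_node(gn_img, mod$inv)$values
    recs$ann_clean <- eit_image(rbf_apply(nets$ann_clean, dv$values),
                                basis = "node", model = mod$inv, kind = "difference")
    recs$post_clean <- eit_image(rbf_apply(nets$post_clean, gn_node),
                                 basis = "node", model = mod$inv, kind = "difference")
    if (train_noisy) {
      recs$ann_noisy <- eit_image(rbf_apply(nets$ann_noisy, dv$values),
                                  basis = "node", model = mod$inv, kind = "difference")
      recs$post_noisy <- eit_image(rbf_apply(nets$post_noisy, gn_node),
                                   basis = "node", model = mod$inv, kind = "difference")
    }
    for (h in heights) {
      truth_r <- rasterize(truth_node, mod$inv, height = h, G = config$grid)
      if (isTRUE(attr(quarter_amplitude_set(truth_r), "flagged"))) next  # target invisible here
      for (meth in methods) {
        mt <- compute_metrics(rasterize(recs[[meth]], mod$inv, height = h,
                                        G = config$grid), truth_r)
        per_scene[[length(per_scene) + 1L]] <- data.frame(
          scene = i, height = h, method = meth,
          target = mt$per_target$target, pe = mt$per_target$pe,
          dres = mt$dres, sd = mt$sd)
      }
    }
  }
  per_scene <- do.call(rbind, per_scene)
  tab <- aggregate_comparison(per_scene, methods)
  structure(list(table = tab, per_scene = per_scene, nets = nets,
                 models = mod, gn_matrix = M, config = config),
            class = "eit_comparison")
}

aggregate_comparison <- function(per_scene, methods) {
  do.call(rbind, lapply(methods, function(m) {
    d <- per_scene[per_scene$method == m, ]
    first <- d[!duplicated(paste(d$scene, d$height)), ]  # dres/sd once per raster
    data.frame(method = m,
               pe_1 = mean(d$pe[d$target == 1], na.rm = TRUE),
               pe_2 = if (any(d$target == 2)) mean(d$pe[d$target == 2], na.rm = TRUE) else NA_real_,
               dres = mean(first$dres, na.rm = TRUE),
               sd = mean(first$sd, na.rm = TRUE),
               missing_targets = sum(is.na(d$pe)))
  }))
}

#' @export
print.eit_comparison <- function(x, ...) {
  cat(sprintf("EIT solver comparison (%s, %s scenes, n_train = %d, H = %d):\n",
              x$config$geometry, x$config$scene_kind, x$config$n_train,
              x$config$hidden))
  tab <- x$table
  tab[, 2:5] <- round(tab[, 2:5], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

method_label <- function(m) {
  c(gn = "One-step GN", pdipm = "PDIPM",
    ann_clean = "ANN (training: no noise)",
    post_clean = "One-step GN + ANN (training: no noise)",
    ann_noisy = "ANN (training: noise)",
    post_noisy = "One-step GN + ANN (training: noise)")[[m]]
}

#' Compare solvers and write outputs to disk
#'
#' Runs [run_comparison()] and writes `comparison.csv` (the aggregate
#' table), `per_scene.csv`, and per-method rasters of the first test scene
#' as CSV grids.
#'
#' @param config an [experiment_config()]
#' @param out_dir output directory
#' @param ... passed to [run_comparison()]
#' @return the `eit_comparison`, invisibly
#' @export
cmd_compare <- function(config, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_comparison(config, ...)
  tab <- res$table
  tab$method <- vapply(tab$method, method_label, character(1))
  write.csv(tab, file.path(out_dir, "comparison.csv"), row.names = FALSE)
  write.csv(res$per_scene, file.path(out_dir, "per_scene.csv"), row.names = FALSE)
  invisible(res)
}
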