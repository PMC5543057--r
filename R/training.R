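# Simulated training scenes and network training sets.
#
# Two stated worlds:
#  * phantom: a saline tank containing 1-2 cylindrical insulators of random
#    size and conductivity below the background; the background itself
#    varies log-uniformly (x/÷ 2 around nominal) across samples.
#  * lungs: a thorax-like section containing two elliptical-cylinder lungs
#    whose resistivity is drawn from 700-2500 ohm.m over a 700 ohm.m
#    background (values at 100 kHz over the breathing cycle); the contour is
#    re-perturbed (up to 10% per Fourier coefficient) for every sample so
#    the forward model never matches the inverse model.
#
# Forward data are always generated on a different (finer) mesh than the
# inverse solve to avoid the inverse crime.

#' Sample a random phantom scene (tank with insulating cylinders)
#'
#' @param model the (tank) model the scene must fit in
#' @param nominal_background nominal background conductivity, S/m
#' @param n_targets number of insulators; `NULL` draws 1 or 2 at random
#' @param seed integer seed
#' @return a [scene_spec()]
#' @export
sample_phantom_scene <- function(model, nominal_background = 1.0,
                                 n_targets = NULL, seed = NULL) {
  g <- model$geometry
  radius <- if (g$type == "cylinder") g$radius else {
    min(fourier_radius(g$coefficients, 2 * pi * (0:255) / 256))  # inscribed
  }
  height <- if (g$type == "cylinder") g$height else 0
  with_seed(seed, {
    bg <- nominal_background * 2^runif(1, -1, 1)     # log-uniform x/÷2
    k <- n_targets %||% sample(1:2, 1)
    zr <- if (height > 0) c(0, height) else c(-1, 1)
    targets <- list()
    for (i in seq_len(k)) {
      r <- runif(1, 0.1, 0.25) * radius
      repeat {
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, radius - r - 1e-9)
        ctr <- c(rad * cos(ang), rad * sin(ang), 0)
        ok <- TRUE
        if (i == 2L) {  # keep two insulators disjoint
          prev <- targets[[1]]
          d <- sqrt(sum((ctr[1:2] - prev$center[1:2])^2))
          ok <- d > r + prev$semi_axes[1] + 0.02 * radius
        }
        if (ok) break
      }
      targets[[i]] <- list(shape = "circular-cylinder", center = ctr, semi_axes = r,
                           height_range = zr, conductivity = bg * runif(1, 0.02, 0.5))
    }
    scene_spec(bg, targets)
  })
}

#' Sample a random lung scene (two elliptical cylinders in a thorax section)
#'
#' @param model the (contour) model the scene must fit in
#' @param resistivity_range lung resistivity bounds, ohm.m (default 700-2500)
#' @param background_resistivity background, ohm.m (default 700)
#' @param seed integer seed
#' @return a [scene_spec()]
#' @export
sample_lung_scene <- function(model, resistivity_range = c(700, 2500),
                              background_resistivity = 700, seed = NULL) {
  g <- model$geometry
  with_seed(seed, {
    bg <- resistivity_to_conductivity(background_resistivity)
    base_r <- if (g$type == "contour") g$coefficients$a[1] else g$radius
    targets <- lapply(c(-1, 1), function(side) {
      ax <- base_r * c(runif(1, 0.28, 0.40), runif(1, 0.42, 0.58))
      ctr <- c(side * base_r * runif(1, 0.40, 0.50),
               base_r * runif(1, -0.06, 0.06), 0)
      rho <- runif(1, resistivity_range[1], resistivity_range[2])
      list(shape = "elliptical-cylinder", center = ctr, semi_axes = ax,
           height_range = NULL, conductivity = resistivity_to_conductivity(rho))
    })
    scene_spec(bg, targets)
  })
}

#' Build a network training set by simulation
#'
#' For each sample: draw a scene, solve the forward problem on the fine
#' model for the homogeneous and inhomogeneous states, optionally corrupt
#' both frames with carrier noise, form the difference frame, and derive the
#' network input — the difference frame itself (`mode = "inverse_solver"`)
#' or the node-basis one-step GN reconstruction on the inverse model
#' (`mode = "post_processor"`). The target is always the true conductivity
#' change painted onto the inverse model's nodes. Forward and inverse models
#' must differ (inverse-crime avoidance); in lung mode the forward contour
#' is additionally re-perturbed per sample.
#'
#' @param n number of samples
#' @param fwd_model fine forward `eit_fem` (ignored per-sample in lung mode
#'   when `contour_perturbation > 0`, where a perturbed fine model is built)
#' @param inv_model coarse inverse `eit_fem`
#' @param protocol shared `eit_protocol`
#' @param mode `"inverse_solver"` or `"post_processor"`
#' @param scene_kind `"phantom"` or `"lung"`
#' @param noise `NULL` for clean data, or a list with `profile`
#'   ([snr_profile()]), `cfg` ([carrier_config()]), and optionally
#'   `nongaussian = TRUE`
#' @param gn an `eit_recon_matrix` for post-processor mode; built
#'   automatically (nominal background, [choose_lambda()]) when `NULL`
#' @param contour_perturbation per-sample Fourier perturbation bound for
#'   lung mode (default 0.10; 0 disables)
#' @param nominal_background phantom nominal background, S/m
#' @param seed master seed; per-sample seeds derive from it
#' @return an `eit_training_set`: `inputs` (n x D), `targets` (n x nodes of
#'   inv_model), `mode`, `gn` (the reconstruction matrix used, if any) and
#'   per-sample `provenance`
#' @export
build_training_set <- function(n, fwd_model, inv_model, protocol,
                               mode = c("inverse_solver", "post_processor"),
                               scene_kind = c("phantom", "lung"),
                               noise = NULL, gn = NULL,
                               contour_perturbation = 0.10,
                               nominal_background = 1.0, seed = 1L) {
  mode <- match.arg(mode)
  scene_kind <- match.arg(scene_kind)
  stopifnot(n >= 1)
  if (identical(fwd_model$name, inv_model$name) &&
      nrow(fwd_model$elements) == nrow(inv_model$elements)) {
    stop("forward and inverse models must differ (inverse crime)")
  }
  bg_nominal <- if (scene_kind == "phantom") nominal_background else
    resistivity_to_conductivity(700)
  if (mode == "post_processor" && is.null(gn)) {
    J <- jacobian(inv_model, rep(bg_nominal, nrow(inv_model$elements)), protocol)
    gn <- build_gn_matrix(J, choose_lambda(J))
  }
  n_nodes <- nrow(inv_model$nodes)
  D <- if (mode == "inverse_solver") protocol$frame_length else n_nodes
  inputs <- matrix(NA_real_, n, D)
  targets <- matrix(NA_real_, n, n_nodes)
  provenance <- vector("list", n)
  for (i in seq_len(n)) {
    si <- child_seed(seed, i)
    res <- tryCatch(
      simulate_sample(i, si, fwd_model, inv_model, protocol, mode, scene_kind,
                      noise, gn, contour_perturbation, nominal_background),
      error = function(e) stop(sprintf("sample %d (seed %d) failed: %s",
                                       i, si, conditionMessage(e)))
    )
    inputs[i, ] <- res$input
    targets[i, ] <- res$target
    provenance[[i]] <- res$provenance
  }
  if (any(!is.finite(inputs)) || any(!is.finite(targets))) {
    stop("non-finite entries in training set")
  }
  structure(list(inputs = inputs, targets = targets, mode = mode,
                 scene_kind = scene_kind, gn = gn,
                 inv_model_id = inv_model$name, protocol_id = protocol$id,
                 provenance = provenance, seed = seed),
            class = "eit_training_set")
}

simulate_sample <- function(i, si, fwd_model, inv_model, protocol, mode,
                            scene_kind, noise, gn, contour_perturbation,
                            nominal_background) {
  fm <- fwd_model
  pert <- NULL
  if (scene_kind == "lung" && contour_perturbation > 0 &&
      !is.null(fwd_model$geometry) && fwd_model$geometry$type == "contour") {
    pert <- perturb_contour(fwd_model$geometry$coefficients,
                            contour_perturbation, seed = child_seed(si, 1))
    fm <- build_contour_model(pert, length(fwd_model$electrodes), "fine")
  }
  scene <- if (scene_kind == "phantom") {
    sample_phantom_scene(fm, nominal_background, seed = child_seed(si, 2))
  } else {
    sample_lung_scene(fm, seed = child_seed(si, 2))
  }
  sig_in <- paint_scene(fm, scene)
  sig_hom <- rep(scene$background, nrow(fm$elements))
  f_in <- solve_forward(fm, sig_in, protocol)$frame
  f_hom <- solve_forward(fm, sig_hom, protocol)$frame
  if (!is.null(noise)) {
    corrupt <- if (isTRUE(noise$nongaussian)) corrupt_frame_nongaussian else corrupt_frame
    f_in <- corrupt(f_in, noise$profile, noise$cfg, protocol, seed = child_seed(si, 3))
    f_hom <- corrupt(f_hom, noise$profile, noise$cfg, protocol, seed = child_seed(si, 4))
  }
  dv <- difference_frame(f_in, f_hom)
  input <- if (mode == "inverse_solver") dv$values else {
    rec <- reconstruct_gn(gn, dv, model = inv_model)
    element_to_node(rec, inv_model)$values
  }
  truth_el <- scene_on_model(inv_model, scene)
  target <- element_to_node(truth_el, inv_model)$values
  list(input = input, target = target,
       provenance = list(sample = i, seed = si, scene = scene,
                         contour = pert, noisy = !is.null(noise)))
}

# True conductivity-change image of a scene on (possibly) another model:
# painted difference sigma - background, element basis.
scene_on_model <- function(model, scene) {
  img <- paint_scene(model, scene)
  eit_image(img$values - scene$background, basis = "element", model = model,
            kind = "difference")
}

#' @export
print.eit_training_set <- function(x, ...) {
  cat(sprintf("EIT training set: %d samples, mode %s (%s scenes), input dim %d, target dim %d\n",
              nrow(x$inputs), x$mode, x$scene_kind, ncol(x$inputs), ncol(x$targets)))
  invisible(x)
}
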