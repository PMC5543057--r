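# Radial basis function network, in the two roles the reconstruction
# comparison needs: a direct inverse solver (difference frame -> nodal
# conductivity change) and a post-processor of the linear reconstruction
# (GN nodal image -> nodal conductivity change). Single Gaussian hidden
# layer, linear output layer fitted by ridge least squares.

#' Train an RBF network
#'
#' Hidden units are Gaussian kernels \eqn{\phi_k(x) = \exp(-\|x - c_k\|^2 /
#' (2 w_k^2))}; the output layer is linear and fitted by ridge-regularised
#' least squares on standardised inputs and outputs. Centers are chosen from
#' the training inputs by greedy maximum-residual selection (the classic
#' constructive scheme, grown up to `hidden` units with the prefix of best
#' validation MSE retained) or by k-means; all units share a constant width,
#' `spread` times the median pairwise distance of the training inputs. An
#' optional particle swarm step refines centers and widths against
#' validation MSE, after which the output layer is refitted. A deterministic
#' 90/10 train/validation split is drawn from `seed`; with fewer than 10
#' samples no split is made and the net interpolates its inputs.
#'
#' @param inputs n x D matrix of training inputs
#' @param targets n x Nout matrix of training targets
#' @param hidden number of hidden units H (default 1000 at full scale;
#'   desk-scale experiments use 200)
#' @param spread width multiplier on the median nearest-center distance
#' @param ridge ridge penalty on the output weights (default 1e-8)
#' @param centers `"greedy"` or `"kmeans"`
#' @param pso optional [pso_config()] for center/width refinement
#' @param seed integer seed controlling the split, k-means and PSO
#' @return an `eit_rbf` with fields `centers`, `widths`, `W` (output
#'   weights), `bias`, input/output scalers and the validation MSE
#' @export
train_rbf <- function(inputs, targets, hidden = 1000L, spread = 1.0,
                      ridge = 1e-8, centers = c("greedy", "kmeans"),
                      pso = NULL, seed = 1L) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  stopifnot(nrow(inputs) == nrow(targets), spread > 0, ridge >= 0)
  centers <- match.arg(centers)
  n <- nrow(inputs)
  hidden <- min(as.integer(hidden), n)
  in_sd <- apply(inputs, 2, sd)
  if (all(in_sd == 0)) stop("degenerate training inputs: zero variance everywhere")
  scaler_in <- list(center = colMeans(inputs), scale = ifelse(in_sd > 0, in_sd, 1))
  scaler_out <- list(center = colMeans(targets), scale = 1)
  X <- scale(inputs, scaler_in$center, scaler_in$scale)
  Y <- sweep(targets, 2, scaler_out$center)

  with_seed(seed, {
    val <- if (n >= 10) sort(sample(n, max(1, round(0.1 * n)))) else integer(0)
    trn <- setdiff(seq_len(n), val)
    Xt <- X[trn, , drop = FALSE]; Yt <- Y[trn, , drop = FALSE]
    if (centers == "greedy" && length(val)) {
      # constructive selection: add the max-residual input as the next
      # center and stop where validation MSE is best (H is only a cap)
      sel <- greedy_centers(Xt, Yt, min(hidden, length(trn)), spread, ridge,
                            X[val, , drop = FALSE], Y[val, , drop = FALSE])
      C <- sel$C
    } else if (centers == "kmeans" && hidden < length(trn)) {
      km <- stats::kmeans(Xt, centers = hidden, iter.max = 50, nstart = 1)
      C <- km$centers
    } else {
      C <- Xt[seq_len(min(hidden, length(trn))), , drop = FALSE]
      if (hidden >= length(trn)) C <- Xt   # every training input is a center
    }
    w <- rbf_widths(C, spread, ref = Xt)
    fit <- fit_output_layer(Xt, Yt, C, w, ridge)
    net <- structure(list(centers = C, widths = w, W = fit$W, bias = fit$bias,
                          input_dim = ncol(X), hidden = nrow(C),
                          scaler_in = scaler_in, scaler_out = scaler_out,
                          spread = spread, ridge = ridge,
                          validation_mse = NA_real_), class = "eit_rbf")
    if (length(val)) {
      net$validation_mse <- rbf_mse(net, X[val, , drop = FALSE], Y[val, , drop = FALSE])
    }
    if (!is.null(pso)) {
      net <- pso_refine(net, X, Y, trn, val, pso)
    }
    net
  })
}

# Greedy max-residual center selection (newrb-style): repeatedly add the
# training input whose target residual under the current net is largest,
# and keep the prefix with the best validation MSE.
greedy_centers <- function(X, Y, hidden, spread, ridge, Xv, Yv) {
  n <- nrow(X)
  resid2 <- rowSums(Y^2)
  chosen <- integer(0)
  best_h <- 1L; best_mse <- Inf
  val_mse <- rep(NA_real_, min(hidden, n))
  w_all <- rbf_widths(X, spread)
  for (h in seq_len(min(hidden, n))) {
    cand <- setdiff(seq_len(n), chosen)
    chosen <- c(chosen, cand[which.max(resid2[cand])])
    C <- X[chosen, , drop = FALSE]
    w <- rep(w_all[1], h)
    fit <- fit_output_layer(X, Y, C, w, ridge)
    Phi <- rbf_design(X, C, w)
    pred <- sweep(Phi %*% t(fit$W), 2, fit$bias, "+")
    resid2 <- rowSums((Y - pred)^2)
    Phv <- rbf_design(Xv, C, w)
    mse <- mean((sweep(Phv %*% t(fit$W), 2, fit$bias, "+") - Yv)^2)
    val_mse[h] <- mse
    if (mse < best_mse) { best_mse <- mse; best_h <- h }
  }
  list(C = X[chosen[seq_len(best_h)], , drop = FALSE], val_mse = val_mse)
}

# Constant width for all hidden units: `spread` times the median pairwise
# distance of the reference points (the training inputs), mirroring the
# constant-spread convention of constructive RBF toolboxes -- widths do not
# shrink as centers are added, which keeps the greedy growth stable.
rbf_widths <- function(C, spread, ref = NULL) {
  H <- nrow(C)
  P <- ref %||% C
  if (nrow(P) == 1L) return(rep(spread, H))
  if (nrow(P) > 400L) P <- P[seq(1L, nrow(P), length.out = 400L), , drop = FALSE]
  d <- stats::dist(P)
  w <- spread * max(median(d), 1e-8)
  rep(w, H)
}

rbf_design <- function(X, C, widths) {
  # ||x - c||^2 via the expansion, vectorised over all pairs
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  D2 <- outer(xx, cc, "+") - 2 * X %*% t(C)
  D2[D2 < 0] <- 0
  exp(-sweep(D2, 2, 2 * widths^2, "/"))
}

fit_output_layer <- function(X, Y, C, widths, ridge) {
  Phi <- rbf_design(X, C, widths)
  H <- ncol(Phi)
  A <- crossprod(Phi) + diag(ridge, H)
  # centred fit: bias absorbs the mean response
  phibar <- colMeans(Phi)
  ybar <- colMeans(Y)
  Phic <- sweep(Phi, 2, phibar)
  Yc <- sweep(Y, 2, ybar)
  Ac <- crossprod(Phic) + diag(max(ridge, 1e-12), H)
  Wt <- tryCatch(solve(Ac, crossprod(Phic, Yc)),
                 error = function(e) MASS_ginv(Ac) %*% crossprod(Phic, Yc))
  W <- t(Wt)                                     # Nout x H
  bias <- ybar - as.numeric(W %*% phibar)
  list(W = W, bias = bias)
}

# Minimal pseudo-inverse fallback (avoids a MASS dependency).
MASS_ginv <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

rbf_mse <- function(net, X, Yc) {
  Phi <- rbf_design(X, net$centers, net$widths)
  pred <- sweep(Phi %*% t(net$W), 2, net$bias, "+")
  mean((pred - Yc)^2)
}

#' Apply an RBF network
#'
#' Evaluates \eqn{y = W\phi(x) + b}, applying the stored input scaler and
#' inverting the output scaler. Input may be a single vector or a matrix of
#' row vectors.
#'
#' @param net an `eit_rbf`
#' @param x input vector of length `input_dim`, or n x input_dim matrix
#' @return numeric vector (or matrix) of outputs in original target units
#' @export
rbf_apply <- function(net, x) {
  X <- if (is.matrix(x)) x else matrix(x, 1)
  if (ncol(X) != net$input_dim) {
    stop(sprintf("input dimension %d does not match network input_dim %d",
                 ncol(X), net$input_dim))
  }
  Xs <- scale(X, net$scaler_in$center, net$scaler_in$scale)
  Phi <- rbf_design(Xs, net$centers, net$widths)
  out <- sweep(Phi %*% t(net$W), 2, net$bias + net$scaler_out$center, "+")
  if (is.matrix(x)) out else as.numeric(out)
}

#' @export
predict.eit_rbf <- function(object, newdata, ...) rbf_apply(object, newdata)

#' @export
print.eit_rbf <- function(x, ...) {
  cat(sprintf("RBF network: %d -> %d (Gaussian) -> %d, spread %g, ridge %g\n",
              x$input_dim, x$hidden, nrow(x$W), x$spread, x$ridge))
  if (!is.na(x$validation_mse)) cat(sprintf("  validation MSE %.4g\n", x$validation_mse))
  invisible(x)
}

#' Particle swarm configuration for RBF refinement
#'
#' @param n_particles swarm size (default 30)
#' @param n_iterations iterations (default 50)
#' @param inertia velocity inertia (default 0.7)
#' @param cognitive,social acceleration coefficients (default 1.5 each)
#' @return a `pso_config`
#' @export
pso_config <- function(n_particles = 30L, n_iterations = 50L, inertia = 0.7,
                       cognitive = 1.5, social = 1.5) {
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 inertia = inertia, cognitive = cognitive, social = social),
            class = "pso_config")
}

# PSO over a global log-width multiplier and a center jitter scale: a low-
# dimensional refinement that keeps the search well-posed at desk scale.
# The output layer is refitted for every candidate; fitness is validation
# MSE (training MSE when the validation split is empty).
pso_refine <- function(net, X, Y, trn, val, cfg) {
  eval_candidate <- function(theta) {
    wmul <- exp(theta[1]); smul <- theta[2]
    C <- net$centers * (1 + smul)
    w <- net$widths * wmul
    fit <- fit_output_layer(X[trn, , drop = FALSE], Y[trn, , drop = FALSE], C, w, net$ridge)
    cand <- net; cand$centers <- C; cand$widths <- w; cand$W <- fit$W; cand$bias <- fit$bias
    idx <- if (length(val)) val else trn
    rbf_mse(cand, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
  }
  d <- 2L
  pos <- matrix(runif(cfg$n_particles * d, -0.3, 0.3), cfg$n_particles, d)
  vel <- matrix(0, cfg$n_particles, d)
  pbest <- pos; pbest_f <- apply(pos, 1, eval_candidate)
  g <- which.min(pbest_f)
  gbest <- pbest[g, ]; gbest_f <- pbest_f[g]
  for (it in seq_len(cfg$n_iterations)) {
    r1 <- matrix(runif(cfg$n_particles * d), cfg$n_particles, d)
    r2 <- matrix(runif(cfg$n_particles * d), cfg$n_particles, d)
    vel <- cfg$inertia * vel +
      cfg$cognitive * r1 * (pbest - pos) +
      cfg$social * r2 * sweep(pos, 2, gbest, function(p, g) g - p)
    pos <- pos + vel
    f <- apply(pos, 1, eval_candidate)
    upd <- f < pbest_f
    pbest[upd, ] <- pos[upd, ]; pbest_f[upd] <- f[upd]
    if (min(pbest_f) < gbest_f) {
      g <- which.min(pbest_f); gbest <- pbest[g, ]; gbest_f <- pbest_f[g]
    }
  }
  wmul <- exp(gbest[1]); smul <- gbest[2]
  net$centers <- net$centers * (1 + smul)
  net$widths <- net$widths * wmul
  fit <- fit_output_layer(X[trn, , drop = FALSE], Y[trn, , drop = FALSE],
                          net$centers, net$widths, net$ridge)
  net$W <- fit$W; net$bias <- fit$bias
  net$validation_mse <- gbest_f
  net
}
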