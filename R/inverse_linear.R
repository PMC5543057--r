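# One-step Gauss-Newton difference reconstruction with the NOSER prior, and
# element-to-node interpolation (the canonical input of the post-processing
# network, whose layers are sized by node count).

#' Build the one-step Gauss-Newton reconstruction matrix
#'
#' Forms \eqn{M = (J^T J + \lambda^2 R)^{-1} J^T} with the NOSER prior
#' \eqn{R = diag(J^T J)^p}. Applying M to a difference frame is the entire
#' reconstruction — a single precomputable matrix-vector product, which is
#' what makes the linear solver viable for real-time imaging.
#'
#' @param J an `eit_jacobian` (or plain matrix)
#' @param lambda regularisation hyperparameter (> 0)
#' @param p NOSER exponent (default 0.5; `p = 0` gives identity-prior
#'   Tikhonov/ridge)
#' @return an `eit_recon_matrix`
#' @export
build_gn_matrix <- function(J, lambda, p = 0.5) {
  stopifnot(lambda > 0)
  Jm <- if (inherits(J, "eit_jacobian")) J$matrix else as.matrix(J)
  JtJ <- crossprod(Jm)
  d <- diag(JtJ)
  if (any(d < 0)) d[d < 0] <- 0
  R <- d^p
  if (p != 0 && any(R == 0)) {
    # elements with zero sensitivity get the smallest positive prior weight
    R[R == 0] <- min(R[R > 0])
  }
  A <- JtJ + diag(lambda^2 * R, nrow(JtJ))
  M <- tryCatch(solve(A, t(Jm)),
                error = function(e) stop("singular regularised normal matrix (lambda too small?): ",
                                         conditionMessage(e)))
  structure(list(matrix = M, lambda = lambda, p = p,
                 model_id = if (inherits(J, "eit_jacobian")) J$model_id else NULL,
                 protocol_id = if (inherits(J, "eit_jacobian")) J$protocol_id else NULL),
            class = "eit_recon_matrix")
}

#' @export
print.eit_recon_matrix <- function(x, ...) {
  cat(sprintf("One-step GN reconstruction matrix: %d elements x %d measurements (lambda = %g, p = %g)\n",
              nrow(x$matrix), ncol(x$matrix), x$lambda, x$p))
  invisible(x)
}

#' One-step Gauss-Newton reconstruction
#'
#' @param M an `eit_recon_matrix` from [build_gn_matrix()]
#' @param dv a difference `eit_frame`
#' @param model optional `eit_fem` for length validation and model id
#' @return an element-basis difference `eit_image`
#' @export
reconstruct_gn <- function(M, dv, model = NULL) {
  if (inherits(dv, "eit_frame")) {
    if (dv$kind != "difference") stop("reconstruct_gn expects a difference frame")
    v <- dv$values
  } else v <- as.numeric(dv)
  if (length(v) != ncol(M$matrix)) stop("frame length does not match reconstruction matrix")
  eit_image(as.numeric(M$matrix %*% v), basis = "element", model = model,
            kind = "difference")
}

#' Choose the GN hyperparameter by noise-figure calibration
#'
#' Selects lambda so that the reconstruction's noise figure — the ratio of
#' the input signal-to-noise ratio to the output signal-to-noise ratio for
#' a small central test target under unit white measurement noise —
#' reaches `nf_target` (default 0.5, the customary calibration for
#' difference imaging). Solved by bisection on log(lambda); the noise
#' figure is monotone in lambda because heavier regularisation suppresses
#' amplified noise faster than signal.
#'
#' @param J an `eit_jacobian` or matrix
#' @param p NOSER exponent
#' @param nf_target target noise figure (default 0.5)
#' @param signal optional measurement-space test signal; defaults to the
#'   column-sum response of the most sensitive decile of elements
#' @return a positive lambda
#' @export
choose_lambda <- function(J, p = 0.5, nf_target = 0.5, signal = NULL) {
  Jm <- if (inherits(J, "eit_jacobian")) J$matrix else as.matrix(J)
  d <- colSums(Jm^2)
  # test target: the most sensitive elements (interior, near the electrode
  # plane), unit conductivity change
  sel <- d >= quantile(d, 0.9)
  v_t <- if (is.null(signal)) as.numeric(Jm %*% as.numeric(sel)) else as.numeric(signal)
  snr_in <- mean(abs(v_t))                      # unit-variance noise reference
  JtJ <- crossprod(Jm)
  R <- d^p
  if (p != 0 && any(R == 0)) R[R == 0] <- min(R[R > 0])
  nf <- function(loglam) {
    lam <- exp(loglam)
    M <- solve(JtJ + diag(lam^2 * R, ncol(Jm)), t(Jm))
    x_t <- M %*% v_t
    noise_out <- sqrt(mean(rowSums(M^2)))       # per-element output noise sd
    snr_out <- mean(abs(x_t)) / noise_out
    snr_in / snr_out
  }
  ref <- 0.5 * log(mean(d)^(1 - p))             # centre the bracket on scale
  lo <- ref - 14; hi <- ref + 8
  f_lo <- nf(lo); f_hi <- nf(hi)
  if ((f_lo - nf_target) * (f_hi - nf_target) > 0) {
    return(exp(ref - 3))                        # bracket failed: fallback scale
  }
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if ((nf(mid) - nf_target) * (f_lo - nf_target) <= 0) hi <- mid else {
      lo <- mid; f_lo <- nf(lo)
    }
  }
  exp((lo + hi) / 2)
}

#' Interpolate an element image onto the nodes
#'
#' Node value = volume-weighted average of the values of the elements
#' adjacent to that node. Constant images are preserved exactly (the weights
#' form a partition of unity at every node).
#'
#' @param img element-basis `eit_image`
#' @param model the `eit_fem` the image lives on
#' @return node-basis `eit_image` of the same kind
#' @export
element_to_node <- function(img, model) {
  v <- if (inherits(img, "eit_image")) {
    stopifnot(img$basis == "element")
    img$values
  } else as.numeric(img)
  if (length(v) != nrow(model$elements)) stop("image length does not match element count")
  el <- model$elements
  k <- ncol(el)
  num <- numeric(nrow(model$nodes))
  den <- numeric(nrow(model$nodes))
  w <- model$volumes
  for (a in seq_len(k)) {
    idx <- el[, a]
    num <- num + unname(tapply_add(idx, w * v, nrow(model$nodes)))
    den <- den + unname(tapply_add(idx, w, nrow(model$nodes)))
  }
  out <- ifelse(den > 0, num / den, 0)
  eit_image(out, basis = "node", model = model,
            kind = if (inherits(img, "eit_image")) img$kind else "difference")
}

tapply_add <- function(idx, vals, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Sample a node image at element centroids
#'
#' Inverse companion of [element_to_node()]: element value = mean of its
#' node values (the linear interpolant at the centroid).
#'
#' @param img node-basis `eit_image`
#' @param model the `eit_fem`
#' @return element-basis `eit_image`
#' @export
node_to_element <- function(img, model) {
  v <- if (inherits(img, "eit_image")) {
    stopifnot(img$basis == "node")
    img$values
  } else as.numeric(img)
  el <- model$elements
  out <- rowMeans(matrix(v[el], nrow(el), ncol(el)))
  eit_image(out, basis = "element", model = model,
            kind = if (inherits(img, "eit_image")) img$kind else "difference")
}
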