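# Primal-dual interior point reconstruction with an L1 data-fidelity norm
# and an L2 (NOSER-weighted) regularisation term:
#
#   min_x  ||Jx - dv||_1 + lambda * x' R x
#
# following the Borsic-Adler formulation for EIT: the dual variable y is
# kept in [-1, 1], the complementarity condition is smoothed with beta
# (f_i = sqrt(r_i^2 + beta^2)), and the primal step is safeguarded by a
# backtracking line search on the exact primal objective. The L1 data norm
# makes the fit robust to heavy-tailed measurement errors at the price of an
# iterative solve.

#' PDIPM solver configuration
#'
#' @param lambda regularisation weight (> 0)
#' @param beta L1 smoothing parameter; `NULL` selects 1e-6 times the median
#'   absolute data value at call time
#' @param max_iterations iteration cap (default 100)
#' @param convergence_tol relative primal-change stopping tolerance
#' @param backtrack line-search shrink factor in (0, 1)
#' @return a `pdipm_config`
#' @export
pdipm_config <- function(lambda = 1e-3, beta = NULL, max_iterations = 100L,
                         convergence_tol = 1e-6, backtrack = 0.5) {
  stopifnot(lambda > 0, is.null(beta) || beta > 0, max_iterations >= 1,
            convergence_tol > 0, backtrack > 0, backtrack < 1)
  structure(list(lambda = lambda, beta = beta,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol, backtrack = backtrack),
            class = "pdipm_config")
}

#' Reconstruct by the primal-dual interior point method
#'
#' @param J an `eit_jacobian` or plain matrix
#' @param dv difference `eit_frame` (or numeric vector)
#' @param cfg a [pdipm_config()]
#' @param prior NOSER prior weights: either the vector diag(J'J)^p or an
#'   exponent given as `list(p = ...)`; default p = 0.5 as for the GN solver
#' @param model optional `eit_fem` for the output image
#' @return element-basis difference `eit_image` with attributes
#'   `iterations` (objective log, one row per accepted iterate) and
#'   `converged`
#' @export
reconstruct_pdipm <- function(J, dv, cfg = pdipm_config(), prior = list(p = 0.5),
                              model = NULL) {
  Jm <- if (inherits(J, "eit_jacobian")) J$matrix else as.matrix(J)
  b <- if (inherits(dv, "eit_frame")) {
    if (dv$kind != "difference") stop("reconstruct_pdipm expects a difference frame")
    dv$values
  } else as.numeric(dv)
  if (length(b) != nrow(Jm)) stop("frame length does not match Jacobian rows")
  Rw <- if (is.list(prior)) {
    d <- colSums(Jm^2)
    w <- d^(prior$p %||% 0.5)
    if (any(w == 0)) w[w == 0] <- min(w[w > 0])
    w
  } else as.numeric(prior)
  lambda <- cfg$lambda
  obj <- function(x) sum(abs(Jm %*% x - b)) + lambda * sum(Rw * x^2)

  n <- ncol(Jm)
  x <- numeric(n)
  if (all(b == 0)) {              # both terms minimised exactly at zero
    img <- eit_image(x, basis = "element", model = model, kind = "difference")
    attr(img, "iterations") <- data.frame(iteration = integer(0), objective = numeric(0))
    attr(img, "converged") <- TRUE
    return(img)
  }
  beta <- cfg$beta %||% max(1e-6 * median(abs(b)), 1e-12 * max(abs(b)))
  y <- numeric(nrow(Jm))          # dual variable, |y| <= 1
  log_obj <- numeric(0)
  converged <- FALSE
  f_old <- obj(x)
  for (it in seq_len(cfg$max_iterations)) {
    r <- as.numeric(Jm %*% x - b)
    f <- sqrt(r^2 + beta^2)
    # Newton direction from the smoothed primal-dual KKT system:
    #   J'y + 2 lambda R x = 0 ;  y f - r = 0
    # eliminating dy gives (J' F^-1 K J + 2 lambda R) dx = -(J'ytilde + 2 lambda R x)
    # with K = diag(1 - y r / f) and ytilde = r / f (the centred dual).
    K <- 1 - y * r / f
    K[K < 1e-10] <- 1e-10
    W <- K / f
    H <- crossprod(Jm * sqrt(W)) + diag(2 * lambda * Rw, n)
    grad <- as.numeric(crossprod(Jm, r / f)) + 2 * lambda * Rw * x
    dx <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) { converged <- TRUE; break }
    # backtracking line search on the exact primal objective
    step <- 1
    repeat {
      x_new <- x + step * dx
      f_new <- obj(x_new)
      if (f_new <= f_old - 1e-12 * abs(f_old) || step < 1e-12) break
      step <- step * cfg$backtrack
    }
    if (step < 1e-12) { converged <- TRUE; break }  # numerically stationary
    # dual update with clamping to the feasible box [-1, 1]
    dy <- (r + Jm %*% dx - y * f) / f
    y <- pmin(1, pmax(-1, y + as.numeric(dy)))
    rel <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x_new^2)), 1e-300)
    x <- x_new
    log_obj <- c(log_obj, f_new)
    dropped <- f_old - f_new
    f_old <- f_new
    if (rel < cfg$convergence_tol || dropped <= 1e-14 * max(1, abs(f_new))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && length(log_obj) == cfg$max_iterations) {
    warning("PDIPM did not converge within max_iterations; returning best iterate")
  }
  img <- eit_image(x, basis = "element", model = model, kind = "difference")
  attr(img, "iterations") <- data.frame(iteration = seq_along(log_obj),
                                        objective = log_obj)
  attr(img, "converged") <- converged
  img
}

#' Write a PDIPM iteration log as CSV
#'
#' @param img the image returned by [reconstruct_pdipm()]
#' @param path output path
#' @export
write_iteration_log <- function(img, path) {
  log <- attr(img, "iterations")
  if (is.null(log)) stop("image carries no iteration log")
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}
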