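# Complete-electrode-model forward problem and adjoint sensitivity.
#
# The FEM system couples N nodal potentials u with L electrode potentials V:
#
#   [ A_sigma + sum_l (1/z_l) M_l    -(1/z_l) s_l ] [u]   [0]
#   [ -(1/z_l) s_l^T                 |E_l|/z_l    ] [V] = [I]
#
# where A_sigma is the conductivity-weighted stiffness matrix, M_l and s_l
# are boundary mass integrals over electrode l, z_l its contact impedance
# and |E_l| its surface measure. A Lagrange multiplier row enforces the
# zero-sum electrode potential gauge, which removes the constant null space
# deterministically. 2D models are treated as unit-thickness slices.

#' @importFrom Matrix sparseMatrix Diagonal t solve crossprod
NULL

# Per-element shape-function gradients (constant for linear simplices).
# Returns a list: grads[[e]] is k x dim.
element_gradients <- function(model) {
  nd <- model$nodes; el <- model$elements
  E <- nrow(el)
  if (model$dim == 2L) {
    x1 <- nd[el[, 1], 1]; y1 <- nd[el[, 1], 2]
    x2 <- nd[el[, 2], 1]; y2 <- nd[el[, 2], 2]
    x3 <- nd[el[, 3], 1]; y3 <- nd[el[, 3], 2]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
    gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
    list(gx = gx, gy = gy, gz = NULL)
  } else {
    k <- 4L
    gx <- gy <- gz <- matrix(0, E, k)
    for (e in seq_len(E)) {
      p <- nd[el[e, ], ]
      Jm <- rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
      Ji <- solve(Jm)            # columns: d(ref coords)/d(x,y,z)
      gref <- rbind(c(-1, -1, -1), diag(3))  # grads of shape fns in ref coords
      g <- gref %*% t(Ji)
      gx[e, ] <- g[, 1]; gy[e, ] <- g[, 2]; gz[e, ] <- g[, 3]
    }
    list(gx = gx, gy = gy, gz = gz)
  }
}

# Stiffness matrix A_sigma (N x N sparse) for element conductivities sigma.
stiffness_matrix <- function(model, sigma, grads = NULL) {
  el <- model$elements
  k <- ncol(el); E <- nrow(el)
  g <- grads %||% element_gradients(model)
  w <- sigma * model$volumes
  ii <- jj <- vv <- vector("list", k * k)
  idx <- 0L
  for (a in seq_len(k)) for (b in seq_len(k)) {
    idx <- idx + 1L
    dot <- g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b]
    if (!is.null(g$gz)) dot <- dot + g$gz[, a] * g$gz[, b]
    ii[[idx]] <- el[, a]; jj[[idx]] <- el[, b]; vv[[idx]] <- w * dot
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
               dims = c(nrow(model$nodes), nrow(model$nodes)))
}

# Boundary integrals for one electrode patch: mass matrix entries (triplets),
# the load vector s (integral of each shape function), and the measure |E_l|.
electrode_integrals <- function(model, faces) {
  nd <- model$nodes
  if (model$dim == 2L) {
    a <- faces[, 1]; b <- faces[, 2]
    len <- sqrt(rowSums((nd[a, 1:2, drop = FALSE] - nd[b, 1:2, drop = FALSE])^2))
    ii <- c(a, b, a, b); jj <- c(a, b, b, a)
    vv <- c(len / 3, len / 3, len / 6, len / 6)
    s <- numeric(nrow(nd))
    for (f in seq_along(len)) {
      s[a[f]] <- s[a[f]] + len[f] / 2
      s[b[f]] <- s[b[f]] + len[f] / 2
    }
    list(ii = ii, jj = jj, vv = vv, s = s, measure = sum(len))
  } else {
    p1 <- nd[faces[, 1], , drop = FALSE]
    p2 <- nd[faces[, 2], , drop = FALSE]
    p3 <- nd[faces[, 3], , drop = FALSE]
    cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                               u[, 3] * v[, 1] - u[, 1] * v[, 3],
                               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area <- 0.5 * sqrt(rowSums(cr(p2 - p1, p3 - p1)^2))
    ii <- jj <- vv <- list()
    pairs <- expand.grid(a = 1:3, b = 1:3)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$a[r]; b <- pairs$b[r]
      ii[[r]] <- faces[, a]; jj[[r]] <- faces[, b]
      vv[[r]] <- area * (if (a == b) 1 / 6 else 1 / 12)
    }
    s <- numeric(nrow(nd))
    for (c in 1:3) for (f in seq_len(nrow(faces))) {
      s[faces[f, c]] <- s[faces[f, c]] + area[f] / 3
    }
    list(ii = unlist(ii), jj = unlist(jj), vv = unlist(vv), s = s, measure = sum(area))
  }
}

# Assemble the full CEM system (N + L + 1 square, sparse, symmetric).
cem_system <- function(model, sigma, grads = NULL) {
  N <- nrow(model$nodes); L <- length(model$electrodes)
  A <- stiffness_matrix(model, sigma, grads)
  ii <- jj <- vv <- list(); idx <- 0L
  svecs <- matrix(0, N, L); meas <- numeric(L)
  for (l in seq_len(L)) {
    e <- electrode_integrals(model, model$electrodes[[l]])
    z <- model$contact_impedance[l]
    idx <- idx + 1L
    ii[[idx]] <- e$ii; jj[[idx]] <- e$jj; vv[[idx]] <- e$vv / z
    svecs[, l] <- e$s / z
    meas[l] <- e$measure / z
  }
  Az <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv), dims = c(N, N))
  Svec <- methods::as(svecs, "CsparseMatrix")
  gauge <- c(rep(0, N), rep(1, L))
  K <- rbind(
    cbind(A + Az, -Svec, Matrix::Matrix(0, N, 1)),
    cbind(-Matrix::t(Svec), Diagonal(x = meas), Matrix::Matrix(1, L, 1)),
    Matrix::Matrix(c(gauge, 0), 1, N + L + 1)
  )
  list(K = K, N = N, L = L)
}

#' Solve the complete-electrode-model forward problem
#'
#' Computes nodal and electrode potentials for every injection of the
#' protocol (unit-current solves scaled by the drive amplitude) and
#' assembles the absolute voltage frame in the protocol's canonical order.
#' Voltage polarity is V(first electrode) - V(second electrode) of each
#' measurement pair.
#'
#' @param model an `eit_fem`
#' @param sigma element-basis absolute `eit_image` (all values > 0), or a
#'   numeric vector of per-element conductivities in S/m
#' @param protocol an `eit_protocol` on the model's electrodes
#' @return an `eit_forward` with `nodal_potentials` (N x n_inj),
#'   `electrode_potentials` (L x n_inj) and `frame` (absolute `eit_frame`)
#' @export
solve_forward <- function(model, sigma, protocol) {
  sig <- if (inherits(sigma, "eit_image")) {
    stopifnot(sigma$basis == "element")
    sigma$values
  } else as.numeric(sigma)
  if (length(sig) != nrow(model$elements)) stop("sigma length does not match element count")
  if (any(sig <= 0)) stop("conductivities must be strictly positive")
  if (protocol$n_electrodes != length(model$electrodes)) {
    stop("protocol electrode count does not match model")
  }
  sys <- cem_system(model, sig)
  N <- sys$N; L <- sys$L
  n_inj <- nrow(protocol$injections)
  rhs <- matrix(0, N + L + 1, n_inj)
  for (i in seq_len(n_inj)) {
    rhs[N + protocol$injections[i, 1], i] <- protocol$current
    rhs[N + protocol$injections[i, 2], i] <- -protocol$current
  }
  sol <- tryCatch(
    as.matrix(Matrix::solve(sys$K, rhs)),
    error = function(e) stop("singular CEM system: ", conditionMessage(e))
  )
  if (any(!is.finite(sol))) stop("forward solve produced non-finite potentials")
  U <- sol[seq_len(N), , drop = FALSE]
  V <- sol[N + seq_len(L), , drop = FALSE]
  structure(list(
    nodal_potentials = U, electrode_potentials = V,
    frame = assemble_frame(V, protocol),
    model_id = model$name, protocol_id = protocol$id
  ), class = "eit_forward")
}

assemble_frame <- function(V, protocol) {
  rows <- protocol_rows(protocol)
  mp <- protocol$measurements
  vals <- V[cbind(mp[rows$measurement, 1], rows$injection)] -
          V[cbind(mp[rows$measurement, 2], rows$injection)]
  eit_frame(vals, protocol, kind = "absolute")
}

#' @export
print.eit_forward <- function(x, ...) {
  cat(sprintf("CEM forward solution on '%s': %d injections, frame length %d\n",
              x$model_id, ncol(x$electrode_potentials), x$frame$frame_length))
  invisible(x)
}

#' Sensitivity (Jacobian) matrix by the adjoint method
#'
#' Row m of the Jacobian gives the derivative of kept measurement m with
#' respect to each element conductivity at the linearisation point
#' `sigma0`. For linear simplices the adjoint formula reduces to
#' \eqn{J[m, e] = -|e| \, \nabla u_d \cdot \nabla u_w} with \eqn{u_d} the
#' drive field (at the protocol current) and \eqn{u_w} the field obtained by
#' driving unit current through the measurement pair; adjacent protocols
#' reuse one solve per distinct electrode pair.
#'
#' @param model an `eit_fem`
#' @param sigma0 background conductivity image (element basis) or vector
#' @param protocol an `eit_protocol`
#' @return an `eit_jacobian` with `matrix` (frame_length x E), the
#'   linearisation background, and model/protocol ids
#' @export
jacobian <- function(model, sigma0, protocol) {
  fw <- solve_forward(model, sigma0, protocol)
  g <- element_gradients(model)
  U <- fw$nodal_potentials / protocol$current  # unit-current fields per pair
  el <- model$elements; k <- ncol(el)
  npair <- ncol(U)
  E <- nrow(el)
  # per-element gradient of each unit-current field
  Gx <- matrix(0, E, npair); Gy <- matrix(0, E, npair)
  Gz <- if (model$dim == 3L) matrix(0, E, npair) else NULL
  for (a in seq_len(k)) {
    Ua <- U[el[, a], , drop = FALSE]
    Gx <- Gx + g$gx[, a] * Ua
    Gy <- Gy + g$gy[, a] * Ua
    if (!is.null(Gz)) Gz <- Gz + g$gz[, a] * Ua
  }
  rows <- protocol_rows(protocol)
  J <- matrix(0, nrow(rows), E)
  vol <- model$volumes
  for (r in seq_len(nrow(rows))) {
    d <- rows$injection[r]; w <- rows$measurement[r]
    dot <- Gx[, d] * Gx[, w] + Gy[, d] * Gy[, w]
    if (!is.null(Gz)) dot <- dot + Gz[, d] * Gz[, w]
    J[r, ] <- -protocol$current * vol * dot
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries")
  bg <- if (inherits(sigma0, "eit_image")) sigma0 else
    eit_image(sigma0, basis = "element", model = model, kind = "absolute")
  structure(list(matrix = J, background = bg, model_id = model$name,
                 protocol_id = protocol$id), class = "eit_jacobian")
}

#' @export
print.eit_jacobian <- function(x, ...) {
  cat(sprintf("EIT Jacobian: %d measurements x %d elements on '%s'\n",
              nrow(x$matrix), ncol(x$matrix), x$model_id))
  invisible(x)
}

#' Analytic boundary potential of a homogeneous disk
#'
#' Series solution for a unit-thickness homogeneous disk of radius `a` and
#' conductivity `sigma`, driven by point currents +I at boundary angle
#' `theta_src` and -I at `theta_snk`:
#' \deqn{u(a,\theta) = \frac{I}{\pi\sigma}\sum_{n\ge 1} \frac{1}{n}
#'   [\cos n(\theta-\theta_{src}) - \cos n(\theta-\theta_{snk})]}
#' Used as an independent oracle for the forward solver.
#'
#' @param theta angles at which to evaluate the boundary potential
#' @param theta_src,theta_snk source and sink angles
#' @param current drive current (A), `sigma` conductivity (S/m)
#' @param sigma conductivity (S/m)
#' @param n_terms series truncation
#' @return boundary potentials (volts, zero-mean over the circle)
#' @export
disk_analytic_potential <- function(theta, theta_src, theta_snk,
                                    current = 1, sigma = 1, n_terms = 400L) {
  out <- numeric(length(theta))
  for (n in seq_len(n_terms)) {
    out <- out + (cos(n * (theta - theta_src)) - cos(n * (theta - theta_snk))) / n
  }
  current / (pi * sigma) * out
}
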