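# Finite element models for EIT: structured meshes of cylindrical tanks and
# thorax-like planar contours, electrode surface patches, and scene painting.
#
# Conventions: coordinates in metres, conductivity in S/m, contact impedance
# in ohm.m^2. In-memory node/element indices are 1-based (R idiom); all file
# formats written by the package use 0-based indices.

#' Construct and validate a finite element model
#'
#' An `eit_fem` object holds the geometry everything else is computed on:
#' node coordinates, simplex connectivity (triangles in 2D, tetrahedra in
#' 3D), the boundary faces forming each electrode, and per-electrode contact
#' impedances for the complete electrode model.
#'
#' @param nodes N x 3 numeric matrix of coordinates (2D models use z = 0)
#' @param elements E x k integer matrix, k = 3 (triangles) or 4 (tetrahedra)
#' @param electrodes list, one entry per electrode, each a matrix of boundary
#'   faces (rows of 2 node indices for edges, 3 for surface triangles)
#' @param contact_impedance numeric vector, ohm.m^2, recycled to the number
#'   of electrodes
#' @param name string identifier
#' @param validate check mesh invariants (positive volumes, index ranges,
#'   electrode faces on the boundary and disjoint)
#' @return an object of class `eit_fem`
#' @export
fe_model <- function(nodes, elements, electrodes, contact_impedance = 0.01,
                     name = "model", validate = TRUE) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) == 2) nodes <- cbind(nodes, 0)
  stopifnot(ncol(nodes) == 3)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  k <- ncol(elements)
  if (!k %in% c(3L, 4L)) stop("elements must be triangles (3) or tetrahedra (4)")
  dim <- if (k == 3L) 2L else 3L
  zl <- rep_len(as.numeric(contact_impedance), length(electrodes))
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("element node index out of range")
  }
  m <- structure(list(
    nodes = nodes, elements = elements, dim = dim,
    electrodes = lapply(electrodes, function(f) {
      f <- as.matrix(f); storage.mode(f) <- "integer"; f
    }),
    contact_impedance = zl, name = name
  ), class = "eit_fem")
  m$volumes <- element_measures(m)
  if (validate) validate_fe_model(m)
  m
}

#' @export
print.eit_fem <- function(x, ...) {
  cat(sprintf("EIT finite element model '%s' (%dD)\n", x$name, x$dim))
  cat(sprintf("  %d nodes, %d %s, %d electrodes\n",
              nrow(x$nodes), nrow(x$elements),
              if (x$dim == 2L) "triangles" else "tetrahedra",
              length(x$electrodes)))
  invisible(x)
}

validate_fe_model <- function(m) {
  n <- nrow(m$nodes)
  el <- m$elements
  if (any(el < 1L) || any(el > n)) stop("element node index out of range")
  if (any(apply(el, 1L, anyDuplicated) > 0L)) stop("element with repeated nodes")
  if (any(m$volumes <= 0)) {
    bad <- which(m$volumes <= 0)
    stop(sprintf("%d degenerate elements (non-positive measure), first at index %d",
                 length(bad), bad[1]))
  }
  bf <- boundary_faces(m)
  bkey <- face_keys(bf)
  seen <- character(0)
  for (i in seq_along(m$electrodes)) {
    f <- m$electrodes[[i]]
    if (nrow(f) == 0L) stop(sprintf("electrode %d has an empty patch", i))
    k <- face_keys(f)
    if (!all(k %in% bkey)) stop(sprintf("electrode %d has faces off the boundary", i))
    if (any(k %in% seen)) stop(sprintf("electrode %d overlaps another patch", i))
    seen <- c(seen, k)
  }
  if (any(m$contact_impedance <= 0)) stop("contact impedances must be positive")
  invisible(TRUE)
}

# Signed measure per element: triangle area (z ignored) or tet volume.
element_measures <- function(m) {
  nd <- m$nodes; el <- m$elements
  if (m$dim == 2L) {
    a <- nd[el[, 1], 1:2, drop = FALSE]
    b <- nd[el[, 2], 1:2, drop = FALSE]
    c <- nd[el[, 3], 1:2, drop = FALSE]
    0.5 * ((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
           (c[, 1] - a[, 1]) * (b[, 2] - a[, 2]))
  } else {
    a <- nd[el[, 1], , drop = FALSE]; b <- nd[el[, 2], , drop = FALSE]
    c <- nd[el[, 3], , drop = FALSE]; d <- nd[el[, 4], , drop = FALSE]
    u <- b - a; v <- c - a; w <- d - a
    (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
  }
}

element_centroids <- function(m) {
  el <- m$elements
  k <- ncol(el)
  out <- matrix(0, nrow(el), 3)
  for (j in seq_len(k)) out <- out + m$nodes[el[, j], , drop = FALSE]
  out / k
}

# All (k-1)-faces of the elements that belong to exactly one element.
boundary_faces <- function(m) {
  el <- m$elements
  if (m$dim == 2L) {
    fa <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  } else {
    fa <- rbind(el[, c(1, 2, 3)], el[, c(1, 2, 4)], el[, c(1, 3, 4)], el[, c(2, 3, 4)])
  }
  keys <- face_keys(fa)
  tab <- table(keys)
  fa[keys %in% names(tab)[tab == 1L], , drop = FALSE]
}

face_keys <- function(fa) {
  srt <- t(apply(as.matrix(fa), 1L, sort))
  do.call(paste, c(as.data.frame(srt), sep = "-"))
}

# Orient all elements to positive measure by swapping the last two nodes of
# any inverted simplex.
orient_positive <- function(nodes, elements, dim) {
  m <- list(nodes = nodes, elements = elements, dim = dim)
  v <- element_measures(m)
  k <- ncol(elements)
  flip <- v < 0
  if (any(flip)) {
    tmp <- elements[flip, k - 1L]
    elements[flip, k - 1L] <- elements[flip, k]
    elements[flip, k] <- tmp
  }
  elements
}

# --- structured planar meshes ------------------------------------------------

# Structured polar mesh of a star-shaped region r <= rho(theta): a centre
# node, n_r rings of the given boundary angles scaled radially, fan triangles
# in the innermost ring and split quads elsewhere. Returns nodes (x, y),
# triangles, and the indices of the boundary ring in angular order.
polar_mesh <- function(theta, rho, n_r) {
  M <- length(theta)
  stopifnot(M >= 4, n_r >= 1, all(rho > 0))
  nodes <- matrix(0, 1 + M * n_r, 2)
  for (i in seq_len(n_r)) {
    s <- i / n_r
    idx <- 1L + (i - 1L) * M + seq_len(M)
    nodes[idx, 1] <- s * rho * cos(theta)
    nodes[idx, 2] <- s * rho * sin(theta)
  }
  ring <- function(i, j) 1L + (i - 1L) * M + ((j - 1L) %% M) + 1L
  tris <- matrix(0L, M * (2L * n_r - 1L), 3L)
  r <- 0L
  for (j in seq_len(M)) {  # centre fan
    r <- r + 1L
    tris[r, ] <- c(1L, ring(1L, j), ring(1L, j + 1L))
  }
  if (n_r > 1L) for (i in seq_len(n_r - 1L)) for (j in seq_len(M)) {
    a <- ring(i, j); b <- ring(i, j + 1L)
    c <- ring(i + 1L, j); d <- ring(i + 1L, j + 1L)
    tris[r + 1L, ] <- c(a, b, d)
    tris[r + 2L, ] <- c(a, d, c)
    r <- r + 2L
  }
  tris <- orient_positive(cbind(nodes, 0), tris, 2L)
  list(nodes = nodes, triangles = tris,
       boundary_ring = 1L + (n_r - 1L) * M + seq_len(M))
}

mesh_density_params <- function(n_electrodes, density) {
  density <- match.arg(density, c("coarse", "fine"))
  # edges-per-electrode-pitch and radial rings; "fine" quadruples elements
  if (density == "coarse") list(k = 2L, n_r = 3L) else list(k = 4L, n_r = 6L)
}

# Contiguous boundary-edge patches, one per electrode, each covering half the
# inter-electrode pitch, for a boundary ring of M = m * k nodes.
ring_electrode_patches <- function(boundary_ring, m, k) {
  M <- length(boundary_ring)
  stopifnot(M == m * k)
  cover <- max(1L, k %/% 2L)
  lapply(seq_len(m), function(e) {
    centre <- (e - 1L) * k  # 0-based slot of electrode centre node
    first <- centre - (cover %/% 2L)
    edges <- matrix(0L, cover, 2L)
    for (t in seq_len(cover)) {
      j <- first + t - 1L
      edges[t, ] <- c(boundary_ring[(j %% M) + 1L], boundary_ring[((j + 1L) %% M) + 1L])
    }
    edges
  })
}

# --- tank (3D cylinder) ------------------------------------------------------

#' Build a cylindrical tank model with rings of electrodes
#'
#' Meshes a cylinder of the given radius and height with tetrahedra
#' (structured extruded disk), and attaches `n_rings` rings of
#' `electrodes_per_ring` electrodes on the lateral surface: rings equally
#' spaced in height, electrodes equally spaced in angle. This is the geometry
#' of a saline-tank phantom; the default experiment uses 4 rings of 8
#' electrodes (32 in total).
#'
#' @param radius,height cylinder dimensions in metres
#' @param n_rings number of electrode rings
#' @param electrodes_per_ring electrodes per ring (>= 4)
#' @param density `"coarse"` or `"fine"`; fine has at least 4x the elements
#' @param order element order; quadratic elements are substituted by a
#'   refined linear mesh (flagged with a message), which serves the same
#'   purpose of separating forward and inverse discretisations
#' @param contact_impedance per-electrode contact impedance, ohm.m^2
#' @return an `eit_fem` with `n_rings * electrodes_per_ring` electrode patches
#' @export
build_tank_model <- function(radius, height, n_rings, electrodes_per_ring,
                             density = c("coarse", "fine"), order = 1L,
                             contact_impedance = 0.01) {
  stopifnot(radius > 0, height > 0, n_rings >= 1, electrodes_per_ring >= 2,
            n_rings * electrodes_per_ring >= 4)
  density <- match.arg(density)
  p <- mesh_density_params(electrodes_per_ring, density)
  if (order == 2L) {
    message("order-2 elements realised as a refined order-1 mesh (forward/inverse mesh separation)")
    p$k <- p$k * 2L; p$n_r <- p$n_r * 2L
  }
  m <- electrodes_per_ring
  M <- m * p$k
  theta <- 2 * pi * (seq_len(M) - 1L) / M
  disk <- polar_mesh(theta, rep(radius, M), p$n_r)
  nz <- 2L * n_rings * (if (density == "fine") 2L else 1L) * (if (order == 2L) 2L else 1L)
  ext <- extrude_to_tets(disk, height, nz)
  # electrode windows: half pitch in angle, 40% of ring spacing in height
  zc <- height * (2 * seq_len(n_rings) - 1) / (2 * n_rings)
  thc <- 2 * pi * (seq_len(m) - 1L) / m
  lat <- lateral_faces(ext, radius)
  patches <- vector("list", n_rings * m)
  cz <- face_centroids(ext$nodes, lat)
  ang <- atan2(cz[, 2], cz[, 1]) %% (2 * pi)
  for (r in seq_len(n_rings)) for (e in seq_len(m)) {
    dth <- abs(((ang - thc[e] + pi) %% (2 * pi)) - pi)
    sel <- dth <= (pi / m) * 0.5 + 1e-9 & abs(cz[, 3] - zc[r]) <= 0.2 * height / n_rings + 1e-9
    if (!any(sel)) {
      stop(sprintf("mesh too coarse to host electrode (ring %d, index %d): radius=%g height=%g rings=%d per_ring=%d density=%s",
                   r, e, radius, height, n_rings, m, density))
    }
    patches[[(r - 1L) * m + e]] <- lat[sel, , drop = FALSE]
  }
  mod <- fe_model(ext$nodes, ext$tets, patches, contact_impedance,
                  name = sprintf("tank_r%g_h%g_%dx%d_%s", radius, height, n_rings, m, density))
  mod$geometry <- list(type = "cylinder", radius = radius, height = height)
  mod
}

# Extrude a triangulated disk to nz layers of prisms, each split into three
# tetrahedra with the minimum-global-index rule (Dompierre et al.), which
# guarantees conforming faces between neighbouring prisms.
extrude_to_tets <- function(disk, height, nz) {
  n2 <- nrow(disk$nodes)
  z <- height * (0:nz) / nz
  nodes <- do.call(rbind, lapply(z, function(zz) cbind(disk$nodes, zz)))
  nid <- function(layer, i) (layer - 1L) * n2 + i  # layer is 1-based
  tets <- vector("list", nz * nrow(disk$triangles))
  cnt <- 0L
  for (l in seq_len(nz)) {
    for (t in seq_len(nrow(disk$triangles))) {
      tri <- disk$triangles[t, ]
      bot <- nid(l, tri); top <- nid(l + 1L, tri)
      pr <- c(bot, top)  # prism vertices v1..v6
      # rotate so the smallest global index is v1 (bottom) with matching top
      o <- which.min(pr)
      if (o > 3L) {  # mirror: make the smallest a bottom vertex by flipping
        pr <- c(pr[4:6], pr[1:3])
      }
      o <- which.min(pr[1:3])
      rot <- ((o - 1L + 0:2) %% 3L) + 1L
      pr <- c(pr[rot], pr[rot + 3L])
      v <- pr
      if (min(v[2], v[6]) < min(v[3], v[5])) {
        tt <- rbind(c(v[1], v[2], v[3], v[6]),
                    c(v[1], v[2], v[6], v[5]),
                    c(v[1], v[5], v[6], v[4]))
      } else {
        tt <- rbind(c(v[1], v[2], v[3], v[5]),
                    c(v[1], v[5], v[3], v[6]),
                    c(v[1], v[5], v[6], v[4]))
      }
      cnt <- cnt + 1L
      tets[[cnt]] <- tt
    }
  }
  tets <- do.call(rbind, tets)
  storage.mode(tets) <- "integer"
  tets <- orient_positive(nodes, tets, 3L)
  list(nodes = nodes, tets = tets)
}

# Boundary triangles whose nodes all sit on the outer radius.
lateral_faces <- function(ext, radius) {
  m <- list(nodes = ext$nodes, elements = ext$tets, dim = 3L)
  bf <- boundary_faces(m)
  r <- sqrt(ext$nodes[, 1]^2 + ext$nodes[, 2]^2)
  on_r <- abs(r - radius) < 1e-9 * max(1, radius)
  keep <- on_r[bf[, 1]] & on_r[bf[, 2]] & on_r[bf[, 3]]
  bf[keep, , drop = FALSE]
}

face_centroids <- function(nodes, faces) {
  out <- matrix(0, nrow(faces), 3)
  for (j in seq_len(ncol(faces))) out <- out + nodes[faces[, j], , drop = FALSE]
  out / ncol(faces)
}

# --- thorax-like contour models (2D) ----------------------------------------

#' Fourier coefficients of an average-thorax-like contour
#'
#' A stand-in polar contour \eqn{\rho(\theta) = a_0 + \sum_k a_k\cos k\theta +
#' b_k \sin k\theta} resembling an adult thorax section (wider than deep,
#' flattened posteriorly), truncated at 8 harmonics. This is a synthetic
#' reference shape for simulation, not a segmentation of any subject.
#'
#' @param n_harmonics truncation order (default 8)
#' @return list with components `a` (cosine, length n_harmonics + 1 including
#'   the constant term) and `b` (sine, length n_harmonics)
#' @export
thorax_coefficients <- function(n_harmonics = 8L) {
  a <- c(0.13, 0, 0.028, 0, -0.006, 0, 0.002, 0, 0)[seq_len(n_harmonics + 1L)]
  b <- c(0, 0.004, 0, 0, 0, 0, 0, 0)[seq_len(n_harmonics)]
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  list(a = a, b = b)
}

fourier_radius <- function(coef, theta) {
  r <- rep(coef$a[1], length(theta))
  for (k in seq_along(coef$a)[-1]) r <- r + coef$a[k] * cos((k - 1) * theta)
  for (k in seq_along(coef$b)) r <- r + coef$b[k] * sin(k * theta)
  r
}

#' Build a planar contour model from Fourier coefficients
#'
#' Meshes the star-shaped region bounded by the truncated Fourier series
#' \eqn{\rho(\theta)} with triangles, placing `n_electrodes` electrode
#' patches equally spaced by arc length around the boundary. With all
#' harmonics zero this reduces to a disk. Used for single-ring thorax
#' imaging (16 electrodes in a plane around the chest).
#'
#' @param coefficients list with `a` (cosine, constant first) and `b` (sine)
#' @param n_electrodes electrode count
#' @inheritParams build_tank_model
#' @return a 2D `eit_fem` with `n_electrodes` electrode patches
#' @export
build_contour_model <- function(coefficients, n_electrodes,
                                density = c("coarse", "fine"), order = 1L,
                                contact_impedance = 0.01) {
  density <- match.arg(density)
  p <- mesh_density_params(n_electrodes, density)
  if (order == 2L) {
    message("order-2 elements realised as a refined order-1 mesh (forward/inverse mesh separation)")
    p$k <- p$k * 2L; p$n_r <- p$n_r * 2L
  }
  # positivity of rho(theta) on a dense grid guarantees a simple closed curve
  thd <- 2 * pi * (0:4095) / 4096
  rd <- fourier_radius(coefficients, thd)
  if (any(rd <= 0)) stop("contour is self-intersecting or degenerate (rho <= 0)")
  # arc-length-equispaced boundary angles
  dth <- thd[2] - thd[1]
  drd <- c(diff(rd), rd[1] - rd[4096]) / dth
  ds <- sqrt(rd^2 + drd^2) * dth
  s <- cumsum(ds)
  total <- s[4096]
  M <- n_electrodes * p$k
  targets <- total * (seq_len(M) - 1L) / M
  theta <- stats::approx(c(0, s), c(thd, 2 * pi), xout = targets, ties = "ordered")$y
  rho <- fourier_radius(coefficients, theta)
  disk <- polar_mesh(theta, rho, p$n_r)
  patches <- ring_electrode_patches(disk$boundary_ring, n_electrodes, p$k)
  mod <- fe_model(cbind(disk$nodes, 0), disk$triangles, patches, contact_impedance,
                  name = sprintf("contour_%del_%s", n_electrodes, density))
  mod$geometry <- list(type = "contour", coefficients = coefficients)
  mod
}

#' Randomly perturb contour Fourier coefficients
#'
#' Scales every coefficient by an independent factor \eqn{1 + u}, with
#' \eqn{u} uniform on (-weight_bound, +weight_bound). With the default bound
#' of 0.10 this yields boundary shapes "similar to the thorax" while varying
#' across training samples, so a network never sees the same contour twice.
#'
#' @param base_coefficients list with `a` and `b` arrays
#' @param weight_bound maximum relative change per coefficient (default 0.10)
#' @param seed integer seed; the same seed reproduces the same perturbation
#' @return a coefficient list of the same shape
#' @export
perturb_contour <- function(base_coefficients, weight_bound = 0.10, seed = NULL) {
  stopifnot(weight_bound >= 0, weight_bound < 1)
  with_seed(seed, {
    pert <- function(v) v * (1 + runif(length(v), -weight_bound, weight_bound))
    list(a = pert(base_coefficients$a), b = pert(base_coefficients$b))
  })
}

# --- scenes ------------------------------------------------------------------

#' Describe a simulated scene
#'
#' A scene is a background conductivity plus a list of cylindrical or
#' elliptic-cylindrical targets to be painted into a model. Conductivities
#' are in S/m; use [resistivity_to_conductivity()] for values quoted in
#' ohm.m.
#'
#' @param background_conductivity background value, S/m (> 0)
#' @param targets list of targets, each a list with `shape`
#'   (`"circular-cylinder"` or `"elliptical-cylinder"`), `center` (x, y and,
#'   for 3D models, z), `semi_axes` (one radius or two semi-axes, metres),
#'   `height_range` (z interval, metres; ignored for 2D models) and
#'   `conductivity` (S/m, > 0)
#' @return a `scene_spec` object
#' @export
scene_spec <- function(background_conductivity, targets = list()) {
  stopifnot(background_conductivity > 0)
  for (t in targets) {
    stopifnot(t$conductivity > 0, all(t$semi_axes > 0))
  }
  structure(list(background = background_conductivity, targets = targets),
            class = "scene_spec")
}

target_semi_axes <- function(t) {
  ax <- t$semi_axes
  if (length(ax) == 1L) c(ax, ax) else ax[1:2]
}

#' Paint a scene onto a model's elements
#'
#' Assigns each element its scene conductivity: the target value when the
#' element centroid falls inside a target, the background otherwise. Targets
#' outside the model boundary are rejected.
#'
#' @param model an `eit_fem`
#' @param scene a [scene_spec()]
#' @return an element-basis `eit_image` of absolute conductivities
#' @export
paint_scene <- function(model, scene) {
  cen <- element_centroids(model)
  vals <- rep(scene$background, nrow(model$elements))
  for (i in seq_along(scene$targets)) {
    t <- scene$targets[[i]]
    check_target_inside(model, t, i)
    inside <- target_mask(model, t, cen)
    vals[inside] <- t$conductivity
  }
  eit_image(vals, basis = "element", model = model, kind = "absolute")
}

target_mask <- function(model, t, cen) {
  ax <- target_semi_axes(t)
  dx <- (cen[, 1] - t$center[1]) / ax[1]
  dy <- (cen[, 2] - t$center[2]) / ax[2]
  inside <- dx^2 + dy^2 <= 1
  if (model$dim == 3L && !is.null(t$height_range)) {
    inside <- inside & cen[, 3] >= t$height_range[1] & cen[, 3] <= t$height_range[2]
  }
  inside
}

check_target_inside <- function(model, t, idx) {
  ax <- target_semi_axes(t)
  th <- 2 * pi * (0:63) / 64
  px <- t$center[1] + ax[1] * cos(th)
  py <- t$center[2] + ax[2] * sin(th)
  g <- model$geometry
  ok <- if (!is.null(g) && g$type == "cylinder") {
    all(sqrt(px^2 + py^2) <= g$radius + 1e-12)
  } else if (!is.null(g) && g$type == "contour") {
    r <- sqrt(px^2 + py^2)
    all(r <= fourier_radius(g$coefficients, atan2(py, px)) + 1e-12)
  } else TRUE
  if (!ok) stop(sprintf("target %d lies outside the model boundary", idx))
  invisible(TRUE)
}

#' Conductivity image on a model
#'
#' @param values numeric vector, one value per element or per node
#' @param basis `"element"` or `"node"`
#' @param model the `eit_fem` the image lives on (used for length checks and
#'   to record the model id)
#' @param kind `"absolute"` (S/m) or `"difference"` (change in S/m)
#' @return an `eit_image`
#' @export
eit_image <- function(values, basis = c("element", "node"), model = NULL,
                      kind = c("absolute", "difference")) {
  basis <- match.arg(basis)
  kind <- match.arg(kind)
  values <- as.numeric(values)
  model_id <- NULL
  if (!is.null(model)) {
    expected <- if (basis == "element") nrow(model$elements) else nrow(model$nodes)
    if (length(values) != expected) {
      stop(sprintf("image length %d does not match %s count %d",
                   length(values), basis, expected))
    }
    model_id <- model$name
  }
  structure(list(values = values, basis = basis, model_id = model_id, kind = kind),
            class = "eit_image")
}

#' @export
print.eit_image <- function(x, ...) {
  cat(sprintf("EIT %s image (%s basis, %d values) on '%s'\n",
              x$kind, x$basis, length(x$values), x$model_id %||% "?"))
  cat(sprintf("  range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# Connected components of a set of elements under shared-face adjacency.
element_components <- function(model, mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(integer(0))
  el <- model$elements[idx, , drop = FALSE]
  k <- ncol(el)
  faces <- if (k == 3L) list(c(1, 2), c(2, 3), c(3, 1)) else
    list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  key2el <- new.env(hash = TRUE)
  nb <- vector("list", length(idx))
  for (e in seq_along(idx)) {
    for (f in faces) {
      key <- paste(sort(el[e, f]), collapse = "-")
      other <- key2el[[key]]
      if (is.null(other)) key2el[[key]] <- e
      else { nb[[e]] <- c(nb[[e]], other); nb[[other]] <- c(nb[[other]], e) }
    }
  }
  comp <- integer(length(idx)); cur <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, nb[[v]][comp[nb[[v]]] == 0L])
    }
  }
  comp
}

# Dense unit-disk model with near-point (two-edge) electrodes and a small
# contact impedance: the discretisation used to compare against the analytic
# homogeneous-disk series solution.
disk_model_point_electrodes <- function(n_electrodes = 16L, M = 256L, n_r = 24L,
                                        radius = 1, contact_impedance = 1e-5) {
  stopifnot(M %% n_electrodes == 0L)
  disk <- polar_mesh(2 * pi * (0:(M - 1L)) / M, rep(radius, M), n_r)
  k <- M %/% n_electrodes
  ring <- disk$boundary_ring
  patches <- lapply(seq_len(n_electrodes), function(e) {
    j <- (e - 1L) * k
    rbind(c(ring[((j - 1L) %% M) + 1L], ring[(j %% M) + 1L]),
          c(ring[(j %% M) + 1L], ring[((j + 1L) %% M) + 1L]))
  })
  mod <- fe_model(cbind(disk$nodes, 0), disk$triangles, patches,
                  contact_impedance, name = sprintf("disk_%del_M%d", n_electrodes, M))
  mod$geometry <- list(type = "cylinder", radius = radius, height = 0)
  mod
}
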