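# GREIT-style figures of merit on rasterised cross-sections: position error
# (PE), resolution difference (|dRES|) and shape deformation (SD), with
# per-target matching by nearest centre of gravity when a scene contains
# more than one target.

#' Rasterise an image on a model cross-section
#'
#' Samples the image on a G x G pixel grid spanning the square bounding the
#' model cross-section at the given height (ignored for planar models).
#' Node-basis images are interpolated linearly within the containing
#' element; element-basis images are piecewise constant. Pixels outside the
#' boundary are masked and ignored by all metrics.
#'
#' @param img an `eit_image` on `model`
#' @param model an `eit_fem`
#' @param height cross-section height in metres (3D models only)
#' @param G grid resolution per axis (default 64)
#' @return an `eit_raster` with `grid` (G x G, NA outside), `inside_mask`,
#'   `pixel_size`, `model_radius` and the pixel-centre coordinates
#' @export
rasterize <- function(img, model, height = 0, G = 64L) {
  stopifnot(inherits(img, "eit_image"))
  if (model$dim == 3L) {
    zr <- range(model$nodes[, 3])
    if (height < zr[1] - 1e-12 || height > zr[2] + 1e-12) {
      stop(sprintf("height %g outside model extent [%g, %g]", height, zr[1], zr[2]))
    }
  }
  g <- model$geometry
  R <- model_radius(model)
  xs <- seq(-R, R, length.out = G + 1L); xs <- (xs[-1] + xs[-(G + 1L)]) / 2
  px <- rep(xs, each = G); py <- rep(xs, G)   # column-major: grid[iy, ix]
  inside <- if (!is.null(g) && g$type == "contour") {
    r <- sqrt(px^2 + py^2)
    r <= fourier_radius(g$coefficients, atan2(py, px)) + 1e-12
  } else {
    px^2 + py^2 <= R^2 + 1e-12
  }
  vals <- rep(NA_real_, G * G)
  pz <- if (model$dim == 3L) rep(height, length(px)) else rep(0, length(px))
  hit <- locate_points(model, cbind(px, py, pz), img)
  # the mask is the meshed region: pixels between the polygonal boundary and
  # the analytic curve are excluded rather than given a made-up value
  inside <- inside & !is.na(hit)
  vals[inside] <- hit[inside]
  structure(list(grid = matrix(vals, G, G), inside_mask = matrix(inside, G, G),
                 pixel_size = 2 * R / G, cross_section_height = height,
                 model_radius = R, x = xs, y = xs),
            class = "eit_raster")
}

model_radius <- function(model) {
  g <- model$geometry
  if (!is.null(g) && g$type == "cylinder") return(g$radius)
  if (!is.null(g) && g$type == "contour") {
    th <- 2 * pi * (0:511) / 512
    return(max(fourier_radius(g$coefficients, th)))
  }
  max(sqrt(model$nodes[, 1]^2 + model$nodes[, 2]^2))
}

# Value of `img` at each query point (rows of pts), NA when no element
# contains the point. Loops over elements, vectorised over the pixels in
# each element's bounding box.
locate_points <- function(model, pts, img) {
  out <- rep(NA_real_, nrow(pts))
  nd <- model$nodes; el <- model$elements
  vals <- img$values
  node_basis <- img$basis == "node"
  tol <- 1e-9
  if (model$dim == 2L) {
    for (e in seq_len(nrow(el))) {
      p <- nd[el[e, ], 1:2, drop = FALSE]
      cand <- which(is.na(out) &
                    pts[, 1] >= min(p[, 1]) - tol & pts[, 1] <= max(p[, 1]) + tol &
                    pts[, 2] >= min(p[, 2]) - tol & pts[, 2] <= max(p[, 2]) + tol)
      if (!length(cand)) next
      b <- barycentric2(p, pts[cand, 1:2, drop = FALSE])
      ok <- rowSums(b < -1e-9) == 0
      if (!any(ok)) next
      idx <- cand[ok]
      out[idx] <- if (node_basis) as.numeric(b[ok, , drop = FALSE] %*% vals[el[e, ]]) else vals[e]
    }
  } else {
    zmin <- pmin(nd[el[, 1], 3], nd[el[, 2], 3], nd[el[, 3], 3], nd[el[, 4], 3])
    zmax <- pmax(nd[el[, 1], 3], nd[el[, 2], 3], nd[el[, 3], 3], nd[el[, 4], 3])
    h <- pts[1, 3]
    sel <- which(zmin - tol <= h & zmax + tol >= h)
    for (e in sel) {
      p <- nd[el[e, ], , drop = FALSE]
      cand <- which(is.na(out) &
                    pts[, 1] >= min(p[, 1]) - tol & pts[, 1] <= max(p[, 1]) + tol &
                    pts[, 2] >= min(p[, 2]) - tol & pts[, 2] <= max(p[, 2]) + tol)
      if (!length(cand)) next
      b <- barycentric3(p, pts[cand, , drop = FALSE])
      ok <- rowSums(b < -1e-9) == 0
      if (!any(ok)) next
      idx <- cand[ok]
      out[idx] <- if (node_basis) as.numeric(b[ok, , drop = FALSE] %*% vals[el[e, ]]) else vals[e]
    }
  }
  out
}

barycentric2 <- function(tri, q) {
  T <- cbind(tri[1, ] - tri[3, ], tri[2, ] - tri[3, ])
  r <- t(q) - tri[3, ]
  l <- solve(T, r)
  cbind(l[1, ], l[2, ], 1 - l[1, ] - l[2, ])
}

barycentric3 <- function(tet, q) {
  T <- cbind(tet[1, ] - tet[4, ], tet[2, ] - tet[4, ], tet[3, ] - tet[4, ])
  r <- t(q) - tet[4, ]
  l <- solve(T, r)
  cbind(l[1, ], l[2, ], l[3, ], 1 - colSums(l))
}

#' Quarter-amplitude set of a raster
#'
#' The operational "reconstructed target": pixels whose value, signed
#' consistently with the dominant amplitude, reaches one quarter of the
#' maximum absolute value inside the mask. An all-zero raster yields an
#' empty set with attribute `flagged = TRUE`.
#'
#' @param r an `eit_raster`
#' @return logical G x G matrix (the set), attribute `sign` giving the
#'   dominant polarity
#' @export
quarter_amplitude_set <- function(r) {
  v <- r$grid
  v[!r$inside_mask] <- NA
  mx <- max(abs(v), na.rm = TRUE)
  if (!is.finite(mx) || mx == 0) {
    out <- matrix(FALSE, nrow(v), ncol(v))
    attr(out, "flagged") <- TRUE
    attr(out, "sign") <- 1
    return(out)
  }
  s <- sign(v[which.max(abs(v))])
  out <- !is.na(v) & (s * v >= 0.25 * mx)
  attr(out, "sign") <- s
  attr(out, "flagged") <- FALSE
  out
}

# Connected components (8-connectivity) of a logical matrix; returns an
# integer matrix of labels (0 = background).
label_components <- function(mask) {
  G1 <- nrow(mask); G2 <- ncol(mask)
  lab <- matrix(0L, G1, G2)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] != 0L || !mask[v]) next
      lab[v] <- cur
      iy <- (v - 1L) %% G1 + 1L; ix <- (v - 1L) %/% G1 + 1L
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0L && dy == 0L) next
        jx <- ix + dx; jy <- iy + dy
        if (jx >= 1L && jx <= G2 && jy >= 1L && jy <= G1) {
          w <- (jx - 1L) * G1 + jy
          if (mask[w] && lab[w] == 0L) stack <- c(stack, w)
        }
      }
    }
  }
  lab
}

raster_cog <- function(r, set) {
  w <- abs(r$grid); w[!set] <- 0; w[is.na(w)] <- 0
  if (sum(w) == 0) return(c(NA_real_, NA_real_))
  ix <- rep(seq_along(r$x), each = length(r$y))
  iy <- rep(seq_along(r$y), length(r$x))
  wx <- as.numeric(w)
  c(sum(r$x[ix] * wx), sum(r$y[iy] * wx)) / sum(wx)
}

#' GREIT figures of merit for a reconstruction against the truth
#'
#' Thresholds both rasters at quarter amplitude, splits each into connected
#' components, matches reconstructed components to true targets by nearest
#' centre of gravity, and reports:
#' \itemize{
#' \item PE, per target: CoG displacement of the matched component, as a
#'   percentage of the model radius;
#' \item |dRES|: absolute difference of \eqn{RES = \sqrt{area / mask\ area}}
#'   between the total reconstructed and true quarter sets, in percent;
#' \item SD: fraction of reconstructed quarter-set pixels falling outside
#'   the reference circle(s) centred at the matched true CoG with the true
#'   component's area, in percent. Unmatched reconstructed pixels count as
#'   outside.
#' }
#' All three are invariant to scaling the reconstruction by a positive
#' constant.
#'
#' @param recon,truth `eit_raster`s on the same grid
#' @param model_radius radius used to normalise PE (defaults to the raster's)
#' @return an `eit_metrics` list: `per_target` data frame (target, PE,
#'   matched component), `dres`, `sd`, `flagged` targets without a match
#' @export
compute_metrics <- function(recon, truth, model_radius = NULL) {
  stopifnot(all(dim(recon$grid) == dim(truth$grid)))
  R <- model_radius %||% recon$model_radius
  qs_r <- quarter_amplitude_set(recon)
  qs_t <- quarter_amplitude_set(truth)
  lab_r <- label_components(qs_r)
  lab_t <- label_components(qs_t)
  n_t <- max(lab_t)
  n_r <- max(lab_r)
  cog_t <- lapply(seq_len(n_t), function(k) raster_cog(truth, lab_t == k))
  cog_r <- lapply(seq_len(n_r), function(k) raster_cog(recon, lab_r == k))
  # match each reconstructed component to the nearest true CoG
  match_of <- integer(n_r)
  if (n_t > 0) for (k in seq_len(n_r)) {
    d <- vapply(cog_t, function(ct) sqrt(sum((cog_r[[k]] - ct)^2)), numeric(1))
    match_of[k] <- which.min(d)
  }
  per_target <- data.frame(target = seq_len(n_t), pe = rep(NA_real_, n_t),
                           component = rep(NA_integer_, n_t))
  flagged <- integer(0)
  for (t in seq_len(n_t)) {
    comps <- which(match_of == t)
    if (!length(comps)) { flagged <- c(flagged, t); next }
    # among components claiming this target, take the largest
    sizes <- vapply(comps, function(k) sum(lab_r == k), numeric(1))
    k <- comps[which.max(sizes)]
    per_target$component[t] <- k
    per_target$pe[t] <- 100 * sqrt(sum((cog_r[[k]] - cog_t[[t]])^2)) / R
  }
  mask_area <- sum(recon$inside_mask)
  res_r <- sqrt(sum(qs_r) / mask_area)
  res_t <- sqrt(sum(qs_t) / mask_area)
  dres <- 100 * abs(res_r - res_t)
  # shape deformation: reconstructed pixels outside the truth-equivalent circles
  px <- recon$pixel_size
  ix <- rep(seq_along(recon$x), each = length(recon$y))
  iy <- rep(seq_along(recon$y), length(recon$x))
  outside <- 0L
  for (k in seq_len(n_r)) {
    sel <- which(as.numeric(lab_r) == k)
    t <- match_of[k]
    if (t == 0L || is.na(per_target$component[t]) || per_target$component[t] != k) {
      outside <- outside + length(sel)   # unmatched component: all outside
      next
    }
    area_t <- sum(lab_t == t) * px^2
    rad <- sqrt(area_t / pi)
    ct <- cog_t[[t]]
    d <- sqrt((recon$x[ix[sel]] - ct[1])^2 + (recon$y[iy[sel]] - ct[2])^2)
    # half-pixel tolerance so that an exactly-reproduced circular target
    # yields SD = 0 despite pixelisation of the reference circle
    outside <- outside + sum(d > rad + px / 2)
  }
  sd_pct <- if (sum(qs_r) > 0) 100 * outside / sum(qs_r) else NA_real_
  structure(list(per_target = per_target, dres = dres, sd = sd_pct,
                 flagged = flagged, n_components = n_r),
            class = "eit_metrics")
}

#' @export
print.eit_metrics <- function(x, ...) {
  cat("GREIT figures of merit:\n")
  for (t in seq_len(nrow(x$per_target))) {
    cat(sprintf("  target %d: PE = %s%%\n", t,
                if (is.na(x$per_target$pe[t])) "missing" else
                  sprintf("%.2f", x$per_target$pe[t])))
  }
  cat(sprintf("  |dRES| = %.2f%%, SD = %.2f%%\n", x$dres, x$sd))
  invisible(x)
}

#' Write a metrics report as CSV/JSON
#'
#' One row per target plus the aggregate resolution and shape terms.
#'
#' @param metrics an `eit_metrics`
#' @param path output path; `.json` selects JSON, anything else CSV
#' @export
write_metrics <- function(metrics, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_target = metrics$per_target,
                              dres = metrics$dres, sd = metrics$sd),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- metrics$per_target
    df$dres <- metrics$dres
    df$sd <- metrics$sd
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Plot a rasterised cross-section
#'
#' Image plot of the raster with the boundary mask greyed out; a quick look
#' at a reconstruction or truth slice.
#'
#' @param x an `eit_raster`
#' @param main title
#' @param ... passed to [graphics::image()]
#' @export
plot.eit_raster <- function(x, main = "", ...) {
  z <- x$grid
  z[!x$inside_mask] <- NA
  graphics::image(x$x, x$y, t(z), asp = 1, xlab = "x (m)", ylab = "y (m)",
                  main = main, col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}
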