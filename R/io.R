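# File interfaces: Gmsh MSH v2 ASCII and VTK legacy unstructured-grid mesh
# I/O (electrode patches carried as tagged boundary faces, tag = electrode
# index + 1000), JSON scene/config serialisation, and plain-text containers
# (CSV + JSON metadata) for Jacobians and trained networks. All indices in
# files are 0-based.

#' Write / read a model in Gmsh MSH v2 ASCII format
#'
#' Elements are written as triangles/tetrahedra; electrode faces follow as
#' lower-dimensional elements whose physical tag is the 0-based electrode
#' index + 1000.
#'
#' @param model an `eit_fem`
#' @param path file path
#' @export
write_msh <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(model$nodes))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(model$nodes)) - 1L,
                     model$nodes[, 1], model$nodes[, 2], model$nodes[, 3]), con)
  writeLines("$EndNodes", con)
  etype <- if (model$dim == 2L) 2L else 4L
  ftype <- if (model$dim == 2L) 1L else 2L
  faces <- do.call(rbind, lapply(seq_along(model$electrodes), function(l) {
    cbind(tag = l - 1L + 1000L, model$electrodes[[l]])
  }))
  total <- nrow(model$elements) + nrow(faces)
  writeLines(c("$Elements", as.character(total)), con)
  id <- 0L
  el0 <- model$elements - 1L
  writeLines(paste(seq_len(nrow(el0)) - 1L, etype, 2L, 0L, 0L,
                   apply(el0, 1, paste, collapse = " ")), con)
  f0 <- faces[, -1, drop = FALSE] - 1L
  writeLines(paste(nrow(el0) + seq_len(nrow(f0)) - 1L, ftype, 2L, faces[, 1], faces[, 1],
                   apply(f0, 1, paste, collapse = " ")), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' @rdname write_msh
#' @param contact_impedance contact impedance to attach on read (not stored
#'   in the format)
#' @param name model name to attach on read
#' @export
read_msh <- function(path, contact_impedance = 0.01, name = NULL) {
  lines <- readLines(path)
  sec <- function(tag) {
    i <- which(lines == paste0("$", tag)) + 1L
    j <- which(lines == paste0("$End", tag)) - 1L
    lines[i:j]
  }
  nl <- sec("Nodes")
  n <- as.integer(nl[1])
  nodes <- matrix(as.numeric(unlist(strsplit(nl[-1], " +"))), ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE]
  el <- sec("Elements")
  recs <- strsplit(el[-1], " +")
  etypes <- vapply(recs, function(r) as.integer(r[2]), integer(1))
  body <- function(r) {
    ntags <- as.integer(r[3])
    as.integer(r[(4 + ntags):length(r)]) + 1L
  }
  volumetric <- etypes %in% c(2L, 4L)
  facerecs <- recs[!volumetric & etypes %in% c(1L, 2L)]
  elems <- do.call(rbind, lapply(recs[volumetric], body))
  tags <- vapply(facerecs, function(r) as.integer(r[4]), integer(1))
  patches <- lapply(sort(unique(tags)), function(tg) {
    do.call(rbind, lapply(facerecs[tags == tg], body))
  })
  fe_model(nodes, elems, patches, contact_impedance,
           name = name %||% sub("\\.msh$", "", basename(path)))
}

#' Write / read a model as a VTK legacy unstructured grid
#'
#' Volume cells first, then electrode faces; the cell scalar field
#' `electrode_tag` is -1 for volume cells and 0-based electrode index + 1000
#' for faces.
#'
#' @param model an `eit_fem`
#' @param path file path
#' @export
write_vtk <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", model$name, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(model$nodes))), con)
  writeLines(sprintf("%.17g %.17g %.17g", model$nodes[, 1], model$nodes[, 2],
                     model$nodes[, 3]), con)
  faces <- do.call(rbind, lapply(seq_along(model$electrodes), function(l) {
    cbind(tag = l - 1L + 1000L, model$electrodes[[l]])
  }))
  k <- ncol(model$elements); fk <- ncol(faces) - 1L
  ncell <- nrow(model$elements) + nrow(faces)
  writeLines(sprintf("CELLS %d %d", ncell,
                     nrow(model$elements) * (k + 1L) + nrow(faces) * (fk + 1L)), con)
  writeLines(paste(k, apply(model$elements - 1L, 1, paste, collapse = " ")), con)
  writeLines(paste(fk, apply(faces[, -1, drop = FALSE] - 1L, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  vt <- if (model$dim == 2L) 5L else 10L
  ft <- if (model$dim == 2L) 3L else 5L
  writeLines(as.character(c(rep(vt, nrow(model$elements)), rep(ft, nrow(faces)))), con)
  writeLines(c(sprintf("CELL_DATA %d", ncell), "SCALARS electrode_tag int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(rep(-1L, nrow(model$elements)), faces[, 1])), con)
  invisible(path)
}

#' @rdname write_vtk
#' @param contact_impedance,name attached on read as for [read_msh()]
#' @export
read_vtk <- function(path, contact_impedance = 0.01, name = NULL) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  nodes <- matrix(as.numeric(unlist(strsplit(lines[ip + seq_len(n)], " +"))),
                  ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)
  ncell <- as.integer(strsplit(lines[ic], " +")[[1]][2])
  cells <- lapply(strsplit(lines[ic + seq_len(ncell)], " +"), as.integer)
  it <- grep("^CELL_TYPES", lines)
  types <- as.integer(lines[it + seq_len(ncell)])
  id <- grep("^SCALARS electrode_tag", lines)
  tags <- as.integer(lines[id + 1L + seq_len(ncell)])
  vol <- types %in% c(5L, 10L)
  elems <- do.call(rbind, lapply(cells[vol], function(c) c[-1] + 1L))
  ft <- cells[!vol]; ftag <- tags[!vol]
  patches <- lapply(sort(unique(ftag)), function(tg) {
    do.call(rbind, lapply(ft[ftag == tg], function(c) c[-1] + 1L))
  })
  fe_model(nodes, elems, patches, contact_impedance,
           name = name %||% sub("\\.vtk$", "", basename(path)))
}

#' Serialise a scene to / from JSON
#'
#' @param scene a [scene_spec()]
#' @param path file path
#' @export
write_scene <- function(scene, path) {
  jsonlite::write_json(list(background_conductivity = scene$background,
                            targets = scene$targets),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  targets <- lapply(x$targets, function(t) {
    t$center <- as.numeric(t$center)
    t$semi_axes <- as.numeric(t$semi_axes)
    if (!is.null(t$height_range)) t$height_range <- as.numeric(t$height_range)
    t
  })
  scene_spec(x$background_conductivity, targets)
}

#' Persist a Jacobian (or reconstruction matrix) as a text container
#'
#' A directory holding `matrix.csv` plus `meta.json` (model id, protocol id,
#' background hash), so precomputed reconstruction matrices can be reused
#' across runs — the linear solver's matrix is measurement-independent and
#' is the expensive part.
#'
#' @param J an `eit_jacobian`
#' @param dir container directory (created if needed)
#' @export
write_jacobian <- function(J, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(J$matrix, file.path(dir, "matrix.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(model_id = J$model_id, protocol_id = J$protocol_id,
                            background_hash = background_hash(J$background$values),
                            rows = nrow(J$matrix), cols = ncol(J$matrix)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_jacobian
#' @export
read_jacobian <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file.path(dir, "matrix.csv"), sep = ","))
  dimnames(m) <- NULL
  structure(list(matrix = m, background = NULL, model_id = meta$model_id,
                 protocol_id = meta$protocol_id), class = "eit_jacobian")
}

background_hash <- function(v) sprintf("%.8e", sum(v * seq_along(v)) / length(v))

#' Persist / restore a trained RBF network as a text container
#'
#' @param net an `eit_rbf`
#' @param dir container directory
#' @export
write_rbf <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.table(m, file.path(dir, f), sep = ",",
                                          row.names = FALSE, col.names = FALSE)
  wr(net$centers, "centers.csv"); wr(net$W, "weights.csv")
  jsonlite::write_json(list(widths = net$widths, bias = net$bias,
                            input_dim = net$input_dim, hidden = net$hidden,
                            spread = net$spread, ridge = net$ridge,
                            validation_mse = net$validation_mse,
                            scaler_in = net$scaler_in, scaler_out = net$scaler_out),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_rbf
#' @export
read_rbf <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rd <- function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = ","))
    dimnames(m) <- NULL
    m
  }
  structure(list(centers = rd("centers.csv"), widths = as.numeric(meta$widths),
                 W = rd("weights.csv"), bias = as.numeric(meta$bias),
                 input_dim = meta$input_dim, hidden = meta$hidden,
                 scaler_in = lapply(meta$scaler_in, as.numeric),
                 scaler_out = lapply(meta$scaler_out, as.numeric),
                 spread = meta$spread, ridge = meta$ridge,
                 validation_mse = meta$validation_mse), class = "eit_rbf")
}
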