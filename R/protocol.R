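# Stimulation/measurement protocols and voltage frames.
#
# Electrode numbering is ring-major: electrode (r, j) has index
# (r-1)*m + j, angular position j, ring r. Adjacent pairs are always taken
# within a ring, cycling around it.

#' Adjacent stimulation and measurement protocol
#'
#' Builds the standard adjacent/adjacent pattern used by serial EIT systems:
#' current is driven through every pair of neighbouring electrodes of each
#' ring in turn, and for each injection the voltages across every
#' neighbouring pair of the same ring are recorded. With
#' `exclude_injecting = TRUE`, measurements involving either driving
#' electrode are discarded, leaving \eqn{m (m - 3)} measurements per ring per
#' injection. A 4-ring, 8-electrode tank therefore yields 32 injections of
#' 29 kept measurements each (928 values per frame); a single ring of 16
#' electrodes yields 208.
#'
#' @param n_rings number of electrode rings
#' @param electrodes_per_ring electrodes per ring (>= 4)
#' @param exclude_injecting drop measurement pairs sharing an electrode with
#'   the active injection pair (default TRUE)
#' @param current drive current amplitude in amperes (default 1 mA)
#' @return an `eit_protocol` with injection pairs, per-injection measurement
#'   pairs, the keep mask and the resulting frame length
#' @export
adjacent_protocol <- function(n_rings, electrodes_per_ring,
                              exclude_injecting = TRUE, current = 1e-3) {
  m <- as.integer(electrodes_per_ring)
  R <- as.integer(n_rings)
  stopifnot(m >= 4, R >= 1, current > 0)
  pair <- function(r, j) {  # adjacent pair j of ring r, 1-based electrodes
    base <- (r - 1L) * m
    c(base + j, base + (j %% m) + 1L)
  }
  pairs <- do.call(rbind, lapply(seq_len(R), function(r) {
    do.call(rbind, lapply(seq_len(m), function(j) pair(r, j)))
  }))
  n_inj <- nrow(pairs)
  keep <- matrix(TRUE, n_inj, n_inj)  # (injection, measurement) cells
  if (exclude_injecting) {
    for (i in seq_len(n_inj)) {
      shared <- pairs[, 1] %in% pairs[i, ] | pairs[, 2] %in% pairs[i, ]
      keep[i, shared] <- FALSE
    }
  }
  structure(list(
    injections = pairs, measurements = pairs, keep = keep,
    n_electrodes = R * m, n_rings = R, electrodes_per_ring = m,
    current = current, frame_length = sum(keep),
    id = sprintf("adj_%dx%d_%s", R, m, if (exclude_injecting) "ex" else "all")
  ), class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat(sprintf("EIT protocol '%s': %d injections, frame length %d (drive %g mA)\n",
              x$id, nrow(x$injections), x$frame_length, x$current * 1e3))
  invisible(x)
}

# (injection, measurement-pair) index table of the kept cells, in canonical
# order: injections ring-major/angular, measurements likewise within each.
protocol_rows <- function(protocol) {
  n_inj <- nrow(protocol$injections)
  out <- which(t(protocol$keep), arr.ind = TRUE)  # iterate measurements fastest
  data.frame(injection = out[, 2], measurement = out[, 1])[
    order(out[, 2], out[, 1]), , drop = FALSE]
}

#' Voltage frame
#'
#' One vector of boundary voltages in the canonical order of a protocol.
#'
#' @param values numeric vector of length `protocol$frame_length`, volts
#' @param protocol the `eit_protocol` the frame belongs to
#' @param kind `"absolute"` or `"difference"`
#' @return an `eit_frame`
#' @export
eit_frame <- function(values, protocol, kind = c("absolute", "difference")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) != protocol$frame_length) {
    stop(sprintf("frame length %d does not match protocol frame_length %d",
                 length(values), protocol$frame_length))
  }
  structure(list(values = values, protocol_id = protocol$id,
                 frame_length = protocol$frame_length, kind = kind),
            class = "eit_frame")
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("EIT %s frame: %d voltages on protocol '%s', range [%.3e, %.3e] V\n",
              x$kind, x$frame_length, x$protocol_id,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Difference frame from two absolute frames
#'
#' Difference EIT reconstructs the change in conductivity between two
#' measurement instants; the data vector is the element-wise difference
#' between the measured and the reference frame, which cancels static
#' modelling errors common to both.
#'
#' @param measured,reference absolute `eit_frame`s on the same protocol
#' @return a difference `eit_frame` (measured minus reference)
#' @export
difference_frame <- function(measured, reference) {
  if (measured$protocol_id != reference$protocol_id) {
    stop("frames come from different protocols")
  }
  if (measured$kind != "absolute" || reference$kind != "absolute") {
    stop("difference_frame expects two absolute frames")
  }
  f <- measured
  f$values <- measured$values - reference$values
  f$kind <- "difference"
  f
}

#' Write / read a frame as CSV
#'
#' Columns: `injection_a`, `injection_b`, `meas_a`, `meas_b` (0-based
#' electrode indices) and `voltage` (volts), one row per kept measurement in
#' canonical order.
#'
#' @param frame an `eit_frame`
#' @param protocol the matching `eit_protocol`
#' @param path output path
#' @export
write_frame_csv <- function(frame, protocol, path) {
  rows <- protocol_rows(protocol)
  inj <- protocol$injections[rows$injection, , drop = FALSE]
  mea <- protocol$measurements[rows$measurement, , drop = FALSE]
  df <- data.frame(injection_a = inj[, 1] - 1L, injection_b = inj[, 2] - 1L,
                   meas_a = mea[, 1] - 1L, meas_b = mea[, 2] - 1L,
                   voltage = frame$values)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @param kind frame kind to restore
#' @export
read_frame_csv <- function(path, protocol, kind = "absolute") {
  df <- read.csv(path)
  eit_frame(df$voltage, protocol, kind = kind)
}

# Brute-force oracle-friendly count of kept measurements per injection.
kept_per_injection <- function(protocol) rowSums(protocol$keep)
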