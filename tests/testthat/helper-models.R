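# Shared small fixtures, built once per test run.

circle_coefficients <- function(radius = 1) {
  list(a = c(radius, rep(0, 8)), b = rep(0, 8))
}

# memoised fixtures: meshing the same small models once keeps the suite fast
.fix <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

disk16_coarse <- function() fixture("disk16_coarse", function() {
  build_contour_model(circle_coefficients(), 16, "coarse")
})
disk16_fine <- function() fixture("disk16_fine", function() {
  build_contour_model(circle_coefficients(), 16, "fine")
})
proto16 <- function() fixture("proto16", function() adjacent_protocol(1, 16))

tank_coarse <- function() fixture("tank_coarse", function() {
  build_tank_model(0.15, 0.3, 4, 8, "coarse")
})
proto_tank <- function() fixture("proto_tank", function() adjacent_protocol(4, 8))

# uniform-conductivity forward solution on the coarse disk, reused widely
disk16_forward <- function() fixture("disk16_forward", function() {
  solve_forward(disk16_coarse(), rep(1, nrow(disk16_coarse()$elements)), proto16())
})

disk16_jacobian <- function() fixture("disk16_jacobian", function() {
  jacobian(disk16_coarse(), rep(1, nrow(disk16_coarse()$elements)), proto16())
})

# synthetic raster helpers: draw an ideal disc indicator directly on a grid
disc_raster <- function(center, radius, G = 64, R = 1, value = 1) {
  xs <- seq(-R, R, length.out = G + 1L); xs <- (xs[-1] + xs[-(G + 1L)]) / 2
  px <- rep(xs, each = G); py <- rep(xs, G)
  inside <- px^2 + py^2 <= R^2
  v <- ifelse((px - center[1])^2 + (py - center[2])^2 <= radius^2, value, 0)
  v[!inside] <- NA
  structure(list(grid = matrix(v, G, G), inside_mask = matrix(inside, G, G),
                 pixel_size = 2 * R / G, cross_section_height = 0,
                 model_radius = R, x = xs, y = xs), class = "eit_raster")
}
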