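# Shared fixtures and independent oracles, built in code at test time.

# polygonal approximation of an ellipse with semi-axes a (x) and b (y)
ellipse_polygon <- function(a, b, n = 720, center = c(0, 0), theta = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(t); y <- b * sin(t)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(cbind(x, y) %*% t(R), 2, center, `+`)
}

# random valid mechanical parameter set (log-uniform over plausible decades)
random_mech <- function() {
  mechanical_params(sigma = 10^runif(1, 0, 1.5),
                    k = 10^runif(1, -1, 0.5),
                    kf = 10^runif(1, 0.5, 1.5),
                    ks = 10^runif(1, -0.5, 0.5),
                    eta_f = 10^runif(1, 0, 1),
                    eta_s = 10^runif(1, 0.5, 1.5))
}

# Independent oracle for the recoil curve: stiff-safe numerical integration
# of the two Kelvin-Voigt force-balance ODEs
#   dxf/dt = (sigma - kf*xf)/eta_f,  dxs/dt = (sigma - ks*xs)/eta_s
# from the pre-ablation initial conditions x_{f,s}(0) = sigma*(1-kappa)/k_{f,s};
# Delta x(t) = xf + xs - (xf(0) + xs(0)).
ode_displacement <- function(times, mech) {
  x0 <- c(xf = mech$sigma * (1 - mech$kappa) / mech$kf,
          xs = mech$sigma * (1 - mech$kappa) / mech$ks)
  deriv <- function(t, x, p) {
    list(c((mech$sigma - mech$kf * x[1]) / mech$eta_f,
           (mech$sigma - mech$ks * x[2]) / mech$eta_s))
  }
  sol <- deSolve::lsoda(x0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  (sol[, "xf"] + sol[, "xs"]) - sum(x0)
}

# Monte-Carlo oracle for the elongation tensor: rejection sampling over the
# polygon bounding box, angles about the sampled-area centroid.
mc_elongation <- function(vertices, n_points = 2e5) {
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  px <- runif(n_points, xr[1], xr[2])
  py <- runif(n_points, yr[1], yr[2])
  inside <- point_in_polygon(px, py, vertices)
  px <- px[inside]; py <- py[inside]
  cx <- mean(px); cy <- mean(py)
  dx <- px - cx; dy <- py - cy
  r2 <- dx^2 + dy^2
  cos2 <- (dx^2 - dy^2) / r2
  sin2 <- 2 * dx * dy / r2
  list(eps_xx = mean(cos2), eps_xy = mean(sin2),
       se_xx = sd(cos2) / sqrt(length(cos2)),
       se_xy = sd(sin2) / sqrt(length(sin2)))
}

# even-odd rule point-in-polygon, vectorised over points
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- (yi > py) != (yj > py) &
      px < (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

paper_range_params <- function() relaxation_params(2.2, 7.0, 0.65, 20)
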