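# Independent oracles and fixtures used across the test files.

# --- flat circular disc mesh (polar rings), for the pressurized-membrane
#     closed-form comparison --------------------------------------------------
disc_mesh <- function(radius, n_rings = 8L) {
  verts <- matrix(c(0, 0, 0), ncol = 3)
  ring_start <- integer(n_rings)
  for (j in seq_len(n_rings)) {
    nj <- 6L * j
    th <- seq(0, 2 * pi, length.out = nj + 1L)[-(nj + 1L)]
    r <- radius * j / n_rings
    ring_start[j] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(r * cos(th), r * sin(th), 0))
  }
  tris <- list()
  # center fan
  n1 <- 6L
  for (k in seq_len(n1)) {
    tris[[length(tris) + 1L]] <- c(1L, ring_start[1] + k - 1L,
                                   ring_start[1] + (k %% n1))
  }
  # ring-to-ring strips: connect each outer-ring vertex to the nearest
  # inner-ring arc
  for (j in seq_len(n_rings - 1L)) {
    ni <- 6L * j; no <- 6L * (j + 1L)
    si <- ring_start[j]; so <- ring_start[j + 1L]
    for (k in 0:(no - 1L)) {
      a <- so + k
      b <- so + ((k + 1L) %% no)
      ii <- floor(k * ni / no)
      tris[[length(tris) + 1L]] <- c(a, b, si + (ii %% ni))
    }
    for (k in 0:(ni - 1L)) {
      a <- si + k
      b <- si + ((k + 1L) %% ni)
      oo <- ceiling((k + 1L) * no / ni)
      tris[[length(tris) + 1L]] <- c(b, a, so + (oo %% no))
    }
  }
  rim <- ring_start[n_rings] + 0:(6L * n_rings - 1L)
  list(vertices = verts, triangles = do.call(rbind, tris), rim = rim)
}

# --- axisymmetric pressurized circular membrane: shooting solution of the
#     finite-deflection (Hencky/Foeppl) membrane equations --------------------
#     vertical (projected-area) pressure p, linear material E, nu, thickness t,
#     clamped rim u(a) = w(a) = 0; returns center deflection w0
hencky_center_deflection <- function(a, p, E, nu, t, n_steps = 4000L) {
  integrate_once <- function(sig0) {
    r0 <- a * 1e-6
    eps0 <- (1 - nu) * sig0 / E
    u <- eps0 * r0
    sig <- sig0
    h <- (a - r0) / n_steps
    r <- r0
    dw_vals <- numeric(n_steps + 1L)
    r_vals <- numeric(n_steps + 1L)
    deriv <- function(r, u, sig) {
      wp <- -p * r / (2 * t * sig)
      eth <- u / r
      # invert sig_r = E/(1-nu^2) (er + nu eth) for the radial strain
      er <- (1 - nu^2) * sig / E - nu * eth
      up <- er - wp^2 / 2
      sth <- E / (1 - nu^2) * (eth + nu * er)
      sigp <- (sth - sig) / r
      c(up, sigp, wp)
    }
    for (i in 0:n_steps) {
      r_vals[i + 1L] <- r
      dw_vals[i + 1L] <- deriv(r, u, sig)[3]
      if (i == n_steps) break
      k1 <- deriv(r, u, sig)
      k2 <- deriv(r + h / 2, u + h / 2 * k1[1], sig + h / 2 * k1[2])
      k3 <- deriv(r + h / 2, u + h / 2 * k2[1], sig + h / 2 * k2[2])
      k4 <- deriv(r + h, u + h * k3[1], sig + h * k3[2])
      u <- u + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      sig <- sig + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      r <- r + h
    }
    list(u_a = u, w0 = -pracma::trapz(r_vals, dw_vals))
  }
  # shoot on the center radial stress so that u(a) = 0
  f <- function(s0) integrate_once(s0)$u_a
  lo <- 1e-6 * E; hi <- E
  while (f(hi) < 0) hi <- hi * 2
  s0 <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  integrate_once(s0)$w0
}

# --- one-way ANOVA from summary statistics (means, SDs, ns) ------------------
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# --- shared small structural solve, computed once per test run ---------------
cached_solve <- local({
  cache <- new.env()
  function(label = "G6", oversizing = 10, seed = 7) {
    key <- paste(label, oversizing, seed, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    mesh <- assemble_valve(valve_designs()[[label]], n_circ = 16L,
                           n_rad = 10L, scale = 0.5)
    lc <- crimp_loadcase(oversizing = oversizing, pressure_mmHg = 20,
                         scale_factor = 0.5, seed = seed)
    st <- solve_static(mesh, pericardium_material(), lc)
    cache[[key]] <- st
    st
  }
})
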