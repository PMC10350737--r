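# Structured-mesh 2D plane-stress finite-element solver.
#
# Total-Lagrangian formulation on 4-node quadrilaterals.  Plane stress is
# enforced pointwise by solving the zero out-of-plane-stress condition for
# the out-of-plane stretch at every integration point; near-incompressibility
# of the hyperelastic laws by a volumetric penalty on J = det F.  The
# consistent tangent is computed by forward differencing of the plane-stress
# first Piola stress, and each load increment is solved by a damped Newton
# iteration with adaptive increment cutbacks.
#
# Units: lengths mm, stresses MPa, forces N per mm out-of-plane thickness.

#' Build a structured quadrilateral mesh of the specimen section
#'
#' Rectangular domain (width x height, mm) discretised into an `n_x` by `n_y`
#' grid of 4-node quadrilaterals with counter-clockwise connectivity, where
#' each axis count is the nearest integer to extent / element size.  The
#' reference geometry (8 mm wide, 1.305 mm mean thickness) gives 4160, 1040
#' and 280 elements at 50, 100 and 200 µm element sizes respectively.
#'
#' @param width Domain width, mm (> 0; default 8).
#' @param height Domain height (cartilage thickness), mm (> 0; default 1.305).
#' @param element_size Target element edge length, µm (> 0).
#' @return An object of class `"fe_mesh"`: node coordinates (mm), element
#'   connectivity, axis counts and boundary node indices.
#' @examples
#' build_mesh(8, 1.305, 200)  # 280 elements
#' @export
build_mesh <- function(width = 8, height = 1.305, element_size = 100) {
  stopifnot(width > 0, height > 0, element_size > 0)
  es_mm <- element_size / 1000
  n_x <- as.integer(round(width / es_mm)); n_y <- as.integer(round(height / es_mm))
  if (n_x < 1 || n_y < 1)
    stop("element_size too coarse: a mesh axis would have zero elements")
  xs <- seq(0, width, length.out = n_x + 1)
  ys <- seq(0, height, length.out = n_y + 1)
  nodes <- cbind(x = rep(xs, times = n_y + 1), y = rep(ys, each = n_x + 1))
  nid <- function(i, j) (j - 1L) * (n_x + 1L) + i        # i along x, j along y
  i <- rep(seq_len(n_x), times = n_y); j <- rep(seq_len(n_y), each = n_x)
  elems <- cbind(nid(i, j), nid(i + 1L, j), nid(i + 1L, j + 1L), nid(i, j + 1L))
  top <- nid(seq_len(n_x + 1L), n_y + 1L)
  base <- nid(seq_len(n_x + 1L), 1L)
  structure(list(
    nodes = nodes, elems = elems, n_x = n_x, n_y = n_y,
    width = width, height = height, element_size = element_size,
    top_nodes = top, base_nodes = base,
    top_centre_node = top[which.min(abs(xs - width / 2))]),
    class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe mesh> %g x %g mm, %d x %d = %d elements (~%g um), %d nodes\n",
              x$width, x$height, x$n_x, x$n_y, x$n_x * x$n_y, x$element_size,
              nrow(x$nodes)))
  invisible(x)
}

#' Finite-element solver options
#'
#' @param n_incr_ramp,n_incr_cyclic Load increments per protocol step
#'   (defaults 20 and 40; the cyclic count keeps the cycle extremes on the
#'   increment grid).
#' @param tol_rel Newton convergence tolerance: residual norm relative to the
#'   applied load norm (default 1e-8).
#' @param max_iter Newton iterations per increment before a cutback.
#' @param max_cutbacks Maximum adaptive halvings of an increment (default 4).
#' @param penalty_factor Volumetric penalty: bulk modulus
#'   `kappa = penalty_factor * mu_ref` where `mu_ref` is `sum(|mu_i|)` for
#'   Ogden materials and the initial shear modulus otherwise (default 1000).
#' @param integration `"full"` (2x2 Gauss, default) or `"reduced"` (1-point
#'   with hourglass stabilisation, mirroring the reduced-integration
#'   plane-stress quad of general-purpose FE codes).
#' @param store_field Keep the final nodal displacement field (default TRUE).
#' @return A list of class `"fe_options"`.
#' @export
fe_options <- function(n_incr_ramp = 20, n_incr_cyclic = 40, tol_rel = 1e-8,
                       max_iter = 30, max_cutbacks = 4, penalty_factor = 1000,
                       integration = c("full", "reduced"), store_field = TRUE) {
  integration <- match.arg(integration)
  structure(list(n_incr_ramp = n_incr_ramp, n_incr_cyclic = n_incr_cyclic,
                 tol_rel = tol_rel, max_iter = max_iter,
                 max_cutbacks = max_cutbacks, penalty_factor = penalty_factor,
                 integration = integration, store_field = store_field),
            class = "fe_options")
}

# ---- material point: plane-stress first Piola stress -----------------------

# Derivative of the deviatoric strain energy with respect to the isochoric
# principal stretch, vectorised over states.
dWdev_dlbar <- function(material, lbar) {
  if (inherits(material, "neo_hookean_material")) {
    c10 <- if (material$convention == "standard_c10") material$c10 else material$c10 / 2
    2 * c10 * lbar
  } else {
    out <- 0
    for (k in seq_along(material$mu))
      out <- out + 2 * material$mu[k] / material$alpha[k] * lbar^(material$alpha[k] - 1)
    out
  }
}

penalty_mu_ref <- function(material) {
  if (inherits(material, "ogden_material")) sum(abs(material$mu))
  else initial_shear_modulus(material)
}

# dW/dlambda_a for the penalty-compressible form
# W = W_dev(J^{-1/3} lambda) + kappa/2 (J-1)^2, vectorised over states.
# l1, l2, l3 are vectors; returns list of three derivative vectors plus J.
dW_dl <- function(material, l1, l2, l3, kappa) {
  J <- l1 * l2 * l3
  Jm13 <- J^(-1 / 3)
  lb1 <- Jm13 * l1; lb2 <- Jm13 * l2; lb3 <- Jm13 * l3
  w1 <- dWdev_dlbar(material, lb1)
  w2 <- dWdev_dlbar(material, lb2)
  w3 <- dWdev_dlbar(material, lb3)
  common <- -(w1 * lb1 + w2 * lb2 + w3 * lb3) / 3 + kappa * (J - 1) * J
  list(d1 = (w1 * lb1 + common) / l1,
       d2 = (w2 * lb2 + common) / l2,
       d3 = (w3 * lb3 + common) / l3, J = J)
}

# Solve the plane-stress condition dW/dlambda3 = 0 for lambda3, vectorised.
solve_lambda3 <- function(material, l1, l2, kappa, l3 = NULL) {
  if (is.null(l3) || length(l3) != length(l1)) l3 <- 1 / (l1 * l2)
  for (it in 1:60) {
    g <- dW_dl(material, l1, l2, l3, kappa)$d3
    if (max(abs(g)) < 1e-14 * kappa) break
    h <- 1e-7 * l3
    gp <- (dW_dl(material, l1, l2, l3 + h, kappa)$d3 - g) / h
    step <- g / gp
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -0.4 * l3), 0.4 * l3)   # keep lambda3 positive
    l3 <- l3 - step
  }
  l3
}

# Plane-stress first Piola stress for a batch of in-plane deformation
# gradients (components as vectors).  Returns P components, the solved
# lambda3, and a validity flag (FALSE on locally inverted states).
ps_stress <- function(material, F11, F12, F21, F22, kappa, l3_guess = NULL) {
  C11 <- F11^2 + F21^2
  C22 <- F12^2 + F22^2
  C12 <- F11 * F12 + F21 * F22
  detF <- F11 * F22 - F12 * F21
  m <- (C11 + C22) / 2
  r <- sqrt(pmax(((C11 - C22) / 2)^2 + C12^2, 0))
  c1 <- m + r; c2 <- m - r
  ok <- is.finite(detF) & detF > 1e-8 & c2 > 1e-10
  if (!all(ok)) {
    bad <- !ok
    c1[bad] <- 1; c2[bad] <- 1; detF[bad] <- 1
  }
  l1 <- sqrt(c1); l2 <- sqrt(c2)
  l3 <- solve_lambda3(material, l1, l2, kappa, l3_guess)
  d <- dW_dl(material, l1, l2, l3, kappa)
  b1 <- d$d1 / l1; b2 <- d$d2 / l2       # principal 2nd Piola values
  # S = q (C - c2 I) + b2 I with q = (b1 - b2)/(c1 - c2); isotropic limit
  dc <- c1 - c2
  iso <- dc < 1e-10 * (c1 + c2)
  q <- ifelse(iso, 0, (b1 - b2) / ifelse(iso, 1, dc))
  bbar <- (b1 + b2) / 2
  S11 <- ifelse(iso, bbar, q * (C11 - c2) + b2)
  S22 <- ifelse(iso, bbar, q * (C22 - c2) + b2)
  S12 <- ifelse(iso, 0, q * C12)
  list(P11 = F11 * S11 + F12 * S12, P12 = F11 * S12 + F12 * S22,
       P21 = F21 * S11 + F22 * S12, P22 = F21 * S12 + F22 * S22,
       l3 = l3, ok = ok)
}

# ---- assembly --------------------------------------------------------------

# Precompute integration-point data for a mesh: per-gp reference shape
# gradients, weights, element/dof bookkeeping.
fe_precompute <- function(mesh, integration) {
  gp1 <- 1 / sqrt(3)
  gauss <- if (integration == "full")
    cbind(xi = c(-gp1, gp1, gp1, -gp1), eta = c(-gp1, -gp1, gp1, gp1), w = 2 / 2)
  else cbind(xi = 0, eta = 0, w = 4 / 2)   # weight folded below
  w_gp <- if (integration == "full") rep(1, 4) else 4
  ne <- nrow(mesh$elems); ngp_e <- nrow(gauss)
  ngp <- ne * ngp_e
  dNdX <- array(0, c(ngp, 4, 2)); wdet <- numeric(ngp)
  idx <- matrix(0L, ngp, 4)
  for (g in seq_len(ngp_e)) {
    xi <- gauss[g, 1]; eta <- gauss[g, 2]
    dNdxi <- matrix(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta),
                      -(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4, 4, 2)
    rows <- (g - 1L) * ne + seq_len(ne)
    for (e in seq_len(ne)) {
      X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE]
      J <- t(X) %*% dNdxi
      dJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      if (dJ <= 0) stop("non-positive element Jacobian")
      dNdX[rows[e], , ] <- dNdxi %*% solve(J)
      wdet[rows[e]] <- w_gp[g] * dJ
    }
    idx[rows, ] <- mesh$elems
  }
  # dof indices (x = 2n-1, y = 2n) per gp and element-local dof (node, comp)
  dofs <- matrix(0L, ngp, 8)
  for (i in 1:4) {
    dofs[, 2 * i - 1] <- 2L * idx[, i] - 1L
    dofs[, 2 * i] <- 2L * idx[, i]
  }
  # element id of each gp row, for aggregating K triplets per element
  list(dNdX = dNdX, wdet = wdet, idx = idx, dofs = dofs, ngp = ngp, ne = ne,
       ngp_e = ngp_e,
       Krow = as.vector(dofs[, rep(1:8, times = 8)]),
       Kcol = as.vector(dofs[, rep(1:8, each = 8)]))
}

# Deformation gradient components at every gp from the nodal displacement
# matrix U (n_nodes x 2).
fe_defgrad <- function(pre, U) {
  F11 <- rep(1, pre$ngp); F12 <- rep(0, pre$ngp)
  F21 <- rep(0, pre$ngp); F22 <- rep(1, pre$ngp)
  for (i in 1:4) {
    u1 <- U[pre$idx[, i], 1]; u2 <- U[pre$idx[, i], 2]
    F11 <- F11 + u1 * pre$dNdX[, i, 1]
    F12 <- F12 + u1 * pre$dNdX[, i, 2]
    F21 <- F21 + u2 * pre$dNdX[, i, 1]
    F22 <- F22 + u2 * pre$dNdX[, i, 2]
  }
  list(F11 = F11, F12 = F12, F21 = F21, F22 = F22)
}

# Internal force vector from gp stresses.
fe_internal_force <- function(pre, P, ndof) {
  fv <- matrix(0, pre$ngp, 8)
  Pm <- list(cbind(P$P11, P$P12), cbind(P$P21, P$P22))
  for (i in 1:4) for (jc in 1:2) {
    fv[, 2 * (i - 1) + jc] <- pre$wdet *
      (Pm[[jc]][, 1] * pre$dNdX[, i, 1] + Pm[[jc]][, 2] * pre$dNdX[, i, 2])
  }
  rs <- rowsum(c(fv), group = c(pre$dofs))      # sorted by dof index
  f <- numeric(ndof)
  f[as.integer(rownames(rs))] <- rs[, 1]
  f
}

# Tangent stiffness by forward differencing of the plane-stress stress.
fe_tangent <- function(material, pre, Fc, kappa, l3, ndof) {
  P0 <- ps_stress(material, Fc$F11, Fc$F12, Fc$F21, Fc$F22, kappa, l3)
  h <- 1e-6
  comp <- c("F11", "F12", "F21", "F22")
  A <- array(0, c(pre$ngp, 4, 4))          # A[, p, q] = dP_p / dF_q
  for (q in 1:4) {
    Fp <- Fc; Fp[[comp[q]]] <- Fp[[comp[q]]] + h
    Pq <- ps_stress(material, Fp$F11, Fp$F12, Fp$F21, Fp$F22, kappa, P0$l3)
    A[, 1, q] <- (Pq$P11 - P0$P11) / h
    A[, 2, q] <- (Pq$P12 - P0$P12) / h
    A[, 3, q] <- (Pq$P21 - P0$P21) / h
    A[, 4, q] <- (Pq$P22 - P0$P22) / h
  }
  # P index p = (jc, k): 1=(1,1), 2=(1,2), 3=(2,1), 4=(2,2); same for q=(nc,l)
  pidx <- function(jc, k) 2L * (jc - 1L) + k
  Kv <- array(0, c(pre$ngp, 8, 8))
  for (i in 1:4) for (jc in 1:2) for (m in 1:4) for (nc in 1:2) {
    acc <- 0
    for (k in 1:2) for (l in 1:2) {
      acc <- acc + A[, pidx(jc, k), pidx(nc, l)] *
        pre$dNdX[, i, k] * pre$dNdX[, m, l]
    }
    Kv[, 2 * (i - 1) + jc, 2 * (m - 1) + nc] <- acc * pre$wdet
  }
  Matrix::sparseMatrix(i = pre$Krow, j = pre$Kcol, x = as.vector(Kv),
                       dims = c(ndof, ndof))
}

# Small-strain plane-stress stiffness for the linear elastic material
# (geometrically linear: the response is exactly proportional to the load).
fe_linear_stiffness <- function(material, pre, ndof) {
  E <- material$youngs_modulus; nu <- material$poisson_ratio
  Eb <- E / (1 - nu^2); G <- E / (2 * (1 + nu))
  A <- array(0, c(4, 4))                   # dsigma_p/dgrad-u_q, p=(j,k)
  pidx <- function(jc, k) 2L * (jc - 1L) + k
  A[pidx(1, 1), pidx(1, 1)] <- Eb;        A[pidx(1, 1), pidx(2, 2)] <- nu * Eb
  A[pidx(2, 2), pidx(2, 2)] <- Eb;        A[pidx(2, 2), pidx(1, 1)] <- nu * Eb
  A[pidx(1, 2), pidx(1, 2)] <- G;         A[pidx(1, 2), pidx(2, 1)] <- G
  A[pidx(2, 1), pidx(1, 2)] <- G;         A[pidx(2, 1), pidx(2, 1)] <- G
  Kv <- array(0, c(pre$ngp, 8, 8))
  for (i in 1:4) for (jc in 1:2) for (m in 1:4) for (nc in 1:2) {
    acc <- 0
    for (k in 1:2) for (l in 1:2) {
      if (A[pidx(jc, k), pidx(nc, l)] != 0)
        acc <- acc + A[pidx(jc, k), pidx(nc, l)] *
          pre$dNdX[, i, k] * pre$dNdX[, m, l]
    }
    Kv[, 2 * (i - 1) + jc, 2 * (m - 1) + nc] <- acc * pre$wdet
  }
  Matrix::sparseMatrix(i = pre$Krow, j = pre$Kcol, x = as.vector(Kv),
                       dims = c(ndof, ndof))
}

# Hourglass stabilisation stiffness for 1-point integration: penalises the
# two hourglass modes of each (rectangular) element with a small artificial
# stiffness proportional to the material shear modulus.
fe_hourglass_stiffness <- function(material, mesh, ndof, coef = 0.01) {
  hvec <- c(1, -1, 1, -1)
  mu <- penalty_mu_ref(material)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  area <- (mesh$width / mesh$n_x) * (mesh$height / mesh$n_y)
  k_hg <- coef * mu * area
  for (e in seq_len(nrow(mesh$elems))) {
    nd <- mesh$elems[e, ]
    for (jc in 1:2) {
      dofv <- 2L * nd - 2L + jc
      ii <- c(ii, rep(dofv, each = 4)); jj <- c(jj, rep(dofv, times = 4))
      xx <- c(xx, k_hg * as.vector(outer(hvec, hvec)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}

fe_boundary <- function(mesh, bc) {
  ndof <- 2L * nrow(mesh$nodes)
  fixed <- logical(ndof)
  if (bc == "platen") {
    fixed[2L * mesh$base_nodes - 1L] <- TRUE    # base: both components
    fixed[2L * mesh$base_nodes] <- TRUE
    fixed[2L * mesh$top_nodes - 1L] <- TRUE     # top: horizontal only
  } else if (bc == "frictionless") {
    fixed[2L * mesh$base_nodes] <- TRUE         # base: vertical only
    mid <- mesh$base_nodes[which.min(abs(mesh$nodes[mesh$base_nodes, 1] -
                                           mesh$width / 2))]
    fixed[2L * mid - 1L] <- TRUE                # pin one node horizontally
  } else stop("unknown bc: ", bc)
  fixed
}

# Consistent nodal loads for uniform (nominal, dead) pressure on the top
# reference edge, pointing in -y.  Per unit out-of-plane thickness.
fe_pressure_load <- function(mesh, ndof) {
  f <- numeric(ndof)
  le <- mesh$width / mesh$n_x
  f[2L * mesh$top_nodes] <- -le
  f[2L * mesh$top_nodes[c(1L, length(mesh$top_nodes))]] <- -le / 2
  f                                          # multiply by pressure (MPa)
}

#' Plane-stress finite-element protocol simulation
#'
#' Runs the two-step loading protocol on a structured mesh of the specimen
#' section.  Boundary conditions `"platen"` reproduce the compression test
#' set-up: the base fully fixed, the top surface restricted to vertical
#' motion, and uniform nominal pressure applied to the top edge.  The
#' `"frictionless"` variant (vertical-only base support, laterally free top)
#' realises a homogeneous uniaxial-stress state and is used for verification
#' against the closed-form solution.
#'
#' The reported trace follows the vertical displacement of the central
#' top-surface node, as a positive compression magnitude in µm.
#'
#' @param model A `cartilage_material`.
#' @param mesh A [build_mesh()] result.
#' @param protocol A [loading_protocol()].
#' @param bc `"platen"` (default) or `"frictionless"`.
#' @param options An [fe_options()] list.
#' @param steps `"both"` (default) or `"ramp"` to stop at the end of the
#'   ramp (used by mesh-convergence studies).
#' @return An object of class `"fe_solution"`: the [solution_trace()]
#'   (`$trace`), convergence diagnostics per increment (`$diagnostics`:
#'   iterations, residual norms, base reaction sums), and the final nodal
#'   displacement field (`$U`, mm).
#' @section Failures: Newton non-convergence after the allowed cutbacks
#'   signals a condition of class `"cartdyn_stability_error"` carrying the
#'   last converged time.
#' @export
fe_simulate <- function(model, mesh = build_mesh(), protocol = loading_protocol(),
                        bc = c("platen", "frictionless"),
                        options = fe_options(), steps = c("both", "ramp")) {
  bc <- match.arg(bc); steps <- match.arg(steps)
  stopifnot(inherits(model, "cartilage_material"), inherits(mesh, "fe_mesh"))
  ndof <- 2L * nrow(mesh$nodes)
  pre <- fe_precompute(mesh, options$integration)
  fixed <- fe_boundary(mesh, bc)
  free <- which(!fixed)
  fp <- fe_pressure_load(mesh, ndof)

  # increment time grid
  t_ramp <- seq(0, protocol$ramp_duration, length.out = options$n_incr_ramp + 1)[-1]
  t_cyc <- if (steps == "both")
    protocol$ramp_duration + protocol$cyclic_duration *
      seq_len(options$n_incr_cyclic) / options$n_incr_cyclic else numeric(0)
  times <- c(t_ramp, t_cyc)
  press <- pressure_at(times, protocol)

  if (inherits(model, "elastic_material")) {
    K <- fe_linear_stiffness(model, pre, ndof)
    if (options$integration == "reduced")
      K <- K + fe_hourglass_stiffness(model, mesh, ndof)
    Kff <- K[free, free]
    u1 <- numeric(ndof)
    u1[free] <- as.numeric(Matrix::solve(Kff, fp[free]))  # unit pressure
    disp <- -1000 * u1[2L * mesh$top_centre_node] * press
    U <- matrix(u1, ncol = 2, byrow = TRUE) * press[length(press)]
    diag_df <- data.frame(time_s = times, iterations = 1L, residual = 0,
                          reaction_sum = press * mesh$width)
    trace <- solution_trace(c(0, times), c(0, press), c(0, disp),
                            c("ramp", ifelse(times <= protocol$ramp_duration,
                                             "ramp", "cyclic")),
                            thickness_mm = mesh$height,
                            frequency_Hz = protocol$frequency,
                            label = paste0(model$label, "/fe-", bc))
    return(structure(list(trace = trace, diagnostics = diag_df,
                          U = if (options$store_field) U else NULL,
                          mesh = mesh, converged = TRUE),
                     class = "fe_solution"))
  }

  kappa <- options$penalty_factor * penalty_mu_ref(model)
  Khg <- if (options$integration == "reduced")
    fe_hourglass_stiffness(model, mesh, ndof) else NULL
  U <- matrix(0, nrow(mesh$nodes), 2)
  l3_env <- new.env(parent = emptyenv()); l3_env$l3 <- NULL
  resid_fun <- function(U, p) {
    Fc <- fe_defgrad(pre, U)
    P <- ps_stress(model, Fc$F11, Fc$F12, Fc$F21, Fc$F22, kappa, l3_env$l3)
    if (!all(P$ok)) return(list(ok = FALSE))
    fi <- fe_internal_force(pre, P, ndof)
    if (!is.null(Khg)) fi <- fi + as.numeric(Khg %*% as.vector(t(U)))
    list(ok = TRUE, r = fi - p * fp, Fc = Fc, l3 = P$l3, fint = fi)
  }
  tangent_fun <- function(Fc, l3) {
    K <- fe_tangent(model, pre, Fc, kappa, l3, ndof)
    if (!is.null(Khg)) K <- K + Khg
    K
  }
  # tolerance referenced to the full applied load norm of the protocol
  tol_abs <- options$tol_rel * max(press) * sqrt(sum(fp[free]^2))
  disp <- numeric(length(times)); iters <- integer(length(times))
  resid <- numeric(length(times)); react <- numeric(length(times))
  rs_last <- NULL
  p_prev <- 0
  for (n in seq_along(times)) {
    p_target <- press[n]
    p_now <- p_prev
    dp <- p_target - p_prev
    cutbacks <- 0
    while (abs(p_target - p_now) > 1e-14) {
      p_try <- if (dp >= 0) min(p_now + dp, p_target) else max(p_now + dp, p_target)
      st <- fe_newton(resid_fun, tangent_fun, U, p_try, free, fp, options,
                      tol_abs)
      if (st$converged) {
        U <- st$U; l3_env$l3 <- st$l3; p_now <- p_try
        iters[n] <- iters[n] + st$iterations; resid[n] <- st$residual
        rs_last <- st$rs
      } else {
        cutbacks <- cutbacks + 1
        if (cutbacks > options$max_cutbacks)
          stop(stability_error(
            sprintf("FE Newton failed to converge at p = %.4g MPa (t = %.3f s); last converged p = %.4g MPa",
                    p_try, times[n], p_now),
            max_pressure = p_now,
            time_s = if (n > 1) times[n - 1] else 0))
        dp <- dp / 2
      }
    }
    p_prev <- p_target
    disp[n] <- -1000 * U[mesh$top_centre_node, 2]
    react[n] <- sum(rs_last$fint[2L * mesh$base_nodes])
  }
  step_lab <- ifelse(times <= protocol$ramp_duration, "ramp", "cyclic")
  trace <- solution_trace(c(0, times), c(0, press), c(0, disp),
                          c("ramp", step_lab), thickness_mm = mesh$height,
                          frequency_Hz = protocol$frequency,
                          label = paste0(model$label, "/fe-", bc))
  structure(list(trace = trace,
                 diagnostics = data.frame(time_s = times, iterations = iters,
                                          residual = resid, reaction_sum = react),
                 U = if (options$store_field) U else NULL,
                 mesh = mesh, converged = TRUE),
            class = "fe_solution")
}

# One damped Newton solve at fixed load level.
fe_newton <- function(resid_fun, tangent_fun, U, p, free, fp, options,
                      tol_abs = 0) {
  ndof <- length(fp)
  f_norm <- sqrt(sum((p * fp[free])^2))
  tol <- max(options$tol_rel * f_norm, tol_abs, 1e-14)
  rs <- resid_fun(U, p)
  if (!rs$ok) return(list(converged = FALSE))
  rnorm <- sqrt(sum(rs$r[free]^2))
  for (it in seq_len(options$max_iter)) {
    if (rnorm <= tol)
      return(list(converged = TRUE, U = U, l3 = rs$l3, iterations = it - 1L,
                  residual = rnorm, rs = rs))
    K <- tangent_fun(rs$Fc, rs$l3)
    du <- numeric(ndof)
    du[free] <- tryCatch(as.numeric(Matrix::solve(K[free, free], -rs$r[free])),
                         error = function(e) rep(NA_real_, length(free)))
    if (any(!is.finite(du))) return(list(converged = FALSE))
    dU <- matrix(du, ncol = 2, byrow = TRUE)
    step <- 1; accepted <- FALSE
    for (ls in 1:20) {
      U_try <- U + step * dU
      rs_try <- resid_fun(U_try, p)
      if (rs_try$ok) {
        r_try <- sqrt(sum(rs_try$r[free]^2))
        if (is.finite(r_try) && (r_try < rnorm || r_try <= tol)) {
          U <- U_try; rs <- rs_try; rnorm <- r_try; accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) return(list(converged = FALSE))
  }
  if (rnorm <= tol)
    list(converged = TRUE, U = U, l3 = rs$l3, iterations = options$max_iter,
         residual = rnorm, rs = rs)
  else list(converged = FALSE)
}

#' @export
print.fe_solution <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<fe solution> %d increments, end displacement %.3f um, max residual %.3g\n",
              nrow(d), x$trace$displacement_um[nrow(x$trace)], max(d$residual)))
  invisible(x)
}

#' Mesh convergence study
#'
#' Runs the ramp step of the protocol at a series of element sizes and
#' tabulates the end-of-ramp top-centre displacement and its successive
#' relative change.
#'
#' @param model A `cartilage_material`.
#' @param protocol A [loading_protocol()].
#' @param element_sizes Element sizes to test, µm.
#' @param width,height Domain size, mm.
#' @param ... Passed to [fe_simulate()] (e.g. `options`).
#' @return Data frame with columns `element_size_um`, `n_elements`,
#'   `ramp_displacement_um`, `rel_change` (NA in the first row).
#' @export
mesh_convergence <- function(model, protocol = loading_protocol(),
                             element_sizes = c(200, 100, 50),
                             width = 8, height = 1.305, ...) {
  stopifnot(length(element_sizes) >= 1)
  rows <- lapply(element_sizes, function(es) {
    mesh <- build_mesh(width, height, es)
    sol <- fe_simulate(model, mesh, protocol, steps = "ramp", ...)
    data.frame(element_size_um = es, n_elements = mesh$n_x * mesh$n_y,
               ramp_displacement_um = ramp_compression(sol$trace))
  })
  out <- do.call(rbind, rows)
  out$rel_change <- c(NA, abs(diff(out$ramp_displacement_um)) /
                        utils::head(out$ramp_displacement_um, -1))
  out
}

#' Deformed-configuration element quality checks
#'
#' Flags elements whose deformed shape has a corner angle below 10 or above
#' 170 degrees (skewness) or an edge aspect ratio above 10, the warning
#' thresholds monitored during the reference simulations.
#'
#' @param mesh A [build_mesh()] result.
#' @param U Nodal displacement field, mm (`n_nodes x 2`); zero if omitted.
#' @return Data frame with columns `element`, `type` (`"skewness"` or
#'   `"aspect_ratio"`), `value` (degrees or ratio); zero rows when clean.
#' @export
check_element_quality <- function(mesh, U = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (is.null(U)) U <- matrix(0, nrow(mesh$nodes), 2)
  xy <- mesh$nodes + U
  out <- list()
  for (e in seq_len(nrow(mesh$elems))) {
    P <- xy[mesh$elems[e, ], , drop = FALSE]
    ang <- numeric(4); len <- numeric(4)
    for (k in 1:4) {
      prev <- P[(k - 2) %% 4 + 1, ]; here <- P[k, ]; nxt <- P[k %% 4 + 1, ]
      v1 <- prev - here; v2 <- nxt - here
      len[k] <- sqrt(sum(v2^2))              # edge k -> k+1
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang[k] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    if (any(ang < 10 | ang > 170))
      out[[length(out) + 1]] <- data.frame(element = e, type = "skewness",
                                           value = ang[which.max(abs(ang - 90))])
    ar <- max(len) / min(len)
    if (ar > 10)
      out[[length(out) + 1]] <- data.frame(element = e, type = "aspect_ratio",
                                           value = ar)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(element = integer(0), type = character(0), value = numeric(0))
}

#' Export a mesh and displacement field as legacy ASCII VTK
#'
#' Writes an unstructured-grid legacy VTK file with the displacement field as
#' point data, for visualisation in standard tools.
#'
#' @param mesh A [build_mesh()] result.
#' @param file Output path.
#' @param U Optional nodal displacement field (mm).
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, U = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cartdyn mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, ne * 5), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L, mesh$elems[, 2] - 1L,
                     mesh$elems[, 3] - 1L, mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)
  if (!is.null(U)) {
    writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS displacement double"), con)
    writeLines(sprintf("%.9g %.9g 0", U[, 1], U[, 2]), con)
  }
  invisible(file)
}
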