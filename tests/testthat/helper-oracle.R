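# Independent steady-state oracle: solves the same continuum model on a
# dense grid by assembling the stationary balance equations directly into
# a full linear system (no time stepping, no shared assembly code with the
# package). Used to validate the package's discretization and solver.
oracle_steady_surface <- function(C_blood_nmoll, u_sweat_n, p,
                                  n_isf = 240L, n_sg = 320L) {
  Cb <- C_blood_nmoll * 1e-6                  # mol m^-3
  Q <- p$L_pc * p$A_c * (p$P_c - p$P_ISF)     # Starling filtration
  uI <- Q / p$A_ISF
  ug <- Q * u_sweat_n / p$A_sg
  ugn <- ug / p$u_passive
  dil <- 1 / (1 + p$K_wc * ugn)
  # wall entry balance: wall influx equals advective carry into the duct
  beta <- ug * p$h_sg * dil / p$D_sg_wall
  entry <- dil / (1 + beta)
  wall <- (p$D_sg_wall / p$h_sg) * beta / (1 + beta)

  src <- p$k_DE * p$V_p / p$V_ISF
  dyI <- p$L_ISF / (n_isf - 1)
  dyG <- p$L_sg / (n_sg - 1)
  n <- n_isf + (n_sg - 1L)
  M <- matrix(0, n, n)
  b <- numeric(n)

  addI <- function(i, j, v) M[i, j] <<- M[i, j] + v
  # ISF nodes 1..n_isf: 0 = src (aCb - C) + diffusion + upwind advection
  for (i in 1:n_isf) {
    addI(i, i, -src)
    b[i] <- b[i] - src * p$alpha * Cb
    # diffusion, zero-flux ends
    if (i > 1) { addI(i, i - 1, p$D_ISF / dyI^2); addI(i, i, -p$D_ISF / dyI^2) }
    if (i < n_isf) { addI(i, i + 1, p$D_ISF / dyI^2); addI(i, i, -p$D_ISF / dyI^2) }
    # advection: solute-free inflow, reflecting outlet
    if (i < n_isf) addI(i, i, -uI / dyI)
    if (i > 1) addI(i, i - 1, uI / dyI)
  }
  # wall exchange sink at ISF outlet node
  addI(n_isf, n_isf, -wall * p$A_sg / (p$A_ISF * dyI))

  # duct nodes 2..n_sg (node 1 is the Dirichlet entry, entry * C[n_isf])
  gidx <- function(j) n_isf + (j - 1L)  # duct node j (j >= 2)
  for (j in 2:n_sg) {
    i <- gidx(j)
    left <- if (j == 2) NULL else gidx(j - 1L)
    # diffusion with zero-flux outlet ghost
    if (j < n_sg) {
      addI(i, gidx(j + 1L), p$D_sg / dyG^2)
      addI(i, i, -p$D_sg / dyG^2)
    }
    addI(i, i, -p$D_sg / dyG^2)
    if (is.null(left)) addI(i, n_isf, entry * p$D_sg / dyG^2)
    else addI(i, left, p$D_sg / dyG^2)
    # upwind advection from the entry side
    addI(i, i, -ug / dyG)
    if (is.null(left)) addI(i, n_isf, entry * ug / dyG)
    else addI(i, left, ug / dyG)
    # enzymatic sink
    addI(i, i, -p$S_enzyme)
  }
  x <- solve(M, b)
  1e6 * x[n]                                  # surface value in nmol/L
}
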