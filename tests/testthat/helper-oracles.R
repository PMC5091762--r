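# Independent reference implementations used as oracles.  They share no
# code with the package internals they check.

# queue-based flood fill, 8-connectivity
flood_fill_labels <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!grid[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            grid[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# total spring energy of a network at nodal displacement u (2n vector),
# small-strain axial law; used for brute-force energy minimization
network_energy <- function(network, k_eff, u) {
  s <- network$springs
  ux <- u[2 * seq_len(network$n_nodes) - 1]
  uy <- u[2 * seq_len(network$n_nodes)]
  dx <- (network$nodes[s$j, 1] - network$nodes[s$i, 1]) / s$rest
  dy <- (network$nodes[s$j, 2] - network$nodes[s$i, 2]) / s$rest
  e <- (ux[s$j] - ux[s$i]) * dx + (uy[s$j] - uy[s$i]) * dy
  sum(0.5 * k_eff * e^2)
}

# minimize total energy over free dofs with prescribed values on the rest
minimize_energy <- function(network, k_eff, cons, u_cons) {
  n_dof <- 2L * network$n_nodes
  free <- setdiff(seq_len(n_dof), cons)
  u0 <- numeric(n_dof); u0[cons] <- u_cons
  obj <- function(uf) {
    u <- u0; u[free] <- uf
    network_energy(network, k_eff, u)
  }
  grad <- function(uf) {
    u <- u0; u[free] <- uf
    s <- network$springs
    dx <- (network$nodes[s$j, 1] - network$nodes[s$i, 1]) / s$rest
    dy <- (network$nodes[s$j, 2] - network$nodes[s$i, 2]) / s$rest
    ux <- u[2 * seq_len(network$n_nodes) - 1]
    uy <- u[2 * seq_len(network$n_nodes)]
    e <- (ux[s$j] - ux[s$i]) * dx + (uy[s$j] - uy[s$i]) * dy
    f <- k_eff * e
    g <- numeric(n_dof)
    for (sp in seq_len(nrow(s))) {
      i <- s$i[sp]; j <- s$j[sp]
      g[2 * i - 1] <- g[2 * i - 1] - f[sp] * dx[sp]
      g[2 * i] <- g[2 * i] - f[sp] * dy[sp]
      g[2 * j - 1] <- g[2 * j - 1] + f[sp] * dx[sp]
      g[2 * j] <- g[2 * j] + f[sp] * dy[sp]
    }
    g[free]
  }
  fit <- stats::optim(u0[free], obj, grad, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
  u <- u0; u[free] <- fit$par
  u
}

# direct evaluation of the two-phase shear-modulus bounds, written
# independently of the package formulas
hs_reference <- function(G1, K1, G2, K2, c2) {
  c1 <- 1 - c2
  lower <- G1 + c2 * (1 / (G2 - G1) +
                        6 * (K1 + 2 * G1) * c1 / (5 * G1 * (3 * K1 + 4 * G1)))^-1
  upper <- G2 + c1 * (1 / (G1 - G2) +
                        6 * (K2 + 2 * G2) * c2 / (5 * G2 * (3 * K2 + 4 * G2)))^-1
  sort(c(lower, upper))
}
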