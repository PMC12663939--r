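# shared fixtures: small networks and boundary conditions used across files

small_net <- function(...) leaf_network(n_layers = 12, ...)

bc_at <- function(psi, vpd = 3.8, gs = 180, T_leaf = 303.15) {
  boundary_conditions(psi, air_state_from_vpd(vpd, T_leaf),
    gs_ad = gs / 2, gs_ab = gs / 2
  )
}

# binary disk / square masks for morphometric oracles
disk_mask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad
  m <- matrix(0, n, n)
  c0 <- (n + 1) / 2
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- 1
  m
}

square_mask <- function(s, pad = 10) {
  m <- matrix(0, s + 2 * pad, s + 2 * pad)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- 1
  m
}
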