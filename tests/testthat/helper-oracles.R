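# Independent brute-force oracles, written against the definitions rather
# than the engine code paths: plain double loops over atoms/residues.

# all-pairs charge-neighbourhood sum
oracle_scm <- function(structure, exposed, snapshot = 1, radius = 10) {
  at <- structure$atoms
  xyz <- structure$coords[, , snapshot]
  n <- nrow(at)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      if (!(at$key[j] %in% exposed)) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= radius) s <- s + at$charge[j]
    }
    out[i] <- s
  }
  out
}

# residues-times-atoms direct summation of the exposure-weighted
# hydrophobicity
oracle_sap <- function(structure, sasa, snapshot = 1, radius = 10,
                       scale = hydrophobicity_scale(),
                       ref = reference_sasa()) {
  at <- structure$atoms
  xyz <- structure$coords[, , snapshot]
  n <- nrow(at)
  out <- numeric(n)
  for (i in seq_len(n)) {
    total <- 0
    for (key in unique(at$key)) {
      sc <- which(at$key == key & at$is_side_chain)
      if (length(sc) == 0) next
      d <- sqrt(colSums((t(xyz[sc, , drop = FALSE]) - xyz[i, ])^2))
      if (!any(d <= radius)) next
      res <- at$resname[sc[1]]
      total <- total + sum(sasa$sasa[sc[d <= radius]]) / ref[[res]] *
        scale[[res]]
    }
    out[i] <- total
  }
  out
}

# point-sampling SASA with an independently coded lattice (latitude bands,
# not the golden spiral) at much higher density
oracle_sasa <- function(structure, snapshot = 1, probe = 1.4,
                        n_points = 10000) {
  at <- structure$atoms
  xyz <- structure$coords[, , snapshot]
  n <- nrow(at)
  # latitude-band lattice: rings of points at equally spaced polar angles
  band_points <- function(m) {
    n_theta <- ceiling(sqrt(m / 2))
    pts <- NULL
    for (t in seq_len(n_theta)) {
      theta <- pi * (t - 0.5) / n_theta
      n_phi <- max(1, round(2 * n_theta * sin(theta)))
      phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
      pts <- rbind(pts, cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                              rep(cos(theta), n_phi)))
    }
    pts
  }
  pts <- band_points(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- at$radius[i] + probe
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      rj <- at$radius[j] + probe
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & (d2 > rj^2)
    }
    out[i] <- 4 * pi * ri^2 * mean(free)
  }
  out
}

# small random atom cluster on two chains, seeded
random_cluster <- function(n_atoms, seed, spread = 6, charges = TRUE) {
  set.seed(seed)
  half <- ceiling(n_atoms / 2)
  role <- rep(c("heavy", "light"), c(half, n_atoms - half))
  df <- data.frame(
    chain = ifelse(role == "heavy", "H", "L"), role = role,
    resno = seq_len(n_atoms), resname = "ALA", name = "CB",
    x = runif(n_atoms, 0, spread), y = runif(n_atoms, 0, spread),
    z = runif(n_atoms, 0, spread),
    charge = if (charges) round(runif(n_atoms, -0.5, 0.5), 3) else 0,
    radius = runif(n_atoms, 1.2, 1.9))
  toy_structure(df, name = paste0("cluster", seed))
}

# canonical structure-level fixture used across scoring tests
scored_fixture <- function(name = "cdr_mixed") make_toy_structure(name)
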