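#' Deterministic unit-sphere point lattice (golden-section spiral)
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by point sampling: each atom's solvent-expanded sphere
#' (radius `r + probe_radius`) carries a deterministic golden-section point
#' lattice; a point is accessible iff it lies strictly outside every other
#' atom's expanded sphere (a point exactly on another sphere's surface counts
#' as buried). SASA = accessible fraction times the expanded sphere area.
#'
#' @param structure an `fv_structure` with radii assigned.
#' @param snapshot snapshot index (default 1).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_points lattice points per atom (default 960).
#' @return A `sasa_result`: list with `sasa` (per-atom, Angstrom^2, in atom
#'   order), `probe_radius`, `n_points`, `snapshot`.
#' @export
shrake_rupley <- function(structure, snapshot = 1, probe_radius = 1.4,
                          n_points = 960) {
  at <- structure$atoms
  if (any(at$radius <= 0))
    stop("radii unassigned; run assign_parameters() first")
  xyz <- snapshot_coords(structure, snapshot)
  n <- nrow(at)
  rad <- at$radius + probe_radius
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2

  sasa <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded sphere can reach atom i's expanded sphere
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    area <- 4 * pi * rad[i]^2
    if (length(nb) == 0) {
      sasa[i] <- area
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    centers <- xyz[nb, , drop = FALSE]
    pd2 <- outer(rowSums(p^2), rowSums(centers^2), "+") -
      2 * p %*% t(centers)
    buried <- rowSums(pd2 <= rep(rad[nb]^2, each = n_points)) > 0
    sasa[i] <- area * sum(!buried) / n_points
  }
  structure(list(sasa = sasa, probe_radius = probe_radius,
                 n_points = n_points, snapshot = snapshot),
            class = "sasa_result")
}

#' Side-chain solvent-accessible area per residue
#'
#' Sums per-atom SASA over each residue's side-chain atoms (backbone atom
#' names per [backbone_atoms()]).
#'
#' @param sasa a `sasa_result` computed on `structure`.
#' @param structure the same `fv_structure`.
#' @return Named numeric vector (residue key -> Angstrom^2), covering every
#'   residue (0 when a residue has no side-chain atoms in the structure).
#' @export
side_chain_sasa <- function(sasa, structure) {
  at <- structure$atoms
  if (length(sasa$sasa) != nrow(at))
    stop("sasa result does not match the structure's atom count")
  keys <- unique(at$key)
  v <- setNames(numeric(length(keys)), keys)
  sc <- at$is_side_chain
  agg <- tapply(sasa$sasa[sc], at$key[sc], sum)
  v[names(agg)] <- agg
  v
}

#' Exposed-residue classification
#'
#' A residue is exposed iff its summed side-chain SASA meets the threshold
#' (inclusive); the conventional cutoff is 10 Angstrom^2.
#'
#' @param side_chain named side-chain SASA vector from [side_chain_sasa()].
#' @param threshold Angstrom^2 (default 10).
#' @return Character vector of exposed residue keys.
#' @export
exposed_residues <- function(side_chain, threshold = 10) {
  stopifnot(threshold >= 0)
  names(side_chain)[side_chain >= threshold]
}
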