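#' Atomic spatial-charge-map field for one snapshot
#'
#' For every atom i, the sum of partial charges of all atoms j of exposed
#' residues within `radius` of i (j != i by default: an atom's own charge is
#' not part of its surroundings). All atoms of an exposed residue contribute,
#' backbone included.
#'
#' @param structure an `fv_structure` with charges assigned.
#' @param exposed character vector of exposed residue keys (see
#'   [exposed_residues()]).
#' @param snapshot snapshot index.
#' @param radius neighbourhood cutoff, Angstrom (default 10, inclusive).
#' @param include_self count atom i's own charge when its residue is exposed
#'   (default FALSE).
#' @param restrict_to_exposed compute the field only for atoms of exposed
#'   residues, zero elsewhere (default FALSE: every atom gets a value).
#' @return Numeric vector of per-atom values (elementary-charge units).
#' @export
atomic_scm <- function(structure, exposed, snapshot = 1, radius = 10,
                       include_self = FALSE, restrict_to_exposed = FALSE) {
  stopifnot(radius > 0)
  at <- structure$atoms
  if (length(exposed) == 0) {
    warning("empty exposed-residue set: all atomic SCM values are 0")
    return(numeric(nrow(at)))
  }
  xyz <- snapshot_coords(structure, snapshot)
  src <- which(at$key %in% exposed)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz[src, , drop = FALSE]^2), "+") -
    2 * xyz %*% t(xyz[src, , drop = FALSE])
  inr <- d2 <= radius^2
  if (!include_self) {
    self <- match(seq_len(nrow(at)), src)
    hit <- which(!is.na(self))
    inr[cbind(hit, self[hit])] <- FALSE
  }
  field <- as.vector(inr %*% at$charge[src])
  if (restrict_to_exposed) field[!(at$key %in% exposed)] <- 0
  field
}

#' Domain-wise positive/negative charge sums for one snapshot
#'
#' Splits the atomic field into its positive and negative parts per region:
#' `SCM_pos(D) = sum_{i in D} SCM_i H(SCM_i)` and
#' `SCM_neg(D) = sum_{i in D} |SCM_i| H(-SCM_i)` with `H(0) = 0`, so both are
#' nonnegative and `SCM_pos - SCM_neg` equals the plain regional sum. An atom
#' belongs to a region iff its residue does.
#'
#' @param field per-atom values from [atomic_scm()].
#' @param domains a `domain_map` for the same structure.
#' @param structure the `fv_structure` the field was computed on.
#' @return data.frame: region, SCM_pos, SCM_neg (one row per region).
#' @export
domain_scm <- function(field, domains, structure) {
  mem <- atom_membership(structure, domains)
  pos <- pmax(field, 0)
  neg <- pmax(-field, 0)
  data.frame(region = colnames(mem),
             SCM_pos = as.vector(pos %*% mem),
             SCM_neg = as.vector(neg %*% mem),
             row.names = NULL)
}

#' Ensemble statistics over per-snapshot region scores
#'
#' Mean, population standard deviation (denominator N, matching an ensemble
#' average over frames) and relative standard deviation per region score.
#' When the mean is zero but the spread is not, the relative standard
#' deviation is undefined and reported as `NA`.
#'
#' @param per_snapshot list (one element per snapshot) of equally named
#'   numeric vectors of region scores.
#' @return data.frame: name, mean, sd, rel_sd.
#' @export
ensemble_stats <- function(per_snapshot) {
  stopifnot(length(per_snapshot) >= 1)
  m <- do.call(rbind, per_snapshot)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  rel <- ifelse(sdev == 0, 0, ifelse(mu == 0, NA_real_, sdev / abs(mu)))
  data.frame(name = colnames(m), mean = unname(mu), sd = unname(sdev),
             rel_sd = unname(rel), row.names = NULL)
}
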