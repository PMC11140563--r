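#' Score an Fv structure: the 30 spatial descriptors
#'
#' Runs the full per-snapshot pipeline (SASA, exposed residues, atomic charge
#' and aggregation-propensity fields, domain sums) and aggregates over
#' snapshots into ensemble mean, standard deviation and relative standard
#' deviation for each of the 30 descriptors: `SAP_pos`, `SCM_pos`, `SCM_neg`
#' over the six CDRs, the combined CDR, `Hv`, `Lv` and `Fv`.
#'
#' @param structure an `fv_structure` with charges and radii assigned.
#' @param scheme numbering scheme for CDR assignment (default `"chothia"`).
#' @param scm_radius,sap_radius neighbourhood cutoffs, Angstrom (default 10).
#' @param exposure_threshold side-chain SASA cutoff for exposure, Angstrom^2
#'   (default 10).
#' @param probe_radius,n_points SASA parameters (defaults 1.4 Angstrom, 960).
#' @param scale,ref hydrophobicity and reference-SASA tables.
#' @return An `fv_descriptors` object: data.frame with columns name,
#'   property, region, mean, sd, rel_sd (30 rows, canonical order); the
#'   per-snapshot score matrix is kept in the `per_snapshot` attribute.
#' @export
score_structure <- function(structure, scheme = "chothia",
                            scm_radius = 10, sap_radius = 10,
                            exposure_threshold = 10, probe_radius = 1.4,
                            n_points = 960,
                            scale = hydrophobicity_scale(),
                            ref = reference_sasa()) {
  domains <- assign_domains(structure, scheme)
  k <- n_snapshots(structure)
  per_snap <- vector("list", k)
  for (m in seq_len(k)) {
    sas <- shrake_rupley(structure, snapshot = m,
                         probe_radius = probe_radius, n_points = n_points)
    exp_res <- exposed_residues(side_chain_sasa(sas, structure),
                                exposure_threshold)
    scm <- atomic_scm(structure, exp_res, snapshot = m, radius = scm_radius)
    sap <- atomic_sap(structure, sas, snapshot = m, radius = sap_radius,
                      scale = scale, ref = ref)
    ds <- domain_scm(scm, domains, structure)
    dp <- domain_sap_pos(sap, domains, structure)
    v <- c(setNames(dp$SAP_pos, paste0("SAP_pos_", dp$region)),
           setNames(ds$SCM_pos, paste0("SCM_pos_", ds$region)),
           setNames(ds$SCM_neg, paste0("SCM_neg_", ds$region)))
    per_snap[[m]] <- v[descriptor_names()]
  }
  st <- ensemble_stats(per_snap)
  st$property <- sub("_(CDR.*|Hv|Lv|Fv)$", "", st$name)
  st$region <- sub("^(SAP_pos|SCM_pos|SCM_neg)_", "", st$name)
  st <- st[, c("name", "property", "region", "mean", "sd", "rel_sd")]
  attr(st, "per_snapshot") <- do.call(rbind, per_snap)
  attr(st, "params") <- list(scheme = scheme, scm_radius = scm_radius,
                             sap_radius = sap_radius,
                             exposure_threshold = exposure_threshold,
                             probe_radius = probe_radius, n_points = n_points)
  attr(st, "structure_name") <- structure$name
  class(st) <- c("fv_descriptors", class(st))
  st
}

#' @export
print.fv_descriptors <- function(x, ...) {
  cat("Spatial descriptors for '", attr(x, "structure_name"), "' (",
      nrow(attr(x, "per_snapshot")), " snapshot(s))\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Flatten descriptor means to a named 30-vector in canonical column order
#' @param x an `fv_descriptors` object.
#' @return Named numeric vector of length 30.
#' @export
descriptor_vector <- function(x) {
  stopifnot(inherits(x, "fv_descriptors"))
  setNames(x$mean, x$name)[descriptor_names()]
}

#' Write descriptors (mean, sd, rel_sd per name) for several structures
#' @param descs list of `fv_descriptors`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(descs, path) {
  if (inherits(descs, "fv_descriptors")) descs <- list(descs)
  rows <- lapply(descs, function(d) {
    wide <- c(setNames(d$mean, d$name),
              setNames(d$sd, paste0(d$name, "_sd")),
              setNames(d$rel_sd, paste0(d$name, "_rel_sd")))
    c(Name = attr(d, "structure_name"), as.list(wide))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
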