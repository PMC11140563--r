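# Synthetic fixtures: toy structures with hand-computable scores, canonical
# template-compatible sequence pairs, sequence->descriptor ground truth for
# surrogate recovery, and a small descriptor/aggregation-rate table.

#' Build an Fv structure object from an explicit atom table
#'
#' @param atoms data.frame with columns chain, role, resno, icode (optional),
#'   resname, name, x, y, z, charge, radius, serial (optional).
#' @param n_snapshots number of frames; frame m adds `offsets[[m]]`.
#' @param offsets list of length `n_snapshots` of 3-vectors (rigid whole-body
#'   translations per frame; default all zero, i.e. identical frames).
#' @param name structure identifier.
#' @return An `fv_structure`.
#' @export
toy_structure <- function(atoms, n_snapshots = 1, offsets = NULL,
                          name = "toy") {
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element))
    atoms$element <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atoms$name)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyDuplicated(xyz))
    stop("atoms at identical coordinates")
  if (is.null(offsets)) offsets <- rep(list(c(0, 0, 0)), n_snapshots)
  stopifnot(length(offsets) == n_snapshots)
  coords <- array(NA_real_, dim = c(nrow(atoms), 3, n_snapshots))
  for (m in seq_len(n_snapshots))
    coords[, , m] <- sweep(xyz, 2, offsets[[m]], "+")
  at <- data.frame(
    serial = atoms$serial, name = atoms$name, element = toupper(atoms$element),
    resname = atoms$resname, aa = aa3to1(atoms$resname), chain = atoms$chain,
    role = atoms$role, resno = atoms$resno, icode = atoms$icode,
    key = residue_key(atoms$role, atoms$resno, atoms$icode),
    is_side_chain = !(atoms$name %in% backbone_atoms()),
    charge = atoms$charge, radius = atoms$radius, stringsAsFactors = FALSE)
  structure(list(name = name, atoms = at, coords = coords),
            class = "fv_structure")
}

#' Catalogue of analytic toy structures
#'
#' Small single-atom-per-residue structures whose per-atom charge and
#' aggregation-propensity fields are hand-computable: separations are chosen
#' so every atom pair is unambiguously inside or outside the 10 Angstrom
#' neighbourhood, and every sphere either is isolated (SASA `4*pi*(r+w)^2`)
#' or intersects exactly one equal sphere (spherical-cap closed form).
#'
#' @return Named list of specs; each spec has `structure` plus a `sheet` of
#'   expected values (`scm` per atom, exact; `sasa` per atom, closed form;
#'   `sap` per atom as a function of the achieved SASA; domain sums).
#' @export
toy_structure_catalog <- function() {
  r <- 1.7; w <- 1.4; R <- r + w
  iso <- 4 * pi * R^2
  # two equal spheres d apart (d < 2R): each loses a cap of height R - d/2
  two_sphere <- function(d) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  h_ala <- unname(hydrophobicity_scale()["ALA"])
  ref_ala <- unname(reference_sasa()["ALA"])

  pair_atoms <- function(sep) data.frame(
    chain = c("H", "L"), role = c("heavy", "light"), resno = c(1, 1),
    resname = "ALA", name = "CB", x = c(0, sep), y = 0, z = 0,
    charge = c(0.5, -0.5), radius = r)

  mixed_atoms <- data.frame(
    chain = c("H", "H", "H", "L", "L"),
    role = c("heavy", "heavy", "heavy", "light", "light"),
    resno = c(30, 96, 60, 91, 60), resname = "ALA", name = "CB",
    x = c(0, 4, 8, 40, 44), y = 0, z = 0,
    charge = c(0.3, -0.2, 0.1, 0.4, -0.1), radius = r)

  list(
    pair_close = list(
      structure = toy_structure(pair_atoms(5), name = "pair_close"),
      sheet = list(
        scm = c(-0.5, 0.5), sasa = rep(two_sphere(5), 2),
        sap = function(sasa) rep(sum(sasa / ref_ala * h_ala), 2),
        domain = list(SCM_neg_Hv = 0.5, SCM_pos_Hv = 0, SCM_pos_Lv = 0.5,
                      SCM_neg_Lv = 0, SCM_pos_Fv = 0.5, SCM_neg_Fv = 0.5))),
    pair_far = list(
      structure = toy_structure(pair_atoms(20), name = "pair_far"),
      sheet = list(
        scm = c(0, 0), sasa = rep(iso, 2),
        sap = function(sasa) sasa / ref_ala * h_ala,  # own residue only
        domain = list(SCM_pos_Fv = 0, SCM_neg_Fv = 0))),
    pair_frames = list(
      structure = toy_structure(pair_atoms(5), n_snapshots = 3,
                                name = "pair_frames"),
      sheet = list(scm = c(-0.5, 0.5), ensemble_sd = 0)),
    cdr_mixed = list(
      structure = toy_structure(mixed_atoms, name = "cdr_mixed"),
      sheet = list(
        scm = c(-0.1, 0.4, 0.1, -0.1, 0.4),
        domain = list(SCM_pos_Hv = 0.5, SCM_neg_Hv = 0.1,
                      SCM_pos_CDRH1 = 0, SCM_neg_CDRH1 = 0.1,
                      SCM_pos_CDRH3 = 0.4, SCM_neg_CDRH3 = 0,
                      SCM_pos_Lv = 0.4, SCM_neg_Lv = 0.1,
                      SCM_pos_CDRL3 = 0, SCM_neg_CDRL3 = 0.1,
                      SCM_pos_Fv = 0.9, SCM_neg_Fv = 0.2)))
  )
}

#' Materialize a catalogued toy structure as a PDB file plus score sheet
#'
#' @param spec a catalogue entry name (see [toy_structure_catalog()]) or a
#'   list with `structure` (and optionally `sheet`).
#' @param pdb_path where to write the (multi-)MODEL PDB; `NULL` skips writing.
#' @return list: `structure`, `sheet`, `pdb_path`.
#' @export
make_toy_structure <- function(spec, pdb_path = NULL) {
  if (is.character(spec)) {
    cat_ <- toy_structure_catalog()
    if (!spec %in% names(cat_)) stop("unknown catalogue entry: ", spec)
    spec <- cat_[[spec]]
  }
  if (!is.null(pdb_path)) write_pdb_structure(spec$structure, pdb_path)
  list(structure = spec$structure, sheet = spec$sheet, pdb_path = pdb_path)
}

#' Generate synthetic paired Fv sequences compatible with the templates
#'
#' Chains have canonical framework lengths and modal CDR1/CDR2 lengths;
#' CDR3 lengths vary (heavy 10-16, light fixed 9). Cysteines are planted at
#' scheme positions 23 and 104 of both chains; random draws avoid cysteine
#' elsewhere. Violation modes plant specific filter failures.
#'
#' @param n number of pairs.
#' @param seed RNG seed.
#' @param violation `NULL` (default, all pass), `"cdrh3_31"` (heavy CDR3 of
#'   31 residues) or `"cys_missing"` (no Cys at heavy position 104).
#' @return data.frame: name, heavy, light.
#' @export
make_synthetic_sequences <- function(n, seed = 1, violation = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  aa <- setdiff(amino_acids(), "C")
  rs <- function(k) paste(sample(aa, k, replace = TRUE), collapse = "")
  plant <- function(s, at, ch) {
    substr(s, at, at) <- ch
    s
  }
  heavy <- character(n); light <- character(n)
  for (i in seq_len(n)) {
    h3 <- if (identical(violation, "cdrh3_31")) 31 else sample(10:16, 1)
    fr1 <- plant(rs(25), 23, "C")
    fr4 <- plant(rs(11), 2, "C")            # scheme slot 104 = 2nd of 103-113
    if (identical(violation, "cys_missing")) fr4 <- plant(fr4, 2, "A")
    heavy[i] <- paste0(fr1, rs(7), rs(19), rs(5), rs(38), rs(h3), fr4)
    lfr1 <- plant(rs(23), 23, "C")
    lfr4 <- plant(rs(10), 7, "C")           # scheme slot 104 = 7th of 98-107
    light[i] <- paste0(lfr1, rs(11), rs(15), rs(7), rs(32), rs(9), lfr4)
  }
  data.frame(name = sprintf("syn_%03d", seq_len(n)), heavy = heavy,
             light = light, stringsAsFactors = FALSE)
}

#' Encoding row indices of each scoring region
#'
#' Rows 1-145 of the one-hot encoding are the heavy template slots, rows
#' 146-272 the light slots; each of the ten regions maps to its slot rows.
#'
#' @return Named list of integer row vectors, one per region.
#' @export
region_encoding_rows <- function() {
  th <- template_meta("heavy")
  tl <- template_meta("light")
  rows <- list()
  for (r in unique(th$region[th$region != "FR"]))
    rows[[r]] <- which(th$region == r)
  for (r in unique(tl$region[tl$region != "FR"]))
    rows[[r]] <- 145L + which(tl$region == r)
  rows$CDR <- sort(unlist(rows[paste0("CDR", c("H1", "H2", "H3",
                                               "L1", "L2", "L3"))],
                          use.names = FALSE))
  rows$Hv <- 1:145
  rows$Lv <- 146:272
  rows$Fv <- 1:272
  rows[ab_regions()]
}

#' Synthetic sequence-to-descriptor ground truth for surrogate recovery
#'
#' Labels are a fixed sparse linear map of the one-hot encoding plus
#' Gaussian noise, built to mirror how one spatial property decomposes over
#' the scoring regions: a single per-residue-type weight vector (a random
#' 20-vector, the synthetic analogue of a hydrophobicity or charge scale;
#' gaps contribute 0) is summed over each region's slots, giving one output
#' per region exactly as one property model predicts its ten domains. The
#' full coefficient array is returned so recovery can be checked exactly.
#'
#' @param n number of antibodies (>= 100 recommended for training).
#' @param seed RNG seed (drives sequences, coefficients and noise).
#' @param noise_sd label noise standard deviation (default 0.1).
#' @param n_outputs number of label columns (default 10, the ten regions;
#'   fewer take the first regions, more recycle them).
#' @return list: `x` (`n x 272 x 21` array), `y` (`n x n_outputs` matrix),
#'   `coefs` (`272 x 21 x n_outputs` array), `pairs` (the sequences),
#'   `signal` (noise-free labels).
#' @export
make_surrogate_dataset <- function(n, seed = 1, noise_sd = 0.1,
                                   n_outputs = 10) {
  pairs <- make_synthetic_sequences(n, seed = seed)
  enc <- encode_pairs(pairs)
  stopifnot(nrow(enc$report) == sum(enc$report$pass))
  x <- enc$x
  set.seed(seed + 1)
  regions <- region_encoding_rows()
  w <- rnorm(20)                             # shared residue-type weights
  coefs <- array(0, dim = c(272, 21, n_outputs))
  for (o in seq_len(n_outputs)) {
    rows <- regions[[(o - 1) %% length(regions) + 1]]
    coefs[rows, 1:20, o] <- matrix(w, length(rows), 20, byrow = TRUE)
  }
  xm <- matrix(x, nrow = n)                  # n x (272*21), position fastest
  cm <- matrix(coefs, nrow = 272 * 21)
  signal <- xm %*% cm
  y <- signal + matrix(rnorm(n * n_outputs, sd = noise_sd), n)
  colnames(y) <- names(regions)[((seq_len(n_outputs) - 1) %%
                                   length(regions)) + 1]
  list(x = x, y = y, coefs = coefs, pairs = pairs, signal = signal)
}

#' Synthetic descriptor/aggregation-rate table
#'
#' Emulates the shape of a small high-concentration mAb aggregation study:
#' n antibodies by 30 descriptor columns (equicorrelated standard normals)
#' plus a target that is a sparse linear signal in three descriptors with
#' Gaussian noise. The generating truth is attached as attributes.
#'
#' @param n rows (default 21).
#' @param support three descriptor names carrying the signal.
#' @param coefs their coefficients.
#' @param noise_sd target noise standard deviation (default 0.5).
#' @param rho pairwise descriptor correlation (default 0.3).
#' @param seed RNG seed.
#' @return data.frame: 30 descriptor columns plus `agg_rate`; attributes
#'   `support`, `coefs`, `noise_sd`.
#' @export
make_agg_dataset <- function(n = 21,
                             support = c("SAP_pos_CDRH3", "SCM_pos_CDRL3",
                                         "SCM_neg_CDRH3"),
                             coefs = c(1.5, -1.2, 0.8),
                             noise_sd = 0.5, rho = 0.3, seed = 1) {
  nm <- descriptor_names()
  stopifnot(all(support %in% nm), length(coefs) == length(support))
  set.seed(seed)
  z <- rnorm(n)
  x <- sqrt(rho) * matrix(z, n, length(nm)) +
    sqrt(1 - rho) * matrix(rnorm(n * length(nm)), n)
  colnames(x) <- nm
  y <- as.vector(x[, support, drop = FALSE] %*% coefs) +
    rnorm(n, sd = noise_sd)
  out <- data.frame(x, agg_rate = y, check.names = FALSE)
  attr(out, "support") <- support
  attr(out, "coefs") <- coefs
  attr(out, "noise_sd") <- noise_sd
  out
}
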