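#' Parse an antibody Fv structure from a PDB file
#'
#' Reads ATOM records (via bio3d), treating MODEL/ENDMDL blocks as structure
#' snapshots (trajectory frames). All snapshots must contain the identical
#' atom set; coordinates are stored per snapshot. Charges and radii are left
#' at zero until [assign_parameters()].
#'
#' @param path PDB file path.
#' @param chain_roles named character vector mapping chain labels to roles,
#'   e.g. `c(H = "heavy", L = "light")`. Chains outside this map are an error.
#' @param name identifier for the structure (defaults to the file stem).
#' @return An `fv_structure`: list with `name`, `atoms` (one row per atom:
#'   serial, name, element, resname, aa, chain, role, resno, icode, key,
#'   is_side_chain, charge, radius) and `coords`, an `n_atoms x 3 x
#'   n_snapshots` array in Angstrom.
#' @export
parse_pdb <- function(path, chain_roles = c(H = "heavy", L = "light"),
                      name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM records in ", path)

  # line-level validation so malformed records are reported with line numbers
  bad <- which(is_atom & nchar(lines) < 54)
  coords_chr <- cbind(substr(lines, 31, 38), substr(lines, 39, 46),
                      substr(lines, 47, 54))
  suppressWarnings(num_ok <- !is.na(as.numeric(coords_chr[, 1])) &
                     !is.na(as.numeric(coords_chr[, 2])) &
                     !is.na(as.numeric(coords_chr[, 3])))
  bad <- sort(c(bad, which(is_atom & !num_ok)))
  if (length(bad) > 0)
    stop("malformed ATOM record at line ", bad[1], ": ", lines[bad[1]])

  # snapshot partition by MODEL blocks and atom-identity consistency
  model_id <- cumsum(rec == "MODEL ")
  if (max(model_id) == 0) model_id <- rep(1L, length(lines))
  atom_model <- model_id[is_atom]
  atom_sig <- paste(substr(lines[is_atom], 13, 27))  # name/res/chain/num/icode
  sigs <- split(atom_sig, atom_model)
  n_snap <- length(sigs)
  if (n_snap > 1) {
    ref <- sigs[[1]]
    for (m in 2:n_snap) {
      cur <- sigs[[m]]
      if (length(cur) != length(ref)) {
        miss <- c(setdiff(ref, cur), setdiff(cur, ref))
        stop("snapshot ", m, " has an inconsistent atom set; first mismatch: ",
             trimws(miss[1]))
      }
      if (any(cur != ref)) {
        i <- which(cur != ref)[1]
        stop("snapshot ", m, " atom ", i, " differs from snapshot 1: '",
             trimws(cur[i]), "' vs '", trimws(ref[i]), "'")
      }
    }
  }

  pdb <- bio3d::read.pdb(path, multi = n_snap > 1, verbose = FALSE)
  at <- pdb$atom
  n_total <- nrow(at)
  n_atoms <- if (n_snap > 1) n_total else n_total
  # bio3d returns the first model's atom table; coordinates per frame in xyz
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) != n_snap)
    n_snap <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nrow(at), 3, n_snap))
  for (m in seq_len(n_snap))
    coords[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)

  chain <- at$chain
  unknown <- setdiff(unique(chain), names(chain_roles))
  if (length(unknown) > 0)
    stop("chain(s) without a declared role: ", paste(unknown, collapse = ", "))
  role <- unname(chain_roles[chain])
  if (!all(role %in% c("heavy", "light")))
    stop("chain roles must be 'heavy' or 'light'")

  resname <- at$resid
  aa <- aa3to1(resname)
  if (anyNA(aa))
    stop("non-canonical residue name(s): ",
         paste(unique(resname[is.na(aa)]), collapse = ", "))
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank))  # fall back to first alphabetic character of the atom name
    elem[blank] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety[blank])
  icode <- at$insert
  icode[is.na(icode)] <- ""
  key <- residue_key(role, at$resno, icode)

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, element = toupper(trimws(elem)),
    resname = resname, aa = aa, chain = chain, role = role,
    resno = at$resno, icode = icode, key = key,
    is_side_chain = !(at$elety %in% backbone_atoms()),
    charge = 0, radius = 0, stringsAsFactors = FALSE)

  structure(list(name = name, atoms = atoms, coords = coords),
            class = "fv_structure")
}

residue_key <- function(role, resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(ifelse(role == "heavy", "H", "L"), ":", resno, icode)
}

#' @export
print.fv_structure <- function(x, ...) {
  cat("Fv structure '", x$name, "': ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$key)), " residues, ",
      dim(x$coords)[3], " snapshot(s)\n", sep = "")
  invisible(x)
}

n_snapshots <- function(structure) dim(structure$coords)[3]

snapshot_coords <- function(structure, snapshot = 1) {
  k <- n_snapshots(structure)
  if (snapshot < 1 || snapshot > k)
    stop("snapshot index out of range (1..", k, ")")
  structure$coords[, , snapshot, drop = TRUE]
}

#' Write an Fv structure to a PDB file
#'
#' Multi-snapshot structures are written as MODEL/ENDMDL blocks.
#'
#' @param structure an `fv_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(structure, path) {
  at <- structure$atoms
  k <- n_snapshots(structure)
  # bio3d expects one row per frame of the flattened x,y,z vector
  flat <- matrix(NA_real_, nrow = k, ncol = nrow(at) * 3)
  for (m in seq_len(k)) flat[m, ] <- as.vector(t(structure$coords[, , m]))
  bio3d::write.pdb(file = path, xyz = flat, resno = at$resno,
                   resid = at$resname, eleno = at$serial, elety = at$name,
                   chain = at$chain, insert = ifelse(nzchar(at$icode),
                                                     at$icode, NA),
                   elesy = at$element)
  invisible(path)
}

#' Assign partial charges and van der Waals radii
#'
#' Looks every atom up in the bundled (or user-supplied) charge and radius
#' tables. Histidines are assigned the protonated (+1) variant, the fixed
#' protonation rule for the mildly acidic formulation pH regime the scores
#' assume. In strict mode an unknown atom name or an incomplete residue
#' (e.g. missing hydrogens) is an error; in permissive mode unknown atoms
#' get zero charge, incomplete residues are tolerated, and the atom coverage
#' fraction is recorded in the `coverage` attribute.
#'
#' @param structure an `fv_structure`.
#' @param charges a charge table as returned by [charge_table()].
#' @param radii named radius vector by element, as [vdw_radii()].
#' @param strict error on unknown atoms / incomplete residues (default TRUE).
#' @param nter,cter optional residue keys to patch as N-/C-terminal.
#' @return The structure with `charge` and `radius` filled in.
#' @export
assign_parameters <- function(structure, charges = charge_table(),
                              radii = vdw_radii(), strict = TRUE,
                              nter = NULL, cter = NULL) {
  at <- structure$atoms
  lk <- charges$lookup
  patch_of <- c(setNames(rep("NTER", length(nter)), nter),
                setNames(rep("CTER", length(cter)), cter))

  # terminal patches override the lookup for the patched residues and adjust
  # the expected atom set (deleted atoms out, added atoms in)
  expected_for <- function(key, res) {
    atoms <- charges$atoms[[res]]
    if (!key %in% names(patch_of)) return(atoms)
    p <- charges$patches[charges$patches$patch == patch_of[[key]], ]
    atoms <- setdiff(atoms, p$atom[p$action == "del"])
    union(atoms, p$atom[p$action == "add"])
  }
  q <- unname(lk[paste(at$resname, at$name)])
  for (key in names(patch_of)) {
    sel <- which(at$key == key)
    if (length(sel) == 0) stop("patched residue not found: ", key)
    p <- charges$patches[charges$patches$patch == patch_of[[key]], ]
    for (i in seq_len(nrow(p))) {
      hit <- sel[at$name[sel] == p$atom[i]]
      if (p$action[i] == "del") {
        if (length(hit) > 0)
          stop("atom ", p$atom[i], " should be absent in patched residue ",
               key)
      } else q[hit] <- p$charge[i]
    }
  }
  unknown <- is.na(q)
  if (any(unknown)) {
    i <- which(unknown)[1]
    msg <- paste0("unknown atom '", at$name[i], "' in residue ",
                  at$resname[i], " ", at$key[i])
    if (strict) stop(msg)
    message(msg, " (skipped; ", sum(unknown), " atom(s) without parameters)")
    q[unknown] <- 0
  }

  r <- unname(radii[at$element])
  if (anyNA(r)) {
    if (strict) stop("no radius for element(s): ",
                     paste(unique(at$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- 1.5
  }

  # completeness: every residue should carry its full tabulated atom set
  cover <- 1
  for (key in unique(at$key)) {
    sel <- at$key == key
    res <- at$resname[sel][1]
    want <- expected_for(key, res)
    matched <- intersect(want, at$name[sel])
    if (length(matched) < length(want) || any(!(at$name[sel] %in% want))) {
      missing <- setdiff(want, at$name[sel])
      if (strict && length(missing) > 0)
        stop("residue ", res, " ", key, " is missing atom(s): ",
             paste(missing, collapse = ", "),
             " (use strict = FALSE for heavy-atom-only structures)")
      cover <- min(cover, length(matched) / length(want))
    }
  }

  structure$atoms$charge <- q
  structure$atoms$radius <- r
  attr(structure, "coverage") <- cover
  structure
}

#' Total formal charge of a structure from its assigned partial charges
#' @param structure an `fv_structure` after [assign_parameters()].
#' @return Numeric scalar.
#' @export
total_charge <- function(structure) sum(structure$atoms$charge)

#' Map residues to the ten scoring regions
#'
#' Assigns every residue to its domains: heavy-chain residues to `Hv` and
#' `Fv`, light-chain residues to `Lv` and `Fv`, residues inside a Chothia CDR
#' interval additionally to that CDR and to the combined `CDR` region.
#' Insertion codes inherit the membership of their base number.
#'
#' @param structure an `fv_structure` (residue numbers in scheme numbering).
#' @param scheme numbering-scheme identifier; only `"chothia"` is bundled.
#' @return A `domain_map`: data.frame of residue keys plus a logical
#'   membership matrix over the ten regions (attribute `membership`).
#' @export
assign_domains <- function(structure, scheme = "chothia") {
  if (!identical(scheme, "chothia"))
    stop("unknown numbering scheme: ", scheme)
  at <- structure$atoms
  res <- unique(at[, c("key", "role", "resno")])
  max_no <- c(heavy = 113, light = 107)
  out_of_range <- res$resno < 1 | res$resno > max_no[res$role]
  if (any(out_of_range))
    stop("residue number outside the chothia variable-region range: ",
         res$key[which(out_of_range)[1]])

  bd <- cdr_boundaries()
  regions <- ab_regions()
  m <- matrix(FALSE, nrow(res), length(regions),
              dimnames = list(res$key, regions))
  m[, "Fv"] <- TRUE
  m[, "Hv"] <- res$role == "heavy"
  m[, "Lv"] <- res$role == "light"
  for (i in seq_len(nrow(bd))) {
    sel <- res$role == bd$chain[i] & res$resno >= bd$start[i] &
      res$resno <= bd$end[i]
    m[sel, bd$region[i]] <- TRUE
  }
  m[, "CDR"] <- rowSums(m[, paste0("CDR", c("H1", "H2", "H3", "L1", "L2", "L3")),
                          drop = FALSE]) > 0
  dm <- res
  attr(dm, "membership") <- m
  class(dm) <- c("domain_map", class(dm))
  dm
}

#' @export
print.domain_map <- function(x, ...) {
  m <- attr(x, "membership")
  cat("Domain map:", nrow(m), "residues\n")
  print(colSums(m))
  invisible(x)
}

#' Region membership of each atom of a structure under a domain map
#' @keywords internal
atom_membership <- function(structure, domains) {
  m <- attr(domains, "membership")
  m[structure$atoms$key, , drop = FALSE]
}
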