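#' @importFrom stats coef cor predict rnorm runif setNames
#' @importFrom utils combn read.csv write.csv head
#' @importFrom Rcpp sourceCpp
#' @useDynLib abprop, .registration = TRUE
NULL

.abprop <- new.env(parent = emptyenv())

param_file <- function(name) {
  path <- system.file("extdata", "params", name, package = "abprop")
  if (!nzchar(path)) stop("parameter file not found: ", name)
  path
}

read_param_tsv <- function(name) {
  read.delim(param_file(name), comment.char = "#", stringsAsFactors = FALSE)
}

#' Canonical region and property vocabulary
#'
#' The ten scoring regions (six Chothia CDRs, their union, and the heavy,
#' light and full variable domains) and the three spatial properties scored
#' over them. `descriptor_names()` enumerates the 30 canonical descriptor
#' columns, property-major (`SAP_pos_CDRH1` ... `SCM_neg_Fv`).
#'
#' @return Character vector of labels.
#' @export
ab_regions <- function() {
  c("CDRH1", "CDRH2", "CDRH3", "CDRL1", "CDRL2", "CDRL3",
    "CDR", "Hv", "Lv", "Fv")
}

#' @rdname ab_regions
#' @export
ab_properties <- function() c("SAP_pos", "SCM_pos", "SCM_neg")

#' @rdname ab_regions
#' @export
descriptor_names <- function() {
  as.vector(t(outer(ab_properties(), ab_regions(), paste, sep = "_")))
}

#' Bundled partial-charge table
#'
#' All-atom partial charges per residue (CHARMM-style naming), with histidine
#' tabulated in its doubly protonated (+1) form, plus terminal patches.
#' Per-residue sums equal the residue's formal charge exactly.
#'
#' @return A list with elements `charges` (data.frame: resname, atom, charge),
#'   `atoms` (named list: expected atom set per residue), `formal` (named
#'   numeric: formal charge per residue) and `patches` (data.frame).
#' @export
charge_table <- function() {
  if (!is.null(.abprop$charge_table)) return(.abprop$charge_table)
  ch <- read_param_tsv("charges.tsv")
  patches <- read_param_tsv("patches.tsv")
  formal <- c(ARG = 1, LYS = 1, HIS = 1, ASP = -1, GLU = -1)
  res <- sort(unique(ch$resname))
  formal <- setNames(ifelse(res %in% names(formal), formal[res], 0), res)
  out <- list(
    charges = ch,
    atoms = split(ch$atom, ch$resname),
    formal = formal,
    patches = patches,
    lookup = setNames(ch$charge, paste(ch$resname, ch$atom))
  )
  .abprop$charge_table <- out
  out
}

#' Bundled van der Waals radii (Bondi set, by element)
#'
#' @return Named numeric vector, Angstrom.
#' @export
vdw_radii <- function() {
  tab <- read_param_tsv("radii.tsv")
  setNames(tab$radius, tab$element)
}

#' Residue hydrophobicity scale
#'
#' Black & Mould normalized hydrophobicity. By default the scale is shifted
#' so glycine scores 0 (hydrophobic residues positive, hydrophilic negative),
#' the convention used by the spatial aggregation propensity.
#'
#' @param gly_zero shift the scale so `GLY` maps to 0 (default `TRUE`).
#' @return Named numeric vector over the 20 canonical residues.
#' @export
hydrophobicity_scale <- function(gly_zero = TRUE) {
  tab <- read_param_tsv("hydrophobicity.tsv")
  v <- setNames(tab$value, tab$resname)
  if (gly_zero) v <- v - v[["GLY"]]
  v
}

#' Fully exposed side-chain reference surface areas
#'
#' @return Named numeric vector, Angstrom^2.
#' @export
reference_sasa <- function() {
  tab <- read_param_tsv("ref_sasa.tsv")
  setNames(tab$sasa, tab$resname)
}

#' Chothia CDR boundary table
#'
#' @return data.frame with columns region, chain, start, end.
#' @export
cdr_boundaries <- function() read_param_tsv("cdr_chothia.tsv")

#' Backbone atom-name list
#'
#' Atom names treated as backbone; every other atom is side chain. Glycine's
#' HA2 is deliberately classified as side chain so its side-chain surface
#' area is defined.
#'
#' @return Character vector.
#' @export
backbone_atoms <- function() {
  ln <- readLines(param_file("backbone_atoms.txt"))
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  trimws(ln)
}

aa3to1 <- function(resname) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  unname(map[resname])
}

aa1to3 <- function(aa) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  unname(map[aa])
}

amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' One-hot channel alphabet: the 20 amino acids (alphabetical) then the gap
#' @return Character vector of length 21.
#' @export
encoding_alphabet <- function() c(amino_acids(), "-")
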