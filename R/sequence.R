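#' Paired Fv sequence constructor
#'
#' @param name identifier.
#' @param heavy,light amino-acid strings (20-letter alphabet).
#' @return An `fv_pair` list.
#' @export
fv_pair <- function(name, heavy, light) {
  for (s in c(heavy, light))
    if (nzchar(s) && !grepl(paste0("^[", paste(amino_acids(), collapse = ""),
                                   "]+$"), s))
      stop("sequence contains characters outside the 20-letter alphabet")
  structure(list(name = name, heavy = heavy, light = light),
            class = "fv_pair")
}

#' Read paired Fv sequences from CSV
#'
#' Expects columns `Name`, `Heavy_Chain`, `Light_Chain` (case-insensitive;
#' `heavy`/`light` also accepted).
#'
#' @param path CSV file.
#' @return data.frame with columns name, heavy, light.
#' @export
read_fv_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("missing column (one of): ", paste(cands, collapse = ", "))
    df[[i]]
  }
  data.frame(name = as.character(pick(c("name", "id"))),
             heavy = toupper(pick(c("heavy_chain", "heavy"))),
             light = toupper(pick(c("light_chain", "light"))),
             stringsAsFactors = FALSE)
}

# ---- numbering templates -------------------------------------------------

template_meta <- function(chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  key <- paste0("tmpl_", chain)
  if (!is.null(.abprop[[key]])) return(.abprop[[key]])
  slots <- readLines(param_file(paste0("slots_", chain, ".txt")))
  slots <- trimws(slots[!grepl("^\\s*#", slots)])
  resno <- as.integer(sub("[A-Z]*$", "", slots))
  base <- !grepl("[A-Z]$", slots)
  bd <- cdr_boundaries()
  bd <- bd[bd$chain == chain, ]
  region <- rep("FR", length(slots))
  for (i in seq_len(nrow(bd)))
    region[resno >= bd$start[i] & resno <= bd$end[i]] <- bd$region[i]
  # framework insertion slots (e.g. heavy 35A/35B, 82A-C) are scheme
  # capacity only; the template aligner never fills them
  cdrs <- unique(region[region != "FR"])
  meta <- list(
    slots = slots, resno = resno, base = base, region = region,
    fr_idx = which(region == "FR" & base),
    cdr = lapply(setNames(cdrs, cdrs), function(r) {
      idx <- which(region == r)
      b <- idx[base[idx]]
      ins <- idx[!base[idx]]
      list(base_n = length(b), capacity = length(idx),
           activation = c(b, ins))  # base slots first, then insertions
    })
  )
  .abprop[[key]] <- meta
  meta
}

#' Align one chain onto its fixed-length scheme template
#'
#' Deterministic template aligner for canonical-framework sequences: the four
#' framework segments take their fixed template lengths, CDR1/CDR2 default to
#' their base lengths and the remaining residues are attributed to CDR3
#' (override with `cdr_lengths` when the true loop lengths are known). CDR
#' residues occupy base slots first, then insertion slots, in template order.
#'
#' @param seq amino-acid string.
#' @param chain `"heavy"` or `"light"`.
#' @param cdr_lengths optional named integer vector (the chain's three CDRs)
#'   overriding the inferred loop lengths.
#' @return list: `aligned` (fixed-length string, gaps as `-`), `positions`
#'   (named residue vector, names = occupied scheme slots), `cdr_lengths`,
#'   `reasons` (character, empty on success), `ok`.
#' @export
align_chain <- function(seq, chain = c("heavy", "light"), cdr_lengths = NULL) {
  chain <- match.arg(chain)
  tm <- template_meta(chain)
  fail <- function(reasons) list(aligned = NA_character_, positions = NULL,
                                 cdr_lengths = NULL, reasons = reasons,
                                 ok = FALSE)
  if (is.na(seq) || !nzchar(seq)) return(fail("NUMBERING_FAIL"))
  if (!grepl(paste0("^[", paste(amino_acids(), collapse = ""), "]+$"), seq))
    return(fail("NUMBERING_FAIL"))
  L <- nchar(seq)
  cdr_names <- names(tm$cdr)
  base_n <- vapply(tm$cdr, `[[`, 0L, "base_n")
  cap <- vapply(tm$cdr, `[[`, 0L, "capacity")
  fr_total <- length(tm$fr_idx)

  reasons <- character(0)
  if (is.null(cdr_lengths)) {
    len <- base_n
    len[3] <- L - fr_total - len[1] - len[2]
  } else {
    len <- cdr_lengths[cdr_names]
    if (sum(len) + fr_total != L) reasons <- c(reasons, "INSERTION")
  }
  if (any(len[1:2] > base_n[1:2])) reasons <- c(reasons, "INSERTION")
  h3 <- cdr_names[3]
  if (len[3] < 1 || any(len[1:2] < 1) || any(len > cap)) {
    code <- if (chain == "heavy" && !is.na(len[3]) && len[3] > cap[3])
      "CDRH3_TOO_LONG" else "NUMBERING_FAIL"
    return(fail(unique(c(reasons, code))))
  }
  if (sum(len) + fr_total != L) return(fail(unique(c(reasons, "NUMBERING_FAIL"))))

  occupied <- tm$fr_idx
  for (i in seq_along(cdr_names)) {
    act <- tm$cdr[[i]]$activation
    occupied <- c(occupied, act[seq_len(len[i])])
  }
  occupied <- sort(occupied)
  aligned <- rep("-", length(tm$slots))
  res <- strsplit(seq, "")[[1]]
  aligned[occupied] <- res
  list(aligned = paste(aligned, collapse = ""),
       positions = setNames(res, tm$slots[occupied]),
       cdr_lengths = setNames(as.integer(len), cdr_names),
       reasons = unique(reasons), ok = TRUE)
}

#' Number and align a paired Fv sequence to the 145 + 127 template
#'
#' @param pair an `fv_pair` (or list with `name`, `heavy`, `light`).
#' @param numberer chain-level numbering function with the signature of
#'   [align_chain()]; defaults to the bundled template aligner. Supply a
#'   wrapper around an external annotator for non-canonical frameworks.
#' @param heavy_cdr,light_cdr optional known CDR lengths per chain.
#' @return An `aligned_fv`: list with `heavy`, `light` (aligned strings of
#'   length 145 and 127), `positions`, `cdr_lengths`, `reasons`, `ok`.
#' @export
number_and_align <- function(pair, numberer = align_chain,
                             heavy_cdr = NULL, light_cdr = NULL) {
  h <- numberer(pair$heavy, "heavy", cdr_lengths = heavy_cdr)
  l <- numberer(pair$light, "light", cdr_lengths = light_cdr)
  structure(list(name = pair$name, heavy = h$aligned, light = l$aligned,
                 positions = list(heavy = h$positions, light = l$positions),
                 cdr_lengths = c(h$cdr_lengths, l$cdr_lengths),
                 reasons = unique(c(h$reasons, l$reasons)),
                 ok = h$ok && l$ok),
            class = "aligned_fv")
}

#' Apply the sequence inclusion filters
#'
#' Reason codes are accumulated, never short-circuited: `UNPAIRED` (an empty
#' chain), `DUPLICATE` (exact heavy+light pair already seen),
#' `NUMBERING_FAIL`, `INSERTION` (insertions outside the loops the template
#' affords / non-canonical framework), `CDRH3_TOO_LONG` (heavy CDR3 over the
#' 30-residue template capacity), `CYS_MISSING` (no cysteine at scheme
#' positions 23 and 104 of each chain).
#'
#' @param pair the `fv_pair`.
#' @param aligned the corresponding [number_and_align()] result.
#' @param seen character vector of previously seen `"heavy|light"` keys.
#' @param strict_cys reject cysteines at positions other than 23/104
#'   (default FALSE: extras are tolerated).
#' @return A `filter_report`: list(pass, reasons, key).
#' @export
apply_filters <- function(pair, aligned, seen = character(),
                          strict_cys = FALSE) {
  reasons <- character(0)
  if (!nzchar(pair$heavy) || !nzchar(pair$light))
    reasons <- c(reasons, "UNPAIRED")
  key <- paste(pair$heavy, pair$light, sep = "|")
  if (key %in% seen) reasons <- c(reasons, "DUPLICATE")
  reasons <- c(reasons, aligned$reasons)
  if (aligned$ok) {
    for (ch in c("heavy", "light")) {
      pos <- aligned$positions[[ch]]
      if (!identical(unname(pos["23"]), "C") ||
          !identical(unname(pos["104"]), "C"))
        reasons <- c(reasons, "CYS_MISSING")
      extra <- setdiff(names(pos)[pos == "C"], c("23", "104"))
      if (length(extra) > 0 && strict_cys)
        reasons <- c(reasons, "CYS_MISSING")
    }
  }
  reasons <- unique(reasons)
  structure(list(pass = length(reasons) == 0, reasons = reasons, key = key),
            class = "filter_report")
}

# ---- one-hot encoding ----------------------------------------------------

#' One-hot encode an aligned Fv pair
#'
#' Concatenates the aligned heavy (145) and light (127) chains and encodes
#' each of the 272 positions over 21 channels: the 20 amino acids in
#' alphabetical one-letter order, then the gap. Exactly one channel is active
#' per position.
#'
#' @param aligned an `aligned_fv`, or a list with `heavy` and `light`
#'   aligned strings.
#' @return `272 x 21` binary matrix (rownames scheme slots, colnames the
#'   channel alphabet).
#' @export
one_hot_encode <- function(aligned) {
  if (is.na(aligned$heavy) || is.na(aligned$light))
    stop("cannot encode a failed alignment")
  stopifnot(nchar(aligned$heavy) == 145, nchar(aligned$light) == 127)
  chars <- c(strsplit(aligned$heavy, "")[[1]], strsplit(aligned$light, "")[[1]])
  alpha <- encoding_alphabet()
  idx <- match(chars, alpha)
  if (anyNA(idx))
    stop("character outside the encoding alphabet: ",
         chars[which(is.na(idx))[1]])
  m <- matrix(0L, length(chars), length(alpha),
              dimnames = list(c(paste0("H", template_meta("heavy")$slots),
                                paste0("L", template_meta("light")$slots)),
                              alpha))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot matrix back to the aligned heavy/light strings
#' @param m a `272 x 21` one-hot matrix from [one_hot_encode()].
#' @return list with `heavy` and `light` aligned strings.
#' @export
decode_one_hot <- function(m) {
  stopifnot(nrow(m) == 272, ncol(m) == 21)
  if (!all(rowSums(m) == 1)) stop("not a one-hot matrix")
  chars <- encoding_alphabet()[max.col(m)]
  list(heavy = paste(chars[1:145], collapse = ""),
       light = paste(chars[146:272], collapse = ""))
}

#' Align, filter and encode a table of paired sequences
#'
#' @param pairs data.frame with columns name, heavy, light.
#' @param drop_duplicates flag exact repeated pairs as DUPLICATE.
#' @return list: `x` (array `n_pass x 272 x 21`), `report` (data.frame with
#'   name, pass, reasons), `aligned` (list of `aligned_fv` for passing rows).
#' @export
encode_pairs <- function(pairs, drop_duplicates = TRUE) {
  n <- nrow(pairs)
  seen <- character(0)
  reports <- vector("list", n)
  aligned_ok <- list()
  mats <- list()
  for (i in seq_len(n)) {
    p <- fv_pair(pairs$name[i], pairs$heavy[i], pairs$light[i])
    al <- number_and_align(p)
    rep_i <- apply_filters(p, al, seen = if (drop_duplicates) seen else character(0))
    if (drop_duplicates) seen <- c(seen, rep_i$key)
    reports[[i]] <- data.frame(name = p$name, pass = rep_i$pass,
                               reasons = paste(rep_i$reasons, collapse = ";"),
                               stringsAsFactors = FALSE)
    if (rep_i$pass) {
      aligned_ok[[length(aligned_ok) + 1]] <- al
      mats[[length(mats) + 1]] <- one_hot_encode(al)
    }
  }
  x <- array(0L, dim = c(length(mats), 272, 21))
  for (j in seq_along(mats)) x[j, , ] <- mats[[j]]
  list(x = x, report = do.call(rbind, reports), aligned = aligned_ok)
}
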