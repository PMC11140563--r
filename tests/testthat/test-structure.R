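test_that("bundled charge table sums to formal charges per residue", {
  ct <- charge_table()
  sums <- tapply(ct$charges$charge, ct$charges$resname, sum)
  expect_true(all(abs(sums - ct$formal[names(sums)]) < 1e-6))
  # protonation convention: His carries +1, the acids -1
  expect_equal(unname(ct$formal[c("HIS", "LYS", "ARG")]), c(1, 1, 1))
  expect_equal(unname(ct$formal[c("ASP", "GLU")]), c(-1, -1))
})

test_that("multi-MODEL files parse into snapshots; malformed input errors", {
  s <- make_toy_structure("pair_frames")$structure
  path <- tempfile(fileext = ".pdb")
  write_pdb_structure(s, path)
  p <- parse_pdb(path, c(H = "heavy", L = "light"))
  expect_equal(dim(p$coords)[3], 3)
  expect_equal(nrow(p$atoms), 2)

  single <- make_toy_structure("pair_close")$structure
  path1 <- tempfile(fileext = ".pdb")
  write_pdb_structure(single, path1)
  p1 <- parse_pdb(path1, c(H = "heavy", L = "light"))
  expect_equal(dim(p1$coords)[3], 1)

  # malformed ATOM record is reported with its line number
  lines <- readLines(path1)
  atom_line <- grep("^ATOM", lines)[1]
  lines[atom_line] <- substr(lines[atom_line], 1, 40)
  bad <- tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(parse_pdb(bad, c(H = "heavy", L = "light")),
               paste0("line ", atom_line))

  # undeclared chain
  expect_error(parse_pdb(path1, c(H = "heavy")), "without a declared role")

  # snapshot with a missing atom names the mismatch
  lines <- readLines(path)
  drop_line <- grep("^ATOM", lines)[4]  # second model, second atom
  writeLines(lines[-drop_line], bad)
  expect_error(parse_pdb(bad, c(H = "heavy", L = "light")), "inconsistent")
})

test_that("round-trip write/parse preserves serials, names and coordinates", {
  s <- random_cluster(12, seed = 3)
  path <- tempfile(fileext = ".pdb")
  write_pdb_structure(s, path)
  p <- parse_pdb(path, c(H = "heavy", L = "light"))
  expect_equal(p$atoms$serial, s$atoms$serial)
  expect_equal(p$atoms$name, s$atoms$name)
  expect_equal(p$coords, s$coords, tolerance = 1e-3)
})

test_that("assign_parameters fills charges/radii and enforces completeness", {
  ct <- charge_table()
  mk_res <- function(resname, chain, role, resno, x0) {
    atoms <- ct$atoms[[resname]]
    data.frame(chain = chain, role = role, resno = resno, resname = resname,
               name = atoms, x = x0 + seq_along(atoms) * 0.9, y = 0, z = 0,
               charge = 0, radius = 0)
  }
  df <- rbind(mk_res("HIS", "H", "heavy", 1, 0),
              mk_res("ALA", "L", "light", 1, 40))
  s <- toy_structure(df, name = "his_ala")
  s <- assign_parameters(s)
  his_sum <- sum(s$atoms$charge[s$atoms$resname == "HIS"])
  ala_sum <- sum(s$atoms$charge[s$atoms$resname == "ALA"])
  expect_equal(his_sum, 1, tolerance = 1e-6)     # protonated at formulation pH
  expect_equal(ala_sum, 0, tolerance = 1e-6)
  expect_true(all(s$atoms$radius > 0))
  expect_equal(total_charge(s), 1, tolerance = 1e-6)

  # unknown atom name errors in strict mode, is skipped in permissive mode
  df_bad <- df
  df_bad$name[1] <- "XX1"
  s_bad <- toy_structure(df_bad, name = "bad")
  expect_error(assign_parameters(s_bad), "XX1")
  expect_message(s_perm <- assign_parameters(s_bad, strict = FALSE), "XX1")
  expect_lt(attr(s_perm, "coverage"), 1)

  # incomplete residue (heavy atoms only) errors in strict mode
  df_heavy <- df[!grepl("^H", df$name) | df$name == "HIS", ]
  df_heavy <- df[substr(df$name, 1, 1) != "H", ]
  s_heavy <- toy_structure(df_heavy, name = "noH")
  expect_error(assign_parameters(s_heavy), "missing atom")
  expect_silent(assign_parameters(s_heavy, strict = FALSE))
})

test_that("terminal patches shift the formal charge by one unit", {
  ct <- charge_table()
  atoms <- ct$atoms[["ALA"]]
  df <- data.frame(chain = "H", role = "heavy", resno = 1, resname = "ALA",
                   name = atoms, x = seq_along(atoms) * 0.9, y = 0, z = 0,
                   charge = 0, radius = 0)
  # C-terminal alanine: O replaced by OT1/OT2
  df_ct <- df[df$name != "O", ]
  df_ct <- rbind(df_ct,
                 transform(df_ct[1:2, ], name = c("OT1", "OT2"),
                           x = c(90, 91)))
  s <- toy_structure(df_ct, name = "cter")
  s <- assign_parameters(s, cter = "H:1")
  expect_equal(total_charge(s), -1, tolerance = 1e-6)
})

test_that("domain assignment respects CDR intervals and partitions", {
  s <- scored_fixture()$structure     # residues H30, H96, H60, L91, L60
  dm <- assign_domains(s)
  m <- attr(dm, "membership")
  expect_setequal(rownames(m)[m[, "CDRH1"]], "H:30")
  expect_setequal(rownames(m)[m[, "CDRH3"]], "H:96")
  expect_setequal(rownames(m)[m[, "CDRL3"]], "L:91")
  expect_false(any(m["H:60", paste0("CDR", c("H1", "H2", "H3"))]))
  # framework residue maps to chain + Fv only
  expect_setequal(colnames(m)[m["H:60", ]], c("Hv", "Fv"))
  # partition invariants
  expect_true(all(m[, "Fv"]))
  expect_true(all(xor(m[, "Hv"], m[, "Lv"])))
  cdrx <- m[, paste0("CDR", c("H1", "H2", "H3", "L1", "L2", "L3"))]
  expect_true(all(rowSums(cdrx) <= 1))          # pairwise disjoint
  expect_equal(m[, "CDR"], rowSums(cdrx) > 0)   # CDR is exactly the union
  # out-of-range residue number
  bad <- s
  bad$atoms$resno[1] <- 200
  bad$atoms$key[1] <- "H:200"
  expect_error(assign_domains(bad), "outside")
})
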