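test_that("PDB round trip preserves atoms, coordinates and waters", {
  fx <- cav_pair()
  cx <- fx$complex
  cx$ligand <- pair_ligand(TRUE)
  cx$waters <- rbind(make_water(c(0, 0, 0)), make_water(c(3, 0, 0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$receptor$atoms), nrow(cx$receptor$atoms))
  expect_equal(nrow(back$ligand$atoms), nrow(cx$ligand$atoms))
  expect_equal(nrow(back$waters), 2)
  # coordinates survive the fixed-width format to 1e-3 A
  expect_lt(max(abs(coords(back$receptor) - coords(cx$receptor))), 1e-3)
  expect_lt(max(abs(as.matrix(back$waters[, 1:9]) -
                    as.matrix(cx$waters[, 1:9]))), 2e-3)
  # each water contributes three records
  lines <- readLines(path)
  expect_equal(sum(grepl("HOH", lines)), 6)
})

test_that("ligand detection picks the largest non-water het group", {
  path <- withr::local_tempfile(fileext = ".pdb")
  cx <- cav_pair()$complex
  cx$ligand <- pair_ligand(TRUE)
  write_pdb(cx, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$ligand$atoms), nrow(cx$ligand$atoms))
  expect_true(all(back$ligand$atoms$resname == "LIG"))
})

test_that("empty and malformed PDB input raise errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_pdb(empty), "empty")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1     bad     0.000   0.000"),
             bad)
  expect_error(read_pdb(bad), "line")
  expect_error(write_pdb(new_complex(new_structure(empty_atoms())),
                         withr::local_tempfile()), "empty")
})

test_that("atom typing assigns chemically forced roles", {
  at <- data.frame(serial = 1:4,
                   name = c("O", "CB", "OG", "N"),
                   element = c("O", "C", "O", "N"),
                   resname = c("ALA", "ALA", "SER", "PRO"),
                   resno = c(1L, 1L, 2L, 3L), chain = "A",
                   x = c(0, 2, 4, 6), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  st <- assign_atom_types(new_structure(at))
  expect_equal(st$atoms$hbond_role,
               c("acceptor", "none", "both", "none"))
  expect_equal(st$atoms$vdw_class[2], "carbon_sp3")
  # carbon atoms are never donors or acceptors anywhere in the table
  tab <- yaml::read_yaml(system.file("extdata", "atom_types.yaml",
                                     package = "hydrosite"))
  for (res in tab$residues) {
    for (entry in res) {
      if (startsWith(entry$vdw, "carbon")) expect_equal(entry$hb, "none")
    }
  }
  # unknown residue/atom with unknown element errors, naming the atom
  at$name[1] <- "XX1"; at$resname[1] <- "UNK"; at$element[1] <- "XX"
  expect_error(assign_atom_types(new_structure(at)), "XX1")
})

test_that("alanine mutation trims the side chain and nothing else", {
  # full leucine residue with backbone
  at <- data.frame(
    serial = 1:8,
    name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C"),
    resname = "LEU", resno = 7L, chain = "A",
    x = c(0, 1.4, 2.4, 3.5, 1.6, 2.8, 3.9, 2.6),
    y = c(0, 0.3, -0.5, -0.2, 1.8, 2.5, 2.0, 4.0), z = 0,
    stringsAsFactors = FALSE)
  rec <- assign_atom_types(new_structure(at))
  cx <- new_complex(rec)
  mut <- mutate_to_alanine(cx, "A", 7)
  a <- mut$receptor$atoms
  expect_setequal(a$name, c("N", "CA", "C", "O", "CB"))
  expect_true(all(a$resname == "ALA"))
  # backbone coordinates untouched, exactly
  expect_identical(a$x[a$name == "CA"], 1.4)
  expect_false(isTRUE(attr(mut, "noop")))
  # ALA -> ALA is a flagged no-op; GLY has no side chain to trim
  expect_true(attr(mutate_to_alanine(mut, "A", 7), "noop"))
  at_gly <- at[1:4, ]; at_gly$resname <- "GLY"
  cx_gly <- new_complex(assign_atom_types(new_structure(at_gly)))
  expect_error(mutate_to_alanine(cx_gly, "A", 7), "GLY")
  expect_error(mutate_to_alanine(cx, "B", 7), "not found")
})

test_that("serine-host mutation removes one H-bond-capable heavy atom", {
  fx <- cav_pair()
  cx <- fx$complex
  n_polar_before <- sum(cx$receptor$atoms$hbond_role != "none" &
                        cx$receptor$atoms$is_heavy)
  mut <- mutate_to_alanine(cx, "A", fx$manifest$host_resno[1])
  n_polar_after <- sum(mut$receptor$atoms$hbond_role != "none" &
                       mut$receptor$atoms$is_heavy)
  expect_equal(n_polar_before - n_polar_after, 1)
})

test_that("pseudo-apo removes the ligand only", {
  cx <- holo_complex(TRUE)
  apo <- make_pseudo_apo(cx)
  expect_null(apo$ligand)
  expect_identical(apo$receptor$atoms, cx$receptor$atoms)
  expect_error(make_pseudo_apo(apo), "already apo")
})

test_that("strip_substituent removes a terminal methyl and caps the bond", {
  lig <- pair_ligand(TRUE)
  cm <- lig$atoms$serial[lig$atoms$name == "CM"]
  stripped <- strip_substituent(lig, cm)
  expect_equal(sum(stripped$atoms$is_heavy), sum(lig$atoms$is_heavy) - 1)
  expect_equal(sum(!stripped$atoms$is_heavy), 1)  # the new cap hydrogen
  # all surviving heavy atoms are bit-identical
  keep <- lig$atoms$serial != cm
  expect_identical(lig$atoms[keep, c("x", "y", "z")],
                   stripped$atoms[stripped$atoms$is_heavy,
                                  c("x", "y", "z")])
  # attachment carbon keeps its aliphatic class
  expect_equal(
    stripped$atoms$vdw_class[stripped$atoms$serial == cm - 1],
    "carbon_sp3")
  # a mid-chain atom is not terminal
  mid <- lig$atoms$serial[lig$atoms$name == "C3"]
  expect_error(strip_substituent(lig, mid), "not terminal")
})
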