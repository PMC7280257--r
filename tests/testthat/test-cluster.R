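# Contact search, cluster assembly and the XYZ / QM-input writers.

# hand-built structure: one ligand atom at the origin, two protein atoms on
# the x axis at 3.5 and 3.51 A
boundary_pdb <- paste(
  "ATOM      1  CA  GLY A   1       3.500   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       3.510   0.000   0.000  1.00  0.00           C",
  "HETATM    3  C1  LIG A 900       0.000   0.000   0.000  1.00  0.00           C",
  sep = "\n")

test_that("the contact cutoff is inclusive at the boundary", {
  mod <- parse_structure(boundary_pdb)
  con <- find_contacts(mod, "LIG", cutoff = 3.5)
  expect_equal(nrow(con), 1)
  expect_equal(con$res_seq, 1)
  expect_equal(con$distance, 3.5)
})

test_that("waters and non-amino-acid het groups are never contacts", {
  txt <- paste(
    "ATOM      1  CA  GLY A   1       2.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 501       1.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3 ZN    ZN A 502       0.000   1.000   0.000  1.00  0.00          ZN",
    "HETATM    4  C1  LIG A 900       0.000   0.000   0.000  1.00  0.00           C",
    sep = "\n")
  con <- find_contacts(parse_structure(txt), "LIG", cutoff = 3.5)
  expect_equal(con$res_name, "GLY")
  expect_equal(nrow(con), 1)
})

test_that("contact search equals the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    n_res <- 2 + (seed %% 5)
    dists <- round(runif(n_res, 1.8, 5.5), 3)
    txt <- make_toy_structure(n_res, dists, ligand_size = 4, seed = seed)
    mod <- parse_structure(txt)
    for (cutoff in c(2.5, 3.5, 4.5)) {
      got <- find_contacts(mod, "LIG", cutoff = cutoff)
      ref <- brute_force_contacts(mod, "LIG", cutoff)
      expect_equal(got$ligand_serial, ref$ligand_serial)
      expect_equal(got$protein_serial, ref$protein_serial)
      expect_equal(got$distance, ref$distance)
    }
  }
})

test_that("contact sets are monotone in the cutoff", {
  txt <- make_toy_structure(5, c(2.0, 2.8, 3.4, 4.1, 5.0), seed = 9)
  mod <- parse_structure(txt)
  key <- function(con) paste(con$ligand_serial, con$protein_serial)
  prev <- character(0)
  for (cutoff in c(1, 2, 3, 4, 5, 6)) {
    cur <- key(find_contacts(mod, "LIG", cutoff = cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("rosters are invariant under atom-order permutation of the file", {
  txt <- make_toy_structure(4, c(2.1, 3.2, 3.45, 4.8), seed = 21)
  lines <- strsplit(txt, "\n")[[1]]
  atoms <- grep("^(ATOM|HETATM)", lines)
  set.seed(99)
  shuffled <- c(lines[sample(atoms)], "END")
  r1 <- build_cluster(parse_structure(txt), "LIG")$roster
  r2 <- build_cluster(parse_structure(shuffled), "LIG")$roster
  expect_equal(r1, r2)
})

test_that("planted residues inside the cutoff are selected, others omitted", {
  txt <- make_toy_structure(3, c(2.0, 3.4, 3.6), seed = 7)
  cl <- build_cluster(parse_structure(txt), "LIG", cutoff = 3.5)
  expect_equal(cl$roster$res_seq, c(1, 2))
  # whole residues: all 5 atoms of each contacting residue, none of residue 3
  expect_equal(nrow(cl$protein), 10)
  expect_equal(sort(unique(cl$protein$res_seq)), c(1, 2))
  expect_equal(nrow(cl$ligand), 5)
})

test_that("degenerate cutoff and wrong ligand raise clear errors", {
  txt <- make_toy_structure(2, c(2.0, 3.0), seed = 5)
  mod <- parse_structure(txt)
  expect_error(build_cluster(mod, "LIG", cutoff = 0), "empty cluster")
  expect_error(find_contacts(mod, "XYZ"), "available heterogroups.*LIG")
})

test_that("clusters built for different ligands have disjoint ligand fragments", {
  t1 <- make_toy_structure(2, c(2.0, 3.0), seed = 31)
  # second heterogroup far away plus its own contacting residue
  extra <- paste(
    "ATOM    900  CA  GLY A  50      52.000  50.000  50.000  1.00  0.00           C",
    "HETATM  901  C1  XYZ A 901      50.000  50.000  50.000  1.00  0.00           C",
    sep = "\n")
  lines <- strsplit(t1, "\n")[[1]]
  txt <- paste(c(setdiff(lines, "END"), extra, "END"), collapse = "\n")
  mod <- parse_structure(txt)
  c1 <- build_cluster(mod, "LIG", cutoff = 3.5)
  c2 <- build_cluster(mod, "XYZ", cutoff = 3.5)
  expect_length(intersect(c1$ligand$serial, c2$ligand$serial), 0)
  expect_equal(c2$roster$res_seq, 50)
})

test_that("XYZ output has a correct count header and round-trips", {
  txt <- make_toy_structure(2, c(2.0, 3.0), ligand_size = 3, seed = 13)
  cl <- build_cluster(parse_structure(txt), "LIG")
  xyz <- write_xyz(cl)
  lines <- strsplit(xyz, "\n")[[1]]
  n <- nrow(cl$protein) + nrow(cl$ligand)
  expect_equal(as.integer(lines[1]), n)
  expect_equal(length(lines), n + 2)
  back <- read_xyz(xyz)
  orig <- rbind(cl$protein, cl$ligand)
  expect_equal(back$x, orig$x, tolerance = 1e-6)
  expect_equal(back$y, orig$y, tolerance = 1e-6)
  expect_equal(back$z, orig$z, tolerance = 1e-6)
  expect_equal(back$element, orig$element)
  # second round trip is byte-identical (idempotence)
  cl2 <- cl
  cl2$protein[c("x", "y", "z")] <- back[seq_len(nrow(cl$protein)), c("x", "y", "z")]
  cl2$ligand[c("x", "y", "z")] <-
    back[-seq_len(nrow(cl$protein)), c("x", "y", "z")]
  expect_identical(write_xyz(cl2, comment = "c"), write_xyz(cl, comment = "c"))
})

test_that("QM-LED input decks assign every atom to exactly one fragment", {
  txt <- make_toy_structure(2, c(2.0, 3.0), seed = 17)
  cl <- build_cluster(parse_structure(txt), "LIG")
  deck <- write_qm_input(cl, qm_settings(charge = 0, mult = 1))
  lines <- strsplit(deck, "\n")[[1]]
  expect_match(lines[1], "DLPNO-CCSD\\(T\\)")
  expect_match(lines[1], "def2-SVP")
  expect_match(lines[1], "LED")
  atom_lines <- grep("^  [A-Z]+\\(\\d\\)", lines, value = TRUE)
  expect_length(atom_lines, nrow(cl$protein) + nrow(cl$ligand))
  frags <- as.integer(sub("^  [A-Z]+\\((\\d)\\).*", "\\1", atom_lines))
  expect_equal(sum(frags == 1), nrow(cl$protein))
  expect_equal(sum(frags == 2), nrow(cl$ligand))
  expect_true(all(tail(frags, nrow(cl$ligand)) == 2))
})

test_that("missing charge/multiplicity falls back to 0/1 with a warning", {
  txt <- make_toy_structure(1, 2.5, seed = 19)
  cl <- build_cluster(parse_structure(txt), "LIG")
  expect_warning(deck <- write_qm_input(cl, qm_settings()),
                 "charge/multiplicity")
  expect_match(deck, "\\* xyz 0 1")
  expect_silent(write_qm_input(cl, qm_settings(charge = -1, mult = 2)))
})
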