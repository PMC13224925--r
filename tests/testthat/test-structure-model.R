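# Structure reading, writing and normalization policies.

test_that("fixture round-trips through PDB with coordinates at format precision", {
  s <- helix_hairpin(entry_id = "RT01", title = "ROUND TRIP FIXTURE",
                     keywords = c("SOLUBLE PROTEIN"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(chains(s2), "A")
  expect_equal(s2$resno, s$resno)
  expect_equal(s2$x, s$x, tolerance = 1e-9)  # writer already rounds to 1e-3
  expect_equal(s2$b, s$b)
  expect_equal(structure_metadata(s2)$title, "ROUND TRIP FIXTURE")
  # second round trip is a fixed point
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("fixture round-trips through mmCIF including helix annotation", {
  s <- helix_hairpin(entry_id = "RT02")
  f <- withr::local_tempfile(fileext = ".cif")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(entry_id(s2), "RT02")
  expect_equal(s2$resno, s$resno)
  expect_equal(s2$x, s$x, tolerance = 1e-9)
  expect_equal(annotated_helices(s2, "A"), annotated_helices(s, "A"))
})

test_that("only model 1 of a multi-model file is kept", {
  lines <- c("MODEL        1",
             sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                     1:6, 1:6, (1:6) * 1.5, 0, 0, 1, 90),
             "ENDMDL", "MODEL        2",
             sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                     1:6, 1:6, (1:6) * 1.5, 9, 9, 1, 90),
             "ENDMDL", "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f)
  expect_equal(nrow(s), 6)
  expect_true(all(s$y == 0))
})

test_that("altloc resolution keeps the highest occupancy, ties alphabetical", {
  mk <- function(alt, occ, x) {
    sprintf("ATOM      1  CA %sALA A  10    %8.3f   0.000   0.000%6.2f 90.00           C",
            alt, x, occ)
  }
  base <- sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                  1:6, 1:6, (1:6) * 1.5, 0, 0, 1, 90)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(base, mk("A", 0.4, 10), mk("B", 0.6, 11), "END"), f)
  s <- read_structure(f)
  # brute-force expectation: the max-occupancy altloc
  expect_equal(s$x[s$resno == 10], 11)
  # tie goes to the alphabetically first id
  writeLines(c(base, mk("B", 0.5, 11), mk("A", 0.5, 10), "END"), f)
  s <- read_structure(f)
  expect_equal(s$x[s$resno == 10], 10)
  expect_equal(s$alt[s$resno == 10], "A")
})

test_that("strip_nonpolymer removes waters and ligands, keeps polymer, idempotent", {
  s <- helix_hairpin(entry_id = "HET1")
  n_poly <- nrow(s)
  het <- tibble::tibble(
    chain = "A", resno = c(101:105, 201), icode = "",
    resid = c(rep("HOH", 5), "LIG"),
    elety = c(rep("O", 5), "C1"), element = c(rep("O", 5), "C"),
    x = 50 + 1:6, y = 0, z = 0, occ = 1, b = 30, alt = "", polymer = FALSE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(helixfuse:::new_structure_model(
    dplyr::bind_rows(tibble::as_tibble(s), het),
    entry_id = "HET1", helix = attr(s, "helix")), f)
  s2 <- read_structure(f)
  expect_equal(sum(!s2$polymer), 6)
  stripped <- strip_nonpolymer(s2)
  expect_equal(nrow(stripped), n_poly)
  expect_equal(stripped$resno, s$resno)            # order untouched
  expect_identical(strip_nonpolymer(stripped), stripped)  # idempotent
})

test_that("modified residues stay in the polymer with parent one-letter code", {
  s <- helix_hairpin()
  tb <- tibble::as_tibble(s)
  tb$resid[tb$resno == 3] <- "MSE"
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(helixfuse:::new_structure_model(tb, entry_id = "MSE1"), f)
  s2 <- read_structure(f)
  expect_true(s2$polymer[s2$resno == 3])
  expect_equal(substr(model_sequence(s2, "A"), 3, 3), "M")
})

test_that("annotated helices echo the records and clip to present residues", {
  s <- helix_hairpin(len_n = 12, len_c = 12, loop_len = 4)
  hx <- annotated_helices(s, "A")
  expect_equal(hx$length, c(12, 12))
  # annotation referencing residues missing from the coordinates is clipped:
  # drop residues 1-2 and the span should start at 3 (set-intersection)
  s_cut <- helixfuse:::new_structure_model(
    dplyr::filter(tibble::as_tibble(s), resno > 2),
    entry_id = "CUT", helix = attr(s, "helix"))
  hx2 <- annotated_helices(s_cut, "A")
  expect_equal(hx2$start[1], 3)
  expect_equal(hx2$length[1], length(intersect(3:28, 1:12)))
  # no records -> empty
  s_bare <- helix_hairpin(annotate = FALSE)
  expect_equal(nrow(annotated_helices(s_bare, "A")), 0)
})

test_that("reader rejects garbage, empty structures, unknown chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), f)
  expect_error(read_structure(f), class = "hf_data_error")
  expect_error(read_structure(tempfile()), class = "hf_io_error")
  s <- helix_hairpin()
  expect_error(annotated_helices(s, "Z"), class = "hf_data_error")
})

test_that("PDB writer refuses residue numbers beyond the fixed-width format", {
  s <- helix_hairpin()
  tb <- tibble::as_tibble(s)
  tb$resno <- tb$resno + 10000L
  big <- helixfuse:::new_structure_model(tb, entry_id = "BIG")
  expect_error(write_structure(big, tempfile(fileext = ".pdb")),
               "mmCIF", class = "hf_data_error")
  # but the mmCIF dialect takes it
  f <- withr::local_tempfile(fileext = ".cif")
  expect_silent(write_structure(big, f))
  expect_equal(min(read_structure(f)$resno), 10001)
})

test_that("metadata scan picks up title, keywords, assembly size and organism", {
  s <- helix_hairpin()
  lines <- c("TITLE     A DIMERIC TEST PROTEIN",
             "KEYWDS    HYDROLASE, THERMOPHILE",
             "SOURCE    ORGANISM_SCIENTIFIC: THERMUS THERMOPHILUS;",
             "REMARK 350 BIOMOLECULE: 1",
             "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A, B",
             "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
             "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
             "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000")
  f <- withr::local_tempfile(fileext = ".pdb")
  body <- helixfuse:::format_pdb(s)
  writeLines(c(lines, body), f)
  md <- structure_metadata(read_structure(f))
  expect_equal(md$title, "A DIMERIC TEST PROTEIN")
  expect_equal(md$keywords, c("HYDROLASE", "THERMOPHILE"))
  expect_equal(md$oligomer_count, 2L)
  expect_equal(md$organism, "THERMUS THERMOPHILUS")
  # absent records -> unknown, never guessed
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(body, f2)
  md2 <- structure_metadata(read_structure(f2))
  expect_true(is.na(md2$oligomer_count))
  expect_true(is.na(md2$organism))
})
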