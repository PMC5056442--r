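test_that("PDB round-trip preserves numbering, names and coordinates", {
  ch <- make_domain_chain(c(100, 110, 120, 130), seed = 7)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, tmp)
  back <- load_structure(tmp)
  expect_equal(back$atoms$resno, ch$atoms$resno)
  expect_equal(back$atoms$resid, ch$atoms$resid)
  expect_equal(back$atoms$chain, ch$atoms$chain)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                    as.matrix(ch$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("round-trip preserves insertion codes and chain order", {
  atoms <- rbind(
    data.frame(chain = "B", resno = c(5L, 5L, 6L), insert = c("", "A", ""),
               resid = "ALA", elety = "CA",
               x = c(0, 1, 2), y = 0, z = 0, occ = 1, alt = ""),
    data.frame(chain = "A", resno = 1:3, insert = "", resid = "GLY",
               elety = "CA", x = c(5, 6, 7), y = 1, z = 1, occ = 1, alt = "")
  )
  s <- bam_structure("ins", atoms)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tmp)
  back <- load_structure(tmp)
  expect_equal(structure_chains(back), c("B", "A"))
  bb <- back$atoms[back$atoms$chain == "B", ]
  expect_equal(bb$insert, c("", "A", ""))
  expect_equal(bb$resno, c(5L, 5L, 6L))
})

test_that("altloc resolution keeps highest occupancy, ties by letter", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "A", "ALA", "A", 1, " ", 1, 0, 0, 0.40),
    pdb_line(2, "CA", "B", "ALA", "A", 1, " ", 2, 0, 0, 0.60),
    pdb_line(3, "CA", "A", "GLY", "A", 2, " ", 3, 0, 0, 0.50),
    pdb_line(4, "CA", "B", "GLY", "A", 2, " ", 4, 0, 0, 0.50),
    "END"), tmp)
  s <- load_structure(tmp)
  expect_equal(nrow(s$atoms), 2L)
  ## residue 1: B wins on occupancy; residue 2: tie broken by letter -> A
  expect_equal(s$atoms$x[s$atoms$resno == 1], 2)
  expect_equal(s$atoms$x[s$atoms$resno == 2], 3)
})

test_that("mmCIF files load with author numbering", {
  ch <- make_domain_chain(c(100, 110, 120, 130))
  tmp <- withr::local_tempfile(fileext = ".cif")
  write_mini_cif(ch, tmp)
  s <- suppressWarnings(load_structure(tmp))
  expect_equal(s$source_format, "mmcif")
  expect_equal(s$atoms$resno, POTRA_ANCHORS)
  expect_lt(max(abs(s$atoms$x - ch$atoms$x)), 1e-3)
})

test_that("unparseable and empty inputs error informatively", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb file", tmp)
  expect_error(load_structure(tmp))
  expect_error(load_structure("no/such/file.pdb"), "not found")
  expect_error(bam_structure("empty", data.frame(
    chain = character(0), resno = integer(0), resid = character(0),
    elety = character(0), x = numeric(0), y = numeric(0), z = numeric(0))),
    "empty")
})

test_that("resolve_selection is total: hits plus missing cover the request", {
  ch <- straight_chain(10, chain = "A", resno_start = 20L)
  ## drop residue 24 to emulate an unmodelled anchor
  ch$atoms <- ch$atoms[ch$atoms$resno != 24L, ]
  r <- resolve_selection(ch, selection("A", c(21, 24, 27)))
  expect_equal(r$resno, c(21L, 27L))
  expect_equal(r$missing, 24L)
  expect_equal(nrow(r$points) + length(r$missing), 3)
  ## range overlapping the gap reports exactly the gap members
  r2 <- resolve_selection(ch, selection("A", 22:26))
  expect_equal(r2$missing, 24L)
  ## absent chain errors; absent atom name lands in missing
  expect_error(resolve_selection(ch, selection("Z", 21)), "chain")
  r3 <- resolve_selection(ch, selection("A", 21, atom = "CB"))
  expect_equal(r3$missing, 21L)
})

test_that("selection strings parse ranges, lists and atom names", {
  sp <- parse_selection("A:24,93,175,266,345,421:CA")
  expect_equal(sp$residues, POTRA_ANCHORS)
  expect_equal(sp$atom, "CA")
  sp2 <- parse_selection("D:100-103")
  expect_equal(sp2$residues, 100:103)
  sp3 <- parse_selection("E:all:CB")
  expect_null(sp3$residues)
  expect_equal(sp3$atom, "CB")
  expect_error(parse_selection("A"), "CHAIN")
  expect_error(parse_selection("A:x"), "residue")
})
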