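test_that("FASTA round trip preserves sequences and header metadata", {
  path <- write_fasta(c(">p1 role=HA_RAMP", "gigkflk",
                        ">p2 role=cTP cleavage=5 family=demo helix=2-6",
                        "ACDEFGHIK"))
  ps <- readPeptides(path)
  expect_s4_class(ps, "PeptideSet")
  expect_identical(length(ps), 2L)
  expect_identical(unname(aaSequences(ps)[1]), "GIGKFLK")  # uppercased
  expect_identical(unname(peptideRoles(ps)), c("HA_RAMP", "cTP"))
  expect_identical(unname(cleavageIndex(ps)), c(NA_integer_, 5L))
  expect_identical(helixSpan(ps)$helix_start, c(NA_integer_, 2L))

  out <- tempfile(fileext = ".fasta")
  writePeptides(ps, out)
  back <- readPeptides(out)
  expect_identical(aaSequences(back), aaSequences(ps))
  expect_identical(cleavageIndex(back), cleavageIndex(ps))
  expect_identical(unname(peptideFamilies(back)), c(NA, "demo"))
})

test_that("the packaged synthetic library has the 17 canonical records", {
  lib <- readPeptides(fig1_path())
  expect_identical(length(lib), 17L)
  roles <- table(peptideRoles(lib))
  expect_identical(unname(roles[["HA_RAMP"]]), 13L)
  expect_identical(unname(roles[["cTP"]]), 1L)
  expect_identical(unname(roles[["mTP"]]), 1L)
  expect_identical(unname(roles[["RANDOM"]]), 2L)
  expect_true(all(canonicalCores() %in% peptideIds(lib)))
  # cleavage indices present for the TP records only
  cl <- cleavageIndex(lib)
  expect_false(anyNA(cl[c("RCA1_cTP", "CAG2_mTP")]))
  expect_true(all(is.na(cl[canonicalCores()])))
})

test_that("malformed FASTA input is rejected with informative errors", {
  bad <- write_fasta(c(">p1", "ACZDE"))
  expect_error(readPeptides(bad), "p1.*position 3")
  dup <- write_fasta(c(">p1", "ACDE", ">p1", "GHIK"))
  expect_error(readPeptides(dup), "duplicate")
  expect_error(readPeptides(tempfile()), "no such file")
  unk <- write_fasta(c(">p1 colour=blue", "ACDE"))
  expect_warning(readPeptides(unk), "unknown header key")
})

test_that("substituteBasic swaps all basic residues and nothing else", {
  ps <- PeptideSet(c(p = "GIGKFLK"))
  expect_identical(unname(aaSequences(substituteBasic(ps, "K_TO_R"))),
                   "GIGRFLR")
  expect_identical(peptideIds(substituteBasic(ps, "K_TO_R")), "p_R")
  # no-op on sequences lacking the source residue
  aa <- PeptideSet(c(q = "AAAA"))
  expect_identical(unname(aaSequences(substituteBasic(aa, "K_TO_R"))), "AAAA")

  # properties on fuzzed peptides: full replacement, length preservation,
  # per-direction idempotence, and K_TO_R then R_TO_K maps K and R to K
  set <- random_peptides(25, seed = 42)
  kr <- substituteBasic(set, "K_TO_R")
  expect_false(any(grepl("K", aaSequences(kr))))
  expect_identical(nchar(aaSequences(kr)), nchar(aaSequences(set)),
                   ignore_attr = TRUE)
  expect_identical(unname(aaSequences(substituteBasic(kr, "K_TO_R"))),
                   unname(aaSequences(kr)))
  back <- substituteBasic(kr, "R_TO_K")
  expect_false(any(grepl("R", aaSequences(back))))
  expected <- chartr("R", "K", chartr("K", "R", aaSequences(set)))
  expect_identical(unname(aaSequences(back)), unname(expected))
})

test_that("extractNElement returns the untouched N-terminal prefix", {
  ps <- PeptideSet(c(p = "ACDEFGHIKLMNPQRSTV"))
  el <- extractNElement(ps, 15)
  expect_identical(unname(aaSequences(el)), "ACDEFGHIKLMNPQR")
  expect_identical(unname(peptideRoles(el)), "ELEMENT")
  expect_error(extractNElement(ps, 0), "positive")
  expect_error(extractNElement(ps, 19), "shorter")
})

test_that("extractCElement slices the cleavage-site region exactly", {
  seq70 <- paste(rep(AA20, length.out = 70), collapse = "")
  tp <- PeptideSet(c(tp = seq70), role = "cTP", cleavage = 36)
  el <- extractCElement(tp)                       # defaults -10/+23
  expect_identical(unname(aaSequences(el)), substr(seq70, 27, 59))
  expect_identical(nchar(unname(aaSequences(el))), 33L)
  expect_identical(unname(cleavageIndex(el)), 10L)

  rec <- extractCElement(tp, upstream = 10, downstream = 0)
  expect_identical(unname(aaSequences(rec)), substr(seq70, 27, 36))

  early <- PeptideSet(c(p = seq70), role = "cTP", cleavage = 5)
  expect_error(extractCElement(early), "cleavage index < upstream")
  nocl <- PeptideSet(c(p = seq70), role = "cTP")
  expect_error(extractCElement(nocl), "cleavage index missing")
  expect_error(extractCElement(tp, downstream = 40), "downstream")
})

test_that("construct codes parse and format as exact inverses", {
  spec <- parseConstructCode("^cB2I_R^m")
  expect_identical(spec@core_id, "B2I")
  expect_identical(spec@basic_variant, "R")
  expect_identical(spec@n_element, "CTP_N")
  expect_identical(spec@c_element, "MTP_C")
  expect_identical(spec@row, "J")
  expect_identical(spec@column, "a")

  mh <- parseConstructCode("MH_R^c")
  expect_identical(mh@core_id, "MH")
  expect_identical(mh@n_element, "NONE")
  expect_identical(mh@c_element, "CTP_C")

  expect_error(parseConstructCode("B2I^q"), "B2I\\^q")

  # round trip over every row/core combination of the grammar
  tab <- constructRowTable()
  for (core in unname(gridColumnMap())) for (i in seq_len(nrow(tab))) {
    code <- formatConstructCode(new("ConstructSpec", core_id = core,
      basic_variant = tab$basic_variant[i], n_element = tab$n_element[i],
      c_element = tab$c_element[i], row = tab$row[i],
      column = NA_character_))
    spec <- parseConstructCode(code)
    expect_identical(formatConstructCode(spec), code)
    expect_identical(spec@row, tab$row[i])
  }
  # degenerate special codes
  for (code in c("^c-^c", "^cAA^c", "^cCH_R^c", "MH_R^m"))
    expect_identical(formatConstructCode(parseConstructCode(code)), code)
})

test_that("every grid cell's code reproduces its row signature", {
  grid <- gridCalls(loadGrid(grid_path()))
  tab <- constructRowTable()
  cells <- grid[grid$core %in% c(canonicalCores(), "RP1", "RP2", "CH", "MH"), ]
  for (i in seq_len(nrow(cells))) {
    sig <- tab[tab$row == cells$row[i], ]
    code <- formatConstructCode(new("ConstructSpec",
      core_id = cells$core[i], basic_variant = sig$basic_variant,
      n_element = sig$n_element, c_element = sig$c_element,
      row = sig$row, column = cells$column[i]))
    spec <- parseConstructCode(code)
    expect_identical(spec@row, cells$row[i])
    expect_identical(spec@column, cells$column[i])
  }
})

test_that("assembleConstruct concatenates elements without linkers", {
  lib <- readPeptides(fig1_path())
  els <- elementLibrary(lib)
  seqs <- aaSequences(els)

  # K->R substituted core followed by the mTP C-element
  mii <- assembleConstruct("MII_R^m", lib, els)
  expect_identical(unname(aaSequences(mii)),
                   paste0(chartr("K", "R", aaSequences(lib)[["MII"]]),
                          seqs[["MTP_C"]]))
  expect_identical(peptideIds(mii), "MII_R^m")
  expect_identical(unname(cleavageIndex(mii)),
                   nchar(aaSequences(lib)[["MII"]]) + 10L)

  # no core: cTP-N fused to cTP-C, 15 + 33 residues
  direct <- assembleConstruct("^c-^c", lib, els)
  expect_identical(nchar(unname(aaSequences(direct))), 48L)
  expect_identical(unname(aaSequences(direct)),
                   paste0(seqs[["CTP_N"]], seqs[["CTP_C"]]))

  # native core with no elements is the library sequence
  b2i <- assembleConstruct(parseConstructCode("B2I"), lib, els)
  expect_identical(unname(aaSequences(b2i)), aaSequences(lib)[["B2I"]])

  # poly-alanine core matches the CH length
  aa <- assembleConstruct("^cAA^c", lib, els)
  expect_identical(nchar(unname(aaSequences(aa))),
                   15L + nchar(seqs[["CH"]]) + 33L)
  expect_error(assembleConstruct("^cXXX^c", lib, els), "unknown core")

  # length additivity and alphabet closure across all grid constructs
  tab <- constructRowTable()
  for (core in c("B2I", "EHF", "CH", "MH")) for (i in c(1, 6, 12)) {
    spec <- new("ConstructSpec", core_id = core,
                basic_variant = tab$basic_variant[i],
                n_element = tab$n_element[i], c_element = tab$c_element[i],
                row = tab$row[i], column = NA_character_)
    cons <- assembleConstruct(spec, lib, els)
    core_len <- nchar(c(aaSequences(lib), aaSequences(els))[[core]])
    exp_len <- core_len +
      (if (tab$n_element[i] == "CTP_N") 15L else 0L) +
      (if (tab$c_element[i] == "NONE") 0L else 33L)
    expect_identical(nchar(unname(aaSequences(cons))), exp_len)
    expect_true(all(chimeraTP:::.residues(aaSequences(cons)[[1]]) %in% AA20))
  }
})
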