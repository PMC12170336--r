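test_that("composition strings parse into residue counts", {
  c1 <- parse_composition("HexNAc(2)Hex(5)")
  expect_equal(c1$hexnac, 2L)
  expect_equal(c1$hex, 5L)
  expect_equal(sum(as.matrix(c1)), 7L)

  c2 <- parse_composition("HexNAc(4)Hex(5)Fuc(1)NeuAc(2)")
  expect_equal(as.integer(c2[1, c("hexnac", "hex", "fuc", "neuac")]),
               c(4L, 5L, 1L, 2L))
  expect_equal(c2$neugc + c2$phospho + c2$sulfo, 0L)

  # dHex is a fucose synonym; duplicated tokens are summed
  expect_equal(parse_composition("Hex(1)dHex(2)")$fuc, 2L)
  expect_equal(parse_composition("Hex(1)Hex(2)")$hex, 3L)

  expect_error(parse_composition("HexNAc(2)Xyl(1)"), "Xyl")
  expect_error(parse_composition(""), "empty")
  expect_error(parse_composition("HexNAc(2)garbage"), "malformed")
})

test_that("format/parse round trip holds for random compositions", {
  set.seed(11)
  counts <- matrix(rpois(7 * 300, 1.2), ncol = 7)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  comp <- as.data.frame(counts)
  names(comp) <- glycan_residues
  rt <- parse_composition(format_composition(comp))
  expect_equal(as.matrix(rt), as.matrix(comp), ignore_attr = TRUE)
})

test_that("glycan masses are residue-count weighted sums", {
  expect_equal(glycan_mass("HexNAc(2)Hex(3)"),
               2 * 203.07937 + 3 * 162.05282, tolerance = 1e-9)
  expect_equal(glycan_mass("HexNAc(2)Hex(3)"), 892.3172, tolerance = 1e-4)
  expect_equal(glycan_mass("NeuAc(1)"), 291.09542)
  zero <- as.data.frame(as.list(setNames(rep(0L, 7), glycan_residues)))
  expect_equal(glycan_mass(zero), 0)
})

test_that("N-glycan hierarchy assigns the documented classes", {
  cases <- c("HexNAc(2)Hex(9)"             = "high_mannose",
             "HexNAc(4)Hex(5)Fuc(1)NeuAc(2)" = "sialylated",
             "HexNAc(2)Hex(3)"             = "paucimannose",
             "HexNAc(5)Hex(4)"             = "complex_hybrid",
             "HexNAc(1)"                   = "small",
             "HexNAc(2)Hex(5)Fuc(1)"       = "fucosylated",
             "HexNAc(2)Hex(6)Phospho(1)"   = "phospho",
             "HexNAc(2)Hex(13)"            = "complex_hybrid",
             "HexNAc(2)"                   = "small")
  expect_equal(as.character(classify_n(names(cases))), unname(cases))
  expect_error(classify_n(data.frame(hexnac = 0L)), "zero")
})

test_that("O-glycan hierarchy assigns the documented classes", {
  cases <- c("HexNAc(1)"                 = "o_glcnac",
             "HexNAc(1)Hex(1)"           = "o_hexose",
             "HexNAc(1)Hex(1)NeuAc(1)"   = "o_sialylated",
             "HexNAc(1)Hex(1)Sulfo(1)"   = "o_sulfated",
             "HexNAc(1)Fuc(1)"           = "o_fucosylated",
             "HexNAc(3)Hex(2)"           = "o_hybrid",
             "HexNAc(1)Phospho(1)"       = "o_phospho")
  expect_equal(as.character(classify_o(names(cases))), unname(cases))
})

test_that("phospho precedence dominates both hierarchies", {
  set.seed(21)
  counts <- matrix(rpois(7 * 100, 1), ncol = 7)
  comp <- as.data.frame(counts)
  names(comp) <- glycan_residues
  comp$phospho <- comp$phospho + 1L
  expect_true(all(classify_n(comp) == "phospho"))
  expect_true(all(classify_o(comp) == "o_phospho"))
})

test_that("database filter applies the three composition rules", {
  db <- filter_database(c("HexNAc(6)Hex(2)",           # rule 1: 6 > 5
                          "HexNAc(2)Hex(4)Fuc(4)",     # rule 2: 4 > 3
                          "HexNAc(4)Hex(5)NeuAc(3)Fuc(3)", # rule 3: 6 > 5
                          "HexNAc(2)Hex(5)"))
  expect_equal(db$rule1_pass, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(db$rule2_pass, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(db$rule3_pass, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(db$retained, c(FALSE, FALSE, FALSE, TRUE))

  # boundary: sialic bound is real-valued hex/2 + 1, not integer division
  expect_true(filter_database("HexNAc(2)Hex(3)NeuAc(2)")$rule2_pass)

  # idempotence: filtering the retained set changes nothing
  kept <- db[db$retained, ]
  again <- filter_database(kept$composition)
  expect_equal(again$composition, kept$composition)
  expect_true(all(again$retained))

  # duplicates collapse
  expect_equal(nrow(filter_database(c("HexNAc(2)Hex(5)",
                                      "Hex(5)HexNAc(2)"))), 1L)
})

test_that("glycan database files round trip through the readers", {
  f <- withr::local_tempfile(fileext = ".txt")
  comps <- c("HexNAc(2)Hex(5)", "HexNAc(4)Hex(5)Fuc(1)")
  writeLines(comps, f)
  expect_equal(read_glycan_database(f), comps)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  db <- write_glycan_classification(comps, f2, mode = "N")
  tab <- read.delim(f2)
  expect_equal(tab$composition, comps)
  expect_equal(tab$class, c("high_mannose", "fucosylated"))
})
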