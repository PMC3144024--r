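test_that("TSV format round-trips stoichiometry and reversibility exactly", {
  net <- fixture_network("PREVNET")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_network(net, path)
  back <- read_tsv_network(path)
  expect_identical(back$stoich, net$stoich)
  expect_identical(back$reversible, net$reversible)
  expect_identical(back$reaction_ids, net$reaction_ids)
  expect_identical(back$metabolite_ids, net$metabolite_ids)

  # non-integer coefficients survive the trip too
  frac <- metabolic_network(matrix(c(0.5, -1/3), 1), c(TRUE, FALSE),
                            "A", c("R1", "R2"))
  write_tsv_network(frac, path)
  expect_identical(read_tsv_network(path)$stoich, frac$stoich)
})

test_that("TSV reversibility header drives the flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#reactions\tR1\tR2\tR3",
               "#reversible\tR2",
               "A\t1\t-1\t0",
               "B\t0\t1\t-1"), path)
  net <- read_tsv_network(path)
  expect_identical(net$reversible, c(FALSE, TRUE, FALSE))
})

test_that("malformed TSV inputs fail with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#reactions\tR1\tR2", "#reversible", "A\t1"), path)
  expect_error(read_tsv_network(path), "row 3 has 2 cells")
  writeLines(c("#reactions\tR1\tR2", "#reversible", "A\t1\tx"), path)
  expect_error(read_tsv_network(path), "row 3, column 3")
  writeLines(c("#reactions\tR1\tR1", "#reversible", "A\t1\t1"), path)
  expect_error(read_tsv_network(path), "duplicate reaction ids")
  writeLines(c("#reactions\tR1\tR2", "#reversible"), path)
  expect_error(read_tsv_network(path), "at least one metabolite row")
})

test_that("SBML reading honours reversibility flags and boundary species", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(chain3_sbml_text(), path)
  net <- read_sbml(path)
  ref <- fixture_network("CHAIN3")
  # boundary species X dropped; default stoichiometry 1 applied
  expect_identical(net$metabolite_ids, c("A", "B"))
  expect_equal(unname(net$stoich), unname(ref$stoich))
  expect_identical(net$reversible, ref$reversible)
  expect_identical(net$reaction_ids, c("R1", "R2", "R3"))
})

test_that("SBML -> TSV -> SBML round trip preserves the model", {
  net <- fixture_network("PREVNET")
  p_sbml <- withr::local_tempfile(fileext = ".xml")
  p_tsv <- withr::local_tempfile(fileext = ".tsv")
  p_sbml2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, p_sbml)
  a <- read_sbml(p_sbml)
  write_tsv_network(a, p_tsv)
  b <- read_tsv_network(p_tsv)
  write_sbml(b, p_sbml2)
  c_ <- read_sbml(p_sbml2)
  expect_identical(c_$stoich, net$stoich)
  expect_identical(c_$reversible, net$reversible)
})

test_that("SBML validation errors are raised on broken inputs", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml>", path)
  expect_error(read_sbml(path), "cannot parse SBML")
  writeLines(sub("(?s)<listOfReactions>.*</listOfReactions>", "",
                 chain3_sbml_text(), perl = TRUE), path)
  expect_error(read_sbml(path), "no reactions")
})

test_that("coupling table output lists codes, blocked reactions and classes", {
  net <- fixture_network("CHAIN3")
  fc <- flux_coupling(net)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coupling_table(fc$coupling, fc$classification, path)
  lines <- readLines(path)
  expect_identical(lines[[1L]], "\tR1\tR2\tR3")
  expect_identical(lines[[2L]], "R1\t1\t1\t1")   # all fully coupled
  expect_identical(lines[[5L]], "#blocked")      # none blocked
  expect_identical(lines[[6L]], "#irev\tR1\tR2\tR3")

  # a network with a blocked reaction: chain with the export deleted
  cut <- metabolic_network(fixture_network("CHAIN3")$stoich[, 1:2],
                           c(FALSE, FALSE), c("A", "B"), c("R1", "R2"))
  fc2 <- flux_coupling(cut)
  write_coupling_table(fc2$coupling, fc2$classification, path)
  lines2 <- readLines(path)
  expect_identical(lines2[[1L]], "")             # no unblocked reactions
  expect_true("#blocked\tR1\tR2" %in% lines2)

  # byte-identical on identical input
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_coupling_table(fc$coupling, fc$classification, p2)
  write_coupling_table(fc$coupling, fc$classification, path)
  expect_identical(readLines(path), readLines(p2))
})

test_that("network construction rejects invalid inputs", {
  expect_error(metabolic_network(matrix(NA_real_, 1, 1), FALSE), "non-finite")
  expect_error(metabolic_network(matrix(1, 1, 2), c(FALSE, FALSE),
                                 "A", c("R1", "R1")), "unique")
  expect_error(metabolic_network(matrix(0, 0, 0), logical()), "at least 1")
})
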