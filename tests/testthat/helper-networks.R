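# Shared fixtures and comparison helpers.

# Source/sink diamond with variable yield on the two routes (A -> B and
# A -> 2B): source and sink force each other but at no constant ratio, the
# canonical partial-coupling example.
variable_yield_net <- function() {
  metabolic_network(
    cbind(c(1, 0), c(-1, 1), c(-1, 2), c(0, -1)),
    reversible = rep(FALSE, 4),
    metabolite_ids = c("A", "B"), reaction_ids = c("R1", "R2", "R3", "R4")
  )
}

# PREVNET and REVPAIR glued as independent blocks: contains Irev, Prev and
# Frev reactions in one network (used to exercise the no-LP prunings).
mixed_type_net <- function() {
  p <- fixture_network("PREVNET"); r <- fixture_network("REVPAIR")
  s <- rbind(cbind(p$stoich, matrix(0, 2, 2)),
             cbind(matrix(0, 2, 5), r$stoich))
  metabolic_network(
    s, c(p$reversible, r$reversible),
    metabolite_ids = c(p$metabolite_ids, paste0("X", r$metabolite_ids)),
    reaction_ids = c(p$reaction_ids, c("Q1", "Q2"))
  )
}

# Relation-for-relation equality of two analyses, ratios within tol.
expect_same_coupling <- function(a, b, tol = 1e-6) {
  expect_identical(a$coupling$pairs$relation, b$coupling$pairs$relation)
  ra <- a$coupling$pairs$ratio; rb <- b$coupling$pairs$ratio
  expect_identical(is.na(ra), is.na(rb))
  expect_true(all(abs(ra[!is.na(ra)] - rb[!is.na(rb)]) <= tol))
}

# Partition equality (the sign-flip bookkeeping is checked separately where
# it is part of the property under test).
expect_same_classification <- function(a, b) {
  for (f in c("blocked", "irev", "prev", "frev"))
    expect_identical(sort(a[[f]]), sort(b[[f]]))
}

# Structural invariants every coupling matrix must satisfy.
check_coupling_invariants <- function(fc) {
  codes <- as_code_matrix(fc$coupling)
  cls <- fc$classification
  u <- fc$coupling$idx
  nu <- length(u)
  # directed "forces" relation: full/partial both ways, 3 means row -> col
  D <- codes == 1L | codes == 2L | codes == 3L
  diag(D) <- TRUE
  FULL <- codes == 1L
  PF <- codes <= 2L
  trans_ok <- function(M) {
    via <- (M %*% M) > 0
    all(!(via & !M))
  }
  expect_true(trans_ok(FULL))   # full coupling is an equivalence relation
  expect_true(trans_ok(PF))     # partial-or-full is an equivalence relation
  expect_true(trans_ok(D))      # directional coupling is transitive
  # reversibility-type restrictions on admissible codes
  type <- vapply(u, function(r) ffca:::rt_of(cls, r), character(1))
  for (a in seq_len(nu)) for (b in seq_len(nu)) {
    if (a == b) next
    key <- paste(sort(c(type[[a]], type[[b]])), collapse = "_")
    code <- codes[a, b]
    if (key %in% c("prev_prev", "frev_frev"))
      expect_true(code %in% c(1L, 5L))
    if (key == "irev_prev") {
      expect_true(code %in% c(3L, 4L, 5L))
      if (code == 3L) expect_identical(type[[a]], "prev")  # only prev -> irev
      if (code == 4L) expect_identical(type[[b]], "prev")
    }
    if (key %in% c("frev_irev", "frev_prev"))
      expect_identical(code, 5L)
  }
  # count identity
  g <- glance(fc)
  expect_equal(g$fully + g$partially + g$directionally + g$uncoupled,
               choose(g$n_unblocked, 2))
}

# A hand-written SBML document: CHAIN3 plus one boundary species "X"
# consumed by R1 (external, so it must not appear as a balance row).
chain3_sbml_text <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="chain3">
    <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
    <listOfSpecies>
      <species id="X" compartment="cell" boundaryCondition="true"/>
      <species id="A" compartment="cell" boundaryCondition="false"/>
      <species id="B" compartment="cell" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" reversible="false">
        <listOfReactants><speciesReference species="X"/></listOfReactants>
        <listOfProducts><speciesReference species="A"/></listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <listOfProducts><speciesReference species="B"/></listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false">
        <listOfReactants><speciesReference species="B"/></listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}

# Small deterministic batch of random networks for module-level properties.
small_suite <- function(n = 25L, seed = 42L) {
  cfg <- random_suite(n, seed = seed)
  cfg$network
}
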