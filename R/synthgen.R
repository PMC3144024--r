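# Deterministic fixture library and seeded random-network generator. These
# supply every test input; no model downloads are involved.

fixture_defs <- list(
  # linear chain: uptake -> A -> B -> export, all irreversible
  CHAIN3 = list(
    stoich = cbind(c(1, 0), c(-1, 1), c(0, -1)),
    mets = c("A", "B"), rxns = c("R1", "R2", "R3"),
    reversible = c(FALSE, FALSE, FALSE)
  ),
  # one uptake feeding two alternative exports
  BRANCH = list(
    stoich = matrix(c(1, -1, -1), 1),
    mets = "A", rxns = c("R1", "R2", "R3"),
    reversible = c(FALSE, FALSE, FALSE)
  ),
  # two reversible reactions forming a 2-cycle: the cone is a line
  REVPAIR = list(
    stoich = cbind(c(-1, 1), c(1, -1)),
    mets = c("A", "B"), rxns = c("R1", "R2"),
    reversible = c(TRUE, TRUE)
  ),
  # reversible A<->B with irreversible routes on both sides, so both of its
  # directions are feasible but the lineality space is trivial (R2 is Prev)
  PREVNET = list(
    stoich = cbind(c(1, 0), c(-1, 1), c(0, -1), c(0, 1), c(-1, 0)),
    mets = c("A", "B"), rxns = c("R1", "R2", "R3", "R4", "R5"),
    reversible = c(FALSE, TRUE, FALSE, FALSE, FALSE)
  ),
  # two parallel routes between source and sink: mutual forcing of the
  # endpoints without a constant ratio on the routes
  DIAMOND = list(
    stoich = cbind(c(1, 0), c(-1, 1), c(-1, 1), c(0, -1)),
    mets = c("A", "B"), rxns = c("R1", "R2", "R3", "R4"),
    reversible = c(FALSE, FALSE, FALSE, FALSE)
  ),
  # chain with a 1:2 stoichiometric step, giving a full coupling ratio of 2
  COEF2 = list(
    stoich = cbind(c(1, 0), c(-1, 2), c(0, -1)),
    mets = c("A", "B"), rxns = c("R1", "R2", "R3"),
    reversible = c(FALSE, FALSE, FALSE)
  )
)

#' Built-in fixture networks
#'
#' Small hand-constructed networks covering the coupling-case taxonomy:
#' `CHAIN3` (all fully coupled), `BRANCH` (directional coupling to the
#' shared uptake), `REVPAIR` (a fully reversible 2-cycle; pure lineality),
#' `PREVNET` (a pseudo-irreversible reaction), `DIAMOND` (partial coupling of
#' source and sink) and `COEF2` (full coupling with ratio 2).
#'
#' @param name fixture name.
#' @return a [metabolic_network].
#' @examples
#' fixture_network("PREVNET")
#' @export
fixture_network <- function(name = names(fixture_defs)) {
  name <- match.arg(name)
  d <- fixture_defs[[name]]
  metabolic_network(d$stoich, d$reversible, d$mets, d$rxns)
}

#' Seeded random metabolic networks
#'
#' Generates a reproducible random network: integer stoichiometric
#' coefficients in `{-3..3} \\ {0}` at the requested density over the
#' internal columns, plus `n_exchanges` single-metabolite exchange columns
#' (the open-boundary convention: external metabolites are simply not
#' balanced). The same configuration always yields the identical network;
#' the generator does not touch the session RNG state.
#'
#' @param n_metabolites,n_reactions dimensions (reactions include exchanges).
#' @param density fraction of non-zero entries in the internal columns,
#'   in (0, 1].
#' @param frac_reversible fraction of reactions marked reversible, in [0, 1].
#' @param n_exchanges number of single-metabolite exchange columns (at least
#'   1, or everything is typically blocked in a mass-balanced network).
#' @param seed integer seed.
#' @return a [metabolic_network].
#' @export
random_network <- function(n_metabolites, n_reactions, density = 0.5,
                           frac_reversible = 0.3, n_exchanges = 2L,
                           seed = 1L) {
  stopifnot(density > 0, density <= 1,
            frac_reversible >= 0, frac_reversible <= 1,
            n_exchanges >= 1L, n_reactions > n_exchanges)
  withr::with_seed(seed, {
    m <- n_metabolites; n <- n_reactions
    stoich <- matrix(0, m, n)
    n_internal <- n - n_exchanges
    for (j in seq_len(n_internal)) {
      nz <- which(stats::runif(m) < density)
      if (length(nz) == 0L) nz <- sample.int(m, 1L)
      stoich[nz, j] <- sample(c(-3:-1, 1:3), length(nz), replace = TRUE)
    }
    for (e in seq_len(n_exchanges)) {
      stoich[sample.int(m, 1L), n_internal + e] <-
        sample(c(-1L, 1L), 1L)
    }
    reversible <- stats::runif(n) < frac_reversible
    metabolic_network(stoich, reversible)
  })
}

#' The seeded random-network verification suite
#'
#' The configurations used for cross-method verification: `n_networks` draws
#' with 2-6 metabolites, 3-12 reactions, internal density 0.3-0.8 and a
#' reversible fraction between 0 and 0.6, each derived deterministically
#' from `seed`.
#'
#' @param n_networks number of networks.
#' @param seed base seed.
#' @return a tibble of generator configurations (one row per network) with a
#'   list-column `network` holding the generated [metabolic_network]s.
#' @export
random_suite <- function(n_networks = 200L, seed = 1L) {
  cfg <- withr::with_seed(seed, tibble(
    id = seq_len(n_networks),
    n_metabolites = sample(2:6, n_networks, replace = TRUE),
    n_reactions = sample(3:12, n_networks, replace = TRUE),
    density = stats::runif(n_networks, 0.3, 0.8),
    frac_reversible = stats::runif(n_networks, 0, 0.6),
    seed = sample.int(.Machine$integer.max, n_networks)
  ))
  cfg$n_exchanges <- pmin(2L, cfg$n_reactions - 1L)
  cfg$network <- purrr::pmap(
    cfg[, c("n_metabolites", "n_reactions", "density", "frac_reversible",
            "n_exchanges", "seed")],
    random_network)
  cfg
}
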