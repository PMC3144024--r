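# Cone system helpers ---------------------------------------------------
#
# The steady-state flux cone is C = { v : S v = 0, v_k >= 0 for k in Irr }.
# All "reaction r active" conditions are realized as pins v_r = +/-1; the cone
# is scale-invariant, so this loses no generality and keeps every LP bounded
# and well scaled.

cone_system <- function(net, nonneg, pinned) {
  feasibility_system(net$stoich, nonneg = nonneg, pinned = pinned)
}

model_irr <- function(net) which(!net$reversible)

#' Find blocked reactions
#'
#' A reaction is blocked when it carries zero flux in every steady-state flux
#' vector. Detection is by pure feasibility tests: `r` is unblocked iff
#' `{S v = 0, v_Irr >= 0, v_r = 1}` is feasible, or (for a reversible `r`)
#' the same system with `v_r = -1` is. No optimization is involved.
#'
#' @param net a [metabolic_network].
#' @return integer vector of blocked reaction indices (possibly empty).
#' @export
find_blocked <- function(net) {
  stopifnot_network(net)
  irr <- model_irr(net)
  blocked <- integer()
  for (r in seq_len(n_reactions(net))) {
    fwd <- is_feasible(cone_system(net, irr, stats::setNames(1, r)),
                       count_as = "preprocess")
    if (fwd) next
    if (net$reversible[[r]]) {
      bwd <- is_feasible(cone_system(net, irr, stats::setNames(-1, r)),
                         count_as = "preprocess")
      if (bwd) next
    }
    blocked <- c(blocked, r)
  }
  blocked
}

#' Partition unblocked reactions by reversibility type
#'
#' Every unblocked reaction is assigned to exactly one of: `Irev` (carries
#' flux in only one direction at steady state), `Prev` (pseudo-irreversible:
#' both directions feasible but always zero on the lineality space of the
#' cone) or `Frev` (fully reversible: can be active with every irreversible
#' reaction shut off). Model-reversible reactions that are feasible only
#' backwards are assigned to `Irev` with their column marked for negation
#' (`flipped`), so downstream systems can assume all `Irev` members run
#' forward.
#'
#' The `Frev` membership test pins `v_i = 1` inside the lineality space
#' `{S v = 0, v_k = 0 for all k in Irr}`; a linear subspace is symmetric, so
#' one sign suffices.
#'
#' @param net a [metabolic_network].
#' @param blocked result of [find_blocked()] on `net`.
#' @return a `reaction_classification`.
#' @export
classify_reversibility <- function(net, blocked = find_blocked(net)) {
  stopifnot_network(net)
  irr <- model_irr(net)
  irev <- integer(); prev <- integer(); frev <- integer(); flipped <- integer()
  lin_pins_base <- stats::setNames(rep(0, length(irr)), irr)
  for (r in setdiff(seq_len(n_reactions(net)), blocked)) {
    if (!net$reversible[[r]]) {
      irev <- c(irev, r)
      next
    }
    fwd <- is_feasible(cone_system(net, irr, stats::setNames(1, r)),
                       count_as = "preprocess")
    bwd <- is_feasible(cone_system(net, irr, stats::setNames(-1, r)),
                       count_as = "preprocess")
    if (fwd && bwd) {
      pins <- lin_pins_base
      pins[as.character(r)] <- 1
      in_lin <- is_feasible(feasibility_system(net$stoich, pinned = pins),
                            count_as = "preprocess")
      if (in_lin) frev <- c(frev, r) else prev <- c(prev, r)
    } else if (fwd) {
      irev <- c(irev, r)
    } else {
      irev <- c(irev, r)
      flipped <- c(flipped, r)
    }
  }
  new_reaction_classification(blocked, irev, prev, frev, flipped,
                              net$reaction_ids)
}

#' Classify a network in one call
#'
#' Convenience wrapper running [find_blocked()] then
#' [classify_reversibility()].
#'
#' @param net a [metabolic_network].
#' @return a `reaction_classification`.
#' @export
classify_reactions <- function(net) {
  classify_reversibility(net, find_blocked(net))
}

# The sign-normalized network: flipped Irev columns negated, so every Irev
# reaction operates forward. All pairwise systems are built on this network.
normalized_network <- function(net, cls) {
  flip_columns(net, cls$flipped)
}

# Non-negativity set used by the pairwise systems: model-irreversible
# reactions plus the Irev class of the sign-normalized network. Adding the
# Irev members does not change the solution set (they are single-signed at
# steady state by definition) but keeps the systems in the shape the case
# dispatch assumes.
nonneg_set <- function(net, cls) {
  sort(union(model_irr(net), cls$irev))
}
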