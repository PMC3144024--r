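# FFCA: feasibility-based flux coupling analysis.
#
# All pairwise decisions reduce to the feasibility of small linear systems
# over the steady-state flux cone of the sign-normalized network. Which
# systems are consulted depends only on the reversibility types of the pair
# (RT-prunings): of the nine type combinations, only four can couple.

#' Build the pairwise feasibility systems (P1)-(P4)
#'
#' For `i, j` in `Irev`, (P1) is `{S v = 0; v_k >= 0 for k in Irr and Irev;
#' v_i = 1; v_j = 0}` on the sign-normalized network, and (P2) is (P1) with
#' the roles swapped: infeasibility of (P1) means `i` cannot run without `j`,
#' i.e. `i -> j`. For `i` in `Irev`, `j` in `Prev`, (P3) is the
#' backward-direction complement of (P2): `{S v = 0; v_k >= 0; v_i = 0;
#' v_j = -1}`. For a `Prev`/`Prev` or `Frev`/`Frev` pair, (P4) drops all
#' non-negativity constraints and the blocked columns: `{S' v = 0; v_i = 0;
#' v_j = 1}` — on that subspace, full coupling is equivalent to "`v_i = 0`
#' implies `v_j = 0`", so a single feasibility test decides the pair
#' (the Prev/Frev improvement).
#'
#' @param net a [metabolic_network].
#' @param cls its `reaction_classification`.
#' @param i,j reaction indices satisfying the case's type precondition.
#' @return a [feasibility_system]; for `build_P4` it carries a `col_map`
#'   attribute giving the original index of each retained column.
#' @name pair_systems
NULL

#' @rdname pair_systems
#' @export
build_P1 <- function(net, cls, i, j) {
  stopifnot(i != j)
  nn <- normalized_network(net, cls)
  cone_system(nn, nonneg_set(net, cls),
              stats::setNames(c(1, 0), c(i, j)))
}

#' @rdname pair_systems
#' @export
build_P2 <- function(net, cls, i, j) build_P1(net, cls, j, i)

#' @rdname pair_systems
#' @export
build_P3 <- function(net, cls, i, j) {
  stopifnot(i %in% cls$irev, j %in% cls$prev)
  nn <- normalized_network(net, cls)
  cone_system(nn, nonneg_set(net, cls),
              stats::setNames(c(0, -1), c(i, j)))
}

#' @rdname pair_systems
#' @export
build_P4 <- function(net, cls, i, j) {
  ok <- (all(c(i, j) %in% cls$prev)) || (all(c(i, j) %in% cls$frev))
  if (!ok || i == j)
    stop("(P4) is only defined for two distinct Prev reactions or two distinct Frev reactions",
         call. = FALSE)
  nn <- normalized_network(net, cls)
  keep <- unblocked_indices(cls)
  s_red <- nn$stoich[, keep, drop = FALSE]
  ri <- match(i, keep); rj <- match(j, keep)
  sys <- feasibility_system(s_red, pinned = stats::setNames(c(0, 1), c(ri, rj)))
  attr(sys, "col_map") <- keep
  sys
}

#' Distinguish full from partial coupling for an Irev pair
#'
#' Once (P1) and (P2) are both infeasible the pair is at least partially
#' coupled. The pair is fully coupled iff the flux ratio `v_j / v_i` is a
#' constant over the cone, decided by two LPs: maximize and minimize `v_j`
#' subject to the cone constraints and `v_i = 1`. Equal finite optima (within
#' `eps_ratio`) give full coupling with that ratio; anything else (including
#' an unbounded maximum) is partial coupling.
#'
#' @inheritParams pair_systems
#' @param tol tolerances, see [ffca_tol()].
#' @param count_as LP counter label.
#' @return a list `(relation, ratio)`; the ratio is in the coordinates of the
#'   sign-normalized network.
#' @export
resolve_full_vs_partial <- function(net, cls, i, j, tol = ffca_tol(),
                                    count_as = "irev_irev") {
  nn <- normalized_network(net, cls)
  sys <- cone_system(nn, nonneg_set(net, cls), stats::setNames(1, i))
  r_max <- lp_optimize(sys, j, "max", count_as = count_as)
  r_min <- lp_optimize(sys, j, "min", count_as = count_as)
  if (r_max$status == "infeasible" || r_min$status == "infeasible")
    stop("internal contradiction: pair flagged coupled but v_i = 1 is infeasible",
         call. = FALSE)
  if (r_max$status == "optimal" && r_min$status == "optimal" &&
      abs(r_max$objective - r_min$objective) <= tol$eps_ratio) {
    new_coupling_relation("full", ratio = r_max$objective)
  } else {
    new_coupling_relation("partial")
  }
}

# Sign factor of reaction r in the normalized network relative to the
# original one: -1 iff its column was flipped.
sign_of <- function(cls, r) if (r %in% cls$flipped) -1 else 1

#' Decide the coupling relation of one pair of unblocked reactions
#'
#' Dispatches on the reversibility types of the pair (RT-prunings). Of the
#' nine type combinations only four can couple; `Irev`/`Frev` and
#' `Prev`/`Frev` pairs are returned uncoupled without any LP call.
#'
#' \itemize{
#'   \item `Irev`/`Irev`: feasibility of (P1) and (P2), then
#'     [resolve_full_vs_partial()] when both are infeasible.
#'   \item `Irev`/`Prev`: feasibility of (P2) and (P3); both infeasible means
#'     the `Prev` reaction is directionally coupled to the `Irev` one (the
#'     only admissible relation); otherwise uncoupled.
#'   \item `Prev`/`Prev` or `Frev`/`Frev`: feasibility of (P4) alone;
#'     infeasible means fully coupled (with the ratio recovered from one
#'     kernel vector of the reduced system), feasible means uncoupled.
#' }
#'
#' @inheritParams resolve_full_vs_partial
#' @return a list `(relation, ratio)` oriented for `(i, j)` — `"dir_1_to_2"`
#'   means `i -> j`. Ratios are reported in original (un-normalized)
#'   coordinates.
#' @export
couple_pair <- function(net, cls, i, j, tol = ffca_tol()) {
  stopifnot(i != j, !(i %in% cls$blocked), !(j %in% cls$blocked))
  ti <- rt_of(cls, i); tj <- rt_of(cls, j)
  key <- paste(sort(c(ti, tj)), collapse = "_")

  if (ti == "irev" && tj == "irev") {
    f1 <- is_feasible(build_P1(net, cls, i, j), count_as = "irev_irev")
    f2 <- is_feasible(build_P2(net, cls, i, j), count_as = "irev_irev")
    if (f1 && f2) return(new_coupling_relation("uncoupled"))
    if (!f1 && f2) return(new_coupling_relation("dir_1_to_2"))
    if (f1 && !f2) return(new_coupling_relation("dir_2_to_1"))
    rel <- resolve_full_vs_partial(net, cls, i, j, tol)
    if (rel$relation == "full")
      rel$ratio <- rel$ratio * sign_of(cls, i) * sign_of(cls, j)
    return(rel)
  }

  if (key == "irev_prev") {
    a <- if (ti == "irev") i else j   # the Irev member
    p <- if (ti == "prev") i else j   # the Prev member
    f2 <- is_feasible(build_P2(net, cls, a, p), count_as = "irev_prev")
    if (f2) return(new_coupling_relation("uncoupled"))
    f3 <- is_feasible(build_P3(net, cls, a, p), count_as = "irev_prev")
    if (f3) return(new_coupling_relation("uncoupled"))
    # only p -> a is admissible
    return(new_coupling_relation(if (p == i) "dir_1_to_2" else "dir_2_to_1"))
  }

  if (key %in% c("prev_prev", "frev_frev")) {
    sys4 <- build_P4(net, cls, i, j)
    if (is_feasible(sys4, count_as = key))
      return(new_coupling_relation("uncoupled"))
    # fully coupled; recover the constant ratio from one kernel vector of the
    # reduced system with v_i = 1 (an extension: the decision itself needs no
    # ratio)
    keep <- attr(sys4, "col_map")
    nn <- normalized_network(net, cls)
    s_red <- nn$stoich[, keep, drop = FALSE]
    wit_sys <- feasibility_system(
      s_red, pinned = stats::setNames(1, match(i, keep)))
    if (!is_feasible(wit_sys, count_as = key))
      stop("internal contradiction: unblocked reaction has no kernel support",
           call. = FALSE)
    k <- last_witness()[[match(j, keep)]]
    return(new_coupling_relation("full", ratio = k))
  }

  # irev/frev and prev/frev combinations cannot couple: no LP is issued
  new_coupling_relation("uncoupled")
}

#' Flux coupling analysis of a metabolic network (FFCA)
#'
#' Runs the full feasibility-based procedure: blocked-reaction detection,
#' reversibility-type classification with sign normalization, then
#' [couple_pair()] over every unordered pair of unblocked reactions in
#' lexicographic input order.
#'
#' @param net a [metabolic_network].
#' @param tol tolerances, see [ffca_tol()].
#' @return an object of class `flux_coupling`: fields `classification`
#'   (`reaction_classification`), `coupling` (`coupling_matrix`), `method`,
#'   `lp_calls` (named counter vector) and `tol`. Use [tidy()] for the pair
#'   table, [glance()] for the one-row count summary, and
#'   [autoplot.flux_coupling()] for a heat-map view.
#' @examples
#' net <- fixture_network("CHAIN3")
#' fc <- flux_coupling(net)
#' glance(fc)
#' @export
flux_coupling <- function(net, tol = ffca_tol()) {
  stopifnot_network(net)
  lp_calls_reset()
  cls <- classify_reactions(net)
  cm <- couple_all(net, cls, tol, couple_pair)
  new_flux_coupling(net, cls, cm, method = "ffca", tol = tol)
}

# Shared pair loop: lexicographic over (i, j), i < j, in input reaction order.
couple_all <- function(net, cls, tol, pair_fun) {
  u <- unblocked_indices(cls)
  pairs <- if (length(u) >= 2L) utils::combn(u, 2L) else
    matrix(integer(), nrow = 2L)
  n_pairs <- ncol(pairs)
  rel <- character(n_pairs); ratio <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    r <- pair_fun(net, cls, pairs[1L, p], pairs[2L, p], tol)
    rel[[p]] <- r$relation
    ratio[[p]] <- if (is.null(r$ratio)) NA_real_ else r$ratio
  }
  new_coupling_matrix(
    tibble(
      i = as.integer(pairs[1L, ]), j = as.integer(pairs[2L, ]),
      rxn_i = net$reaction_ids[pairs[1L, ]],
      rxn_j = net$reaction_ids[pairs[2L, ]],
      relation = rel, ratio = ratio
    ),
    reactions = net$reaction_ids[u], idx = u
  )
}

new_flux_coupling <- function(net, cls, cm, method, tol) {
  structure(
    list(classification = cls, coupling = cm, method = method,
         lp_calls = lp_calls(), tol = tol,
         n_reactions = n_reactions(net), reaction_ids = net$reaction_ids),
    class = "flux_coupling")
}

#' @export
print.flux_coupling <- function(x, ...) {
  cat(sprintf("<flux_coupling> method '%s'\n", x$method))
  print(x$classification)
  print(x$coupling)
  cat(sprintf("LP calls: %d (%s)\n", sum(x$lp_calls),
              paste(sprintf("%s=%d", names(x$lp_calls), x$lp_calls),
                    collapse = ", ")))
  invisible(x)
}
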