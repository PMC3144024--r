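# Optimality-based flux coupling: the classical split-network algorithm and
# its improved no-splitting variants. These serve as independent
# cross-validation for FFCA; all variants must produce identical coupling
# matrices and differ only in how many LPs they solve.

# Interval of v[target] over the sign-normalized cone with v[pin] = val.
# Returns c(lo, hi) where an unbounded side is +/-Inf, or NULL when the
# pinned system is infeasible.
flux_interval <- function(net, cls, pin, val, target, count_as) {
  nn <- normalized_network(net, cls)
  sys <- cone_system(nn, nonneg_set(net, cls), stats::setNames(val, pin))
  lo <- lp_optimize(sys, target, "min", count_as = count_as)
  hi <- lp_optimize(sys, target, "max", count_as = count_as)
  if (lo$status == "infeasible" || hi$status == "infeasible") return(NULL)
  c(if (lo$status == "unbounded") -Inf else lo$objective,
    if (hi$status == "unbounded") Inf else hi$objective)
}

interval_forces <- function(iv, zero_tol) {
  !is.null(iv) && (iv[[1L]] > zero_tol || iv[[2L]] < -zero_tol)
}

interval_ratio <- function(iv, s, eps_ratio) {
  # constant ratio candidate v_target / v_pin when the interval collapses
  if (is.null(iv) || !is.finite(iv[[1L]]) || !is.finite(iv[[2L]])) return(NA_real_)
  if (abs(iv[[2L]] - iv[[1L]]) > eps_ratio) return(NA_real_)
  (iv[[1L]] + iv[[2L]]) / 2 / s
}

# Feasible flux signs of reaction r in the sign-normalized network.
feasible_signs <- function(cls, r) {
  if (r %in% cls$irev) 1 else c(1, -1)
}

# One direction of the optimality test: does pinning `from` force `to`
# active, and at what constant ratio (if any)? Uses 2 LPs per feasible sign.
directional_probe <- function(net, cls, from, to, tol, count_as) {
  signs <- feasible_signs(cls, from)
  forced <- logical(length(signs)); ratio <- numeric(length(signs))
  for (k in seq_along(signs)) {
    iv <- flux_interval(net, cls, from, signs[[k]], to, count_as)
    if (is.null(iv))
      stop("internal contradiction: classified-feasible direction is infeasible",
           call. = FALSE)
    forced[[k]] <- interval_forces(iv, tol$zero_tol)
    ratio[[k]] <- interval_ratio(iv, signs[[k]], tol$eps_ratio)
  }
  k <- if (all(forced) && !anyNA(ratio) &&
           max(ratio) - min(ratio) <= tol$eps_ratio) mean(ratio) else NA_real_
  list(forces = all(forced), ratio = k)
}

#' Optimality-based coupling decision for one pair
#'
#' The flux-coupling-finder decision rule on the unsplit network: for each
#' feasible sign of `v_i`, minimize and maximize `v_j` over the cone with
#' `v_i` pinned; `i` forces `j` iff zero is outside every such interval
#' (convexity makes the attainable `v_j` values exactly that interval). A
#' collapsed interval is a constant flux ratio; a constant non-zero ratio
#' under forcing already implies full coupling, otherwise the symmetric LPs
#' decide directional, partial or no coupling.
#'
#' `mode` selects the pruning level: `"wfcf"` runs the rule blindly on every
#' pair; `"wrfcf"` first dispatches on reversibility types and only tests the
#' four combinations that can couple (with cheaper one-sided tests where the
#' admissible relation is known); `"wrpfcf"` additionally replaces the
#' Prev/Prev and Frev/Frev optimality tests by the single (P4) feasibility
#' test.
#'
#' @inheritParams resolve_full_vs_partial
#' @param mode one of `"wfcf"`, `"wrfcf"`, `"wrpfcf"`.
#' @return a list `(relation, ratio)` oriented for `(i, j)`, ratios in
#'   original coordinates.
#' @export
fcf_pair_optimality <- function(net, cls, i, j, tol = ffca_tol(),
                                mode = c("wfcf", "wrfcf", "wrpfcf")) {
  mode <- match.arg(mode)
  if (i == j) return(new_coupling_relation("full", ratio = 1))
  ti <- rt_of(cls, i); tj <- rt_of(cls, j)
  key <- paste(sort(c(ti, tj)), collapse = "_")

  if (mode != "wfcf" && !(key %in% c("irev_irev", "irev_prev",
                                     "prev_prev", "frev_frev")))
    return(new_coupling_relation("uncoupled"))

  if (mode != "wfcf" && key == "irev_prev") {
    a <- if (ti == "irev") i else j; p <- if (ti == "prev") i else j
    # only p -> a is admissible; a is non-negative, so one min-LP per sign
    nn <- normalized_network(net, cls)
    for (s in c(1, -1)) {
      sys <- cone_system(nn, nonneg_set(net, cls), stats::setNames(s, p))
      lo <- lp_optimize(sys, a, "min", count_as = mode)
      if (lo$status != "optimal" || lo$objective <= tol$zero_tol)
        return(new_coupling_relation("uncoupled"))
    }
    return(new_coupling_relation(if (p == i) "dir_1_to_2" else "dir_2_to_1"))
  }

  if (mode == "wrpfcf" && key %in% c("prev_prev", "frev_frev"))
    return(couple_pair(net, cls, i, j, tol))   # the single-LP (P4) test

  if (mode == "wrfcf" && key %in% c("prev_prev", "frev_frev")) {
    # only full coupling is admissible: the forward probe alone decides
    probe <- directional_probe(net, cls, i, j, tol, mode)
    if (probe$forces && !is.na(probe$ratio) && abs(probe$ratio) > tol$zero_tol)
      return(new_coupling_relation("full", ratio = probe$ratio *
                                     sign_of(cls, i) * sign_of(cls, j)))
    return(new_coupling_relation("uncoupled"))
  }

  # generic optimality rule (wfcf always; wrfcf for irev/irev)
  fwd <- directional_probe(net, cls, i, j, tol, mode)
  if (fwd$forces && !is.na(fwd$ratio) && abs(fwd$ratio) > tol$zero_tol)
    return(new_coupling_relation("full", ratio = fwd$ratio *
                                   sign_of(cls, i) * sign_of(cls, j)))
  bwd <- directional_probe(net, cls, j, i, tol, mode)
  if (fwd$forces && bwd$forces) return(new_coupling_relation("partial"))
  if (fwd$forces) return(new_coupling_relation("dir_1_to_2"))
  if (bwd$forces) return(new_coupling_relation("dir_2_to_1"))
  new_coupling_relation("uncoupled")
}

# -- splitting ----------------------------------------------------------

#' Split reversible reactions
#'
#' Replaces every reversible reaction by a forward and an added backward
#' irreversible reaction (the backward column is the negated forward column).
#' The result is a network whose cone lies in the non-negative orthant, as
#' assumed by the classical flux-coupling-finder algorithm.
#'
#' @param net a [metabolic_network].
#' @return an object of class `split_network`: `base` (the input), `split`
#'   (the all-irreversible network with `n + |Rev|` columns) and `split_map`
#'   (named integer vector: reversible index -> its backward column).
#' @export
split_reversibles <- function(net) {
  stopifnot_network(net)
  rev_idx <- which(net$reversible)
  n <- n_reactions(net)
  s <- net$stoich
  if (length(rev_idx) > 0L) {
    bwd <- -s[, rev_idx, drop = FALSE]
    colnames(bwd) <- paste0(net$reaction_ids[rev_idx], "__bwd")
    s <- cbind(s, bwd)
  }
  split <- metabolic_network(s, rep(FALSE, ncol(s)),
                             net$metabolite_ids, colnames(s))
  split_map <- stats::setNames(n + seq_along(rev_idx), rev_idx)
  structure(list(base = net, split = split, split_map = split_map),
            class = "split_network")
}

#' @export
print.split_network <- function(x, ...) {
  cat(sprintf("<split_network> %d original -> %d split reactions\n",
              n_reactions(x$base), n_reactions(x$split)))
  invisible(x)
}

# Split-network column realizing direction `s` of original reaction `r`,
# and its partner (the opposite direction's column, NA for an unsplit one).
direction_column <- function(sn, r, s) {
  if (s > 0) r else unname(sn$split_map[[as.character(r)]])
}
partner_column <- function(sn, r, s) {
  key <- as.character(r)
  if (!(key %in% names(sn$split_map))) return(NA_integer_)
  if (s > 0) unname(sn$split_map[[key]]) else r
}

# All per-direction flux intervals on the split network. For each ordered
# pair of feasible directions (a of i, b of j), min/max v_b over the split
# cone with v_a = 1, the partner of a pinned to 0 (so "direction a at unit
# rate" has no two-cycle component) and the partner of b pinned to 0 (so
# v_b is the net flux of j in that direction).
split_relations <- function(sn, cls, count_as = "fcf_split") {
  net <- sn$base
  u <- unblocked_indices(cls)
  rows <- list()
  flip_sign <- function(r, s) s * sign_of(cls, r)  # direction in original coords
  for (i in u) for (j in u) {
    if (i == j) next
    for (si in feasible_signs(cls, i)) for (sj in feasible_signs(cls, j)) {
      # feasible_signs() speaks normalized coordinates; map to original ones
      oi <- flip_sign(i, si); oj <- flip_sign(j, sj)
      ca <- direction_column(sn, i, oi); pa <- partner_column(sn, i, oi)
      cb <- direction_column(sn, j, oj); pb <- partner_column(sn, j, oj)
      pins <- stats::setNames(1, ca)
      if (!is.na(pa)) pins[as.character(pa)] <- 0
      if (!is.na(pb)) pins[as.character(pb)] <- 0
      sys <- cone_system(sn$split, seq_len(n_reactions(sn$split)), pins)
      lo <- lp_optimize(sys, cb, "min", count_as = count_as)
      hi <- lp_optimize(sys, cb, "max", count_as = count_as)
      feas <- lo$status != "infeasible"
      rows[[length(rows) + 1L]] <- tibble(
        i = i, j = j, si = si, sj = sj, feasible = feas,
        lo = if (feas) lo$objective else NA_real_,
        hi = if (!feas) NA_real_ else
          if (hi$status == "unbounded") Inf else hi$objective)
    }
  }
  if (length(rows) == 0L)
    return(tibble(i = integer(), j = integer(), si = numeric(),
                  sj = numeric(), feasible = logical(),
                  lo = numeric(), hi = numeric()))
  dplyr::bind_rows(rows)
}

# Fold the two per-direction-of-j intervals (forward and backward) into the
# interval of the net flux of j given direction si of i at unit rate.
net_interval_for <- function(rel, i, j, si, cls) {
  sub <- rel[rel$i == i & rel$j == j & rel$si == si, ]
  lo <- Inf; hi <- -Inf; any_feas <- FALSE
  for (r in seq_len(nrow(sub))) {
    if (!sub$feasible[[r]]) next
    any_feas <- TRUE
    sgn <- sub$sj[[r]] * sign_of(cls, j)   # original-coordinate sign of v_j
    a <- sub$lo[[r]] * sgn; b <- sub$hi[[r]] * sgn
    lo <- min(lo, a, b); hi <- max(hi, a, b)
  }
  if (!any_feas)
    stop("inconsistent split relations: no feasible direction of j under an unblocked direction of i",
         call. = FALSE)
  c(lo, hi)
}

#' Merge split-network coupling relations back to original reactions
#'
#' The classical algorithm computes relations between split (directional)
#' reactions; this post-processing folds them back: original `i` forces
#' original `j` iff, for every feasible direction of `i`, the attainable net
#' flux of `j` excludes zero; the pair is fully coupled iff those net-flux
#' intervals collapse to one consistent ratio.
#'
#' @param rel tibble of per-direction intervals from the split network (one
#'   row per ordered feasible direction pair, columns `i`, `j`, `si`, `sj`,
#'   `feasible`, `lo`, `hi`).
#' @param net the original [metabolic_network].
#' @param cls its `reaction_classification`.
#' @param tol tolerances, see [ffca_tol()].
#' @return a `coupling_matrix` over the original unblocked reactions.
#' @export
postprocess_split_relations <- function(rel, net, cls, tol = ffca_tol()) {
  pair_fun <- function(net, cls, i, j, tol) {
    probe <- function(from, to) {
      signs <- feasible_signs(cls, from)
      forced <- logical(length(signs)); ratio <- numeric(length(signs))
      for (k in seq_along(signs)) {
        iv <- net_interval_for(rel, from, to, signs[[k]], cls)
        forced[[k]] <- interval_forces(iv, tol$zero_tol)
        os <- signs[[k]] * sign_of(cls, from)  # original-coordinate pin value
        ratio[[k]] <- interval_ratio(iv, os, tol$eps_ratio)
      }
      k <- if (all(forced) && !anyNA(ratio) &&
               max(ratio) - min(ratio) <= tol$eps_ratio) mean(ratio) else NA_real_
      list(forces = all(forced), ratio = k)
    }
    fwd <- probe(i, j)
    if (fwd$forces && !is.na(fwd$ratio) && abs(fwd$ratio) > tol$zero_tol)
      return(new_coupling_relation("full", ratio = fwd$ratio))
    bwd <- probe(j, i)
    if (fwd$forces && bwd$forces) return(new_coupling_relation("partial"))
    if (fwd$forces) return(new_coupling_relation("dir_1_to_2"))
    if (bwd$forces) return(new_coupling_relation("dir_2_to_1"))
    new_coupling_relation("uncoupled")
  }
  couple_all(net, cls, tol, pair_fun)
}

#' Run one flux coupling analysis variant
#'
#' Executes the chosen method end-to-end (shared preprocessing, then the
#' pairwise phase) and reports LP-call counts. All variants produce the same
#' coupling matrix on any network; they differ in how many LPs the pairwise
#' phase needs: classical splitting (`fcf-split`) solves the most, the
#' no-splitting rule (`wfcf`) fewer, reversibility-type prunings (`wrfcf`)
#' fewer again, and the added Prev/Frev single-LP test (`wrpfcf`) the fewest.
#' `"ffca"` and `"oracle"` are accepted for convenience.
#'
#' @param net a [metabolic_network].
#' @param variant method name.
#' @param tol tolerances, see [ffca_tol()].
#' @return a `flux_coupling` object (see [flux_coupling()]).
#' @export
run_variant <- function(net,
                        variant = c("ffca", "wrpfcf", "wrfcf", "wfcf",
                                    "fcf-split", "oracle"),
                        tol = ffca_tol()) {
  variant <- match.arg(variant)
  stopifnot_network(net)
  if (variant == "ffca") return(flux_coupling(net, tol))
  if (variant == "oracle") return(oracle_coupling(net))
  lp_calls_reset()
  cls <- classify_reactions(net)
  if (variant == "fcf-split") {
    sn <- split_reversibles(net)
    rel <- split_relations(sn, cls)
    cm <- postprocess_split_relations(rel, net, cls, tol)
  } else {
    pair_fun <- function(net, cls, i, j, tol)
      fcf_pair_optimality(net, cls, i, j, tol, mode = variant)
    cm <- couple_all(net, cls, tol, pair_fun)
  }
  new_flux_coupling(net, cls, cm, method = variant, tol = tol)
}

# LP calls attributable to the pairwise phase (shared preprocessing excluded).
pairwise_lp_calls <- function(fc) {
  calls <- fc$lp_calls
  sum(calls[setdiff(names(calls), "preprocess")])
}
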