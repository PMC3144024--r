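# Brute-force ground truth on small networks.
#
# The generators of the steady-state flux cone are enumerated with the double
# description method on the split cone (every reversible reaction replaced by
# a forward and a backward irreversible one), in exact integer arithmetic:
# stoichiometric coefficients are rationalized and rows rescaled to integers,
# and every ray update is an integer combination reduced by its gcd. All
# activity and ratio judgments downstream are therefore tolerance-free, which
# is what makes this module an independent oracle rather than a second LP
# code path.

# -- exact helpers -------------------------------------------------------

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

gcd_vec <- function(v) {
  g <- 0
  for (x in v) { g <- gcd2(g, x); if (g == 1) break }
  g
}

# Best rational approximation p/q with q <= max_den (continued fractions).
rationalize_scalar <- function(x, max_den = 1e6) {
  if (x == round(x)) return(c(round(x), 1))
  sign <- if (x < 0) -1 else 1
  x <- abs(x)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    frac <- r - a
    if (frac < 1e-15) break
    r <- 1 / frac
  }
  c(sign * p1, q1)
}

# Rescale every row of S to integer entries (row scaling does not change the
# kernel or the cone).
integerize_rows <- function(S, max_den = 1e6) {
  out <- matrix(0, nrow(S), ncol(S))
  for (r in seq_len(nrow(S))) {
    pq <- vapply(S[r, ], rationalize_scalar, numeric(2), max_den = max_den)
    dens <- pq[2, ]
    l <- 1
    for (d in dens) l <- l / gcd2(l, d) * d   # lcm
    row <- pq[1, ] * (l / pq[2, ])
    g <- gcd_vec(row)
    if (g > 1) row <- row / g
    out[r, ] <- row
  }
  out
}

check_magnitude <- function(m) {
  if (length(m) > 0 && max(abs(m)) > 2^40)
    stop("oracle: integer entries grew beyond the exact range", call. = FALSE)
  m
}

# -- double description --------------------------------------------------

# Extreme rays of { x >= 0, A x = 0 } for an integer matrix A, as integer
# row vectors reduced by their gcd. Standard iterative DD with the
# combinatorial adjacency test on zero sets.
dd_rays <- function(A) {
  n <- ncol(A)
  rays <- diag(n)
  for (h in seq_len(nrow(A))) {
    d <- as.vector(rays %*% A[h, ])
    zero <- which(d == 0); pos <- which(d > 0); neg <- which(d < 0)
    if (length(pos) == 0L && length(neg) == 0L) next
    zsets <- rays == 0
    new_rays <- list()
    for (p in pos) for (q in neg) {
      common <- zsets[p, ] & zsets[q, ]
      adjacent <- TRUE
      for (r in seq_len(nrow(rays))) {
        if (r == p || r == q) next
        if (all(zsets[r, common])) { adjacent <- FALSE; break }
      }
      if (!adjacent) next
      w <- d[p] * rays[q, ] - d[q] * rays[p, ]
      g <- gcd_vec(w)
      if (g > 1) w <- w / g
      new_rays[[length(new_rays) + 1L]] <- w
    }
    rays <- rbind(rays[zero, , drop = FALSE],
                  if (length(new_rays)) do.call(rbind, new_rays))
    if (is.null(rays) || nrow(rays) == 0L)
      return(matrix(0, 0L, n))
    check_magnitude(rays)
  }
  rays
}

# Deterministic order: lexicographic over the integer entries.
sort_rows_lex <- function(m) {
  if (nrow(m) <= 1L) return(m)
  key <- do.call(order, c(lapply(seq_len(ncol(m)), function(j) m[, j])))
  m[key, , drop = FALSE]
}

# Maximal linearly independent subset of integer rows, by fraction-free
# forward elimination. Returns row indices.
independent_rows <- function(m) {
  if (nrow(m) == 0L) return(integer())
  work <- m
  chosen <- integer()
  pivots <- list()  # list of (row vector, pivot column)
  for (r in seq_len(nrow(m))) {
    row <- work[r, ]
    for (pv in pivots) {
      pr <- pv$row; pc <- pv$col
      if (row[pc] != 0) {
        row <- row * pr[pc] - pr * row[pc]
        g <- gcd_vec(row)
        if (g > 1) row <- row / g
      }
    }
    if (any(row != 0)) {
      chosen <- c(chosen, r)
      pivots[[length(pivots) + 1L]] <-
        list(row = row, col = which(row != 0)[[1L]])
    }
  }
  chosen
}

#' Enumerate the generators of the flux cone of a small network
#'
#' Splits every reversible reaction, enumerates the extreme rays of the split
#' cone by the double description method in exact integer arithmetic, folds
#' them back to original coordinates (backward-direction activity becomes a
#' negative entry) and discards the trivial two-cycle rays (forward plus
#' backward of one reversible reaction). The folded vectors are the
#' elementary flux modes of the network; those supported entirely on
#' reversible reactions span the lineality space, from which an exact basis
#' is extracted.
#'
#' @param net a [metabolic_network].
#' @param max_reactions refusal cap on the number of reactions (the
#'   enumeration is combinatorial; the oracle is for verification on small
#'   networks only).
#' @param max_den denominator cap used when rationalizing coefficients.
#' @return an object of class `generator_set`: `rays` (integer matrix, one
#'   generator per row, gcd-normalized and lexicographically sorted),
#'   `lin_basis` (basis of the lineality space), `efms` (all folded
#'   elementary modes, the union used for inference) and bookkeeping ids.
#' @examples
#' gen <- enumerate_generators(fixture_network("BRANCH"))
#' gen$rays
#' @export
enumerate_generators <- function(net, max_reactions = 16L, max_den = 1e6) {
  stopifnot_network(net)
  n <- n_reactions(net)
  if (n > max_reactions)
    stop(sprintf("oracle refuses networks with more than %d reactions (got %d)",
                 max_reactions, n), call. = FALSE)
  S <- integerize_rows(net$stoich, max_den)
  rev_idx <- which(net$reversible)
  S_split <- cbind(S, if (length(rev_idx)) -S[, rev_idx, drop = FALSE])
  raw <- dd_rays(S_split)

  # drop two-cycle artifacts and fold backward activity into negative entries
  efms <- matrix(0, 0L, n)
  for (r in seq_len(nrow(raw))) {
    ray <- raw[r, ]
    v <- ray[seq_len(n)]
    if (length(rev_idx))
      v[rev_idx] <- v[rev_idx] - ray[n + seq_along(rev_idx)]
    supp <- which(ray != 0)
    if (length(rev_idx)) {
      two_cycle <- length(supp) == 2L && all(v == 0)
      if (two_cycle) next
    }
    g <- gcd_vec(v)
    if (g > 1) v <- v / g
    efms <- rbind(efms, v)
  }
  efms <- sort_rows_lex(efms)
  dimnames(efms) <- NULL

  irr <- which(!net$reversible)
  in_lin <- if (nrow(efms) == 0L) logical() else
    apply(efms, 1L, function(v) all(v[irr] == 0))
  lin_efms <- efms[in_lin, , drop = FALSE]
  lin_basis <- lin_efms[independent_rows(lin_efms), , drop = FALSE]
  rays <- efms[!in_lin, , drop = FALSE]

  structure(list(rays = rays, lin_basis = lin_basis, efms = efms,
                 reaction_ids = net$reaction_ids,
                 reversible = net$reversible),
            class = "generator_set")
}

#' @export
print.generator_set <- function(x, ...) {
  cat(sprintf("<generator_set> %d rays, lineality dimension %d\n",
              nrow(x$rays), nrow(x$lin_basis)))
  invisible(x)
}

#' Derive classification and coupling relations from the generators
#'
#' Every steady-state flux vector is a conformal (cancellation-free) sum of
#' elementary modes, so activity questions reduce to co-appearance patterns:
#' a reaction is blocked iff zero in every mode; `i` is directionally coupled
#' to `j` iff every mode active in `i` is active in `j`; a mutually coupled
#' pair is fully coupled iff the flux ratio `v_j / v_i` is the same exact
#' fraction in every mode active in `i` (checked by integer
#' cross-multiplication, no tolerance). `Frev` membership is non-zeroness in
#' the lineality span; `Irev` is constancy of sign across all modes.
#'
#' @param gen a `generator_set` from [enumerate_generators()].
#' @return a list with `classification` (a `reaction_classification`) and
#'   `coupling` (a `coupling_matrix`).
#' @export
coupling_from_generators <- function(gen) {
  stopifnot(inherits(gen, "generator_set"))
  E <- gen$efms
  n <- length(gen$reaction_ids)
  active <- if (nrow(E)) E != 0 else matrix(FALSE, 0L, n)
  blocked <- which(colSums(active) == 0L)
  unblocked <- setdiff(seq_len(n), blocked)

  frev <- intersect(unblocked, which(colSums(gen$lin_basis != 0) > 0L))
  irev <- integer(); prev <- integer(); flipped <- integer()
  for (r in setdiff(unblocked, frev)) {
    vals <- E[active[, r], r]
    if (all(vals > 0)) {
      irev <- c(irev, r)
    } else if (all(vals < 0)) {
      irev <- c(irev, r)
      flipped <- c(flipped, r)
    } else {
      prev <- c(prev, r)
    }
  }
  cls <- new_reaction_classification(blocked, irev, prev, sort(frev), flipped,
                                     gen$reaction_ids)

  pairs <- if (length(unblocked) >= 2L) utils::combn(unblocked, 2L) else
    matrix(integer(), nrow = 2L)
  n_pairs <- ncol(pairs)
  rel <- character(n_pairs); ratio <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    fwd <- !any(active[, i] & !active[, j])   # i -> j
    bwd <- !any(active[, j] & !active[, i])   # j -> i
    if (fwd && bwd) {
      rows <- which(active[, i])
      r1 <- rows[[1L]]
      constant <- all(E[rows, j] * E[r1, i] == E[r1, j] * E[rows, i])
      if (constant) {
        rel[[p]] <- "full"; ratio[[p]] <- E[r1, j] / E[r1, i]
      } else {
        rel[[p]] <- "partial"; ratio[[p]] <- NA_real_
      }
    } else if (fwd) {
      rel[[p]] <- "dir_1_to_2"; ratio[[p]] <- NA_real_
    } else if (bwd) {
      rel[[p]] <- "dir_2_to_1"; ratio[[p]] <- NA_real_
    } else {
      rel[[p]] <- "uncoupled"; ratio[[p]] <- NA_real_
    }
  }
  cm <- new_coupling_matrix(
    tibble(
      i = as.integer(pairs[1L, ]), j = as.integer(pairs[2L, ]),
      rxn_i = gen$reaction_ids[pairs[1L, ]],
      rxn_j = gen$reaction_ids[pairs[2L, ]],
      relation = rel, ratio = ratio
    ),
    reactions = gen$reaction_ids[unblocked], idx = unblocked
  )
  list(classification = cls, coupling = cm)
}

#' Oracle flux coupling analysis (small networks)
#'
#' Convenience wrapper: [enumerate_generators()] followed by
#' [coupling_from_generators()], packaged like a [flux_coupling()] result.
#'
#' @inheritParams enumerate_generators
#' @return a `flux_coupling` object with `method = "oracle"` (its `lp_calls`
#'   are zero: no LP is involved).
#' @export
oracle_coupling <- function(net, max_reactions = 16L) {
  lp_calls_reset()
  res <- coupling_from_generators(enumerate_generators(net, max_reactions))
  new_flux_coupling(net, res$classification, res$coupling,
                    method = "oracle", tol = ffca_tol())
}

# Does the support of `v` decompose over the modes? True iff supp(v) equals
# the union of supports of modes that fit conformally inside v. Used as the
# soundness property linking LP witnesses to the generator description.
support_is_union_of_modes <- function(v, gen, zero_tol = 1e-8) {
  supp <- abs(v) > zero_tol
  sign_v <- sign(v) * supp
  covered <- rep(FALSE, length(v))
  for (r in seq_len(nrow(gen$efms))) {
    e <- gen$efms[r, ]
    inside <- all(e == 0 | (supp & sign(e) == sign_v))
    if (inside) covered <- covered | (e != 0)
  }
  identical(which(covered), which(supp))
}
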