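#' @importFrom tibble tibble as_tibble
NULL

# Relation vocabulary. "dir_1_to_2" means the pair's first (lower-index)
# reaction is directionally coupled to the second: i -> j.
relation_levels <- c("full", "partial", "dir_1_to_2", "dir_2_to_1", "uncoupled")
relation_codes <- c(full = 1L, partial = 2L, dir_1_to_2 = 3L,
                    dir_2_to_1 = 4L, uncoupled = 5L)

new_coupling_relation <- function(relation, ratio = NA_real_) {
  stopifnot(relation %in% relation_levels)
  if (relation == "full" && (is.na(ratio) || ratio == 0))
    stop("a fully coupled pair carries a non-zero ratio", call. = FALSE)
  if (relation != "full") ratio <- NA_real_
  list(relation = relation, ratio = ratio)
}

#' Construct a coupling matrix result
#'
#' Holds the pairwise coupling relation for every unordered pair of unblocked
#' reactions, in input reaction order. Pairs are stored as a tibble so the
#' result composes with dplyr verbs; `as_code_matrix()` renders the classic
#' square integer-code view (1 = fully, 2 = partially, 3 = row to column,
#' 4 = column to row, 5 = uncoupled; diagonal 1).
#'
#' @param pairs tibble with columns `i`, `j` (original column indices, `i < j`),
#'   `rxn_i`, `rxn_j`, `relation`, `ratio`.
#' @param reactions character ids of the unblocked reactions (input order).
#' @param idx integer original indices of `reactions`.
#' @keywords internal
new_coupling_matrix <- function(pairs, reactions, idx) {
  u <- length(reactions)
  if (nrow(pairs) != u * (u - 1L) / 2L)
    stop("coupling matrix must define every pair of distinct unblocked reactions",
         call. = FALSE)
  if (any(pairs$i >= pairs$j))
    stop("pairs must be stored with i < j", call. = FALSE)
  bad <- pairs$relation == "full" & (is.na(pairs$ratio) | pairs$ratio == 0)
  if (any(bad))
    stop("fully coupled pairs must carry a non-zero ratio", call. = FALSE)
  structure(list(pairs = pairs, reactions = reactions, idx = idx),
            class = "coupling_matrix")
}

#' Render a coupling matrix as integer codes
#'
#' @param cm a `coupling_matrix`.
#' @return integer matrix over unblocked reactions with codes 1-5 and a unit
#'   diagonal; dimnames are the reaction ids.
#' @export
as_code_matrix <- function(cm) {
  stopifnot(inherits(cm, "coupling_matrix"))
  u <- length(cm$reactions)
  out <- matrix(1L, u, u, dimnames = list(cm$reactions, cm$reactions))
  lookup <- stats::setNames(seq_along(cm$idx), cm$idx)  # original index -> position
  for (r in seq_len(nrow(cm$pairs))) {
    a <- lookup[[as.character(cm$pairs$i[r])]]
    b <- lookup[[as.character(cm$pairs$j[r])]]
    code <- relation_codes[[cm$pairs$relation[r]]]
    out[a, b] <- code
    # mirror: directional codes swap orientation across the diagonal
    out[b, a] <- switch(cm$pairs$relation[r],
                        dir_1_to_2 = 4L, dir_2_to_1 = 3L, code)
  }
  out
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cnt <- coupling_counts(x)
  cat(sprintf(
    "<coupling_matrix> %d unblocked reactions; pairs: %d fully, %d partially, %d directionally, %d uncoupled\n",
    length(x$reactions), cnt[["fully"]], cnt[["partially"]],
    cnt[["directionally"]], cnt[["uncoupled"]]))
  invisible(x)
}

# Pair counts in the conventional report layout.
coupling_counts <- function(cm) {
  rel <- cm$pairs$relation
  c(fully = sum(rel == "full"),
    partially = sum(rel == "partial"),
    directionally = sum(rel %in% c("dir_1_to_2", "dir_2_to_1")),
    uncoupled = sum(rel == "uncoupled"))
}

# Look up the relation of one unordered pair (original indices).
pair_relation <- function(cm, i, j) {
  if (i == j) return(list(relation = "full", ratio = 1))
  a <- min(i, j); b <- max(i, j)
  row <- cm$pairs[cm$pairs$i == a & cm$pairs$j == b, ]
  if (nrow(row) != 1L) stop("pair not found in coupling matrix", call. = FALSE)
  rel <- row$relation
  ratio <- row$ratio
  if (i > j) {  # caller asked in reversed orientation
    rel <- switch(rel, dir_1_to_2 = "dir_2_to_1", dir_2_to_1 = "dir_1_to_2", rel)
    if (!is.na(ratio)) ratio <- 1 / ratio
  }
  list(relation = rel, ratio = ratio)
}

#' Construct a reaction classification
#'
#' The partition of reactions into blocked (`Blk`) and the three
#' reversibility types of unblocked reactions: `Irev` (one direction only at
#' steady state), `Prev` (pseudo-irreversible: both directions feasible but
#' zero on the lineality space) and `Frev` (fully reversible: active somewhere
#' on the lineality space). `flipped` records reversible reactions whose
#' column was negated so that their feasible direction is forward.
#'
#' @keywords internal
new_reaction_classification <- function(blocked, irev, prev, frev, flipped,
                                        reaction_ids) {
  n <- length(reaction_ids)
  all_idx <- sort(c(blocked, irev, prev, frev))
  if (!identical(all_idx, seq_len(n)))
    stop("blocked/irev/prev/frev must partition the reaction set", call. = FALSE)
  if (length(intersect(flipped, c(blocked, prev, frev))) > 0L)
    stop("only Irev reactions can be sign-flipped", call. = FALSE)
  structure(list(blocked = as.integer(blocked), irev = as.integer(irev),
                 prev = as.integer(prev), frev = as.integer(frev),
                 flipped = as.integer(flipped), n = n,
                 reaction_ids = reaction_ids),
            class = "reaction_classification")
}

#' @export
print.reaction_classification <- function(x, ...) {
  cat(sprintf(
    "<reaction_classification> %d reactions: %d blocked, %d Irev, %d Prev, %d Frev (%d flipped)\n",
    x$n, length(x$blocked), length(x$irev), length(x$prev), length(x$frev),
    length(x$flipped)))
  invisible(x)
}

# Reversibility type of reaction `i` as a string, "blocked" included.
rt_of <- function(cls, i) {
  if (i %in% cls$blocked) return("blocked")
  if (i %in% cls$irev) return("irev")
  if (i %in% cls$prev) return("prev")
  "frev"
}

unblocked_indices <- function(cls) {
  setdiff(seq_len(cls$n), cls$blocked)
}

#' @rdname tidy.flux_coupling
#' @export
tidy.reaction_classification <- function(x, ...) {
  cls_vec <- character(x$n)
  cls_vec[x$blocked] <- "blocked"
  cls_vec[x$irev] <- "irev"
  cls_vec[x$prev] <- "prev"
  cls_vec[x$frev] <- "frev"
  tibble(index = seq_len(x$n), reaction = x$reaction_ids, class = cls_vec,
         flipped = seq_len(x$n) %in% x$flipped)
}
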