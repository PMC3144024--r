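#' Construct a metabolic network
#'
#' A metabolic network is the stoichiometric matrix \eqn{S} (rows = internal
#' metabolites, columns = reactions) together with a per-reaction
#' reversibility flag. It is the single source of truth for the steady-state
#' flux cone \eqn{C = \{v : S v = 0,\ v_i \ge 0\ \forall i \in Irr\}}; no flux
#' bounds are carried.
#'
#' @param stoich numeric matrix, `m` metabolites by `n` reactions; entry
#'   `stoich[i, j]` is the stoichiometric coefficient of metabolite `i` in
#'   reaction `j` (negative = consumed, positive = produced).
#' @param reversible logical vector of length `n`; `TRUE` marks a reversible
#'   reaction (member of `Rev`), `FALSE` an irreversible one (`Irr`).
#' @param metabolite_ids,reaction_ids unique character ids; default to the
#'   dimnames of `stoich` or generated `M1..`/`R1..` names.
#'
#' @return An object of class `metabolic_network` with fields `stoich`,
#'   `reversible`, `metabolite_ids`, `reaction_ids`.
#' @examples
#' net <- metabolic_network(
#'   stoich = cbind(c(1, 0), c(-1, 1), c(0, -1)),
#'   reversible = c(FALSE, FALSE, FALSE)
#' )
#' net
#' @export
metabolic_network <- function(stoich, reversible,
                              metabolite_ids = NULL, reaction_ids = NULL) {
  stoich <- as.matrix(stoich)
  storage.mode(stoich) <- "double"
  m <- nrow(stoich); n <- ncol(stoich)
  if (m < 1L || n < 1L)
    stop("a metabolic network needs at least 1 metabolite and 1 reaction",
         call. = FALSE)
  if (any(!is.finite(stoich)))
    stop("stoichiometric matrix contains non-finite entries", call. = FALSE)
  reversible <- as.logical(reversible)
  if (length(reversible) != n || anyNA(reversible))
    stop("`reversible` must be a logical vector with one entry per reaction",
         call. = FALSE)
  if (is.null(metabolite_ids)) metabolite_ids <- rownames(stoich)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  if (is.null(reaction_ids)) reaction_ids <- colnames(stoich)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  if (length(metabolite_ids) != m || anyDuplicated(metabolite_ids))
    stop("metabolite ids must be unique and match the number of rows",
         call. = FALSE)
  if (length(reaction_ids) != n || anyDuplicated(reaction_ids))
    stop("reaction ids must be unique and match the number of columns",
         call. = FALSE)
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  structure(
    list(stoich = stoich, reversible = reversible,
         metabolite_ids = metabolite_ids, reaction_ids = reaction_ids),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network> %d metabolites x %d reactions (%d reversible)\n",
    nrow(x$stoich), ncol(x$stoich), sum(x$reversible)))
  invisible(x)
}

#' @export
dim.metabolic_network <- function(x) dim(x$stoich)

n_reactions <- function(net) ncol(net$stoich)
n_metabolites <- function(net) nrow(net$stoich)

is_metabolic_network <- function(x) inherits(x, "metabolic_network")

stopifnot_network <- function(net) {
  if (!is_metabolic_network(net))
    stop("expected a `metabolic_network` object", call. = FALSE)
  invisible(net)
}

# Negate the columns listed in `flip` (1-based indices). Used to sign-normalize
# reversible reactions that can only run backwards at steady state.
flip_columns <- function(net, flip) {
  if (length(flip) == 0L) return(net)
  s <- net$stoich
  s[, flip] <- -s[, flip, drop = FALSE]
  metabolic_network(s, net$reversible, net$metabolite_ids, net$reaction_ids)
}
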