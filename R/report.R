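#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the results of a flux coupling analysis
#'
#' `tidy()` on a `flux_coupling` returns one row per unordered pair of
#' unblocked reactions with its relation and (for fully coupled pairs) the
#' flux ratio; on a `reaction_classification` it returns one row per
#' reaction with its class. `glance()` returns the one-row run summary in
#' the conventional layout (fully / partially / directionally coupled /
#' uncoupled pair counts), which always satisfies
#' `fully + partially + directionally + uncoupled == choose(n_unblocked, 2)`.
#'
#' @param x a `flux_coupling` (or `reaction_classification`) object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.flux_coupling <- function(x, ...) {
  x$coupling$pairs
}

#' @rdname tidy.flux_coupling
#' @export
glance.flux_coupling <- function(x, ...) {
  cnt <- coupling_counts(x$coupling)
  tibble(
    method = x$method,
    n_total = x$n_reactions,
    n_unblocked = length(x$coupling$reactions),
    n_blocked = length(x$classification$blocked),
    fully = cnt[["fully"]], partially = cnt[["partially"]],
    directionally = cnt[["directionally"]], uncoupled = cnt[["uncoupled"]],
    lp_calls = sum(x$lp_calls)
  )
}

#' Assemble a structured run report
#'
#' The machine-readable summary written next to the coupling table: pair
#' counts, reaction counts, per-case LP-call counts, the method and the
#' tolerances used. The count identity
#' `fully + partially + directionally + uncoupled == choose(n_unblocked, 2)`
#' is checked before the report is issued.
#'
#' @param fc a `flux_coupling` object.
#' @return a list ready for JSON serialization (schema version 1).
#' @export
run_report <- function(fc) {
  stopifnot(inherits(fc, "flux_coupling"))
  cnt <- coupling_counts(fc$coupling)
  u <- length(fc$coupling$reactions)
  if (sum(cnt) != u * (u - 1) / 2)
    stop("pair counts do not add up to choose(n_unblocked, 2); refusing to report",
         call. = FALSE)
  list(
    schema = 1L,
    method = fc$method,
    counts = as.list(cnt),
    n_unblocked = u,
    n_total = fc$n_reactions,
    lp_calls = as.list(fc$lp_calls),
    parameters = fc$tol
  )
}

#' Heat-map view of a coupling matrix
#'
#' Tiles the pairwise relation codes over unblocked reactions, in input
#' order.
#'
#' @param object a `flux_coupling` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flux_coupling <- function(object, ...) {
  codes <- as_code_matrix(object$coupling)
  ids <- rownames(codes)
  df <- tibble(
    row = factor(rep(ids, times = ncol(codes)), levels = ids),
    col = factor(rep(ids, each = nrow(codes)), levels = ids),
    relation = factor(
      names(relation_codes)[as.vector(codes)],
      levels = names(relation_codes),
      labels = c("fully", "partially", "row → col", "col → row",
                 "uncoupled"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$relation)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_discrete(limits = rev(ids)) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "coupling") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
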