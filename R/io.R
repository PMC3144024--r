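#' Read a metabolic network from the plain TSV format
#'
#' The format is: line 1 `#reactions<TAB>id1<TAB>...<TAB>idn`; line 2
#' `#reversible<TAB>id...` (a subset of the reaction ids; the tag alone means
#' none); every further non-empty line `metabolite_id<TAB>coef1<TAB>...<TAB>coefn`.
#'
#' @param path file path.
#' @return a [metabolic_network].
#' @export
read_tsv_network <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L)
    stop("TSV network needs a #reactions line, a #reversible line and at least one metabolite row",
         call. = FALSE)
  head1 <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (head1[[1L]] != "#reactions" || length(head1) < 2L)
    stop("line 1 must be `#reactions<TAB>id...`", call. = FALSE)
  rxn_ids <- head1[-1L]
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids in line 1", call. = FALSE)
  head2 <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  if (head2[[1L]] != "#reversible")
    stop("line 2 must be `#reversible<TAB>id...`", call. = FALSE)
  rev_ids <- head2[-1L]
  unknown <- setdiff(rev_ids, rxn_ids)
  if (length(unknown) > 0L)
    stop("unknown reaction ids in #reversible line: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  body <- lines[-(1:2)]
  n <- length(rxn_ids)
  met_ids <- character(length(body))
  stoich <- matrix(0, length(body), n)
  for (r in seq_along(body)) {
    cells <- strsplit(body[[r]], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != n + 1L)
      stop(sprintf("row %d has %d cells, expected %d (metabolite id + %d coefficients)",
                   r + 2L, length(cells), n + 1L, n), call. = FALSE)
    met_ids[[r]] <- cells[[1L]]
    vals <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[[1L]]
      stop(sprintf("non-numeric cell at row %d, column %d: '%s'",
                   r + 2L, bad + 1L, cells[[bad + 1L]]), call. = FALSE)
    }
    stoich[r, ] <- vals
  }
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite ids", call. = FALSE)
  metabolic_network(stoich, rxn_ids %in% rev_ids, met_ids, rxn_ids)
}

#' Write a metabolic network in the plain TSV format
#'
#' The inverse of [read_tsv_network()]; output is byte-deterministic and
#' round-trips stoichiometry and reversibility exactly.
#'
#' @param net a [metabolic_network].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv_network <- function(net, path) {
  stopifnot_network(net)
  fmt <- function(x) {
    out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
    sub("^(-?\\d+)\\.0*$", "\\1", out)
  }
  lines <- c(
    paste(c("#reactions", net$reaction_ids), collapse = "\t"),
    paste(c("#reversible", net$reaction_ids[net$reversible]), collapse = "\t"),
    vapply(seq_len(nrow(net$stoich)), function(r) {
      paste(c(net$metabolite_ids[[r]], fmt(net$stoich[r, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a metabolic network from an SBML file
#'
#' Reads the stoichiometric subset of SBML Level 2/3: species, reactions with
#' reactant/product `speciesReference` stoichiometries, and the per-reaction
#' `reversible` attribute. Flux-bound parameters are ignored: the analysis is
#' over the unbounded flux cone, and only the `reversible` flag defines `Rev`.
#' Species marked `boundaryCondition="true"`, or whose compartment is listed
#' in `external_compartments`, are treated as external and removed from the
#' balance rows, so exchange reactions appear as unbalanced columns.
#'
#' @param path file path to an SBML document.
#' @param external_compartments character vector of compartment ids whose
#'   species are external (default none beyond `boundaryCondition` flags).
#' @return a [metabolic_network]; columns in document order.
#' @export
read_sbml <- function(path, external_compartments = character()) {
  if (!file.exists(path))
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse SBML file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop(sprintf("'%s' has no <model> element", path), call. = FALSE)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  external <- (!is.na(sp_boundary) & tolower(sp_boundary) == "true") |
    (!is.na(sp_comp) & sp_comp %in% external_compartments)
  internal_ids <- sp_id[!external]

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L)
    stop(sprintf("'%s' contains no reactions", path), call. = FALSE)
  rxn_ids <- xml2::xml_attr(rx_nodes, "id")
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  # SBML Level 2 defaults `reversible` to true when absent.
  reversible <- is.na(rev_attr) | tolower(rev_attr) == "true"

  if (length(internal_ids) == 0L)
    stop(sprintf("'%s' has no internal (non-boundary) species", path),
         call. = FALSE)
  stoich <- matrix(0, length(internal_ids), length(rx_nodes),
                   dimnames = list(internal_ids, rxn_ids))
  add_refs <- function(j, refs, sign) {
    for (ref in refs) {
      sp <- xml2::xml_attr(ref, "species")
      coef <- xml2::xml_attr(ref, "stoichiometry")
      coef <- if (is.na(coef)) 1 else as.numeric(coef)
      if (is.na(coef))
        stop(sprintf("non-numeric stoichiometry on species '%s'", sp),
             call. = FALSE)
      if (sp %in% internal_ids)
        stoich[sp, j] <<- stoich[sp, j] + sign * coef
    }
  }
  for (j in seq_along(rx_nodes)) {
    add_refs(j, xml2::xml_find_all(rx_nodes[[j]],
                                   "./listOfReactants/speciesReference"), -1)
    add_refs(j, xml2::xml_find_all(rx_nodes[[j]],
                                   "./listOfProducts/speciesReference"), +1)
  }
  metabolic_network(stoich, reversible, internal_ids, rxn_ids)
}

#' Write a metabolic network as a minimal SBML Level 2 document
#'
#' Emits the stoichiometric subset only (species, reactions, reversibility),
#' sufficient for a lossless round trip through [read_sbml()].
#'
#' @param net a [metabolic_network].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  stopifnot_network(net)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4", level = "2",
    version = "4")
  model <- xml2::xml_add_child(doc, "model", id = "model")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (sid in net$metabolite_ids)
    xml2::xml_add_child(sps, "species", id = sid, compartment = "cell",
                        boundaryCondition = "false")
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  fmt <- function(v) sub("^(-?\\d+)\\.0*$", "\\1", sprintf("%.17g", v))
  for (j in seq_len(ncol(net$stoich))) {
    rx <- xml2::xml_add_child(rxs, "reaction", id = net$reaction_ids[[j]],
                              reversible = tolower(as.character(net$reversible[[j]])))
    col <- net$stoich[, j]
    if (any(col < 0)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in which(col < 0))
        xml2::xml_add_child(lr, "speciesReference",
                            species = net$metabolite_ids[[i]],
                            stoichiometry = fmt(-col[[i]]))
    }
    if (any(col > 0)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in which(col > 0))
        xml2::xml_add_child(lp, "speciesReference",
                            species = net$metabolite_ids[[i]],
                            stoichiometry = fmt(col[[i]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a coupling result as a TSV table
#'
#' Writes the square integer-code matrix over unblocked reactions (codes:
#' 1 fully, 2 partially, 3 row-to-column, 4 column-to-row, 5 uncoupled;
#' diagonal 1) followed by footer lines listing blocked reactions and the
#' Irev/Prev/Frev assignment. Output is byte-deterministic.
#'
#' @param couplings a `coupling_matrix` (from [flux_coupling()] etc.).
#' @param classification the matching `reaction_classification`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_coupling_table <- function(couplings, classification, path) {
  stopifnot(inherits(couplings, "coupling_matrix"),
            inherits(classification, "reaction_classification"))
  codes <- as_code_matrix(couplings)
  ids <- classification$reaction_ids
  lines <- c(
    paste(c("", couplings$reactions), collapse = "\t"),
    vapply(seq_len(nrow(codes)), function(r) {
      paste(c(couplings$reactions[[r]], codes[r, ]), collapse = "\t")
    }, character(1)),
    paste(c("#blocked", ids[classification$blocked]), collapse = "\t"),
    paste(c("#irev", ids[classification$irev]), collapse = "\t"),
    paste(c("#prev", ids[classification$prev]), collapse = "\t"),
    paste(c("#frev", ids[classification$frev]), collapse = "\t")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
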