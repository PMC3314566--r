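#' Construct an OntologyDag from child-to-parent edges
#'
#' @param edges two-column data.frame (child, parent) of subsumption edges,
#'   or a named list mapping each term to a character vector of parents.
#' @return A validated \linkS4class{OntologyDag}.
#' @export
OntologyDag <- function(edges) {
  if (is.data.frame(edges)) {
    child <- as.character(edges[[1L]])
    parent <- as.character(edges[[2L]])
    terms <- unique(c(child, parent))
    parents <- split(parent, factor(child, levels = terms))
    parents <- lapply(parents, unique)
  } else if (is.list(edges)) {
    parents <- lapply(edges, as.character)
    terms <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
    missing <- setdiff(terms, names(parents))
    parents[missing] <- list(character(0))
    parents <- parents[terms]
  } else stop("edges must be a data.frame or a named list")
  roots <- terms[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L)
    stop(sprintf("expected a single root, found %d: %s", length(roots),
                 paste(utils::head(roots, 5L), collapse = ", ")))
  new("OntologyDag", terms = terms, parents = parents, root = roots)
}

#' Read an ontology DAG from OBO or a child-parent TSV
#'
#' OBO input is parsed minimally: \code{[Term]} stanzas, their \code{id},
#' \code{namespace} and \code{is_a} lines; obsolete terms and all other
#' edge types are ignored. TSV input is a headerless two-column
#' child\code{<TAB>}parent edge list.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"obo"} or \code{"tsv"}.
#' @param namespace for OBO input, restrict to one namespace
#'   (e.g. \code{"biological_process"} or \code{"molecular_function"}).
#' @return An \linkS4class{OntologyDag}.
#' @export
readOntology <- function(path, format = c("auto", "obo", "tsv"),
                         namespace = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obo$", path, ignore.case = TRUE)) "obo" else "tsv"
  if (format == "tsv") {
    edges <- utils::read.table(path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)
    return(OntologyDag(edges[, 1:2]))
  }
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  ends <- c(starts[-1L] - 1L, length(lines))
  child <- character(0); parent <- character(0); solo <- character(0)
  for (s in seq_along(starts)) {
    block <- lines[starts[s]:ends[s]]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1L])
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", block))) next
    if (!is.null(namespace)) {
      ns <- sub("^namespace: *", "", grep("^namespace: ", block, value = TRUE))
      if (length(ns) && !ns[1L] %in% namespace) next
    }
    isa <- sub(" *!.*$", "", sub("^is_a: *", "",
                                 grep("^is_a: ", block, value = TRUE)))
    if (length(isa)) {
      child <- c(child, rep(id, length(isa)))
      parent <- c(parent, isa)
    } else solo <- c(solo, id)
  }
  # parents restricted to kept terms (cross-namespace is_a edges dropped)
  kept <- unique(c(child, parent, solo))
  keep <- parent %in% kept & child %in% kept
  OntologyDag(data.frame(child = child[keep], parent = parent[keep],
                         stringsAsFactors = FALSE))
}

# Ancestor sets (each term included in its own set), computed once per DAG
# call by dynamic programming over the parent lists.
.ancestorSets <- function(dag) {
  anc <- vector("list", length(dag@terms))
  names(anc) <- dag@terms
  fill <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    ps <- dag@parents[[t]]
    res <- unique(c(t, unlist(lapply(ps, fill), use.names = FALSE)))
    anc[[t]] <<- res
    res
  }
  for (t in dag@terms) fill(t)
  anc
}

#' Term ancestors (the term itself included)
#'
#' @param dag an \linkS4class{OntologyDag}.
#' @param term a term identifier.
#' @return Character vector of ancestors, per the true-path rule.
#' @export
termAncestors <- function(dag, term) {
  if (!term %in% dag@terms) stop(sprintf("unknown term '%s'", term))
  .ancestorSets(dag)[[term]]
}

#' Read a feature annotation table
#'
#' Two-column TSV (feature_id, term_id), multiple rows per feature;
#' duplicated (feature, term) pairs are collapsed.
#'
#' @param path file path.
#' @return Named list mapping each feature to its set of directly annotated
#'   terms.
#' @export
readAnnotations <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(split(tab[[2L]], tab[[1L]]), unique)
}

setMethod("show", "OntologyDag", function(object) {
  cat(sprintf("OntologyDag: %d terms, root '%s'\n",
              length(object@terms), object@root))
})
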