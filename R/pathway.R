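#' Construct a pathway entry
#'
#' One node of a KEGG pathway graph: a gene (possibly naming several genes),
#' a chemical compound, a group of other entries, or a link to another map.
#'
#' @param entry_id Identifier unique within the owning pathway.
#' @param kind One of `"gene"`, `"compound"`, `"group"`, `"map"`, `"other"`.
#' @param names Character vector of identifier strings; required non-empty
#'   for genes and compounds.
#' @param members Character vector of member entry ids; required non-empty
#'   for groups.
#' @return A `pathway_entry` list.
#' @export
pathway_entry <- function(entry_id, kind, names = character(), members = character()) {
  kind <- match.arg(kind, c("gene", "compound", "group", "map", "other"))
  if (kind %in% c("gene", "compound") && length(names) == 0L) {
    stop(sprintf("entry '%s' of kind '%s' must carry at least one name", entry_id, kind))
  }
  if (kind == "group" && length(members) == 0L) {
    stop(sprintf("group entry '%s' must have members", entry_id))
  }
  structure(
    list(
      entry_id = as.character(entry_id)[1L],
      kind = kind,
      names = as.character(names),
      members = as.character(members)
    ),
    class = "pathway_entry"
  )
}

#' Construct a pathway relation
#'
#' @param source,target Entry ids of the related entries.
#' @param rel_type One of `"PPrel"`, `"ECrel"`, `"GErel"`, `"PCrel"`,
#'   `"compound_compound"`, `"maplink"`, `"other"`.
#' @param via_compound Optional entry id of a mediating compound (the KGML
#'   `subtype name="compound"` value).
#' @return A `pathway_relation` list.
#' @export
pathway_relation <- function(source, target, rel_type = "PPrel", via_compound = NA_character_) {
  rel_type <- match.arg(
    rel_type,
    c("PPrel", "ECrel", "GErel", "PCrel", "compound_compound", "maplink", "other")
  )
  structure(
    list(
      source = as.character(source)[1L],
      target = as.character(target)[1L],
      rel_type = rel_type,
      via_compound = as.character(via_compound)[1L]
    ),
    class = "pathway_relation"
  )
}

#' Construct a pathway reaction
#'
#' @param reaction_id Opaque identifier (usually a KEGG reaction accession).
#' @param enzymes Entry ids of the gene entries catalyzing the reaction.
#' @param substrates,products Entry ids of compound entries; at least one of
#'   the two must be non-empty.
#' @return A `pathway_reaction` list.
#' @export
pathway_reaction <- function(reaction_id, enzymes, substrates = character(),
                             products = character()) {
  if (length(enzymes) == 0L) {
    stop(sprintf("reaction '%s' must name at least one enzyme entry", reaction_id))
  }
  if (length(substrates) == 0L && length(products) == 0L) {
    stop(sprintf("reaction '%s' must have a substrate or a product", reaction_id))
  }
  structure(
    list(
      reaction_id = as.character(reaction_id)[1L],
      enzymes = as.character(enzymes),
      substrates = as.character(substrates),
      products = as.character(products)
    ),
    class = "pathway_reaction"
  )
}

#' Construct a pathway
#'
#' In-memory model of the KGML subset used for conversion: typed entries,
#' typed relations and enzymatic reactions. Graphics and coordinates are not
#' modeled.
#'
#' @param pathway_id Pathway accession (e.g. `"sce00010"`).
#' @param organism Organism code (e.g. `"sce"`).
#' @param entries List of [pathway_entry()] objects.
#' @param relations List of [pathway_relation()] objects.
#' @param reactions List of [pathway_reaction()] objects.
#' @return A validated object of class `kegg_pathway`; entries are keyed by
#'   their `entry_id`.
#' @export
pathway <- function(pathway_id, organism = "", entries = list(),
                    relations = list(), reactions = list()) {
  ids <- vapply(entries, function(e) e$entry_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate entry ids in pathway '", pathway_id, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(entries) <- ids
  p <- structure(
    list(
      pathway_id = as.character(pathway_id)[1L],
      organism = as.character(organism)[1L],
      entries = entries,
      relations = relations,
      reactions = reactions
    ),
    class = "kegg_pathway"
  )
  validate_pathway(p)
  p
}

# Check that every id referenced by groups, relations and reactions resolves
# to an entry of the pathway; error lists all dangling ids at once.
validate_pathway <- function(p) {
  ids <- names(p$entries)
  referenced <- c(
    unlist(lapply(p$entries, function(e) e$members)),
    unlist(lapply(p$relations, function(r) {
      c(r$source, r$target, if (!is.na(r$via_compound)) r$via_compound)
    })),
    unlist(lapply(p$reactions, function(r) c(r$enzymes, r$substrates, r$products)))
  )
  dangling <- setdiff(unique(referenced), ids)
  if (length(dangling) > 0L) {
    stop(sprintf(
      "pathway '%s' references unresolved entry id(s): %s",
      p$pathway_id, paste(dangling, collapse = ", ")
    ))
  }
  invisible(p)
}

#' @export
print.kegg_pathway <- function(x, ...) {
  kinds <- vapply(x$entries, function(e) e$kind, character(1))
  cat(sprintf(
    "kegg_pathway '%s' (%s): %d entries (%d gene, %d compound, %d group), %d relations, %d reactions\n",
    x$pathway_id, x$organism, length(x$entries),
    sum(kinds == "gene"), sum(kinds == "compound"), sum(kinds == "group"),
    length(x$relations), length(x$reactions)
  ))
  invisible(x)
}

# kinds of all entries, named by entry id
entry_kinds <- function(p) {
  vapply(p$entries, function(e) e$kind, character(1))
}

# Canonical gene names carried by one entry; a group is expanded to the
# union of its gene members' names (one level is enough for KGML groups).
entry_gene_names <- function(p, entry_id) {
  e <- p$entries[[entry_id]]
  if (is.null(e)) return(character())
  if (e$kind == "gene") {
    canonical_gene_id(e$names)
  } else if (e$kind == "group") {
    unique(unlist(lapply(e$members, function(m) entry_gene_names(p, m))))
  } else {
    character()
  }
}

# entry ids of compounds reachable from an entry id (the id itself, or the
# compound members of a group)
entry_compound_ids <- function(p, entry_id) {
  e <- p$entries[[entry_id]]
  if (is.null(e)) return(character())
  if (e$kind == "compound") {
    e$entry_id
  } else if (e$kind == "group") {
    unique(unlist(lapply(e$members, function(m) entry_compound_ids(p, m))))
  } else {
    character()
  }
}
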