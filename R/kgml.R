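#' Read a KGML pathway file
#'
#' Parses the KGML dialect used by KEGG pathway exchange files: `entry`
#' elements (with `group` entries holding `component` children), `relation`
#' elements with optional `subtype name="compound"` carrying the mediating
#' compound's entry id, and `reaction` elements with `substrate`/`product`
#' children. Enzymes of a reaction are the gene entries whose `reaction`
#' attribute names it; when no entry does, the reaction's own `id` attribute
#' is taken as the catalyzing entry id (both layouts occur in the wild).
#' Entries of unrecognized type map to kind `"other"`; graphics are ignored.
#'
#' @param path KGML file.
#' @return A [pathway()] object.
#' @export
read_kgml <- function(path) {
  if (!file.exists(path)) stop("KGML file not found: ", path)
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop(sprintf("malformed XML in '%s': %s", path, conditionMessage(e)))
  )
  root <- xml2::xml_find_first(doc, "//pathway")
  if (inherits(root, "xml_missing")) {
    stop(sprintf("'%s' has no <pathway> element", path))
  }
  pid <- xml2::xml_attr(root, "name")
  if (is.na(pid)) pid <- ""
  pid <- sub("^path:", "", pid)
  org <- xml2::xml_attr(root, "org")
  if (is.na(org)) org <- ""

  entry_nodes <- xml2::xml_find_all(root, "./entry")
  reaction_attr <- character()
  entries <- lapply(entry_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    type <- xml2::xml_attr(nd, "type")
    kind <- switch(type,
      gene = "gene", ortholog = "gene", enzyme = "gene",
      compound = "compound", group = "group", map = "map",
      "other"
    )
    nm <- xml2::xml_attr(nd, "name")
    nm <- if (is.na(nm) || !nzchar(nm)) character() else strsplit(trimws(nm), "\\s+")[[1L]]
    members <- xml2::xml_attr(xml2::xml_find_all(nd, "./component"), "id")
    pathway_entry(id, kind, names = nm, members = members)
  })
  # reaction attribute of gene entries, for enzyme resolution
  rx_of_entry <- vapply(entry_nodes, function(nd) {
    a <- xml2::xml_attr(nd, "reaction")
    if (is.na(a)) "" else a
  }, character(1))
  names(rx_of_entry) <- vapply(entries, function(e) e$entry_id, character(1))

  relations <- lapply(xml2::xml_find_all(root, "./relation"), function(nd) {
    type <- xml2::xml_attr(nd, "type")
    rel_type <- if (is.na(type)) {
      "other"
    } else if (type %in% c("PPrel", "ECrel", "GErel", "PCrel", "maplink", "compound_compound")) {
      type
    } else {
      "other"
    }
    via <- xml2::xml_attr(
      xml2::xml_find_first(nd, "./subtype[@name='compound']"), "value"
    )
    pathway_relation(
      xml2::xml_attr(nd, "entry1"), xml2::xml_attr(nd, "entry2"),
      rel_type = rel_type,
      via_compound = if (length(via) == 0L || is.na(via)) NA_character_ else via
    )
  })

  reactions <- lapply(xml2::xml_find_all(root, "./reaction"), function(nd) {
    rname <- xml2::xml_attr(nd, "name")
    rid <- if (!is.na(rname) && nzchar(rname)) rname else xml2::xml_attr(nd, "id")
    enz <- names(rx_of_entry)[vapply(
      strsplit(rx_of_entry, "\\s+"),
      function(tok) !is.na(rname) && rname %in% tok, logical(1)
    )]
    if (length(enz) == 0L) enz <- xml2::xml_attr(nd, "id")
    pathway_reaction(
      rid,
      enzymes = enz,
      substrates = xml2::xml_attr(xml2::xml_find_all(nd, "./substrate"), "id"),
      products = xml2::xml_attr(xml2::xml_find_all(nd, "./product"), "id")
    )
  })

  pathway(pid, org, entries = entries, relations = relations, reactions = reactions)
}

#' Write a pathway as a KGML file
#'
#' Emits the modeled subset of KGML such that
#' `read_kgml(write_kgml(p, f))` equals `p` on entries, relations and
#' reactions. Enzyme membership of reactions is encoded through the
#' `reaction` attribute of the gene entries.
#'
#' @param pathway A [pathway()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(pathway, path) {
  stopifnot(inherits(pathway, "kegg_pathway"))
  validate_pathway(pathway)
  doc <- xml2::xml_new_root(
    "pathway",
    name = paste0("path:", pathway$pathway_id),
    org = pathway$organism,
    title = pathway$pathway_id
  )
  # reaction attribute per enzyme entry
  rx_attr <- list()
  for (r in pathway$reactions) {
    for (e in r$enzymes) rx_attr[[e]] <- c(rx_attr[[e]], r$reaction_id)
  }
  for (e in pathway$entries) {
    nd <- xml2::xml_add_child(
      doc, "entry",
      id = e$entry_id,
      name = paste(e$names, collapse = " "),
      type = if (e$kind == "other") "other" else e$kind
    )
    if (!is.null(rx_attr[[e$entry_id]])) {
      xml2::xml_set_attr(nd, "reaction", paste(rx_attr[[e$entry_id]], collapse = " "))
    }
    for (m in e$members) xml2::xml_add_child(nd, "component", id = m)
  }
  for (r in pathway$relations) {
    nd <- xml2::xml_add_child(
      doc, "relation",
      entry1 = r$source, entry2 = r$target, type = r$rel_type
    )
    if (!is.na(r$via_compound)) {
      xml2::xml_add_child(nd, "subtype", name = "compound", value = r$via_compound)
    }
  }
  for (r in pathway$reactions) {
    nd <- xml2::xml_add_child(
      doc, "reaction",
      id = r$enzymes[1L], name = r$reaction_id, type = "irreversible"
    )
    for (s in r$substrates) xml2::xml_add_child(nd, "substrate", id = s, name = s)
    for (p in r$products) xml2::xml_add_child(nd, "product", id = p, name = p)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Structural equality of two pathways
#'
#' Compares the modeled fields (entries, relations, reactions) after
#' normalizing order; ids, kinds, names, members, relation endpoints and
#' types, and reaction rosters must all agree.
#'
#' @param a,b [pathway()] objects.
#' @return Logical scalar.
#' @export
pathway_equal <- function(a, b) {
  norm_entries <- function(p) {
    es <- lapply(p$entries, function(e) {
      list(e$entry_id, e$kind, sort(e$names), sort(e$members))
    })
    es[order(names(p$entries))]
  }
  norm_relations <- function(p) {
    rs <- lapply(p$relations, function(r) {
      ends <- sort(c(r$source, r$target))
      list(ends[1L], ends[2L], r$rel_type, r$via_compound)
    })
    rs[order(vapply(rs, function(x) paste(unlist(x), collapse = "\r"), character(1)))]
  }
  norm_reactions <- function(p) {
    rs <- lapply(p$reactions, function(r) {
      list(r$reaction_id, sort(r$enzymes), sort(r$substrates), sort(r$products))
    })
    rs[order(vapply(rs, function(x) paste(unlist(x), collapse = "\r"), character(1)))]
  }
  identical(a$pathway_id, b$pathway_id) &&
    identical(a$organism, b$organism) &&
    identical(norm_entries(a), norm_entries(b)) &&
    identical(norm_relations(a), norm_relations(b)) &&
    identical(norm_reactions(a), norm_reactions(b))
}
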