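#' Convert a KEGG pathway into a gene association network
#'
#' Produces the highest-abstraction view of a pathway: an undirected simple
#' graph over canonical gene identifiers. The rules are:
#'
#' * every gene-gene relation (`PPrel`, `ECrel`, `GErel`) contributes an
#'   undirected edge between all gene names of its two entries (an `ECrel`
#'   mediated by a compound still yields the direct edge);
#' * compound nodes are removed; every gene adjacent to a compound — through
#'   a gene-compound relation (`PCrel` or any relation with a compound
#'   endpoint), through a relation's mediating `via_compound`, or through a
#'   reaction in which the compound is a substrate or product — is pairwise
#'   connected with all other genes adjacent to that compound;
#' * compounds linked to each other (compound-compound relations) are merged
#'   into a single bridging component first, so genes joined by a chain of
#'   compounds are also connected;
#' * group entries are expanded to their member genes before the rules above;
#' * `map` and `maplink` elements are ignored, all directions are dropped,
#'   multi-gene entries are expanded to one node per gene name.
#'
#' @param pathway A [pathway()] object.
#' @return A `gene_network` labelled with the pathway id. A pathway with no
#'   gene entries yields an empty network.
#' @export
convert_pathway <- function(pathway) {
  stopifnot(inherits(pathway, "kegg_pathway"))
  validate_pathway(pathway)
  kinds <- entry_kinds(pathway)
  gene_ids <- names(kinds)[kinds == "gene"]
  compound_ids <- names(kinds)[kinds == "compound"]
  all_genes <- unique(unlist(lapply(gene_ids, function(id) entry_gene_names(pathway, id))))
  if (length(all_genes) == 0L) {
    return(gene_network(genes = character(), label = pathway$pathway_id))
  }

  from <- character()
  to <- character()
  add_cross <- function(ga, gb) {
    if (length(ga) == 0L || length(gb) == 0L) return()
    pairs <- expand.grid(ga, gb, stringsAsFactors = FALSE)
    from <<- c(from, pairs[[1L]])
    to <<- c(to, pairs[[2L]])
  }
  add_clique <- function(gs) {
    gs <- unique(gs)
    if (length(gs) < 2L) return()
    pairs <- utils::combn(gs, 2L)
    from <<- c(from, pairs[1L, ])
    to <<- c(to, pairs[2L, ])
  }

  # gene neighborhood of each compound entry id
  cpd_genes <- stats::setNames(vector("list", length(compound_ids)), compound_ids)
  note_adjacent <- function(cpds, genes) {
    for (cp in cpds) cpd_genes[[cp]] <<- c(cpd_genes[[cp]], genes)
  }
  # compound-compound links, for merging into bridge components
  cc_from <- character()
  cc_to <- character()

  for (r in pathway$relations) {
    if (r$rel_type == "maplink") next
    src_g <- entry_gene_names(pathway, r$source)
    tgt_g <- entry_gene_names(pathway, r$target)
    src_c <- entry_compound_ids(pathway, r$source)
    tgt_c <- entry_compound_ids(pathway, r$target)
    if (r$rel_type %in% c("PPrel", "ECrel", "GErel")) {
      add_cross(src_g, tgt_g)
    }
    # any gene endpoint is adjacent to any compound endpoint
    note_adjacent(src_c, tgt_g)
    note_adjacent(tgt_c, src_g)
    # a mediating compound sees the genes of both endpoints
    if (!is.na(r$via_compound) && r$via_compound %in% compound_ids) {
      note_adjacent(r$via_compound, c(src_g, tgt_g))
    }
    if (length(src_c) > 0L && length(tgt_c) > 0L) {
      pairs <- expand.grid(src_c, tgt_c, stringsAsFactors = FALSE)
      cc_from <- c(cc_from, pairs[[1L]])
      cc_to <- c(cc_to, pairs[[2L]])
    }
  }

  for (rx in pathway$reactions) {
    enz_g <- unique(unlist(lapply(rx$enzymes, function(id) entry_gene_names(pathway, id))))
    note_adjacent(intersect(c(rx$substrates, rx$products), compound_ids), enz_g)
  }

  # merge linked compounds into bridge components, then clique each
  # component's gene neighborhood
  if (length(compound_ids) > 0L) {
    comp_of <- stats::setNames(seq_along(compound_ids), compound_ids)
    if (length(cc_from) > 0L) {
      cg <- igraph::graph_from_data_frame(
        data.frame(cc_from, cc_to, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = compound_ids, stringsAsFactors = FALSE)
      )
      comp_of <- igraph::components(cg)$membership[compound_ids]
    }
    for (comp in unique(comp_of)) {
      members <- compound_ids[comp_of == comp]
      add_clique(unlist(cpd_genes[members]))
    }
  }

  gene_network(cbind(from, to), genes = all_genes, label = pathway$pathway_id)
}

#' Relation-only gold standard of a pathway
#'
#' The network used by the classical precision baseline: undirected edges
#' from direct gene-gene relations (`PPrel`, `ECrel`, `GErel`) only — no
#' compound bridging, no reaction transfer edges. Group entries are still
#' expanded to their member genes.
#'
#' @param pathway A [pathway()] object.
#' @return A `gene_network` over the pathway's gene names.
#' @export
relation_gold_standard <- function(pathway) {
  stopifnot(inherits(pathway, "kegg_pathway"))
  validate_pathway(pathway)
  kinds <- entry_kinds(pathway)
  gene_ids <- names(kinds)[kinds == "gene"]
  all_genes <- unique(unlist(lapply(gene_ids, function(id) entry_gene_names(pathway, id))))
  from <- character()
  to <- character()
  for (r in pathway$relations) {
    if (!r$rel_type %in% c("PPrel", "ECrel", "GErel")) next
    src_g <- entry_gene_names(pathway, r$source)
    tgt_g <- entry_gene_names(pathway, r$target)
    if (length(src_g) == 0L || length(tgt_g) == 0L) next
    pairs <- expand.grid(src_g, tgt_g, stringsAsFactors = FALSE)
    from <- c(from, pairs[[1L]])
    to <- c(to, pairs[[2L]])
  }
  gene_network(cbind(from, to), genes = all_genes,
               label = paste0(pathway$pathway_id, ":relations"))
}
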