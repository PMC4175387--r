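#' Specification for a synthetic pathway fixture
#'
#' Parameters for [make_pathway()]. Compounds are consumed by three motif
#' classes in rotation: a two-gene bridge (one compound between two genes),
#' a multi-gene compound (three genes sharing one compound), and a
#' compound chain (two compounds linked to each other, each linked to one
#' gene) when at least two compounds remain. Each reaction motif emulates a
#' compound transfer: one producing and one consuming reaction sharing a
#' dedicated compound, so the two enzyme genes must end up connected.
#'
#' @param gene_count Number of gene entries (>= 2 when any relation is
#'   requested).
#' @param compound_count Compound entries available to the relation motifs.
#' @param relation_density Fraction of gene-entry pairs receiving a direct
#'   gene-gene relation, in (0, 1].
#' @param reaction_count Number of transfer-reaction motifs (each adds one
#'   extra compound entry of its own).
#' @param group_count Number of two-member group entries, each related to
#'   one further gene entry.
#' @param seed Integer seed; generation is fully reproducible from the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(gene_count = 30L, compound_count = 8L,
                         relation_density = 0.05, reaction_count = 2L,
                         group_count = 1L, seed = 1L) {
  stopifnot(
    gene_count >= 0L, compound_count >= 0L, reaction_count >= 0L, group_count >= 0L,
    relation_density > 0, relation_density <= 1
  )
  if ((relation_density > 0 && gene_count > 0L && gene_count < 2L) ||
      ((compound_count > 0L || reaction_count > 0L || group_count > 0L) && gene_count < 2L)) {
    stop("at least 2 gene entries are required for any relation motif")
  }
  structure(
    list(
      gene_count = as.integer(gene_count),
      compound_count = as.integer(compound_count),
      relation_density = relation_density,
      reaction_count = as.integer(reaction_count),
      group_count = as.integer(group_count),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a synthetic pathway with its expected converted network
#'
#' Builds a random pathway realizing the motif classes a metabolic pathway
#' exhibits (direct gene-gene relations, gene-compound-gene bridges,
#' multi-gene compounds, compound chains, transfer reactions, group
#' entries) and, alongside it, the gene association network the conversion
#' is expected to produce. The expectation is assembled constructively,
#' motif by motif, while the pathway is built — independently of
#' [convert_pathway()] — so the pair serves as a conversion oracle. Every
#' compound participates in exactly one motif, which keeps the constructive
#' expectation exact.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `pathway` (a [pathway()]) and `expected`
#'   (a `gene_network`).
#' @export
make_pathway <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, make_pathway_impl(spec))
}

make_pathway_impl <- function(spec) {
  org <- "syn"
  gene_names <- sprintf("G%03d", seq_len(spec$gene_count))
  entries <- list()
  relations <- list()
  reactions <- list()
  exp_from <- character()
  exp_to <- character()
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    as.character(next_id)
  }

  # gene entries; one entry carries two gene names when there is room,
  # exercising multi-gene entry expansion
  gene_ids <- character()
  i <- 1L
  while (i <= spec$gene_count) {
    id <- new_id()
    if (i == 3L && spec$gene_count >= 4L) {
      nm <- paste0(org, ":", tolower(gene_names[c(i, i + 1L)]))
      i <- i + 2L
    } else {
      nm <- paste0(org, ":", tolower(gene_names[i]))
      i <- i + 1L
    }
    entries[[id]] <- pathway_entry(id, "gene", names = nm)
    gene_ids <- c(gene_ids, id)
  }
  names_of <- lapply(gene_ids, function(id) canonical_gene_id(entries[[id]]$names))
  names(names_of) <- gene_ids
  add_expected_cross <- function(ga, gb) {
    grid <- expand.grid(ga, gb, stringsAsFactors = FALSE)
    exp_from <<- c(exp_from, grid[[1L]])
    exp_to <<- c(exp_to, grid[[2L]])
  }
  add_expected_clique <- function(gs) {
    gs <- unique(gs)
    if (length(gs) < 2L) return()
    pr <- utils::combn(gs, 2L)
    exp_from <<- c(exp_from, pr[1L, ])
    exp_to <<- c(exp_to, pr[2L, ])
  }

  # direct gene-gene relations at the requested density
  rel_types <- c("PPrel", "ECrel", "GErel")
  if (length(gene_ids) >= 2L) {
    pair_idx <- utils::combn(gene_ids, 2L)
    n_rel <- max(1L, round(spec$relation_density * ncol(pair_idx)))
    pick <- sample.int(ncol(pair_idx), min(n_rel, ncol(pair_idx)))
    for (j in seq_along(pick)) {
      a <- pair_idx[1L, pick[j]]
      b <- pair_idx[2L, pick[j]]
      relations[[length(relations) + 1L]] <-
        pathway_relation(a, b, rel_type = rel_types[(j - 1L) %% 3L + 1L])
      add_expected_cross(names_of[[a]], names_of[[b]])
    }
  }

  # a map entry, ignored by conversion
  map_id <- new_id()
  entries[[map_id]] <- pathway_entry(map_id, "map", names = "path:syn00999")

  # compound motifs: bridge, multi-gene, chain (in rotation)
  cpd_left <- spec$compound_count
  cpd_n <- 0L
  new_compound <- function() {
    cpd_n <<- cpd_n + 1L
    id <- new_id()
    entries[[id]] <<- pathway_entry(id, "compound", names = sprintf("cpd:C%05d", cpd_n))
    id
  }
  motif <- 0L
  while (cpd_left > 0L) {
    motif <- motif + 1L
    kind <- switch((motif - 1L) %% 3L + 1L, "bridge", "multi", "chain")
    if (kind == "chain" && cpd_left < 2L) kind <- "bridge"
    if (kind == "bridge") {
      c1 <- new_compound()
      gs <- sample(gene_ids, 2L)
      relations[[length(relations) + 1L]] <- pathway_relation(gs[1L], c1, rel_type = "PCrel")
      relations[[length(relations) + 1L]] <- pathway_relation(c1, gs[2L], rel_type = "PCrel")
      add_expected_clique(unlist(names_of[gs]))
      cpd_left <- cpd_left - 1L
    } else if (kind == "multi") {
      c1 <- new_compound()
      gs <- sample(gene_ids, min(3L, length(gene_ids)))
      for (g in gs) {
        relations[[length(relations) + 1L]] <- pathway_relation(g, c1, rel_type = "PCrel")
      }
      add_expected_clique(unlist(names_of[gs]))
      cpd_left <- cpd_left - 1L
    } else {
      c1 <- new_compound()
      c2 <- new_compound()
      gs <- sample(gene_ids, 2L)
      relations[[length(relations) + 1L]] <- pathway_relation(gs[1L], c1, rel_type = "PCrel")
      relations[[length(relations) + 1L]] <-
        pathway_relation(c1, c2, rel_type = "compound_compound")
      relations[[length(relations) + 1L]] <- pathway_relation(c2, gs[2L], rel_type = "PCrel")
      add_expected_clique(unlist(names_of[gs]))
      cpd_left <- cpd_left - 2L
    }
  }

  # transfer reactions: enzyme A produces a compound consumed by enzyme B
  for (k in seq_len(spec$reaction_count)) {
    c1 <- new_compound()
    gs <- sample(gene_ids, 2L)
    reactions[[length(reactions) + 1L]] <-
      pathway_reaction(sprintf("rn:R%05da", k), enzymes = gs[1L], products = c1)
    reactions[[length(reactions) + 1L]] <-
      pathway_reaction(sprintf("rn:R%05db", k), enzymes = gs[2L], substrates = c1)
    add_expected_clique(unlist(names_of[gs]))
  }

  # group entries: two gene members, related as a block to a third gene
  for (k in seq_len(spec$group_count)) {
    gs <- sample(gene_ids, min(3L, length(gene_ids)))
    gid <- new_id()
    entries[[gid]] <- pathway_entry(gid, "group", members = gs[1:2])
    if (length(gs) >= 3L) {
      relations[[length(relations) + 1L]] <- pathway_relation(gid, gs[3L], rel_type = "PPrel")
      add_expected_cross(unique(unlist(names_of[gs[1:2]])), names_of[[gs[3L]]])
    }
  }

  p <- pathway(
    sprintf("syn%05d", spec$seed %% 100000L), org,
    entries = entries, relations = relations, reactions = reactions
  )
  expected <- gene_network(cbind(exp_from, exp_to), genes = gene_names,
                           label = p$pathway_id)
  list(pathway = p, expected = expected)
}

#' Write a synthetic ROC benchmark bundle
#'
#' Generates a panel of synthetic pathways, a "real" input network built by
#' sampling a fraction of the pooled gold-standard edges and adding a
#' fraction of random non-edges (so the ground-truth separation is
#' controlled), and a set of null networks matched to the real network.
#' Everything is written to `dir` as KGML and TSV files plus a JSON
#' manifest recording all seeds and parameters.
#'
#' @param real_spec [fixture_spec()] shared by the pathways (pathway `i`
#'   uses `seed + i - 1`).
#' @param null_count Number of null networks (>= 1).
#' @param topology Null topology, `"pure_random"` or `"scale_free"`.
#' @param seed Integer master seed.
#' @param dir Output directory (created if missing).
#' @param n_pathways Number of pathways in the panel (default 3).
#' @param keep_fraction Fraction of gold-standard edges kept in the real
#'   network (default 0.8).
#' @param noise_fraction Fraction of random extra edges added to the real
#'   network (default 0.1).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_benchmark <- function(real_spec, null_count = 5L,
                           topology = c("pure_random", "scale_free"),
                           seed = 1L, dir = tempfile("benchmark"),
                           n_pathways = 3L, keep_fraction = 0.8,
                           noise_fraction = 0.1) {
  stopifnot(inherits(real_spec, "fixture_spec"), null_count >= 1L, n_pathways >= 1L)
  topology <- match.arg(topology)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create benchmark directory: ", dir)

  pw_files <- character(n_pathways)
  nets <- vector("list", n_pathways)
  pw_seeds <- real_spec$seed + seq_len(n_pathways) - 1L
  for (i in seq_len(n_pathways)) {
    sp <- real_spec
    sp$seed <- pw_seeds[i]
    fx <- make_pathway(sp)
    pw_files[i] <- file.path(dir, sprintf("pathway_%02d.xml", i))
    write_kgml(fx$pathway, pw_files[i])
    nets[[i]] <- convert_pathway(fx$pathway)
  }
  kgn <- build_kgn(nets)

  real <- withr::with_seed(as.integer(seed), {
    ne <- nrow(kgn$edges)
    keep <- sample.int(ne, max(1L, round(keep_fraction * ne)))
    extra_n <- round(noise_fraction * ne)
    kept <- kgn$edges[keep, , drop = FALSE]
    extra <- matrix(character(), ncol = 2L)
    kk <- paste(kept[, 1L], kept[, 2L], sep = "\r")
    while (nrow(extra) < extra_n) {
      cand <- sample_edge_set(kgn$genes, extra_n - nrow(extra))
      ck <- paste(pmin(cand[, 1L], cand[, 2L]), pmax(cand[, 1L], cand[, 2L]), sep = "\r")
      ok <- !(ck %in% c(kk, paste(extra[, 1L], extra[, 2L], sep = "\r"))) & !duplicated(ck)
      extra <- rbind(extra, cand[ok, , drop = FALSE])
    }
    gene_network(rbind(kept, extra[seq_len(extra_n), , drop = FALSE]),
                 genes = kgn$genes, label = "real")
  })
  real_file <- file.path(dir, "real.tsv")
  write_network(real, real_file, format = "tsv")

  null_seeds <- as.integer(seed) + 1000L + seq_len(null_count)
  null_files <- character(null_count)
  for (j in seq_len(null_count)) {
    nl <- random_network(real, topology = topology, seed = null_seeds[j])
    null_files[j] <- file.path(dir, sprintf("null_%03d.tsv", j))
    write_network(nl, null_files[j], format = "tsv")
  }

  manifest <- list(
    seed = as.integer(seed),
    topology = topology,
    n_pathways = as.integer(n_pathways),
    pathway_seeds = pw_seeds,
    pathway_spec = unclass(real_spec)[c("gene_count", "compound_count",
                                        "relation_density", "reaction_count",
                                        "group_count")],
    keep_fraction = keep_fraction,
    noise_fraction = noise_fraction,
    null_seeds = null_seeds,
    pathway_files = basename(pw_files),
    real_file = basename(real_file),
    null_files = basename(null_files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
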